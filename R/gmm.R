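# Growth mixture models: finite mixtures of Gaussian latent growth curves
# fitted by EM under a missing-at-random full-information likelihood.
#
# Model, class k (probability pi_k):
#   y_i = X beta_k + Z b_i + e_i,  b_i ~ N(0, Sigma_b),  e_i ~ N(0, sigma2 I)
# with X the polynomial time design over years 1..T (time centred at
# (T+1)/2), Z its first two columns (intercept + slope) when random effects
# are requested, and Sigma_b shared across classes. Marginally, within class
# k, y_i ~ MVN(X beta_k, Z Sigma_b Z' + sigma2 I); missing years are handled
# by row-subsetting that marginal (full-information ML under MAR).

#' Polynomial design matrices for growth curves
#'
#' Time is coded `1..T` and centred at `(T+1)/2` so that polynomial columns
#' are close to orthogonal (a pure conditioning choice; fitted mean curves are
#' unaffected).
#'
#' @param T Number of annual measurement occasions.
#' @param degree Polynomial degree of the mean curve (0 = intercept only,
#'   1 linear, 2 quadratic, 3 cubic).
#' @return List with `X` (`T x (degree+1)` fixed-effects matrix) and `Z`
#'   (`T x 2` random-effects matrix: intercept and centred slope).
#' @examples
#' design_matrices(10, 2)$X[1:3, ]
#' @export
design_matrices <- function(T, degree) {
  T <- as.integer(T)
  degree <- as.integer(degree)
  if (!degree %in% 0:3) stop("degree must be in 0..3")
  if (T < degree + 1L)
    stop(sprintf("T=%d is too small for degree %d (%d coefficients)",
                 T, degree, degree + 1L))
  tc <- seq_len(T) - (T + 1) / 2
  X <- outer(tc, 0:degree, `^`)
  colnames(X) <- c("intercept", "t", "t2", "t3")[seq_len(degree + 1L)]
  Zc <- outer(tc, 0:1, `^`)
  colnames(Zc) <- c("intercept", "t")
  list(X = X, Z = Zc)
}

#' Specify a growth mixture model
#'
#' @param K Number of latent trajectory classes (>= 1).
#' @param degree Polynomial degree of the class mean curves (1, 2 or 3;
#'   0 allowed for degenerate intercept-only fits).
#' @param random_effects `"none"` (latent class growth analysis) or
#'   `"intercept_slope"` (random intercept and slope, covariance shared
#'   across classes).
#' @param n_starts Number of random initialisations; the best short-run
#'   starts are iterated to convergence and the highest log-likelihood kept.
#' @param max_iter,tol EM stopping rule: stop when the increase in
#'   log-likelihood falls below `tol` (absolute) or after `max_iter`
#'   iterations.
#' @param seed Integer seed controlling initialisation.
#' @return An object of class `gmm_spec`.
#' @export
gmm_spec <- function(K, degree = 2L, random_effects = c("none",
                     "intercept_slope"), n_starts = 50L, max_iter = 1000L,
                     tol = 1e-6, seed = 1L) {
  random_effects <- match.arg(random_effects)
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (!as.integer(degree) %in% 0:3) stop("degree must be in 0..3")
  structure(list(K = K, degree = as.integer(degree),
                 random_effects = random_effects,
                 n_starts = as.integer(n_starts),
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed)),
            class = "gmm_spec")
}

#' @export
print.gmm_spec <- function(x, ...) {
  cat(sprintf("<gmm_spec> K=%d, degree=%d, random effects: %s\n",
              x$K, x$degree, x$random_effects))
  invisible(x)
}

#' Class-conditional log-likelihood of one subject
#'
#' Log multivariate-normal density of the observed entries of `y` under one
#' class's growth curve: mean `(X beta_k)[O]`, covariance
#' `(Z Sigma_b Z' + sigma2 I)[O, O]` with `O` the observed index set
#' (full-information handling of missing years).
#'
#' @param y Numeric length-`T` outcome vector, `NA` = missing year.
#' @param beta_k Class mean-curve coefficients (length `ncol(X)`).
#' @param Sigma_b 2x2 random-effect covariance, or `NULL` for no random
#'   effects.
#' @param sigma2 Residual variance (> 0).
#' @param X,Z Design matrices from [design_matrices()].
#' @param subject_id Optional label used in error messages.
#' @return Scalar log-density.
#' @export
class_conditional_loglik <- function(y, beta_k, Sigma_b, sigma2, X,
                                     Z = NULL, subject_id = "?") {
  obs <- which(!is.na(y))
  if (!length(obs)) stop("subject ", subject_id, ": no observed years")
  m <- X[obs, , drop = FALSE] %*% beta_k
  V <- diag(sigma2, length(obs))
  if (!is.null(Sigma_b)) {
    Zo <- Z[obs, , drop = FALSE]
    V <- V + Zo %*% Sigma_b %*% t(Zo)
  }
  R <- tryCatch(chol(V), error = function(e)
    stop("singular covariance for subject ", subject_id))
  r <- backsolve(R, y[obs] - m, transpose = TRUE)
  -0.5 * (length(obs) * log(2 * pi)) - sum(log(diag(R))) -
    0.5 * sum(r^2)
}

# ---- internal: pattern-grouped likelihood machinery ------------------------

# Missingness patterns let us factor the per-subject MVN computations: all
# subjects sharing an observed-year mask share one covariance Cholesky. The
# pattern cache also pre-extracts the per-pattern design and data blocks.
.patterns <- function(Y, X = NULL, Z = NULL) {
  obs <- !is.na(Y)
  key <- apply(obs, 1L, function(r) paste(as.integer(r), collapse = ""))
  lapply(split(seq_len(nrow(Y)), key), function(rows) {
    o <- which(obs[rows[1L], ])
    p <- list(rows = rows, obs = o, n = length(rows), m = length(o),
              Yp = Y[rows, o, drop = FALSE])
    if (!is.null(X)) p$Xo <- X[o, , drop = FALSE]
    if (!is.null(Z)) {
      p$Zo <- Z[o, , drop = FALSE]
      p$ZtZ <- crossprod(p$Zo)
    }
    p
  })
}

# Per-pattern covariance pieces for the current variance parameters.
.var_structs <- function(pats, Sigma_b, sigma2) {
  lapply(pats, function(p) {
    V <- diag(sigma2, p$m)
    if (!is.null(Sigma_b)) V <- V + p$Zo %*% Sigma_b %*% t(p$Zo)
    R <- chol(V)
    Vi <- chol2inv(R)
    C <- if (!is.null(Sigma_b))
      solve(solve(Sigma_b + diag(1e-10, 2)) + p$ZtZ / sigma2) else NULL
    list(Vi = Vi, logdet = 2 * sum(log(diag(R))), C = C)
  })
}

# n x K matrix of class-conditional log-likelihoods using cached structures.
.ll_matrix <- function(n, pats, vs, beta, X) {
  K <- ncol(beta)
  out <- matrix(NA_real_, n, K)
  M <- X %*% beta                      # T x K class mean curves
  for (j in seq_along(pats)) {
    p <- pats[[j]]
    v <- vs[[j]]
    cst <- -0.5 * (p$m * log(2 * pi) + v$logdet)
    for (k in seq_len(K)) {
      E <- p$Yp - rep(M[p$obs, k], each = p$n)
      out[p$rows, k] <- cst - 0.5 * rowSums((E %*% v$Vi) * E)
    }
  }
  out
}

# log-sum-exp across classes with prior weights; returns list(loglik, post).
.posteriors <- function(ll, pi) {
  lw <- ll + rep(log(pi), each = nrow(ll))
  mx <- lw[, 1L]
  if (ncol(lw) > 1L)
    for (k in 2:ncol(lw)) mx <- pmax(mx, lw[, k])
  w <- exp(lw - mx)
  s <- rowSums(w)
  list(loglik = sum(mx + log(s)), post = w / s)
}

# Posterior-weighted GLS update of all class curves (cached Vi).
.update_beta <- function(pats, vs, post, X) {
  K <- ncol(post)
  p <- ncol(X)
  A <- array(0, c(p, p, K))
  b <- matrix(0, p, K)
  for (j in seq_along(pats)) {
    pt <- pats[[j]]
    Vi <- vs[[j]]$Vi
    XtVi <- crossprod(pt$Xo, Vi)
    XtViX <- XtVi %*% pt$Xo
    Pp <- post[pt$rows, , drop = FALSE]
    XtViYt <- XtVi %*% t(pt$Yp)                  # p x n_p
    for (k in seq_len(K)) {
      A[, , k] <- A[, , k] + sum(Pp[, k]) * XtViX
      b[, k] <- b[, k] + XtViYt %*% Pp[, k]
    }
  }
  beta <- matrix(0, p, K)
  for (k in seq_len(K)) beta[, k] <- solve(A[, , k], b[, k])
  rownames(beta) <- colnames(X)
  beta
}

# Closed-form variance updates treating the random effects as latent data:
# E-step moments of b_i at (new beta, old variances), then M-step for
# (Sigma_b, sigma2).
.update_variances_re <- function(pats, vs, post, beta, sigma2, X) {
  K <- ncol(post)
  M <- X %*% beta
  Sb_new <- matrix(0, 2, 2)
  rss <- 0
  m_tot <- 0
  n <- 0
  for (j in seq_along(pats)) {
    pt <- pats[[j]]
    C <- vs[[j]]$C
    Pp <- post[pt$rows, , drop = FALSE]
    m_tot <- m_tot + pt$m * pt$n
    n <- n + pt$n
    trZZC <- sum(pt$ZtZ * C)
    ZCt <- pt$Zo %*% C / sigma2                  # |o| x 2
    for (k in seq_len(K)) {
      E <- pt$Yp - rep(M[pt$obs, k], each = pt$n)
      Bhat <- E %*% ZCt                          # n_p x 2 posterior means
      wk <- Pp[, k]
      sw <- sum(wk)
      Sb_new <- Sb_new + crossprod(Bhat * sqrt(wk)) + sw * C
      R2 <- E - tcrossprod(Bhat, pt$Zo)
      rss <- rss + sum(wk * rowSums(R2^2)) + sw * trZZC
    }
  }
  list(Sigma_b = Sb_new / n, sigma2 = max(rss / m_tot, 1e-8))
}

# Residual variance update without random effects.
.update_sigma2_nore <- function(pats, post, beta, X) {
  M <- X %*% beta
  rss <- 0
  m_tot <- 0
  for (pt in pats) {
    Pp <- post[pt$rows, , drop = FALSE]
    m_tot <- m_tot + pt$m * pt$n
    for (k in seq_len(ncol(post))) {
      E <- pt$Yp - rep(M[pt$obs, k], each = pt$n)
      rss <- rss + sum(Pp[, k] * rowSums(E^2))
    }
  }
  max(rss / m_tot, 1e-8)
}

# Perturbed k-means initial responsibilities.
.init_responsibilities <- function(Y, K, start_index) {
  n <- nrow(Y)
  Yi <- Y
  rm <- rowMeans(Y, na.rm = TRUE)
  for (j in seq_len(ncol(Y))) {
    miss <- is.na(Yi[, j])
    Yi[miss, j] <- rm[miss]
  }
  assign <- if (K == 1L) rep(1L, n) else {
    km <- tryCatch(stats::kmeans(Yi, centers = K, nstart = 1L),
                   error = function(e) NULL)
    if (is.null(km)) sample.int(K, n, replace = TRUE) else km$cluster
  }
  post <- matrix(0.1 / max(K - 1, 1), n, K)
  post[cbind(seq_len(n), assign)] <- 0.9
  if (K == 1L) post[] <- 1
  if (start_index > 1L && K > 1L) {
    # perturb: reassign a random fifth of subjects to random classes
    flip <- sample.int(n, max(1L, round(0.2 * n)))
    post[flip, ] <- 0.1 / (K - 1)
    post[cbind(flip, sample.int(K, length(flip), replace = TRUE))] <- 0.9
  }
  post / rowSums(post)
}

# Pack/unpack the full parameter state on an unconstrained scale (softmax
# logits for pi, log-Cholesky for Sigma_b, log sigma2, raw beta). Used both
# by the accelerated EM and by the sandwich-variance code.
.pack_state <- function(pi, th) {
  v <- log(pmax(pi, 1e-300))
  v <- v - v[length(v)]
  out <- c(v[-length(v)], as.vector(th$beta))
  if (!is.null(th$Sigma_b)) {
    L <- t(suppressWarnings(chol(th$Sigma_b + diag(1e-12, 2))))
    out <- c(out, log(L[1, 1]), L[2, 1], log(L[2, 2]))
  }
  c(out, log(th$sigma2))
}

.unpack_state <- function(v, K, p, re) {
  eta <- if (K > 1L) v[seq_len(K - 1L)] else numeric(0)
  pi <- exp(c(eta, 0) - max(c(eta, 0)))
  pi <- pi / sum(pi)
  i <- K - 1L
  beta <- matrix(v[i + seq_len(p * K)], p, K)
  i <- i + p * K
  Sigma_b <- NULL
  if (re) {
    L <- matrix(c(exp(v[i + 1L]), v[i + 2L], 0, exp(v[i + 3L])), 2, 2)
    Sigma_b <- L %*% t(L)
    i <- i + 3L
  }
  list(pi = pi, beta = beta, Sigma_b = Sigma_b, sigma2 = exp(v[i + 1L]))
}

# Run EM from given responsibilities; returns fit pieces or degenerate flag.
# Each EM map: refresh covariance structures, E-step over classes, closed
# form pi, GLS class curves, then (for random-effect models) closed-form
# variance updates with the random effects as latent data. Every piece
# increases the EM minorant, so the observed log-likelihood is monotone.
# After a short plain phase, SQUAREM-style extrapolation (on the
# unconstrained parameter scale, accepted only when it does not decrease the
# log-likelihood) accelerates the slow linear tail typical of near-boundary
# variance components.
.em_run <- function(Y, pats, post, X, Z, re, max_iter, tol,
                    theta = NULL) {
  n <- nrow(Y)
  K <- ncol(post)
  p <- ncol(X)
  pi <- colMeans(post)
  th <- theta
  if (is.null(th)) {
    s2 <- stats::var(as.vector(Y), na.rm = TRUE)
    if (re) {
      vs0 <- .var_structs(pats, diag(c(1, 0.01)), max(s2 / 2, 1e-4))
      th <- list(beta = .update_beta(pats, vs0, post, X),
                 Sigma_b = diag(c(1, 0.01)), sigma2 = max(s2 / 2, 1e-4))
    } else {
      vs0 <- .var_structs(pats, NULL, 1)
      beta0 <- .update_beta(pats, vs0, post, X)
      th <- list(beta = beta0, Sigma_b = NULL,
                 sigma2 = .update_sigma2_nore(pats, post, beta0, X))
    }
  }
  degen <- FALSE
  # one EM map on the packed state; returns loglik AT v and the mapped state
  em_map <- function(v) {
    st <- .unpack_state(v, K, p, re)
    vs <- .var_structs(pats, st$Sigma_b, st$sigma2)
    ll <- .ll_matrix(n, pats, vs, st$beta, X)
    es <- .posteriors(ll, st$pi)
    pi_new <- colMeans(es$post)
    if (any(pi_new < 1 / n)) {
      degen <<- TRUE
      return(list(loglik = es$loglik, v = v))
    }
    beta_new <- .update_beta(pats, vs, es$post, X)
    th_new <- if (re) {
      up <- .update_variances_re(pats, vs, es$post, beta_new, st$sigma2, X)
      list(beta = beta_new, Sigma_b = up$Sigma_b, sigma2 = up$sigma2)
    } else {
      list(beta = beta_new, Sigma_b = NULL,
           sigma2 = .update_sigma2_nore(pats, es$post, beta_new, X))
    }
    list(loglik = es$loglik, v = .pack_state(pi_new, th_new))
  }
  v <- .pack_state(pi, th)
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  ll_prev <- -Inf
  alpha_max <- 4
  while (it < max_iter) {
    m1 <- em_map(v)
    it <- it + 1L
    trace <- c(trace, m1$loglik)
    if (degen) return(list(degenerate = TRUE))
    if (abs(m1$loglik - ll_prev) < tol && it > 1L) {
      converged <- TRUE
      v <- m1$v
      break
    }
    ll_prev <- m1$loglik
    if (it <= 5L || it + 2L > max_iter) {
      v <- m1$v
      next
    }
    m2 <- em_map(m1$v)
    it <- it + 1L
    trace <- c(trace, m2$loglik)
    if (degen) return(list(degenerate = TRUE))
    if (abs(m2$loglik - ll_prev) < tol) {
      converged <- TRUE
      v <- m2$v
      break
    }
    ll_prev <- m2$loglik
    r <- m1$v - v
    vv <- (m2$v - m1$v) - r
    sv <- sqrt(sum(vv^2))
    if (sv < 1e-12) {
      v <- m2$v
      next
    }
    alpha <- max(-alpha_max, min(-sqrt(sum(r^2)) / sv, -1))
    v_try <- v - 2 * alpha * r + alpha^2 * vv
    if (all(is.finite(v_try))) {
      mt <- em_map(v_try)
      it <- it + 1L
      if (!degen && is.finite(mt$loglik) && mt$loglik >= ll_prev) {
        trace <- c(trace, mt$loglik)
        ll_prev <- mt$loglik
        v <- mt$v
        if (alpha <= -alpha_max + 1e-9) alpha_max <- 2 * alpha_max
        next
      }
      degen <- FALSE                      # rejected extrapolation: fall back
      alpha_max <- max(4, alpha_max / 2)
    }
    v <- m2$v
  }
  st <- .unpack_state(v, K, p, re)
  if (any(!is.finite(unlist(st)))) return(list(degenerate = TRUE))
  list(degenerate = FALSE, pi = st$pi,
       theta = list(beta = st$beta, Sigma_b = st$Sigma_b,
                    sigma2 = st$sigma2),
       loglik = if (length(trace)) trace[length(trace)] else -Inf,
       converged = converged, trace = trace, n_iter = it)
}

#' Fit a growth mixture model by EM
#'
#' Multi-start EM for a `K`-class mixture of Gaussian latent growth curves.
#' The E-step computes posterior class probabilities from the class marginal
#' multivariate-normal likelihoods (missing years handled by full-information
#' row subsetting); the M-step updates mixing proportions in closed form,
#' class curves by posterior-weighted generalised least squares and, for
#' random-effect models, the shared random-effect covariance and residual
#' variance by closed-form ECM cycles that treat the subject-level effects as
#' additional latent data.
#'
#' Starts follow a two-phase scheme: all `n_starts` perturbed k-means
#' initialisations are run for a short burn-in, the most promising are
#' iterated to convergence, and the best log-likelihood is kept. Starts in
#' which a class collapses below 1/n are discarded and re-drawn. Classes are
#' reordered by descending mixing proportion.
#'
#' @param Y `n x T` outcome matrix (rows = subjects, `NA` = missing year), or
#'   a `psytraj_cohort` (aggregated via [annual_matrix()]).
#' @param spec A [gmm_spec()].
#' @param T Horizon used when `Y` is a cohort.
#' @return An object of class `gmm_fit`: mixing proportions `pi`, class curve
#'   coefficients `beta` (one column per class), `Sigma_b`, `sigma2`,
#'   `loglik`, `posteriors`, `bic`, `entropy`, `n_params`, `converged`,
#'   `n_used`, plus the spec and design matrices.
#' @export
fit_gmm <- function(Y, spec, T = 10L) {
  stopifnot(inherits(spec, "gmm_spec"))
  if (inherits(Y, "psytraj_cohort")) Y <- annual_matrix(Y, T)
  Y <- as.matrix(Y)
  all_na <- rowSums(!is.na(Y)) == 0L
  if (any(all_na)) {
    warning(sum(all_na), " subject(s) with no observed years dropped")
    Y <- Y[!all_na, , drop = FALSE]
  }
  n <- nrow(Y)
  Tn <- ncol(Y)
  dm <- design_matrices(Tn, spec$degree)
  re <- spec$random_effects == "intercept_slope"
  Z <- if (re) dm$Z else NULL
  K <- spec$K
  n_params <- (K - 1L) + K * (spec$degree + 1L) + 1L + if (re) 3L else 0L
  if (n <= n_params)
    warning(sprintf("n=%d subjects for %d parameters: estimates unstable",
                    n, n_params))
  pats <- .patterns(Y, dm$X, dm$Z)

  burn_iter <- 12L
  n_keep <- max(1L, min(5L, spec$n_starts))
  runs <- vector("list", spec$n_starts)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  for (s in seq_len(spec$n_starts)) {
    set.seed(spec$seed + 7919L * (s - 1L))
    post0 <- .init_responsibilities(Y, K, s)
    r <- .em_run(Y, pats, post0, dm$X, Z, re, burn_iter, spec$tol)
    tries <- 0L
    while (isTRUE(r$degenerate) && tries < 3L) {
      tries <- tries + 1L
      post0 <- .init_responsibilities(Y, K, s + 1000L * tries)
      r <- .em_run(Y, pats, post0, dm$X, Z, re, burn_iter, spec$tol)
    }
    r$start <- s
    runs[[s]] <- r
  }
  ok <- !vapply(runs, function(r) isTRUE(r$degenerate), logical(1))
  if (!any(ok))
    stop("all EM starts degenerated (a class emptied); ",
         "consider fewer classes")
  runs <- runs[ok]
  lls <- vapply(runs, `[[`, numeric(1), "loglik")
  keep <- order(lls, decreasing = TRUE)[seq_len(min(n_keep, length(runs)))]
  best <- NULL
  for (i in keep) {
    r0 <- runs[[i]]
    vs0 <- .var_structs(pats, r0$theta$Sigma_b, r0$theta$sigma2)
    ll0 <- .ll_matrix(n, pats, vs0, r0$theta$beta, dm$X)
    post0 <- .posteriors(ll0, r0$pi)$post
    r <- .em_run(Y, pats, post0, dm$X, Z, re, spec$max_iter, spec$tol,
                 theta = r0$theta)
    if (isTRUE(r$degenerate)) next
    r$start <- r0$start
    if (is.null(best) || r$loglik > best$loglik ||
        (r$loglik == best$loglik && r$start < best$start)) best <- r
  }
  if (is.null(best)) stop("no EM start converged; diagnostics: ",
                          length(runs), " starts survived burn-in")
  if (!best$converged)
    warning("EM reached max_iter without meeting tol; result may be ",
            "short of the optimum")

  ord <- order(best$pi, decreasing = TRUE)
  pi <- best$pi[ord]
  beta <- best$theta$beta[, ord, drop = FALSE]
  rownames(beta) <- colnames(dm$X)
  colnames(beta) <- paste0("class_", seq_len(K))
  vs <- .var_structs(pats, best$theta$Sigma_b, best$theta$sigma2)
  ll <- .ll_matrix(n, pats, vs, beta, dm$X)
  es <- .posteriors(ll, pi)
  post <- es$post
  rownames(post) <- rownames(Y)
  colnames(post) <- colnames(beta)
  fit <- structure(list(
    pi = stats::setNames(pi, colnames(beta)),
    beta = beta,
    Sigma_b = best$theta$Sigma_b,
    sigma2 = best$theta$sigma2,
    loglik = es$loglik,
    posteriors = post,
    n_params = n_params,
    converged = best$converged,
    n_used = n,
    n_iter = best$n_iter,
    loglik_trace = best$trace,
    spec = spec, X = dm$X, Z = Z, T = Tn,
    Y = Y),
    class = "gmm_fit")
  fit$bic <- compute_bic(fit$loglik, fit$n_params, n)
  fit$entropy <- compute_entropy(post)
  fit
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf(
    "<gmm_fit> K=%d, degree=%d, RE=%s | logLik %.3f, BIC %.2f, entropy %s\n",
    x$spec$K, x$spec$degree, x$spec$random_effects, x$loglik, x$bic,
    ifelse(is.na(x$entropy), "NA", sprintf("%.3f", x$entropy))))
  cat("  class shares:", paste(sprintf("%.1f%%", 100 * x$pi),
                               collapse = " "), "\n")
  invisible(x)
}

#' Fitted class mean curves on the months-per-year scale
#'
#' @param object A `gmm_fit`.
#' @param ... Unused.
#' @return `T x K` matrix of fitted annual means.
#' @export
fitted.gmm_fit <- function(object, ...) {
  M <- object$X %*% object$beta
  rownames(M) <- paste0("year_", seq_len(nrow(M)))
  M
}

#' Plot fitted class trajectories
#'
#' @param x A `gmm_fit`.
#' @param labels Optional class label vector (e.g. from [label_classes()]).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.gmm_fit <- function(x, labels = NULL, ...) {
  M <- fitted(x)
  graphics::matplot(seq_len(nrow(M)), M, type = "b", pch = 16, lty = 1,
                    xlab = "Year of follow-up",
                    ylab = "Months psychotic per year", ylim = c(0, 12), ...)
  lab <- if (is.null(labels)) sprintf("class %d (%.1f%%)",
                                      seq_along(x$pi), 100 * x$pi)
         else sprintf("%s (%.1f%%)", labels, 100 * x$pi)
  graphics::legend("topleft", legend = lab, col = seq_along(x$pi),
                   lty = 1, pch = 16, bty = "n", cex = 0.8)
  invisible(x)
}

# ---- fit summaries ---------------------------------------------------------

#' Bayesian Information Criterion
#'
#' `BIC = -2 logLik + p log(n)` with `n` the number of subjects.
#'
#' @param loglik Maximised log-likelihood.
#' @param n_params Number of free parameters `p`.
#' @param n Number of subjects.
#' @return Scalar BIC (lower = better).
#' @export
compute_bic <- function(loglik, n_params, n) {
  if (n < 1) stop("n must be >= 1")
  -2 * loglik + n_params * log(n)
}

#' Entropy of a posterior classification
#'
#' Normalised classification sharpness,
#' `E = 1 - sum_i sum_k (-p_ik log p_ik) / (n log K)`, ranging from 0
#' (posteriors uniform, classes indistinguishable) to 1 (every subject
#' assigned with certainty). Undefined for one class (`NA`).
#'
#' @param posteriors `n x K` matrix with rows summing to 1.
#' @return Scalar in `[0, 1]`, or `NA` when `K = 1`.
#' @export
compute_entropy <- function(posteriors) {
  posteriors <- as.matrix(posteriors)
  K <- ncol(posteriors)
  if (K < 2L) return(NA_real_)
  if (any(abs(rowSums(posteriors) - 1) > 1e-6))
    stop("posterior rows must sum to 1")
  h <- posteriors * log(posteriors)
  h[posteriors == 0] <- 0
  1 - sum(-h) / (nrow(posteriors) * log(K))
}

#' Average posterior probability by modal class
#'
#' For each class, the mean posterior probability of that class among the
#' subjects whose most likely (modal) class it is -- the standard diagnostic
#' of assignment certainty. Classes that are nobody's modal class return
#' `NA`.
#'
#' @param posteriors `n x K` posterior matrix.
#' @return Numeric vector of length `K`.
#' @export
avg_posterior_by_modal_class <- function(posteriors) {
  posteriors <- as.matrix(posteriors)
  K <- ncol(posteriors)
  modal <- max.col(posteriors, ties.method = "first")
  vapply(seq_len(K), function(k) {
    in_k <- modal == k
    if (!any(in_k)) NA_real_ else mean(posteriors[in_k, k])
  }, numeric(1))
}

# ---- robust (sandwich) standard errors -------------------------------------

# Unconstrained parameter vector: class-K-referenced log-odds for pi, raw
# beta, log-Cholesky of Sigma_b, log sigma2.
.pack_params <- function(fit) {
  th <- c()
  K <- fit$spec$K
  if (K > 1L)
    th <- c(th, stats::setNames(log(fit$pi[-K] / fit$pi[K]),
                                paste0("logit_pi_", seq_len(K - 1L))))
  bn <- as.vector(outer(rownames(fit$beta), colnames(fit$beta),
                        function(a, b) paste0(b, ":", a)))
  th <- c(th, stats::setNames(as.vector(fit$beta), bn))
  if (!is.null(fit$Sigma_b)) {
    L <- t(chol(fit$Sigma_b + diag(1e-10, 2)))
    th <- c(th, lchol_11 = log(L[1, 1]), lchol_21 = L[2, 1],
            lchol_22 = log(L[2, 2]))
  }
  c(th, log_sigma2 = log(fit$sigma2))
}

.unpack_params <- function(th, fit) {
  K <- fit$spec$K
  p <- nrow(fit$beta)
  i <- 0L
  if (K > 1L) {
    eta <- th[seq_len(K - 1L)]
    i <- K - 1L
    pi <- exp(c(eta, 0))
    pi <- pi / sum(pi)
  } else pi <- 1
  beta <- matrix(th[i + seq_len(p * K)], p, K)
  i <- i + p * K
  Sigma_b <- NULL
  if (!is.null(fit$Sigma_b)) {
    L <- matrix(c(exp(th[i + 1L]), th[i + 2L], 0, exp(th[i + 3L])), 2, 2)
    Sigma_b <- L %*% t(L)
    i <- i + 3L
  }
  list(pi = pi, beta = beta, Sigma_b = Sigma_b, sigma2 = exp(th[i + 1L]))
}

# Per-subject mixture log-likelihood vector at parameter vector th.
.subject_logliks <- function(th, fit, pats) {
  pr <- .unpack_params(th, fit)
  vs <- .var_structs(pats, pr$Sigma_b, pr$sigma2)
  ll <- .ll_matrix(fit$n_used, pats, vs, pr$beta, fit$X)
  lw <- ll + rep(log(pr$pi), each = nrow(ll))
  mx <- lw[, 1L]
  if (ncol(lw) > 1L) for (k in 2:ncol(lw)) mx <- pmax(mx, lw[, k])
  mx + log(rowSums(exp(lw - mx)))
}

#' Robust (sandwich) standard errors for a fitted model
#'
#' Sandwich estimator `A^-1 B A^-T`, with `A` the observed information
#' (numerical Hessian of the total log-likelihood) and `B` the outer product
#' of per-subject score vectors obtained by central differences. Mean-curve
#' coefficients are reported on their natural scale; mixing proportions and
#' variance components on their unconstrained (log / log-odds) scales, as
#' named.
#'
#' @param fit A converged `gmm_fit`.
#' @return Data frame with columns `parameter`, `estimate`, `se_robust`,
#'   `se_model` (inverse-information standard error).
#' @export
robust_standard_errors <- function(fit) {
  stopifnot(inherits(fit, "gmm_fit"))
  if (!fit$converged) stop("robust SEs require a converged fit")
  pats <- .patterns(fit$Y, fit$X, fit$Z)
  th <- .pack_params(fit)
  p <- length(th)
  n <- fit$n_used
  h <- 1e-5 * pmax(abs(th), 1)
  # per-subject scores, central differences
  S <- matrix(0, n, p)
  for (j in seq_len(p)) {
    tp <- th; tp[j] <- tp[j] + h[j]
    tm <- th; tm[j] <- tm[j] - h[j]
    S[, j] <- (.subject_logliks(tp, fit, pats) -
               .subject_logliks(tm, fit, pats)) / (2 * h[j])
  }
  B <- crossprod(S)
  # observed information: Hessian of total loglik by differencing gradients
  gr <- function(t0) {
    g <- numeric(p)
    for (j in seq_len(p)) {
      tp <- t0; tp[j] <- tp[j] + h[j]
      tm <- t0; tm[j] <- tm[j] - h[j]
      g[j] <- (sum(.subject_logliks(tp, fit, pats)) -
               sum(.subject_logliks(tm, fit, pats))) / (2 * h[j])
    }
    g
  }
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    tp <- th; tp[j] <- tp[j] + h[j]
    tm <- th; tm[j] <- tm[j] - h[j]
    H[, j] <- (gr(tp) - gr(tm)) / (2 * h[j])
  }
  H <- (H + t(H)) / 2
  A <- -H
  Ai <- tryCatch(solve(A), error = function(e)
    stop("observed information is not invertible; ",
         "consider a simpler model (fewer classes or no random effects)"))
  V_rob <- Ai %*% B %*% t(Ai)
  data.frame(parameter = names(th), estimate = unname(th),
             se_robust = sqrt(pmax(diag(V_rob), 0)),
             se_model = sqrt(pmax(diag(Ai), 0)),
             stringsAsFactors = FALSE)
}
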