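# Model-selection ladder: fit a grid of growth mixture models over class
# counts, polynomial degrees and random-effect structures, then apply the
# published decision rules (BIC differences >= 10, entropy, no class below
# 5% of subjects) plus the Lo-Mendell-Rubin and bootstrapped likelihood
# ratio tests for k vs k-1 classes.

#' Fit a grid of growth mixture models
#'
#' Fits every combination of `degrees` x `random_effects` x `1..K_max`
#' classes via [fit_gmm()]. Individual cell failures are recorded, not
#' fatal.
#'
#' @param Y Outcome matrix (or `psytraj_cohort`).
#' @param degrees Integer vector of polynomial degrees (default `c(1, 2)`;
#'   cubic models are specifiable but frequently unidentified on 10
#'   occasions -- such cells simply record their failure).
#' @param random_effects Character vector over `"none"`,
#'   `"intercept_slope"`.
#' @param K_max Largest class count (grid is `1..K_max`).
#' @param n_starts,seed,... Passed to [gmm_spec()].
#' @return An object of class `model_ladder`: a data frame (one row per
#'   cell: `degree`, `random_effects`, `K`, `loglik`, `n_params`, `bic`,
#'   `entropy`, `min_class_share`, `min_avg_posterior`, `converged`,
#'   `failed`) with the fitted objects in `attr(, "fits")`.
#' @export
run_model_ladder <- function(Y, degrees = c(1L, 2L),
                             random_effects = c("none", "intercept_slope"),
                             K_max = 6L, n_starts = 20L, seed = 1L, ...) {
  if (inherits(Y, "psytraj_cohort")) Y <- annual_matrix(Y)
  grid <- expand.grid(K = seq_len(K_max), degree = degrees,
                      random_effects = random_effects,
                      stringsAsFactors = FALSE)
  fits <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    sp <- gmm_spec(K = g$K, degree = g$degree,
                   random_effects = g$random_effects,
                   n_starts = n_starts, seed = seed + i, ...)
    f <- tryCatch(suppressWarnings(fit_gmm(Y, sp)),
                  error = function(e) e)
    if (inherits(f, "error")) {
      rows[[i]] <- data.frame(
        degree = g$degree, random_effects = g$random_effects, K = g$K,
        loglik = NA_real_, n_params = NA_integer_, bic = NA_real_,
        entropy = NA_real_, min_class_share = NA_real_,
        min_avg_posterior = NA_real_, converged = FALSE, failed = TRUE,
        message = conditionMessage(f), stringsAsFactors = FALSE)
    } else {
      fits[[i]] <- f
      rows[[i]] <- data.frame(
        degree = g$degree, random_effects = g$random_effects, K = g$K,
        loglik = f$loglik, n_params = f$n_params, bic = f$bic,
        entropy = f$entropy, min_class_share = min(f$pi),
        min_avg_posterior =
          min(avg_posterior_by_modal_class(f$posteriors), na.rm = TRUE),
        converged = f$converged, failed = FALSE, message = "",
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (all(tab$failed)) stop("every ladder cell failed to fit")
  structure(tab, fits = fits, class = c("model_ladder", "data.frame"))
}

#' @export
print.model_ladder <- function(x, ...) {
  cat("<model_ladder> ", nrow(x), " cells\n", sep = "")
  print.data.frame(x[, setdiff(names(x), "message")], digits = 4,
                   row.names = FALSE)
  invisible(x)
}

#' Lo-Mendell-Rubin adjusted likelihood ratio test
#'
#' Compares a `k`-class fit against the `(k-1)`-class fit of the same model
#' family. The raw statistic is `2 (L_k - L_{k-1})`; the adjusted variant
#' divides by the correction factor `1 + 1 / (d log n)` (`d` = difference in
#' free parameters) and refers the result to a chi-square with `d` degrees
#' of freedom. Small p favours the larger model. Constant-level differences
#' from other implementations of the approximation are expected; the
#' parametric bootstrap ([bootstrap_lrt()]) is the heavier-duty alternative.
#'
#' @param fit_k,fit_k_minus_1 `gmm_fit` objects with class counts differing
#'   by one, fitted to the same data.
#' @param n Number of subjects (defaults to `fit_k$n_used`).
#' @return List with `statistic` (raw LR), `adjusted_statistic`, `df`,
#'   `p_value` (`NA` with a warning when the larger model has the smaller
#'   log-likelihood, indicating an optimisation failure).
#' @export
lmr_test <- function(fit_k, fit_k_minus_1, n = fit_k$n_used) {
  stopifnot(inherits(fit_k, "gmm_fit"), inherits(fit_k_minus_1, "gmm_fit"))
  if (fit_k$spec$K != fit_k_minus_1$spec$K + 1L)
    stop("fits must have class counts k and k-1")
  lr <- 2 * (fit_k$loglik - fit_k_minus_1$loglik)
  d <- fit_k$n_params - fit_k_minus_1$n_params
  if (lr < 0) {
    warning("k-class log-likelihood below (k-1)-class value; ",
            "optimisation failure, p set to NA")
    return(list(statistic = lr, adjusted_statistic = NA_real_, df = d,
                p_value = NA_real_))
  }
  adj <- lr / (1 + 1 / (d * log(n)))
  list(statistic = lr, adjusted_statistic = adj, df = d,
       p_value = stats::pchisq(adj, df = d, lower.tail = FALSE))
}

#' Bootstrapped likelihood ratio test for k vs k-1 classes
#'
#' Parametric bootstrap: `B` datasets are simulated from the fitted
#' `(k-1)`-class model, reproducing each subject's observed-year pattern;
#' both models are refitted to every draw and the observed statistic
#' `2 (L_k - L_{k-1})` is referred to the bootstrap distribution. The
#' p-value uses the add-one convention `(1 + #{LR_b >= LR_obs}) / (B + 1)`,
#' so it can never be exactly zero.
#'
#' @param Y Outcome matrix (or cohort) both fits were obtained from.
#' @param fit_k,fit_k_minus_1 The two fitted models.
#' @param B Number of bootstrap draws (published analyses use 500; tests
#'   here use far fewer).
#' @param seed Seed for the bootstrap simulations.
#' @param n_starts Starts per bootstrap refit (default 10, fewer than a
#'   final fit: a deliberate runtime trade-off).
#' @return List with `statistic`, `p_value`, `B_effective`, and the vector
#'   of bootstrap statistics `lr_boot`.
#' @export
bootstrap_lrt <- function(Y, fit_k, fit_k_minus_1, B = 500L, seed = 1L,
                          n_starts = 10L) {
  if (inherits(Y, "psytraj_cohort")) Y <- annual_matrix(Y)
  Y <- as.matrix(Y)
  if (B < 1L) stop("B must be >= 1")
  lr_obs <- 2 * (fit_k$loglik - fit_k_minus_1$loglik)
  sp0 <- fit_k_minus_1$spec
  sp1 <- fit_k$spec
  lr_boot <- rep(NA_real_, B)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  for (b in seq_len(B)) {
    set.seed(seed + 131L * b)
    Yb <- .simulate_from_fit(fit_k_minus_1, Y)
    f0 <- tryCatch(suppressWarnings(fit_gmm(Yb, .respec(sp0, n_starts,
                                                        seed + 7L * b))),
                   error = function(e) NULL)
    f1 <- tryCatch(suppressWarnings(fit_gmm(Yb, .respec(sp1, n_starts,
                                                        seed + 7L * b + 3L))),
                   error = function(e) NULL)
    if (is.null(f0) || is.null(f1)) next
    lr_boot[b] <- 2 * (f1$loglik - f0$loglik)
  }
  ok <- !is.na(lr_boot)
  if (mean(ok) < 0.9)
    stop(sprintf("%d of %d bootstrap draws failed to fit", sum(!ok), B))
  if (!all(ok))
    warning(sum(!ok), " bootstrap draw(s) failed and were dropped")
  lr_b <- lr_boot[ok]
  p <- (1 + sum(lr_b >= lr_obs)) / (length(lr_b) + 1)
  list(statistic = lr_obs, p_value = p, B_effective = length(lr_b),
       lr_boot = lr_b)
}

.respec <- function(sp, n_starts, seed) {
  gmm_spec(K = sp$K, degree = sp$degree, random_effects = sp$random_effects,
           n_starts = n_starts, max_iter = sp$max_iter, tol = sp$tol,
           seed = as.integer(seed %% .Machine$integer.max))
}

# Simulate a dataset from a fitted model, preserving each row's
# observed-year pattern (parametric bootstrap under MAR).
.simulate_from_fit <- function(fit, Y) {
  n <- nrow(Y)
  Tn <- ncol(Y)
  K <- fit$spec$K
  cls <- sample.int(K, n, replace = TRUE, prob = fit$pi)
  M <- fit$X %*% fit$beta               # T x K means
  Yb <- matrix(NA_real_, n, Tn)
  re <- !is.null(fit$Sigma_b)
  if (re) Lb <- t(chol(fit$Sigma_b + diag(1e-12, 2)))
  for (i in seq_len(n)) {
    mu <- M[, cls[i]]
    if (re) mu <- mu + as.vector(fit$Z %*% (Lb %*% stats::rnorm(2)))
    yi <- mu + stats::rnorm(Tn, 0, sqrt(fit$sigma2))
    obs <- !is.na(Y[i, ])
    Yb[i, obs] <- yi[obs]
  }
  rownames(Yb) <- rownames(Y)
  Yb
}

#' Apply the published selection rules to a fitted ladder
#'
#' Rules, in order, among converged cells: (1) drop cells containing a
#' latent class with fewer than `min_share` of subjects; (2) keep cells
#' within `delta_bic` of the best remaining BIC (a difference of 10 or more
#' is treated as decisive); (3) among the remainder prefer higher entropy,
#' then fewer classes, then lower BIC. Every rule firing is recorded in the
#' trace. If the class-size rule eliminates everything, the best-BIC
#' converged cell is returned with a prominent warning.
#'
#' @param ladder A `model_ladder` (or plain data frame with its columns).
#' @param delta_bic Decisive BIC difference (default 10).
#' @param min_share Smallest acceptable class share (default 0.05).
#' @return List with `selected` (row index into `ladder`), `trace`
#'   (character vector of rule firings) and `table` (the ladder with a
#'   `selected` flag column).
#' @export
select_final_model <- function(ladder, delta_bic = 10, min_share = 0.05) {
  tab <- as.data.frame(ladder)
  if (!nrow(tab)) stop("empty ladder")
  trace <- character(0)
  say <- function(...) trace <<- c(trace, sprintf(...))
  cand <- which(!tab$failed & tab$converged)
  if (!length(cand)) stop("no converged ladder cell")
  if (length(cand) < nrow(tab))
    say("dropped %d unconverged/failed cell(s)", nrow(tab) - length(cand))
  ok_share <- cand[tab$min_class_share[cand] >= min_share |
                     tab$K[cand] == 1L]
  for (i in setdiff(cand, ok_share))
    say("row %d (K=%d, degree=%d, RE=%s): smallest class %.1f%% < %.0f%% rule",
        i, tab$K[i], tab$degree[i], tab$random_effects[i],
        100 * tab$min_class_share[i], 100 * min_share)
  if (!length(ok_share)) {
    best <- cand[which.min(tab$bic[cand])]
    warning("no model satisfies the minimum class-share rule; ",
            "returning the best-BIC model regardless")
    say("WARNING: class-share rule eliminated all cells; best BIC kept")
    tab$selected <- seq_len(nrow(tab)) == best
    return(list(selected = best, trace = trace, table = tab))
  }
  best_bic <- min(tab$bic[ok_share])
  near <- ok_share[tab$bic[ok_share] - best_bic < delta_bic]
  for (i in setdiff(ok_share, near))
    say("row %d: BIC %.1f is >= %.0f above best (%.1f), rejected",
        i, tab$bic[i], delta_bic, best_bic)
  if (length(near) > 1L)
    say("%d cells within %.0f BIC of best: preferring entropy, then fewer classes",
        length(near), delta_bic)
  ent <- ifelse(is.na(tab$entropy[near]), -Inf, tab$entropy[near])
  pick <- near[order(-ent, tab$K[near], tab$bic[near])][1L]
  say("selected row %d: K=%d, degree=%d, RE=%s (BIC %.1f, entropy %s)",
      pick, tab$K[pick], tab$degree[pick], tab$random_effects[pick],
      tab$bic[pick],
      ifelse(is.na(tab$entropy[pick]), "NA",
             sprintf("%.3f", tab$entropy[pick])))
  tab$selected <- seq_len(nrow(tab)) == pick
  list(selected = pick, trace = trace, table = tab)
}

#' Label the classes of a 4-class trajectory fit
#'
#' Computes each class's fitted mean curve, its early mean (years 1-3) and
#' late mean (years 8-10), calls a level above 6 months/year "high", and
#' maps: low/low to `remitting`, low/high to `late_decline`, high/low to
#' `late_improvement`, high/high to `persistent`. For `K != 4` generic
#' `class_k` labels are returned. If two classes map to one label the
#' labels are suffix-indexed with a warning.
#'
#' @param fit A `gmm_fit`.
#' @param high_threshold Months/year above which a period counts as high.
#' @return Character vector of labels, one per class (in fit class order).
#' @export
label_classes <- function(fit, high_threshold = 6) {
  stopifnot(inherits(fit, "gmm_fit"))
  K <- fit$spec$K
  if (K != 4L) return(paste0("class_", seq_len(K)))
  M <- fitted(fit)
  Tn <- nrow(M)
  early <- colMeans(M[1:min(3, Tn), , drop = FALSE])
  late <- colMeans(M[max(1, Tn - 2):Tn, , drop = FALSE])
  lab <- character(K)
  for (k in seq_len(K)) {
    hi_e <- early[k] > high_threshold
    hi_l <- late[k] > high_threshold
    lab[k] <- if (!hi_e && !hi_l) "remitting"
      else if (!hi_e && hi_l) "late_decline"
      else if (hi_e && !hi_l) "late_improvement"
      else "persistent"
  }
  if (anyDuplicated(lab)) {
    warning("two classes mapped to the same label; suffix-indexed")
    dup <- lab[duplicated(lab)]
    for (d in unique(dup)) {
      idx <- which(lab == d)
      lab[idx] <- paste0(d, "_", seq_along(idx))
    }
  }
  names(lab) <- colnames(fit$beta)
  lab
}
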