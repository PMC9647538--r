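# growth mixture model core: design, likelihood, EM, summaries, sandwich SEs

test_that("design_matrices builds centred polynomial bases", {
  d1 <- design_matrices(10, 1)
  expect_equal(dim(d1$X), c(10L, 2L))
  d2 <- design_matrices(10, 2)
  expect_equal(dim(d2$X), c(10L, 3L))
  expect_equal(sum(d2$X[, 2]), 0)       # centring kills the linear sum
  expect_equal(d2$Z, d2$X[, 1:2])
  expect_error(design_matrices(3, 3), "too small")
})

test_that("class_conditional_loglik matches closed forms and a matrix oracle", {
  dm <- design_matrices(10, 1)
  # single observed point, unit total variance, y = mean -> std normal at 0
  y <- c(0, rep(NA, 9))
  ll <- class_conditional_loglik(y, beta_k = c(0, 0), Sigma_b = NULL,
                                 sigma2 = 1, X = dm$X)
  expect_equal(ll, -0.5 * log(2 * pi), tolerance = 1e-10)
  # Sigma_b = 0 reduces to a sum of independent normal densities
  set.seed(3)
  y2 <- rnorm(10, 2, 1.3)
  beta <- c(2, 0.1)
  ll_re0 <- class_conditional_loglik(y2, beta, Sigma_b = diag(0, 2),
                                     sigma2 = 1.69, X = dm$X, Z = dm$Z)
  mu <- as.vector(dm$X %*% beta)
  expect_equal(ll_re0, sum(dnorm(y2, mu, 1.3, log = TRUE)),
               tolerance = 1e-10)
  # random 5-point case vs explicit matrix-inversion oracle
  y3 <- c(1.2, NA, 0.5, NA, 2.2, NA, NA, 1.1, NA, 0.4)
  Sb <- matrix(c(0.9, 0.2, 0.2, 0.3), 2)
  s2 <- 0.7
  obs <- which(!is.na(y3))
  V <- (dm$Z %*% Sb %*% t(dm$Z) + diag(s2, 10))[obs, obs]
  r <- y3[obs] - (dm$X %*% beta)[obs]
  oracle <- -0.5 * (length(obs) * log(2 * pi) + log(det(V)) +
                      as.numeric(t(r) %*% solve(V) %*% r))
  expect_equal(class_conditional_loglik(y3, beta, Sb, s2, dm$X, dm$Z),
               oracle, tolerance = 1e-10)
})

test_that("K=1 fit without random effects equals the pooled OLS MLE", {
  sim <- simulate_gaussian_mixture(80, 1, matrix(c(3, -0.4, 0.05), 3),
                                   sigma = 1.2, seed = 7, miss_prob = 0.15)
  fit <- fit_gmm(sim$Y, gmm_spec(K = 1, degree = 2, n_starts = 1,
                                 tol = 1e-10))
  # oracle: stack observed rows, ordinary least squares, sigma2 = RSS/N
  rows <- which(!is.na(sim$Y), arr.ind = TRUE)
  yv <- sim$Y[rows]
  Xv <- sim$X[rows[, 2], ]
  bh <- solve(crossprod(Xv), crossprod(Xv, yv))
  s2h <- mean((yv - Xv %*% bh)^2)
  llh <- sum(dnorm(yv, Xv %*% bh, sqrt(s2h), log = TRUE))
  expect_equal(unname(fit$beta[, 1]), as.vector(bh), tolerance = 1e-6)
  expect_equal(fit$sigma2, s2h, tolerance = 1e-6)
  expect_equal(fit$loglik, llh, tolerance = 1e-6)
  expect_equal(unname(fit$pi), 1)
})

test_that("K=1 fit with random effects matches the lme4 ML oracle", {
  sim <- simulate_gaussian_mixture(150, 1, matrix(c(5, -0.3, 0.02), 3),
                                   Sigma_b = matrix(c(1.5, 0.3, 0.3, 0.09),
                                                    2),
                                   sigma = 1, seed = 17, miss_prob = 0.1)
  fit <- fit_gmm(sim$Y, gmm_spec(K = 1, degree = 2,
                                 random_effects = "intercept_slope",
                                 n_starts = 1, tol = 1e-10,
                                 max_iter = 5000))
  long <- data.frame(y = as.vector(t(sim$Y)),
                     id = rep(seq_len(nrow(sim$Y)), each = 10),
                     t1 = rep(sim$X[, 2], nrow(sim$Y)),
                     t2 = rep(sim$X[, 3], nrow(sim$Y)))
  long <- long[!is.na(long$y), ]
  lfit <- lme4::lmer(y ~ t1 + t2 + (1 + t1 | id), data = long, REML = FALSE)
  expect_equal(fit$loglik, as.numeric(stats::logLik(lfit)),
               tolerance = 1e-6)
  expect_equal(unname(fit$beta[, 1]), unname(lme4::fixef(lfit)),
               tolerance = 1e-4)
})

test_that("two well-separated classes are recovered (n=400)", {
  beta <- cbind(c(9, -0.2, 0.01), c(2, 0.3, -0.02))
  sim <- simulate_gaussian_mixture(400, c(0.6, 0.4), beta, sigma = 1,
                                   seed = 23, miss_prob = 0.1)
  fit <- fit_gmm(sim$Y, gmm_spec(K = 2, degree = 2, n_starts = 5,
                                 seed = 2))
  expect_true(fit$converged)
  expect_lt(abs(fit$pi[1] - 0.6), 0.05)
  # beta within 3 Monte-Carlo SEs (per-class GLS covariance oracle)
  for (k in 1:2) {
    nk <- 400 * c(0.6, 0.4)[k]
    se <- sqrt(diag(solve(crossprod(sim$X))) / nk)  # sigma = 1
    expect_true(all(abs(fit$beta[, k] - beta[, k]) < 3 * se + 1e-8))
  }
  # single-class data at K=1: pi is exactly 1
  fit1 <- fit_gmm(sim$Y[sim$class == 1, ], gmm_spec(K = 1, degree = 2))
  expect_equal(unname(fit1$pi), 1)
})

test_that("EM log-likelihood is monotone and label order is canonical", {
  beta <- cbind(c(8, 0, 0), c(2, 0, 0))
  sim <- simulate_gaussian_mixture(150, c(0.7, 0.3), beta, sigma = 1.5,
                                   seed = 5)
  fit <- fit_gmm(sim$Y, gmm_spec(K = 2, degree = 2, n_starts = 4, seed = 3))
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  expect_true(all(diff(fit$pi) <= 1e-12))   # descending mixing proportions
  expect_equal(unname(rowSums(fit$posteriors)), rep(1, fit$n_used),
               tolerance = 1e-9)
})

test_that("entropy, BIC and average posteriors match hand calculations", {
  # BIC
  expect_equal(compute_bic(0, 0, 10), 0)
  expect_equal(compute_bic(-100, 5, 326), 200 + 5 * log(326))
  expect_equal(compute_bic(-100, 6, 326) - compute_bic(-100, 5, 326),
               log(326))
  # entropy: degenerate -> 1, uniform -> 0, worked 2x2 example -> 0.40453
  expect_equal(compute_entropy(rbind(c(1, 0), c(0, 1))), 1)
  expect_equal(compute_entropy(matrix(0.25, 3, 4)), 0)
  e <- compute_entropy(rbind(c(0.9, 0.1), c(0.8, 0.2)))
  expect_equal(e, 1 - 0.8254851 / (2 * log(2)), tolerance = 1e-6)
  expect_equal(e, 0.4045, tolerance = 1e-4)
  expect_true(is.na(compute_entropy(matrix(1, 5, 1))))
  # average posterior by modal class
  expect_equal(avg_posterior_by_modal_class(rbind(c(1, 0), c(0, 1))),
               c(1, 1))
  one <- avg_posterior_by_modal_class(matrix(c(0.7, 0.3), 1))
  expect_equal(one[1], 0.7)
  expect_true(is.na(one[2]))
  set.seed(12)
  P <- matrix(rexp(300), 100, 3)
  P <- P / rowSums(P)
  ap <- avg_posterior_by_modal_class(P)
  modal <- apply(P, 1, which.max)
  oracle <- sapply(1:3, function(k) mean(P[modal == k, k]))
  expect_equal(ap, oracle)
})

test_that("entropy and BIC are invariant under class relabelling", {
  set.seed(4)
  P <- matrix(rexp(200), 50, 4)
  P <- P / rowSums(P)
  perm <- c(3, 1, 4, 2)
  expect_equal(compute_entropy(P), compute_entropy(P[, perm]))
  expect_equal(sort(avg_posterior_by_modal_class(P)),
               sort(avg_posterior_by_modal_class(P[, perm])))
})

test_that("estimates are stable under additional MCAR deletion", {
  beta <- cbind(c(8, -0.2, 0), c(2, 0.3, 0))
  sim <- simulate_gaussian_mixture(1500, c(0.6, 0.4), beta, sigma = 1,
                                   seed = 31)
  f_full <- fit_gmm(sim$Y, gmm_spec(K = 2, degree = 2, n_starts = 3,
                                    seed = 1))
  Y2 <- sim$Y
  set.seed(99)
  drop <- matrix(runif(length(Y2)) < 0.2, nrow(Y2))
  for (i in which(rowSums(!drop) == 0)) drop[i, 1] <- FALSE
  Y2[drop] <- NA
  f_mcar <- fit_gmm(Y2, gmm_spec(K = 2, degree = 2, n_starts = 3, seed = 1))
  se_pi <- sqrt(0.6 * 0.4 / 1500)
  expect_lt(abs(f_full$pi[1] - f_mcar$pi[1]), 3 * se_pi)
  se_b <- sqrt(diag(solve(crossprod(sim$X))) / (1500 * 0.4))
  expect_true(all(abs(f_full$beta - f_mcar$beta) < 3 * (se_b + 1e-3) + 0.05))
})

test_that("sandwich SE equals s/sqrt(n) for the normal-mean model", {
  set.seed(8)
  Y <- matrix(rnorm(60 * 4, mean = 5, sd = 2), 60, 4)
  # intercept-only: collapse to per-subject data via degree 0
  fit <- fit_gmm(Y, gmm_spec(K = 1, degree = 0, n_starts = 1, tol = 1e-12))
  se <- robust_standard_errors(fit)
  i <- grep("intercept", se$parameter)
  # per-subject score of the mean of 4 iid obs: sandwich = sd_ml/sqrt(n)
  subj_means <- rowMeans(Y)
  expect_equal(fit$beta[1, 1], mean(Y), tolerance = 1e-8)
  s_ml <- sqrt(mean((subj_means - mean(subj_means))^2) / 4)  # per-occasion
  # closed form: Var(mu_hat) = Var(subject mean)/n
  se_oracle <- sqrt(mean((subj_means - mean(subj_means))^2) / 60)
  expect_equal(se$se_robust[i], se_oracle, tolerance = 1e-3)
})

test_that("robust and model-based SEs agree under correct specification, diverge under misspecification", {
  beta <- matrix(c(4, -0.3, 0.02), 3)
  sim <- simulate_gaussian_mixture(1000, 1, beta, sigma = 1, seed = 41)
  fit <- fit_gmm(sim$Y, gmm_spec(K = 1, degree = 2, n_starts = 1,
                                 tol = 1e-10))
  se <- robust_standard_errors(fit)
  bi <- grep("intercept|:t", se$parameter)
  expect_true(all(abs(se$se_robust[bi] / se$se_model[bi] - 1) < 0.2))
  # misspecification: strong within-subject correlation ignored by the
  # independence model inflates the robust SE above the model-based one
  sim2 <- simulate_gaussian_mixture(400, 1, beta,
                                    Sigma_b = diag(c(4, 1e-6)), sigma = 1,
                                    seed = 43)
  fit2 <- fit_gmm(sim2$Y, gmm_spec(K = 1, degree = 2, n_starts = 1,
                                   tol = 1e-10))
  se2 <- robust_standard_errors(fit2)
  i2 <- grep(":intercept", se2$parameter)
  expect_gt(se2$se_robust[i2], 1.5 * se2$se_model[i2])
})
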