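# model ladder, LMR / bootstrap LRT, selection rules, class labelling

make_ladder_row <- function(K, bic, min_share, entropy = 0.9, degree = 2,
                            re = "intercept_slope", converged = TRUE,
                            failed = FALSE) {
  data.frame(degree = degree, random_effects = re, K = K, loglik = -bic / 2,
             n_params = 3 * K, bic = bic, entropy = entropy,
             min_class_share = min_share, min_avg_posterior = 0.95,
             converged = converged, failed = failed, message = "",
             stringsAsFactors = FALSE)
}

test_that("run_model_ladder covers the grid and tolerates K=1 cells", {
  beta <- cbind(c(8, -0.2, 0.01), c(2, 0.3, -0.02))
  sim <- simulate_gaussian_mixture(120, c(0.6, 0.4), beta, sigma = 1,
                                   seed = 11)
  lad <- run_model_ladder(sim$Y, degrees = 1:2, random_effects = "none",
                          K_max = 2, n_starts = 3, seed = 5)
  expect_s3_class(lad, "model_ladder")
  expect_equal(nrow(lad), 4L)           # 2 degrees x 1 RE x 2 K
  expect_true(all(is.na(lad$entropy[lad$K == 1])))
  expect_true(all(!lad$failed))
  # within-degree: 2 classes fit these two-class data far better
  for (d in 1:2)
    expect_lt(lad$bic[lad$K == 2 & lad$degree == d],
              lad$bic[lad$K == 1 & lad$degree == d])
})

test_that("lmr_test handles identical, nested and pathological fits", {
  beta <- cbind(c(8, -0.2, 0.01), c(2, 0.3, -0.02))
  sim <- simulate_gaussian_mixture(150, c(0.6, 0.4), beta, sigma = 1,
                                   seed = 13)
  f1 <- fit_gmm(sim$Y, gmm_spec(K = 1, degree = 2))
  f2 <- fit_gmm(sim$Y, gmm_spec(K = 2, degree = 2, n_starts = 4, seed = 2))
  out <- lmr_test(f2, f1)
  expect_gt(out$statistic, 0)
  expect_equal(out$df, f2$n_params - f1$n_params)
  expect_lt(out$p_value, 0.01)          # strong separation: decisive
  # identical fits: statistic 0, p ~ 1 (construct a self-comparison)
  f2b <- f2
  f2b$spec$K <- f1$spec$K + 1L
  f2b$loglik <- f1$loglik
  f2b$n_params <- f1$n_params + 4L
  expect_equal(lmr_test(f2b, f1)$statistic, 0)
  expect_equal(lmr_test(f2b, f1)$p_value, 1)
  # decreasing log-likelihood flags an optimisation failure
  f2c <- f2b
  f2c$loglik <- f1$loglik - 5
  expect_warning(res <- lmr_test(f2c, f1), "optimisation failure")
  expect_true(is.na(res$p_value))
})

test_that("bootstrap_lrt follows the add-one p-value convention and has power", {
  beta <- cbind(c(8, -0.2, 0.01), c(2, 0.3, -0.02))
  sim <- simulate_gaussian_mixture(200, c(0.6, 0.4), beta, sigma = 1,
                                   seed = 17)
  f1 <- fit_gmm(sim$Y, gmm_spec(K = 1, degree = 2))
  f2 <- fit_gmm(sim$Y, gmm_spec(K = 2, degree = 2, n_starts = 4, seed = 2))
  out <- bootstrap_lrt(sim$Y, f2, f1, B = 50, seed = 3, n_starts = 2)
  # two well-separated classes: observed LR beats every null draw
  expect_equal(out$p_value, (1 + 0) / (out$B_effective + 1))
  expect_lte(out$p_value, 0.05)
  # LR_obs = 0 -> p = 1 by the formula
  f2z <- f2
  f2z$loglik <- f1$loglik
  outz <- bootstrap_lrt(sim$Y, f2z, f1, B = 19, seed = 4, n_starts = 2)
  expect_equal(outz$p_value, 1)
})

test_that("selection engine applies the class-share and delta-BIC rules", {
  # one row selects trivially
  one <- make_ladder_row(3, 1000, 0.2)
  sel <- select_final_model(one)
  expect_equal(sel$selected, 1L)
  # 5-class BIC lower by 12 but smallest class 3% -> 4-class wins,
  # trace cites the share rule
  two <- rbind(make_ladder_row(4, 1012, 0.056, entropy = 0.92),
               make_ladder_row(5, 1000, 0.030, entropy = 0.95))
  sel2 <- select_final_model(two)
  expect_equal(sel2$selected, 1L)
  expect_true(any(grepl("< 5% rule", sel2$trace)))
  # within 10 BIC: entropy breaks the tie
  three <- rbind(make_ladder_row(3, 1000, 0.2, entropy = 0.95),
                 make_ladder_row(4, 1004, 0.1, entropy = 0.80))
  expect_equal(select_final_model(three)$selected, 1L)
  three$entropy <- c(0.80, 0.95)
  expect_equal(select_final_model(three)$selected, 2L)
  # >= 10 BIC difference is decisive regardless of entropy
  four <- rbind(make_ladder_row(3, 1000, 0.2, entropy = 0.5),
                make_ladder_row(4, 1012, 0.1, entropy = 0.99))
  sel4 <- select_final_model(four)
  expect_equal(sel4$selected, 1L)
  expect_true(any(grepl("rejected", sel4$trace)))
  # share rule eliminating everything falls back with a warning
  five <- rbind(make_ladder_row(4, 1000, 0.02), make_ladder_row(5, 990, 0.01))
  expect_warning(sel5 <- select_final_model(five), "class-share")
  expect_equal(sel5$selected, 2L)
  # unconverged rows never win
  six <- rbind(make_ladder_row(3, 900, 0.2, converged = FALSE),
               make_ladder_row(2, 1000, 0.3))
  expect_equal(select_final_model(six)$selected, 2L)
  expect_error(select_final_model(six[six$K == 99, ]), "empty")
})

test_that("bootstrap_lrt is reproducible given its seed", {
  beta <- cbind(c(7, -0.2, 0.01), c(2, 0.3, -0.02))
  sim <- simulate_gaussian_mixture(80, c(0.6, 0.4), beta, sigma = 1.5,
                                   seed = 21)
  f1 <- fit_gmm(sim$Y, gmm_spec(K = 1, degree = 2))
  f2 <- fit_gmm(sim$Y, gmm_spec(K = 2, degree = 2, n_starts = 3, seed = 2))
  a <- bootstrap_lrt(sim$Y, f2, f1, B = 15, seed = 9, n_starts = 2)
  b <- bootstrap_lrt(sim$Y, f2, f1, B = 15, seed = 9, n_starts = 2)
  expect_identical(a$p_value, b$p_value)
  expect_identical(a$lr_boot, b$lr_boot)
})

test_that("selection is a pure function of the table", {
  tab <- rbind(make_ladder_row(2, 1000, 0.3, entropy = 0.91),
               make_ladder_row(3, 995, 0.12, entropy = 0.93),
               make_ladder_row(4, 996, 0.06, entropy = 0.97))
  a <- select_final_model(tab)
  b <- select_final_model(tab)
  expect_identical(a, b)
})

test_that("label_classes maps curve shapes to the canonical names", {
  dm <- design_matrices(10, 2)
  # construct a synthetic fit object: flat-low, flat-high, rising, falling
  curves <- cbind(rep(1, 10), rep(11, 10),
                  seq(1, 11, length.out = 10), seq(11, 1, length.out = 10))
  beta <- qr.solve(dm$X, curves)
  fit <- structure(list(
    pi = c(0.5, 0.3, 0.1, 0.1), beta = beta, X = dm$X,
    spec = gmm_spec(K = 4, degree = 2)), class = "gmm_fit")
  colnames(fit$beta) <- paste0("class_", 1:4)
  lab <- label_classes(fit)
  expect_equal(unname(lab),
               c("remitting", "persistent", "late_decline",
                 "late_improvement"))
  # K = 2 gets generic labels
  fit2 <- structure(list(pi = c(0.6, 0.4), beta = beta[, 1:2], X = dm$X,
                         spec = gmm_spec(K = 2, degree = 2)),
                    class = "gmm_fit")
  expect_equal(label_classes(fit2), c("class_1", "class_2"))
  # duplicate shapes get suffixed labels
  fit3 <- fit
  fit3$beta[, 3] <- fit3$beta[, 1]
  expect_warning(lab3 <- label_classes(fit3), "same label")
  expect_true(all(c("remitting_1", "remitting_2") %in% lab3))
})

test_that("labelling the generator-default fit recovers the true class names", {
  sim <- simulate_cohort(generator_config(seed = 14))
  fit <- fit_gmm(annual_matrix(sim$cohort),
                 gmm_spec(K = 4, degree = 2,
                          random_effects = "intercept_slope",
                          n_starts = 20, seed = 6))
  lab <- modal_classes(fit)
  agree <- mean(lab[names(sim$true_class)] == sim$true_class)
  expect_gt(agree, 0.9)
  expect_setequal(unique(unname(label_classes(fit))),
                  c("remitting", "late_decline", "late_improvement",
                    "persistent"))
})
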