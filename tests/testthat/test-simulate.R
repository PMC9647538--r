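# synthetic cohort generator

test_that("generator config validates its inputs", {
  expect_error(generator_config(class_proportions = c(0.5, 0.2, 0.2, 0.2)),
               "simplex")
  expect_error(generator_config(markov_persistence = 1), "persistence")
  expect_error(generator_config(random_effect_sds = c(-1, 0.1)), "SDs")
  cfg <- generator_config()
  expect_equal(sum(cfg$class_proportions), 1)
})

test_that("simulate_cohort is seed-deterministic", {
  a <- simulate_cohort(generator_config(n_subjects = 40, seed = 9))
  b <- simulate_cohort(generator_config(n_subjects = 40, seed = 9))
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$true_class, b$true_class)
  c2 <- simulate_cohort(generator_config(n_subjects = 40, seed = 10))
  expect_false(identical(a$cohort, c2$cohort))
})

test_that("degenerate class proportions give a single class", {
  sim <- simulate_cohort(generator_config(
    n_subjects = 30, seed = 2,
    class_proportions = c(remitting = 1, late_decline = 0,
                          late_improvement = 0, persistent = 0)))
  expect_true(all(sim$true_class == "remitting"))
})

test_that("empirical class shares match the simplex within 3 SE (n=5000)", {
  sim <- simulate_cohort(generator_config(n_subjects = 5000, seed = 31))
  p <- generator_config()$class_proportions
  phat <- table(factor(sim$true_class, names(p)))[names(p)] / 5000
  se <- sqrt(p * (1 - p) / 5000)
  expect_true(all(abs(as.numeric(phat) - p) <= 3 * se))
})

test_that("monthly series hits deterministic edge cases", {
  flat0 <- generator_config()
  flat0$class_curves[] <- 0
  set.seed(1)
  tl <- simulate_monthly_series(1, c(0, 0), flat0, 60)
  expect_true(all(tl$statuses == "A"))
  flat12 <- generator_config()
  flat12$class_curves[] <- 0
  flat12$class_curves[1, ] <- 12
  tl <- simulate_monthly_series(1, c(0, 0), flat12, 60)
  expect_true(all(tl$statuses == "P"))
})

test_that("annual present counts track the persistent mean curve", {
  cfg <- generator_config()
  co <- cfg$class_curves[, "persistent"]
  curve_mean <- mean(co[1] + co[2] * (1:10) + co[3] * (1:10)^2)
  set.seed(5)
  # ~10,000 subject-months: 84 subjects x 120 months
  ys <- replicate(84, {
    b <- rnorm(2, 0, cfg$random_effect_sds)
    mean(aggregate_to_annual(
      simulate_monthly_series("persistent", b, cfg, 120), 10)$y)
  })
  expect_lt(abs(mean(ys) - curve_mean), 0.5)
})

test_that("covariate model reproduces the configured odds ratios", {
  # implied OR from two prevalences: (0.6/0.4)/(0.44/0.56) ~= 1.91
  or <- (0.6 / 0.4) / (0.44 / 0.56)
  expect_equal(or, 1.909091, tolerance = 1e-6)
  cfg <- generator_config()
  pm <- cfg$covariate_model
  expect_equal((pm$persistent$sex[["male"]] / (1 - pm$persistent$sex[["male"]])) /
                 (pm$remitting$sex[["male"]] / (1 - pm$remitting$sex[["male"]])),
               1.89, tolerance = 0.02)
  # identical prevalences -> implied OR exactly 1
  expect_equal((0.3 / 0.7) / (0.3 / 0.7), 1)
  # DUP gamma rates encode log(1.05) per month exactly
  expect_equal(pm$remitting$dup_months$rate - pm$persistent$dup_months$rate,
               log(1.05), tolerance = 1e-12)
})

test_that("GAF-D class means are reproduced at n=10000 (CLT bound)", {
  cfg <- generator_config()
  set.seed(11)
  for (cl in c("remitting", "persistent")) {
    g <- replicate(10000, simulate_covariates(cl, cfg)$outcome$gaf_d)
    target <- cfg$covariate_model[[cl]]$gaf_d$mean
    expect_lt(abs(mean(g) - target), 0.5)
  }
})

test_that("apply_missingness honours the edge probabilities", {
  sim <- simulate_cohort(generator_config(n_subjects = 20, seed = 3,
    missing_year_prob = list(base = 0, logodds = numeric(0))))
  expect_true(all(vapply(sim$cohort$timelines,
                         function(tl) !any(tl$statuses == "M"),
                         logical(1))))
  cfg1 <- generator_config(n_subjects = 10, seed = 3,
                           missing_year_prob = list(base = 1,
                                                    logodds = numeric(0)))
  sim1 <- simulate_cohort(cfg1)
  expect_true(all(vapply(sim1$cohort$timelines,
                         function(tl) all(tl$statuses == "M"),
                         logical(1))))
  expect_error(apply_missingness(sim$cohort$timelines, sim$cohort$baseline,
                                 generator_config(missing_year_prob =
                                   list(base = 2, logodds = numeric(0)))),
               "simplex|probability")
})

test_that("marginal missing-year rate is near its configured value", {
  cfg <- generator_config(n_subjects = 250, seed = 21,
                          missing_year_prob = list(base = 0.1,
                                                   logodds = numeric(0)))
  sim <- simulate_cohort(cfg)
  miss <- unlist(lapply(sim$cohort$timelines, function(tl) {
    ny <- floor(tl$followup_months / 12)
    vapply(seq_len(ny), function(t)
      all(tl$statuses[(12 * (t - 1) + 1):(12 * t)] == "M"), logical(1))
  }))
  rate <- mean(miss)                      # ~2400 subject-years
  se <- sqrt(0.1 * 0.9 / length(miss))
  expect_lt(abs(rate - 0.1), 3 * se)
})

test_that("the year masker is MAR by construction: blanks do not depend on statuses", {
  # two cohorts whose covariates and seeds agree but whose symptom values
  # differ must be blanked in exactly the same places
  cfg <- generator_config(n_subjects = 30, seed = 8,
                          missing_year_prob = list(base = 0.3,
                                                   logodds = numeric(0)))
  sim <- simulate_cohort(cfg)
  tls_all_p <- lapply(sim$cohort$timelines, function(tl)
    monthly_timeline(tl$subject_id, rep("P", tl$followup_months)))
  names(tls_all_p) <- names(sim$cohort$timelines)
  tls_all_a <- lapply(sim$cohort$timelines, function(tl)
    monthly_timeline(tl$subject_id, rep("A", tl$followup_months)))
  names(tls_all_a) <- names(sim$cohort$timelines)
  set.seed(99)
  mp <- apply_missingness(tls_all_p, sim$cohort$baseline, cfg)
  set.seed(99)
  ma <- apply_missingness(tls_all_a, sim$cohort$baseline, cfg)
  mask_p <- lapply(mp, function(tl) tl$statuses == "M")
  mask_a <- lapply(ma, function(tl) tl$statuses == "M")
  expect_identical(mask_p, mask_a)
})

test_that("generator config survives a JSON round-trip", {
  cfg <- generator_config(n_subjects = 77, seed = 13,
                          markov_persistence = 0.4)
  td <- withr::local_tempdir()
  f <- file.path(td, "cfg.json")
  write_generator_config(cfg, f)
  cfg2 <- read_generator_config(f)
  expect_equal(cfg2$n_subjects, 77L)
  expect_equal(cfg2$markov_persistence, 0.4)
  expect_equal(unname(cfg2$class_curves), unname(cfg$class_curves),
               tolerance = 1e-12)
  expect_equal(simulate_cohort(cfg2)$cohort, simulate_cohort(cfg)$cohort)
})
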