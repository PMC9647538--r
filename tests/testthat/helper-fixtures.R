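# Shared fixture builders. Everything is generated in code; no stored data.

# A tiny hand-written cohort: three subjects, two years of follow-up.
tiny_cohort <- function() {
  tls <- list(
    monthly_timeline("a", rep(c("P", "A"), each = 12)),
    monthly_timeline("b", rep("A", 24)),
    monthly_timeline("c", c(rep("P", 20), rep("M", 4))))
  bl <- data.frame(subject_id = c("a", "b", "c"),
                   centre = c("London", "Nottingham", "London"),
                   sex = c("male", "female", "male"),
                   age_at_onset = c(25, 31.5, 40),
                   dup_months = c(2, 0.5, 12),
                   stringsAsFactors = FALSE)
  oc <- data.frame(subject_id = c("a", "b", "c"),
                   gaf_d = c(70, 85, NA),
                   in_relationship = c(TRUE, NA, FALSE),
                   employed = c(TRUE, TRUE, FALSE),
                   stringsAsFactors = FALSE)
  cohort(tls, bl, oc)
}

# Gaussian data simulated directly from the growth-mixture model itself
# (not through the monthly chain): the clean world for estimator oracles.
simulate_gaussian_mixture <- function(n, pi, beta, Sigma_b = NULL,
                                      sigma = 1, T = 10, seed = 1,
                                      miss_prob = 0) {
  set.seed(seed)
  dm <- design_matrices(T, nrow(beta) - 1L)
  cls <- sample.int(ncol(beta), n, replace = TRUE, prob = pi)
  Y <- matrix(NA_real_, n, T)
  for (i in seq_len(n)) {
    mu <- dm$X %*% beta[, cls[i]]
    if (!is.null(Sigma_b))
      mu <- mu + dm$Z %*% (t(chol(Sigma_b)) %*% rnorm(2))
    Y[i, ] <- mu + rnorm(T, 0, sigma)
  }
  if (miss_prob > 0) {
    mask <- matrix(runif(n * T) < miss_prob, n, T)
    # keep at least one observed year per subject
    for (i in which(rowSums(!mask) == 0)) mask[i, 1] <- FALSE
    Y[mask] <- NA
  }
  rownames(Y) <- sprintf("g%04d", seq_len(n))
  list(Y = Y, class = cls, X = dm$X, Z = dm$Z)
}

# Acceptance protocol: generator seeds derived from one master seed.
acceptance_seeds <- function(master, n = 5L)
  (as.integer(master) * 1000L + seq_len(n)) %% 2147483000L
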