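# Synthetic cohort generator. Emulates the statistical structure the
# trajectory analysis assumes: four latent classes with quadratic mean curves
# of months-psychotic-per-year, subject-level random intercepts/slopes,
# serially correlated monthly presence/absence underlying the annual counts,
# whole-year missing-at-random gaps, and class-conditional covariate and
# outcome distributions calibrated to published effect sizes.

.CLASS_NAMES <- c("remitting", "late_decline", "late_improvement",
                  "persistent")

# Calibration anchors for the four class mean curves (months psychotic per
# year at years 1, 5.5 and 10). These are invented constants chosen to
# satisfy the verbal class descriptions -- remitting: moderate and falling;
# late decline: low early, high from mid follow-up; late improvement: the
# mirror image; persistent: high throughout -- with enough separation that a
# well-specified 4-class fit classifies sharply. They are not measurements.
.CLASS_ANCHORS <- list(
  remitting        = cbind(t = c(1, 5.5, 10), y = c(4.2, 1.6, 0.6)),
  late_decline     = cbind(t = c(1, 5.5, 10), y = c(1.2, 5.5, 11.8)),
  late_improvement = cbind(t = c(1, 5.5, 10), y = c(11.3, 6.5, 1.0)),
  persistent       = cbind(t = c(1, 5.5, 10), y = c(10.8, 10.5, 10.0)))

.anchor_coefs <- function() {
  sapply(.CLASS_ANCHORS, function(a)
    solve(cbind(1, a[, "t"], a[, "t"]^2), a[, "y"]))
}

.default_covariate_model <- function() {
  # Class-conditional distributions. Categorical entries are named
  # probability vectors; prevalences are set so that the implied
  # persistent-vs-remitting odds ratios match published adjusted ORs
  # (male 1.89, black Caribbean 1.96, affective diagnosis 0.17). DUP uses
  # gamma distributions with a shared shape, so the class-conditional
  # log-density ratio -- hence the implied logistic coefficient -- is exactly
  # linear in DUP with slope rate_remitting - rate_persistent = log(1.05).
  shp <- 1.3
  r_rem <- shp / 6                      # remitting mean DUP 6 months
  r_per <- r_rem - log(1.05)            # implied OR 1.05 per month
  base <- list(
    centre = c(London = 0.55, Nottingham = 0.45),
    sex = c(male = 0.44, female = 0.56),
    ethnicity = c(white_british = 0.45, black_caribbean = 0.22,
                  other = 0.33),
    education = c(university = 0.25, further = 0.40, school = 0.35),
    disadvantage_index = stats::setNames(c(0.35, 0.25, 0.18, 0.12, 0.10),
                                         0:4),
    premorbid_iq_quartile = stats::setNames(rep(0.25, 4), 1:4),
    diagnosis = c(affective = 0.45, non_affective = 0.55),
    mode_of_onset = c(acute = 0.55, insidious = 0.45),
    age_at_onset = list(mean = 28, sd = 9, min = 16, max = 64),
    dup_months = list(shape = shp, rate = r_rem),
    gaf_d = list(mean = 63.7, sd = 17.9),
    in_relationship = 0.38,
    employed = 0.35)
  poor <- base
  poor$centre <- c(London = 0.66, Nottingham = 0.34)
  poor$sex <- c(male = 0.60, female = 0.40)
  poor$ethnicity <- c(white_british = 0.34, black_caribbean = 0.356,
                      other = 0.304)
  poor$education <- c(university = 0.10, further = 0.38, school = 0.52)
  poor$disadvantage_index <- stats::setNames(c(0.15, 0.20, 0.22, 0.22, 0.21),
                                             0:4)
  poor$premorbid_iq_quartile <- stats::setNames(c(0.35, 0.28, 0.20, 0.17),
                                                4:1)[as.character(1:4)]
  poor$diagnosis <- c(affective = 0.122, non_affective = 0.878)
  poor$mode_of_onset <- c(acute = 0.35, insidious = 0.65)
  poor$dup_months <- list(shape = shp, rate = r_per)
  persistent <- poor
  persistent$gaf_d <- list(mean = 45.9, sd = 12.2)
  persistent$in_relationship <- 0.20
  persistent$employed <- 0.08
  late_decline <- poor                  # baseline profile resembles persistent
  late_decline$gaf_d <- list(mean = 41.2, sd = 17.4)
  late_decline$in_relationship <- 0.25
  late_decline$employed <- 0.12
  late_improvement <- base              # baseline profile resembles remitting
  late_improvement$dup_months <- list(shape = shp, rate = 0.35)
  late_improvement$gaf_d <- list(mean = 49.8, sd = 12.4)
  late_improvement$in_relationship <- 0.30
  late_improvement$employed <- 0.20
  list(remitting = base, late_decline = late_decline,
       late_improvement = late_improvement, persistent = persistent)
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults describe a first-episode psychosis cohort followed for about 10
#' years: 326 subjects split over four latent trajectory classes in the
#' proportions 58.5 / 5.6 / 5.4 / 30.6 percent, quadratic class mean curves
#' on the months-psychotic-per-year scale, subject-level random intercepts
#' and slopes, a monthly two-state chain with persistence `rho`, and
#' whole-year missing-at-random gaps.
#'
#' @param n_subjects Cohort size.
#' @param class_proportions Named simplex over
#'   `remitting, late_decline, late_improvement, persistent`.
#' @param class_curves `3 x 4` matrix of per-class quadratic coefficients
#'   (rows: intercept, linear, quadratic in the year `t = 1..10`; columns:
#'   classes) on the months-per-year scale.
#' @param random_effect_sds Length-2 vector `(sd_b0, sd_b1)`: SDs of the
#'   subject-level intercept (months/year) and slope (months/year per year)
#'   deviations.
#' @param residual_sd Extra year-level Gaussian noise added to the latent
#'   curve before conversion to monthly probabilities (default 0: all
#'   residual variation then comes from the monthly chain).
#' @param markov_persistence Probability `rho` in `[0, 1)` that a month
#'   simply carries the previous month's state forward.
#' @param missing_year_prob List with `base` (marginal probability that a
#'   subject-year is blanked) and `logodds` (named log-odds shifts per
#'   baseline covariate; names are either a numeric column or
#'   `"column=level"`). The masker sees covariates and time only, never the
#'   symptom values, so missingness is MAR by construction.
#' @param covariate_model Class-conditional covariate/outcome distributions;
#'   see the package vignette. Default calibrated to published adjusted odds
#'   ratios (male 1.89, black Caribbean 1.96, affective 0.17, DUP 1.05 per
#'   month) and GAF-D class means.
#' @param outcome_missing_prob Named vector of independent missingness
#'   probabilities for the follow-up outcomes.
#' @param followup_mean_years,followup_sd_years Normal distribution of
#'   per-subject follow-up length (clamped to 9.5--11 years).
#' @param seed Integer seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(
    n_subjects = 326L,
    class_proportions = c(remitting = 0.585, late_decline = 0.056,
                          late_improvement = 0.054, persistent = 0.306),
    class_curves = .anchor_coefs(),
    random_effect_sds = c(0.4, 0.04),
    residual_sd = 0,
    markov_persistence = 0.25,
    missing_year_prob = list(base = 0.04, logodds = numeric(0)),
    covariate_model = .default_covariate_model(),
    outcome_missing_prob = c(gaf_d = 0.15, in_relationship = 0.03,
                             employed = 0.11),
    followup_mean_years = 10.6,
    followup_sd_years = 1.1,
    seed = 1L) {
  if (length(class_proportions) != 4L)
    stop("class_proportions must have 4 entries")
  if (is.null(names(class_proportions)))
    names(class_proportions) <- .CLASS_NAMES
  if (any(class_proportions < 0) ||
      abs(sum(class_proportions) - 1) > 0.005)
    stop("class_proportions must be a simplex (non-negative, sum 1)")
  # published shares carry rounding (they sum to 100.1%); renormalise
  class_proportions <- class_proportions / sum(class_proportions)
  if (any(random_effect_sds < 0) || residual_sd < 0)
    stop("SDs must be >= 0")
  if (markov_persistence < 0 || markov_persistence >= 1)
    stop("markov_persistence must be in [0, 1)")
  if (missing_year_prob$base < 0 || missing_year_prob$base > 1)
    stop("missing_year_prob$base must be a probability")
  class_curves <- as.matrix(class_curves)
  if (!all(dim(class_curves) == c(3L, 4L)))
    stop("class_curves must be 3 x 4")
  colnames(class_curves) <- names(class_proportions)
  structure(list(
    n_subjects = as.integer(n_subjects),
    class_proportions = class_proportions,
    class_curves = class_curves,
    random_effect_sds = random_effect_sds,
    residual_sd = residual_sd,
    markov_persistence = markov_persistence,
    missing_year_prob = missing_year_prob,
    covariate_model = covariate_model,
    outcome_missing_prob = outcome_missing_prob,
    followup_mean_years = followup_mean_years,
    followup_sd_years = followup_sd_years,
    seed = as.integer(seed)),
    class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config> n=%d, classes %s, rho=%.2f, seed=%d\n",
              x$n_subjects,
              paste(sprintf("%s %.1f%%", names(x$class_proportions),
                            100 * x$class_proportions), collapse = ", "),
              x$markov_persistence, x$seed))
  invisible(x)
}

#' Simulate one subject's monthly symptom timeline
#'
#' The per-month presence probability is the subject's latent curve value on
#' the months-per-year scale divided by 12,
#' `p_m = clamp((b0k + b1k t + b2k t^2 + b0 + b1 t) / 12, 0, 1)` with `t` the
#' fractional year of month `m`, and months follow a two-state chain: with
#' probability `rho` the previous month's state carries forward, otherwise
#' the state is a fresh Bernoulli draw at `p_m`. The expected number of
#' symptomatic months per year therefore tracks the class curve.
#'
#' @param class_k Class index (1..4) or name.
#' @param subject_effects Length-2 numeric `(b0, b1)` subject deviation;
#'   optionally attribute-free extra year noise via `year_noise`.
#' @param cfg A [generator_config()].
#' @param followup_months Timeline length (default 120).
#' @param subject_id Identifier for the returned timeline.
#' @return A [monthly_timeline()] with no missing months (missingness is
#'   applied separately by [apply_missingness()]).
#' @export
simulate_monthly_series <- function(class_k, subject_effects, cfg,
                                    followup_months = 120L,
                                    subject_id = "sim") {
  if (is.character(class_k)) class_k <- match(class_k, .CLASS_NAMES)
  if (is.na(class_k) || class_k < 1L || class_k > 4L)
    stop("invalid class index")
  co <- cfg$class_curves[, class_k]
  m <- seq_len(followup_months) - 1L
  tfrac <- (m + 0.5) / 12 + 0.5          # mid-month, year scale 1..T
  mu <- co[1] + co[2] * tfrac + co[3] * tfrac^2 +
    subject_effects[1] + subject_effects[2] * tfrac
  if (cfg$residual_sd > 0) {
    yr <- pmin(floor(m / 12) + 1L, ceiling(followup_months / 12))
    eps <- stats::rnorm(max(yr), 0, cfg$residual_sd)
    mu <- mu + eps[yr]
  }
  p <- pmin(pmax(mu / 12, 0), 1)
  rho <- cfg$markov_persistence
  u <- stats::runif(followup_months)
  carry <- stats::runif(followup_months) < rho
  s <- integer(followup_months)
  s[1L] <- as.integer(u[1L] < p[1L])
  for (i in seq_len(followup_months - 1L) + 1L)
    s[i] <- if (carry[i]) s[i - 1L] else as.integer(u[i] < p[i])
  monthly_timeline(subject_id, ifelse(s == 1L, "P", "A"))
}

.draw_cat <- function(probs) sample(names(probs), 1L, prob = probs)

#' Simulate one subject's baseline covariates and follow-up outcomes
#'
#' Draws from the class-conditional distributions in
#' `cfg$covariate_model`. Categorical covariates are sampled from named
#' probability vectors, age from a truncated normal, DUP from a gamma
#' distribution, GAF-D from a class-specific normal clamped to 1--100.
#'
#' @param class_k Class index or name.
#' @param cfg A [generator_config()].
#' @param subject_id Identifier.
#' @return List with one-row data frames `baseline` and `outcome`.
#' @export
simulate_covariates <- function(class_k, cfg, subject_id = "sim") {
  if (is.character(class_k)) class_k <- match(class_k, .CLASS_NAMES)
  cm <- cfg$covariate_model[[class_k]]
  ag <- cm$age_at_onset
  age <- min(max(stats::rnorm(1, ag$mean, ag$sd), ag$min), ag$max)
  baseline <- data.frame(
    subject_id = subject_id,
    centre = .draw_cat(cm$centre),
    sex = .draw_cat(cm$sex),
    age_at_onset = round(age, 1),
    ethnicity = .draw_cat(cm$ethnicity),
    education = .draw_cat(cm$education),
    disadvantage_index = as.integer(.draw_cat(cm$disadvantage_index)),
    premorbid_iq_quartile = as.integer(.draw_cat(cm$premorbid_iq_quartile)),
    diagnosis = .draw_cat(cm$diagnosis),
    dup_months = round(stats::rgamma(1, shape = cm$dup_months$shape,
                                     rate = cm$dup_months$rate), 2),
    mode_of_onset = .draw_cat(cm$mode_of_onset),
    stringsAsFactors = FALSE)
  gaf <- min(max(stats::rnorm(1, cm$gaf_d$mean, cm$gaf_d$sd), 1), 100)
  outcome <- data.frame(
    subject_id = subject_id,
    gaf_d = round(gaf, 1),
    in_relationship = stats::runif(1) < cm$in_relationship,
    employed = stats::runif(1) < cm$employed,
    stringsAsFactors = FALSE)
  list(baseline = baseline, outcome = outcome)
}

#' Blank whole years of timeline data, missing at random
#'
#' Each subject-year is independently set to missing with probability
#' `plogis(qlogis(base) + sum of configured covariate log-odds)`. The
#' decision reads only the baseline covariates and the year index -- never
#' the symptom statuses being blanked -- so missingness is MAR by
#' construction.
#'
#' @param timelines Named list of [monthly_timeline()] objects.
#' @param baselines Baseline data frame aligned with `timelines`.
#' @param cfg A [generator_config()] (fields `missing_year_prob`).
#' @return The timelines with blanked years (`"M"` months).
#' @export
apply_missingness <- function(timelines, baselines, cfg) {
  myp <- cfg$missing_year_prob
  if (myp$base < 0 || myp$base > 1) stop("missing probability outside [0,1]")
  if (myp$base == 0 && !length(myp$logodds)) return(timelines)
  eta0 <- stats::qlogis(min(max(myp$base, 1e-12), 1 - 1e-12))
  shift <- rep(0, length(timelines))
  if (length(myp$logodds)) {
    for (nm in names(myp$logodds)) {
      if (grepl("=", nm, fixed = TRUE)) {
        parts <- strsplit(nm, "=", fixed = TRUE)[[1L]]
        x <- as.numeric(baselines[[parts[1L]]] == parts[2L])
      } else {
        x <- as.numeric(baselines[[nm]])
      }
      shift <- shift + myp$logodds[[nm]] * x
    }
  }
  p_i <- stats::plogis(eta0 + shift)
  if (myp$base == 1) p_i <- rep(1, length(timelines))
  for (i in seq_along(timelines)) {
    tl <- timelines[[i]]
    n_years <- ceiling(tl$followup_months / 12)
    blank <- stats::runif(n_years) < p_i[i]
    for (t in which(blank)) {
      mo <- (12L * (t - 1L) + 1L):min(12L * t, tl$followup_months)
      tl$statuses[mo] <- "M"
    }
    timelines[[i]] <- monthly_timeline(tl$subject_id, tl$statuses)
  }
  timelines
}

#' Simulate a full synthetic cohort
#'
#' Draws, per subject: a latent class from `class_proportions`; random
#' intercept/slope deviations; a follow-up length; a monthly timeline via
#' [simulate_monthly_series()]; baseline covariates and outcomes via
#' [simulate_covariates()]. Whole-year MAR missingness and outcome
#' missingness are applied last. Reproducible: the same config (including
#' seed) yields an identical cohort.
#'
#' @param cfg A [generator_config()].
#' @return List with elements `cohort` (a [cohort()]), `true_class` (named
#'   character vector of generating classes) and `config`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  set.seed(cfg$seed)
  n <- cfg$n_subjects
  ids <- sprintf("S%04d", seq_len(n))
  classes <- sample(names(cfg$class_proportions), n, replace = TRUE,
                    prob = cfg$class_proportions)
  fup <- pmin(pmax(round(12 * stats::rnorm(n, cfg$followup_mean_years,
                                           cfg$followup_sd_years)), 114L),
              132L)
  timelines <- vector("list", n)
  bl <- vector("list", n)
  oc <- vector("list", n)
  for (i in seq_len(n)) {
    b <- stats::rnorm(2, 0, cfg$random_effect_sds)
    timelines[[i]] <- simulate_monthly_series(classes[i], b, cfg,
                                              followup_months = fup[i],
                                              subject_id = ids[i])
    cv <- simulate_covariates(classes[i], cfg, subject_id = ids[i])
    bl[[i]] <- cv$baseline
    oc[[i]] <- cv$outcome
  }
  baseline <- do.call(rbind, bl)
  outcome <- do.call(rbind, oc)
  names(timelines) <- ids
  timelines <- apply_missingness(timelines, baseline, cfg)
  for (nm in names(cfg$outcome_missing_prob)) {
    miss <- stats::runif(n) < cfg$outcome_missing_prob[[nm]]
    outcome[[nm]][miss] <- NA
  }
  list(cohort = cohort(timelines, baseline, outcome),
       true_class = stats::setNames(classes, ids),
       config = cfg)
}

# ---- config file I/O -------------------------------------------------------

#' Read or write a generator configuration as JSON
#'
#' @param cfg A [generator_config()].
#' @param path File path.
#' @return `write_generator_config` returns the path invisibly;
#'   `read_generator_config` returns a `generator_config`.
#' @export
write_generator_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "generator_config"))
  # named atomic vectors must become JSON objects, not arrays, or their
  # names (category labels) would be lost in the round trip
  namedify <- function(x) {
    if (is.list(x)) lapply(x, namedify)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  jsonlite::write_json(namedify(unclass(cfg)), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cm <- lapply(x$covariate_model, function(cl) {
    for (nm in c("centre", "sex", "ethnicity", "education",
                 "disadvantage_index", "premorbid_iq_quartile",
                 "diagnosis", "mode_of_onset"))
      cl[[nm]] <- unlist(cl[[nm]])
    for (nm in c("age_at_onset", "dup_months", "gaf_d"))
      cl[[nm]] <- as.list(cl[[nm]])
    cl
  })
  generator_config(
    n_subjects = x$n_subjects,
    class_proportions = unlist(x$class_proportions),
    class_curves = if (is.matrix(x$class_curves)) x$class_curves else
      matrix(unlist(x$class_curves), 3, 4, byrow = TRUE),
    random_effect_sds = unlist(x$random_effect_sds),
    residual_sd = x$residual_sd,
    markov_persistence = x$markov_persistence,
    missing_year_prob = list(base = x$missing_year_prob$base,
                             logodds = unlist(x$missing_year_prob$logodds) %||%
                               numeric(0)),
    covariate_model = cm,
    outcome_missing_prob = unlist(x$outcome_missing_prob),
    followup_mean_years = x$followup_mean_years,
    followup_sd_years = x$followup_sd_years,
    seed = x$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
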