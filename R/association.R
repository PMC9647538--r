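# Baseline-covariate associations with trajectory class (pairwise logistic
# regressions against the remitting reference), the random-intercept
# logistic missingness check of the MAR assumption, and per-class outcome
# summaries.

.ADJUSTERS_DEFAULT <- c("centre", "sex", "age_at_onset", "ethnicity")

#' Odds ratios for baseline covariates by trajectory class
#'
#' Binary logistic regression of membership in a comparison class versus the
#' reference class (default `remitting`, the largest) on one covariate plus
#' adjusters, maximum-likelihood fitted with Wald 95% confidence intervals.
#' Categorical covariates yield one odds ratio per non-reference level;
#' numeric covariates (e.g. DUP in months) one odds ratio per unit. When
#' the covariate is itself one of the adjusters it is dropped from the
#' adjuster set.
#'
#' @param labels Named vector, subject id -> class label (e.g. from
#'   [modal_classes()]).
#' @param baselines Baseline data frame (column `subject_id`).
#' @param covariate Name of the baseline column of interest.
#' @param comparison Comparison class label (default `"persistent"`).
#' @param reference Reference class label (default `"remitting"`).
#' @param adjusters Character vector of adjuster columns; default centre,
#'   sex, age and ethnicity.
#' @return Data frame with one row per estimated contrast: `covariate`,
#'   `level`, `comparison`, `reference`, `or`, `ci_lo`, `ci_hi`, `n`.
#'   Separation or empty cells give `NA` odds ratios with a warning.
#' @export
class_association_or <- function(labels, baselines, covariate,
                                 comparison = "persistent",
                                 reference = "remitting",
                                 adjusters = .ADJUSTERS_DEFAULT) {
  stopifnot(covariate %in% names(baselines))
  adjusters <- setdiff(adjusters, covariate)
  adjusters <- intersect(adjusters, names(baselines))
  bl <- baselines[match(names(labels), baselines$subject_id), ,
                  drop = FALSE]
  keep <- labels %in% c(comparison, reference) & !is.na(bl$subject_id)
  d <- bl[keep, , drop = FALSE]
  d$.y <- as.integer(labels[keep] == comparison)
  for (v in c(covariate, adjusters))
    if (is.character(d[[v]])) d[[v]] <- factor(d[[v]])
  fml <- stats::reformulate(c(covariate, adjusters), response = ".y")
  fit <- tryCatch(
    stats::glm(fml, data = d, family = stats::binomial()),
    error = function(e) NULL, warning = function(w) {
      suppressWarnings(stats::glm(fml, data = d,
                                  family = stats::binomial()))
    })
  empty_row <- function(lv) data.frame(
    covariate = covariate, level = lv, comparison = comparison,
    reference = reference, or = NA_real_, ci_lo = NA_real_,
    ci_hi = NA_real_, n = nrow(d), stringsAsFactors = FALSE)
  if (is.null(fit)) {
    warning("logistic fit failed for ", covariate)
    return(empty_row(NA_character_))
  }
  cf <- summary(fit)$coefficients
  idx <- grep(paste0("^", covariate), rownames(cf))
  if (!length(idx)) {
    warning("no estimable contrast for ", covariate)
    return(empty_row(NA_character_))
  }
  out <- lapply(idx, function(i) {
    b <- cf[i, 1]
    se <- cf[i, 2]
    lv <- sub(paste0("^", covariate), "", rownames(cf)[i])
    if (!nzchar(lv)) lv <- "per_unit"
    if (abs(b) > 10 || se > 10) {
      warning("separation / empty cell for ", covariate, " level ", lv)
      return(empty_row(lv))
    }
    data.frame(covariate = covariate, level = lv, comparison = comparison,
               reference = reference, or = exp(b),
               ci_lo = exp(b - 1.96 * se), ci_hi = exp(b + 1.96 * se),
               n = nrow(d), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Full class-association table (every covariate, every comparison class)
#'
#' @param labels,baselines As in [class_association_or()].
#' @param covariates Columns to test (default: all baseline columns except
#'   the id).
#' @param comparisons Comparison classes (default: every label except the
#'   reference).
#' @param reference Reference class.
#' @param adjusters Adjuster columns.
#' @return Row-bound data frame of [class_association_or()] results.
#' @export
association_table <- function(labels, baselines,
                              covariates = setdiff(names(baselines),
                                                   "subject_id"),
                              comparisons = NULL,
                              reference = "remitting",
                              adjusters = .ADJUSTERS_DEFAULT) {
  if (is.null(comparisons))
    comparisons <- setdiff(unique(labels), reference)
  out <- list()
  for (cmp in comparisons)
    for (cv in covariates)
      out[[paste(cmp, cv)]] <- tryCatch(
        class_association_or(labels, baselines, cv, comparison = cmp,
                             reference = reference, adjusters = adjusters),
        error = function(e) NULL)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Random-intercept logistic check of the MAR assumption
#'
#' Builds the subject-year missingness indicator from the annual series and
#' regresses it on each baseline covariate in turn with a subject-level
#' random intercept (`lme4::glmer`). A strong association between an
#' observed covariate and missingness would not itself violate MAR, but the
#' absence of such associations supports treating the timeline gaps as
#' ignorable.
#'
#' @param x A `psytraj_cohort`.
#' @param covariates Baseline columns to test (default all but the id).
#' @param T Follow-up horizon in years.
#' @return Data frame with `covariate`, `level`, `estimate` (log-odds),
#'   `se`, `z`, `p`, `converged`. Degenerate cases (no missingness at all,
#'   or none of a covariate level) are flagged, not errors.
#' @export
missingness_mar_check <- function(x, covariates = NULL, T = 10L) {
  stopifnot(inherits(x, "psytraj_cohort"))
  if (is.null(covariates))
    covariates <- setdiff(names(x$baseline), "subject_id")
  Y <- annual_matrix(x, T)
  miss <- is.na(Y)
  # drop years beyond each subject's follow-up (structurally absent, not
  # "missing ratings"): a year entirely past follow-up is not informative
  fup <- vapply(x$timelines, `[[`, integer(1), "followup_months")
  for (i in seq_len(nrow(miss))) {
    past <- which((seq_len(T) - 1L) * 12L >= fup[i])
    if (length(past)) miss[i, past] <- NA
  }
  long <- data.frame(
    subject_id = rep(rownames(Y), times = T),
    year = rep(seq_len(T), each = nrow(Y)),
    miss = as.integer(as.vector(miss)))
  long <- long[!is.na(long$miss), ]
  long <- merge(long, x$baseline, by = "subject_id")
  rows <- list()
  if (sum(long$miss) == 0 || all(long$miss == 1)) {
    warning("degenerate missingness (all observed or all missing); ",
            "model not identifiable")
    return(data.frame(covariate = covariates, level = NA_character_,
                      estimate = NA_real_, se = NA_real_, z = NA_real_,
                      p = NA_real_, converged = FALSE,
                      stringsAsFactors = FALSE))
  }
  for (cv in covariates) {
    d <- long
    if (is.character(d[[cv]])) d[[cv]] <- factor(d[[cv]])
    fml <- stats::as.formula(paste("miss ~", cv, "+ (1 | subject_id)"))
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::glmer(fml, data = d, family = stats::binomial(),
                    nAGQ = 1L))),
      error = function(e) NULL)
    if (is.null(fit)) {
      rows[[cv]] <- data.frame(covariate = cv, level = NA_character_,
                               estimate = NA_real_, se = NA_real_,
                               z = NA_real_, p = NA_real_,
                               converged = FALSE, stringsAsFactors = FALSE)
      next
    }
    cf <- stats::coef(summary(fit))
    idx <- grep(paste0("^", cv), rownames(cf))
    conv <- length(fit@optinfo$conv$lme4) == 0L
    rows[[cv]] <- do.call(rbind, lapply(idx, function(i) {
      lv <- sub(paste0("^", cv), "", rownames(cf)[i])
      if (!nzchar(lv)) lv <- "per_unit"
      data.frame(covariate = cv, level = lv, estimate = cf[i, 1],
                 se = cf[i, 2], z = cf[i, 3],
                 p = 2 * stats::pnorm(-abs(cf[i, 3])),
                 converged = conv, stringsAsFactors = FALSE)
    }))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Per-class outcome summaries with one-way F test
#'
#' For a numeric outcome: per-class mean, SD and n (missing values
#' excluded) plus the classical one-way ANOVA F statistic across classes.
#' For logical outcomes: per-class proportions.
#'
#' @param labels Named vector, subject id -> class label.
#' @param outcomes Outcome data frame (column `subject_id`).
#' @param variable Outcome column (default `"gaf_d"`).
#' @return List with `by_class` (data frame) and, for numeric outcomes,
#'   `F`, `df`, `p` (all `NA` when fewer than 2 classes have data).
#' @export
outcome_summaries <- function(labels, outcomes, variable = "gaf_d") {
  stopifnot(variable %in% names(outcomes))
  oc <- outcomes[match(names(labels), outcomes$subject_id), , drop = FALSE]
  v <- oc[[variable]]
  keep <- !is.na(v) & !is.na(oc$subject_id)
  v <- v[keep]
  l <- labels[keep]
  if (is.logical(v)) {
    by_class <- do.call(rbind, lapply(split(v, l), function(x)
      data.frame(n = length(x), proportion = mean(x))))
    return(list(by_class = data.frame(class = rownames(by_class), by_class,
                                      row.names = NULL)))
  }
  by_class <- do.call(rbind, lapply(split(v, l), function(x)
    data.frame(n = length(x), mean = mean(x),
               sd = if (length(x) >= 2) stats::sd(x) else NA_real_)))
  by_class <- data.frame(class = rownames(by_class), by_class,
                         row.names = NULL, stringsAsFactors = FALSE)
  groups <- unique(l)
  if (length(groups) < 2L)
    return(list(by_class = by_class, F = NA_real_, df = c(NA, NA),
                p = NA_real_))
  fit <- stats::lm(v ~ factor(l))
  a <- stats::anova(fit)
  list(by_class = by_class, F = a$`F value`[1],
       df = c(a$Df[1], a$Df[2]), p = a$`Pr(>F)`[1])
}
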