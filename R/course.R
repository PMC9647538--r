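# Classical course typology: maximal runs of presence/absence, the 6-month
# episodic/continuous/neither rules, the 2-year symptomatic recovery rule,
# and trajectory-by-outcome cross-tabulations.

#' Extract maximal symptom runs from a timeline
#'
#' Returns the alternating runs of consecutive `PRESENT` / `ABSENT` months.
#' Short missing gaps (at most `bridge` months) flanked on both sides by the
#' same state are bridged -- assigned that state and absorbed into the
#' surrounding run. Longer gaps, gaps with disagreeing flanks, and leading /
#' trailing missing months split the sequence: runs on either side stay
#' separate.
#'
#' @param tl A [monthly_timeline()].
#' @param bridge Longest missing gap (months) that may be bridged
#'   (default 2).
#' @return Data frame with columns `state` (`"P"`/`"A"`), `start_month`
#'   (0-based) and `length_months`; zero rows for an all-missing timeline.
#' @examples
#' extract_runs(monthly_timeline("s", c("P", "M", "P", "A", "A")))
#' @export
extract_runs <- function(tl, bridge = 2L) {
  stopifnot(inherits(tl, "monthly_timeline"))
  st <- tl$statuses
  r <- rle(st)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # bridge short interior missing gaps with agreeing flanks
  for (j in seq_along(r$values)) {
    if (r$values[j] == "M" && r$lengths[j] <= bridge &&
        j > 1L && j < length(r$values) &&
        r$values[j - 1L] == r$values[j + 1L]) {
      st[starts[j]:ends[j]] <- r$values[j - 1L]
    }
  }
  r2 <- rle(st)
  ends2 <- cumsum(r2$lengths)
  starts2 <- ends2 - r2$lengths + 1L
  keep <- r2$values != "M"
  data.frame(state = r2$values[keep],
             start_month = starts2[keep] - 1L,
             length_months = r2$lengths[keep],
             stringsAsFactors = FALSE)
}

#' Classify a run sequence into the classical course types
#'
#' The traditional typology with a 6-month cut point: `episodic` when no
#' symptomatic episode lasted 6 months or more; otherwise `continuous` when
#' no remission lasted 6 months or more; otherwise `neither` (an episode of
#' 6+ months and a remission of 6+ months both occurred). A timeline with
#' neither long episodes nor long remissions is episodic. No rateable months
#' at all gives `unclassifiable`.
#'
#' @param runs Data frame from [extract_runs()] (or a `monthly_timeline`,
#'   which is converted first).
#' @param cut_months Episode/remission length threshold (default 6).
#' @return One of `"episodic"`, `"continuous"`, `"neither"`,
#'   `"unclassifiable"`.
#' @export
classify_course <- function(runs, cut_months = 6L) {
  if (inherits(runs, "monthly_timeline")) runs <- extract_runs(runs)
  if (!nrow(runs)) return("unclassifiable")
  long_episode <- any(runs$state == "P" & runs$length_months >= cut_months)
  long_remission <- any(runs$state == "A" & runs$length_months >= cut_months)
  if (!long_episode) "episodic"
  else if (!long_remission) "continuous"
  else "neither"
}

#' Symptomatic recovery at follow-up
#'
#' A subject counts as recovered when the final 24 months of the timeline
#' contain no month rated symptomatic and at least 12 of them were actually
#' rated (clear-information rule). Follow-ups shorter than 24 months are
#' unclassifiable (`NA`).
#'
#' @param tl A [monthly_timeline()].
#' @return `TRUE`, `FALSE`, or `NA` (unclassifiable); the reason for `FALSE`
#'   / `NA` is attached as attribute `"reason"` when informative.
#' @export
assess_recovery <- function(tl) {
  stopifnot(inherits(tl, "monthly_timeline"))
  M <- tl$followup_months
  if (M < 24L)
    return(structure(NA, reason = "follow-up shorter than 24 months"))
  tail24 <- tl$statuses[(M - 23L):M]
  if (any(tail24 == "P")) return(FALSE)
  if (sum(tail24 != "M") < 12L)
    return(structure(FALSE, reason = "fewer than 12 rated months"))
  TRUE
}

#' Per-subject course and recovery table for a cohort
#'
#' @param x A `psytraj_cohort`.
#' @return Data frame with `subject_id`, `course`, `recovered`.
#' @export
course_table <- function(x) {
  stopifnot(inherits(x, "psytraj_cohort"))
  data.frame(
    subject_id = subject_ids(x),
    course = vapply(x$timelines, function(tl)
      classify_course(extract_runs(tl)), character(1)),
    recovered = vapply(x$timelines, function(tl)
      as.logical(assess_recovery(tl)), logical(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Cross-tabulate trajectory class against a course or outcome variable
#'
#' For a categorical factor: counts plus row and column percentages. For a
#' numeric outcome (e.g. GAF-D): per-class mean, SD and n. No test
#' statistics are computed.
#'
#' @param labels Named vector (subject id -> class label), e.g. modal class
#'   assignments.
#' @param factor Named vector (subject id -> value); character/factor/
#'   logical values give a contingency table, numeric values per-class
#'   summaries. Missing values are dropped (and counted).
#' @return For categorical input, a list with `counts`, `row_pct`,
#'   `col_pct`, `n_missing`; for numeric input a data frame with `class`,
#'   `n`, `mean`, `sd`, plus `n_missing` as an attribute.
#' @export
crosstab_class_by <- function(labels, factor) {
  ids <- intersect(names(labels), names(factor))
  if (!length(ids)) stop("labels and factor share no subject ids")
  l <- labels[ids]
  f <- factor[ids]
  drop <- is.na(f)
  n_missing <- sum(drop)
  l <- l[!drop]
  f <- f[!drop]
  if (is.numeric(f)) {
    out <- do.call(rbind, lapply(split(f, l), function(v)
      data.frame(n = length(v), mean = mean(v),
                 sd = if (length(v) >= 2) stats::sd(v) else NA_real_)))
    out <- data.frame(class = rownames(out), out, row.names = NULL,
                      stringsAsFactors = FALSE)
    attr(out, "n_missing") <- n_missing
    return(out)
  }
  counts <- table(class = l, value = as.character(f))
  list(counts = counts,
       row_pct = prop.table(counts, 1) * 100,
       col_pct = prop.table(counts, 2) * 100,
       n_missing = n_missing)
}

#' Modal class labels for a fitted model
#'
#' Convenience: hard (modal) assignment of every subject, optionally mapped
#' through [label_classes()] names.
#'
#' @param fit A `gmm_fit`.
#' @param labels Optional per-class label vector (default
#'   [label_classes()]).
#' @return Named character vector, subject id -> class label.
#' @export
modal_classes <- function(fit, labels = label_classes(fit)) {
  m <- max.col(fit$posteriors, ties.method = "first")
  stats::setNames(labels[m], rownames(fit$posteriors))
}
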