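# Core data types for month-by-month symptom timelines and their annual
# aggregation.  A cohort bundles timelines with a baseline covariate table and
# a follow-up outcome table, joined on subject_id.

#' Monthly symptom status codes
#'
#' Timelines use three single-letter codes per month: `"P"` (psychotic
#' symptoms present), `"A"` (absent) and `"M"` (missing -- insufficient
#' information to rate the month either way).
#'
#' @format Character vector of length 3.
#' @export
STATUS_CODES <- c(PRESENT = "P", ABSENT = "A", MISSING = "M")

#' Construct a monthly symptom timeline
#'
#' A timeline records, for one subject, the presence or absence of psychotic
#' symptoms for every month from first presentation onward. Months that could
#' not be rated are coded missing.
#'
#' @param subject_id Scalar identifier (coerced to character).
#' @param statuses Character vector over months `0..M-1`, each element one of
#'   `"P"`, `"A"`, `"M"`.
#' @return An object of class `monthly_timeline`: a list with elements
#'   `subject_id`, `statuses` and `followup_months`.
#' @examples
#' tl <- monthly_timeline("s1", c("P", "P", "A", "M", "A"))
#' tl$followup_months
#' @export
monthly_timeline <- function(subject_id, statuses) {
  if (length(subject_id) != 1L || is.na(subject_id))
    stop("subject_id must be a non-missing scalar")
  statuses <- as.character(statuses)
  if (length(statuses) < 1L)
    stop("a timeline needs at least one month")
  bad <- which(!statuses %in% STATUS_CODES)
  if (length(bad))
    stop(sprintf("subject %s: invalid status code '%s' at month %d",
                 subject_id, statuses[bad[1L]], bad[1L] - 1L))
  structure(
    list(subject_id = as.character(subject_id),
         statuses = statuses,
         followup_months = length(statuses)),
    class = "monthly_timeline")
}

#' @export
print.monthly_timeline <- function(x, ...) {
  cat(sprintf("<monthly_timeline> subject %s, %d months (%d P / %d A / %d M)\n",
              x$subject_id, x$followup_months,
              sum(x$statuses == "P"), sum(x$statuses == "A"),
              sum(x$statuses == "M")))
  invisible(x)
}

#' Assemble a cohort from timelines, baseline and outcome tables
#'
#' Joins the three components on `subject_id`. The timeline collection defines
#' cohort membership: baseline or outcome rows for subjects without a timeline
#' are dropped with a message (mirroring analyses that include only subjects
#' for whom a symptom timeline could be completed).
#'
#' @param timelines List of [monthly_timeline()] objects.
#' @param baseline Data frame with one row per subject (column `subject_id`
#'   plus covariates). May be `NULL`.
#' @param outcome Data frame with one row per subject (column `subject_id`
#'   plus follow-up outcomes). May be `NULL`.
#' @return An object of class `psytraj_cohort`.
#' @export
cohort <- function(timelines, baseline = NULL, outcome = NULL) {
  if (length(timelines)) {
    ok <- vapply(timelines, inherits, logical(1), "monthly_timeline")
    if (!all(ok)) stop("timelines must all be monthly_timeline objects")
    ids <- vapply(timelines, `[[`, character(1), "subject_id")
    if (anyDuplicated(ids))
      stop("duplicate subject_id in timelines: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    names(timelines) <- ids
  } else {
    ids <- character(0)
  }
  join_tab <- function(tab, what) {
    if (is.null(tab)) return(NULL)
    tab <- as.data.frame(tab)
    if (!"subject_id" %in% names(tab))
      stop(what, " table lacks a subject_id column")
    tab$subject_id <- as.character(tab$subject_id)
    if (anyDuplicated(tab$subject_id))
      stop("duplicate subject_id in ", what, " table")
    drop <- setdiff(tab$subject_id, ids)
    if (length(drop)) {
      message(sprintf("%d %s row(s) without a timeline excluded: %s",
                      length(drop), what,
                      paste(utils::head(drop, 5), collapse = ", ")))
      tab <- tab[tab$subject_id %in% ids, , drop = FALSE]
    }
    m <- match(ids, tab$subject_id)
    tab[m[!is.na(m)], , drop = FALSE]
  }
  baseline <- join_tab(baseline, "baseline")
  outcome <- join_tab(outcome, "outcome")
  rownames(baseline) <- NULL
  rownames(outcome) <- NULL
  structure(list(timelines = timelines, baseline = baseline,
                 outcome = outcome),
            class = "psytraj_cohort")
}

#' @export
print.psytraj_cohort <- function(x, ...) {
  fm <- vapply(x$timelines, `[[`, integer(1), "followup_months")
  cat(sprintf("<psytraj_cohort> %d subjects, follow-up %d-%d months\n",
              length(x$timelines),
              if (length(fm)) min(fm) else 0L,
              if (length(fm)) max(fm) else 0L))
  if (!is.null(x$baseline))
    cat("  baseline covariates:",
        paste(setdiff(names(x$baseline), "subject_id"), collapse = ", "), "\n")
  if (!is.null(x$outcome))
    cat("  outcomes:",
        paste(setdiff(names(x$outcome), "subject_id"), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.psytraj_cohort <- function(x) length(x$timelines)

#' Subject identifiers of a cohort
#' @param x A `psytraj_cohort`.
#' @return Character vector of subject ids, in cohort order.
#' @export
subject_ids <- function(x) {
  stopifnot(inherits(x, "psytraj_cohort"))
  names(x$timelines)
}

# ---- file I/O --------------------------------------------------------------

#' Read a cohort from long-format delimited files
#'
#' The timeline file is long format with columns `subject_id`, `month`
#' (0-based integer) and `status` (`P`/`A`/`M`). Baseline and outcome files
#' have one row per subject. Any of `baseline_path` / `outcome_path` may be
#' `NULL`.
#'
#' Unknown status codes and duplicated (subject, month) pairs are hard errors
#' naming the offending row; months must form a gapless `0..M-1` sequence per
#' subject. Baseline/outcome rows for subjects absent from the timeline file
#' are excluded with a message.
#'
#' @param timeline_path,baseline_path,outcome_path File paths (CSV).
#' @return A [cohort()] object.
#' @export
read_cohort <- function(timeline_path, baseline_path = NULL,
                        outcome_path = NULL) {
  tl <- utils::read.csv(timeline_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "month", "status")
  if (!all(need %in% names(tl)))
    stop("timeline file must have columns: ", paste(need, collapse = ", "))
  tl$subject_id <- as.character(tl$subject_id)
  bad <- which(!tl$status %in% STATUS_CODES)
  if (length(bad))
    stop(sprintf("timeline row %d (subject %s, month %s): unknown status '%s'",
                 bad[1L], tl$subject_id[bad[1L]], tl$month[bad[1L]],
                 tl$status[bad[1L]]))
  key <- paste(tl$subject_id, tl$month)
  dup <- which(duplicated(key))
  if (length(dup))
    stop(sprintf("timeline row %d: duplicate (subject %s, month %s)",
                 dup[1L], tl$subject_id[dup[1L]], tl$month[dup[1L]]))
  tls <- lapply(split(tl, tl$subject_id), function(d) {
    d <- d[order(d$month), , drop = FALSE]
    if (!identical(as.integer(d$month), seq_len(nrow(d)) - 1L))
      stop("subject ", d$subject_id[1L],
           ": months must form a gapless 0..M-1 sequence")
    monthly_timeline(d$subject_id[1L], d$status)
  })
  # preserve first-appearance order of the file
  tls <- tls[unique(tl$subject_id)]
  read_tab <- function(p) {
    if (is.null(p)) return(NULL)
    utils::read.csv(p, stringsAsFactors = FALSE)
  }
  cohort(tls, read_tab(baseline_path), read_tab(outcome_path))
}

#' Write a cohort to long-format delimited files
#'
#' Inverse of [read_cohort()]: `read_cohort()` applied to the written files
#' reproduces the cohort exactly (round-trip identity). Tables that are absent
#' from the cohort are skipped unless a path was given, in which case a
#' header-only file is written.
#'
#' @param x A `psytraj_cohort`.
#' @param timeline_path,baseline_path,outcome_path Output file paths; the
#'   baseline/outcome paths may be `NULL`.
#' @return Invisibly, the vector of paths written.
#' @export
write_cohort <- function(x, timeline_path, baseline_path = NULL,
                         outcome_path = NULL) {
  stopifnot(inherits(x, "psytraj_cohort"))
  rows <- lapply(x$timelines, function(tl)
    data.frame(subject_id = tl$subject_id,
               month = seq_along(tl$statuses) - 1L,
               status = tl$statuses, stringsAsFactors = FALSE))
  tl <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(), month = integer(),
               status = character())
  written <- character(0)
  wr <- function(d, p) {
    tryCatch(utils::write.csv(d, p, row.names = FALSE, quote = FALSE),
             error = function(e) stop("cannot write ", p, ": ",
                                      conditionMessage(e)))
    p
  }
  written <- c(written, wr(tl, timeline_path))
  if (!is.null(baseline_path)) {
    b <- x$baseline
    if (is.null(b)) b <- data.frame(subject_id = character())
    written <- c(written, wr(b, baseline_path))
  }
  if (!is.null(outcome_path)) {
    o <- x$outcome
    if (is.null(o)) o <- data.frame(subject_id = character())
    written <- c(written, wr(o, outcome_path))
  }
  invisible(written)
}

#' Read or write a whole cohort as one bundled JSON file
#'
#' Convenience for fixtures and transport: the three cohort tables in a
#' single structured-text file. `read_cohort_bundle(write_cohort_bundle(x))`
#' is the identity on validated cohorts.
#'
#' @param x A `psytraj_cohort`.
#' @param path File path (JSON).
#' @return `write_cohort_bundle` returns the path invisibly;
#'   `read_cohort_bundle` returns a [cohort()].
#' @export
write_cohort_bundle <- function(x, path) {
  stopifnot(inherits(x, "psytraj_cohort"))
  tls <- lapply(x$timelines, function(tl)
    paste(tl$statuses, collapse = ""))
  jsonlite::write_json(
    list(timelines = tls, baseline = x$baseline, outcome = x$outcome),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_cohort_bundle
#' @export
read_cohort_bundle <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  tls <- lapply(names(b$timelines), function(id)
    monthly_timeline(id, strsplit(b$timelines[[id]], "")[[1L]]))
  as_tab <- function(d) {
    if (is.null(d) || (is.data.frame(d) && !nrow(d))) return(NULL)
    as.data.frame(d, stringsAsFactors = FALSE)
  }
  cohort(tls, as_tab(b$baseline), as_tab(b$outcome))
}

# ---- annual aggregation ----------------------------------------------------

#' Aggregate a monthly timeline to months-psychotic-per-year
#'
#' Year `t` (1-based) covers months `12(t-1) .. 12t-1`. Months beyond the
#' subject's follow-up count as unrated. A year with more than 6 of its 12
#' month-slots unrated is missing (`NA`); otherwise the observed fraction of
#' symptomatic months is rescaled to a 12-month basis:
#' `y_t = 12 * n_present / n_observed`, so `y_t` always lies in `[0, 12]`.
#'
#' @param tl A [monthly_timeline()].
#' @param T Follow-up horizon in years (default 10). Longer follow-ups are
#'   truncated; years entirely beyond follow-up are `NA`.
#' @return An object of class `annual_series`: list with `subject_id`,
#'   `y` (numeric length `T`, `NA` = missing) and `T`.
#' @examples
#' tl <- monthly_timeline("s1", rep(c("P", "A"), each = 6))
#' aggregate_to_annual(tl, T = 1)$y  # 6 present of 12 observed -> 6
#' @export
aggregate_to_annual <- function(tl, T = 10L) {
  stopifnot(inherits(tl, "monthly_timeline"))
  T <- as.integer(T)
  if (T < 1L) stop("T must be >= 1")
  y <- rep(NA_real_, T)
  for (t in seq_len(T)) {
    mo <- (12L * (t - 1L)):(12L * t - 1L)
    mo <- mo[mo < tl$followup_months]
    st <- tl$statuses[mo + 1L]
    n_obs <- sum(st != "M")
    if (12L - n_obs > 6L) next  # unrated slots (missing or past follow-up)
    y[t] <- 12 * sum(st == "P") / n_obs
  }
  structure(list(subject_id = tl$subject_id, y = y, T = T),
            class = "annual_series")
}

#' @export
print.annual_series <- function(x, ...) {
  cat(sprintf("<annual_series> subject %s, T=%d\n  y: %s\n", x$subject_id,
              x$T, paste(ifelse(is.na(x$y), "NA", sprintf("%.2f", x$y)),
                         collapse = " ")))
  invisible(x)
}

#' Annual outcome matrix for a whole cohort
#'
#' Applies [aggregate_to_annual()] to every subject and stacks the results
#' into the `n x T` outcome matrix consumed by [fit_gmm()].
#'
#' @param x A `psytraj_cohort`.
#' @param T Follow-up horizon in years.
#' @return Numeric matrix (rownames = subject ids); `NA` marks missing years.
#' @export
annual_matrix <- function(x, T = 10L) {
  stopifnot(inherits(x, "psytraj_cohort"))
  Y <- t(vapply(x$timelines, function(tl) aggregate_to_annual(tl, T)$y,
                numeric(T)))
  rownames(Y) <- subject_ids(x)
  Y
}
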