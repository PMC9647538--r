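# End-to-end orchestration: simulate or read a cohort, aggregate, check
# missingness, run the model ladder, select and label the final model,
# classify classical course, cross-tabulate and estimate covariate
# associations; write every artefact with the configuration and seeds
# echoed so a bundle can be regenerated exactly.

#' Pipeline configuration
#'
#' Exactly one of `input_paths` (list with `timeline`, `baseline`,
#' `outcome`) or `generator` (a [generator_config()]) must be given.
#'
#' @param input_paths List of cohort file paths, or `NULL`.
#' @param generator A [generator_config()], or `NULL`.
#' @param T Follow-up horizon (years).
#' @param degrees,random_effects,K_max Model-ladder grid.
#' @param n_starts Starts per ladder cell.
#' @param blrt_draws Bootstrap draws for the final k vs k-1 test (0 skips
#'   it).
#' @param seed Master seed; stage-level seeds are derived from it.
#' @param output_dir Where [run_pipeline()] writes artefacts (`NULL`: write
#'   nothing).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_paths = NULL, generator = NULL, T = 10L,
                            degrees = c(1L, 2L),
                            random_effects = c("none", "intercept_slope"),
                            K_max = 6L, n_starts = 20L, blrt_draws = 0L,
                            seed = 1L, output_dir = NULL) {
  if (is.null(input_paths) == is.null(generator))
    stop("exactly one of input_paths or generator must be supplied")
  structure(list(input_paths = input_paths, generator = generator, T = T,
                 degrees = degrees, random_effects = random_effects,
                 K_max = K_max, n_starts = n_starts,
                 blrt_draws = blrt_draws, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

# Named sub-streams of the master seed, kept below 2^31.
.substream <- function(seed, stream) {
  offs <- c(generator = 104729L, ladder = 130363L, blrt = 499979L)
  (as.integer(seed) * 31L + offs[[stream]]) %% 2147483000L
}

#' Run the full trajectory-analysis pipeline
#'
#' Stages run in order: simulate/read, aggregate, MAR missingness check,
#' model ladder, selection, labelling, classical course classification,
#' cross-tabulations, covariate associations. A stage failure marks the
#' bundle partial (element `failed_stage`) instead of aborting. Identical
#' configurations (including seeds) produce identical bundles.
#'
#' @param cfg A [pipeline_config()].
#' @return A `pipeline_bundle` list; see [render_report()].
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  bundle <- list(config = cfg, created = "run_pipeline",
                 failed_stage = NULL)
  failed <- NULL
  stage <- function(name, expr) {
    if (!is.null(failed)) return(NULL)
    tryCatch(expr, error = function(e) {
      failed <<- paste0(name, ": ", conditionMessage(e))
      NULL
    })
  }
  inp <- stage("input", {
    if (!is.null(cfg$generator)) {
      gen <- cfg$generator
      gen$seed <- .substream(cfg$seed, "generator")
      sim <- simulate_cohort(gen)
      list(cohort = sim$cohort, true_class = sim$true_class)
    } else {
      list(cohort = read_cohort(cfg$input_paths$timeline,
                                cfg$input_paths$baseline,
                                cfg$input_paths$outcome),
           true_class = NULL)
    }
  })
  bundle$cohort <- inp$cohort
  bundle$true_class <- inp$true_class
  bundle$Y <- stage("aggregate", annual_matrix(bundle$cohort, cfg$T))
  bundle$mar_check <- stage("mar_check", suppressWarnings(
    missingness_mar_check(bundle$cohort, T = cfg$T)))
  bundle$ladder <- stage("ladder", run_model_ladder(
    bundle$Y, degrees = cfg$degrees, random_effects = cfg$random_effects,
    K_max = cfg$K_max, n_starts = cfg$n_starts,
    seed = .substream(cfg$seed, "ladder")))
  bundle$selection <- stage("select", select_final_model(bundle$ladder))
  bundle$fit <- stage("final_fit",
                      attr(bundle$ladder, "fits")[[bundle$selection$selected]])
  bundle$labels <- stage("label", label_classes(bundle$fit))
  bundle$modal <- stage("modal", modal_classes(bundle$fit, bundle$labels))
  if (cfg$blrt_draws > 0L) {
    bundle$blrt <- stage("blrt", {
      sel <- bundle$selection$table[bundle$selection$selected, ]
      fits <- attr(bundle$ladder, "fits")
      tab <- as.data.frame(bundle$ladder)
      i_prev <- which(tab$degree == sel$degree &
                        tab$random_effects == sel$random_effects &
                        tab$K == sel$K - 1L & !tab$failed)
      if (length(i_prev) == 1L && sel$K > 1L)
        bootstrap_lrt(bundle$Y, bundle$fit, fits[[i_prev]],
                      B = cfg$blrt_draws,
                      seed = .substream(cfg$seed, "blrt"))
      else NULL
    })
  }
  bundle$course <- stage("course", course_table(bundle$cohort))
  bundle$crosstabs <- stage("crosstab", {
    co <- stats::setNames(bundle$course$course, bundle$course$subject_id)
    rec <- stats::setNames(bundle$course$recovered,
                           bundle$course$subject_id)
    list(course = crosstab_class_by(bundle$modal, co),
         recovery = crosstab_class_by(bundle$modal, rec))
  })
  bundle$gaf <- stage("outcomes", outcome_summaries(
    bundle$modal, bundle$cohort$outcome, "gaf_d"))
  bundle$associations <- stage("associate", suppressWarnings(
    association_table(bundle$modal, bundle$cohort$baseline)))
  bundle$failed_stage <- failed
  class(bundle) <- "pipeline_bundle"
  if (!is.null(cfg$output_dir)) .write_bundle(bundle, cfg$output_dir)
  bundle
}

.write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f) utils::write.csv(d, file.path(dir, f),
                                       row.names = FALSE)
  write_cohort(bundle$cohort, file.path(dir, "timeline.csv"),
               file.path(dir, "baseline.csv"),
               file.path(dir, "outcome.csv"))
  if (!is.null(bundle$ladder)) w(as.data.frame(bundle$ladder), "ladder.csv")
  if (!is.null(bundle$selection))
    writeLines(bundle$selection$trace, file.path(dir, "selection_trace.txt"))
  if (!is.null(bundle$course)) w(bundle$course, "course.csv")
  if (!is.null(bundle$associations)) w(bundle$associations,
                                       "associations.csv")
  if (!is.null(bundle$mar_check)) w(bundle$mar_check, "mar_check.csv")
  if (!is.null(bundle$modal))
    w(data.frame(subject_id = names(bundle$modal), class = bundle$modal),
      "modal_class.csv")
  if (!is.null(bundle$fit)) {
    post <- data.frame(subject_id = rownames(bundle$fit$posteriors),
                       bundle$fit$posteriors)
    w(post, "posteriors.csv")
  }
  writeLines(render_report(bundle), file.path(dir, "report.txt"))
  cfg <- bundle$config
  if (!is.null(cfg$generator)) cfg$generator <- unclass(cfg$generator)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}

#' Render a human-readable pipeline report
#'
#' One text document: ladder table, selection trace, estimated class curves
#' (tabulated), class shares, course cross-tabulation and association
#' table. A partial bundle reports the failing stage and whatever sections
#' exist.
#'
#' @param bundle A `pipeline_bundle` from [run_pipeline()].
#' @return Character vector of report lines (invisibly printable via
#'   `cat(..., sep = "\n")`).
#' @export
render_report <- function(bundle) {
  stopifnot(inherits(bundle, "pipeline_bundle"))
  out <- c("== Symptom trajectory pipeline report ==",
           sprintf("master seed: %d", bundle$config$seed))
  if (!is.null(bundle$failed_stage))
    out <- c(out, "", sprintf("PARTIAL BUNDLE - failed stage: %s",
                              bundle$failed_stage))
  section <- function(title, lines) c("", paste0("-- ", title, " --"), lines)
  fmt_df <- function(d) utils::capture.output(print(d, digits = 4,
                                                    row.names = FALSE))
  if (!is.null(bundle$ladder))
    out <- c(out, section("model ladder",
                          fmt_df(as.data.frame(bundle$ladder)[,
                            c("degree", "random_effects", "K", "loglik",
                              "bic", "entropy", "min_class_share",
                              "converged")])))
  else out <- c(out, section("model ladder", "missing"))
  if (!is.null(bundle$selection))
    out <- c(out, section("selection trace", bundle$selection$trace))
  else out <- c(out, section("selection trace", "missing"))
  if (!is.null(bundle$fit)) {
    M <- fitted(bundle$fit)
    colnames(M) <- if (!is.null(bundle$labels)) bundle$labels else
      colnames(M)
    out <- c(out, section("estimated class curves (months/year)",
                          fmt_df(as.data.frame(round(M, 2)))))
    shares <- 100 * bundle$fit$pi
    names(shares) <- colnames(M)
    out <- c(out, section("class shares (%)",
                          paste(sprintf("%s: %.1f", names(shares), shares),
                                collapse = "  ")))
  } else {
    out <- c(out, section("estimated class curves (months/year)", "missing"),
             section("class shares (%)", "missing"))
  }
  if (!is.null(bundle$crosstabs))
    out <- c(out, section("course by class (counts)",
                          utils::capture.output(
                            print(bundle$crosstabs$course$counts))))
  else out <- c(out, section("course by class (counts)", "missing"))
  if (!is.null(bundle$associations))
    out <- c(out, section("covariate associations (OR, 95% CI)",
                          fmt_df(bundle$associations)))
  else out <- c(out, section("covariate associations (OR, 95% CI)",
                             "missing"))
  out
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}
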