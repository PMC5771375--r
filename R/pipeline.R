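#' Validate a trial table
#'
#' Structural checks on a trial data frame or CSV path: required
#' columns, value ranges (`rt_s > 0`, `correct` in 0/1, known task
#' labels, single-digit symbolic stimuli, dot counts within range) and
#' duplicate subject-task-item keys.
#'
#' @param trials Trial data frame or path to a trial CSV.
#' @return A data frame of diagnostics (zero rows when the table is
#'   well formed) with columns `row`, `column`, `problem`.
#' @export
validate_input <- function(trials) {
  if (is.character(trials)) trials <- read_trials(trials)
  diag <- list()
  note <- function(row, column, problem)
    diag[[length(diag) + 1L]] <<- data.frame(row = row, column = column,
                                             problem = problem,
                                             stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "task", "item_index", "correct", "rt_s")
  for (cl in setdiff(need, names(trials)))
    note(NA_integer_, cl, "required column missing")
  if (length(diag)) return(do.call(rbind, diag))

  bad <- which(!is.finite(trials$rt_s) | trials$rt_s <= 0)
  for (r in bad) note(r, "rt_s", "response time must be positive")
  bad <- which(!trials$correct %in% c(0, 1))
  for (r in bad) note(r, "correct", "correctness must be 0 or 1")
  bad <- which(!trials$task %in% c("symbolic", "nonsymbolic"))
  for (r in bad) note(r, "task", "unknown task label")

  sym <- trials$task == "symbolic"
  if ("left_value" %in% names(trials)) {
    bad <- which(sym & (!trials$left_value %in% 1:9 |
                          !trials$right_value %in% 1:9 |
                          trials$left_value == trials$right_value))
    for (r in bad) note(r, "left_value",
                        "symbolic stimuli must be unequal single digits")
  }
  if ("n1" %in% names(trials)) {
    ns <- trials$task == "nonsymbolic"
    bad <- which(ns & (!(trials$n1 %in% 5:21) | !(trials$n2 %in% 5:21)))
    for (r in bad) note(r, "n1", "dot counts must lie in 5..21")
  }
  key <- paste(trials$subject_id, trials$task, trials$item_index)
  dup <- which(duplicated(key))
  for (r in dup) note(r, "item_index", "duplicate subject-task-item key")
  if (!length(diag))
    return(data.frame(row = integer(0), column = character(0),
                      problem = character(0), stringsAsFactors = FALSE))
  do.call(rbind, diag)
}

#' Run the full study pipeline
#'
#' One-command orchestration: generate (or accept) trial data, clean
#' it, fit the diffusion model per subject and task, compute
#' descriptive measures and Weber fractions, and assemble the report
#' tables: filter report, per-subject summary, split-half reliability,
#' correlations with achievement, group comparison (effect sizes,
#' Welch tests) and the two-by-two mixed ANOVAs on drift rate and
#' boundary separation.  Deterministic given `seed`.
#'
#' @param trials Optional trial data frame or CSV path; when `NULL` a
#'   synthetic cohort is generated from `config`.
#' @param config Population configuration for synthetic generation
#'   (defaults to [default_population_config()]).
#' @param subjects Optional per-subject covariate table
#'   (`subject_id`, `achievement`) for the correlation analysis; filled
#'   automatically for synthetic cohorts.
#' @param seed Master seed.
#' @param rt_lo,rt_hi RT cut-offs in seconds.
#' @param min_trials Minimum trials per fit.
#' @param fit_control Optional list overriding the per-fit optimiser
#'   settings (`n_restarts`, `reltol`, `maxit`); useful for large
#'   cohorts where a lighter search is acceptable.
#' @param quartile_mode Quartile convention for fit assessment.
#' @param reliability Compute split-half reliability (doubles the
#'   fitting work).
#' @param contaminate Inject contaminants into synthetic data at the
#'   configured rates.
#' @param out_dir Optional directory; when given, all tables are
#'   written there as CSV plus a provenance YAML.
#' @return An object of class `study_report`.
#' @export
run_study <- function(trials = NULL, config = default_population_config(),
                      subjects = NULL, seed = 1, rt_lo = 0.250,
                      rt_hi = 4.0, min_trials = 10, fit_control = list(),
                      quartile_mode = c("all", "correct"),
                      reliability = TRUE, contaminate = TRUE,
                      out_dir = NULL) {
  quartile_mode <- match.arg(quartile_mode)
  set.seed(seed)
  synthetic <- is.null(trials)
  population <- NULL
  if (synthetic) {
    population <- sample_population(config)
    trials <- simulate_dataset(population)
    if (contaminate)
      trials <- inject_contaminants(trials,
                                    config$contaminants[["fast"]],
                                    config$contaminants[["slow"]])
    subjects <- population[, c("subject_id", "achievement")]
  } else if (is.character(trials)) {
    trials <- read_trials(trials)
  }
  diagnostics <- validate_input(trials)
  if (nrow(diagnostics))
    stop("input validation failed; first problem: row ",
         diagnostics$row[1], ", column ", diagnostics$column[1], ": ",
         diagnostics$problem[1])

  pre <- preprocess_trials(trials, lo = rt_lo, hi = rt_hi)
  clean <- pre$trials

  fc <- utils::modifyList(list(n_restarts = 5, reltol = 1e-5,
                               maxit = 500), fit_control)
  summ <- subject_summary(clean)
  fits <- fit_dataset(clean, min_trials = min_trials,
                      n_restarts = fc$n_restarts, reltol = fc$reltol,
                      maxit = fc$maxit, seed = seed)
  summ <- merge(summ, fits[, c("subject_id", "task", "a", "v", "t0",
                               "st0", "ks_stat", "converged")],
                by = c("subject_id", "task"), all.x = TRUE, sort = FALSE)

  # Weber fraction for non-symbolic cells
  summ$weber <- NA_real_
  ns <- clean[clean$task == "nonsymbolic", , drop = FALSE]
  for (id in unique(ns$subject_id)) {
    wf <- tryCatch(fit_weber(ns[ns$subject_id == id, , drop = FALSE]),
                   error = function(e) NULL)
    if (!is.null(wf))
      summ$weber[summ$subject_id == id & summ$task == "nonsymbolic"] <-
        wf$w
  }
  if (!is.null(subjects))
    summ <- merge(summ, subjects[, c("subject_id", "achievement")],
                  by = "subject_id", all.x = TRUE, sort = FALSE)
  summ <- summ[order(summ$subject_id, summ$task), , drop = FALSE]
  rownames(summ) <- NULL

  measures <- c("v", "a", "t0", "st0", "accuracy", "weber", "median_rt")
  rel <- if (reliability)
    split_half_reliability(clean, n_restarts = fc$n_restarts,
                           reltol = fc$reltol, maxit = fc$maxit,
                           seed = seed + 10000L) else NULL
  cors <- if (!is.null(subjects)) {
    st <- summ
    st$score <- st$achievement
    correlation_table(st, measures, score_col = "score")
  } else NULL
  comparison <- group_comparison(summ, measures)
  anovas <- list()
  for (par in c("v", "a")) {
    long <- data.frame(subject_id = summ$subject_id, group = summ$group,
                       task = summ$task, value = summ[[par]],
                       stringsAsFactors = FALSE)
    anovas[[par]] <- mixed_anova(long)
  }

  report <- structure(list(
    filter_report = pre$report,
    subject_summary = summ,
    reliability = rel,
    correlations = cors$correlations,
    williams = cors$williams,
    comparison = comparison,
    anova = anovas,
    provenance = list(seed = seed,
                      package_version =
                        as.character(utils::packageVersion("mcdiff")),
                      synthetic = synthetic,
                      config = if (synthetic) yaml::as.yaml(config)
                               else NULL)),
    class = "study_report")
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

#' Write a study report as delimited text
#'
#' Persists every table of a [run_study()] report as CSV plus a
#' `provenance.yaml` capturing the seed and configuration, which
#' suffice to regenerate the whole run.
#'
#' @param report A `study_report` object.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    if (!is.null(df))
      write.csv(df, file.path(dir, paste0(name, ".csv")),
                row.names = FALSE)
  }
  wr(report$subject_summary, "subject_summary")
  wr(report$reliability, "reliability")
  wr(report$correlations, "correlations")
  wr(report$williams, "williams")
  wr(report$comparison, "group_comparison")
  for (par in names(report$anova))
    wr(as.data.frame(report$anova[[par]]), paste0("anova_", par))
  fr <- report$filter_report
  wr(data.frame(n_input = fr$n_input,
                n_removed_practice = fr$n_removed_practice,
                n_removed_fast = fr$n_removed_fast,
                n_removed_slow = fr$n_removed_slow,
                n_excluded_subjects = length(fr$excluded_subjects)),
     "filter_report")
  prov <- report$provenance
  writeLines(yaml::as.yaml(prov), file.path(dir, "provenance.yaml"))
  invisible(dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("study report\n============\n")
  print(x$filter_report)
  cat(sprintf("subjects summarised: %d\n",
              length(unique(x$subject_summary$subject_id))))
  if (!is.null(x$comparison)) {
    cat("\ngroup comparison (d with CI, Holm-adjusted p):\n")
    cmp <- x$comparison
    print(data.frame(task = cmp$task, measure = cmp$measure,
                     d = round(cmp$d, 2),
                     ci = sprintf("[%.2f, %.2f]", cmp$ci_low, cmp$ci_up),
                     p_holm = signif(cmp$p_holm, 2)), row.names = FALSE)
  }
  for (par in names(x$anova)) {
    cat(sprintf("\nmixed ANOVA on %s:\n", par))
    print(as.data.frame(x$anova[[par]]), row.names = FALSE)
  }
  invisible(x)
}
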