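#' Read or write a trial-level table
#'
#' The standard delimited trial format: one row per response with columns
#' `subject_id`, `group` (`con`/`dys`), `task` (`symbolic`/`nonsymbolic`),
#' `item_index` (1-based within task), `left_value`, `right_value`
#' (numeral pair, symbolic only), `n1`, `n2`, `ratio_bin`, `size_control`
#' (dot pair metadata, non-symbolic only), `correct` (0/1) and `rt_s`
#' (response time in seconds).  Stimulus columns not used by a task are
#' left missing.
#'
#' @param path File path of a CSV with a header row (UTF-8).
#' @return A data frame of trials.
#' @export
read_trials <- function(path) {
  tr <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "task", "item_index", "correct", "rt_s")
  miss <- setdiff(need, names(tr))
  if (length(miss))
    stop("trial file is missing required columns: ",
         paste(miss, collapse = ", "))
  tr
}

#' @rdname read_trials
#' @param trials A trial data frame.
#' @export
write_trials <- function(trials, path) {
  write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.new_filter_report <- function() {
  structure(list(n_input = 0L, n_removed_practice = 0L,
                 n_removed_fast = 0L, n_removed_slow = 0L,
                 frac_removed_fast = 0, frac_removed_slow = 0,
                 excluded_subjects = character(0)),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("trial filter report\n")
  cat(sprintf("  input responses:        %d\n", x$n_input))
  cat(sprintf("  practice items removed: %d\n", x$n_removed_practice))
  cat(sprintf("  fast responses removed: %d (%.2f%%)\n",
              x$n_removed_fast, 100 * x$frac_removed_fast))
  cat(sprintf("  slow responses removed: %d (%.2f%%)\n",
              x$n_removed_slow, 100 * x$frac_removed_slow))
  cat(sprintf("  subjects excluded:      %d\n", length(x$excluded_subjects)))
  invisible(x)
}

#' Remove leading items treated as additional practice
#'
#' Item-level inspection in magnitude-comparison sessions typically shows
#' very slow first responses; such leading test items are treated as
#' additional practice and dropped.  By default the first symbolic item
#' and the first three non-symbolic items are removed, leaving 23 and 45
#' analysable items of the 24/48 administered.
#'
#' @param trials Trial data frame (see [read_trials()]).
#' @param rules Named list mapping task label to the item indices to
#'   drop; an empty list leaves the data untouched.
#' @return A list with `trials` (retained rows) and `report`
#'   (a `filter_report`).
#' @export
drop_practice_items <- function(trials,
                                rules = list(symbolic = 1L,
                                             nonsymbolic = 1:3)) {
  rep0 <- .new_filter_report()
  rep0$n_input <- nrow(trials)
  if (length(rules)) {
    unknown <- setdiff(names(rules), unique(trials$task))
    if (length(unknown))
      stop("practice rules name unknown task label(s): ",
           paste(unknown, collapse = ", "))
  }
  drop <- rep(FALSE, nrow(trials))
  for (task in names(rules))
    drop <- drop | (trials$task == task & trials$item_index %in% rules[[task]])
  rep0$n_removed_practice <- sum(drop)
  list(trials = trials[!drop, , drop = FALSE], report = rep0)
}

#' Remove responses outside fixed RT cut-offs
#'
#' Responses faster than `lo` (default 250 ms: fast guesses) or slower
#' than `hi` (default 4 s: outliers) are discarded.  The inequalities are
#' strict, so responses at exactly the cut-off are kept.
#'
#' @param trials Trial data frame.
#' @param lo,hi Lower and upper cut-offs in seconds.
#' @return A list with `kept`, `removed` (with a `removal` column naming
#'   the category) and `report`.
#' @export
apply_rt_cutoffs <- function(trials, lo = 0.250, hi = 4.0) {
  stopifnot(lo < hi)
  rep0 <- .new_filter_report()
  rep0$n_input <- nrow(trials)
  fast <- trials$rt_s < lo
  slow <- trials$rt_s > hi
  rep0$n_removed_fast <- sum(fast)
  rep0$n_removed_slow <- sum(slow)
  if (nrow(trials)) {
    rep0$frac_removed_fast <- rep0$n_removed_fast / nrow(trials)
    rep0$frac_removed_slow <- rep0$n_removed_slow / nrow(trials)
  }
  removed <- trials[fast | slow, , drop = FALSE]
  if (nrow(removed))
    removed$removal <- ifelse(removed$rt_s < lo, "fast", "slow")
  else removed$removal <- character(0)
  list(kept = trials[!(fast | slow), , drop = FALSE],
       removed = removed, report = rep0)
}

#' Exclude subjects with too many out-of-range responses
#'
#' A subject is dropped entirely when, in either task, strictly more than
#' `threshold` (default one half) of that task's post-practice items fell
#' outside the RT cut-offs.
#'
#' @param kept Trials retained by [apply_rt_cutoffs()].
#' @param removed Trials removed by [apply_rt_cutoffs()].
#' @param threshold Exclusion fraction.
#' @return A list with `trials` (kept rows of retained subjects) and
#'   `excluded` (character vector of subject ids).
#' @export
exclude_subjects <- function(kept, removed, threshold = 0.5) {
  all_ids <- function(df) paste(df$subject_id, df$task, sep = "\r")
  n_kept <- table(all_ids(kept))
  n_rem <- table(all_ids(removed))
  keys <- union(names(n_kept), names(n_rem))
  kk <- as.numeric(n_kept[keys]); kk[is.na(kk)] <- 0
  rr <- as.numeric(n_rem[keys]); rr[is.na(rr)] <- 0
  frac <- rr / (kk + rr)
  bad_keys <- keys[frac > threshold]
  excluded <- unique(vapply(strsplit(bad_keys, "\r", fixed = TRUE),
                            `[`, character(1), 1L))
  list(trials = kept[!(kept$subject_id %in% excluded), , drop = FALSE],
       excluded = excluded)
}

#' Full trial-cleaning pass
#'
#' Applies, in order: practice-item removal, RT cut-offs, and whole-
#' subject exclusion (the exclusion denominator is the post-practice item
#' count per task).
#'
#' @inheritParams drop_practice_items
#' @inheritParams apply_rt_cutoffs
#' @inheritParams exclude_subjects
#' @return A list with `trials`, `removed` and a combined `report`.
#' @export
preprocess_trials <- function(trials,
                              rules = list(symbolic = 1L, nonsymbolic = 1:3),
                              lo = 0.250, hi = 4.0, threshold = 0.5) {
  st1 <- drop_practice_items(trials, rules)
  st2 <- apply_rt_cutoffs(st1$trials, lo, hi)
  st3 <- exclude_subjects(st2$kept, st2$removed, threshold)
  rep0 <- st2$report
  rep0$n_input <- nrow(trials)
  rep0$n_removed_practice <- st1$report$n_removed_practice
  rep0$excluded_subjects <- st3$excluded
  list(trials = st3$trials, removed = st2$removed, report = rep0)
}

#' Median RT of correct responses
#'
#' @param trials Trial data frame (any subset, typically one
#'   subject-task cell).
#' @return Median of `rt_s` over rows with `correct == 1`; `NA` when no
#'   correct trials exist (the missing value propagates, analyses drop
#'   the subject pairwise).
#' @export
median_rt_correct <- function(trials) {
  rt <- trials$rt_s[trials$correct == 1]
  if (!length(rt)) return(NA_real_)
  median(rt)
}

#' Mean accuracy
#'
#' @param trials Trial data frame with at least one row.
#' @return Mean of the 0/1 `correct` indicator.
#' @export
mean_accuracy <- function(trials) {
  if (!nrow(trials)) stop("no trials: accuracy is undefined")
  mean(trials$correct)
}

#' Per-subject, per-task descriptive summaries
#'
#' @param trials Cleaned trial data frame.
#' @return A data frame with one row per subject and task: `n_trials`,
#'   `accuracy`, `median_rt` (seconds).
#' @export
subject_summary <- function(trials) {
  key <- interaction(trials$subject_id, trials$task, drop = TRUE)
  parts <- split(trials, key)
  out <- do.call(rbind, lapply(parts, function(d) {
    data.frame(subject_id = d$subject_id[1], group = d$group[1],
               task = d$task[1], n_trials = nrow(d),
               accuracy = mean_accuracy(d),
               median_rt = median_rt_correct(d),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$subject_id, out$task), , drop = FALSE]
}
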