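#' Pearson correlation with pairwise deletion
#'
#' Product-moment correlation with a two-sided p-value; rows with a
#' missing value in either variable are dropped pairwise.
#'
#' @param x,y Paired numeric vectors.
#' @return A list with `r`, `p`, `n` (complete pairs) and `df`.
#' @export
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       df = unname(ct$parameter))
}

#' Bonferroni-Holm adjustment
#'
#' Step-down Holm correction of a family of p-values (monotone, capped
#' at 1, never below the raw values).
#'
#' @param pvals Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
holm_adjust <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  p.adjust(pvals, method = "holm")
}

#' Williams' test for two dependent correlations sharing a variable
#'
#' Tests whether the correlation of `j` with `k` differs from the
#' correlation of `j` with `h`, given that all three variables were
#' measured on the same `n` subjects (Williams' t, `df = n - 3`).  Used
#' to compare a measure's correlation with achievement between the two
#' task types.
#'
#' @param r_jk Correlation of the shared variable with the first
#'   measure.
#' @param r_jh Correlation of the shared variable with the second
#'   measure.
#' @param r_kh Correlation between the two measures.
#' @param n Number of subjects.
#' @return A list with `t`, `df` and the two-sided `p`.
#' @export
williams_test <- function(r_jk, r_jh, r_kh, n) {
  stopifnot(n > 3, abs(r_jk) < 1, abs(r_jh) < 1, abs(r_kh) < 1)
  detR <- 1 - r_jk^2 - r_jh^2 - r_kh^2 + 2 * r_jk * r_jh * r_kh
  if (detR <= 0) stop("singular correlation matrix")
  rbar <- (r_jk + r_jh) / 2
  tval <- (r_jk - r_jh) *
    sqrt((n - 1) * (1 + r_kh) /
           (2 * detR * (n - 1) / (n - 3) + rbar^2 * (1 - r_kh)^3))
  df <- n - 3
  list(t = tval, df = df, p = 2 * pt(-abs(tval), df))
}

#' Spearman-Brown step-up correction
#'
#' Projects a half-test correlation to full test length: `2 r / (1 + r)`.
#'
#' @param r Split-half correlation.
#' @return Corrected reliability.
#' @export
spearman_brown <- function(r) 2 * r / (1 + r)

#' Split-half reliability of the diffusion parameters
#'
#' Splits each subject's trials into halves (default: odd versus even
#' item order), refits the diffusion model on each half, correlates the
#' two half estimates across subjects for each parameter and task, and
#' applies the Spearman-Brown correction.  Subjects whose half-fits fail
#' are dropped pairwise.
#'
#' @param trials Cleaned trial data frame.
#' @param split `"odd_even"` (by item order) or `"first_second"`.
#' @param seed Base seed forwarded to the half fits.
#' @inheritParams fit_subject_task
#' @return A data frame with one row per parameter (`a`, `v`, `t0`) and
#'   task: `r` (half correlation), `r_sb` (corrected), `n_subjects`,
#'   `n_failed`.
#' @export
split_half_reliability <- function(trials, split = c("odd_even",
                                                     "first_second"),
                                   min_trials = 4, n_restarts = 5,
                                   reltol = 1e-5, maxit = 500,
                                   seed = 1) {
  split <- match.arg(split)
  key <- interaction(trials$subject_id, trials$task, drop = TRUE)
  parts <- split(trials, key)
  halves <- lapply(seq_along(parts), function(i) {
    d <- parts[[i]]
    d <- d[order(d$item_index), , drop = FALSE]
    pick <- if (split == "odd_even") seq_len(nrow(d)) %% 2 == 1
            else seq_len(nrow(d)) <= nrow(d) / 2
    fit1 <- tryCatch(fit_subject_task(d[pick, ], min_trials = min_trials,
                                      n_restarts = n_restarts,
                                      reltol = reltol, maxit = maxit,
                                      seed = seed + 2L * i),
                     error = function(e) NULL)
    fit2 <- tryCatch(fit_subject_task(d[!pick, ], min_trials = min_trials,
                                      n_restarts = n_restarts,
                                      reltol = reltol, maxit = maxit,
                                      seed = seed + 2L * i + 1L),
                     error = function(e) NULL)
    list(task = d$task[1], fit1 = fit1, fit2 = fit2)
  })
  out <- list()
  for (task in unique(trials$task)) {
    hh <- Filter(function(h) h$task == task, halves)
    ok <- Filter(function(h) !is.null(h$fit1) && !is.null(h$fit2), hh)
    for (par in c("a", "v", "t0")) {
      x <- vapply(ok, function(h) h$fit1$params[[par]], numeric(1))
      y <- vapply(ok, function(h) h$fit2$params[[par]], numeric(1))
      r <- cor(x, y)
      out[[length(out) + 1L]] <- data.frame(
        parameter = par, task = task, r = r, r_sb = spearman_brown(r),
        n_subjects = length(ok), n_failed = length(hh) - length(ok),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Pooled-variance Cohen's d with confidence interval
#'
#' Standardised mean difference using the pooled standard deviation,
#' with a large-sample normal confidence interval based on
#' `SE = sqrt((n1 + n2)/(n1 n2) + d^2 / (2 (n1 + n2)))`.
#'
#' @param m1,s1,n1 Mean, SD and size of the first group.
#' @param m2,s2,n2 Mean, SD and size of the second group.
#' @param conf Confidence level (default 0.95).
#' @return A list with `d`, `ci_low`, `ci_up`, `n1`, `n2`.
#' @examples
#' cohens_d(2.44, 0.9, 272, 1.92, 0.62, 81)$d  # ~0.62
#' @export
cohens_d <- function(m1, s1, n1, m2, s2, n2, conf = 0.95) {
  stopifnot(s1 > 0, s2 > 0, n1 >= 2, n2 >= 2)
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  d <- (m1 - m2) / sp
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  zc <- -qnorm((1 - conf) / 2)
  list(d = d, ci_low = d - zc * se, ci_up = d + zc * se, n1 = n1, n2 = n2)
}

#' Welch's two-sample t-test from summary statistics
#'
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value.
#'
#' @inheritParams cohens_d
#' @return A list with `t`, `df`, `p`.
#' @export
welch_t <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(s1 > 0, s2 > 0, n1 >= 2, n2 >= 2)
  se1 <- s1^2 / n1; se2 <- s2^2 / n2
  tval <- (m1 - m2) / sqrt(se1 + se2)
  df <- (se1 + se2)^2 / (se1^2 / (n1 - 1) + se2^2 / (n2 - 1))
  list(t = tval, df = df, p = 2 * pt(-abs(tval), df))
}

#' Two-by-two mixed (split-plot) ANOVA
#'
#' One between-subject factor (group) and one within-subject factor
#' (task), one observation per subject and task.  The group effect is
#' tested against subject-within-group error; the task and
#' group-by-task effects against the subject-by-task error.  Reports
#' classical eta squared (`SS_effect / SS_total`, summed over both
#' strata) as the primary effect size and partial eta squared for
#' transparency.  Subjects missing either task value are dropped and
#' counted.
#'
#' @param data Data frame with columns `subject_id`, `group`, `task`,
#'   `value`.
#' @return An object of class `mixed_anova`: a data frame with rows
#'   `group`, `task`, `group:task` and columns `F`, `p`, `eta2`,
#'   `eta2_partial`, `df1`, `df2`, plus attributes `n_subjects` and
#'   `n_dropped`.
#' @export
mixed_anova <- function(data) {
  stopifnot(all(c("subject_id", "group", "task", "value") %in% names(data)))
  data <- data[is.finite(data$value), , drop = FALSE]
  counts <- table(data$subject_id)
  complete <- names(counts)[counts == 2]
  dropped <- length(counts) - length(complete)
  d <- data[data$subject_id %in% complete, , drop = FALSE]
  if (length(unique(d$group)) != 2 || length(unique(d$task)) != 2)
    stop("need exactly two groups and two tasks")
  d$subject_id <- factor(d$subject_id)
  d$group <- factor(d$group)
  d$task <- factor(d$task)
  fit <- aov(value ~ group * task + Error(subject_id), data = d)
  sm <- summary(fit)
  between <- as.data.frame(sm[["Error: subject_id"]][[1]])
  within <- as.data.frame(sm[["Error: Within"]][[1]])
  rn_b <- trimws(rownames(between))
  rn_w <- trimws(rownames(within))
  ss <- function(tab, rn, term) tab[match(term, rn), "Sum Sq"]
  df1 <- function(tab, rn, term) tab[match(term, rn), "Df"]
  ss_total <- sum(between[, "Sum Sq"]) + sum(within[, "Sum Sq"])
  err_b <- ss(between, rn_b, "Residuals")
  err_w <- ss(within, rn_w, "Residuals")
  row <- function(term) {
    tab <- if (term == "group") between else within
    rn <- if (term == "group") rn_b else rn_w
    err <- if (term == "group") err_b else err_w
    dferr <- if (term == "group") df1(between, rn_b, "Residuals")
             else df1(within, rn_w, "Residuals")
    s <- ss(tab, rn, term)
    d1 <- df1(tab, rn, term)
    Fv <- (s / d1) / (err / dferr)
    data.frame(effect = term, F = Fv, p = pf(Fv, d1, dferr,
                                             lower.tail = FALSE),
               eta2 = s / ss_total, eta2_partial = s / (s + err),
               df1 = d1, df2 = dferr, stringsAsFactors = FALSE)
  }
  out <- rbind(row("group"), row("task"), row("group:task"))
  rownames(out) <- NULL
  attr(out, "n_subjects") <- length(complete)
  attr(out, "n_dropped") <- dropped
  class(out) <- c("mixed_anova", "data.frame")
  out
}

#' Group-comparison table (effect sizes, Welch tests, Holm adjustment)
#'
#' Builds the per-task, per-measure comparison of the two groups:
#' group means and SDs, pooled Cohen's d with confidence interval,
#' Welch's t with Satterthwaite df, and Holm-adjusted p-values.  The
#' Weber fraction, being almost perfectly (negatively) collinear with
#' mean accuracy, is excluded from the adjustment family (its raw p is
#' still reported).
#'
#' @param subjects Per-subject table with a `group` column, a `task`
#'   column and the measure columns in `measures`.
#' @param measures Character vector of measure column names.
#' @param groups Length-2 character vector naming the reference and
#'   comparison group (d is reference minus comparison).
#' @param adjust_exclude Measures excluded from the Holm family.
#' @return A data frame mirroring the task x measure comparison layout.
#' @export
group_comparison <- function(subjects, measures,
                             groups = c("con", "dys"),
                             adjust_exclude = "weber") {
  rows <- list()
  for (task in unique(subjects$task)) {
    st <- subjects[subjects$task == task, , drop = FALSE]
    for (ms in measures) {
      if (!ms %in% names(st)) next
      x1 <- st[st$group == groups[1], ms]; x1 <- x1[is.finite(x1)]
      x2 <- st[st$group == groups[2], ms]; x2 <- x2[is.finite(x2)]
      if (length(x1) < 2 || length(x2) < 2) next
      es <- cohens_d(mean(x1), sd(x1), length(x1),
                     mean(x2), sd(x2), length(x2))
      wt <- welch_t(mean(x1), sd(x1), length(x1),
                    mean(x2), sd(x2), length(x2))
      rows[[length(rows) + 1L]] <- data.frame(
        task = task, measure = ms,
        m1 = mean(x1), sd1 = sd(x1), n1 = length(x1),
        m2 = mean(x2), sd2 = sd(x2), n2 = length(x2),
        d = es$d, ci_low = es$ci_low, ci_up = es$ci_up,
        t = wt$t, df = wt$df, p = wt$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  fam <- !(out$measure %in% adjust_exclude)
  out$p_holm <- NA_real_
  out$p_holm[fam] <- holm_adjust(out$p[fam])
  out
}

#' Correlations of task measures with an achievement score
#'
#' Pearson correlations (pairwise deletion) of each per-subject measure
#' with a subject-level score, by task, with one Holm family across all
#' measure-task cells except those excluded; plus Williams' test
#' comparing each measure's correlation with the score between the two
#' tasks (using the empirical cross-task correlation of the measure).
#'
#' @param subjects Per-subject long table (`subject_id`, `task`, measure
#'   columns) including a `score` column replicated within subject.
#' @param measures Character vector of measure column names.
#' @param score_col Name of the score column.
#' @param adjust_exclude Measures excluded from the Holm family.
#' @return A list with `correlations` (task x measure rows) and
#'   `williams` (one row per measure present in both tasks).
#' @export
correlation_table <- function(subjects, measures, score_col = "score",
                              adjust_exclude = "weber") {
  tasks <- unique(subjects$task)
  rows <- list()
  for (task in tasks) {
    st <- subjects[subjects$task == task, , drop = FALSE]
    for (ms in measures) {
      if (!ms %in% names(st)) next
      ok <- is.finite(st[[ms]]) & is.finite(st[[score_col]])
      if (sum(ok) < 3) next
      pr <- pearson_r(st[[ms]][ok], st[[score_col]][ok])
      rows[[length(rows) + 1L]] <- data.frame(
        task = task, measure = ms, r = pr$r, p = pr$p, n = pr$n,
        stringsAsFactors = FALSE)
    }
  }
  cors <- do.call(rbind, rows)
  fam <- !(cors$measure %in% adjust_exclude)
  cors$p_holm <- NA_real_
  cors$p_holm[fam] <- holm_adjust(cors$p[fam])

  wrows <- list()
  if (length(tasks) == 2) {
    for (ms in measures) {
      c1 <- cors[cors$task == tasks[1] & cors$measure == ms, ]
      c2 <- cors[cors$task == tasks[2] & cors$measure == ms, ]
      if (!nrow(c1) || !nrow(c2)) next
      wide <- merge(
        subjects[subjects$task == tasks[1], c("subject_id", ms)],
        subjects[subjects$task == tasks[2], c("subject_id", ms)],
        by = "subject_id")
      ok <- is.finite(wide[[2]]) & is.finite(wide[[3]])
      if (sum(ok) < 4) next
      r_kh <- cor(wide[[2]][ok], wide[[3]][ok])
      n <- sum(ok)
      wt <- tryCatch(williams_test(c1$r, c2$r, r_kh, n),
                     error = function(e) NULL)
      if (is.null(wt)) next
      wrows[[length(wrows) + 1L]] <- data.frame(
        measure = ms, r_task1 = c1$r, r_task2 = c2$r, r_between = r_kh,
        t = wt$t, df = wt$df, p = wt$p, stringsAsFactors = FALSE)
    }
  }
  list(correlations = cors,
       williams = if (length(wrows)) do.call(rbind, wrows) else NULL)
}
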