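#' Default synthetic-population configuration
#'
#' The generator's defaults encode the study conditions the analysis is
#' designed for: two groups of elementary-school children (`con`,
#' n = 272; `dys`, n = 81) whose per-task diffusion parameters follow
#' group-specific normal distributions (truncated to valid ranges), a
#' group-specific Weber fraction and mathematical-achievement score, and
#' a latent achievement factor that loads positively on drift rate and
#' negatively (symbolic-weighted) on boundary separation so that
#' achievement-parameter correlations of realistic magnitude (about
#' 0.2-0.3 absolute before attenuation) emerge.  Cross-task correlation
#' of the same parameter defaults to 0.5.  Contaminant rates default to
#' the removal fractions the cleaning stage is designed around (1.01%
#' fast, 1.25% slow).
#'
#' @return A nested list; edit fields and pass to
#'   [sample_population()].
#' @export
default_population_config <- function() {
  list(
    groups = list(
      con = list(
        n = 272,
        achievement = list(mean = 107.81, sd = 12.31),
        weber = list(mean = 0.77, sd = 0.72),
        symbolic = list(a = c(1.50, 0.48), v = c(2.44, 0.90),
                        t0 = c(0.73, 0.17), st0 = c(0.23, 0.22)),
        nonsymbolic = list(a = c(1.49, 0.47), v = c(1.68, 0.70),
                           t0 = c(0.61, 0.33), st0 = c(0.26, 0.23))),
      dys = list(
        n = 81,
        achievement = list(mean = 78.89, sd = 4.18),
        weber = list(mean = 0.85, sd = 0.76),
        symbolic = list(a = c(1.73, 0.41), v = c(1.92, 0.62),
                        t0 = c(0.78, 0.18), st0 = c(0.33, 0.30)),
        nonsymbolic = list(a = c(1.60, 0.43), v = c(1.46, 0.69),
                           t0 = c(0.80, 0.57), st0 = c(0.43, 0.43)))),
    loadings = list(v = list(symbolic = 0.35, nonsymbolic = 0.35),
                    a = list(symbolic = -0.30, nonsymbolic = -0.05),
                    t0 = list(symbolic = -0.15, nonsymbolic = -0.08),
                    st0 = list(symbolic = -0.20, nonsymbolic = -0.20)),
    achievement_loading = 0.8,
    cross_task_cor = 0.5,
    contaminants = list(fast = 0.0101, slow = 0.0125),
    # truncation limits for the true parameters: drifts stay above
    # chance-adjacent values, non-decision time stays physiologically
    # plausible for children (its window never reaches below ter_floor),
    # so that genuine responses rarely leave the 250 ms / 4 s window
    bounds = list(a = c(0.2, 4), v = c(0.3, 6), t0 = c(0.30, 2.0),
                  st0_min = 0.01, ter_floor = 0.15)
  )
}

#' @rdname default_population_config
#' @param path YAML file to read or write.
#' @export
read_population_config <- function(path) yaml::read_yaml(path)

#' @rdname default_population_config
#' @param config A configuration list.
#' @export
write_population_config <- function(config, path) {
  writeLines(yaml::as.yaml(config), path)
  invisible(path)
}

#' Symbolic comparison design (numeral pairs)
#'
#' 24 test items of single-digit pairs whose numerical distances follow
#' a balanced design: each distance 1-6 appears exactly four times, with
#' the larger numeral on the left for half the items of each distance.
#' Three flagged practice items precede the test items.  Item order is
#' shuffled, so the design depends on the RNG state.
#'
#' @return A data frame with columns `task`, `practice`, `item_index`
#'   (1-based within the test phase, `NA` for practice), `left_value`,
#'   `right_value`.
#' @export
make_symbolic_design <- function() {
  one <- function(d, larger_left) {
    small <- sample(seq_len(9 - d), 1)
    if (larger_left) c(small + d, small) else c(small, small + d)
  }
  dist <- rep(1:6, each = 4)
  side <- as.logical(rep(c(TRUE, TRUE, FALSE, FALSE), times = 6))
  pairs <- t(mapply(one, dist, side))
  ord <- sample(24)
  test <- data.frame(task = "symbolic", practice = FALSE,
                     item_index = 1:24,
                     left_value = pairs[ord, 1],
                     right_value = pairs[ord, 2])
  pr <- t(mapply(one, sample(1:6, 3), sample(c(TRUE, FALSE), 3,
                                             replace = TRUE)))
  practice <- data.frame(task = "symbolic", practice = TRUE,
                         item_index = NA_integer_,
                         left_value = pr[, 1], right_value = pr[, 2])
  rbind(practice, test)
}

#' Non-symbolic comparison design (dot pairs)
#'
#' 48 test items of dot-set pairs, 12 per ratio bin (approximately 1.2,
#' 1.4, 1.6 and 2.6; integer pairs whose ratio is within 0.05 of the
#' bin target), all counts between 5 and 21, with exactly half the items
#' per bin flagged as controlled for average dot size (the rest for
#' total area).  Two flagged practice items precede the test items.
#'
#' @param ratio_bins Target ratios.
#' @param dot_range Admissible dot counts.
#' @param tol Admitted deviation of the integer-pair ratio from the bin
#'   target.
#' @return A data frame with columns `task`, `practice`, `item_index`,
#'   `n1`, `n2`, `ratio_bin`, `size_control`.
#' @export
make_nonsymbolic_design <- function(ratio_bins = c(1.2, 1.4, 1.6, 2.6),
                                    dot_range = 5:21, tol = 0.05) {
  candidates <- function(target) {
    grid <- expand.grid(lo = dot_range, hi = dot_range)
    grid <- grid[grid$hi > grid$lo, , drop = FALSE]
    grid <- grid[abs(grid$hi / grid$lo - target) <= tol, , drop = FALSE]
    if (!nrow(grid))
      stop("no integer dot pair matches ratio bin ", target)
    grid
  }
  rows <- lapply(ratio_bins, function(target) {
    cand <- candidates(target)
    pick <- cand[sample(nrow(cand), 12, replace = TRUE), , drop = FALSE]
    swap <- sample(c(TRUE, FALSE), 12, replace = TRUE)
    data.frame(n1 = ifelse(swap, pick$hi, pick$lo),
               n2 = ifelse(swap, pick$lo, pick$hi),
               ratio_bin = target,
               size_control = sample(rep(c(TRUE, FALSE), 6)))
  })
  items <- do.call(rbind, rows)
  items <- items[sample(48), , drop = FALSE]
  test <- data.frame(task = "nonsymbolic", practice = FALSE,
                     item_index = 1:48, items, row.names = NULL)
  pr_pick <- candidates(2.6)
  pr <- pr_pick[sample(nrow(pr_pick), 2, replace = TRUE), , drop = FALSE]
  practice <- data.frame(task = "nonsymbolic", practice = TRUE,
                         item_index = NA_integer_,
                         n1 = pr$hi, n2 = pr$lo, ratio_bin = 2.6,
                         size_control = c(TRUE, FALSE),
                         row.names = NULL)
  rbind(practice, test)
}

# one truncated-normal draw built from a fixed latent part plus a
# redrawn residual; falls back to clamping if rejection keeps failing
.trunc_draw <- function(mu, sigma, latent, resid_sd, lo, hi) {
  if (sigma == 0) return(min(max(mu, lo), hi))
  for (i in 1:100) {
    x <- mu + sigma * (latent + resid_sd * rnorm(1))
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mu + sigma * latent, lo), hi)
}

#' Draw a synthetic subject population
#'
#' Each subject receives a group label, an observed achievement score,
#' per-task true diffusion parameters drawn from truncated normal
#' distributions around the group means, and a true Weber fraction.  A
#' standard-normal latent achievement factor, shared across tasks and
#' parameters with the configured loadings, induces the
#' achievement-parameter correlation structure; the remaining variance
#' is split between a subject-level component (cross-task correlation)
#' and task noise.
#'
#' @param config Configuration list, see
#'   [default_population_config()].
#' @param seed Optional seed (`set.seed` is called when given).
#' @return A data frame with one row per subject: `subject_id`,
#'   `group`, `achievement`, `weber_true` and columns
#'   `<param>_<task>` for the true parameter values.
#' @export
sample_population <- function(config = default_population_config(),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bounds <- config$bounds
  rho <- config$cross_task_cor
  rows <- list()
  sid <- 0L
  for (gname in names(config$groups)) {
    g <- config$groups[[gname]]
    if (g$n < 2) stop("group sizes must be at least 2")
    for (i in seq_len(g$n)) {
      sid <- sid + 1L
      z <- rnorm(1)
      lam_ach <- config$achievement_loading
      ach <- g$achievement[["mean"]] + g$achievement[["sd"]] *
        (lam_ach * z + sqrt(1 - lam_ach^2) * rnorm(1))
      row <- list(subject_id = sprintf("S%03d", sid), group = gname,
                  achievement = ach)
      for (par in c("a", "v", "t0", "st0")) {
        shared <- rnorm(1)
        for (task in c("symbolic", "nonsymbolic")) {
          lam <- config$loadings[[par]][[task]]
          resid <- sqrt(max(0, 1 - lam^2))
          # split residual into shared (cross-task) and task-specific
          latent <- lam * z + resid * sqrt(rho) * shared
          resid_sd <- resid * sqrt(1 - rho)
          ms <- g[[task]][[par]]
          lims <- switch(par,
                         a = bounds$a, v = bounds$v, t0 = bounds$t0,
                         st0 = c(bounds$st0_min, Inf))
          val <- .trunc_draw(ms[1], ms[2], latent, resid_sd,
                             lims[1], lims[2])
          row[[paste(par, task, sep = "_")]] <- val
        }
      }
      ter_floor <- if (is.null(bounds$ter_floor)) 0.15 else
        bounds$ter_floor
      for (task in c("symbolic", "nonsymbolic")) {
        t0v <- row[[paste0("t0_", task)]]
        # keep the earliest non-decision time at or above ter_floor
        row[[paste0("st0_", task)]] <-
          min(row[[paste0("st0_", task)]],
              2 * max(t0v - ter_floor, 0.005))
      }
      wb <- g$weber
      row$weber_true <- .trunc_draw(wb[["mean"]], wb[["sd"]], 0, 1, 0.02, 3)
      rows[[sid]] <- as.data.frame(row, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a trial table for a population
#'
#' Runs the diffusion simulator for every subject and test item.
#' Symbolic items share the subject's symbolic drift rate; non-symbolic
#' item drift scales with the log of the dot ratio, normalised so the
#' subject's configured drift is the design-average drift (harder
#' ratios yield lower accuracy and slower responses, while a single
#' drift per subject-task remains the estimand).
#'
#' @param population Data frame from [sample_population()].
#' @param designs List with `symbolic` and `nonsymbolic` design data
#'   frames; fresh designs are drawn when `NULL`.
#' @param dt Simulator step size (seconds).
#' @param seed Optional seed.
#' @return A trial data frame in the standard format (see
#'   [read_trials()]).
#' @export
simulate_dataset <- function(population, designs = NULL, dt = 1e-4,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(designs))
    designs <- list(symbolic = make_symbolic_design(),
                    nonsymbolic = make_nonsymbolic_design())
  sym <- designs$symbolic[!designs$symbolic$practice, , drop = FALSE]
  nsym <- designs$nonsymbolic[!designs$nonsymbolic$practice, , drop = FALSE]
  ratio <- pmax(nsym$n1, nsym$n2) / pmin(nsym$n1, nsym$n2)
  scale <- log(ratio) / mean(log(ratio))
  out <- vector("list", 2L * nrow(population))
  k <- 0L
  for (i in seq_len(nrow(population))) {
    s <- population[i, ]
    p_sym <- diffusion_params(s$a_symbolic, s$v_symbolic,
                              s$t0_symbolic, s$st0_symbolic)
    sim <- simulate_trials(nrow(sym), p_sym, dt = dt)
    k <- k + 1L
    out[[k]] <- data.frame(
      subject_id = s$subject_id, group = s$group, task = "symbolic",
      item_index = sym$item_index,
      left_value = sym$left_value, right_value = sym$right_value,
      n1 = NA_integer_, n2 = NA_integer_, ratio_bin = NA_real_,
      size_control = NA,
      correct = sim$correct, rt_s = round(sim$rt, 3),
      stringsAsFactors = FALSE)
    p_ns <- diffusion_params(s$a_nonsymbolic, s$v_nonsymbolic,
                             s$t0_nonsymbolic, s$st0_nonsymbolic)
    sim2 <- simulate_trials(nrow(nsym), p_ns, dt = dt,
                            drift = s$v_nonsymbolic * scale)
    k <- k + 1L
    out[[k]] <- data.frame(
      subject_id = s$subject_id, group = s$group, task = "nonsymbolic",
      item_index = nsym$item_index,
      left_value = NA_integer_, right_value = NA_integer_,
      n1 = nsym$n1, n2 = nsym$n2, ratio_bin = nsym$ratio_bin,
      size_control = nsym$size_control,
      correct = sim2$correct, rt_s = round(sim2$rt, 3),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Inject contaminant response times
#'
#' Replaces a random fraction of responses with fast guesses (RT uniform
#' on 0.05-0.25 s, correctness re-drawn at chance) and another fraction
#' with slow outliers (RT uniform on 4-8 s, correctness kept),
#' exercising the cleaning stage at realistic contamination rates.
#'
#' @param trials Trial data frame.
#' @param fast_rate,slow_rate Contamination fractions in `[0, 0.5)`.
#' @param seed Optional seed.
#' @return The trial data frame with contaminated rows replaced.
#' @export
inject_contaminants <- function(trials, fast_rate = 0.0101,
                                slow_rate = 0.0125, seed = NULL) {
  stopifnot(fast_rate >= 0, fast_rate < 0.5,
            slow_rate >= 0, slow_rate < 0.5)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(trials)
  if (fast_rate + slow_rate == 0 || n == 0) return(trials)
  n_fast <- round(fast_rate * n)
  n_slow <- round(slow_rate * n)
  pick <- sample(n, n_fast + n_slow)
  fast <- pick[seq_len(n_fast)]
  slow <- pick[n_fast + seq_len(n_slow)]
  if (length(fast)) {
    trials$rt_s[fast] <- round(runif(length(fast), 0.05, 0.25), 3)
    trials$correct[fast] <- rbinom(length(fast), 1, 0.5)
  }
  if (length(slow))
    trials$rt_s[slow] <- round(runif(length(slow), 4, 8), 3)
  trials
}
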