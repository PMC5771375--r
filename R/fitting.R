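#' Empirical signed response-time distribution
#'
#' Encodes each response on the signed axis (error responses at `-rt`,
#' correct responses at `+rt`) and returns the right-continuous empirical
#' step function.  The value just left of 0 equals the observed error
#' proportion.
#'
#' @param trials Trial data frame with `correct` and `rt_s` columns (a
#'   bare data frame with `correct`/`rt` is also accepted).
#' @return A step function (class `stepfun`) with the sorted signed
#'   values attached as attribute `"jumps"`.
#' @export
empirical_signed_cdf <- function(trials) {
  s <- .signed_values(trials)
  if (!length(s)) stop("no trials: empirical CDF is undefined")
  f <- ecdf(s)
  attr(f, "jumps") <- sort(s)
  f
}

.signed_values <- function(trials) {
  rt <- if (!is.null(trials$rt_s)) trials$rt_s else trials$rt
  ifelse(trials$correct == 1, rt, -rt)
}

#' Kolmogorov-Smirnov distance between model and data
#'
#' Supremum over the real line of the absolute difference between the
#' model signed-RT CDF ([signed_rt_cdf()]) and the empirical signed-RT
#' CDF.  Because the model CDF is continuous and nondecreasing the
#' supremum is attained at an empirical jump point, approached from one
#' side or the other; both one-sided limits of every jump are evaluated.
#'
#' @param params A [diffusion_params()] object.
#' @param trials Trial data frame.
#' @return The KS statistic in `[0, 1]`.
#' @export
ks_statistic <- function(params, trials) {
  p <- .as_dp(params)
  s <- sort(.signed_values(trials))
  n <- length(s)
  if (!n) stop("no trials: KS statistic is undefined")
  u <- unique(s)
  hi <- cumsum(tabulate(match(s, u), nbins = length(u))) / n
  lo <- c(0, hi[-length(hi)])
  gl <- .gauss_legendre_01(12L)
  .ks_stat_cpp(u, hi, lo, p$a, p$v, p$t0, p$st0, gl$x, gl$w)
}

#' Closed-form starting values (EZ-style inversion)
#'
#' Inverts mean accuracy and the mean/variance of correct RTs into
#' starting values for `(a, v, t0)` under unit diffusion coefficient;
#' `st0` starts at a fixed fraction (0.3) of `t0`.  Accuracy exactly 0, 1
#' or 0.5 is edge-corrected before the logit.  Used only to initialise
#' the optimiser.
#'
#' @param accuracy Mean proportion correct.
#' @param rt_mean_correct Mean RT of correct responses in seconds.
#' @param rt_var_correct Variance of correct RTs.
#' @param n Number of trials behind `accuracy` (for the edge
#'   correction).
#' @return A [diffusion_params()] object.
#' @export
ez_init <- function(accuracy, rt_mean_correct, rt_var_correct, n) {
  fallback <- function() {
    t0 <- max(0.05, rt_mean_correct - 0.3)
    diffusion_params(1.2, 1.5, t0, 0.3 * t0)
  }
  if (!is.finite(rt_var_correct) || rt_var_correct <= 0 ||
      !is.finite(rt_mean_correct) || !is.finite(accuracy))
    return(fallback())
  acc <- accuracy
  if (acc >= 1) acc <- (n - 0.5) / n
  if (acc <= 0) acc <- 0.5 / n
  if (abs(acc - 0.5) < 1e-9) acc <- 0.5 + 1 / (2 * n)  # tie-break upward
  L <- qlogis(acc)
  x <- L * (L * acc^2 - L * acc + acc - 0.5) / rt_var_correct
  if (!is.finite(x) || x <= 0) return(fallback())
  v <- sign(acc - 0.5) * x^0.25
  a <- L / v
  if (!is.finite(a) || a <= 0) return(fallback())
  mdt <- mean_decision_time(diffusion_params(a, v))
  t0 <- max(0.05, rt_mean_correct - mdt)
  diffusion_params(a, v, t0, 0.3 * t0)
}

# run fn with a temporary RNG state seeded at `seed`
.with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Fit the diffusion model to one subject-task cell
#'
#' Minimises the Kolmogorov-Smirnov distance between the model and
#' empirical signed-RT distributions over `(a, v, t0, st0)` with a
#' derivative-free simplex search: one start from the closed-form
#' [ez_init()] values plus `n_restarts - 1` seeded perturbations of it,
#' each start iterating fresh simplexes from its best point until no
#' further improvement (the KS surface has narrow curved valleys that
#' a single simplex run tends to stall in).
#'
#' Parameters are optimised on an unconstrained scale mapped into
#' bounds.  The non-decision component is parameterised by the lower
#' edge of the uniform window, `e = t0 - st0/2` in
#' `[0.025, min observed rt]`, and its half-width `h = st0/2` in
#' `[0, 1]`; this keeps the window non-negative and, unlike bounding
#' `t0` itself by the fastest response, does not exclude solutions
#' where `t0` exceeds the minimum RT by part of the window.  Boundary
#' separation is bounded in `[0.2, 4]` and drift in `[-6, 6]`,
#' generously covering values observed in children's magnitude
#' comparison.
#'
#' @param trials Trial data frame for a single subject and task.
#' @param min_trials Minimum number of trials required (default 10).
#' @param n_restarts Number of simplex starts (default 5).
#' @param reltol Convergence tolerance on the objective (default 1e-5).
#' @param maxit Iteration cap per simplex run.
#' @param seed Seed for the restart perturbations; identical seed and
#'   data give a bit-identical result.
#' @return An object of class `dm_fit`: `params`
#'   ([diffusion_params()]), `ks_stat`, `n_trials`, `n_restarts`,
#'   `converged` and the per-start objective values (`restart_values`).
#' @export
fit_subject_task <- function(trials, min_trials = 10, n_restarts = 5,
                             reltol = 1e-5, maxit = 500, seed = 1) {
  n <- nrow(trials)
  if (n < min_trials)
    stop("too few trials to fit (", n, " < ", min_trials, ")",
         call. = FALSE)
  rt <- if (!is.null(trials$rt_s)) trials$rt_s else trials$rt
  stopifnot(all(rt > 0))
  min_rt <- min(rt)
  b_a <- c(0.2, 4); b_v <- c(-6, 6)
  b_e <- c(0.025, max(0.03, min_rt)); b_h <- c(0, 1)

  map <- function(theta) {
    a <- b_a[1] + diff(b_a) * plogis(theta[1])
    v <- b_v[1] + diff(b_v) * plogis(theta[2])
    e <- b_e[1] + diff(b_e) * plogis(theta[3])
    h <- b_h[1] + diff(b_h) * plogis(theta[4])
    diffusion_params(a, v, e + h, 2 * h)
  }
  unmap_component <- function(x, b) {
    qlogis(pmin(pmax((x - b[1]) / diff(b), 1e-4), 1 - 1e-4))
  }
  s <- sort(.signed_values(trials))
  u <- unique(s)
  e_hi <- cumsum(tabulate(match(s, u), nbins = length(u))) / n
  e_lo <- c(0, e_hi[-length(e_hi)])
  gl <- .gauss_legendre_01(12L)
  da <- diff(b_a); dv <- diff(b_v); de <- diff(b_e); dh <- diff(b_h)
  objective <- function(theta) {
    a <- b_a[1] + da * plogis(theta[1])
    v <- b_v[1] + dv * plogis(theta[2])
    e <- b_e[1] + de * plogis(theta[3])
    h <- b_h[1] + dh * plogis(theta[4])
    .ks_stat_cpp(u, e_hi, e_lo, a, v, e + h, 2 * h, gl$x, gl$w)
  }

  rc <- trials$correct == 1
  start <- ez_init(mean(trials$correct),
                   mean(rt[rc]),
                   if (sum(rc) > 1) var(rt[rc]) else var(rt),
                   n)
  theta0 <- c(unmap_component(start$a, b_a),
              unmap_component(start$v, b_v),
              unmap_component(max(start$t0 - start$st0 / 2, 0.03), b_e),
              unmap_component(max(start$st0 / 2, 0.02), b_h))

  # one multi-start: iterate re-centred simplex runs from the best point
  # (re-centring gives every run a uniform initial simplex step)
  run_start <- function(th) {
    best <- NULL
    for (round in 1:6) {
      off <- th - 2
      o <- optim(rep(2, 4), function(u) objective(u + off),
                 method = "Nelder-Mead",
                 control = list(reltol = reltol, maxit = maxit))
      o$par <- o$par + off
      improved <- is.null(best) || o$value < best$value - 1e-6
      if (is.null(best) || o$value < best$value) best <- o
      th <- best$par
      if (!improved) break
    }
    best
  }

  fits <- .with_seed(seed, function() {
    lapply(seq_len(n_restarts), function(i) {
      th <- if (i == 1) theta0 else theta0 + rnorm(4, 0, 0.7)
      run_start(th)
    })
  })
  vals <- vapply(fits, `[[`, numeric(1), "value")
  best <- fits[[which.min(vals)]]
  structure(list(params = map(best$par),
                 ks_stat = best$value,
                 n_trials = n,
                 n_restarts = n_restarts,
                 converged = best$convergence == 0,
                 restart_values = vals),
            class = "dm_fit")
}

#' @export
print.dm_fit <- function(x, ...) {
  cat(sprintf(
    "diffusion fit (KS): a=%.3f v=%.3f t0=%.3f st0=%.3f | D=%.4f n=%d%s\n",
    x$params$a, x$params$v, x$params$t0, x$params$st0, x$ks_stat,
    x$n_trials, if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Fit every subject-task cell of a dataset
#'
#' @param trials Cleaned trial data frame.
#' @param seed Base seed; each cell uses `seed + cell index` for its
#'   restart perturbations, so the whole table is reproducible.
#' @inheritParams fit_subject_task
#' @return A data frame with one row per subject and task:
#'   `a, v, t0, st0, ks_stat, n_trials, converged` (cells with too few
#'   trials get `NA` estimates and `converged = FALSE`).
#' @export
fit_dataset <- function(trials, min_trials = 10, n_restarts = 5,
                        reltol = 1e-5, maxit = 400, seed = 1) {
  key <- interaction(trials$subject_id, trials$task, drop = TRUE)
  parts <- split(trials, key)
  rows <- lapply(seq_along(parts), function(i) {
    d <- parts[[i]]
    base <- data.frame(subject_id = d$subject_id[1], group = d$group[1],
                       task = d$task[1], stringsAsFactors = FALSE)
    fit <- tryCatch(
      fit_subject_task(d, min_trials = min_trials,
                       n_restarts = n_restarts, reltol = reltol,
                       maxit = maxit, seed = seed + i),
      error = function(e) NULL)
    if (is.null(fit)) {
      cbind(base, data.frame(a = NA_real_, v = NA_real_, t0 = NA_real_,
                             st0 = NA_real_, ks_stat = NA_real_,
                             n_trials = nrow(d), converged = FALSE))
    } else {
      cbind(base, data.frame(a = fit$params$a, v = fit$params$v,
                             t0 = fit$params$t0, st0 = fit$params$st0,
                             ks_stat = fit$ks_stat,
                             n_trials = fit$n_trials,
                             converged = fit$converged))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$subject_id, out$task), , drop = FALSE]
}

#' Predicted versus observed accuracy and RT quartiles
#'
#' Pairs the model-implied accuracy and RT quartiles at the fitted
#' parameters with their observed counterparts for one subject-task
#' cell; the standard graphical model-fit check (one point per subject
#' in a predicted-observed scatter).
#'
#' @param fit A `dm_fit` object.
#' @param trials The trials the fit was computed from.
#' @param mode Quartile convention passed to [predicted_quartiles()].
#' @return A list with `predicted` and `observed`, each holding
#'   `accuracy` and `quartiles`, plus the `residuals`
#'   (observed - predicted quartiles).
#' @export
assess_fit <- function(fit, trials, mode = c("all", "correct")) {
  mode <- match.arg(mode)
  if (!fit$converged)
    warning("assessing a fit flagged as not converged")
  pred <- predicted_quartiles(fit$params, mode = mode)
  rt <- if (!is.null(trials$rt_s)) trials$rt_s else trials$rt
  obs_rt <- if (mode == "all") rt else rt[trials$correct == 1]
  obs <- list(accuracy = mean_accuracy(trials),
              quartiles = quantile(obs_rt, c(0.25, 0.5, 0.75),
                                   names = FALSE))
  names(obs$quartiles) <- names(pred$quartiles)
  list(predicted = pred, observed = obs,
       residuals = obs$quartiles - pred$quartiles)
}
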