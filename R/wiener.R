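#' Probability of a correct response
#'
#' For an unbiased diffusion process (start `a/2`, unit diffusion
#' coefficient) the probability of absorption at the correct boundary is
#' `exp(a v) / (1 + exp(a v))`; it depends on the parameters only through
#' the product `a * v`.
#'
#' @param params A [diffusion_params()] object.
#' @return A probability in (0, 1).
#' @examples
#' p_correct(diffusion_params(a = 1.5, v = 2.44))  # ~0.975
#' @export
p_correct <- function(params) {
  p <- .as_dp(params)
  plogis(p$a * p$v)
}

#' Expected decision time
#'
#' Mean time the diffusion process itself takes to reach a boundary,
#' `(a / (2 v)) * tanh(a v / 2)`, with the drift-free limit `a^2 / 4`.
#' Strictly positive and decreasing in `|v|` at fixed `a`.
#'
#' @inheritParams p_correct
#' @return Expected decision time in seconds.
#' @export
mean_decision_time <- function(params) {
  p <- .as_dp(params)
  if (abs(p$a * p$v) < 1e-9) return(p$a^2 / 4)
  (p$a / (2 * p$v)) * tanh(p$a * p$v / 2)
}

#' Expected response time
#'
#' Expected total response time: expected decision time plus the mean
#' non-decision time `t0`.  The uniform non-decision window `st0` is
#' centred on `t0` and does not shift the mean.
#'
#' @inheritParams p_correct
#' @return Expected response time in seconds.
#' @export
expected_rt <- function(params) {
  p <- .as_dp(params)
  mean_decision_time(p) + p$t0
}

.boundary_arg <- function(boundary) {
  match.arg(boundary, c("correct", "error"))
}

#' Defective first-passage-time density
#'
#' Density of the decision time `Td` (no non-decision component) jointly
#' with absorption at the named boundary.  Integrates over `(0, Inf)` to
#' [p_correct()] at the correct boundary and to its complement at the
#' error boundary.  Evaluated with the classical image (small-time) and
#' eigenfunction (large-time) series with an automatic crossover.
#'
#' @inheritParams p_correct
#' @param t Vector of decision times in seconds (positive).
#' @param boundary `"correct"` or `"error"`.
#' @return Density values, same length as `t`.
#' @export
fpt_density <- function(t, params, boundary = c("correct", "error")) {
  p <- .as_dp(params)
  boundary <- .boundary_arg(boundary)
  if (any(!is.finite(t)))
    stop("'t' must be finite")
  .wfpt_density_cpp(as.numeric(t), p$a, p$v, 0.5, boundary == "error")
}

#' Defective first-passage-time distribution function
#'
#' `P(Td <= t, absorbed at boundary)`.  Nondecreasing in `t`, 0 at
#' `t = 0`, and tends to the defective mass ([p_correct()] or its
#' complement) as `t` grows.
#'
#' @inheritParams fpt_density
#' @param t Vector of decision times in seconds (non-negative; `Inf`
#'   returns the total defective mass).
#' @return Probabilities, same length as `t`.
#' @export
fpt_cdf <- function(t, params, boundary = c("correct", "error")) {
  p <- .as_dp(params)
  boundary <- .boundary_arg(boundary)
  .wfpt_cdf_cpp(as.numeric(t), p$a, p$v, 0.5, boundary == "error")
}

# P(hit boundary, Td + Ter <= t) with Ter ~ U(t0 - st0/2, t0 + st0/2):
# recovered from the signed CDF (the convolution itself lives in C++
# beside the series code).  q is the error probability.
.conv_cdf <- function(t, params, boundary) {
  p <- .as_dp(params)
  q <- 1 - p_correct(p)
  gl <- .gauss_legendre_01(12L)
  if (boundary == "correct") {
    .signed_cdf_cpp(pmax(t, 0), p$a, p$v, p$t0, p$st0, gl$x, gl$w) - q
  } else {
    q - .signed_cdf_cpp(-pmax(t, 0), p$a, p$v, p$t0, p$st0, gl$x, gl$w)
  }
}

#' Signed response-time distribution function
#'
#' The joint response/RT distribution on one axis: error responses are
#' mapped to the negative half line (value `-rt`), correct responses to
#' the positive half line.  This is the model-side object the
#' Kolmogorov-Smirnov objective compares against its empirical
#' counterpart.  Obtained by convolving the defective decision-time
#' distributions with the uniform non-decision window.
#'
#' @inheritParams p_correct
#' @param t_signed Vector of signed times (any real values).
#' @return Probabilities in `[0, 1]`; the value at 0 equals the error
#'   probability.
#' @export
signed_rt_cdf <- function(t_signed, params) {
  p <- .as_dp(params)
  gl <- .gauss_legendre_01(12L)
  .signed_cdf_cpp(as.numeric(t_signed), p$a, p$v, p$t0, p$st0,
                  gl$x, gl$w)
}

#' Simulate diffusion-model trials
#'
#' Draws trial outcomes (correct/error and total response time) by
#' Euler-Maruyama simulation of the decision process (step `dt`, default
#' 1e-4 s) plus a uniform non-decision time draw.  Over many trials the
#' simulated accuracy and mean RT converge to [p_correct()] and
#' [expected_rt()]; the discretisation bias at the default step is
#' checked in the package test suite.  Uses R's RNG stream, so results
#' are reproducible under `set.seed()`.
#'
#' @inheritParams p_correct
#' @param n Number of trials.
#' @param dt Euler step size in seconds.
#' @param drift Optional vector of per-trial drift rates (length `n`)
#'   overriding `params$v`, used for designs whose difficulty varies by
#'   item.
#' @return A data frame with columns `correct` (0/1) and `rt` (seconds).
#' @examples
#' set.seed(1)
#' trials <- simulate_trials(500, diffusion_params(1.5, 2, 0.7, 0.2))
#' mean(trials$correct)
#' @export
simulate_trials <- function(n, params, dt = 1e-4, drift = NULL) {
  p <- .as_dp(params)
  stopifnot(n >= 1, dt > 0, dt <= 1e-3)
  v <- if (is.null(drift)) rep(p$v, n) else {
    stopifnot(length(drift) == n)
    as.numeric(drift)
  }
  sim <- .sim_wiener_cpp(v, p$a, p$t0, p$st0, dt)
  data.frame(correct = sim$correct, rt = sim$rt)
}

#' Model-implied accuracy and RT quartiles
#'
#' Accuracy from the closed form and the 25/50/75% quantiles of the
#' model RT distribution, found by bracketing and bisection of the
#' convolved CDF to 1e-6 s.  Quartiles can be taken over the
#' boundary-pooled RT distribution (`mode = "all"`) or over correct
#' responses only (`mode = "correct"`); both conventions are offered
#' because published fit plots do not always state which is used.
#'
#' @inheritParams p_correct
#' @param mode `"all"` (pooled over both response types) or `"correct"`.
#' @param probs Quantile levels, default the quartiles.
#' @return A list with `accuracy` and `quartiles` (named vector,
#'   seconds).
#' @export
predicted_quartiles <- function(params, mode = c("all", "correct"),
                                probs = c(0.25, 0.5, 0.75)) {
  p <- .as_dp(params)
  mode <- match.arg(mode)
  pc <- p_correct(p)
  mass_fun <- if (mode == "all") {
    function(t) .conv_cdf(t, p, "correct") + .conv_cdf(t, p, "error")
  } else {
    function(t) .conv_cdf(t, p, "correct") / pc
  }
  lo0 <- max(p$t0 - p$st0 / 2, 0)
  hi0 <- p$t0 + p$st0 / 2 + p$a^2 + 1
  while (mass_fun(hi0) < max(probs) + 1e-9) hi0 <- hi0 * 2
  qs <- vapply(probs, function(q) {
    lo <- lo0; hi <- hi0
    while (hi - lo > 1e-6) {
      mid <- (lo + hi) / 2
      if (mass_fun(mid) < q) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
  list(accuracy = pc,
       quartiles = setNames(qs, paste0("q", round(100 * probs))))
}
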