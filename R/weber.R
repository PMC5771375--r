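#' Probability correct under the linear ANS model
#'
#' Two dot sets of sizes `n1`, `n2` are represented as Gaussians with
#' means `n` and standard deviations `w * n` (linear scalar variability).
#' The probability of choosing the larger set is then
#' `Phi(|n1 - n2| / (w * sqrt(n1^2 + n2^2)))`, equivalently
#' `1 - erfc(|n1 - n2| / (sqrt(2) w sqrt(n1^2 + n2^2))) / 2`.  It
#' decreases from 1 (noiseless, `w -> 0`) to 1/2 (pure guessing,
#' `w -> Inf`).
#'
#' @param n1,n2 Dot counts (vectors, `n1 != n2` elementwise).
#' @param w Weber fraction, non-negative scalar.
#' @return Probabilities of a correct (larger-set) response.
#' @examples
#' weber_p_correct(12, 10, 0.25)  # ~0.696
#' @export
weber_p_correct <- function(n1, n2, w) {
  stopifnot(length(w) == 1L, w >= 0)
  if (any(n1 == n2))
    stop("equal dot counts: the comparison has no correct answer")
  if (w == 0) return(rep(1, length(n1)))
  pnorm(abs(n1 - n2) / (w * sqrt(n1^2 + n2^2)))
}

#' Maximum-likelihood Weber fraction
#'
#' Maximises the Bernoulli log-likelihood of the observed correctness
#' indicators under [weber_p_correct()] over `w` in `[0, 3]`: a dense
#' grid (step `grid_step`) followed by golden-section refinement in the
#' bracketing interval.  Optima at either end of the interval are
#' flagged (`at_boundary`): all-correct data push `w` toward 0,
#' chance-level data toward the upper limit 3.
#'
#' @param trials Non-symbolic trial data frame with `n1`, `n2` and
#'   `correct` columns (trials removed by preprocessing should not be
#'   passed in).
#' @param grid_step Grid resolution for the first pass.
#' @param upper Upper end of the admissible interval.
#' @return An object of class `weber_fit`: `w`, `loglik`,
#'   `at_boundary`, `n_trials`.
#' @export
fit_weber <- function(trials, grid_step = 0.005, upper = 3) {
  ok <- trials$n1 != trials$n2
  n1 <- trials$n1[ok]; n2 <- trials$n2[ok]
  corr <- trials$correct[ok]
  if (!length(n1)) stop("no informative trials (need n1 != n2)")
  negll <- function(w) {
    p <- weber_p_correct(n1, n2, w)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(corr * log(p) + (1 - corr) * log(1 - p))
  }
  grid <- seq(grid_step, upper, by = grid_step)
  vals <- vapply(grid, negll, numeric(1))
  i <- which.min(vals)
  lo <- if (i == 1) 0 else grid[i - 1]
  hi <- if (i == length(grid)) upper else grid[i + 1]
  opt <- optimize(negll, c(lo, hi), tol = 1e-6)
  w_hat <- opt$minimum
  # accept the interval end itself when the likelihood is monotone there
  if (i == 1 && negll(grid_step * 0.01) <= opt$objective + 1e-9)
    w_hat <- 0
  if (i == length(grid) && negll(upper) <= opt$objective + 1e-9)
    w_hat <- upper
  at_boundary <- w_hat <= grid_step | w_hat >= upper - grid_step
  structure(list(w = w_hat, loglik = -negll(max(w_hat, 1e-12)),
                 at_boundary = at_boundary, n_trials = length(n1)),
            class = "weber_fit")
}

#' @export
print.weber_fit <- function(x, ...) {
  cat(sprintf("Weber fraction fit: w = %.4f (loglik %.2f, n = %d)%s\n",
              x$w, x$loglik, x$n_trials,
              if (x$at_boundary) " [boundary]" else ""))
  invisible(x)
}
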