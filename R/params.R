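#' Diffusion-model parameter set
#'
#' Bundles the four estimated quantities of the unbiased diffusion model:
#' boundary separation `a` (response caution), mean drift rate `v`
#' (ability, signed toward the correct boundary, evidence units per
#' second), mean non-decision time `t0` (seconds) and its inter-trial
#' uniform range `st0` (seconds).  The starting point is fixed at `a/2`
#' (no response bias) and the diffusion coefficient at 1; neither is ever
#' a free parameter.
#'
#' @param a Boundary separation, must be positive.
#' @param v Mean drift rate; positive values drift toward the correct
#'   response.
#' @param t0 Mean non-decision time in seconds, non-negative.
#' @param st0 Inter-trial range of non-decision time in seconds;
#'   non-decision time is uniform on `[t0 - st0/2, t0 + st0/2]`, so
#'   `t0 - st0/2` must be non-negative.
#' @return An object of class `diffusion_params`.
#' @examples
#' diffusion_params(a = 1.5, v = 2.44, t0 = 0.73, st0 = 0.23)
#' @export
diffusion_params <- function(a, v, t0 = 0, st0 = 0) {
  stopifnot(is.numeric(a), is.numeric(v), is.numeric(t0), is.numeric(st0),
            length(a) == 1L, length(v) == 1L, length(t0) == 1L,
            length(st0) == 1L)
  if (!is.finite(a) || a <= 0)
    stop("boundary separation 'a' must be a positive finite number")
  if (!is.finite(v))
    stop("drift rate 'v' must be finite")
  if (!is.finite(t0) || t0 < 0)
    stop("non-decision time 't0' must be non-negative")
  if (!is.finite(st0) || st0 < 0)
    stop("non-decision range 'st0' must be non-negative")
  if (t0 - st0 / 2 < -1e-12)
    stop("'t0 - st0/2' is negative: non-decision time would go below zero")
  structure(list(a = a, v = v, t0 = t0, st0 = st0),
            class = "diffusion_params")
}

#' @export
print.diffusion_params <- function(x, ...) {
  cat(sprintf(
    "diffusion parameters: a = %.4g, v = %.4g, t0 = %.4g s, st0 = %.4g s\n",
    x$a, x$v, x$t0, x$st0))
  invisible(x)
}

#' @export
as.data.frame.diffusion_params <- function(x, ...) {
  data.frame(a = x$a, v = x$v, t0 = x$t0, st0 = x$st0)
}

# accept either a diffusion_params object or a bare list with a/v/t0/st0
.as_dp <- function(params) {
  if (inherits(params, "diffusion_params")) return(params)
  diffusion_params(params$a, params$v,
                   if (is.null(params$t0)) 0 else params$t0,
                   if (is.null(params$st0)) 0 else params$st0)
}
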