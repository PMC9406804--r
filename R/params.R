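#' Continuous random-walk parameters
#'
#' Physical parameters of the continuous drift-diffusion description of
#' per-follicle ISR activity: `dX = -V dt + sqrt(2 D) dW`, started at `x0`,
#' absorbed at the growth threshold 0 and (optionally) the death threshold
#' `L`.
#'
#' @param D Diffusivity, per year.  Size of the stochastic ISR fluctuations.
#'   Must be positive.  Default 0.004, the value fitted to human primordial
#'   follicle counts.
#' @param V Drift, per year.  Deterministic rate of decrease of ISR activity
#'   (biologically, efficiency of cellular repair).  May be negative.
#'   Default 0.051, the fitted value.
#' @param x0 Initial ISR activity (dimensionless).  The activity scale is
#'   arbitrary, so 1 is used throughout.
#' @param L Death threshold (dimensionless), above `x0`.  `Inf` (the
#'   default) removes the upper boundary; the decay curve for any `L >= 2`
#'   is practically indistinguishable from the `L = Inf` limit at the
#'   default `D` and `V`.
#' @return An object of class `"continuous_params"`: a list with elements
#'   `D`, `V`, `x0`, `L`.
#' @seealso [fp_survival()], [expected_reserve()], [params_from_discrete()]
#' @export
#' @examples
#' continuous_params()            # fitted human parameters
#' continuous_params(L = 2)       # with a finite death threshold
continuous_params <- function(D = 0.004, V = 0.051, x0 = 1, L = Inf) {
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D <= 0)
    stop("D must be a single positive finite number", call. = FALSE)
  if (!is.numeric(V) || length(V) != 1L || !is.finite(V))
    stop("V must be a single finite number", call. = FALSE)
  if (!is.numeric(x0) || length(x0) != 1L || !is.finite(x0) || x0 <= 0)
    stop("x0 must be a single positive finite number", call. = FALSE)
  if (!is.numeric(L) || length(L) != 1L || is.na(L) || L <= x0)
    stop("L must exceed x0 (use L = Inf for no death threshold)",
         call. = FALSE)
  structure(list(D = D, V = V, x0 = x0, L = L), class = "continuous_params")
}

#' @export
print.continuous_params <- function(x, ...) {
  cat("Continuous walk parameters:\n")
  cat(sprintf("  D  = %g / yr (diffusivity)\n", x$D))
  cat(sprintf("  V  = %g / yr (drift)\n", x$V))
  cat(sprintf("  x0 = %g, L = %g\n", x$x0, x$L))
  invisible(x)
}

#' Discrete random-walk parameters
#'
#' Step parameters of the discrete walk: ISR activity moves by `+dx` with
#' probability `p` and `-dx` with probability `1 - p` every `dt` years.
#'
#' @param dx Step size (dimensionless), positive.
#' @param dt Time step in years, positive.
#' @param p Probability of an upward step, in `[0, 1]`.
#' @return An object of class `"discrete_params"`.
#' @seealso [params_from_discrete()], [discrete_from_params()]
#' @export
discrete_params <- function(dx, dt, p) {
  if (!is.numeric(dx) || length(dx) != 1L || !is.finite(dx) || dx <= 0)
    stop("dx must be a single positive finite number", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive finite number", call. = FALSE)
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("p must be a probability in [0, 1]", call. = FALSE)
  structure(list(dx = dx, dt = dt, p = p), class = "discrete_params")
}

#' @export
print.discrete_params <- function(x, ...) {
  cat(sprintf("Discrete walk: dx = %g, dt = %g yr, p(up) = %g\n",
              x$dx, x$dt, x$p))
  invisible(x)
}

#' Map discrete step parameters to continuous diffusivity and drift
#'
#' The discrete walk with step `dx`, time step `dt` and up-probability `p`
#' corresponds, for small steps, to the continuous model with
#' `D = dx^2 / (2 dt)` and `V = (2 dx / dt) (1/2 - p)`.
#'
#' @param disc A [discrete_params()] object.
#' @param x0,L Thresholds passed through to the returned parameter object.
#' @return A [continuous_params()] object.
#' @export
#' @examples
#' params_from_discrete(discrete_params(dx = 1, dt = 1, p = 0.5))  # D = 0.5, V = 0
params_from_discrete <- function(disc, x0 = 1, L = Inf) {
  stopifnot(inherits(disc, "discrete_params"))
  D <- disc$dx^2 / (2 * disc$dt)
  V <- (2 * disc$dx / disc$dt) * (0.5 - disc$p)
  continuous_params(D = D, V = V, x0 = x0, L = L)
}

#' Map continuous diffusivity and drift to discrete step parameters
#'
#' Inverts the discrete-to-continuous map under the convention
#' `dx = sqrt(2 D dt)`, giving `p = 1/2 - V dt / (2 dx)`.  Round-trips with
#' [params_from_discrete()] to machine precision.
#'
#' @param D Diffusivity, per year (positive).
#' @param V Drift, per year.
#' @param dt Time step in years (positive).
#' @return A [discrete_params()] object.
#' @export
#' @examples
#' discrete_from_params(0.004, 0.051, 1 / 12)
discrete_from_params <- function(D, V, dt) {
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D <= 0)
    stop("D must be a single positive finite number", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive finite number", call. = FALSE)
  dx <- sqrt(2 * D * dt)
  p <- 0.5 - V * dt / (2 * dx)
  if (is.na(p) || p < 0 || p > 1) {
    vmax <- dx / dt  # |V| at which p leaves [0, 1]
    stop(sprintf(
      "drift too large for the step size: |V| must not exceed sqrt(2 D / dt) = %g / yr",
      vmax), call. = FALSE)
  }
  discrete_params(dx = dx, dt = dt, p = p)
}
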