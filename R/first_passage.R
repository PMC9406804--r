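# Closed-form first-passage mathematics of the drifted walk.
#
# With no death threshold (L = Inf) the exit time to the growth threshold at
# 0 from x0 > 0 under dX = -V dt + sqrt(2D) dW has the inverse-Gaussian-type
# survival function
#
#   S(t) = Phi((x0 - V t)/sqrt(2 D t))
#          - exp(V x0 / D) Phi(-(x0 + V t)/sqrt(2 D t)).
#
# The second term is the product of a huge exponential and a tiny normal
# tail (V x0 / D = 12.75 at the default parameters); it is evaluated as
# exp(V x0 / D + pnorm(..., log.p = TRUE)) so that neither factor is formed
# on its own.

# Vectorised over t and V (internal workhorse).
.surv_lower <- function(t, D, V, x0) {
  n <- max(length(t), length(V))
  t <- rep_len(t, n); V <- rep_len(V, n)
  out <- numeric(n)
  zero <- t <= 0
  out[zero] <- 1
  if (any(!zero)) {
    tt <- t[!zero]; vv <- V[!zero]
    s <- sqrt(2 * D * tt)
    S <- pnorm((x0 - vv * tt) / s) -
      exp(vv * x0 / D + pnorm(-(x0 + vv * tt) / s, log.p = TRUE))
    out[!zero] <- pmin(pmax(S, 0), 1)
  }
  out
}

#' Exit-time survival function of the drifted walk (no death threshold)
#'
#' Probability that a follicle whose ISR activity starts at `x0` has not yet
#' crossed the growth threshold at 0 by age `t`, in the limit of an
#' infinitely high death threshold.  Evaluated in a numerically stable form
#' (the `exp(V x0 / D)` factor never appears alone), so large `V / D` ratios
#' are safe.
#'
#' @param t Age(s) in years, non-negative.  Vectorised.
#' @param params A [continuous_params()] object with `L = Inf`.
#' @return Survival probabilities in `[0, 1]`; `S(0) = 1` exactly, and for
#'   `V > 0`, `S(t) -> 0` as `t -> Inf`.
#' @seealso [finite_L_survival()] for a finite death threshold,
#'   [expected_reserve()] for the decay curve.
#' @export
#' @examples
#' p <- continuous_params()
#' fp_survival(c(0, 25, 51), p)
fp_survival <- function(t, params) {
  stopifnot(inherits(params, "continuous_params"))
  if (is.finite(params$L))
    stop("fp_survival requires L = Inf; use finite_L_survival for finite L",
         call. = FALSE)
  if (any(!is.finite(t)) || any(t < 0))
    stop("t must be non-negative and finite", call. = FALSE)
  .surv_lower(t, params$D, params$V, params$x0)
}

#' Expected number of primordial follicles remaining at a given age
#'
#' The expected reserve is `N * S(t)`: with independent, identically
#' distributed exit times across the starting supply of `N` follicles, the
#' expected count remaining at age `t` is the starting supply times the
#' exit-time survival function.
#'
#' @param t Age(s) in years.  Vectorised.
#' @param N Starting supply (follicle count at birth), positive.
#' @param params A [continuous_params()] object (`L = Inf`).
#' @return Expected follicle counts.
#' @export
#' @examples
#' expected_reserve(c(0, 51), N = 3.23e5, continuous_params())
expected_reserve <- function(t, N, params) {
  if (!is.numeric(N) || length(N) != 1L || !is.finite(N) || N <= 0)
    stop("N must be a single positive number", call. = FALSE)
  N * fp_survival(t, params)
}

#' Age at which the expected decay curve crosses the menopause threshold
#'
#' Solves `expected_reserve(t) = threshold` for `t` by bracketing root
#' search.  At the default parameters and the median starting supply
#' `3.23e5`, the curve crosses the 1,000-follicle threshold at an age that
#' rounds to 51 years, the population median age at natural menopause.
#'
#' @param N Starting supply, must exceed `threshold`.
#' @param params A [continuous_params()] object (`L = Inf`).
#' @param threshold Menopause threshold in follicles (default 1,000).
#' @return The crossing age in years (absolute tolerance `1e-6` yr).
#'   Returns 0 with a warning when `threshold >= N`; returns `NA` with a
#'   warning if the curve never falls below the threshold (possible when
#'   `V <= 0`).
#' @export
#' @examples
#' anm_from_curve(3.23e5, continuous_params())  # about 51 years
anm_from_curve <- function(N, params, threshold = 1000) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("threshold must be a single positive count", call. = FALSE)
  if (threshold >= N) {
    warning("starting supply is not above the threshold; ANM is 0")
    return(0)
  }
  f <- function(t) expected_reserve(t, N, params) - threshold
  upper <- 200
  while (f(upper) > 0 && upper < 1e5) upper <- upper * 2
  if (f(upper) > 0) {
    warning("expected reserve never falls below the threshold")
    return(NA_real_)
  }
  uniroot(f, c(0, upper), tol = 1e-6)$root
}

#' Exit-time survival with a finite death threshold
#'
#' Survival of the two-sided absorbing problem on `(0, L)`: the follicle
#' remains in the reserve while its ISR activity has touched neither the
#' growth threshold 0 nor the death threshold `L`.  Computed by the
#' eigenfunction series of the drift-diffusion equation, truncated when the
#' next term magnitude falls below `1e-12` (hard cap `1e4` terms).
#' Converges to [fp_survival()] as `L -> Inf`; at the default `D`, `V` the
#' difference is already negligible for `L = 2`.
#'
#' @param t Age(s) in years.  Vectorised.
#' @param params A [continuous_params()] object with finite `L > x0`.
#' @return Survival probabilities in `[0, 1]`.
#' @export
#' @examples
#' finite_L_survival(c(10, 30), continuous_params(L = 2))
finite_L_survival <- function(t, params) {
  stopifnot(inherits(params, "continuous_params"))
  L <- params$L
  if (!is.finite(L)) stop("finite_L_survival requires a finite L", call. = FALSE)
  D <- params$D; V <- params$V; x0 <- params$x0
  if (x0 <= 0 || x0 >= L) stop("x0 must lie strictly inside (0, L)", call. = FALSE)
  if (any(!is.finite(t)) || any(t < 0))
    stop("t must be non-negative and finite", call. = FALSE)
  a <- -V / (2 * D)                       # exponent coefficient mu / sigma^2
  eaL <- exp(a * L)
  pre <- exp(V * x0 / (2 * D))
  vapply(t, function(ti) {
    if (ti == 0) return(1)
    acc <- 0
    decay0 <- -V^2 * ti / (4 * D)
    prev <- Inf  # sin(k x0) can vanish exactly (e.g. x0 = L/2), so demand
    for (n in seq_len(10000L)) {  # two consecutive sub-tolerance terms
      k <- n * pi / L
      term <- (2 / L) * pre * exp(decay0 - D * k^2 * ti) *
        sin(k * x0) * k * (1 - (-1)^n * eaL) / (a^2 + k^2)
      acc <- acc + term
      if (n > 3 && abs(term) < 1e-12 && prev < 1e-12) break
      prev <- abs(term)
    }
    min(max(acc, 0), 1)
  }, numeric(1))
}

#' Probability of dying (hitting the death threshold) before activating
#'
#' Probability that the walk reaches the death threshold `L` before the
#' growth threshold 0, starting from `x0`.  By the scale function of the
#' drifted diffusion this is `(exp(V x0 / D) - 1) / (exp(V L / D) - 1)`,
#' evaluated in log space so large `V L / D` does not overflow; `V = 0` is
#' handled as the limit `x0 / L`.  At the default parameters with `L = 2`
#' the probability is about `exp(-V / D) = 2.9e-6`, which is why the
#' one-sided decay curve is an excellent approximation.
#'
#' @param params A [continuous_params()] object with finite `L`.
#' @return A probability.
#' @export
#' @examples
#' hit_upper_probability(continuous_params(L = 2))
hit_upper_probability <- function(params) {
  stopifnot(inherits(params, "continuous_params"))
  L <- params$L
  if (!is.finite(L)) stop("hit_upper_probability requires a finite L", call. = FALSE)
  D <- params$D; V <- params$V; x0 <- params$x0
  if (x0 <= 0 || x0 >= L) stop("x0 must lie strictly inside (0, L)", call. = FALSE)
  a0 <- V * x0 / D
  aL <- V * L / D
  if (V == 0) return(x0 / L)
  if (V > 0) {
    # log(e^a - 1) = a + log1p(-e^-a), stable for any a > 0
    exp((a0 + log1p(-exp(-a0))) - (aL + log1p(-exp(-aL))))
  } else {
    expm1(a0) / expm1(aL)
  }
}
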