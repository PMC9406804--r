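# Stochastic simulation of the discrete walk and its deterministic
# (occupancy-propagation) counterpart.  Positions live on a lattice of step
# dx; x0 and L are snapped to the nearest lattice site.

#' Configuration of a discrete-walk simulation
#'
#' Describes one follicle's walk: lattice step parameters, starting
#' activity, death threshold and horizon.  `x0` and `L` are snapped to the
#' nearest lattice multiple of `dx` (an error if the snapped start lands on
#' a boundary).  An optional [drift_schedule()] makes the up-step
#' probability age-dependent via `p(age) = 1/2 - V(age) dt / (2 dx)`.
#'
#' @param disc A [discrete_params()] object; its `p` is used when no
#'   schedule is given.
#' @param x0 Initial ISR activity (default 1).
#' @param L Death threshold, or `Inf` (default) for absorption at 0 only.
#' @param max_age Simulation horizon in years (default 120); walks still in
#'   the reserve at the horizon are censored.
#' @param schedule Optional [drift_schedule()] of mean drift by age.
#' @return An object of class `"walk_config"`.
#' @export
walk_config <- function(disc, x0 = 1, L = Inf, max_age = 120,
                        schedule = NULL) {
  stopifnot(inherits(disc, "discrete_params"))
  if (!is.null(schedule)) stopifnot(inherits(schedule, "drift_schedule"))
  if (!is.numeric(max_age) || length(max_age) != 1L || max_age <= 0)
    stop("max_age must be a single positive number of years", call. = FALSE)
  x0_idx <- as.integer(round(x0 / disc$dx))
  L_idx <- if (is.finite(L)) as.integer(round(L / disc$dx)) else NA_integer_
  if (x0_idx <= 0L)
    stop("x0 snaps onto (or below) the growth threshold; increase x0 or refine dx",
         call. = FALSE)
  if (!is.na(L_idx) && x0_idx >= L_idx)
    stop("x0 snaps onto (or above) the death threshold L", call. = FALSE)
  structure(list(disc = disc, x0 = x0, L = L, x0_idx = x0_idx,
                 L_idx = L_idx, max_age = max_age, schedule = schedule),
            class = "walk_config")
}

# Up-step probabilities for every step of a config's horizon.
.p_by_step <- function(cfg) {
  disc <- cfg$disc
  n_steps <- as.integer(ceiling(cfg$max_age / disc$dt))
  if (is.null(cfg$schedule)) return(rep(disc$p, 1L))
  ages <- (seq_len(n_steps) - 1L) * disc$dt
  v <- drift_at_age(cfg$schedule, ages)
  p <- 0.5 - v * disc$dt / (2 * disc$dx)
  if (any(p < 0 | p > 1))
    stop("schedule drift too large for the lattice: p outside [0, 1]",
         call. = FALSE)
  p
}

.exit_sides <- c("growth", "death", "censored")

#' Simulate one follicle's walk to exit
#'
#' Walks from the snapped `x0` in steps of `+dx` (probability `p`) or `-dx`
#' until the position first reaches `<= 0` (growth activation) or `>= L`
#' (death), or the horizon is reached (censored).
#'
#' @param cfg A [walk_config()] object.
#' @return A list with `exit_time` (years, a multiple of `dt`; equal to
#'   `max_age` when censored) and `exit_side` (one of `"growth"`,
#'   `"death"`, `"censored"`).
#' @export
simulate_exit <- function(cfg) {
  rec <- sample_exit_times(1L, cfg)
  list(exit_time = rec$exit_time[1L], exit_side = rec$exit_side[1L])
}

#' Simulate many independent follicle walks
#'
#' Draws `n` independent exit records.  Reproducible: the same `seed` and
#' configuration give identical records.
#'
#' @param n Number of walks (0 allowed).
#' @param cfg A [walk_config()] object.
#' @param seed Optional integer seed (`set.seed` is called when supplied).
#' @return A data frame with columns `exit_time` (years) and `exit_side`
#'   (factor: growth / death / censored).
#' @export
#' @examples
#' cfg <- walk_config(discrete_from_params(0.004, 0.051, 1 / 12), L = 2)
#' sample_exit_times(5, cfg, seed = 1)
sample_exit_times <- function(n, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "walk_config"))
  if (!is.numeric(n) || length(n) != 1L || n < 0)
    stop("n must be a single non-negative count", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  dt <- cfg$disc$dt
  max_steps <- as.integer(ceiling(cfg$max_age / dt))
  L_idx <- if (is.na(cfg$L_idx)) -1L else cfg$L_idx
  res <- cpp_sample_exit_steps(n, cfg$x0_idx, L_idx, .p_by_step(cfg),
                               max_steps)
  data.frame(
    exit_time = pmin(res$steps * dt, cfg$max_age),
    exit_side = factor(.exit_sides[res$side + 1L], levels = .exit_sides)
  )
}

#' Deterministic occupancy propagation of the lattice walk
#'
#' Propagates the exact marginal law of the walk: at each step a fraction
#' `p` of the mass at every interior lattice site moves up one site and
#' `1 - p` moves down; mass crossing the boundaries accumulates as absorbed
#' (growth side below, death side above).  This is the exact expectation of
#' the Monte-Carlo walk, including under age-varying drift, and yields the
#' survival curve and per-step exit hazards.
#'
#' @param cfg A [walk_config()] object.  A finite `L` is required; with
#'   `L = Inf` an effective ceiling is chosen high enough that the
#'   death-side hit probability is below `1e-10` (falling back to
#'   `x0 + 10` when the drift is not positive).
#' @param steps Number of steps to propagate (default: the full horizon).
#' @return A list with `time` (ages after 0..steps steps), `survival`
#'   (interior mass), `hazard` (per-step exit hazard), cumulative
#'   `absorbed_growth` and `absorbed_death`, and the final interior `mass`.
#' @export
#' @examples
#' cfg <- walk_config(discrete_from_params(0.004, 0.051, 1 / 12), L = 2)
#' occ <- propagate_occupancy(cfg, steps = 600)
#' occ$survival[601] + occ$absorbed_growth[601] + occ$absorbed_death[601]  # 1
propagate_occupancy <- function(cfg, steps = NULL) {
  stopifnot(inherits(cfg, "walk_config"))
  dt <- cfg$disc$dt
  if (is.null(steps)) steps <- as.integer(ceiling(cfg$max_age / dt))
  steps <- as.integer(steps)
  if (steps < 0) stop("steps must be non-negative", call. = FALSE)
  K <- if (!is.na(cfg$L_idx)) cfg$L_idx else {
    .effective_upper_index(cfg)
  }
  mass <- numeric(K - 1L)
  mass[cfg$x0_idx] <- 1
  res <- cpp_propagate_occupancy(mass, 0, 0, .p_by_step(cfg), steps)
  surv <- res$survival
  haz <- c(NA_real_, ifelse(surv[-length(surv)] > 0,
                            (surv[-length(surv)] - surv[-1L]) /
                              surv[-length(surv)], 0))
  haz <- pmin(pmax(haz, 0), 1)  # clear summation noise of order eps
  list(time = (0:steps) * dt, survival = surv, hazard = haz,
       absorbed_growth = res$absorbed_growth,
       absorbed_death = res$absorbed_death, mass = res$mass)
}

# Lattice index of an effective death threshold when L = Inf: chosen so the
# scale-function probability of ever reaching it is < 1e-10 for the
# smallest drift in play.
.effective_upper_index <- function(cfg) {
  disc <- cfg$disc
  par <- params_from_discrete(disc)
  vmin <- if (is.null(cfg$schedule)) par$V else min(cfg$schedule$values)
  L_eff <- if (vmin > 0) cfg$x0 + 24 * par$D / vmin else cfg$x0 + 10
  max(cfg$x0_idx + 2L, as.integer(ceiling(L_eff / disc$dx)))
}
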