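# Parameter estimation: least squares on log follicle counts for (D, V),
# log-normal fit for the starting-supply distribution, and a seeded
# synthetic-count generator for recovery testing.

#' A dataset of primordial follicle counts by age
#'
#' @param age_years Ages in years.  Prenatal ages down to -0.75 are
#'   accepted on input but excluded from decay fits (the decay curve starts
#'   at birth).
#' @param pf_count Positive follicle counts (their logarithm is taken).
#' @param provenance Free-text tag recording where the records came from.
#' @return A data frame of class `"pf_count_dataset"` with columns
#'   `age_years`, `pf_count` and a `provenance` attribute.
#' @export
pf_count_dataset <- function(age_years, pf_count, provenance = "user") {
  age_years <- as.numeric(age_years)
  pf_count <- as.numeric(pf_count)
  if (length(age_years) != length(pf_count))
    stop("age_years and pf_count must have the same length", call. = FALSE)
  if (any(!is.finite(age_years)) || any(age_years < -0.75))
    stop("ages must be finite and at least -0.75 years", call. = FALSE)
  if (any(!is.finite(pf_count)) || any(pf_count <= 0))
    stop("pf_count must be positive (its logarithm is taken)", call. = FALSE)
  out <- data.frame(age_years = age_years, pf_count = pf_count)
  attr(out, "provenance") <- provenance
  class(out) <- c("pf_count_dataset", "data.frame")
  out
}

#' Sum of squared errors on log counts
#'
#' The fitting objective: the sum over records of
#' `(log E[F(age)] - log count)^2`, natural logarithms, with
#' `E[F(t)] = N * S(t)` the closed-form expected decay curve.
#'
#' @param dataset A [pf_count_dataset()] (or data frame with `age_years`,
#'   `pf_count`).
#' @param N Starting supply used for the model curve.
#' @param params A [continuous_params()] object.
#' @return A non-negative number.
#' @export
sse_log <- function(dataset, N, params) {
  ages <- dataset$age_years
  counts <- dataset$pf_count
  if (any(counts <= 0)) stop("counts must be positive", call. = FALSE)
  if (any(ages < 0))
    stop("the decay curve starts at birth; drop prenatal ages before scoring",
         call. = FALSE)
  model <- expected_reserve(ages, N, params)
  if (any(model <= 0))
    stop("model curve is not positive at all dataset ages", call. = FALSE)
  sum((log(model) - log(counts))^2)
}

#' Fit diffusivity and drift to follicle-count data
#'
#' Minimises [sse_log()] over `(D, V)` with `N` held fixed (the median
#' starting supply is estimated first, from counts near birth; see
#' [fit_lognormal_supply()]).  Optimisation is bounded L-BFGS-B on
#' `(log D, log V)` from a 5 x 5 log-spaced multi-start grid
#' (`D` in 1e-4..0.1, `V` in 0.01..0.2), because the objective surface may
#' be multimodal; deterministic given the data and settings.  A joint
#' three-parameter fit including `N` is available with `fit_N = TRUE`.
#'
#' @param dataset A [pf_count_dataset()]; only postnatal records
#'   (`age_years >= 0`) are used, and at least 3 are required.
#' @param N Fixed starting supply for the curve.
#' @param init Optional `c(D, V)` start added to the grid.
#' @param bounds List with `D` and `V` ranges (defaults `D` in (1e-6, 1),
#'   `V` in (1e-6, 1)).
#' @param fit_N Also estimate `N` (log-scale, bounded by 10 x the data
#'   range)?  Default `FALSE`.
#' @return A list of class `"fit_result"`: `estimates` (named `D`, `V`,
#'   and `N` if fitted), `objective`, `converged`, `convergence_code`,
#'   `n_used`.
#' @export
#' @examples
#' d <- generate_synthetic_counts(continuous_params(), N = 3.23e5,
#'                                ages = seq(0, 55, length.out = 30))
#' fit_decay_params(d, N = 3.23e5)$estimates
fit_decay_params <- function(dataset, N, init = NULL,
                             bounds = list(D = c(1e-6, 1), V = c(1e-6, 1)),
                             fit_N = FALSE) {
  keep <- dataset$age_years >= 0
  data <- dataset[keep, , drop = FALSE]
  if (nrow(data) < 3L)
    stop("insufficient data: at least 3 postnatal records are required",
         call. = FALSE)
  lb <- log(c(bounds$D[1], bounds$V[1]))
  ub <- log(c(bounds$D[2], bounds$V[2]))
  if (fit_N) {
    lb <- c(lb, log(max(data$pf_count) / 10))
    ub <- c(ub, log(max(data$pf_count) * 10))
  }
  obj <- function(theta) {
    D <- exp(theta[1]); V <- exp(theta[2])
    Nv <- if (fit_N) exp(theta[3]) else N
    val <- tryCatch(sse_log(data, Nv, continuous_params(D = D, V = V)),
                    error = function(e) Inf)
    if (!is.finite(val)) 1e12 else val
  }
  grid <- expand.grid(D = exp(seq(log(1e-4), log(0.1), length.out = 5)),
                      V = exp(seq(log(0.01), log(0.2), length.out = 5)))
  starts <- lapply(seq_len(nrow(grid)),
                   function(i) log(c(grid$D[i], grid$V[i])))
  if (!is.null(init)) starts <- c(list(log(init[1:2])), starts)
  if (fit_N) starts <- lapply(starts, function(s) c(s, log(N)))
  best <- NULL
  codes <- integer(0)
  for (s in starts) {
    fit <- tryCatch(
      optim(s, obj, method = "L-BFGS-B", lower = lb, upper = ub,
            control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(fit)) next
    codes <- c(codes, fit$convergence)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("optimisation failed from every start", call. = FALSE)
  est <- exp(best$par)
  names(est) <- if (fit_N) c("D", "V", "N") else c("D", "V")
  Nv <- if (fit_N) est[["N"]] else N
  objective <- sse_log(data, Nv,
                       continuous_params(D = est[["D"]], V = est[["V"]]))
  structure(list(estimates = est, objective = objective,
                 converged = best$convergence == 0,
                 convergence_code = best$convergence,
                 n_used = nrow(data)),
            class = "fit_result")
}

#' Fit the log-normal starting-supply distribution
#'
#' Maximum-likelihood fit of a log-normal to counts near birth:
#' `mu` is the mean of the natural logs and `sigma` the standard deviation
#' of the logs with denominator `n` (the MLE).  A Kolmogorov-Smirnov
#' statistic against the fitted log-normal is reported as a distributional
#' adequacy check (its p-value is approximate because the parameters are
#' estimated from the same data).  Optional percentile bootstrap intervals.
#'
#' @param counts Positive follicle counts (at least 2).
#' @param n_boot Number of bootstrap resamples for percentile confidence
#'   intervals (0 = none).
#' @param conf Confidence level for the bootstrap intervals.
#' @return A list of class `"fit_result"`: `estimates` (`mu`, `sigma`),
#'   `objective` (the maximised log-likelihood), `ks_statistic`,
#'   `ks_p_value`, and `ci` (matrix, when `n_boot > 0`).
#' @export
fit_lognormal_supply <- function(counts, n_boot = 0, conf = 0.95) {
  counts <- as.numeric(counts)
  if (length(counts) < 2L)
    stop("at least 2 counts are required", call. = FALSE)
  if (any(!is.finite(counts)) || any(counts <= 0))
    stop("counts must be positive", call. = FALSE)
  lx <- log(counts)
  n <- length(lx)
  mu <- mean(lx)
  sigma <- sqrt(mean((lx - mu)^2))
  ks <- suppressWarnings(ks.test(counts, "plnorm", meanlog = mu,
                                 sdlog = sigma))
  ll <- sum(stats::dlnorm(counts, mu, sigma, log = TRUE))
  ci <- NULL
  if (n_boot > 0) {
    boots <- vapply(seq_len(n_boot), function(i) {
      b <- sample(lx, n, replace = TRUE)
      m <- mean(b)
      c(m, sqrt(mean((b - m)^2)))
    }, numeric(2))
    alpha <- (1 - conf) / 2
    ci <- rbind(mu = quantile(boots[1, ], c(alpha, 1 - alpha), names = FALSE),
                sigma = quantile(boots[2, ], c(alpha, 1 - alpha),
                                 names = FALSE))
    colnames(ci) <- c("lower", "upper")
  }
  structure(list(estimates = c(mu = mu, sigma = sigma), objective = ll,
                 ks_statistic = unname(ks$statistic),
                 ks_p_value = ks$p.value, ci = ci, n_used = n),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Fit result:\n")
  print(signif(x$estimates, 6))
  cat(sprintf("  objective = %g (n = %d)\n", x$objective, x$n_used))
  invisible(x)
}

#' Generate a synthetic follicle-count dataset
#'
#' Counts are the expected decay curve at the requested ages, perturbed by
#' multiplicative log-normal noise, rounded, and floored at 1:
#' `max(1, round(E[F(age)] * exp(eps)))`, `eps ~ Normal(0, log_noise_sd^2)`.
#' Seeded and reproducible; used as the stand-in for histological count
#' datasets in recovery tests.
#'
#' @param params A [continuous_params()] object.
#' @param N Starting supply of the generating curve.
#' @param ages Ages in years, non-negative.
#' @param log_noise_sd Standard deviation of the log-scale noise (default
#'   0: noiseless).
#' @param seed Optional integer seed.
#' @return A [pf_count_dataset()] with provenance `"synthetic"`.
#' @export
generate_synthetic_counts <- function(params, N, ages, log_noise_sd = 0,
                                      seed = NULL) {
  if (any(ages < 0)) stop("ages must be non-negative", call. = FALSE)
  if (!is.numeric(log_noise_sd) || log_noise_sd < 0)
    stop("log_noise_sd must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  curve <- expected_reserve(ages, N, params)
  eps <- if (log_noise_sd > 0) rnorm(length(ages), 0, log_noise_sd) else 0
  counts <- pmax(1, round(curve * exp(eps)))
  pf_count_dataset(ages, counts, provenance = "synthetic")
}

#' Read / write follicle-count datasets as CSV
#'
#' The on-disk format is a comma-separated file with header
#' `age_years,pf_count`.
#'
#' @param path File path.
#' @param dataset A [pf_count_dataset()].
#' @return `read_pf_counts` returns a [pf_count_dataset()];
#'   `write_pf_counts` returns `path` invisibly.
#' @export
read_pf_counts <- function(path) {
  df <- read.csv(path)
  if (!all(c("age_years", "pf_count") %in% names(df)))
    stop("expected columns age_years, pf_count", call. = FALSE)
  pf_count_dataset(df$age_years, df$pf_count,
                   provenance = basename(path))
}

#' @rdname read_pf_counts
#' @export
write_pf_counts <- function(dataset, path) {
  write.csv(dataset[, c("age_years", "pf_count")], path, row.names = FALSE)
  invisible(path)
}

#' Calibrate diffusivity to a target threshold-crossing age
#'
#' Under a time-variant drift schedule there is one free physical parameter
#' left once the drift values are fixed: the diffusivity.  This solves for
#' the `D` at which the median-woman expected decay curve (starting supply
#' `N`, occupancy-propagated survival under `schedule`) first crosses
#' `threshold` at `target_age`.  Useful when a drift schedule is specified
#' on its own scale and must be anchored to an observed median age at
#' menopause.
#'
#' @param schedule A [drift_schedule()].
#' @param N Starting supply (default the median, `exp(12.686)`).
#' @param threshold Menopause threshold (default 1,000).
#' @param target_age Desired crossing age in years (default 51, the
#'   population median ANM).
#' @param x0 Initial ISR activity (default 1).
#' @param dt Grid step for the occupancy propagation (default 1/12 yr).
#' @param interval Search interval for `D` (log-scale root search).
#' @return The calibrated diffusivity, per year.
#' @export
#' @examples
#' \donttest{
#' calibrate_diffusivity(drift_schedule(38, c(0.024, 0.033)))
#' }
calibrate_diffusivity <- function(schedule, N = exp(12.686),
                                  threshold = 1000, target_age = 51,
                                  x0 = 1, dt = 1 / 12,
                                  interval = c(1e-6, 0.01)) {
  stopifnot(inherits(schedule, "drift_schedule"))
  ages <- seq(0, 120, by = dt)
  crossing <- function(logD) {
    params <- continuous_params(D = exp(logD), V = schedule$values[1],
                                x0 = x0)
    spec <- subject_spec(2, schedule = schedule, menopause_threshold = 1)
    S <- .subject_survival(spec, params, ages, dt)
    lf <- log(pmax(N * S, .Machine$double.xmin))
    i <- which(lf < log(threshold))[1]
    if (is.na(i)) return(120)          # never crosses: treat as late
    if (i == 1L) return(0)
    # linear interpolation on log counts between bracketing grid ages
    ages[i - 1L] + dt * (lf[i - 1L] - log(threshold)) / (lf[i - 1L] - lf[i])
  }
  f <- function(logD) crossing(logD) - target_age
  # the monthly lattice requires |V| <= sqrt(2 D / dt): keep D feasible
  d_min <- 1.05 * max(abs(schedule$values))^2 * dt / 2
  lo <- log(max(interval[1], d_min)); hi <- log(interval[2])
  if (f(lo) * f(hi) > 0)
    stop("target age not bracketed by the diffusivity interval", call. = FALSE)
  exp(uniroot(f, c(lo, hi), tol = 1e-6)$root)
}
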