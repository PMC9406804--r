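# Closed-form first-passage mathematics: parameter maps, survival curve,
# threshold crossing, finite death threshold.

test_that("discrete-to-continuous parameter map matches the defining formulas", {
  p1 <- params_from_discrete(discrete_params(dx = 1, dt = 1, p = 0.5))
  expect_equal(p1$D, 0.5)
  expect_equal(p1$V, 0)

  p2 <- params_from_discrete(discrete_params(dx = 1, dt = 2, p = 1))
  expect_equal(p2$D, 0.25)
  expect_equal(p2$V, -0.5)

  # monthly steps realising the fitted human parameters (closed-form algebra:
  # dx = sqrt(2 D dt), p = 1/2 - V dt / (2 dx))
  d <- discrete_from_params(0.004, 0.051, 1 / 12)
  expect_equal(d$dx, sqrt(2 * 0.004 / 12), tolerance = 1e-12)
  expect_equal(d$dx, 0.0258199, tolerance = 1e-6)
  expect_equal(d$p, 0.417699, tolerance = 1e-6)
  back <- params_from_discrete(d)
  expect_equal(back$D, 0.004, tolerance = 1e-12)
  expect_equal(back$V, 0.051, tolerance = 1e-12)
})

test_that("parameter maps validate their inputs", {
  expect_error(discrete_params(dx = -1, dt = 1, p = 0.5), "dx")
  expect_error(discrete_params(dx = 1, dt = 0, p = 0.5), "dt")
  expect_error(discrete_params(dx = 1, dt = 1, p = 1.5), "probability")
  # drift too large for the step: error names the admissible bound
  expect_error(discrete_from_params(0.004, 10, 1 / 12), "must not exceed")
  expect_error(continuous_params(D = 0), "positive")
  expect_error(continuous_params(L = 0.5), "L must exceed x0")
})

test_that("round trip discrete <-> continuous is the identity", {
  grid <- expand.grid(D = c(1e-4, 0.004, 0.5), V = c(-0.1, 0, 0.051),
                      dt = c(1e-3, 1 / 12, 1))
  grid <- grid[abs(grid$V) <= sqrt(2 * grid$D / grid$dt), ]  # lattice-feasible
  for (i in seq_len(nrow(grid))) {
    d <- discrete_from_params(grid$D[i], grid$V[i], grid$dt[i])
    back <- params_from_discrete(d)
    expect_equal(back$D, grid$D[i], tolerance = 1e-12)
    expect_equal(back$V, grid$V[i], tolerance = 1e-12)
  }
})

test_that("survival starts at one, decreases, and vanishes at long times", {
  p <- human_params()
  expect_identical(fp_survival(0, p), 1)
  tg <- seq(0, 120, length.out = 1e4)
  S <- fp_survival(tg, p)
  expect_true(all(diff(S) <= 0))
  expect_lt(fp_survival(1e6, p), 1e-12)
  expect_error(fp_survival(-1, p), "non-negative")
  # stability under a much harsher drift-to-diffusivity ratio
  harsh <- continuous_params(D = 1e-4, V = 0.2)
  Sh <- fp_survival(seq(0, 120, length.out = 500), harsh)
  expect_true(all(is.finite(Sh)) && all(Sh >= 0) && all(diff(Sh) <= 0))
})

test_that("survival at 51 years matches the Monte-Carlo walk frequency", {
  p <- human_params()
  s51 <- fp_survival(51, p)
  expect_gt(s51, 2.5e-3)
  expect_lt(s51, 4e-3)
  cfg <- walk_config(discrete_from_params(0.004, 0.051, 1e-3), L = 10,
                     max_age = 60)
  ex <- sample_exit_times(2e4, cfg, seed = 301)
  phat <- mean(ex$exit_time > 51)
  se <- sqrt(phat * (1 - phat) / 2e4)
  expect_lt(abs(phat - s51), 3 * se + 1e-4)
})

test_that("expected reserve is linear in the starting supply", {
  p <- human_params()
  expect_equal(expected_reserve(0, 3.23e5, p), 3.23e5)
  tg <- c(1, 10, 35, 51)
  expect_equal(expected_reserve(tg, 2 * 3.23e5, p),
               2 * expected_reserve(tg, 3.23e5, p))
  expect_true(all(diff(expected_reserve(tg, 3.23e5, p)) < 0))
})

test_that("decay-curve threshold crossing behaves and rounds to 51 years", {
  p <- human_params()
  anm <- anm_from_curve(median_supply(), p, threshold = 1000)
  expect_equal(round(anm), 51)
  expect_warning(a0 <- anm_from_curve(1000, p, threshold = 1000), "threshold")
  expect_identical(a0, 0)
  expect_error(anm_from_curve(1e5, p, threshold = -5), "positive")
  expect_gt(anm_from_curve(2 * median_supply(), p), anm)
})

test_that("finite death threshold at L = 2 is practically indistinguishable", {
  p2 <- human_params(L = 2)
  pinf <- human_params()
  tg <- seq(0, 100, by = 0.5)
  d <- abs(finite_L_survival(tg, p2) - fp_survival(tg, pinf))
  expect_lte(max(d), 1e-4)
})

test_that("driftless two-sided survival is symmetric about the midpoint", {
  a <- continuous_params(D = 0.004, V = 0, x0 = 0.5, L = 2)
  b <- continuous_params(D = 0.004, V = 0, x0 = 1.5, L = 2)
  for (t in c(0.5, 3, 10))
    expect_equal(finite_L_survival(t, a), finite_L_survival(t, b),
                 tolerance = 1e-10)
})

test_that("two-sided survival matches Monte-Carlo two-boundary walks", {
  pl <- human_params(L = 2)
  cfg <- walk_config(discrete_from_params(0.004, 0.051, 1e-3), L = 2,
                     max_age = 21)
  ex <- sample_exit_times(2e4, cfg, seed = 99)
  for (t in c(1, 5, 20)) {
    S <- finite_L_survival(t, pl)
    phat <- mean(ex$exit_time > t)
    se <- sqrt(max(S * (1 - S), 1e-6) / 2e4)
    # 3 Monte-Carlo standard errors plus room for the dt = 1e-3 lattice bias
    expect_lt(abs(phat - S), 3 * se + 2e-3)
  }
})

test_that("death-before-activation probability follows the scale function", {
  expect_equal(hit_upper_probability(continuous_params(D = 1, V = 0, L = 2)),
               0.5)
  h <- hit_upper_probability(human_params(L = 2))
  exact <- (exp(0.051 / 0.004) - 1) / (exp(2 * 0.051 / 0.004) - 1)
  expect_equal(h, exact, tolerance = 1e-12)
  expect_equal(h, exp(-0.051 / 0.004), tolerance = 1e-2)
  # x0 -> 0 limit and V = 0 continuity
  expect_lt(hit_upper_probability(continuous_params(D = 1, V = 0.5,
                                                    x0 = 1e-8, L = 2)), 1e-7)
  expect_equal(hit_upper_probability(continuous_params(D = 1, V = 1e-10,
                                                       x0 = 1, L = 2)),
               0.5, tolerance = 1e-6)
  # deep-tail case stays finite and matches exp(V (x0 - L) / D)
  deep <- hit_upper_probability(continuous_params(D = 1e-2, V = 0.5, L = 5))
  expect_equal(log(deep), 0.5 * (1 - 5) / 1e-2, tolerance = 1e-6)
})
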