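# Subject- and population-level simulation of reserve decay and ANM.

test_that("starting-supply sampling reproduces the log-normal model", {
  deg <- sample_starting_supply(50, supply_distribution(sigma = 0), seed = 1)
  expect_true(all(deg == round(exp(12.686))))
  expect_equal(signif(round(exp(12.686)), 3), 3.23e5)

  x <- sample_starting_supply(1e5, supply_distribution(), seed = 2)
  expect_lt(abs(median(x) / exp(12.686) - 1), 0.01)
  lx <- log(x)
  sk <- mean((lx - mean(lx))^3) / sd(lx)^3
  expect_lt(abs(sk), 0.05)
})

test_that("drift multipliers have unit mean and spread c", {
  expect_true(all(sample_drift_multipliers(100, c = 0, seed = 1) == 1))
  m <- sample_drift_multipliers(1e5, c = 0.03, seed = 3)
  expect_lt(abs(mean(m) - 1), 3 * 0.03 / sqrt(1e5))
  expect_lt(abs(sd(m) - 0.03), 3 * 0.03 / sqrt(2 * 1e5))
})

test_that("drift schedules look up piecewise-constant values by age", {
  s <- drift_schedule(38, c(0.024, 0.033))
  expect_equal(drift_at_age(s, 37), 0.024)
  expect_equal(drift_at_age(s, 39), 0.033)
  expect_equal(drift_at_age(s, 38), 0.033)  # left-closed segment at 38
  const <- drift_schedule(numeric(0), 0.051)
  expect_equal(drift_at_age(const, c(0, 50, 100)), rep(0.051, 3))
  expect_error(drift_schedule(c(40, 38), c(1, 2, 3)), "ascending")
  expect_error(drift_schedule(38, 0.02), "one more value")
})

test_that("median woman reaches menopause at an age rounding to 51", {
  p <- human_params()
  s <- subject_spec(median_supply())
  t1 <- simulate_subject(s, p, seed = 4)
  expect_equal(round(t1$anm), 51)
  t2 <- simulate_subject(s, p, method = "per_follicle", seed = 5)
  expect_equal(round(t2$anm), 51)
  expect_identical(t1$reserve[1], as.integer(median_supply()))
  expect_true(all(diff(t1$reserve) <= 0))
})

test_that("a subject starting below the threshold has ANM zero", {
  s <- subject_spec(500, menopause_threshold = 1000)
  tr <- simulate_subject(s, human_params(), seed = 1)
  expect_equal(tr$anm, 0)
})

test_that("vanishing diffusivity concentrates exits at x0 / V", {
  p <- continuous_params(D = 1e-8, V = 0.051)
  s <- subject_spec(1e5)
  tr <- simulate_subject(s, p, seed = 6)
  i18 <- which.min(abs(tr$ages - 18))
  i21 <- which.min(abs(tr$ages - 21))
  expect_equal(tr$reserve[i18], 1e5)
  expect_equal(tr$reserve[i21], 0)
  expect_lt(abs(tr$anm - 1 / 0.051), 0.5)
})

test_that("median-woman trajectory tracks the expected decay curve", {
  p <- human_params()
  s <- subject_spec(median_supply())
  tr <- simulate_subject(s, p, seed = 8)
  EF <- expected_reserve(tr$ages, median_supply(), p)
  se <- sqrt(pmax(EF * (1 - EF / median_supply()), 1))
  expect_true(all(abs(tr$reserve - EF) <= 3 * se + 1))
})

test_that("acute losses thin the reserve and accelerate menopause", {
  ev <- intervention_event(12, 0.5)
  expect_equal(apply_acute_loss(1000, ev), 500)
  expect_error(intervention_event(12, 1.5), "probability")
  p <- human_params()

  keep_all <- subject_spec(median_supply(),
                           interventions = list(intervention_event(12, 1)))
  plain <- subject_spec(median_supply())
  expect_identical(simulate_subject(keep_all, p, seed = 9)$reserve,
                   simulate_subject(plain, p, seed = 9)$reserve)

  lose_all <- subject_spec(median_supply(),
                           interventions = list(intervention_event(12, 0)))
  expect_equal(simulate_subject(lose_all, p, seed = 9)$anm, 12)

  half <- subject_spec(median_supply(),
                       interventions = list(intervention_event(12, 0.5)))
  anm_half <- vapply(1:20, function(i)
    simulate_subject(half, p, seed = 100 + i)$anm, numeric(1))
  anm_plain <- vapply(1:20, function(i)
    simulate_subject(plain, p, seed = 200 + i)$anm, numeric(1))
  expect_lt(mean(anm_half), mean(anm_plain))
  # per-follicle path honours interventions too
  tr_pf <- simulate_subject(half, p, method = "per_follicle", seed = 10)
  expect_lt(tr_pf$anm, 51)
})

test_that("coupled runs are monotone in supply and drift", {
  p <- human_params()
  anm_at <- function(N, mult) {
    s <- subject_spec(N, drift_multiplier = mult)
    simulate_subject(s, p, seed = 42)$anm
  }
  base <- anm_at(median_supply(), 1)
  expect_gte(anm_at(2 * median_supply(), 1), base)
  expect_lte(anm_at(median_supply(), 1.2), base)
})

test_that("population simulation is reproducible and summarised correctly", {
  pop <- simulate_population(300, seed = 21)
  pop2 <- simulate_population(300, seed = 21)
  expect_identical(pop$anm_samples, pop2$anm_samples)
  s <- pop$summary
  expect_equal(s$median_anm, median(pop$anm_samples, na.rm = TRUE))
  expect_equal(unname(s$quantiles["q25"]),
               unname(quantile(pop$anm_samples, 0.25, na.rm = TRUE)))
  expect_equal(s$iqr, unname(diff(quantile(pop$anm_samples, c(.25, .75),
                                           na.rm = TRUE))))
  # degenerate population equals the median woman
  one <- simulate_population(1, dist = supply_distribution(sigma = 0),
                             c = 0, seed = 30)
  expect_equal(round(one$anm_samples), 51)
})

test_that("subject-variable drift broadens the ANM distribution", {
  fixed <- simulate_population(2000, c = 0, seed = 61)
  varied <- simulate_population(2000, c = 0.03, seed = 61)
  expect_gt(varied$summary$iqr, fixed$summary$iqr)
})

test_that("per-follicle and thinning methods agree in distribution", {
  d <- supply_distribution(log(1e4), 0)
  a <- simulate_population(300, dist = d, seed = 71)$anm_samples
  b <- simulate_population(300, dist = d, method = "per_follicle",
                           seed = 72)$anm_samples
  expect_gt(suppressWarnings(ks.test(a, b))$p.value, 0.01)
})

test_that("time-variant accelerating drift caps late menopause ages", {
  sched <- drift_schedule(38, c(0.024, 0.033))
  D <- calibrate_diffusivity(sched)
  pop <- simulate_population(1000, schedule = sched, c = 0.03,
                             params = continuous_params(D = D, V = 0.024),
                             seed = 81, max_age = 100)
  expect_equal(sum(pop$anm_samples > 62, na.rm = TRUE), 0)
  expect_equal(round(pop$summary$median_anm), 51)
})
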