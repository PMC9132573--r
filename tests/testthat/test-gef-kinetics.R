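test_that("exponential fit round-trips noiseless loading and unloading curves", {
  for (phase in c("loading", "unloading")) {
    tc <- make_exchange_timecourse(9.28, amplitude = 1200, baseline = 150,
                                   phase = phase)
    fit <- fit_exponential(tc)
    expect_false(fit$no_exchange)
    expect_lt(abs(fit$t_half - 9.28) / 9.28, 1e-6)
    expect_lt(abs(fit$amplitude - 1200) / 1200, 1e-6)
    expect_identical(fit$t_half, log(2) / fit$rate)
  }
})

test_that("half-life recovery across a grid is unbiased at 2% noise", {
  for (th in c(5, 10, 20, 30)) {
    errs <- vapply(1:30, function(r) {
      tc <- make_exchange_timecourse(
        th, noise = noise_model(0.02, seed = 1000 * th + r, relative = TRUE))
      fit_exponential(tc)$t_half / th - 1
    }, numeric(1))
    expect_lt(abs(mean(errs)), 0.01)
  }
})

test_that("a constant signal is classified as no exchange", {
  tc <- exchange_timecourse(seq(0, 3600, 10), rep(500, 361))
  fit <- fit_exponential(tc)
  expect_true(fit$no_exchange)
  expect_true(is.na(fit$t_half))
})

test_that("initial velocity converts fluorescence slope through the calibration", {
  cal <- build_calibration(c(31.5e-9, 62.5e-9, 125e-9, 250e-9, 500e-9, 1e-6),
                           gains = c(31.5e-9, 62.5e-9, 125e-9, 250e-9,
                                     500e-9, 1e-6) * 20e-6 * 1e12 * 40)
  expect_equal(cal$slope, 40, tolerance = 1e-9)
  # line rising at exactly (calibration slope) au/min is 1 pmol/min
  tc <- exchange_timecourse(seq(0, 300, 5), 100 + cal$slope * seq(0, 300, 5) / 60)
  v <- initial_velocity(tc, calibration = cal)
  expect_equal(as.numeric(v), 1, tolerance = 1e-9)
  expect_identical(attr(v, "units"), "pmol/min")
  v_raw <- initial_velocity(tc)
  expect_identical(attr(v_raw, "units"), "au/min")
  expect_equal(as.numeric(v_raw), cal$slope, tolerance = 1e-9)
})

test_that("velocities from near-linear exchange curves obey the Michaelis-Menten law", {
  v_max <- 1.86; k_m <- 0.36e-6
  cal <- build_calibration(c(62.5e-9, 250e-9, 1e-6),
                           gains = c(62.5e-9, 250e-9, 1e-6) * 20e-6 * 1e12 * 40)
  concs <- c(0.0625, 0.125, 0.25, 0.5, 1, 1.5, 2, 4) * 1e-6
  r <- 0.005  # per min: slow saturation keeps the 50-200 s window near-linear
  vels <- vapply(concs, function(cc) {
    v <- v_max * cc / (k_m + cc)
    times <- seq(0, 300, 5)
    y <- 100 + (v * cal$slope / r) * (1 - exp(-r * times / 60))
    tc <- exchange_timecourse(times, y, substrate_concentration = cc)
    as.numeric(initial_velocity(tc, calibration = cal))
  }, numeric(1))
  expect_true(all(abs(vels / (v_max * concs / (k_m + concs)) - 1) < 0.02))
})

test_that("initial-velocity window shifts are benign for slow kinetics", {
  tc <- make_exchange_timecourse(60, cadence = 5)
  cal <- build_calibration(c(1e-7, 5e-7, 1e-6), c(10, 50, 100))
  v0 <- as.numeric(initial_velocity(tc, c(50, 200), cal))
  v1 <- as.numeric(initial_velocity(tc, c(25, 175), cal))
  v2 <- as.numeric(initial_velocity(tc, c(75, 225), cal))
  expect_lt(abs(v1 / v0 - 1), 0.05)
  expect_lt(abs(v2 / v0 - 1), 0.05)
})

test_that("calibration slope survives 5% noise within 10%", {
  concs <- c(31.5e-9, 62.5e-9, 125e-9, 250e-9, 500e-9, 1e-6)
  pmol <- concs * 20e-6 * 1e12
  true_slope <- 85
  set.seed(77)
  gains <- true_slope * pmol * (1 + stats::rnorm(6, 0, 0.05))
  cal <- build_calibration(concs, gains)
  expect_lt(abs(cal$slope / true_slope - 1), 0.10)
  expect_error(build_calibration(concs, -gains), "positive")
})

test_that("Michaelis-Menten fit recovers noiseless parameters exactly", {
  tab <- make_mm_titration(1.86, 0.36e-6, replicates = 1)
  fit <- fit_michaelis_menten(tab$concentration, tab$velocity)
  expect_lt(abs(fit$v_max - 1.86) / 1.86, 1e-6)
  expect_lt(abs(fit$k_m - 0.36e-6) / 0.36e-6, 1e-6)
  expect_equal(fit$k_cat, fit$v_max / 0.4)
  expect_equal(fit$specificity, fit$k_cat / (fit$k_m * 1e6))
})

test_that("turnover number follows the catalytic-site stoichiometry", {
  expect_equal(kcat_from_vmax(0.66, 10e-9, 20e-6, 2), 1.65)
  expect_equal(kcat_from_vmax(1.86, 10e-9, 20e-6, 2), 4.65)
  expect_equal(kcat_from_vmax(0, 10e-9, 20e-6, 2), 0)
  # linear in v_max, inverse-linear in catalytic amount
  expect_equal(kcat_from_vmax(1.32, 10e-9, 20e-6, 2),
               2 * kcat_from_vmax(0.66, 10e-9, 20e-6, 2))
  expect_equal(kcat_from_vmax(0.66, 20e-9, 20e-6, 2),
               kcat_from_vmax(0.66, 10e-9, 20e-6, 2) / 2)
  expect_error(kcat_from_vmax(1, 0, 20e-6, 2), "positive")
})

test_that("replicate t-test behaves at the boundaries and detects the known difference", {
  same <- compare_replicates(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  expect_warning(one <- compare_replicates(1.86, c(0.6, 0.7)), "refused")
  expect_identical(one$test, "none")
  expect_true(is.na(one$p_value))

  # power against the observed Vmax difference at n = 3
  set.seed(42)
  reject <- vapply(1:1000, function(i) {
    a <- stats::rnorm(3, 1.86, 0.13)
    b <- stats::rnorm(3, 0.66, 0.03)
    compare_replicates(a, b)$significant
  }, logical(1))
  expect_gt(mean(reject), 0.95)
})

test_that("replicate-structured MM fits are unbiased at 5% noise", {
  v_err <- numeric(100); k_err <- numeric(100)
  for (b in 1:100) {
    tab <- make_mm_titration(1.86, 0.36e-6, replicates = 3,
                             noise = noise_model(0.05, seed = 5000 + 7 * b,
                                                 relative = TRUE))
    fit <- fit_michaelis_menten(tab$concentration, tab$velocity,
                                tab$replicate)
    v_err[b] <- fit$v_max / 1.86 - 1
    k_err[b] <- fit$k_m / 0.36e-6 - 1
  }
  expect_lt(abs(mean(v_err)), 0.02)
  expect_lt(abs(mean(k_err)), 0.10)
})
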