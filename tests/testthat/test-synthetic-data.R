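test_that("generators are byte-deterministic in the seed", {
  a <- make_sensorgram_set(wt_scheme(), noise = noise_model(0.01, 5, TRUE),
                           time_step = 1)
  b <- make_sensorgram_set(wt_scheme(), noise = noise_model(0.01, 5, TRUE),
                           time_step = 1)
  c <- make_sensorgram_set(wt_scheme(), noise = noise_model(0.01, 6, TRUE),
                           time_step = 1)
  expect_identical(a, b)
  expect_false(identical(a, c))

  t1 <- make_exchange_timecourse(9.28, noise = noise_model(5, 3))
  t2 <- make_exchange_timecourse(9.28, noise = noise_model(5, 3))
  expect_identical(t1, t2)

  m1 <- make_mm_titration(1.86, 0.36e-6, noise = noise_model(0.05, 8, TRUE))
  m2 <- make_mm_titration(1.86, 0.36e-6, noise = noise_model(0.05, 8, TRUE))
  expect_identical(m1, m2)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- stats::runif(1)
  set.seed(123)
  invisible(make_mm_titration(1, 1e-6, noise = noise_model(0.05, 99, TRUE)))
  after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("noiseless sensorgram generation equals the forward simulation", {
  concs <- 62.5e-9 / 2^(0:2)
  gen <- make_sensorgram_set(wt_scheme(), concs, 60, 120, 100, 1)
  for (i in seq_along(concs)) {
    direct <- simulate_sensorgram(wt_scheme(), concs[i], 60, 120, 100, 1)
    expect_identical(gen[[i]]$signal, direct$signal)
  }
})

test_that("noiseless exchange and MM generators match their analytic laws", {
  tc <- make_exchange_timecourse(9.28, amplitude = 1000, baseline = 100)
  expect_equal(tc$time, seq(0, 3600, 10))
  analytic <- 100 + 1000 * (1 - exp(-log(2) / 9.28 * tc$time / 60))
  expect_lt(max(abs(tc$fluorescence - analytic)), 1e-10)

  tab <- make_mm_titration(1.86, 0.36e-6, replicates = 2)
  expect_lt(max(abs(tab$velocity -
                      1.86 * tab$concentration /
                        (0.36e-6 + tab$concentration))), 1e-10)

  flat <- make_fret_titration(NA, floor = 0.31)
  expect_equal(unique(flat$response), 0.31)
})

test_that("toy structure pairs carry exact ground truth", {
  same <- make_toy_structures(0, 0)
  expect_equal(same$reference$atoms[, c("x", "y", "z")],
               same$moved$atoms[, c("x", "y", "z")], tolerance = 1e-12)
  toy <- make_toy_structures(12, 1.5, seed = 4)
  expect_equal(toy$ground_truth$hinge_angle, 12)
  hm <- hinge_angle(toy$reference, toy$moved,
                    toy$ground_truth$reference_selection,
                    toy$ground_truth$mobile_selection)
  expect_equal(hm$angle, 12, tolerance = 1e-6)
  expect_error(make_toy_structures(45, 0), "hinge_angle")
})
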