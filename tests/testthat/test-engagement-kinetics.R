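test_that("scheme construction validates rates and exposes the step-2 equilibrium", {
  s <- two_step_scheme(7e5, 0.12, 0.35, 0.044)
  expect_equal(scheme_occupancy_ratio(s), 0.35 / 0.044)
  expect_error(two_step_scheme(-1, 0.1), "non-negative")
  expect_error(two_step_scheme(NaN, 0.1), "finite")
  expect_equal(scheme_occupancy_ratio(two_step_scheme(1e5, 0.1)), 0)
})

test_that("simulated trajectories conserve mass and respect signal bounds", {
  set.seed(101)
  for (i in 1:10) {
    s <- two_step_scheme(10^stats::runif(1, 4, 6), stats::runif(1, 0.01, 1),
                         stats::runif(1, 0, 1), stats::runif(1, 0.001, 0.5))
    sg <- simulate_sensorgram(s, stats::runif(1, 1e-9, 1e-6), 60, 120, 100, 1)
    st <- attr(sg, "states")
    u <- 1 - st$P - st$F
    expect_lt(max(abs(u + st$P + st$F - 1)), 1e-8)
    expect_true(all(sg$signal >= 0 & sg$signal <= 100))
    expect_true(all(u > -1e-8))
  }
})

test_that("one-step limit matches the closed-form association/dissociation solution", {
  ka <- 1.5e6; kd <- 0.12; conc <- 62.5e-9; cap <- 100
  s <- two_step_scheme(ka, kd)
  sg <- simulate_sensorgram(s, conc, 60, 300, cap, 0.25)
  kobs <- ka * conc + kd
  req <- cap * ka * conc / kobs
  assoc <- association_segment(sg)
  expect_lt(max(abs(assoc$signal - req * (1 - exp(-kobs * assoc$time)))) /
              req, 1e-6)
  dis <- dissociation_segment(sg)
  r0 <- req * (1 - exp(-kobs * 60))
  expect_lt(max(abs(dis$signal - r0 * exp(-kd * dis$time))) / r0, 1e-6)
})

test_that("zero analyte concentration gives an identically zero trace", {
  sg <- simulate_sensorgram(wt_scheme(), 0, 30, 60, 100, 1)
  expect_equal(max(abs(sg$signal)), 0)
})

test_that("ODE dissociation decay matches the eigen-decomposition biexponential", {
  s <- two_step_scheme(7.0e5, 0.12, 0.35, 0.044)
  sg <- simulate_sensorgram(s, 62.5e-9, 300, 600, 100, 0.5)
  st <- attr(sg, "states")
  i0 <- which(st$time == 300)
  tail_idx <- st$time > 300
  dec <- dissociation_eigen_decay(s, st$P[i0], st$F[i0],
                                  st$time[tail_idx] - 300)
  ode_sig <- (st$P + st$F)[tail_idx]
  expect_lt(max(abs(ode_sig - dec$signal)) / max(dec$signal), 1e-6)
  # eigen rates match the quadratic (trace/det) roots computed by hand
  m <- dissociation_matrix(s)
  tr <- sum(diag(m)); dt <- det(m)
  roots <- (-tr + c(1, -1) * sqrt(tr^2 - 4 * dt)) / 2
  expect_equal(sort(dec$rates), sort(roots), tolerance = 1e-12)
})

test_that("association titration fit recovers ka to 0.1% on noiseless one-step cycles", {
  ka <- 1.5e6; kd <- 0.12
  cycles <- make_sensorgram_set(two_step_scheme(ka, kd),
                                concentrations = 62.5e-9 / 2^(0:5),
                                association_durations = 60,
                                dissociation_duration = 10,
                                capacity = 100, time_step = 0.5)
  fit <- fit_association(cycles)
  expect_false(fit$no_binding)
  expect_lt(abs(fit$ka - ka) / ka, 1e-3)
  expect_lt(abs(fit$kd_apparent - kd) / kd, 1e-3)
  # per-cycle kobs obeys kobs = ka C + kd
  expect_equal(fit$kobs_per_cycle,
               ka_cycle <- fit$ka * fit$concentrations + fit$kd_apparent,
               tolerance = 1e-10)
  expect_equal(fit$kobs_single_exp, fit$kobs_per_cycle, tolerance = 1e-3)
})

test_that("a flat titration is reported as no binding, not an error", {
  flat <- lapply(c(1e-9, 2e-9), function(cc) {
    sensorgram(0:100, rep(0, 101), cc, 60)
  })
  fit <- fit_association(flat)
  expect_true(fit$no_binding)
  expect_true(is.na(fit$ka))
})

test_that("biphasic dissociation fit round-trips noiseless generating parameters", {
  tr <- biphasic_truth()
  sg <- simulate_sensorgram(biphasic_scheme(), 62.5e-9, 480, 600, 100, 0.5,
                            dissociation = "phase")
  fit <- fit_dissociation(sg, n_phases = 2)
  expect_equal(fit$n_phases, 2L)
  expect_lt(abs(fit$kd_fast - tr$kd_fast) / tr$kd_fast, 1e-6)
  expect_lt(abs(fit$kd_slow - tr$kd_slow) / tr$kd_slow, 1e-6)
  # amplitude fraction equals the partial-state fraction at dissociation start
  st <- attr(sg, "states")
  i0 <- which(st$time == 480)
  f_true <- st$P[i0] / (st$P[i0] + st$F[i0])
  expect_lt(abs(fit$fraction_fast - f_true) / f_true, 1e-6)
  expect_gte(fit$kd_fast, fit$kd_slow)
})

test_that("single-exponential input under a 2-phase request degrades gracefully", {
  sg <- simulate_sensorgram(two_step_scheme(7e5, 0.12), 62.5e-9, 60, 300,
                            100, 0.5)
  expect_warning(fit <- fit_dissociation(sg, n_phases = 2),
                 "single-phase|indistinguishable|zero")
  expect_equal(fit$fraction_fast, 1)
  expect_true(fit$degenerate)
  expect_lt(abs(fit$kd_fast - 0.12) / 0.12, 1e-4)
})

test_that("k-minus-2 derivation follows the stated dissociation relation", {
  expect_equal(derive_k_minus2(0.12, 5.3e-3), 5.3e-3 / 0.12)
  expect_equal(derive_k_minus2(0.12, 4.2e-3), 0.035)
  expect_equal(derive_k_minus2(0.5, 0), 0)
  expect_error(derive_k_minus2(0, 0.01), "positive")
  expect_error(derive_k_minus2(0.1, 0.2), "kd_slow")
})

test_that("eigenvalue-consistent k-minus-2 reproduces the observed slow eigenvalue", {
  for (pars in list(c(4.2e-3, 0.12, 0.3), c(5.3e-3, 0.12, 0.05),
                    c(1e-3, 0.5, 1))) {
    km2 <- derive_k_minus2_eigen(pars[1], pars[2], pars[3])
    s <- two_step_scheme(1e5, pars[2], pars[3], km2)
    slow <- min(-eigen(dissociation_matrix(s))$values)
    expect_equal(slow, pars[1], tolerance = 1e-10)
  }
  expect_error(derive_k_minus2_eigen(0.2, 0.1, 1), "exceed")
})

test_that("affinity records are the exact rate quotient with 2-sf display only", {
  rec <- compute_affinity(7.0e5, 4.2e-3, "slow")
  expect_identical(rec$kd_molar, 4.2e-3 / 7.0e5)
  expect_equal(rec$kd_nm_display, 6.0)
  expect_equal(compute_affinity(1.5e6, 0.12)$kd_nm_display, 80)
  expect_equal(compute_affinity(1, 0)$kd_nm_display, 0)
  expect_error(compute_affinity(0, 1), "positive")
})

test_that("occupancy ratio inverts the fast-phase percentage", {
  expect_equal(occupancy_ratio(50), 1)
  expect_equal(occupancy_ratio(55), 45 / 55)
  for (f in seq(5, 95, by = 5)) {
    expect_equal(occupancy_ratio(f) * f / (100 - f), 1)
  }
  expect_warning(r0 <- occupancy_ratio(0), "infinite")
  expect_identical(r0, Inf)
  expect_warning(r1 <- occupancy_ratio(100), "zero")
  expect_identical(r1, 0)
})

test_that("free-energy profile reflects the step equilibria", {
  s_even <- two_step_scheme(7e5, 0.12, 0.05, 0.05)
  prof <- free_energy_profile(s_even, 298)
  expect_equal(prof$state_free_energies[3] - prof$state_free_energies[2], 0)

  s8 <- two_step_scheme(7e5, 0.12, 8 * 0.044, 0.044)
  prof8 <- free_energy_profile(s8, 298)
  dg2 <- prof8$state_free_energies[3] - prof8$state_free_energies[2]
  expect_equal(dg2, -8.31446261815324 * 298 * log(8) / 1000,
               tolerance = 1e-12)
  expect_equal(dg2, -5.15, tolerance = 0.001)

  expect_error(free_energy_profile(two_step_scheme(7e5, 0.12, 0, 0.04)),
               "zero rate|rates > 0")

  # mutant's full-engagement state destabilized relative to WT
  s1 <- two_step_scheme(7e5, 0.12, 0.044, 0.044)
  ddg <- energy_profile_difference(free_energy_profile(s1, 298), prof8)
  expect_gt(ddg[["full_IF1_4"]], 0)
})

test_that("variable-association analysis recovers the steady-state partial fraction", {
  s <- wt_scheme()
  cycles <- make_sensorgram_set(s, 62.5e-9,
                                association_durations = c(5, 10, 20, 40, 80,
                                                          160, 320, 480),
                                dissociation_duration = 600,
                                capacity = 100, time_step = 1,
                                dissociation = "phase")
  va <- suppressWarnings(variable_association_analysis(cycles))
  expect_true(all(diff(va$fraction_fast_series) < 1e-6))
  target <- steady_state_partial_fraction(s)
  expect_lt(abs(utils::tail(va$fraction_fast_series, 1) - target) / target,
            0.02)
  expect_lt(abs(va$plateau_fraction - target), 1)
  expect_gt(va$t_half, 0)
})

test_that("without a second step every cycle is pure fast phase", {
  s <- two_step_scheme(7e5, 0.12)
  cycles <- make_sensorgram_set(s, 62.5e-9,
                                association_durations = c(5, 20, 80, 320),
                                dissociation_duration = 300,
                                capacity = 100, time_step = 1,
                                dissociation = "phase")
  va <- suppressWarnings(variable_association_analysis(cycles))
  expect_equal(va$fraction_fast_series, rep(100, 4))
  expect_equal(va$plateau_fraction, 100)
})
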