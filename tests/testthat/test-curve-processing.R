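test_that("baseline correction recovers drift and is idempotent", {
  # already-zero baseline: returned unchanged
  cu <- simulate_retract_curve(1e-9, acq = quiet_acq())
  cb <- correct_baseline(cu)
  expect_identical(cb$intercept, 0)
  expect_identical(cb$slope, 0)
  expect_identical(cb$curve$segments$retract$force, cu$segments$retract$force)
  # synthetic drift recovered within 2% (noise-free)
  cud <- simulate_retract_curve(1e-9, acq = quiet_acq(drift_slope = 2e-5))
  cbd <- correct_baseline(cud)
  expect_equal(cbd$slope, 2e-5, tolerance = 0.02)
  # second pass is a no-op: coefficients ~ 0 relative to the first
  cb2 <- correct_baseline(cbd$curve)
  expect_lt(abs(cb2$slope), 1e-6 * abs(cbd$slope) + 1e-18)
  expect_lt(abs(cb2$intercept), 1e-20)
  # corrected tail mean is compatible with zero at noise scale
  cun <- simulate_retract_curve(1e-9, acq = quiet_acq(noise_sd = 1e-11,
                                                      drift_slope = 1e-5),
                                seed = 3)
  cbn <- correct_baseline(cun)
  h <- cbn$curve$segments$retract$height
  tail <- h >= 0.7 * max(h)
  expect_lt(abs(mean(cbn$curve$segments$retract$force[tail])),
            3 * cbn$noise_sd / sqrt(sum(tail)))
  # degenerate tails are rejected
  short <- force_curve("s", list(retract = list(height = seq(0, 1e-6, length.out = 20),
                                                force = numeric(20))))
  expect_error(correct_baseline(short, tail_fraction = 0.1), "fewer than 10")
})

test_that("adhesion force equals the array-minimum oracle and the truth", {
  # flat zero curve
  flat <- simulate_retract_curve(0, acq = quiet_acq())
  expect_identical(extract_adhesion_force(flat), 0)
  # noise-free: equals generator truth exactly
  cu <- simulate_retract_curve(1.5e-9, acq = quiet_acq())
  expect_identical(extract_adhesion_force(cu), 1.5e-9)
  # noisy curves: matches -min of the corrected array bit for bit, and
  # recovers the truth within the noise floor (1000 curves)
  set.seed(21)
  errs <- replicate(200, {
    f_true <- runif(1, 2e-10, 3e-9)
    cu <- simulate_retract_curve(f_true, acq = quiet_acq(noise_sd = 1e-11))
    cb <- correct_baseline(cu)
    oracle <- max(0, -min(cb$curve$segments$retract$force))
    expect_identical(extract_adhesion_force(cu), oracle)
    abs(oracle - f_true)
  })
  expect_lt(mean(errs), 3 * 1e-11)
  expect_lt(median(errs), 2 * 1e-11)
  no_retract <- structure(list(curve_id = "x",
                               segments = list(approach = list(height = c(0, 1),
                                                               force = c(0, 0))),
                               meta = list()), class = "force_curve")
  expect_error(extract_adhesion_force(no_retract), "retract")
})

test_that("rupture events are detected at the injected positions", {
  acq <- sm_acquisition_params(noise_sd = 0)
  d <- acq$retract_distance
  # single noise-free rupture: one event, height within one sample spacing
  cu <- simulate_retract_curve(6e-11, list(c(0.5 * d, 6e-11)), acq = acq)
  ev <- detect_rupture_events(cu)
  expect_identical(nrow(ev), 1L)
  spacing <- diff(cu$segments$retract$height[1:2])
  expect_lt(abs(ev$height_m - 0.5 * d), spacing + 1e-12)
  expect_gt(ev$step_N, 0.8 * 6e-11)
  # two ruptures in height order
  cu2 <- simulate_retract_curve(8e-11,
                                list(c(0.45 * d, 8e-11), c(0.62 * d, 5e-11)),
                                acq = acq)
  ev2 <- detect_rupture_events(cu2)
  expect_identical(nrow(ev2), 2L)
  expect_true(all(diff(ev2$height_m) > 0))
  # pure-noise null: false-event rate at most 1% (k_sigma = 5)
  acqn <- sm_acquisition_params()
  n_false <- sum(vapply(1:300, function(i) {
    cu <- simulate_retract_curve(0, acq = acqn, seed = 1000 + i)
    nrow(detect_rupture_events(cu))
  }, 0L))
  expect_lte(n_false / 300, 0.01)
  expect_error(detect_rupture_events(cu, k_sigma = 0), "> 0")
})

test_that("specific-binding calls separate bound from baseline curves", {
  acq <- sm_acquisition_params()
  base <- simulate_retract_curve(0, acq = acq, seed = 7)
  expect_false(call_specific_binding(base))
  d <- acq$retract_distance
  bound <- simulate_retract_curve(6e-11, list(c(0.5 * d, 6e-11)),
                                  acq = acq, seed = 8)
  expect_true(call_specific_binding(bound))
  # batch at p_bind = 0: positive-call rate <= 1%
  b0 <- simulate_single_molecule_batch(tiny_condition(p_bind = 0), 2, 100,
                                       seed = 31)
  fe <- extract_features(b0$curves)
  expect_lte(mean(fe$specific_binding), 0.01)
})

test_that("binding probability is the per-cell binomial MLE", {
  # one cell, 4 curves, 1 bound: p = 0.25, sd flagged undefined
  one <- estimate_binding_probability(
    data.frame(cell_id = "c1", bound = c(TRUE, FALSE, FALSE, FALSE)))
  expect_equal(one$mean, 0.25)
  expect_identical(one$sd, 0)
  expect_false(one$sd_defined)
  expect_identical(one$n_curves, 4L)
  expect_error(estimate_binding_probability(
    data.frame(cell_id = character(), bound = logical())), "empty")
  # simulated recovery through the full call pipeline (binomial oracle)
  b <- simulate_single_molecule_batch(tiny_condition(p_bind = 0.25), 10, 100,
                                      seed = 17)
  fe <- extract_features(b$curves)
  est <- estimate_binding_probability(
    data.frame(cell_id = fe$cell_id, bound = fe$specific_binding))
  expect_lt(abs(est$mean - 0.25), 3 * sqrt(0.25 * 0.75 / 1000))
  expect_identical(est$n_cells, 10L)
})

test_that("thermal-noise calibration recovers the spring constant", {
  tr <- simulate_thermal_noise(0.06, 310, 1e5, seed = 2)
  k <- calibrate_spring_constant(tr, 310)
  expect_lt(abs(k / 0.06 - 1), 0.03)
  # exact scale equivariance: k(c * trace) = k(trace) / c^2
  expect_equal(calibrate_spring_constant(3 * tr, 310), k / 9)
  # invariant to added linear drift after detrending
  drifted <- tr + seq(0, 5e-9, length.out = length(tr))
  expect_equal(calibrate_spring_constant(drifted, 310), k, tolerance = 0.05)
  expect_error(calibrate_spring_constant(numeric(2000), 310), "zero-variance")
  expect_error(calibrate_spring_constant(tr[1:100], 310), "1000")
})
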