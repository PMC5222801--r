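test_that("parameter invariants are enforced", {
  expect_error(neuron_params(v_thresh = -1), "v_thresh")
  expect_error(neuron_params(v_reset = 25), "v_reset")
  expect_error(neuron_params(refractory = -0.001), "refractory")
  expect_error(neuron_params(escape_width = -1), "escape_width")
})

test_that("a quiescent neuron with the noise current off emits no spikes", {
  p <- neuron_params(noise_mean = 0, noise_sd = 0)
  tr <- simulate_postsynaptic(NULL, weights = 0, params = p, duration = 10,
                              seed = 1)
  expect_length(tr$post_spikes, 0)
})

test_that("shipped defaults fire near 10 Hz with all weights at zero", {
  r <- baseline_rate(neuron_params(), duration = 100, seed = 12)
  expect_lt(abs(r - 10), 1)
})

test_that("very strong drive approaches the rate ceiling from below", {
  # hard-threshold variant: ceiling is the inverse refractory period
  ph <- neuron_params(noise_mean = 5000, escape_width = 0)
  trh <- simulate_postsynaptic(NULL, weights = 0, params = ph, duration = 5,
                               seed = 3)
  expect_lt(trh$rate, 1 / ph$refractory)
  expect_gt(trh$rate, 0.9 / ph$refractory)
  # escape variant: the saturating hazard adds a mean wait of 1/rate_max
  pe <- neuron_params(noise_mean = 5000)
  tre <- simulate_postsynaptic(NULL, weights = 0, params = pe, duration = 5,
                               seed = 3)
  ceiling_e <- 1 / (pe$refractory + 1 / pe$escape_rate_max)
  expect_lt(tre$rate, ceiling_e * 1.05)
  expect_gt(tre$rate, 0.9 * ceiling_e)
})

test_that("consecutive output spikes respect the refractory period", {
  p <- neuron_params(noise_mean = 30) # strongly driven
  tr <- simulate_postsynaptic(NULL, weights = 0, params = p, duration = 5,
                              seed = 4)
  expect_gt(length(tr$post_spikes), 10)
  expect_true(all(diff(tr$post_spikes) >= p$refractory))
})

test_that("zero-weight rate is non-decreasing in the mean noise current", {
  rates <- vapply(c(2, 6, 9.46, 12, 16), function(mu)
    baseline_rate(neuron_params(noise_mean = mu), duration = 30, seed = 7), 0)
  expect_true(all(diff(rates) >= 0))
})

test_that("output rate increases with synaptic weight", {
  cfg <- input_ensemble_config(1, base_rate = 20, signal_sd = 0)
  inputs <- generate_input_ensemble(cfg, 30, seed = 8)
  rates <- vapply(c(0, 4, 8), function(w)
    simulate_postsynaptic(inputs, w, neuron_params(), seed = 9)$rate, 0)
  expect_true(all(diff(rates) > 0))
})

test_that("simulation is reproducible under a fixed seed and validates inputs", {
  cfg <- input_ensemble_config(2, base_rate = 10)
  inputs <- generate_input_ensemble(cfg, 5, seed = 1)
  a <- simulate_postsynaptic(inputs, c(3, 3), seed = 11)
  b <- simulate_postsynaptic(inputs, c(3, 3), seed = 11)
  expect_identical(a$post_spikes, b$post_spikes)
  expect_error(simulate_postsynaptic(inputs, c(1, 2, 3)), "one weight per")
})

test_that("noise calibration hits the target and transfers across seeds", {
  p0 <- neuron_params(noise_mean = 5) # start well off target
  pc <- calibrate_noise(p0, target_rate = 10, tolerance = 1, seed = 21,
                        duration = 100)
  # validate on an independent seed: within two tolerances
  r <- baseline_rate(pc, duration = 100, seed = 77)
  expect_lt(abs(r - 10), 2)
  # unreachable target errors out
  expect_error(calibrate_noise(neuron_params(), target_rate = 0.0001,
                               tolerance = 0.00005, duration = 20,
                               bounds = c(5, 40)),
               "calibration error")
})
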