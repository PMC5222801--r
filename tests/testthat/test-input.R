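test_that("config invariants are enforced", {
  expect_error(input_ensemble_config(0), "n_inputs")
  expect_error(input_ensemble_config(10, base_rate = -1), "base_rate")
  expect_error(input_ensemble_config(10, training_index = 11), "training_index")
  expect_error(input_ensemble_config(10, training_gain = -0.5), "training_gain")
  cfg <- input_ensemble_config(10)
  expect_s3_class(cfg, "input_ensemble_config")
})

test_that("mixing kernel rows are a normalized Gaussian over index distance", {
  cfg <- input_ensemble_config(12, mixing_width = 1.5)
  k <- mixing_kernel(cfg)
  expect_equal(rowSums(k), rep(1, 12))
  expect_true(all(k >= 0))
  # weight decays with index distance
  expect_gt(k[6, 6], k[6, 7])
  expect_gt(k[6, 7], k[6, 9])
  # width 0 gives the identity
  expect_equal(mixing_kernel(input_ensemble_config(5, mixing_width = 0)), diag(5))
})

test_that("signals: zero rate, determinism, independence", {
  cfg0 <- input_ensemble_config(3, base_rate = 0)
  expect_true(all(generate_signals(cfg0, 1, seed = 1) == 0))

  cfg <- input_ensemble_config(4)
  s1 <- generate_signals(cfg, 2, seed = 99)
  s2 <- generate_signals(cfg, 2, seed = 99)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 0))
  expect_error(generate_signals(cfg, -1), "duration")

  # raw signals of different channels are uncorrelated (200 s sample)
  cfg2 <- input_ensemble_config(2)
  s <- generate_signals(cfg2, 200, seed = 3)
  expect_lt(abs(cor(s[, 1], s[, 2])), 0.05)
})

test_that("rectified signals keep their configured mean", {
  cfg <- input_ensemble_config(6, base_rate = 10)
  s <- generate_signals(cfg, 300, seed = 11)
  expect_equal(colMeans(s), rep(10, 6), tolerance = 0.05)
})

test_that("mixing conserves means and orders correlations by distance", {
  cfg <- input_ensemble_config(10)
  # identity limit
  cfg0 <- input_ensemble_config(10, mixing_width = 0)
  s <- generate_signals(cfg0, 1, seed = 5)
  expect_equal(mix_signals(s, cfg0), s, ignore_attr = TRUE)
  # constant signals stay constant at base rate
  su <- matrix(10, 50, 10); attr(su, "rate_dt") <- 0.005
  mu <- mix_signals(su, cfg)
  expect_equal(as.vector(mu), rep(10, 500))
  # neighbors more correlated than distant pairs (200 s Monte-Carlo)
  s2 <- generate_signals(cfg, 200, seed = 8)
  r <- mix_signals(s2, cfg)
  expect_gt(cor(r[, 5], r[, 6]), cor(r[, 5], r[, 10]))
  expect_error(mix_signals(-s2, cfg), "non-negative")
})

test_that("correlation of rate traces is non-increasing in index distance", {
  # averaged over 20 seeds
  cfg <- input_ensemble_config(10)
  cors <- matrix(0, 20, 4)
  for (k in 1:20) {
    r <- mix_signals(generate_signals(cfg, 50, seed = 100 + k), cfg)
    cors[k, ] <- vapply(1:4, function(d) cor(r[, 3], r[, 3 + d]), 0)
  }
  m <- colMeans(cors)
  expect_true(all(diff(m) <= 0))
})

test_that("training boost is local, exact, and trivial at gain 1", {
  cfg1 <- input_ensemble_config(10, training_index = 4, training_gain = 1)
  s <- generate_signals(cfg1, 5, seed = 2)
  r <- mix_signals(s, cfg1)
  expect_identical(apply_training_boost(r, cfg1), r)

  cfg2 <- input_ensemble_config(10, training_index = 4, training_gain = 2)
  rb <- apply_training_boost(r, cfg2)
  expect_equal(colMeans(rb)[4], 2 * colMeans(r)[4])   # doubled at the target
  expect_equal(colMeans(rb)[3], 1.5 * colMeans(r)[3]) # half the excess at +-1
  expect_identical(rb[, 9], r[, 9])                   # bit-identical far away
  expect_identical(rb[, c(1, 2, 6:10)], r[, c(1, 2, 6:10)])

  # boost at the edge with clip boundaries does not wrap around
  cfge <- input_ensemble_config(10, training_index = 1, training_gain = 2)
  re <- apply_training_boost(r, cfge)
  expect_identical(re[, 10], r[, 10])
  expect_identical(re[, 3:10], r[, 3:10])
})

test_that("Poisson sampling respects rates, dt and determinism", {
  cfg <- input_ensemble_config(1, base_rate = 10, signal_sd = 0)
  s <- generate_signals(cfg, 100)
  expect_error(sample_poisson_spikes(s, dt = 0.2), "smaller dt")

  set.seed(1)
  counts <- vapply(1:50, function(i)
    length(sample_poisson_spikes(s, dt = 1e-4)$spikes[[1]]), 0)
  # 50 trials of 100 s at 10 Hz: mean count within 3 standard errors of 1000
  expect_lt(abs(mean(counts) - 1000), 3 * sd(counts) / sqrt(50))

  # halving dt leaves the mean count unchanged within sampling error
  set.seed(2)
  counts2 <- vapply(1:50, function(i)
    length(sample_poisson_spikes(s, dt = 5e-5)$spikes[[1]]), 0)
  se <- sqrt(sd(counts)^2 + sd(counts2)^2) / sqrt(50)
  expect_lt(abs(mean(counts) - mean(counts2)), 3 * se)

  # spike trains are strictly increasing, within [0, duration), one per bin
  sts <- sample_poisson_spikes(s, dt = 1e-4, seed = 9)
  tt <- sts$spikes[[1]]
  expect_true(all(diff(tt) > 0))
  expect_true(all(tt >= 0 & tt < sts$duration))
  expect_true(all(diff(floor(tt / sts$dt)) >= 1))
  # zero rate gives empty trains
  cfg0 <- input_ensemble_config(2, base_rate = 0)
  s0 <- generate_signals(cfg0, 1)
  expect_equal(lengths(sample_poisson_spikes(s0, seed = 1)$spikes), c(0L, 0L))
  # determinism under a fixed seed
  a <- sample_poisson_spikes(s, dt = 1e-4, seed = 5)
  b <- sample_poisson_spikes(s, dt = 1e-4, seed = 5)
  expect_identical(a$spikes, b$spikes)
})

test_that("time-averaged rates converge to base_rate without training boost", {
  cfg <- input_ensemble_config(5, base_rate = 10)
  sts <- generate_input_ensemble(cfg, 100, seed = 4)
  rates <- lengths(sts$spikes) / sts$duration
  expect_equal(unname(rates), rep(10, 5), tolerance = 0.1)
})

test_that("spike trains round-trip through the two-column text format", {
  cfg <- input_ensemble_config(3, base_rate = 20)
  sts <- generate_input_ensemble(cfg, 2, seed = 6)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spike_trains(sts, path)
  back <- read_spike_trains(path, n_neurons = 3, duration = 2)
  expect_equal(back$spikes, sts$spikes, tolerance = 1e-12)
})
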