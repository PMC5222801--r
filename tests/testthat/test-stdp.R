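test_that("brute-force pair sum handles trivial cases", {
  w <- learning_window("DP")
  expect_identical(brute_force_pair_sum(numeric(0), numeric(0), w), 0)
  expect_identical(brute_force_pair_sum(c(0.1), numeric(0), w), 0)
  # single causal pair equals the window value
  expect_equal(brute_force_pair_sum(0, 10e-3, w), window_value(w, 10e-3))
  # a coincident pair contributes nothing
  expect_identical(brute_force_pair_sum(0.5, 0.5, w), 0)
})

test_that("online trace updater equals the all-pairs oracle for all rules", {
  set.seed(101)
  for (i in 1:25) {
    tr <- rand_train_pair(n_pre = sample(5:30, 1), n_post = sample(5:30, 1))
    for (r in all_rules) {
      w <- learning_window(r, alpha = runif(1, 0.5, 2),
                           tau_causal = runif(1, 0.01, 0.05),
                           tau_acausal = runif(1, 0.01, 0.05))
      expected <- brute_force_pair_sum(tr$pre, tr$post, w)
      got <- online_stdp(tr$pre, tr$post, w)
      expect_equal(got, expected, tolerance = 1e-12)
    }
  }
})

test_that("online triplet updater equals the exhaustive triplet enumeration", {
  set.seed(202)
  tp <- triplet_params(a3_causal = 0.004, a3_acausal = 0.003)
  for (i in 1:20) {
    tr <- rand_train_pair(n_pre = sample(4:15, 1), n_post = sample(4:15, 1))
    w <- learning_window("DP")
    expected <- brute_force_triplet_sum(tr$pre, tr$post, w, tp)
    got <- online_stdp(tr$pre, tr$post, w, triplet = tp)
    expect_equal(got, expected, tolerance = 1e-12)
  }
  # with triplet amplitudes zero the triplet rule reduces to the pair rule
  tr <- rand_train_pair(25, 25)
  w <- learning_window("PP")
  expect_identical(online_stdp(tr$pre, tr$post, w, triplet = triplet_params(0, 0)),
                   online_stdp(tr$pre, tr$post, w))
  expect_equal(brute_force_triplet_sum(tr$pre, tr$post, w, triplet_params(0, 0)),
               brute_force_pair_sum(tr$pre, tr$post, w), tolerance = 1e-12)
})

test_that("alpha = 0 freezes learning regardless of activity", {
  set.seed(7)
  tr <- rand_train_pair(30, 30)
  w0 <- learning_window("DP", alpha = 0)
  expect_identical(online_stdp(tr$pre, tr$post, w0), 0)
  expect_identical(brute_force_pair_sum(tr$pre, tr$post, w0), 0)
})

test_that("bounds clip hard and idempotently", {
  x <- c(-1, 0, 5, 10, 12)
  expect_equal(apply_bounds(x, 0, 10), c(0, 0, 5, 10, 10))
  expect_equal(apply_bounds(apply_bounds(x, 0, 10), 0, 10),
               apply_bounds(x, 0, 10))
  expect_equal(apply_bounds(c(1, 2), 0, 10), c(1, 2)) # in-range untouched
  expect_error(apply_bounds(x, 5, 5), "w_min")
})

test_that("multiplicative normalization rescales to the target sum", {
  expect_equal(normalize_weights(c(1, 3), 2), c(0.5, 1.5))
  v <- c(0.5, 1.5)
  expect_equal(normalize_weights(v, 2), v) # already at target
  out <- normalize_weights(runif(10, 0, 1), 5)
  expect_equal(sum(out), 5, tolerance = 1e-12)
  expect_warning(z <- normalize_weights(c(0, 0), 1), "zero")
  expect_equal(z, c(0, 0))
  expect_error(normalize_weights(c(1, 2), 0), "target_sum")
})

test_that("expected drift matches the window integral times the pair rate", {
  wb <- learning_window("DP")
  expect_equal(expected_drift(10, 10, wb), 0) # balanced antisymmetric window
  wd <- learning_window("DP", depression_excess = 0.02)
  expect_lt(expected_drift(10, 10, wd), 0) # depression-dominated
  wp <- learning_window("PP", alpha = 2)
  expect_equal(expected_drift(5, 20, wp), 5 * 20 * 2 * (2 * 0.01 * 0.02))
})

test_that("frozen-weight simulation of independent Poisson trains matches the drift formula", {
  # independent pre and post trains: the online updater's mean change per
  # second must converge to expected_drift (Monte-Carlo vs closed form)
  set.seed(42)
  dur <- 10
  for (win in list(learning_window("DP", depression_excess = 0.02),
                   learning_window("PP"))) {
    n_trials <- 200
    drifts <- vapply(seq_len(n_trials), function(i) {
      pre <- rand_train(rpois(1, 10 * dur), dur)
      post <- rand_train(rpois(1, 10 * dur), dur)
      online_stdp(pre, post, win) / dur
    }, 0)
    target <- expected_drift(10, 10, win)
    se <- sd(drifts) / sqrt(n_trials)
    expect_lt(abs(mean(drifts) - target), 3 * se)
  }
})
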