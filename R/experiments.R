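#' Tuned initial weight profile
#'
#' Gaussian bump over input index: baseline plus a peaked component, the
#' canonical "already tuned to input 7" starting receptive field.
#'
#' @param n_inputs number of inputs.
#' @param peak_index preferred input (1-based).
#' @param peak weight at the preferred input.
#' @param baseline weight far from the preferred input.
#' @param width Gaussian width in index units.
#' @return weight vector of length `n_inputs`.
#' @export
tuned_profile <- function(n_inputs = 10, peak_index = 7, peak = 7,
                          baseline = 2, width = 1.5) {
  i <- seq_len(n_inputs)
  baseline + (peak - baseline) * exp(-(i - peak_index)^2 / (2 * width^2))
}

# one plastic trial on the coupled network; the workhorse behind all
# experiments. Returns the recorded weight trajectory and postsynaptic rate.
run_plastic_trial <- function(input_config, duration, window,
                              triplet = NULL,
                              neuron = neuron_params(),
                              initial_weights,
                              w_min = 0, w_max = 10,
                              freeze_weights = FALSE,
                              normalize = FALSE,
                              norm_scheme = c("multiplicative", "subtractive"),
                              norm_target = sum(initial_weights),
                              norm_interval = 0.1,
                              seed = NULL, dt = 1e-4,
                              record_dt = 0.1) {
  stopifnot(inherits(window, "learning_window"),
            inherits(neuron, "neuron_params"))
  norm_scheme <- match.arg(norm_scheme)
  if (is.null(triplet)) triplet <- triplet_off()
  if (!is.null(seed)) set.seed(seed)
  inputs <- generate_input_ensemble(input_config, duration, dt = dt)
  ev <- as_event_stream(inputs, dt)
  n_steps <- as.integer(round(duration / dt))
  res <- engine_run(ev$step, ev$id,
                    n_inputs = input_config$n_inputs, n_steps = n_steps,
                    dt = dt,
                    w0 = as.numeric(initial_weights),
                    w_min = w_min, w_max = w_max,
                    tau_m = neuron$tau_m, v_rest = neuron$v_rest,
                    v_thresh = neuron$v_thresh, v_reset = neuron$v_reset,
                    refrac_steps = as.integer(round(neuron$refractory / dt)),
                    tau_syn = neuron$tau_syn, syn_gain = neuron$syn_gain,
                    noise_mean = neuron$noise_mean, noise_sd = neuron$noise_sd,
                    escape_rate0 = neuron$escape_rate0,
                    escape_width = neuron$escape_width,
                    escape_rate_max = neuron$escape_rate_max,
                    plastic = TRUE,
                    alpha = window$alpha,
                    a_causal = window$a_causal, a_acausal = window$a_acausal,
                    tau_causal = window$tau_causal,
                    tau_acausal = window$tau_acausal,
                    a3_causal = triplet$a3_causal,
                    a3_acausal = triplet$a3_acausal,
                    tau_x = triplet$tau_x, tau_y = triplet$tau_y,
                    freeze_weights = freeze_weights,
                    norm_mode = if (!normalize) 0L
                                else if (norm_scheme == "multiplicative") 1L
                                else 2L,
                    norm_target = norm_target,
                    norm_interval = as.integer(round(norm_interval / dt)),
                    record_interval = as.integer(round(record_dt / dt)),
                    record_v = FALSE)
  list(times = res$rec_times, weights = res$weights,
       w_final = res$w_final, dw_total = res$dw_total,
       post_times = res$post_times,
       post_rate = res$n_post / duration)
}

#' Weight trajectory container
#'
#' @param times recording times, s.
#' @param weights matrix, time x synapses.
#' @param w_min,w_max bounds.
#' @return an object of class `weight_trajectory`.
#' @export
weight_trajectory <- function(times, weights, w_min = 0, w_max = 10) {
  stopifnot(length(times) == nrow(weights))
  structure(list(times = times, weights = weights,
                 w_min = w_min, w_max = w_max),
            class = "weight_trajectory")
}

#' @export
as.data.frame.weight_trajectory <- function(x, ...) {
  n <- ncol(x$weights)
  data.frame(time_s = rep(x$times, n),
             synapse_index = rep(seq_len(n), each = length(x$times)),
             weight = as.vector(x$weights))
}

#' @export
print.weight_trajectory <- function(x, ...) {
  cat("<weight_trajectory>", ncol(x$weights), "synapses,",
      length(x$times), "time points, bounds [",
      x$w_min, ",", x$w_max, "]\n")
  invisible(x)
}

#' Symmetry-breaking experiment
#'
#' Many presynaptic neurons with identical initial weights project to one
#' postsynaptic neuron. Under the antisymmetric DP window with a small
#' depression excess, the combination of causal correlations (strong inputs
#' help trigger postsynaptic spikes) and the net-negative window integral
#' splits the population: part of the weights is driven to the upper bound,
#' the rest to the lower bound. Potentiation-only windows (PP, UP) push all
#' weights to the ceiling; depression-only (DU) pushes all to the floor.
#'
#' @param n_inputs number of inputs (100 in the full-size run).
#' @param duration simulated time, s.
#' @param rule learning rule id.
#' @param depression_excess relative depression excess for DP (default 2%).
#' @param alpha learning-rate multiplier. For the antisymmetric DP window it
#'   is kept small (2) so that synapses differentiate while crossing the
#'   bistable region instead of being swept coherently to one bound; the
#'   monotone rules (PP, UP, DU), whose drift is not a small residual of
#'   opposing terms, use a larger default (6) and reach their bound within
#'   seconds.
#' @param base_rate mean input rate, Hz.
#' @param initial_weight common initial weight. Development starts from weak
#'   synapses (10% of the ceiling): the winners are the correlated clusters
#'   that grow out of this weak state, the rest are pushed to the floor as
#'   the rising output rate strengthens acausal depression.
#' @param signal_sd rate-signal fluctuation scale, Hz. Development is
#'   simulated with weakly modulated inputs (30% of the base rate): strong
#'   common bursts make the causal correlation shared by all inputs dominate
#'   the small depression excess and suppress competition.
#' @param w_min,w_max weight bounds.
#' @param neuron a [neuron_params()].
#' @param input_config optional [input_ensemble_config()] override
#'   (supersedes `signal_sd`).
#' @param seed integer seed.
#' @param record_dt trajectory recording interval, s.
#' @param margin bound margin used for the bound-fraction metric.
#' @return list with `trajectory` (a [weight_trajectory()]), `final_weights`,
#'   `histogram` (of final weights), `bimodality`, `post_rate`.
#' @export
run_symmetry_breaking <- function(n_inputs = 100, duration = 2000,
                                  rule = "DP",
                                  depression_excess = if (rule == "DP") 0.02 else 0,
                                  alpha = if (rule == "DP") 2 else 6,
                                  initial_weight = 1,
                                  base_rate = 10,
                                  signal_sd = 0.3 * base_rate,
                                  w_min = 0, w_max = 10,
                                  neuron = neuron_params(),
                                  input_config = NULL,
                                  seed = 1, record_dt = 0.5,
                                  margin = 0.05 * (w_max - w_min)) {
  if (is.null(input_config))
    input_config <- input_ensemble_config(n_inputs, base_rate = base_rate,
                                          signal_sd = signal_sd)
  win <- learning_window(rule, alpha = alpha,
                         depression_excess = depression_excess)
  tr <- run_plastic_trial(input_config, duration, win,
                          initial_weights = rep(initial_weight, n_inputs),
                          w_min = w_min, w_max = w_max,
                          neuron = neuron, seed = seed,
                          record_dt = record_dt)
  list(trajectory = weight_trajectory(tr$times, tr$weights, w_min, w_max),
       final_weights = tr$w_final,
       histogram = hist(tr$w_final, breaks = seq(w_min, w_max, length.out = 21),
                        plot = FALSE),
       bimodality = bimodality_fraction(tr$w_final, w_min, w_max, margin),
       post_rate = tr$post_rate)
}

#' Receptive-field adaptation experiment
#'
#' A 10-input network whose postsynaptic neuron starts out tuned to input 7.
#' Optionally one stimulus (input 4, the "training input") is
#' over-represented: its rate is boosted 100% and its neighbors 50%,
#' modeling the pairing of a sensory stimulus with a neuromodulatory state.
#' Trajectories are averaged over independent trials; the "input
#' specificity" `w[training] - w[initial preferred]` tracks the
#' receptive-field shift over time.
#'
#' @param rule learning rule id.
#' @param training logical: over-represent the training input?
#' @param n_trials number of independent trials (100 in the full-size run).
#' @param duration simulated time per trial, s.
#' @param alpha learning-rate multiplier.
#' @param n_inputs number of inputs.
#' @param training_index,initial_pref_index training and initially preferred
#'   inputs.
#' @param initial_weights starting receptive field (default: [tuned_profile()]
#'   peaked at `initial_pref_index`).
#' @param normalize apply weight normalization (conserving the initial
#'   weight sum) every `norm_interval` seconds.
#' @param norm_scheme normalization scheme, `"multiplicative"` or
#'   `"subtractive"` (see [normalize_weights()]).
#' @param norm_interval normalization interval, s.
#' @param triplet optional [triplet_params()] for the triplet rule.
#' @param w_min,w_max weight bounds.
#' @param neuron a [neuron_params()].
#' @param base_rate untrained mean input rate, Hz.
#' @param signal_sd rate-signal fluctuation scale, Hz.
#' @param signal_timescale correlation time of the rate signals, s.
#' @param mixing_width correlation width of the input ensemble, indices.
#' @param seed master seed, expanded into one sub-seed per trial.
#' @param record_dt recording interval, s.
#' @return list with `mean_trajectory` and `sd_trajectory`
#'   ([weight_trajectory()] of per-time mean/sd over trials), `times`,
#'   `specificity_mean`, `specificity_sd` (time series),
#'   `final_weights_mean`, `final_weights` (trials x inputs), `peak_index`
#'   of the mean final receptive field, `trial_seeds`.
#' @export
run_rf_adaptation <- function(rule = "DP", training = FALSE,
                              n_trials = 100, duration = 40,
                              alpha = 2.3, n_inputs = 10,
                              training_index = 4, initial_pref_index = 7,
                              initial_weights = NULL,
                              normalize = FALSE,
                              norm_scheme = c("multiplicative", "subtractive"),
                              norm_interval = 0.1,
                              triplet = NULL,
                              w_min = 0, w_max = 10,
                              neuron = neuron_params(),
                              base_rate = 5,
                              signal_sd = 0.8 * base_rate,
                              signal_timescale = 0.05,
                              mixing_width = 1,
                              seed = 1, record_dt = 0.5) {
  if (is.null(initial_weights))
    initial_weights <- tuned_profile(n_inputs, peak_index = initial_pref_index,
                                     peak = 0.45 * w_max, baseline = 0.2 * w_max)
  cfg <- input_ensemble_config(
    n_inputs, base_rate = base_rate,
    signal_sd = signal_sd, signal_timescale = signal_timescale,
    mixing_width = mixing_width,
    training_index = if (training) training_index else NULL)
  win <- learning_window(rule, alpha = alpha)
  seeds <- derive_seeds(seed, n_trials)
  acc <- NULL; acc2 <- NULL
  finals <- matrix(NA_real_, n_trials, n_inputs)
  times <- NULL
  for (k in seq_len(n_trials)) {
    tr <- run_plastic_trial(cfg, duration, win, triplet = triplet,
                            neuron = neuron,
                            initial_weights = initial_weights,
                            w_min = w_min, w_max = w_max,
                            normalize = normalize,
                            norm_scheme = norm_scheme,
                            norm_interval = norm_interval,
                            seed = seeds[k], record_dt = record_dt)
    if (is.null(acc)) {
      acc <- tr$weights; acc2 <- tr$weights^2; times <- tr$times
    } else {
      acc <- acc + tr$weights; acc2 <- acc2 + tr$weights^2
    }
    finals[k, ] <- tr$w_final
  }
  mean_w <- acc / n_trials
  var_w <- pmax(acc2 / n_trials - mean_w^2, 0)
  spec_mean <- mean_w[, training_index] - mean_w[, initial_pref_index]
  spec_trials <- finals[, training_index] - finals[, initial_pref_index]
  list(mean_trajectory = weight_trajectory(times, mean_w, w_min, w_max),
       sd_trajectory = weight_trajectory(times, sqrt(var_w), w_min, w_max),
       times = times,
       specificity_mean = spec_mean,
       specificity_final = spec_trials,
       final_weights_mean = mean_w[nrow(mean_w), ],
       final_weights = finals,
       peak_index = which.max(mean_w[nrow(mean_w), ]),
       initial_weights = initial_weights,
       trial_seeds = seeds,
       rule = rule, training = training, normalize = normalize)
}

#' Receptive-field adaptation with weight normalization
#'
#' Same protocol as [run_rf_adaptation()] with the multiplicative
#' normalization rule enabled, so the weight budget is conserved and the
#' inputs compete explicitly. The default scheme here is subtractive:
#' removing the common component of growth is what turns the shared weight
#' budget into genuine competition (sharpening under potentiation-dominated
#' rules, a receptive-field shift to an over-represented stimulus);
#' multiplicative rescaling remains available via `norm_scheme`.
#'
#' @inheritParams run_rf_adaptation
#' @export
run_rf_adaptation_normalized <- function(rule = "DP", training = FALSE,
                                         norm_scheme = "subtractive",
                                         duration = 200, ...) {
  run_rf_adaptation(rule = rule, training = training, normalize = TRUE,
                    norm_scheme = norm_scheme, duration = duration, ...)
}

#' Modulation sweep on a single synapse
#'
#' One presynaptic Poisson neuron (constant rate `nu`) drives the
#' postsynaptic neuron through a synapse held ("frozen") at a probe weight
#' `w`; the plasticity the standard antisymmetric window (unit amplitudes,
#' learning rate `alpha`) would have produced is accumulated without being
#' applied, and reported as the relative change `dw/w` per trial. Sweeping
#' `alpha` at fixed `nu` probes the gating-of-plasticity mechanism; sweeping
#' `nu` at fixed `alpha` probes the activity-upregulation mechanism.
#'
#' @param w_grid probe weights (> 0).
#' @param alpha_grid learning-rate values (the canonical reference is
#'   `alpha0 = 5e-4`).
#' @param nu_grid presynaptic rates, Hz (reference `nu0 = 10`).
#' @param n_trials trials per grid point (200 in the full-size run).
#' @param trial_duration measurement window per trial, s.
#' @param triplet optional [triplet_params()] for the triplet rule.
#' @param neuron a [neuron_params()].
#' @param seed master seed.
#' @param dt integration step, s.
#' @return an object of class `modulation_sweep_result`: a data frame with
#'   one row per (w, alpha, nu) holding `dwow_mean`, `dwow_sd`, `dwow_se`
#'   and `n_trials`.
#' @export
run_modulation_pair_sweep <- function(w_grid = c(3, 7),
                                      alpha_grid = 5e-4 * (1:4),
                                      nu_grid = 10,
                                      n_trials = 200,
                                      trial_duration = 10,
                                      triplet = NULL,
                                      neuron = neuron_params(),
                                      seed = 1, dt = 1e-4) {
  if (any(w_grid <= 0)) stop("probe weights must be > 0 (dw/w undefined at 0)")
  if (!length(alpha_grid) || !length(nu_grid)) stop("grids must be non-empty")
  grid <- expand.grid(w = w_grid, alpha = alpha_grid, nu = nu_grid,
                      KEEP.OUT.ATTRS = FALSE)
  seeds <- derive_seeds(seed, n_trials)
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    w <- grid$w[g]; al <- grid$alpha[g]; nu <- grid$nu[g]
    cfg <- input_ensemble_config(1, base_rate = nu, signal_sd = 0,
                                 mixing_width = 0)
    win <- learning_window("DP", a_causal = 1, a_acausal = -1, alpha = al)
    dwow <- numeric(n_trials)
    for (k in seq_len(n_trials)) {
      tr <- run_plastic_trial(cfg, trial_duration, win, triplet = triplet,
                              neuron = neuron, initial_weights = w,
                              freeze_weights = TRUE,
                              seed = seeds[k], dt = dt,
                              record_dt = trial_duration)
      dwow[k] <- tr$dw_total / w
    }
    rows[[g]] <- data.frame(w = w, alpha = al, nu = nu,
                            dwow_mean = mean(dwow), dwow_sd = sd(dwow),
                            dwow_se = sd(dwow) / sqrt(n_trials),
                            n_trials = n_trials)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("modulation_sweep_result", "data.frame")
  out
}

#' Fit the proportionality dw/w = k * alpha
#'
#' For every (w, nu) condition of a sweep, fits the straight line through
#' the origin relating the mean relative weight change to the learning rate,
#' and reports the slope `k` together with the worst residual of an
#' unconstrained linear fit as a fraction of the response range (a
#' linearity diagnostic).
#'
#' @param sweep a `modulation_sweep_result` with at least two alpha values
#'   per condition.
#' @return data frame with columns `w`, `nu`, `k`, `max_resid_frac`.
#' @export
fit_modulation_slopes <- function(sweep) {
  stopifnot(inherits(sweep, "modulation_sweep_result"))
  conds <- unique(sweep[, c("w", "nu")])
  rows <- lapply(seq_len(nrow(conds)), function(i) {
    s <- sweep[sweep$w == conds$w[i] & sweep$nu == conds$nu[i], ]
    if (nrow(s) < 2)
      return(data.frame(w = conds$w[i], nu = conds$nu[i],
                        k = s$dwow_mean / s$alpha, max_resid_frac = NA_real_))
    k <- sum(s$alpha * s$dwow_mean) / sum(s$alpha^2)
    fit <- lm(dwow_mean ~ alpha, data = s)
    rng <- diff(range(s$dwow_mean))
    data.frame(w = conds$w[i], nu = conds$nu[i], k = k,
               max_resid_frac = if (rng > 0)
                 max(abs(residuals(fit))) / rng else 0)
  })
  do.call(rbind, rows)
}

#' Network-level modulation experiment
#'
#' Ten presynaptic neurons with a tuned initial receptive field (peak at
#' input 7) drive the postsynaptic neuron under the standard antisymmetric
#' window (unit amplitudes, learning rate `alpha`) at presynaptic rate
#' `nu`. Initial and final tuning curves are averaged over trials and
#' rescaled to unit maximum, and their widths at half maximum are compared:
#' sharpening (width shrinks) or broadening (width grows).
#'
#' @param alpha learning rate.
#' @param nu presynaptic rate, Hz.
#' @param n_trials trials (50 in the full-size run).
#' @param duration simulated time per trial, s.
#' @param n_inputs number of inputs.
#' @param initial_weights starting receptive field.
#' @param triplet optional [triplet_params()].
#' @param w_min,w_max weight bounds.
#' @param neuron a [neuron_params()].
#' @param seed master seed.
#' @param record_dt recording interval, s.
#' @return list with rescaled `initial_curve` and `final_curve`,
#'   `initial_width`, `final_width`, `final_weights_mean`, `trial_seeds`.
#' @export
run_modulation_network <- function(alpha = 0.02, nu = 10,
                                   n_trials = 50, duration = 150,
                                   n_inputs = 10,
                                   initial_weights = tuned_profile(n_inputs),
                                   triplet = NULL,
                                   w_min = 0, w_max = 10,
                                   neuron = neuron_params(),
                                   seed = 1, record_dt = 1) {
  cfg <- input_ensemble_config(n_inputs, base_rate = nu)
  win <- learning_window("DP", a_causal = 1, a_acausal = -1, alpha = alpha)
  seeds <- derive_seeds(seed, n_trials)
  acc <- 0
  for (k in seq_len(n_trials)) {
    tr <- run_plastic_trial(cfg, duration, win, triplet = triplet,
                            neuron = neuron,
                            initial_weights = initial_weights,
                            w_min = w_min, w_max = w_max,
                            seed = seeds[k], record_dt = record_dt)
    acc <- acc + tr$w_final
  }
  final_mean <- acc / n_trials
  init_curve <- rescale_tuning(initial_weights)
  final_curve <- rescale_tuning(final_mean)
  list(initial_curve = init_curve, final_curve = final_curve,
       initial_width = width_at_half_max(init_curve),
       final_width = width_at_half_max(final_curve),
       final_weights_mean = final_mean,
       alpha = alpha, nu = nu, trial_seeds = seeds)
}
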