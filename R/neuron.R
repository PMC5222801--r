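#' Postsynaptic neuron parameters
#'
#' Current-based leaky integrate-and-fire neuron in dimensionless voltage
#' units (rest 0, threshold 20). Each presynaptic spike at synapse `i`
#' injects a current step of `weight_i * syn_gain` that decays with
#' `tau_syn`. A background noise current drives baseline firing: its mean
#' `noise_mean` is calibrated so the neuron fires at roughly 10 Hz when all
#' feedforward weights are zero (the shipped default was obtained once with
#' [calibrate_noise()] and is re-derivable at any time), and an optional
#' Gaussian white component of amplitude `noise_sd` can be added.
#'
#' Spike emission is stochastic ("escape noise"): spikes are emitted with
#' instantaneous hazard `escape_rate0 * exp((V - v_thresh)/escape_width)`,
#' followed by reset and an absolute refractory period. The soft threshold
#' makes the response to a strong synchronous EPSP supralinear — a synapse
#' whose EPSP approaches the threshold region recruits postsynaptic spikes
#' far more effectively than a synapse half as strong — while reset and
#' refractoriness saturate the response at high drive. Setting
#' `escape_width = 0` recovers a hard deterministic threshold.
#'
#' @param tau_m membrane time constant, s.
#' @param v_rest,v_thresh,v_reset resting, (soft) threshold and reset
#'   potentials (arbitrary units; `v_thresh > v_rest`,
#'   `v_reset < v_thresh`).
#' @param refractory absolute refractory period, s.
#' @param tau_syn synaptic current time constant, s.
#' @param syn_gain current injected per presynaptic spike per unit weight.
#'   With the default, a unitary weight of 7 (the strong probe used in the
#'   modulation experiments) gives an EPSP peak of about 5.4 voltage units,
#'   reaching well into the escape region, while a weight of 3 stays mostly
#'   below it.
#' @param noise_mean mean background current (voltage units).
#' @param noise_sd optional white-noise amplitude of the background current
#'   (0 by default: baseline variability comes from the escape process).
#' @param escape_rate0 hazard at `V = v_thresh`, Hz (before saturation).
#' @param escape_width voltage scale of the exponential hazard; 0 disables
#'   escape noise (hard threshold).
#' @param escape_rate_max saturation level of the hazard, Hz (soft cap,
#'   `lambda / (1 + lambda/escape_rate_max)`). Saturation is what lets a
#'   rising output rate act as a competitive signal: once the neuron is
#'   strongly driven, additional presynaptic input recruits few extra
#'   spikes, while acausal depression keeps growing with the output rate.
#'   `0` disables the cap.
#' @return an object of class `neuron_params`.
#' @export
neuron_params <- function(tau_m = 0.020,
                          v_rest = 0, v_thresh = 20, v_reset = 0,
                          refractory = 0.002,
                          tau_syn = 0.002,
                          syn_gain = 10,
                          noise_mean = 9.64,
                          noise_sd = 0,
                          escape_rate0 = 500,
                          escape_width = 3,
                          escape_rate_max = 250) {
  if (v_thresh <= v_rest) stop("v_thresh must be > v_rest")
  if (v_reset >= v_thresh) stop("v_reset must be < v_thresh")
  if (refractory < 0) stop("refractory must be >= 0")
  if (tau_m <= 0 || tau_syn <= 0) stop("time constants must be > 0")
  if (escape_rate0 <= 0) stop("escape_rate0 must be > 0")
  if (escape_width < 0) stop("escape_width must be >= 0")
  if (escape_rate_max < 0) stop("escape_rate_max must be >= 0")
  structure(list(tau_m = tau_m, v_rest = v_rest, v_thresh = v_thresh,
                 v_reset = v_reset, refractory = refractory,
                 tau_syn = tau_syn, syn_gain = syn_gain,
                 noise_mean = noise_mean, noise_sd = noise_sd,
                 escape_rate0 = escape_rate0, escape_width = escape_width,
                 escape_rate_max = escape_rate_max),
            class = "neuron_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("<neuron_params> LIF: tau_m =", x$tau_m * 1e3, "ms, threshold",
      x$v_thresh, ", refractory", x$refractory * 1e3, "ms\n")
  cat("  synapse: tau_syn =", x$tau_syn * 1e3, "ms, gain", x$syn_gain, "\n")
  cat("  noise: mean", x$noise_mean, ", sd", x$noise_sd, "\n")
  invisible(x)
}

#' Simulate the postsynaptic neuron (weights fixed)
#'
#' Forward-Euler leaky integrate-and-fire dynamics at resolution `dt` driven
#' by the given spike trains through fixed synaptic weights, plus the
#' background noise current. No plasticity.
#'
#' @param inputs a `spike_train_set` (or `NULL` for no feedforward input).
#' @param weights one non-negative weight per input train.
#' @param params a [neuron_params()].
#' @param duration simulated time, s; defaults to `inputs$duration`.
#' @param seed optional integer seed (background noise).
#' @param dt integration step, s.
#' @param record_v record the membrane trace.
#' @return an object of class `simulation_trace`: list with `post_spikes`
#'   (times, s), `rate` (Hz), `duration`, and optionally `v_trace`.
#' @export
simulate_postsynaptic <- function(inputs, weights, params = neuron_params(),
                                  duration = NULL, seed = NULL, dt = 1e-4,
                                  record_v = FALSE) {
  stopifnot(inherits(params, "neuron_params"))
  if (is.null(inputs)) {
    inputs <- structure(list(duration = duration, dt = dt,
                             spikes = rep(list(numeric(0)), length(weights))),
                        class = "spike_train_set")
  }
  if (length(weights) != length(inputs$spikes))
    stop("need exactly one weight per input train")
  if (is.null(duration)) duration <- inputs$duration
  if (is.null(duration) || duration <= 0) stop("duration must be > 0")
  if (!is.null(seed)) set.seed(seed)
  ev <- as_event_stream(inputs, dt)
  n_steps <- as.integer(round(duration / dt))
  res <- engine_run(ev$step, ev$id,
                    n_inputs = length(weights), n_steps = n_steps, dt = dt,
                    w0 = as.numeric(weights), w_min = 0,
                    w_max = max(1, max(weights)) * 2,
                    tau_m = params$tau_m, v_rest = params$v_rest,
                    v_thresh = params$v_thresh, v_reset = params$v_reset,
                    refrac_steps = as.integer(round(params$refractory / dt)),
                    tau_syn = params$tau_syn, syn_gain = params$syn_gain,
                    noise_mean = params$noise_mean, noise_sd = params$noise_sd,
                    escape_rate0 = params$escape_rate0,
                    escape_width = params$escape_width,
                    escape_rate_max = params$escape_rate_max,
                    plastic = FALSE,
                    alpha = 0, a_causal = 0, a_acausal = 0,
                    tau_causal = 0.02, tau_acausal = 0.02,
                    a3_causal = 0, a3_acausal = 0, tau_x = 0.1, tau_y = 0.1,
                    freeze_weights = TRUE,
                    norm_mode = 0L, norm_target = 0, norm_interval = 0,
                    record_interval = 0, record_v = record_v)
  out <- list(post_spikes = res$post_times, duration = duration,
              rate = res$n_post / duration)
  if (record_v) out$v_trace <- res$v_trace
  structure(out, class = "simulation_trace")
}

#' @export
print.simulation_trace <- function(x, ...) {
  cat("<simulation_trace>", length(x$post_spikes), "spikes over",
      x$duration, "s (", round(x$rate, 3), "Hz )\n")
  invisible(x)
}

#' Zero-weight baseline firing rate
#'
#' Firing rate of the postsynaptic neuron with every feedforward weight at
#' zero, i.e. driven by the background noise current alone.
#'
#' @inheritParams simulate_postsynaptic
#' @return rate, Hz.
#' @export
baseline_rate <- function(params = neuron_params(), duration = 100,
                          seed = NULL, dt = 1e-4) {
  simulate_postsynaptic(NULL, weights = 0, params = params,
                        duration = duration, seed = seed, dt = dt)$rate
}

#' Calibrate the background noise current to a target baseline rate
#'
#' Deterministic bisection on `noise_mean` (common random numbers: every
#' candidate is evaluated on the same noise realization, so the estimated
#' rate is monotone in `noise_mean` and the search is reproducible given
#' `seed`). The zero-weight firing rate of the returned parameters matches
#' `target_rate` within `tolerance`, estimated over `duration` seconds.
#'
#' @param params starting [neuron_params()]; all fields except `noise_mean`
#'   are kept.
#' @param target_rate desired zero-weight firing rate, Hz (> 0).
#' @param tolerance acceptable rate deviation, Hz.
#' @param seed integer seed for the evaluation noise.
#' @param duration evaluation duration per candidate, s (>= 100 recommended).
#' @param bounds search interval for `noise_mean`.
#' @param max_iter bisection iteration cap.
#' @return a `neuron_params` with adjusted `noise_mean`.
#' @export
calibrate_noise <- function(params = neuron_params(), target_rate = 10,
                            tolerance = 1, seed = 1, duration = 100,
                            bounds = c(0, 2 * params$v_thresh),
                            max_iter = 40) {
  stopifnot(inherits(params, "neuron_params"))
  if (target_rate <= 0) stop("target_rate must be > 0")
  eval_rate <- function(mu) {
    p <- params; p$noise_mean <- mu
    baseline_rate(p, duration = duration, seed = seed)
  }
  lo <- bounds[1]; hi <- bounds[2]
  r_lo <- eval_rate(lo); r_hi <- eval_rate(hi)
  if (r_lo > target_rate || r_hi < target_rate)
    stop(sprintf(paste0("calibration error: target %.4g Hz outside achievable",
                        " range [%.4g, %.4g] Hz for noise_mean in [%g, %g]"),
                 target_rate, r_lo, r_hi, lo, hi))
  for (k in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    r <- eval_rate(mid)
    if (abs(r - target_rate) <= tolerance / 2) break
    if (r < target_rate) lo <- mid else hi <- mid
  }
  if (abs(r - target_rate) > tolerance)
    stop(sprintf("calibration error: best rate %.3g Hz misses target %.3g Hz",
                 r, target_rate))
  params$noise_mean <- mid
  params
}
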