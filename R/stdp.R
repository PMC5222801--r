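#' Brute-force all-to-all pair sum (oracle)
#'
#' Total weight change from summing the learning window over every
#' (pre, post) spike pair. Quadratic in the number of spikes; intended as
#' the reference implementation against which the online trace updater is
#' verified.
#'
#' @param pre_spikes,post_spikes sorted spike-time vectors, s.
#' @param window a [learning_window()].
#' @return total weight change (dimensionless).
#' @export
brute_force_pair_sum <- function(pre_spikes, post_spikes, window) {
  if (!length(pre_spikes) || !length(post_spikes)) return(0)
  sum(window_value(window, outer(post_spikes, pre_spikes, "-")))
}

#' Brute-force triplet sum (oracle)
#'
#' Exhaustive enumeration of the all-to-all triplet rule: every causal pair
#' is weighted by `a_causal + a3_causal * sum over earlier post spikes`, and
#' every acausal pair by `a_acausal - a3_acausal * sum over earlier pre
#' spikes`, with the slow traces evaluated just before the triggering spike.
#' Cubic in spike counts; use on small trains only.
#'
#' @inheritParams brute_force_pair_sum
#' @param triplet a [triplet_params()].
#' @return total weight change.
#' @export
brute_force_triplet_sum <- function(pre_spikes, post_spikes, window, triplet) {
  stopifnot(inherits(window, "learning_window"),
            inherits(triplet, "triplet_params"))
  total <- 0
  for (tp in post_spikes) { # potentiation, triggered by post spikes
    earlier_pre <- pre_spikes[pre_spikes < tp]
    if (!length(earlier_pre)) next
    r1 <- sum(exp(-(tp - earlier_pre) / window$tau_causal))
    earlier_post <- post_spikes[post_spikes < tp]
    o2 <- if (length(earlier_post))
      sum(exp(-(tp - earlier_post) / triplet$tau_y)) else 0
    total <- total + window$alpha * r1 *
      (window$a_causal + triplet$a3_causal * o2)
  }
  for (tq in pre_spikes) { # depression, triggered by pre spikes
    earlier_post <- post_spikes[post_spikes < tq]
    if (!length(earlier_post)) next
    o1 <- sum(exp(-(tq - earlier_post) / window$tau_acausal))
    earlier_pre <- pre_spikes[pre_spikes < tq]
    r2 <- if (length(earlier_pre))
      sum(exp(-(tq - earlier_pre) / triplet$tau_x)) else 0
    total <- total + window$alpha * o1 *
      (window$a_acausal - triplet$a3_acausal * r2)
  }
  total
}

#' Online trace-based STDP updater
#'
#' Event-driven implementation of the all-to-all pair rule (and, when
#' `triplet` is supplied, the triplet rule) via exponentially decaying
#' eligibility traces: a presynaptic trace per branch and a postsynaptic
#' trace per branch, decayed exactly between events. The cumulative change
#' it returns equals [brute_force_pair_sum()] (resp.
#' [brute_force_triplet_sum()]) up to floating-point roundoff. Spikes of
#' both kinds at exactly the same time contribute nothing to each other.
#'
#' @inheritParams brute_force_pair_sum
#' @param triplet optional [triplet_params()]; `NULL` for the pure pair rule.
#' @return total weight change.
#' @export
online_stdp <- function(pre_spikes, post_spikes, window, triplet = NULL) {
  stopifnot(inherits(window, "learning_window"))
  if (is.null(triplet)) triplet <- triplet_off()
  times <- sort(unique(c(pre_spikes, post_spikes)))
  if (!length(times)) return(0)
  r1 <- 0; r2 <- 0; o1 <- 0; o2 <- 0
  t_last <- times[1]
  total <- 0
  pre_set <- pre_spikes; post_set <- post_spikes
  for (t in times) {
    d <- t - t_last
    if (d > 0) {
      r1 <- r1 * exp(-d / window$tau_causal)
      r2 <- r2 * exp(-d / triplet$tau_x)
      o1 <- o1 * exp(-d / window$tau_acausal)
      o2 <- o2 * exp(-d / triplet$tau_y)
      t_last <- t
    }
    is_pre <- any(pre_set == t)
    is_post <- any(post_set == t)
    if (is_pre)
      total <- total + window$alpha * o1 *
        (window$a_acausal - triplet$a3_acausal * r2)
    if (is_post)
      total <- total + window$alpha * r1 *
        (window$a_causal + triplet$a3_causal * o2)
    if (is_pre) { r1 <- r1 + 1; r2 <- r2 + 1 }
    if (is_post) { o1 <- o1 + 1; o2 <- o2 + 1 }
  }
  total
}

#' Clip weights to their bounds
#'
#' Hard clipping to `[w_min, w_max]`; idempotent.
#'
#' @param weights numeric vector.
#' @param w_min,w_max bounds (`w_min < w_max`).
#' @return clipped vector.
#' @export
apply_bounds <- function(weights, w_min = 0, w_max = 10) {
  if (w_min >= w_max) stop("w_min must be < w_max")
  pmin(pmax(weights, w_min), w_max)
}

#' Weight normalization
#'
#' Restores the total weight to `target_sum`, then clips to the bounds.
#' Applied periodically during learning, this implements explicit
#' competition: a synapse can only grow at the expense of the others. Two
#' schemes are provided:
#'
#' * `"multiplicative"` (default): rescale the vector by
#'   `target_sum / sum(weights)`. Conserves the weight profile's shape and
#'   yields graded, stable weight distributions.
#' * `"subtractive"`: shift every weight by a common offset, solved (given
#'   the bound clipping) so the sum equals `target_sum`. Removes the common
#'   component of weight growth, so only differential (correlation-driven)
#'   growth survives — the strongly competitive scheme.
#'
#' An all-zero vector cannot be rescaled multiplicatively; it is returned
#' unchanged with a warning.
#'
#' @param weights numeric vector (non-negative).
#' @param target_sum desired total weight (> 0).
#' @param w_min,w_max bounds applied after normalization.
#' @param scheme `"multiplicative"` or `"subtractive"`.
#' @return normalized (and clipped) vector.
#' @export
normalize_weights <- function(weights, target_sum, w_min = 0, w_max = 10,
                              scheme = c("multiplicative", "subtractive")) {
  scheme <- match.arg(scheme)
  if (target_sum <= 0) stop("target_sum must be > 0")
  s <- sum(weights)
  if (scheme == "multiplicative") {
    if (s <= 0) {
      warning("normalization skipped: weight vector sums to zero")
      return(weights)
    }
    return(apply_bounds(weights * target_sum / s, w_min, w_max))
  }
  if (s == target_sum) return(apply_bounds(weights, w_min, w_max))
  clip_sum <- function(d) sum(apply_bounds(weights + d, w_min, w_max))
  rng <- w_max - w_min
  lo <- -rng; hi <- rng
  for (it in 1:60) {
    d <- (lo + hi) / 2
    if (clip_sum(d) < target_sum) lo <- d else hi <- d
  }
  apply_bounds(weights + (lo + hi) / 2, w_min, w_max)
}

#' Expected weight drift for independent Poisson trains
#'
#' Closed-form mean weight change per second under the all-to-all pair rule
#' when pre- and postsynaptic trains are statistically independent Poisson
#' processes: every branch of the window is sampled uniformly, so the drift
#' is the pair rate times the window integral,
#' `nu_pre * nu_post * alpha * (a_causal*tau_causal + a_acausal*tau_acausal)`.
#' A balanced antisymmetric window gives zero drift; a depression excess
#' makes the window integral — and hence the drift — negative.
#'
#' @param nu_pre,nu_post firing rates, Hz.
#' @param window a [learning_window()].
#' @return expected weight change per second.
#' @export
expected_drift <- function(nu_pre, nu_post, window) {
  stopifnot(inherits(window, "learning_window"))
  nu_pre * nu_post * window$alpha *
    (window$a_causal * window$tau_causal +
       window$a_acausal * window$tau_acausal)
}
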