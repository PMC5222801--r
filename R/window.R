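#' STDP learning windows for four neuromodulatory states
#'
#' The learning window gives the weight change elicited by a pre/post spike
#' pair as a function of the timing difference `dt = t_post - t_pre`:
#' `alpha * a_causal * exp(-dt/tau_causal)` for `dt > 0` and
#' `alpha * a_acausal * exp(dt/tau_acausal)` for `dt < 0` (signed amplitudes;
#' negative means depression). Exactly coincident spikes (`dt = 0`)
#' contribute nothing. The four rules model different neuromodulatory
#' states:
#'
#' * `DP` (Depression-Potentiation): the standard antisymmetric Hebbian
#'   window — causal potentiation, acausal depression.
#' * `PP` (Potentiation-Potentiation): symmetric, every pairing potentiates.
#' * `UP` (Unchanged-Potentiation): causal potentiation only.
#' * `DU` (Depression-Unchanged): acausal depression only.
#'
#' @param rule one of `"DP"`, `"PP"`, `"UP"`, `"DU"`.
#' @param a amplitude magnitude used on active branches (default 0.01).
#' @param a_causal,a_acausal explicit branch amplitudes; defaults follow the
#'   rule (`a_acausal` is signed: negative = depression).
#' @param tau_causal,tau_acausal branch time constants, s.
#' @param alpha global learning-rate multiplier (the neuromodulatory gating
#'   knob; `alpha = 0` freezes learning).
#' @param depression_excess for `DP`, relative excess of the depression
#'   amplitude over the potentiation amplitude; `0.02` gives the slightly
#'   depression-dominated window (negative window integral) that drives
#'   competitive symmetry breaking.
#' @return an object of class `learning_window`.
#' @export
learning_window <- function(rule = c("DP", "PP", "UP", "DU"),
                            a = 0.01,
                            a_causal = NULL, a_acausal = NULL,
                            tau_causal = 0.020, tau_acausal = 0.020,
                            alpha = 1, depression_excess = 0) {
  rule <- match.arg(rule)
  if (tau_causal <= 0 || tau_acausal <= 0) stop("time constants must be > 0")
  if (alpha < 0) stop("alpha must be >= 0")
  if (is.null(a_causal))
    a_causal <- switch(rule, DP = a, PP = a, UP = a, DU = 0)
  if (is.null(a_acausal))
    a_acausal <- switch(rule,
                        DP = -a * (1 + depression_excess),
                        PP = a, UP = 0, DU = -a)
  ok <- switch(rule,
               DP = a_causal > 0 && a_acausal < 0,
               PP = a_causal > 0 && a_acausal > 0,
               UP = a_causal > 0 && a_acausal == 0,
               DU = a_causal == 0 && a_acausal < 0)
  if (!ok) stop(sprintf("amplitudes (%g, %g) violate the sign pattern of rule %s",
                        a_causal, a_acausal, rule))
  structure(list(rule = rule, a_causal = a_causal, a_acausal = a_acausal,
                 tau_causal = tau_causal, tau_acausal = tau_acausal,
                 alpha = alpha),
            class = "learning_window")
}

#' @export
print.learning_window <- function(x, ...) {
  cat(sprintf("<learning_window %s> a+ = %g (tau %g ms), a- = %g (tau %g ms), alpha = %g\n",
              x$rule, x$a_causal, x$tau_causal * 1e3,
              x$a_acausal, x$tau_acausal * 1e3, x$alpha))
  invisible(x)
}

#' Evaluate a learning window
#'
#' @param window a [learning_window()].
#' @param delta_t spike-timing difference(s) `t_post - t_pre`, seconds
#'   (vectorized).
#' @return weight change(s), dimensionless.
#' @export
window_value <- function(window, delta_t) {
  stopifnot(inherits(window, "learning_window"))
  out <- numeric(length(delta_t))
  pos <- delta_t > 0
  neg <- delta_t < 0
  out[pos] <- window$alpha * window$a_causal * exp(-delta_t[pos] / window$tau_causal)
  out[neg] <- window$alpha * window$a_acausal * exp(delta_t[neg] / window$tau_acausal)
  out
}

#' Triplet-rule parameters
#'
#' Amplitudes and slow time constants of the triplet STDP extension
#' (two traces per side). On a postsynaptic spike the pair potentiation
#' amplitude is augmented by `a3_causal` times the slow postsynaptic trace
#' (decay `tau_y`); on a presynaptic spike the pair depression amplitude is
#' augmented by `a3_acausal` times the slow presynaptic trace (decay
#' `tau_x`). With both triplet amplitudes at 0 the rule reduces exactly to
#' the pair-based window. Default slow time constants follow the standard
#' triplet-model fits for visual cortex (101 ms and 125 ms).
#'
#' @param a3_causal triplet potentiation amplitude (>= 0).
#' @param a3_acausal triplet depression amplitude (>= 0).
#' @param tau_x,tau_y slow pre/post trace time constants, s.
#' @return an object of class `triplet_params`.
#' @export
triplet_params <- function(a3_causal = 0.005, a3_acausal = 0.005,
                           tau_x = 0.101, tau_y = 0.125) {
  if (a3_causal < 0 || a3_acausal < 0) stop("triplet amplitudes must be >= 0")
  if (tau_x <= 0 || tau_y <= 0) stop("time constants must be > 0")
  structure(list(a3_causal = a3_causal, a3_acausal = a3_acausal,
                 tau_x = tau_x, tau_y = tau_y),
            class = "triplet_params")
}

# internal: no-op triplet block
triplet_off <- function() triplet_params(0, 0)
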