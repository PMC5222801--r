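#' Input specificity
#'
#' Difference between the weight of the training input and the weight of the
#' initially preferred input, `w[training] - w[initial_pref]`. Positive
#' values indicate a receptive-field shift toward the trained stimulus.
#'
#' @param weights weight vector.
#' @param training_index,initial_pref_index 1-based input indices.
#' @return weight difference (arbitrary units).
#' @export
input_specificity <- function(weights, training_index, initial_pref_index) {
  n <- length(weights)
  if (training_index < 1 || training_index > n ||
      initial_pref_index < 1 || initial_pref_index > n)
    stop("index out of range")
  weights[[training_index]] - weights[[initial_pref_index]]
}

#' Rescale a tuning curve to unit maximum
#'
#' Element-wise division by the maximum weight, so curves measured under
#' different conditions can be compared by shape alone.
#'
#' @param weights weight vector with at least one positive entry.
#' @return rescaled curve with maximum 1.
#' @export
rescale_tuning <- function(weights) {
  m <- max(weights)
  if (m <= 0) stop("cannot rescale an all-zero tuning curve")
  weights / m
}

#' Fraction of weights at the bounds
#'
#' Proportion of weights lying within `margin` of either bound — the
#' signature of competitive symmetry breaking, where some weights are driven
#' to the floor and the rest to the ceiling.
#'
#' @param weights weight vector.
#' @param w_min,w_max bounds.
#' @param margin distance from a bound that still counts as "at the bound";
#'   must satisfy `0 < margin < (w_max - w_min)/2`. Default: 5% of the range.
#' @return proportion in `[0, 1]`.
#' @export
bimodality_fraction <- function(weights, w_min = 0, w_max = 10,
                                margin = 0.05 * (w_max - w_min)) {
  if (margin <= 0 || margin >= (w_max - w_min) / 2)
    stop("margin must be in (0, (w_max - w_min)/2)")
  mean(weights <= w_min + margin | weights >= w_max - margin)
}

#' Width at half maximum of a rescaled tuning curve
#'
#' Linear-interpolated extent (in index units) of the region where the
#' rescaled curve is at least 0.5. Quantifies sharpening (width decreases)
#' versus broadening (width increases) of receptive-field tuning. A flat
#' curve at the maximum returns the full extent `n - 1` by convention.
#'
#' @param rescaled_curve tuning curve with maximum 1 (see [rescale_tuning()]).
#' @return width in index units.
#' @export
width_at_half_max <- function(rescaled_curve) {
  f <- as.numeric(rescaled_curve)
  n <- length(f)
  if (n < 2) return(0)
  thr <- 0.5
  w <- 0
  for (i in seq_len(n - 1)) {
    a <- f[i]; b <- f[i + 1]
    if (a >= thr && b >= thr) {
      w <- w + 1
    } else if (a >= thr && b < thr) {
      w <- w + (a - thr) / (a - b)
    } else if (a < thr && b >= thr) {
      w <- w + (b - thr) / (b - a)
    }
  }
  w
}

#' Summary of a receptive-field weight vector
#'
#' @param weights weight vector.
#' @param w_min,w_max bounds.
#' @param margin bound margin for [bimodality_fraction()].
#' @param training_index,initial_pref_index optional indices for
#'   [input_specificity()].
#' @return an object of class `tuning_summary`: peak index, rescaled curve,
#'   width at half maximum, bound fraction, and (if indices are given)
#'   input specificity.
#' @export
tuning_summary <- function(weights, w_min = 0, w_max = 10,
                           margin = 0.05 * (w_max - w_min),
                           training_index = NULL,
                           initial_pref_index = NULL) {
  curve <- rescale_tuning(weights)
  out <- list(
    peak_index = which.max(weights),
    rescaled_curve = curve,
    width_at_half_max = width_at_half_max(curve),
    bimodality_fraction = bimodality_fraction(weights, w_min, w_max, margin),
    specificity = if (!is.null(training_index) && !is.null(initial_pref_index))
      input_specificity(weights, training_index, initial_pref_index)
    else NA_real_)
  structure(out, class = "tuning_summary")
}

#' @export
print.tuning_summary <- function(x, ...) {
  cat("<tuning_summary> peak:", x$peak_index,
      " width@half-max:", round(x$width_at_half_max, 3),
      " bound fraction:", round(x$bimodality_fraction, 3))
  if (!is.na(x$specificity)) cat("  specificity:", round(x$specificity, 4))
  cat("\n")
  invisible(x)
}
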