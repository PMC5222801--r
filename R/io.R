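#' Build configuration objects from a YAML file
#'
#' Reads a pipeline configuration with optional top-level blocks `input`,
#' `neuron`, `window` and `triplet`, whose keys mirror the arguments of
#' [input_ensemble_config()], [neuron_params()], [learning_window()] and
#' [triplet_params()].
#'
#' @param path path to a YAML file.
#' @return named list with any of `input`, `neuron`, `window`, `triplet`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(raw$input))
    out$input <- do.call(input_ensemble_config, raw$input)
  if (!is.null(raw$neuron))
    out$neuron <- do.call(neuron_params, raw$neuron)
  if (!is.null(raw$window))
    out$window <- do.call(learning_window, raw$window)
  if (!is.null(raw$triplet))
    out$triplet <- do.call(triplet_params, raw$triplet)
  out
}

#' Write a weight trajectory as tidy CSV
#'
#' Long format with columns `time_s`, `synapse_index`, `weight`.
#'
#' @param trajectory a [weight_trajectory()].
#' @param path output file.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "weight_trajectory"))
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}
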