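#' Spike raster
#'
#' Container for per-neuron, per-trial spike times (seconds, relative to the
#' protocol alignment). Neuron order is fixed at construction as the
#' lexicographic order of the neuron ids, so downstream barcodes and weight
#' vectors are comparable across analysis stages.
#'
#' @param spikes data.frame with columns `neuron_id`, `trial`,
#'   `spike_time_s`. Spike times must be sorted ascending within each
#'   (neuron, trial); trials must be integers in `1..n_trials`.
#' @param neuron_ids optional character vector of all neuron ids (a neuron
#'   may fire no spikes); defaults to the ids present in `spikes`.
#' @param n_trials optional trial count; defaults to `max(spikes$trial)`.
#' @return An object of class `spike_raster`: the spike table plus
#'   attributes `neuron_ids` (sorted) and `n_trials`.
#' @export
spike_raster <- function(spikes, neuron_ids = NULL, n_trials = NULL) {
  spikes <- as.data.frame(spikes)
  stopifnot(all(c("neuron_id", "trial", "spike_time_s") %in% names(spikes)))
  spikes$neuron_id <- as.character(spikes$neuron_id)
  spikes$trial <- as.integer(spikes$trial)
  spikes$spike_time_s <- as.numeric(spikes$spike_time_s)
  if (is.null(neuron_ids)) neuron_ids <- unique(spikes$neuron_id)
  neuron_ids <- sort(as.character(unique(neuron_ids)))
  if (!all(spikes$neuron_id %in% neuron_ids))
    stop("spikes reference neuron ids absent from neuron_ids")
  if (is.null(n_trials))
    n_trials <- if (nrow(spikes)) max(spikes$trial) else 1L
  n_trials <- as.integer(n_trials)
  if (nrow(spikes) && (any(spikes$trial < 1L) || any(spikes$trial > n_trials)))
    stop("trial indices must lie in 1..n_trials")
  # sortedness within (neuron, trial) is a construction invariant
  o <- order(spikes$neuron_id, spikes$trial)
  sp <- spikes[o, , drop = FALSE]
  key <- paste(sp$neuron_id, sp$trial)
  same <- key[-1] == key[-length(key)]
  if (length(key) > 1 &&
      any(same & diff(sp$spike_time_s) < 0))
    stop("spike times must be sorted ascending within each (neuron, trial)")
  rownames(sp) <- NULL
  structure(sp, class = c("spike_raster", "data.frame"),
            neuron_ids = neuron_ids, n_trials = n_trials)
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> %d spikes, %d neurons, %d trials\n",
              nrow(x), length(attr(x, "neuron_ids")), attr(x, "n_trials")))
  invisible(x)
}

#' Read / write spike tables as CSV
#'
#' CSV columns: `neuron_id,trial,spike_time_s`.
#'
#' @param path file path.
#' @param neuron_ids,n_trials passed through to [spike_raster()].
#' @export
read_spikes <- function(path, neuron_ids = NULL, n_trials = NULL) {
  sp <- data.table::fread(path, colClasses = list(
    character = "neuron_id", integer = "trial", numeric = "spike_time_s"))
  spike_raster(as.data.frame(sp), neuron_ids = neuron_ids,
               n_trials = n_trials)
}

#' @rdname read_spikes
#' @param raster a [spike_raster()].
#' @export
write_spikes <- function(raster, path) {
  stopifnot(inherits(raster, "spike_raster"))
  data.table::fwrite(as.data.frame(unclass(raster))[
    c("neuron_id", "trial", "spike_time_s")], path)
  invisible(path)
}
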