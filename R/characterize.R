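#' Binary per-neuron barcode
#'
#' A barcode labels every neuron in the fixed ensemble order with a single
#' boolean — responsive/non-responsive, or early/late-responder — for one
#' condition. Barcodes support the set algebra of [consistent_set()] and
#' [unique_consistent_set()] and supply the weights of the flexible decoder.
#'
#' @param labels named logical vector, one element per neuron, in the fixed
#'   (lexicographic) neuron order.
#' @param context list describing what the labels mean, e.g.
#'   `list(odor = "hex", history = "solitary", criterion = "6.5sd")`.
#' @return object of class `barcode` (a named logical vector).
#' @export
barcode <- function(labels, context = list()) {
  stopifnot(is.logical(labels), !is.null(names(labels)),
            !anyNA(labels))
  structure(labels, class = "barcode", context = context)
}

#' @export
print.barcode <- function(x, ...) {
  cat(sprintf("<barcode> %d/%d responsive\n", sum(x), length(x)))
  invisible(x)
}

#' Per-neuron response threshold from pre-stimulus activity
#'
#' The responsiveness criterion: a neuron's threshold is the mean plus
#' `k_sd` standard deviations of its trial-averaged pre-stimulus PSTH (by
#' default the 2 s window just before the first stimulus, i.e. 40 bins at
#' 50 ms). A silent neuron (zero pre-stimulus s.d.) gets threshold
#' `mean + 1/n_trials`, so that at least two evoked spikes across trials in
#' one bin are needed to qualify.
#'
#' @param tensor a [bin_spikes()] tensor covering the pre-stimulus window.
#' @param pre_window numeric length-2, pre-stimulus interval (s); must
#'   contain at least 2 bins.
#' @param k_sd threshold multiplier (default 6.5).
#' @return named numeric vector of thresholds in trial-averaged counts/bin.
#' @export
response_threshold <- function(tensor, pre_window, k_sd = 6.5) {
  stopifnot(inherits(tensor, "binned_tensor"), length(pre_window) == 2)
  bs <- attr(tensor, "bin_starts")
  pre <- bs >= pre_window[1] & bs < pre_window[2]
  if (sum(pre) < 2)
    stop("pre-stimulus window must contain at least 2 bins")
  psth <- apply(unclass(tensor)[, , pre, drop = FALSE], c(1, 3), mean)
  mu <- rowMeans(psth)
  sdv <- apply(psth, 1, stats::sd)
  n_trials <- dim(tensor)[2]
  thr <- ifelse(sdv > 0, mu + k_sd * sdv, mu + 1 / n_trials)
  names(thr) <- dimnames(tensor)[[1]]
  thr
}

#' Classify neurons as responsive or non-responsive
#'
#' A neuron is a responder if any bin of its trial-averaged PSTH within the
#' stimulus window exceeds its [response_threshold()] (mean + `k_sd` s.d.
#' of pre-stimulus activity).
#'
#' @param tensor a [bin_spikes()] tensor covering both windows.
#' @param pre_window pre-stimulus interval (2 s just before the first
#'   stimulus).
#' @param stim_window stimulus interval over which bins are tested.
#' @param k_sd threshold multiplier (default 6.5).
#' @param context stored on the returned barcode.
#' @return a [barcode()] of responders.
#' @export
classify_responders <- function(tensor, pre_window, stim_window,
                                k_sd = 6.5, context = list()) {
  stopifnot(inherits(tensor, "binned_tensor"), length(stim_window) == 2)
  thr <- response_threshold(tensor, pre_window, k_sd)
  bs <- attr(tensor, "bin_starts")
  stim <- bs >= stim_window[1] & bs < stim_window[2]
  if (!any(stim)) stop("stimulus window contains no bins")
  psth <- apply(unclass(tensor)[, , stim, drop = FALSE], c(1, 3), mean)
  resp <- apply(psth > thr, 1, any)
  names(resp) <- dimnames(tensor)[[1]]
  context$criterion <- sprintf("mean+%.1f s.d.", k_sd)
  barcode(resp, context)
}

#' Response latency per neuron
#'
#' Latency is the start time (relative to stimulus onset) of the first
#' 50 ms bin meeting the response criterion. In `"solitary"` mode that is
#' the first trial-averaged bin exceeding the neuron's pre-stimulus
#' threshold. In `"sequential"` mode the first difference of the PSTH must
#' additionally be positive at that bin (the criterion used when a target
#' follows a distractor, where firing may still be decaying). Neurons that
#' never qualify get latency `NA`.
#'
#' @inheritParams classify_responders
#' @param mode `"solitary"` or `"sequential"`.
#' @return object of class `latency_vector`: data.frame with columns
#'   `neuron_id`, `latency_bin` (1-based bin index within the stimulus
#'   window, `NA` when absent), `latency_s` (bin start minus onset).
#' @export
compute_latency <- function(tensor, pre_window, stim_window,
                            mode = c("solitary", "sequential"),
                            k_sd = 6.5) {
  mode <- match.arg(mode)
  stopifnot(inherits(tensor, "binned_tensor"), length(stim_window) == 2)
  thr <- response_threshold(tensor, pre_window, k_sd)
  bs <- attr(tensor, "bin_starts")
  psth_full <- apply(unclass(tensor), c(1, 3), mean)
  stim_idx <- which(bs >= stim_window[1] & bs < stim_window[2])
  if (!length(stim_idx)) stop("stimulus window contains no bins")
  ids <- dimnames(tensor)[[1]]
  lat_bin <- rep(NA_integer_, length(ids))
  for (i in seq_along(ids)) {
    qual <- psth_full[i, stim_idx] > thr[i]
    if (mode == "sequential") {
      d <- rep(NA_real_, length(stim_idx))
      ok <- stim_idx >= 2L
      d[ok] <- psth_full[i, stim_idx[ok]] - psth_full[i, stim_idx[ok] - 1L]
      qual <- qual & !is.na(d) & d > 0
    }
    if (any(qual)) lat_bin[i] <- which(qual)[1]
  }
  w <- attr(tensor, "bin_width")
  out <- data.frame(neuron_id = ids, latency_bin = lat_bin,
                    latency_s = (lat_bin - 1L) * w +
                      (bs[stim_idx[1]] - stim_window[1]))
  structure(out, class = c("latency_vector", "data.frame"),
            mode = mode, bin_width = w, stim_window = stim_window)
}

#' Early versus late/non-responders
#'
#' A neuron is an early responder iff it has a latency and that latency
#' (bin start time) is strictly below the cutoff; a latency of exactly
#' 600 ms is late.
#'
#' @param latencies a [compute_latency()] result.
#' @param cutoff_s early/late boundary in seconds (default 0.6).
#' @return a [barcode()] with `TRUE` = early responder.
#' @export
early_late <- function(latencies, cutoff_s = 0.6) {
  stopifnot(inherits(latencies, "latency_vector"))
  early <- !is.na(latencies$latency_s) & latencies$latency_s < cutoff_s
  names(early) <- latencies$neuron_id
  barcode(early, list(criterion = sprintf("latency < %g s", cutoff_s)))
}

check_aligned <- function(barcodes) {
  ids <- names(barcodes[[1]])
  for (b in barcodes) {
    stopifnot(inherits(b, "barcode"))
    if (!identical(names(b), ids))
      stop("barcodes must share the same neurons in the same order")
  }
  ids
}

#' Neurons responsive in every condition
#'
#' Elementwise AND across barcodes: the "consistent set" of neurons that
#' responded to every introduction of the target stimulus.
#'
#' @param barcodes non-empty list of aligned [barcode()]s.
#' @return a [barcode()].
#' @export
consistent_set <- function(barcodes) {
  stopifnot(is.list(barcodes), length(barcodes) >= 1)
  check_aligned(barcodes)
  out <- Reduce(`&`, lapply(barcodes, as.logical))
  names(out) <- names(barcodes[[1]])
  barcode(out, list(criterion = "consistent (AND)"))
}

#' Consistent responders unique to the target
#'
#' Removes from the consistent set every neuron that responds to any
#' distractor: `consistent AND NOT (OR of distractor barcodes)`. With no
#' distractors the consistent set is returned unchanged.
#'
#' @param consistent a [barcode()] from [consistent_set()].
#' @param distractor_barcodes list (possibly empty) of aligned barcodes.
#' @return a [barcode()].
#' @export
unique_consistent_set <- function(consistent, distractor_barcodes = list()) {
  stopifnot(inherits(consistent, "barcode"))
  if (!length(distractor_barcodes))
    return(consistent)
  check_aligned(c(list(consistent), distractor_barcodes))
  any_d <- Reduce(`|`, lapply(distractor_barcodes, as.logical))
  out <- as.logical(consistent) & !any_d
  names(out) <- names(consistent)
  barcode(out, list(criterion = "consistent AND unique"))
}

#' Write / read a barcode as CSV (`neuron_id,label`)
#'
#' @param bc a [barcode()].
#' @param path file path.
#' @export
write_barcode <- function(bc, path) {
  stopifnot(inherits(bc, "barcode"))
  data.table::fwrite(data.frame(neuron_id = names(bc),
                                label = as.integer(bc)), path)
  invisible(path)
}

#' @rdname write_barcode
#' @export
read_barcode <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  barcode(stats::setNames(df$label != 0, df$neuron_id))
}
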