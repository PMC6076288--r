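#' Bin spike times into a neuron x trial x bin count tensor
#'
#' Counts spikes in non-overlapping bins of width `bin_width` covering
#' `window` (times relative to the protocol alignment). Bins are half-open
#' `[left, right)`: a spike exactly at the window end is excluded, which
#' makes a 4 s window at 50 ms resolution an unambiguous 80 bins. Spikes
#' outside the window are silently excluded.
#'
#' @param raster a [spike_raster()].
#' @param bin_width bin width in seconds (default 0.05).
#' @param window numeric length-2 `(start_s, end_s)`; `bin_width` must divide
#'   the window length to within one part in 1e9.
#' @return A 3-d integer array of class `binned_tensor` with dims
#'   `neuron x trial x bin`, dimnames on neurons, and attributes
#'   `bin_width`, `window`, `bin_starts`.
#' @examples
#' r <- spike_raster(data.frame(neuron_id = "a", trial = 1,
#'                              spike_time_s = c(0.01, 0.02, 0.06)))
#' drop(bin_spikes(r, 0.05, c(0, 0.15)))   # 2 1 0
#' @export
bin_spikes <- function(raster, bin_width = 0.05, window) {
  stopifnot(inherits(raster, "spike_raster"),
            length(window) == 2, window[1] < window[2], bin_width > 0)
  span <- window[2] - window[1]
  n_bins <- round(span / bin_width)
  if (abs(span / bin_width - n_bins) > 1e-9 * max(1, n_bins))
    stop("bin_width must divide the window length")
  n_bins <- as.integer(n_bins)
  ids <- attr(raster, "neuron_ids")
  n_trials <- attr(raster, "n_trials")
  counts <- array(0L, dim = c(length(ids), n_trials, n_bins),
                  dimnames = list(neuron = ids, trial = NULL, bin = NULL))
  t <- raster$spike_time_s
  keep <- t >= window[1] & t < window[2]
  if (any(keep)) {
    b <- pmin(floor((t[keep] - window[1]) / bin_width), n_bins - 1L) + 1L
    i <- match(raster$neuron_id[keep], ids)
    tr <- raster$trial[keep]
    tab <- table(factor(i, levels = seq_along(ids)),
                 factor(tr, levels = seq_len(n_trials)),
                 factor(b, levels = seq_len(n_bins)))
    counts[] <- as.integer(tab)
  }
  structure(counts, class = "binned_tensor",
            bin_width = bin_width, window = as.numeric(window),
            bin_starts = window[1] + bin_width * (seq_len(n_bins) - 1))
}

#' @export
print.binned_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<binned_tensor> %d neurons x %d trials x %d bins (%.0f ms bins, window [%g, %g) s)\n",
    d[1], d[2], d[3], attr(x, "bin_width") * 1000,
    attr(x, "window")[1], attr(x, "window")[2]))
  invisible(x)
}

#' Trial-averaged response matrix
#'
#' Averages a [bin_spikes()] tensor over trials, giving the neuron x bin
#' "response matrix" (a trial-averaged PSTH per neuron; each column is the
#' population vector of one 50 ms bin).
#'
#' @param tensor a `binned_tensor`.
#' @param provenance list carrying condition labels, e.g.
#'   `list(odor = "hex", history = "solitary")`; stored with the matrix.
#' @return numeric matrix of class `response_matrix` (neurons x bins) with
#'   attributes `provenance`, `bin_starts`, `bin_width`, `window`,
#'   `n_trials`.
#' @export
trial_average <- function(tensor, provenance = list()) {
  stopifnot(inherits(tensor, "binned_tensor"))
  if (dim(tensor)[2] < 1) stop("at least one trial is required")
  m <- apply(unclass(tensor), c(1, 3), mean)
  dimnames(m) <- list(neuron = dimnames(tensor)[[1]], bin = NULL)
  structure(m, class = c("response_matrix", "matrix"),
            provenance = provenance,
            bin_starts = attr(tensor, "bin_starts"),
            bin_width = attr(tensor, "bin_width"),
            window = attr(tensor, "window"),
            n_trials = dim(tensor)[2])
}

#' Concatenate response matrices across conditions
#'
#' Stacks the columns (time bins) of several response matrices that share
#' the same neuron axis, in the given order. Each column keeps a provenance
#' record `(condition, bin, bin_start)` so concatenation is invertible with
#' [split_conditions()]. This is the data matrix whose covariance drives the
#' population PCA: e.g. six 80-bin conditions give an 85 x 480 matrix.
#'
#' @param matrices named list of `response_matrix` objects (names become the
#'   condition labels; unnamed lists are labeled `cond1`, `cond2`, ...).
#' @return A `response_matrix` whose `provenance` attribute is a data.frame
#'   with one row per column.
#' @export
concatenate_conditions <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 1)
  if (is.null(names(matrices)) || any(!nzchar(names(matrices))))
    names(matrices) <- sprintf("cond%d", seq_along(matrices))
  ids <- rownames(matrices[[1]])
  for (m in matrices) {
    stopifnot(inherits(m, "response_matrix"))
    if (!identical(rownames(m), ids))
      stop("all matrices must share the same neuron ids in the same order")
  }
  out <- do.call(cbind, lapply(matrices, unclass))
  prov <- do.call(rbind, lapply(names(matrices), function(nm) {
    m <- matrices[[nm]]
    data.frame(condition = nm, bin = seq_len(ncol(m)),
               bin_start = attr(m, "bin_starts"))
  }))
  rownames(prov) <- NULL
  structure(out, class = c("response_matrix", "matrix"),
            provenance = prov,
            bin_width = attr(matrices[[1]], "bin_width"))
}

#' Undo [concatenate_conditions()]
#'
#' @param concatenated a concatenated `response_matrix`.
#' @return Named list of `response_matrix` objects, one per condition, in
#'   first-appearance order.
#' @export
split_conditions <- function(concatenated) {
  prov <- attr(concatenated, "provenance")
  stopifnot(is.data.frame(prov), nrow(prov) == ncol(concatenated))
  conds <- unique(prov$condition)
  out <- lapply(conds, function(cd) {
    sel <- prov$condition == cd
    structure(unclass(concatenated)[, sel, drop = FALSE],
              class = c("response_matrix", "matrix"),
              provenance = list(condition = cd),
              bin_starts = prov$bin_start[sel],
              bin_width = attr(concatenated, "bin_width"))
  })
  names(out) <- conds
  out
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> %d neurons x %d bins\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Write / read a response matrix as CSV
#'
#' Rows are labeled with neuron ids and columns with bin start times.
#'
#' @param matrix a `response_matrix`.
#' @param path file path.
#' @export
write_response_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "response_matrix"))
  bs <- attr(matrix, "bin_starts")
  prov <- attr(matrix, "provenance")
  if (is.null(bs) && is.data.frame(prov)) bs <- prov$bin_start
  df <- data.frame(neuron_id = rownames(matrix),
                   unclass(matrix), check.names = FALSE)
  names(df)[-1] <- if (!is.null(bs)) sprintf("t%g", bs) else
    sprintf("bin%d", seq_len(ncol(matrix)))
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_response_matrix
#' @export
read_response_matrix <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  bs <- suppressWarnings(as.numeric(sub("^t", "", colnames(m))))
  colnames(m) <- NULL
  structure(m, class = c("response_matrix", "matrix"),
            bin_starts = if (!anyNA(bs)) bs else NULL,
            provenance = list())
}
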