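#' Stimulus protocol
#'
#' A protocol describes the odor epochs delivered in one trial block: an
#' ordered set of non-overlapping pulses, the number of trials, and which
#' epoch's onset defines the alignment time `t = 0`. In the sequential
#' paradigm a 4 s distractor pulse precedes a 4 s target pulse with a 500 ms
#' gap; target analyses align to the target onset and distractor analyses to
#' the distractor onset.
#'
#' @param epochs data.frame with columns `odor` (character), `onset_s`,
#'   `offset_s` (numeric seconds, absolute protocol time). Epochs must be
#'   time-ordered and non-overlapping, with `offset_s > onset_s`.
#' @param trial_count positive integer number of trials.
#' @param alignment odor label (or integer index) of the epoch whose onset is
#'   taken as `t = 0` by [aligned_epochs()].
#' @return An object of class `stim_protocol`.
#' @examples
#' p <- sequence_protocol("2oct", "hex")
#' aligned_epochs(p)
#' @export
stim_protocol <- function(epochs, trial_count, alignment) {
  epochs <- as.data.frame(epochs)
  stopifnot(all(c("odor", "onset_s", "offset_s") %in% names(epochs)),
            nrow(epochs) >= 1)
  epochs$odor <- as.character(epochs$odor)
  if (any(epochs$offset_s <= epochs$onset_s))
    stop("every epoch offset must exceed its onset")
  if (is.unsorted(epochs$onset_s, strictly = TRUE))
    stop("epochs must be strictly time-ordered")
  if (nrow(epochs) > 1 &&
      any(epochs$onset_s[-1] < epochs$offset_s[-nrow(epochs)]))
    stop("epochs must not overlap")
  trial_count <- as.integer(trial_count)
  if (is.na(trial_count) || trial_count < 1)
    stop("trial_count must be a positive integer")
  if (is.numeric(alignment)) {
    idx <- as.integer(alignment)
    if (idx < 1 || idx > nrow(epochs)) stop("alignment index out of range")
  } else {
    idx <- match(as.character(alignment), epochs$odor)
    if (is.na(idx)) stop("alignment label not found among epochs: ", alignment)
  }
  structure(list(epochs = epochs, trial_count = trial_count,
                 alignment = idx),
            class = "stim_protocol")
}

#' Epoch table shifted so the alignment epoch starts at t = 0
#'
#' @param protocol a [stim_protocol()].
#' @return data.frame like `protocol$epochs` with times relative to the
#'   alignment epoch's onset.
#' @export
aligned_epochs <- function(protocol) {
  stopifnot(inherits(protocol, "stim_protocol"))
  e <- protocol$epochs
  t0 <- e$onset_s[protocol$alignment]
  e$onset_s <- e$onset_s - t0
  e$offset_s <- e$offset_s - t0
  e
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("<stim_protocol> %d epoch(s), %d trial(s), aligned to '%s'\n",
              nrow(x$epochs), x$trial_count,
              x$epochs$odor[x$alignment]))
  print(aligned_epochs(x))
  invisible(x)
}

#' Single-pulse protocol
#'
#' Convenience constructor: one 4 s odor pulse starting at `t = 0`.
#'
#' @param odor odor label.
#' @param duration_s pulse duration (default 4 s).
#' @param trial_count trials (default 10).
#' @export
solitary_protocol <- function(odor, duration_s = 4, trial_count = 10L) {
  stim_protocol(data.frame(odor = odor, onset_s = 0, offset_s = duration_s),
                trial_count = trial_count, alignment = odor)
}

#' Distractor-then-target protocol
#'
#' Two non-overlapping 4 s pulses with a 500 ms inter-stimulus gap, aligned
#' to the target onset (so the distractor occupies `[-4.5, -0.5]` s).
#'
#' @param distractor,target odor labels.
#' @param duration_s pulse duration (default 4 s).
#' @param gap_s gap between distractor offset and target onset (default 0.5).
#' @param trial_count trials (default 10).
#' @param align `"target"` or `"distractor"`.
#' @export
sequence_protocol <- function(distractor, target, duration_s = 4,
                              gap_s = 0.5, trial_count = 10L,
                              align = c("target", "distractor")) {
  align <- match.arg(align)
  ep <- data.frame(
    odor = c(distractor, target),
    onset_s = c(-(duration_s + gap_s), 0),
    offset_s = c(-gap_s, duration_s))
  stim_protocol(ep, trial_count = trial_count,
                alignment = if (align == "target") 2L else 1L)
}

#' Read / write a protocol as JSON
#'
#' The JSON carries `epochs` (array of `{odor, onset_s, offset_s}`),
#' `trial_count` and `alignment` (odor label).
#'
#' @param path file path.
#' @return `read_protocol()` returns a [stim_protocol()];
#'   `write_protocol()` returns `path` invisibly.
#' @export
read_protocol <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  stim_protocol(j$epochs, j$trial_count, j$alignment)
}

#' @rdname read_protocol
#' @param protocol a [stim_protocol()].
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "stim_protocol"))
  jsonlite::write_json(
    list(epochs = protocol$epochs,
         trial_count = protocol$trial_count,
         alignment = protocol$epochs$odor[protocol$alignment]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
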