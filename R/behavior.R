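#' Palp-opening response trace
#'
#' A uniformly sampled palp-distance time series (arbitrary units) for one
#' subject, trial and condition, covering a pre-stimulus baseline and the
#' response window.
#'
#' @param samples data.frame with columns `time_s` (uniform grid) and
#'   `distance`.
#' @param subject,trial,condition identifiers.
#' @return object of class `por_trace`.
#' @export
por_trace <- function(samples, subject = NA_character_, trial = NA_integer_,
                      condition = NA_character_) {
  samples <- as.data.frame(samples)
  stopifnot(all(c("time_s", "distance") %in% names(samples)),
            nrow(samples) >= 2)
  dt <- diff(samples$time_s)
  if (any(abs(dt - dt[1]) > 1e-9))
    stop("trace must be uniformly sampled")
  structure(samples, class = c("por_trace", "data.frame"),
            subject = subject, trial = trial, condition = condition,
            dt = dt[1])
}

#' @export
print.por_trace <- function(x, ...) {
  cat(sprintf("<por_trace> %d samples @ %.0f ms, [%g, %g] s (%s)\n",
              nrow(x), attr(x, "dt") * 1000, min(x$time_s), max(x$time_s),
              attr(x, "condition")))
  invisible(x)
}

#' Read POR traces from CSV
#'
#' CSV columns: `subject,trial,condition,time_s,distance`; one trace per
#' (subject, trial, condition).
#'
#' @param path file path.
#' @return list of [por_trace()] objects.
#' @export
read_por <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  key <- interaction(df$subject, df$trial, df$condition, drop = TRUE)
  lapply(split(df, key), function(g)
    por_trace(g[order(g$time_s), c("time_s", "distance")],
              subject = as.character(g$subject[1]),
              trial = as.integer(g$trial[1]),
              condition = as.character(g$condition[1])))
}

#' @rdname read_por
#' @param traces list of [por_trace()] objects.
#' @export
write_por <- function(traces, path) {
  if (inherits(traces, "por_trace")) traces <- list(traces)
  df <- do.call(rbind, lapply(traces, function(tr)
    data.frame(subject = attr(tr, "subject"), trial = attr(tr, "trial"),
               condition = attr(tr, "condition"),
               time_s = tr$time_s, distance = tr$distance)))
  data.table::fwrite(df, path)
  invisible(path)
}

#' Classify a POR trace as responsive or non-responsive
#'
#' A locust is responsive iff (a) the maximum palp distance during the
#' stimulus window exceeds the pre-stimulus mean + `k_sd` s.d., and (b) the
#' trace stays above 20% of its in-stimulus peak for an uninterrupted
#' second or more within the stimulus window.
#'
#' @param trace a [por_trace()].
#' @param pre_window baseline interval preceding the odor onset.
#' @param stim_window stimulus interval.
#' @param k_sd baseline threshold multiplier (default 6.5).
#' @param min_duration_s minimum uninterrupted supra-20% time (default 1).
#' @return logical: `TRUE` = responsive.
#' @export
classify_por <- function(trace, pre_window, stim_window, k_sd = 6.5,
                         min_duration_s = 1) {
  stopifnot(inherits(trace, "por_trace"))
  t <- trace$time_s; v <- trace$distance
  base <- v[t >= pre_window[1] & t < pre_window[2]]
  if (!length(base)) stop("baseline window contains no samples")
  stim <- t >= stim_window[1] & t < stim_window[2]
  if (!any(stim)) stop("stimulus window contains no samples")
  peak <- max(v[stim])
  amp_ok <- peak > mean(base) + k_sd * stats::sd(base)
  above <- v[stim] > 0.2 * peak
  r <- rle(above)
  dt <- attr(trace, "dt")
  dur_ok <- any(r$values & r$lengths * dt >= min_duration_s)
  isTRUE(amp_ok && dur_ok)
}

#' ON and OFF weight vectors for the behavioral model
#'
#' Copies the ON-window and OFF-window responder barcodes of the trained
#' odor into the two binary weight vectors of the ON-OFF model, and reports
#' their Jaccard overlap `|ON & OFF| / |ON | OFF|` (recorded ensembles are
#' nearly non-overlapping).
#'
#' @param on_barcode responder [barcode()] for the stimulus window.
#' @param off_barcode responder [barcode()] for the OFF window (the 4 s
#'   window starting 500 ms after stimulus offset).
#' @return list: `V_ON`, `V_OFF` (named logical vectors), `overlap`.
#' @export
build_on_off_weights <- function(on_barcode, off_barcode) {
  check_aligned(list(on_barcode, off_barcode))
  v_on <- as.logical(on_barcode); v_off <- as.logical(off_barcode)
  if (!any(v_on) && !any(v_off))
    stop("both barcodes are empty; no template to build")
  structure(list(
    V_ON = stats::setNames(v_on, names(on_barcode)),
    V_OFF = stats::setNames(v_off, names(off_barcode)),
    overlap = sum(v_on & v_off) / max(1L, sum(v_on | v_off))),
    class = "on_off_weights")
}

#' ON-OFF model parameters
#'
#' Output stage of the behavioral model: the ON and OFF classification
#' probabilities are thresholded (`theta_on`, `theta_off`), their rectified
#' difference scaled by `gain` drives a causal first-order low-pass with
#' time constant `tau_s`, and the filtered output is clipped at zero.
#'
#' @param gain output scale (palp-distance units).
#' @param theta_on,theta_off probability thresholds in `[0, 1]`.
#' @param tau_s filter time constant in seconds (default 0.5).
#' @return object of class `on_off_params`.
#' @export
on_off_params <- function(gain, theta_on, theta_off, tau_s = 0.5) {
  stopifnot(gain >= 0, theta_on >= 0, theta_on <= 1,
            theta_off >= 0, theta_off <= 1, tau_s > 0)
  structure(list(gain = gain, theta_on = theta_on, theta_off = theta_off,
                 tau_s = tau_s), class = "on_off_params")
}

#' Predict the palp-opening response from classification probabilities
#'
#' `drive(t) = gain * (max(0, p_on(t) - theta_on) -
#' max(0, p_off(t) - theta_off))`; the output is the causal first-order
#' low-pass of the drive (`y_k = a y_{k-1} + (1 - a) drive_k`,
#' `a = exp(-dt / tau)`, zero initial state), clipped at zero. ON matches
#' open the palps; OFF matches close them, so a distractor matching both
#' templates cancels out.
#'
#' @param p_on,p_off [classification_probability()] vectors on the same
#'   bin grid.
#' @param params an [on_off_params()].
#' @param dt_s bin width of the probability grid (default 0.05 s).
#' @param bin_starts optional time axis; taken from `p_on` when present.
#' @return a [por_trace()] of the predicted palp distance.
#' @export
predict_por <- function(p_on, p_off, params, dt_s = 0.05,
                        bin_starts = attr(p_on, "bin_starts")) {
  stopifnot(inherits(params, "on_off_params"))
  if (length(p_on) != length(p_off))
    stop("p_on and p_off must share the same bin grid")
  drive <- params$gain * (pmax(0, as.numeric(p_on) - params$theta_on) -
                            pmax(0, as.numeric(p_off) - params$theta_off))
  a <- exp(-dt_s / params$tau_s)
  y <- stats::filter((1 - a) * drive, a, method = "recursive", init = 0)
  y <- pmax(0, as.numeric(y))
  if (is.null(bin_starts)) bin_starts <- dt_s * (seq_along(y) - 1)
  por_trace(data.frame(time_s = bin_starts, distance = y),
            subject = "model", condition = attr(p_on, "condition"))
}

#' Fit the ON-OFF output stage on the solitary trained-odor condition
#'
#' Deterministic grid search minimizing the squared error between the
#' predicted and the mean observed solitary POR. The lattice: `gain` over
#' 20 log-spaced values from 0.5x to 50x the observed peak, thresholds over
#' `{0, 0.05, ..., 0.95}`, time constant over `{0.1, 0.25, 0.5, 1}` s.
#' Only solitary trained-odor data enter the fit; ties go to the first
#' lattice point in enumeration order (tau, theta_on, theta_off, gain).
#'
#' @param solitary_por mean observed [por_trace()] for the solitary trained
#'   odor, already on (or resampled to, see [resample_por()]) the decoder
#'   bin grid.
#' @param p_on,p_off classification probabilities for the same condition
#'   and grid.
#' @param dt_s bin width (default 0.05 s).
#' @return the best [on_off_params()], with attributes `sse` and `grid`.
#' @export
fit_on_off_params <- function(solitary_por, p_on, p_off, dt_s = 0.05) {
  stopifnot(inherits(solitary_por, "por_trace"))
  obs <- solitary_por$distance
  if (length(obs) != length(p_on))
    stop("observed trace and probabilities must share the bin grid")
  peak <- max(obs)
  if (peak <= 0) stop("flat observed POR; nothing to fit")
  gains <- peak * 10^seq(log10(0.5), log10(50), length.out = 20)
  thetas <- seq(0, 0.95, by = 0.05)
  taus <- c(0.1, 0.25, 0.5, 1)
  best <- NULL; best_sse <- Inf
  for (tau in taus) for (th_on in thetas) for (th_off in thetas)
    for (g in gains) {
      par <- on_off_params(g, th_on, th_off, tau)
      pred <- predict_por(p_on, p_off, par, dt_s = dt_s,
                          bin_starts = solitary_por$time_s)$distance
      sse <- sum((pred - obs)^2)
      if (sse < best_sse - 1e-12) { best_sse <- sse; best <- par }
    }
  attr(best, "sse") <- best_sse
  attr(best, "grid") <- list(gains = gains, thetas = thetas, taus = taus)
  best
}

#' Resample an observed POR trace to the decoder bin grid
#'
#' Averages samples falling within each 50 ms bin (half-open bins).
#'
#' @param trace a [por_trace()].
#' @param bin_starts bin start times.
#' @param bin_width_s bin width (default 0.05 s).
#' @return a [por_trace()] on the bin grid (bins without samples get `NA`).
#' @export
resample_por <- function(trace, bin_starts, bin_width_s = 0.05) {
  stopifnot(inherits(trace, "por_trace"))
  # half-open bins with a 1 ns guard against floating-point edge jitter
  rel <- (trace$time_s - bin_starts[1]) / bin_width_s
  idx <- floor(rel + 1e-9) + 1L
  ok <- idx >= 1L & idx <= length(bin_starts)
  m <- tapply(trace$distance[ok], factor(idx[ok],
                                         levels = seq_along(bin_starts)),
              mean)
  por_trace(data.frame(time_s = bin_starts, distance = as.numeric(m)),
            subject = attr(trace, "subject"),
            condition = attr(trace, "condition"))
}

#' Correlation between predicted and observed PORs
#'
#' Pearson correlation over a common time grid; zero-variance inputs give
#' `NA` with a warning.
#'
#' @param predicted,observed [por_trace()] objects on the same grid.
#' @param window optional evaluation interval; default: full overlap.
#' @return numeric correlation coefficient (possibly `NA`).
#' @export
por_correlation <- function(predicted, observed, window = NULL) {
  stopifnot(inherits(predicted, "por_trace"),
            inherits(observed, "por_trace"))
  t_common <- intersect(round(predicted$time_s, 9), round(observed$time_s, 9))
  if (!is.null(window))
    t_common <- t_common[t_common >= window[1] & t_common < window[2]]
  if (length(t_common) < 3) stop("traces share too few time points")
  a <- predicted$distance[match(t_common, round(predicted$time_s, 9))]
  b <- observed$distance[match(t_common, round(observed$time_s, 9))]
  ok <- !is.na(a) & !is.na(b)
  if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
    warning("zero-variance trace; correlation undefined")
    return(NA_real_)
  }
  stats::cor(a[ok], b[ok])
}
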