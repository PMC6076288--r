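#' Generator configuration for synthetic PN ensembles
#'
#' Describes the statistical world the spike-train generator draws from:
#' ensemble size, per-odor tuning fractions, the shape of the ON transient,
#' OFF ensembles, and the history cross-talk factors. Defaults emulate the
#' recorded data structure: 85 PNs, 10 trials, 4 s pulses, a fast transient
#' (~1.25 s) decaying to half its peak, OFF ensembles nearly disjoint from
#' ON ensembles, and suppression/enhancement of target responses by the
#' preceding distractor.
#'
#' @param n_neurons ensemble size (85).
#' @param n_trials trials per condition (10).
#' @param baseline_mean_hz,baseline_shape mean and gamma shape of per-neuron
#'   spontaneous rates (3 Hz, shape 4).
#' @param responsive_fraction fraction of neurons in each odor's ON set
#'   (0.30).
#' @param inhibited_fraction fraction inhibited below baseline during each
#'   odor (0.10).
#' @param inhibition_depth multiplicative baseline factor while inhibited
#'   (0.2).
#' @param on_amplitude_hz peak ON rate above baseline (20 Hz).
#' @param off_amplitude_hz peak OFF rate above baseline (defaults to
#'   `on_amplitude_hz`).
#' @param transient_duration_s decay time constant of the ON transient
#'   (1.25 s).
#' @param steady_fraction steady-state ON rate as a fraction of peak (0.5).
#' @param off_fraction fraction of neurons in each odor's OFF set (0.25).
#' @param off_overlap_with_on cap on |ON intersect OFF| / |ON| per odor
#'   (0.05).
#' @param off_delay_s,off_duration_s OFF window: starts `off_delay_s` after
#'   pulse offset (0.5 s) and lasts `off_duration_s` (4 s).
#' @param rho_sup suppression factor in `[0, 1]` applied to the target-epoch
#'   response of neurons that also responded to the distractor (0.4; 1
#'   disables the cross-talk).
#' @param rho_enh enhancement factor `>= 1` applied to target responders
#'   that were inhibited by the distractor (1.5).
#' @param por_max,por_overlap_threshold,por_noise_sd,por_tau_s,por_close_tau_s
#'   palp-opening trace model: maximum amplitude (1 a.u.), minimum ON-set
#'   overlap with the trained odor needed to evoke a response (0.15),
#'   observation noise s.d. (0.02 a.u.), opening time constant (0.5 s),
#'   and closing time constant (0.15 s). Closing is fast because it is
#'   actively driven by the odor's OFF ensemble, which activates
#'   `off_delay_s` after stimulus termination; the palps therefore stay
#'   open through the OFF delay and then shut quickly.
#' @param seed integer seed fixing every draw.
#' @return validated list of class `generator_config`.
#' @export
generator_config <- function(n_neurons = 85L, n_trials = 10L,
                             baseline_mean_hz = 3, baseline_shape = 4,
                             responsive_fraction = 0.30,
                             inhibited_fraction = 0.10,
                             inhibition_depth = 0.2,
                             on_amplitude_hz = 20,
                             off_amplitude_hz = on_amplitude_hz,
                             transient_duration_s = 1.25,
                             steady_fraction = 0.5,
                             off_fraction = 0.25,
                             off_overlap_with_on = 0.05,
                             off_delay_s = 0.5, off_duration_s = 4,
                             rho_sup = 0.4, rho_enh = 1.5,
                             por_max = 1, por_overlap_threshold = 0.15,
                             por_noise_sd = 0.02, por_tau_s = 0.5,
                             por_close_tau_s = 0.15,
                             seed = 1L) {
  cfg <- list(n_neurons = as.integer(n_neurons), n_trials = as.integer(n_trials),
              baseline_mean_hz = baseline_mean_hz,
              baseline_shape = baseline_shape,
              responsive_fraction = responsive_fraction,
              inhibited_fraction = inhibited_fraction,
              inhibition_depth = inhibition_depth,
              on_amplitude_hz = on_amplitude_hz,
              off_amplitude_hz = off_amplitude_hz,
              transient_duration_s = transient_duration_s,
              steady_fraction = steady_fraction,
              off_fraction = off_fraction,
              off_overlap_with_on = off_overlap_with_on,
              off_delay_s = off_delay_s, off_duration_s = off_duration_s,
              rho_sup = rho_sup, rho_enh = rho_enh,
              por_max = por_max,
              por_overlap_threshold = por_overlap_threshold,
              por_noise_sd = por_noise_sd, por_tau_s = por_tau_s,
              por_close_tau_s = por_close_tau_s,
              seed = as.integer(seed))
  fr <- c(cfg$responsive_fraction, cfg$inhibited_fraction, cfg$off_fraction,
          cfg$off_overlap_with_on, cfg$steady_fraction)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  if (cfg$responsive_fraction + cfg$inhibited_fraction > 1)
    stop("responsive_fraction + inhibited_fraction must not exceed 1")
  if (cfg$rho_sup < 0 || cfg$rho_sup > 1)
    stop("rho_sup must lie in [0, 1]")
  if (cfg$rho_enh < 1) stop("rho_enh must be at least 1")
  rates <- c(cfg$baseline_mean_hz, cfg$on_amplitude_hz, cfg$off_amplitude_hz)
  if (any(rates < 0)) stop("rates must be non-negative")
  if (cfg$n_neurons < 1 || cfg$n_trials < 1)
    stop("n_neurons and n_trials must be positive")
  class(cfg) <- "generator_config"
  cfg
}

# half-up rounding with a float guard; fixes the set-size rule
# (e.g. 0.30 * 85 -> 26) independently of IEC 60559 round-half-even
round_half_up <- function(x) floor(x + 0.5 + 1e-9)

#' Ground truth of a synthetic ensemble
#'
#' The latent structure behind a simulation: which neurons form each odor's
#' ON, OFF and inhibited sets, and each neuron's spontaneous rate. Usually
#' produced by [sample_tuning()]; constructing it directly lets tests build
#' fully controlled worlds.
#'
#' @param on,off,inhibited named lists (one element per odor) of neuron-id
#'   character vectors.
#' @param baseline_hz named numeric vector of spontaneous rates, one per
#'   neuron; names define the ensemble and its lexicographic order.
#' @param config the [generator_config()] the tuning belongs to.
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(on, off, inhibited, baseline_hz, config) {
  stopifnot(inherits(config, "generator_config"))
  ids <- sort(names(baseline_hz))
  baseline_hz <- baseline_hz[ids]
  odors <- names(on)
  stopifnot(!is.null(odors), identical(sort(odors), sort(names(off))),
            identical(sort(odors), sort(names(inhibited))))
  for (o in odors) {
    if (!all(c(on[[o]], off[[o]], inhibited[[o]]) %in% ids))
      stop("tuning sets reference unknown neuron ids (odor ", o, ")")
    if (length(intersect(on[[o]], inhibited[[o]])))
      stop("ON and inhibited sets must be disjoint (odor ", o, ")")
    cap <- round_half_up(config$off_overlap_with_on * length(on[[o]]))
    if (length(intersect(on[[o]], off[[o]])) > cap)
      stop("ON/OFF overlap exceeds the configured cap (odor ", o, ")")
    if (any(baseline_hz < 0)) stop("baseline rates must be non-negative")
  }
  structure(list(on = on, off = off, inhibited = inhibited,
                 baseline_hz = baseline_hz, neuron_ids = ids,
                 odors = odors, config = config),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d neurons, odors: %s\n",
              length(x$neuron_ids), paste(x$odors, collapse = ", ")))
  invisible(x)
}

#' Draw per-odor tuning sets and baseline rates
#'
#' For each odor, draws disjoint ON and inhibited sets of sizes
#' `round(responsive_fraction * n)` and `round(inhibited_fraction * n)`
#' (half-up rounding), then an OFF set of size `round(off_fraction * n)`
#' sampled so that its overlap with the ON set cannot exceed
#' `off_overlap_with_on * |ON|` neurons (a zero cap forces disjoint sets).
#' Baseline rates are gamma-distributed across neurons.
#'
#' @param config a [generator_config()].
#' @param odors character vector of odor labels to tune.
#' @param seed seed (defaults to `config$seed`); the same seed always
#'   returns the same ground truth.
#' @return a [ground_truth()].
#' @export
sample_tuning <- function(config, odors, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"), length(odors) >= 1)
  set.seed(seed)
  n <- config$n_neurons
  ids <- sprintf("pn%03d", seq_len(n))
  baseline <- stats::rgamma(n, shape = config$baseline_shape,
                            scale = config$baseline_mean_hz /
                              config$baseline_shape)
  names(baseline) <- ids
  n_on <- round_half_up(config$responsive_fraction * n)
  n_inh <- round_half_up(config$inhibited_fraction * n)
  n_off <- round_half_up(config$off_fraction * n)
  on <- off <- inh <- stats::setNames(vector("list", length(odors)), odors)
  for (o in odors) {
    on[[o]] <- sort(sample(ids, n_on))
    inh[[o]] <- sort(sample(setdiff(ids, on[[o]]), n_inh))
    cap <- round_half_up(config$off_overlap_with_on * n_on)
    # restrict the OFF pool so the ON/OFF overlap cannot exceed the cap
    pool <- c(setdiff(ids, on[[o]]),
              if (cap > 0) sample(on[[o]], min(cap, n_on)))
    off[[o]] <- sort(sample(pool, min(n_off, length(pool))))
  }
  ground_truth(on, off, inh, baseline, config)
}

#' History cross-talk applied to a target epoch
#'
#' Implements the cross-talk rule observed in sequential presentations: a
#' target responder that also responded to the preceding distractor has its
#' target response scaled by `rho_sup` (< 1); a target responder that was
#' inhibited by the distractor is scaled by `rho_enh` (> 1); every other
#' neuron keeps its solitary response. Baseline epochs are untouched.
#'
#' @param gt a [ground_truth()].
#' @param sequence character length-2 `(distractor, target)`; both odors
#'   must be tuned in `gt`.
#' @return data.frame with one row per target-ON neuron: `neuron_id`,
#'   solitary `amplitude_hz` (above baseline), the multiplicative `factor`,
#'   and the `modulated_hz` rate above baseline used in the target epoch.
#' @export
apply_history_modulation <- function(gt, sequence) {
  stopifnot(inherits(gt, "ground_truth"), length(sequence) == 2)
  d <- sequence[1]; tg <- sequence[2]
  if (!all(c(d, tg) %in% gt$odors))
    stop("unknown odor label in sequence: ",
         paste(setdiff(sequence, gt$odors), collapse = ", "))
  cfg <- gt$config
  ids <- gt$on[[tg]]
  factor <- rep(1, length(ids))
  factor[ids %in% gt$on[[d]]] <- cfg$rho_sup
  factor[ids %in% gt$inhibited[[d]]] <- cfg$rho_enh
  data.frame(neuron_id = ids,
             amplitude_hz = cfg$on_amplitude_hz,
             factor = factor,
             modulated_hz = cfg$on_amplitude_hz * factor)
}

# Piecewise firing-rate components for every neuron under a protocol.
# Returns a list per neuron: baseline rate, inhibition intervals, and
# additive components (t0, t1, amplitude) with the shared transient shape.
rate_components <- function(gt, protocol) {
  cfg <- gt$config
  ep <- aligned_epochs(protocol)
  comps <- lapply(gt$neuron_ids, function(id) {
    add <- list(); inhiv <- NULL
    for (k in seq_len(nrow(ep))) {
      o <- ep$odor[k]
      amp <- cfg$on_amplitude_hz
      if (k > 1) {   # cross-talk from the immediately preceding epoch
        m <- apply_history_modulation(gt, c(ep$odor[k - 1], o))
        j <- match(id, m$neuron_id)
        if (!is.na(j)) amp <- cfg$on_amplitude_hz * m$factor[j]
      }
      if (id %in% gt$on[[o]])
        add[[length(add) + 1]] <- c(ep$onset_s[k], ep$offset_s[k], amp)
      if (id %in% gt$off[[o]])
        add[[length(add) + 1]] <- c(ep$offset_s[k] + cfg$off_delay_s,
                                    ep$offset_s[k] + cfg$off_delay_s +
                                      cfg$off_duration_s,
                                    cfg$off_amplitude_hz)
      if (id %in% gt$inhibited[[o]])
        inhiv <- rbind(inhiv, c(ep$onset_s[k], ep$offset_s[k]))
    }
    list(baseline = unname(gt$baseline_hz[id]), add = add, inh = inhiv)
  })
  names(comps) <- gt$neuron_ids
  comps
}

# Evaluate one neuron's rate (Hz) at times t from its components.
eval_rate <- function(comp, t, cfg) {
  r <- rep(comp$baseline, length(t))
  if (!is.null(comp$inh)) {
    for (k in seq_len(nrow(comp$inh))) {
      sel <- t >= comp$inh[k, 1] & t < comp$inh[k, 2]
      r[sel] <- comp$baseline * cfg$inhibition_depth
    }
  }
  s <- cfg$steady_fraction
  for (a in comp$add) {
    sel <- t >= a[1] & t < a[2]
    if (any(sel))
      r[sel] <- r[sel] + a[3] *
        (s + (1 - s) * exp(-(t[sel] - a[1]) / cfg$transient_duration_s))
  }
  r
}

#' Simulate spike trains for a protocol
#'
#' Draws inhomogeneous-Poisson spike trains for every neuron and trial by
#' thinning: the piecewise rate is the spontaneous baseline, plus an ON
#' component during each pulse the neuron responds to (peak `on_amplitude`
#' decaying exponentially toward `steady_fraction` of peak with time
#' constant `transient_duration_s`), plus an OFF component in the 4 s window
#' starting 500 ms after a pulse the neuron is OFF-tuned to; inhibited
#' neurons drop to `inhibition_depth` of baseline during the pulse. Target
#' epochs inherit the [apply_history_modulation()] cross-talk from the
#' immediately preceding epoch.
#'
#' @param config a [generator_config()].
#' @param protocol a [stim_protocol()]; its epochs must lie inside `span`.
#' @param gt optional [ground_truth()]; when `NULL`, [sample_tuning()] is
#'   run on the protocol's odors first.
#' @param span simulated time range (seconds, alignment-relative); defaults
#'   to 2.5 s before the first onset through 5 s after the last offset so
#'   the pre-stimulus and OFF windows are always covered.
#' @param seed seed (defaults to `config$seed`); identical seeds give
#'   identical rasters.
#' @return list with elements `raster` (a [spike_raster()]) and `truth`
#'   (the [ground_truth()] used).
#' @export
simulate_trials <- function(config, protocol, gt = NULL, span = NULL,
                            seed = config$seed) {
  stopifnot(inherits(config, "generator_config"),
            inherits(protocol, "stim_protocol"))
  set.seed(seed)
  ep <- aligned_epochs(protocol)
  if (is.null(span))
    span <- c(min(ep$onset_s) - 2.5, max(ep$offset_s) + 5)
  if (min(ep$onset_s) < span[1] || max(ep$offset_s) > span[2])
    stop("protocol epochs must lie within the simulated span")
  if (is.null(gt)) {
    gt <- sample_tuning(config, unique(ep$odor), seed = seed)
  } else {
    stopifnot(inherits(gt, "ground_truth"))
    if (!all(unique(ep$odor) %in% gt$odors))
      stop("ground truth lacks tuning for some protocol odors")
  }
  comps <- rate_components(gt, protocol)
  n_trials <- protocol$trial_count
  dur <- span[2] - span[1]
  res <- vector("list", length(gt$neuron_ids))
  for (i in seq_along(gt$neuron_ids)) {
    comp <- comps[[i]]
    rmax <- comp$baseline + sum(vapply(comp$add, `[`, 0, 3))
    if (rmax <= 0) { res[[i]] <- NULL; next }
    n_cand <- stats::rpois(n_trials, rmax * dur)
    tot <- sum(n_cand)
    if (tot == 0) next
    tt <- span[1] + stats::runif(tot) * dur
    keep <- stats::runif(tot) < eval_rate(comp, tt, config) / rmax
    tr <- rep(seq_len(n_trials), n_cand)[keep]
    tt <- tt[keep]
    if (!length(tt)) next
    o <- order(tr, tt)
    res[[i]] <- data.frame(neuron_id = gt$neuron_ids[i],
                           trial = tr[o], spike_time_s = tt[o])
  }
  sp <- do.call(rbind, res)
  if (is.null(sp))
    sp <- data.frame(neuron_id = character(), trial = integer(),
                     spike_time_s = numeric())
  list(raster = spike_raster(sp, neuron_ids = gt$neuron_ids,
                             n_trials = n_trials),
       truth = gt)
}

#' Simulate a palp-opening trace for a protocol
#'
#' Emulates the behavioral readout: a smooth non-negative palp-distance
#' trace that rises after the final (target) epoch's onset whenever the
#' presented odor's ON set overlaps the trained odor's ON set by at least
#' `por_overlap_threshold`, with amplitude scaling linearly with the
#' overlap fraction, plus seeded Gaussian observation noise.
#'
#' @param gt a [ground_truth()] containing the trained odor.
#' @param trained_odor label of the conditioned stimulus.
#' @param protocol a [stim_protocol()]; the last epoch is taken as the
#'   evaluated presentation.
#' @param span time range of the trace; defaults as in [simulate_trials()].
#' @param dt_s sample interval (default 0.05 s, the decoder bin grid).
#' @param seed seed for the observation noise.
#' @param subject,trial identifiers stored on the trace.
#' @return a [por_trace()].
#' @export
simulate_por <- function(gt, trained_odor, protocol, span = NULL,
                         dt_s = 0.05, seed = gt$config$seed,
                         subject = "sim", trial = 1L) {
  stopifnot(inherits(gt, "ground_truth"))
  if (!trained_odor %in% gt$odors) stop("trained odor not in ground truth")
  cfg <- gt$config
  set.seed(seed)
  ep <- aligned_epochs(protocol)
  if (is.null(span))
    span <- c(min(ep$onset_s) - 2.5, max(ep$offset_s) + 5)
  last <- nrow(ep)
  presented <- ep$odor[last]
  ov <- length(intersect(gt$on[[presented]], gt$on[[trained_odor]])) /
    max(1L, length(gt$on[[trained_odor]]))
  amp <- if (ov >= cfg$por_overlap_threshold) cfg$por_max * ov else 0
  t <- seq(span[1], span[2] - dt_s / 2, by = dt_s)
  y <- numeric(length(t))
  on <- ep$onset_s[last]; off <- ep$offset_s[last]
  rise <- t >= on & t < off
  y[rise] <- amp * (1 - exp(-(t[rise] - on) / cfg$por_tau_s))
  plateau_val <- amp * (1 - exp(-(off - on) / cfg$por_tau_s))
  # palps stay open through the OFF delay, then the OFF ensemble drives
  # a closure faster than the opening dynamics
  close_t <- off + cfg$off_delay_s
  hold <- t >= off & t < close_t
  y[hold] <- plateau_val
  after <- t >= close_t
  y[after] <- plateau_val * exp(-(t[after] - close_t) / cfg$por_close_tau_s)
  y <- pmax(0, y + stats::rnorm(length(t), sd = cfg$por_noise_sd))
  por_trace(data.frame(time_s = t, distance = y),
            subject = subject, trial = trial,
            condition = paste(ep$odor, collapse = "-"))
}

#' Write the latent structure of a simulation as JSON
#'
#' Serializes tuning sets, baseline rates and cross-talk factors so tests
#' and reports can audit a run against its generator.
#'
#' @param gt a [ground_truth()].
#' @param path output path (conventionally `ground_truth.json`).
#' @export
write_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "ground_truth"))
  jsonlite::write_json(
    list(neuron_ids = gt$neuron_ids, odors = gt$odors,
         on = gt$on, off = gt$off, inhibited = gt$inhibited,
         baseline_hz = as.list(gt$baseline_hz),
         rho_sup = gt$config$rho_sup, rho_enh = gt$config$rho_enh),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
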