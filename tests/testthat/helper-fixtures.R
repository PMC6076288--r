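# Shared fixture builders. Everything is generated in code; no data files.

# Strip class and metadata attributes, keeping only dim: for comparing
# the numeric content of tensors/matrices.
bare <- function(x) {
  y <- unclass(x)
  attributes(y) <- attributes(y)["dim"]
  y
}

# Tiny deterministic raster: one neuron, one trial.
tiny_raster <- function(times = c(0.010, 0.020, 0.060), id = "a",
                        trial = 1L) {
  spike_raster(data.frame(neuron_id = id, trial = trial,
                          spike_time_s = times))
}

# Random raster for property tests (homogeneous Poisson per neuron/trial).
random_raster <- function(n_neurons = 4, n_trials = 3, rate = 20,
                          t_range = c(-1, 2), seed = 1) {
  set.seed(seed)
  rows <- list()
  ids <- sprintf("n%02d", seq_len(n_neurons))
  for (id in ids) for (tr in seq_len(n_trials)) {
    n <- stats::rpois(1, rate * diff(t_range))
    if (n > 0)
      rows[[length(rows) + 1]] <- data.frame(
        neuron_id = id, trial = tr,
        spike_time_s = sort(stats::runif(n, t_range[1], t_range[2])))
  }
  spike_raster(do.call(rbind, rows), neuron_ids = ids, n_trials = n_trials)
}

# Hand-built binned tensor from a neuron x trial x bin array.
make_tensor <- function(counts, bin_width = 0.05, window_start = -2) {
  n_bins <- dim(counts)[3]
  if (is.null(dimnames(counts)[[1]]))
    dimnames(counts) <- list(sprintf("n%02d", seq_len(dim(counts)[1])),
                             NULL, NULL)
  structure(counts, class = "binned_tensor",
            bin_width = bin_width,
            window = c(window_start, window_start + n_bins * bin_width),
            bin_starts = window_start + bin_width * (seq_len(n_bins) - 1))
}

# Hand-built response matrix.
make_rm <- function(values, bin_width = 0.05, window_start = 0) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("n%02d", seq_len(nrow(values)))
  structure(values, class = c("response_matrix", "matrix"),
            provenance = list(),
            bin_starts = window_start + bin_width * (seq_len(ncol(values)) - 1),
            bin_width = bin_width)
}

pn_ids <- function(n) sprintf("pn%03d", seq_len(n))

# Controlled world for the OR-of-ANDs robustness scenario: the target's ON
# set has n_on neurons; each of n_hist distractors shares a distinct block
# of `silenced_per_history` target-ON neurons (rho_sup = 0 silences them),
# so jointly they cover the whole ON set and the consistent-and-unique set
# is empty, while any single history leaves n_on - silenced_per_history
# template neurons live.
flex_world <- function(n_neurons = 85, n_on = 20, n_hist = 5,
                       silenced_per_history = 4, on_amplitude = 60,
                       seed = 1) {
  stopifnot(n_hist * silenced_per_history == n_on)
  ids <- pn_ids(n_neurons)
  cfg <- generator_config(n_neurons = n_neurons,
                          on_amplitude_hz = on_amplitude,
                          rho_sup = 0, rho_enh = 1.5, seed = seed)
  target_on <- ids[seq_len(n_on)]
  dists <- sprintf("d%d", seq_len(n_hist))
  on <- list(tgt = target_on)
  off <- list(tgt = ids[(n_on + 1):(n_on + 10)])
  inh <- list(tgt = character())
  extra <- n_on + 10
  for (k in seq_len(n_hist)) {
    block <- target_on[((k - 1) * silenced_per_history + 1):
                         (k * silenced_per_history)]
    own <- ids[(extra + 1):(extra + 6)]; extra <- extra + 6
    on[[dists[k]]] <- c(block, own)
    off[[dists[k]]] <- character()
    inh[[dists[k]]] <- character()
  }
  set.seed(seed)
  base <- stats::setNames(stats::rgamma(n_neurons, 4, scale = 0.75), ids)
  list(gt = ground_truth(on, off, inh, base, cfg), cfg = cfg,
       target = "tgt", distractors = dists)
}

# Controlled world for the ON-OFF cancellation scenario: trained odor "cs"
# with disjoint ON (A) and OFF (B) ensembles; distractor "amb" activates
# large parts of both A and B during its own presentation (the
# apple-like case: the OFF pattern match at least balances the ON match,
# so opening and closing drives cancel); distractor "fpo" activates part
# of A only (false-positive POR).
onoff_world <- function(n_neurons = 85, n_set = 20, n_match_on = 13,
                        n_match_off = 20, on_amplitude = 60, seed = 1) {
  ids <- pn_ids(n_neurons)
  A <- ids[seq_len(n_set)]
  B <- ids[(n_set + 1):(2 * n_set)]
  cfg <- generator_config(n_neurons = n_neurons,
                          on_amplitude_hz = on_amplitude,
                          rho_sup = 1, rho_enh = 1, seed = seed)
  on <- list(cs = A,
             amb = c(A[seq_len(n_match_on)], B[seq_len(n_match_off)]),
             fpo = A[seq_len(n_match_on)])
  off <- list(cs = B, amb = character(), fpo = character())
  inh <- list(cs = character(), amb = character(), fpo = character())
  set.seed(seed)
  base <- stats::setNames(stats::rgamma(n_neurons, 4, scale = 0.75), ids)
  list(gt = ground_truth(on, off, inh, base, cfg), cfg = cfg)
}

# Condition tensors for one distractor/target pair under a shared tuning.
simulate_pair <- function(cfg, gt, distractor, target, seed) {
  sD <- simulate_trials(cfg, solitary_protocol(distractor), gt = gt,
                        seed = seed)
  sT <- simulate_trials(cfg, solitary_protocol(target), gt = gt,
                        seed = seed + 1L)
  sQ <- simulate_trials(cfg, sequence_protocol(distractor, target),
                        gt = gt, seed = seed + 2L)
  list(D = bin_spikes(sD$raster, 0.05, c(-2.5, 9)),
       T = bin_spikes(sT$raster, 0.05, c(-2.5, 9)),
       S = bin_spikes(sQ$raster, 0.05, c(-7, 9)))
}
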