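---
title: "Models, parameters and numerical conventions in flexdecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and numerical conventions in flexdecode}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexdecode)
```

## The problem

Locust antennal-lobe projection neurons (PNs) encode odor identity in
which neurons fire and when. When the same target odor arrives after
different distractor odors (two non-overlapping 4 s pulses separated by
500 ms), the target-evoked ensemble response changes with that history:
shared responders are suppressed, previously inhibited neurons are
enhanced. The population response decorrelates from the preceding
stimulus — a temporal contrast-enhancement computation — at the cost of
response stability: across all histories there may be *no* neuron that
responds consistently and uniquely to the target. `flexdecode`
implements the analysis chain that quantifies this trade-off and the
decoding schemes that resolve it: an optimal linear (SVM) reference
decoder, a one-parameter flexible m-of-n (OR-of-ANDs) template decoder,
and an ON–OFF extension that maps classifier outputs onto the
palp-opening response (POR), the appetitive behavioral readout.

## Data model and conventions

Spike times are seconds relative to a protocol's alignment epoch (t = 0
at the target onset for target analyses, at the distractor onset for
distractor analyses). Counting uses half-open bins `[left, right)` of
50 ms: a spike exactly at the window end is excluded, which makes "4 s
of activity" an unambiguous 80 bins. Neuron order is fixed once, as the
lexicographic order of neuron ids, so barcodes and weight vectors remain
comparable across stages. The trial-averaged neuron x bin matrix is the
unit every downstream analysis consumes; each of its columns is the
population vector `x(t)` of one bin.

Bin-edge assignment is a genuine convention choice (no rule is implied
by the data): we chose left-closed bins and state it rather than infer
it.

## The synthetic world

No recordings are distributed with the analyses this package implements,
so a seeded generator stands in for them, with its latent structure
exported as ground truth. Its defaults are the stated conditions of the
emulated experiments; where only qualitative statements exist, one
realistic value was chosen and is fixed:

| parameter | default | rationale |
|---|---|---|
| `n_neurons`, `n_trials` | 85, 10 | recorded ensemble size and trial blocks |
| `baseline_mean_hz` (gamma, shape 4) | 3 Hz | typical PN spontaneous rates, right-skewed across cells |
| `responsive_fraction` | 0.30 | per-odor ON set (26 of 85); a config value, not a measured one |
| `inhibited_fraction`, `inhibition_depth` | 0.10, 0.2 | "reduced below baseline" made concrete |
| `on_amplitude_hz` | 20 Hz | evoked peak above baseline; ~4x the per-bin baseline s.d. at defaults |
| `transient_duration_s`, `steady_fraction` | 1.25 s, 0.5 | fast transient (~1–1.5 s) decaying exponentially to a steady state |
| `off_fraction`, `off_overlap_with_on` | 0.25, 0.05 | OFF ensemble active 0.5–4.5 s after offset, nearly disjoint from ON |
| `rho_sup`, `rho_enh` | 0.4, 1.5 | history cross-talk factors on shared / previously inhibited responders |

Spiking is inhomogeneous Poisson, sampled exactly by thinning against a
per-neuron rate bound; the Poisson choice is ours (no distributional
claim is inherited). The bounds `rho_sup` in [0, 1] and `rho_enh` >= 1
admit the identity limit (`rho_sup = rho_enh = 1` reproduces the
solitary response), which doubles as a control condition in tests.

The POR trace rises exponentially (tau = 0.5 s) after the target onset
when the presented odor's ON set overlaps the trained odor's ON set
(linear amplitude scaling above an overlap threshold of 0.15), holds
through the 500 ms OFF delay, then closes with a faster time constant
(0.15 s). The fast, delayed closure encodes the modeled biology — palp
closing is actively driven by the stimulus OFF ensemble — and it is what
makes the ON–OFF output stage identifiable from solitary data alone: if
the trace decayed at the passive filter rate, the fit could ignore the
OFF channel entirely.

What a green test does **not** establish: the generator has no LN/PN
circuit dynamics, no odor-specific temporal patterning beyond the shared
transient, no trial-order (adaptation) effects, and statistically
homogeneous amplitudes across neurons. Recovery and decoding results on
this world validate the pipeline's logic, not the biology.

## Response characterization

A neuron is a responder when any bin of its trial-averaged PSTH in the
stimulus window exceeds `mean + 6.5 s.d.` of its trial-averaged
pre-stimulus PSTH (the 2 s window just before the first stimulus, 40
bins). Computing the pre-stimulus statistics from the trial-averaged
(not per-trial) PSTH matches the trial-averaged test quantity and is
stable at 10 trials. A silent neuron has zero pre-stimulus s.d.; its
threshold becomes `mean + 1/n_trials`, so at least two evoked spikes
across trials in one bin are required — raising `k_sd` never adds
responders (a tested monotonicity property).

Latency is the start time of the first qualifying bin. In sequential
mode the first difference of the PSTH must also be positive, because the
target arrives on the decaying tail of the distractor response; both the
derivative condition and the 6.5 s.d. criterion are enforced (the
sources leave their conjunction ambiguous; we chose the stricter
reading). "Early" means latency strictly below 600 ms: a latency of
exactly 600 ms is late. The pre-stimulus window for sequences precedes
the *whole* sequence, not the target.

## Ensemble geometry

PCA treats every 50 ms population vector of the concatenated conditions
as an observation; the covariance is mean-centered over all concatenated
bins (centering is the standard convention; the sources do not state
it). Projections onto the top three eigenvectors are, per condition,
first-bin baseline subtracted and then smoothed with a three-point
moving average whose end windows shrink so the point count is preserved.
Eigenvector sign is fixed by making the largest-magnitude component
positive. LDA maximizes between- over within-class scatter; with 85
neurons and few bins per class the within-class scatter can be singular
and is ridge-regularized by `1e-6 * trace / n` on the diagonal.

Ensemble correlations are Pearson (the sources say only "correlation"),
computed between per-neuron mean counts over the first 1 s after each
condition's onset — per trial, pairing trials by index, with the
trial-averaged vectors giving the summary value. The per-trial variant
compares trial `k` of one condition with trial `k` of the other; an
alternative (each trial against the other condition's trial average) was
considered and rejected as statistically dependent across trials. The
contrast test is a two-sided paired t-test on those per-trial
correlations; degenerate inputs are resolved explicitly (identical
samples give p = 1, a constant non-zero difference gives the smallest
representable p).

## Decoders

The SVM is the textbook soft-margin primal at box constraint `C = 0.01`,
solved in the dual by sequential minimal optimization with second-order
working-set selection (compiled; deterministic for a fixed row order;
stopping at dual gap 1e-8). First-order (maximal-violating-pair)
selection stalls on integer count data, which is why the second-order
rule is used. A decision score of exactly zero is classified "absent":
presence requires positive evidence. The negative class composition is
unspecified in the sources; the default is all solitary-distractor
stimulus bins plus the pre-stimulus bins of every solitary condition,
and it is configurable.

The flexible decoder's weights are the solitary-target responder
barcode. The analog threshold default is `tau = (m/n) * mean(v'x)` over
solitary-target stimulus bins, exposing `m` (equivalently `tau`) as the
single tunable. The digital variant binarizes `x(t)` with the same
per-neuron 6.5 s.d. thresholds as the responder criterion — the sources
define the digital decoder but not its binarization rule, so reusing
the responder criterion is our choice. At the default 20 Hz amplitude
this front-end marks mainly transient bins active (steady-state bins sit
below `mean + 6.5 s.d.`), so digital classification probabilities are
transient-weighted; with stronger responders (40–60 Hz) the whole 4 s
window qualifies.

The confusion matrix uses leave-one-trial-out nearest-centroid
classification. Feature and distance are unstated in the sources; we use
the per-trial mean population vector over the first 1 s (the same window
as the correlation analyses) and Euclidean distance, with ties broken
toward the first class in sorted label order.

## The ON–OFF behavioral model

`V_ON` and `V_OFF` are the responder barcodes of the stimulus window and
of the OFF window (4 s starting 500 ms after offset); their Jaccard
overlap is reported and is near zero by construction of the world. Two
digital flexible decoders produce per-bin classification probabilities
`p_ON`, `p_OFF`, and the output stage is

    drive(t) = gain * (max(0, p_ON(t) - theta_ON) - max(0, p_OFF(t) - theta_OFF))

followed by a causal first-order low-pass (default tau 0.5 s) and
rectification at zero. This rectified-difference-plus-filter form is the
minimal causal model that yields graded openings, active closings, and
exact cancellation when both templates match — the "thresholded and
scaled" output stage is under-specified in the sources, and this is our
reading, recorded as a design choice. Parameters are fit by
deterministic grid search (gain: 20 log-spaced multiples of the observed
peak from 0.5x to 50x; thresholds 0 to 0.95 in steps of 0.05; tau in
{0.1, 0.25, 0.5, 1} s) against the mean solitary trained-odor POR only;
sequential data never enter the fit, and ties go to the first lattice
point in enumeration order. Because the gain lattice is peak-relative,
exact parameter recovery is only defined for truths placed on the
realizable lattice; the test suite constructs such a truth by
root-finding.

A distractor matching both templates drives `p_ON` and `p_OFF`
together, and the two rectified terms cancel (up to the fitted threshold
gap); a distractor matching only the ON template produces a graded false
positive — the behavior the paired decoder exists to explain.

## Reproducibility and limits

Every stochastic step takes an explicit seed; `run_pipeline()` derives
per-condition seeds from the run seed, and identical config + seed give
byte-identical CSV/JSON outputs. Known limitations: the SMO solver's
1e-8 gap target can require many iterations on large ill-conditioned
training sets (a warning reports the achieved gap); the digital
binarization makes steady-state bins invisible at low amplitudes (above);
and all acceptance-style results are statements about the stated
synthetic world, at desk scale, not reanalyses of the original
recordings.
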