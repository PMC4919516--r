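---
title: "Methods: stimulus-response tuning analysis for AOB single units"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stimulus-response tuning analysis for AOB single units}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`aobtune` implements the single-unit analysis chain used to characterise
chemosensory tuning of accessory olfactory bulb (AOB) mitral cells recorded
during vomeronasal stimulation: firing-rate responses and their significance,
per-cell tuning curves and population overlap summaries, consensus clustering
of tuning curves, and a d′ discriminability statistic with a
shuffled-population significance test. Because raw recordings of this kind
are rarely public, the package ships a spike-train simulator with planted
ground truth, so every stage of the chain can be validated by parameter
recovery rather than by eye.

## The data model

A *session* couples one or more sorted spike trains (spike times in seconds
from session start) with a trial table (stimulus id, onset, offset, repeat
index) and a stimulus panel that designates exactly one solvent control
(Ringer's solution in the experiments this models). Stimulus epochs last
3–5 s and are delivered interleaved — each stimulus once per block, block
order randomised — with at least three repeats per stimulus. Sessions are
stored as plain-text directories (`spikes.csv`, `trials.csv`, `cells.csv`,
`panel.json`, `meta.json`); numbers are written at 17 significant digits so
`read_session(write_session(s))` is the identity. The three-repeat minimum
is enforced at analysis time, not at load time, so partial sessions remain
inspectable.

## Response quantification

All windows are onset-relative and counted half-open `[a, b)`:

* **response window**: 1 s to 5 s after onset (4 s; the 1 s delay lets the
  stimulus line's dead volume clear),
* **baseline window**: the 5 s before onset,
* **peristimulus window**: −5 s to +15 s in 1 s bins (20 bins).

The change in firing rate is
ΔR = (response-window count)/4 s − (baseline-window count)/5 s.
The published definition fixes the 4 s response window but leaves the
baseline extent as "before stimulus delivery"; we adopt 5 s, matching the
pre-stimulus extent of the displayed PSTHs, and expose it in
`analysis_windows()`.

A cell × stimulus pair is *significant* iff both hold:

1. a two-sample Student's t-test (classical equal-variance form, as named;
   Welch available via `var_equal = FALSE`) of the per-trial ΔR values
   against the control-stimulus trials gives *P* < 0.05, and
2. the mean rate increase exceeds 1 Hz.

Two readings of the 1 Hz criterion are defensible — mean ΔR > 1 Hz, or the
absolute response-window rate > 1 Hz. Both are implemented
(`rate_criterion = "delta_r"` / `"absolute"`); the ΔR reading is the default
as the most literal rendering of a rate *increase*. Likewise the t-test
compares per-trial ΔR distributions (rather than raw window rates) by
default. No multiple-testing correction is applied across stimuli — the
procedure mirrors a fixed per-comparison threshold.

**Control responsiveness.** A two-sample test of control against itself can
never fire, yet control-responsive cells must be discarded. We therefore
call the control with a separate one-sample rule: one-sample t-test of the
control ΔR trials against 0 at *P* < 0.05, plus mean control ΔR > 1 Hz. A
cell is *included* iff it has ≥ 1 significant non-control stimulus, a
non-significant control, and ≥ 3 complete trials for every tested stimulus.

Each included cell's mean-ΔR vector over non-control stimuli is normalized
by its maximum **absolute** entry, so the strongest response maps to ±1 and
inhibitory responses cannot exceed unit magnitude. The control is excluded
from the maximum.

## Population summaries

`classify_tuning()` partitions cells by named stimulus sets (exclusive to
one set, responsive to a combination, or "other" — included cells responding
to neither). Percentages are printed to one decimal using
round-half-away-from-zero, matching the reporting style of the source
experiments. `overlap_venn()` counts response-pattern regions among cells
responding to at least one of 2–3 stimuli, and `pairwise_overlap()` reports
100 · |responders to both| / |responders to the row stimulus|, with
zero-responder rows reported as missing rather than 0.

## Consensus clustering and its numerical choices

Tuning curves are clustered in two stages. First, many non-deterministic
base clusterings build a co-assignment *similarity matrix*: each of
`n_runs` (default 500; ≥ 100 recommended) runs clusters a random 80%
subsample of the cells by k-means with random initialisation and k drawn
uniformly from `k_range` (default 2–12, additionally capped at max(2, n/4)
and at the number of distinct rows); similarity(i, j) is the fraction of
co-sampled runs that co-assign i and j. Second, the rows of the similarity
matrix are clustered by flat-kernel mean shift, and the resulting labels
(1-based, ordered by decreasing cluster size) are the final partition.

Two choices here deserve justification:

* **Subsampling and the k cap.** k-means is nearly deterministic given the
  data, so repeated full-sample runs resolve the *same* noise-level splits
  and depress within-cluster co-assignment; at small n, k values far above
  the true cluster count shatter the similarity structure entirely. The 80%
  subsample is the standard consensus-clustering perturbation (Monti et al.
  2003, *Machine Learning* 52:91–118), and capping k at n/4 keeps base
  clusters at a handful of cells. With both in place, planted archetypes
  (2 groups of 10; 4 groups of 15) are recovered at adjusted Rand index 1.
* **Mean-shift bandwidth.** Consensus similarity rows have a strongly
  bimodal pairwise-distance distribution — small within clusters, large
  between. A fixed-quantile k-NN bandwidth (the common default, quantile
  0.3) exceeds the between-cluster separation whenever clusters hold fewer
  than 30% of the cells, merging everything. The default here
  (`estimate_bandwidth(method = "gap")`) instead places the bandwidth at
  the midpoint of the largest gap in the central 90% of the sorted pairwise
  distances, which adapts to the actual cluster granularity; the quantile
  heuristic remains available via `bandwidth_method = "quantile"`.

Degenerate inputs are defined: fewer than 2 cells returns a single cluster
with a warning; identical rows give similarity ≡ 1 and one cluster; a zero
bandwidth (all points coincident) yields one cluster. Everything is
deterministic given `seed`.

`mds_embed()` displays the similarity structure by nonmetric
(Kruskal) MDS on the dissimilarity 1 − similarity in 3 dimensions
(`MASS::isoMDS`, initialised from classical scaling), reporting the stress.
Zero off-diagonal dissimilarities are lifted to 1e−8 (isoMDS rejects exact
zeros); an all-equal dissimilarity matrix returns a zero-spread embedding
with a warning.

## Discriminability

For one cell and two stimuli with per-trial responses,
d′ = |ΔR̄₁ − ΔR̄₂| / √((σ₁² + σ₂²)/2), with sample variances (n − 1).
The absolute value makes d′ non-negative and argument-symmetric. Both
variances zero with equal means gives 0; with unequal means, d′ is
undefined and an error.

The population shuffle test asks whether the observed d′ distribution
reflects systematic discrimination: each of `n_model` (default 100,000;
10⁴ is ample for calibration checks) model populations pairs, for every
model cell, one cell's stimulus-1 responses with an *independently* chosen
cell's stimulus-2 responses (with replacement), destroying the within-cell
pairing while preserving the marginals. Model and observed d′ distributions
are compared by a tie-corrected two-group Kruskal–Wallis test; a model
population counts as *statistically lower* when *P* < 0.05 **and** its
median d′ is below the observed median (the one-sided reading of "lower").
The reported statistic is the fraction of such model populations.

The published description assigns single "normalized ΔR values" to model
cells, but a per-model-cell d′ needs a variance. We resample whole per-cell
trial sets by default (`mode = "trial_sets"`), the only reading under which
the model d′ is directly computable with each donor's across-trial variance
intact; `mode = "values"` implements the literal value-level reading by
rebuilding trial sets from value pools across cells. Whether d′ is fed
normalized or raw ΔR is equally unstated in the source; `trial_sets()`
defaults to normalized (per-cell max |mean ΔR| scaling, as in the shuffle
description) with `normalized = FALSE` available. The internal two-group
Kruskal–Wallis statistic is algebraically the standard one (the test suite
cross-checks it against `stats::kruskal.test` to 1e−10).

## The synthetic-data generator

`simulate_session()` draws spikes from a piecewise-constant-rate Poisson
process: baseline rate λ₀ per cell (default drawn uniformly from 0.5–3 Hz,
the sparse spontaneous regime typical of AOB mitral cells), elevated by
Δ(cell, stimulus) Hz inside the 4 s response window of each event.
Across-trial variability is a unit-mean log-normal factor on Δ (log-sd 0.2
by default — unreported in the source recordings, so a free parameter of
the generator, exposed in the config). Negative post-jitter rates (possible
for inhibitory Δ) are clipped to 0 and counted. The control stimulus never
carries a planted effect — the analysis layer must nonetheless *handle*
control responders, and the one-sample control rule is exercised by chance
false positives. Defaults: 5 trials per stimulus, 4 s epochs, 20 s between
onsets (room for the full peristimulus window).

The generator emulates exactly what the downstream statistics consume —
window rates with trial-to-trial variability under an interleaved design.
It does **not** emulate temporal response shape (onset transients,
adaptation), spike-sorting artefacts, baseline drift, or correlated noise
across cells. Passing recovery tests therefore validates the statistical
machinery, not robustness to those real-data features.

## Test and validation sizes

The suite validates each operation against independent brute-force oracles
(naive window counting, explicit-moment d′, set-intersection overlap) on
100 random instances each, and runs the full chain at the following sizes,
chosen to give stable Monte-Carlo estimates while keeping the suite quick:
caller calibration and power on 200-cell sessions (type-I rate compatible
with ≤ 0.05; power ≥ 0.99 at Δ = 10 Hz over λ₀ = 2 Hz); shuffle-test
calibration at 10⁴ model populations on 200-cell populations (null fraction
≪ 0.05, monotone in planted selectivity 0/2/5/10 Hz); archetype recovery on
60 cells × 4 archetypes at Δ = 8 Hz over 20 seeds (median adjusted Rand
index 1). `scripts/acceptance.R` recomputes all of these from scratch.

## Known limitations

* The exact base clusterer and the "modified" element of the original
  mean-shift consensus procedure are unpublished; this implementation fixes
  a fully specified, validated variant but makes no claim of reproducing
  the original cluster counts on the recorded populations.
* The published population shuffle fractions (e.g. 98.9% for urine vs
  faeces) depend on the unavailable recorded data; the package substitutes
  calibration and monotonicity guarantees on synthetic populations.
* The baseline-window length (5 s) and the control-responsiveness rule are
  package conventions where the source is silent; both are configurable.
* Percentages are rounded half-away-from-zero to one decimal; a printed
  source value that truncates rather than rounds can differ by 0.1.
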