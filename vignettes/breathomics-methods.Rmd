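---
title: "Methods: respiratory waveform analysis and regulatory omics integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: respiratory waveform analysis and regulatory omics integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathomics)
```

breathomics implements the quantitative backbone of a transcription-factor
dosage study in the developing lung: respiratory phenotyping of neonatal
mice by head-out pneumotachography, microarray-style differential
expression in gain- and loss-of-function models, and triangulation of
direct regulatory targets by ChIP-seq peak-to-gene assignment. This
vignette documents the models, the parameters that matter, the numerical
choices, and what the synthetic-data validation does and does not show.

## Pneumotachography model and signal processing

A head-out pneumotachograph measures airflow at the snout as a pressure
signal (mV). Integrating the flow yields a relative volume waveform whose
per-breath peak height, compared against known-volume injections, gives
tidal volume:

* $V_f$ — respiratory rate, $60 \cdot n_\text{breaths} / t$ (breaths/min),
* $V_T$ — tidal volume, mean calibrated breath amplitude (µl),
* $V_E = V_f \cdot V_T$ — minute ventilation (µl/min).

`integrate_flow()` computes the cumulative trapezoidal integral and leaves
the raw pressure trace untouched; no filtering or smoothing is applied to
the pressure waveform at any point. Integration, however, accumulates
sensor offset and integrated noise into a slow baseline wander that must be
removed for peak heights to be meaningful.

**Drift correction.** The default baseline estimate is a *rolling low
quantile*: the 10th percentile of the volume waveform per window-eighth
block, followed by a running minimum across one full window (2 s) and
linear interpolation. A rolling median — the textbook choice — is biased
here: at 180 breaths/min with 0.2 s pulses the breath occupies ~60% of any
window, so the median tracks the pulse flanks rather than the baseline, and
it swings across apneas. Empirically the median baseline displaced ~10% of
detected onsets by more than 25 ms; the low-quantile baseline tracks the
true inter-breath baseline regardless of duty cycle. `rolling_median`,
`linear` and `none` remain available; calibration recordings, which are
short and pulse-dominated, use a linear detrend.

**Breath segmentation** (`segment_breaths()`) is hysteresis peak
detection: a breath opens when the volume rises above `hi_frac` (0.5) of
the local amplitude scale after having been below `lo_frac` (0.25), one
breath per excursion, with a 100 ms refractory period. The amplitude scale
and baseline are robust quantiles (1st–99th percentile span) over 10 s
blocks, making detection invariant under uniform gain. Amplitude is peak
minus preceding trough, with ties broken toward the earlier sample. The
onset is placed by extrapolating the upstroke back to baseline: breath
pulses start quadratically, so level-crossing times scale as $\sqrt{c}$;
from the last samples below 5% and 25% of the amplitude the zero crossing
is $t_1 - 0.809\,(t_2 - t_1)$. This estimator is exactly unbiased for the
raised-sine pulse shape and keeps recovered onsets within ±25 ms of truth
at nominal noise, including the wider breaths preceding apneas.

**Analysis windows** (`select_windows()`) implement the data-sufficiency
rules: ventilation summaries use maximal artifact-free runs of ≥ 10 s from
the last 300 s of a condition and are flagged insufficient below 60 s
cumulative; pattern statistics (apneas, variability, Poincaré pairs) use
artifact-free runs anywhere in the condition up to 600 s cumulative, taken
chronologically with the run crossing the cap truncated. An interbreath
interval spanning a window boundary is excluded from pattern statistics.

**Pattern statistics.** An apnea is an IBI *strictly* longer than 1.5 s
(`detect_apneas()`; an IBI of exactly 1.5 s does not qualify). The
variability measure `variability_cv()` defaults to the standard-error
convention $\mathrm{CV} = (\mathrm{SD}/\sqrt{n})/\text{mean}$, because that
is how the instability measure is defined in this analysis tradition's
parenthetical form; the conventional $\mathrm{SD}/\text{mean}$ is available
via `type = "sd"`. Whether the original convention was truly SE-based
cannot be resolved from text alone, so both are first-class. Group
comparisons use the pooled-variance unpaired t-test at $P \le 0.05$ with no
multiple-testing correction across respiratory panels, and genotype ratios
from timed matings use the χ² goodness-of-fit test.

## Differential expression

Expression matrices are log2-scale intensities. The original platform's
bead-level robust-spline normalization and variance-stabilizing transform
require bead-level variance data that only exist inside the array platform;
`normalize_quantile()` (mean-of-order-statistics quantile normalization,
via limma) is this package's documented stand-in, preserving the
statistical shape of the analysis. Fold changes on the linear scale are
realized as $2^{\Delta \log_2}$ with the signed convention
`signed_fold_change()`: $2^{x}$ for $x \ge 0$, $-2^{-x}$ otherwise, so a
threshold of "≥ 1.2 and ≤ −1.2" is natural and no value falls in $(-1,1)$.

`de_test()` applies the pooled two-sample t-test per gene (vectorized, but
identical gene-by-gene to `compare_groups()`), and `bh_fdr()` adjusts
p-values by Benjamini–Hochberg step-up (the FDR procedure is fixed by
decision; the original names none). Genes with zero variance in both groups
and equal means report $t = 0, p = 1$ rather than NaN so gene counts stay
stable. `threshold_filter()` calls a gene deregulated when FDR < 0.05 and
|signed FC| ≥ 1.2 (boundary included).

Two statistical caveats the validation quantifies:

* **BH false-discovery arithmetic.** With ~200 true discoveries among 2000
  genes at FDR 0.05, the expected number of false calls is
  $\approx 0.045 \times 210 \approx 10$ — controlling the *rate*, not an
  absolute handful. Recovery tests therefore assert realized FDR ≤ 0.1
  alongside ≥ 95% sensitivity.
* **Quantile normalization under strong global deregulation.** When 10% of
  genes carry ±2 log2-unit shifts in one group, forcing both groups onto a
  common distribution redistributes the tails and roughly triples the
  false-positive count relative to testing the common-scale data directly.
  This is a known pathology of quantile normalization, not of the test; it
  matters little at the weak-to-moderate effect sizes typical of real
  arrays, but users planting extreme synthetic effects should be aware.

qPCR quantification (`delta_delta_ct()`) is the standard
$2^{-\Delta\Delta C_T}$ double normalization to a reference gene and a
control condition.

## Cross-study integration

`overlap_test()` scores the overlap of two deregulated gene sets by the
one-sided hypergeometric tail $P(X \ge m)$ over a shared gene universe (the
original names no test; hypergeometric is the field default).
`classify_reciprocity()` tallies direction combinations between studies;
reciprocal genes (up in one, down in the other) are the dosage-responsive
signature. `reciprocity_test()` uses an exact one-sided Binomial$(m, 1/2)$
null — each overlap gene equally likely concordant or reciprocal — which is
an assumption, documented as such; the true null behind any published
reciprocity p-value is unstated, so those printed values are not
reproduction targets.

`assign_peaks()` re-implements GREAT-style basal-plus-extension regulatory
domains: each gene owns a strand-aware basal domain (5 kb upstream, 1 kb
downstream of the TSS), extended in both directions to the nearest
neighboring basal domain and capped at 1 Mb beyond the basal edge; a peak
(anchored at its midpoint, since BED3 input carries no summit) is assigned
to every gene whose domain contains the midpoint, with signed distance
negative upstream. Coordinates are 0-based half-open throughout (BED
convention). Two adjacent genes' extended domains both cover the gap
between them, so a mid-gap peak is associated with both — this is the
GREAT behaviour, not a bug. `three_way_intersect()` intersects
peak-associated genes with both deregulated sets, optionally demanding
reciprocal directions.

## The synthetic-data generators

The generators exist so that every downstream stage can be validated
against known ground truth; their defaults *are* the study conditions.

* `sim_breath_trace()`: each breath is a raised-sine volume pulse
  $A_i \sin^2(\pi (t - t_i)/T_i)$ with $T_i = \min(0.6\,\mathrm{IBI}_i,
  0.4\text{ s})$; the emitted flow channel is the analytic derivative plus
  Gaussian noise, so each breath's net flow integral is exactly zero before
  noise and integration recovers the pulses. IBIs are Gamma (mean
  $60/V_f$, CV `ibi_cv`), replaced by Uniform(1.8, 3.0 s) apneas with
  probability `p_apnea` — strictly above the 1.5 s threshold so planted
  apneas are unambiguous. Defaults: 600 s at 1 kHz, 180 breaths/min, 10 µl,
  IBI CV 0.15, 5% apneas, flow noise a tenth of the pulse amplitude.
  Sampling rate and noise characteristics are stated defaults, not inferred
  quantities. Artifacts are high-amplitude broadband bursts exposed via the
  mask. All randomness flows from one seed per call with the caller's RNG
  state restored.
* `sim_expression_pair()`: two case/control studies over a shared
  universe; planted genes shift by ±2 log2 units against 0.5 log2-unit
  sample noise, with a configurable fraction of the shared genes
  reciprocal. The default 3 samples per group mirrors the original array
  design. End-to-end recovery validations run at 10 samples per group: an
  a priori power calculation (pooled t, BH across 2000 genes) gives
  per-gene power ≈ 0.1 at $n = 3$ but ≈ 1 at $n = 10$, and a validation of
  *complete* target recovery is only informative when per-target power is
  ≈ 1. The paper-scale $n = 3$ design simply cannot support near-complete
  recovery claims, which is itself a finding the tests document.
* `sim_peaks_genes()`: genes are placed with ≥ 10 kb TSS spacing
  (stick-breaking placement) inside a gene territory at the chromosome
  start; in-domain peaks are planted strictly inside target genes' basal
  domains (so each maps to exactly its target), and out-of-domain peaks in
  the desert beyond any capped extension, hence unassignable. If the
  genome leaves no desert, generation errors rather than silently
  misplacing peaks.

**What passing tests do not show.** The generators emulate the statistical
skeleton, not the biology: real traces have breath-shape variability,
temperature drift and non-Gaussian artifacts; real arrays have probe
effects, correlated genes and batch structure; real peaks cluster in
enhancers rather than uniformly in basal domains. Recovery at the planted
conditions demonstrates correctness of the computation, not performance on
real recordings.

## Problem sizes and reproducibility

Validation uses 600 s traces at 1 kHz (~1400 breaths), 2000-gene universes
with 20 null replicates for type-I control, $10^5$–$10^6$-draw Monte-Carlo
oracles for the exact tails, and 10 seeded end-to-end triangulation
studies — sizes chosen so the full suite exercises every claim at
meaningful statistical resolution while remaining desk-scale. The pipeline
is deterministic given `pipeline_config()$seed`; `scripts/acceptance.R`
re-runs the whole validation from a single `--seed` and writes the
recomputed quantities as JSON.

## Known limitations

* No temperature/barometric correction of volumes, and no modeling of
  gas-exchange physiology; challenge conditions are epoch labels.
* $V_T$ is the mean breath volume over windows (median not offered); the
  original does not state which was used.
* The reciprocity null and the hypergeometric overlap test are fixed
  choices where the original is silent; published p-values for those
  quantities are therefore not comparable targets.
* Probe-to-gene collapsing, GO enrichment, motif analysis and peak calling
  are out of scope; peaks are consumed pre-thresholded as BED3.
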