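# breathomics

Analysis toolkit for transcription-factor **dosage studies of lung
development**, where a lethal vascular disorder (ACDMPV-like) is probed
from two sides at once: respiratory phenotyping of neonatal mice and
integration of gain-/loss-of-function expression data with ChIP-seq
binding. The package implements three arms behind one pipeline:

1. **Head-out pneumotachography.** A flow trace (mV) is integrated into a
   relative volume waveform, calibrated against 20 µl injections at 3 Hz,
   and segmented into breaths by hysteresis detection. Summaries follow the
   standard definitions — respiratory rate `V_f = 60·n/t`, tidal volume
   `V_T` (mean calibrated peak height, µl), minute ventilation
   `V_E = V_f·V_T` — over artifact-free analysis windows (runs ≥ 10 s,
   ≥ 60 s cumulative from the last 5 min of a condition). Pattern analysis
   counts apneas (interbreath interval strictly > 1.5 s), computes IBI and
   amplitude instability (`CV = SE/mean`, with `SD/mean` as an option) and
   Poincaré pairs.
2. **Differential expression.** Per-gene pooled two-sample t-tests on
   quantile-normalized log2 intensities, Benjamini–Hochberg FDR, and
   signed fold-change thresholds (FDR < 0.05, signed FC ≥ 1.2 or ≤ −1.2),
   plus ΔΔCt qPCR quantification (fold = 2^−ΔΔCt).
3. **Omics integration.** One-sided hypergeometric tests for cross-study
   deregulated-set overlap, exact Binomial(m, ½) tests for an excess of
   reciprocal (dosage-responsive) expression trends, GREAT-style
   basal-plus-extension assignment of ChIP-seq peaks to genes (5 kb/1 kb
   basal, ≤ 1 Mb extension), signed TSS-distance histograms, and the
   three-way intersection that nominates direct regulatory targets.

A synthetic-data module (`sim_breath_trace()`, `sim_expression_pair()`,
`sim_peaks_genes()`) generates every pipeline input with known ground
truth, so each stage is testable without any external download.

## Worked example

```r
library(breathomics)

# simulate a 600 s neonatal recording: 180 breaths/min, 10 ul tidal
# volume, 5% apneas, flow SNR 10
s <- sim_breath_trace(breath_sim_params(seed = 101))
cal    <- calibrate(s$cal_trace)          # 20 ul injections at 3 Hz
series <- segment_breaths(integrate_flow(s$trace))
win    <- select_windows(s$trace, "room_air", "ventilation")
ventilation_summary(series, cal, win)
#> <respiratory_summary>
#>   V_f 136.2 breaths/min, V_T 10.04 ul, V_E 1368 ul/min (n=681)

pat <- pattern_summary(series, select_windows(s$trace, "room_air", "pattern"))
pat$apnea_count / length(pat$ibis_s)      # recovered apnea fraction
#> [1] 0.05090909
```

`V_f` lands at 136/min rather than the nominal 180 because 5% of the
interbreath intervals are apneas of 1.8–3 s — exactly what the planted
ground truth predicts for this window (`s$truth`). The omics arm runs the
same way from simulated studies:

```r
sim <- sim_expression_pair(expr_pair_sim_params(samples_per_group = 10, seed = 5))
pg  <- sim_peaks_genes(peak_sim_params(n_genes = 2000, n_peaks = 40,
                                       fraction_in_domains = 0.5, seed = 6),
                       gene_ids = sim$truth$universe,
                       target_gene_ids = sim$truth$reciprocal_genes[1:8])
rep <- run_pipeline(pipeline_config(),
                    list(expr = list(a = sim$study_a, b = sim$study_b),
                         chip = list(peaks = pg$peaks, genes = pg$genes)))
rep
#> <pipeline_report>
#>   DE study a: 114 up, 120 down
#>   DE study b: 124 up, 111 down
#>   overlap 103 (p=1.13e-42), reciprocal 76 (p=7.23e-07)
#>   peak-gene associations: 20
#>   triangulated genes: 8 (8 reciprocal)
```

All eight planted reciprocal targets carrying peaks in their regulatory
domains are recovered, with no false targets. `write_report_json()` emits
the report deterministically (identical bytes for identical config and
inputs).

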