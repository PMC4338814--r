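# sacmod — saccadic latency modulation analysis

`sacmod` is an R package for studying how cognitive task demand modulates
saccadic latency (SL) in video-oculography, and for asking whether a
*failure* of that modulation can separate patients with schizophrenia from
healthy controls and unaffected first-degree relatives. It is aimed at
oculomotor/psychiatry researchers who need a tested, reproducible
implementation of this analysis — from raw gaze traces to group statistics
and classification — together with a synthetic-cohort generator that
provides ground truth where no raw clinical eye-tracking data are publicly
available.

## What it computes

In a two-task peripheral recognition paradigm (color discrimination =
low demand, Landolt-ring orientation = high demand; targets at ±55°,
80 cm viewing distance, 200 Hz sampling; 96 trials in 3 balanced blocks),
the quantities of interest are:

- **Saccadic latency** per trial: the delay from second-target onset to
  the onset of the first valid saccade toward the target. Saccades are
  detected on the artifact-masked (750 °/s ceiling), 20 ms
  moving-average-smoothed horizontal velocity signal with a dual velocity
  threshold (onset 60 °/s, offset 15 °/s).
- **Saccadic latency difference** per subject,
  `SLD = mean SL(color) − mean SL(landolt)`; positive SLD means the
  higher-demand task sped the saccades up.
- **Group statistics**: percent reduction `100·(SL_c − SL_l)/SL_c`,
  two-sided paired t per group, RMS-pooled Cohen's
  `d = (m_a − m_b)/√((s_a² + s_b²)/2)`, Welch t on SLD between groups,
  Levene variance tests, Wilcoxon rank tests, a mixed-design ANOVA
  (between: group; within: task) on behavioural response times, Pearson
  correlation, χ² independence, and paired-t power from the noncentral t
  distribution.
- **Classification**: Monte Carlo balanced subsampling (13 + 13 subjects
  per iteration) with leave-one-out cross-validated radial-kernel SVMs on
  the two features (SL in each task), reporting mean sensitivity,
  specificity and confusion counts per scheme.

## Worked example

```r
library(sacmod)

cfg <- cohort_config(seed = 42)          # 13 patients, 24 controls, 10 relatives
res <- run_pipeline(cfg, out_dir = "sl_run", iterations = 1000, seed = 42)

round(sapply(res$stats$groups, function(g)
  c(color = g$mean_color, landolt = g$mean_landolt, sld = g$mean_sld,
    p = g$paired_t$p, d = g$cohens_d)), 3)
#>         patient control relative
#> color   229.808 252.252  228.979
#> landolt 213.404 190.417  187.161
#> sld      16.403  61.835   41.818
#> p         0.032   0.001    0.002
#> d         0.261   1.036    1.419

res$classification$P_vs_RC
#> <classification_result> scheme P_vs_RC, 1000 iterations
#>   sensitivity 59.2%, specificity 58.4%, accuracy 58.8%
#>   mean confusion: TP 7.7, FP 5.4, TN 7.6, FN 5.3

res$classification$PR_vs_C
#> <classification_result> scheme PR_vs_C, 1000 iterations
#>   sensitivity 68.3%, specificity 42.9%, accuracy 55.6%
#>   mean confusion: TP 8.9, FP 7.4, TN 5.6, FN 4.1
```

This run simulates the full 47-subject cohort (traces included), detects
every saccade, and recovers the expected pattern: patients show a small
SLD (~16 ms, d ≈ 0.3) while controls and relatives show large ones
(~62 and ~42 ms, d ≈ 1.0–1.4), and classifying patients against the
*merged* relatives/controls pool (`P_vs_RC`, 58.8%) beats merging the
relatives with the patients (`PR_vs_C`, 55.6%) — the ordering that marks
impaired modulation as a state rather than trait feature. 99.7% of the
4512 trials yield a valid latency; `res$qc` itemizes the rest
(anticipatory / wrong direction / none found).

`run_pipeline()` also writes `latencies.tsv`, `qc.tsv`, `stats.json`,
`classification.json` and a `provenance.json` (config hash, seed,
versions) to the output directory; re-running the same config and seed
reproduces them bitwise.

See the vignette (`vignettes/saccadic-latency-modulation.Rmd`) for the
models behind the generator and detector, all tunable parameters with
their defaults and units, and the package's design and calibration
choices.

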