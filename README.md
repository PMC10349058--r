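# cfAneuploidy

Genome-wide aneuploidy scoring of plasma cell-free DNA (cfDNA) from
chromosome-arm read counts, with the biomarker-validation statistics used
to compare the score against circulating tumor cell (CTC) counts and
clinical outcome.

## Who this is for

Liquid-biopsy groups using LINE-1 amplicon shallow sequencing
(mFAST-SeqS) — or any assay producing per-arm read counts of cfDNA — who
want a reproducible, tested implementation of:

* the **aneuploidy score**: per-arm read fractions, Z-scores against a
  healthy-control panel, the genome-wide statistic `S = Σ z_a²`, and the
  score `(S − μ_S)/σ_S` in control-SD units, dichotomized at the
  established cut-off of 5 (inclusive boundary);
* the **marker-comparison layer**: score/CTC cross-tabulation with
  discordance rate, Spearman correlation, Jonckheere–Terpstra trend test,
  Mann–Whitney, 2×2 chi-square;
* the **survival layer**: Kaplan–Meier with complementary-log-log median
  CIs, log-rank (including a 1-df trend version over ordered marker
  strata), and Cox proportional-hazards with a univariable p < 0.1 screen
  followed by backward stepwise selection;
* a **synthetic cohort generator** (Dirichlet-multinomial arm counts
  under a tumor-fraction mixture, tf-linked negative-binomial CTC counts,
  proportional-hazards outcomes) so the full pipeline can be exercised
  and validated without patient data.

The central objects are Bioconductor-style S4: `ArmCounts` /
`ArmFractions` extend `RangedSummarizedExperiment` (arms as genomic
ranges × samples), `ControlPanel` holds the reference calibration
(leave-one-out by default), `AneuploidyResults` the per-sample scores.

## The model in brief

For sample read counts `n_a` over the 41 included arms (all autosomal
arms plus Xp/Xq, excluding the acrocentric short arms 13p/14p/15p/21p/22p
and chromosome Y):

```
f_a = n_a / Σ_b n_b                  per-arm read fraction
z_a = (f_a − μ_a) / σ_a              Z-score vs healthy controls
S   = Σ_a z_a²                       genome-wide statistic
score = (S − μ_S) / σ_S              aneuploidy score, class high iff ≥ 5
```

`μ_S, σ_S` are calibrated leave-one-out across the controls so that
held-out control scores are standardized (mean ≈ 0, SD ≈ 1).

## Worked example

```r
library(cfAneuploidy)

sim <- simulateCohort(simulationConfig(n_controls = 20, n_patients = 6,
                                       seed = 42))
res <- scoreSamples(normalizeToFractions(sim$patients), sim$panel)
res
#> AneuploidyResults for 6 sample(s), 41 arms
#>   score >= 5 (high): 1/6
#>    sample_id   s_value      score score_class
#> 1 patient001 121.37849  4.5291500         low
#> 2 patient002 289.33091 15.1281188        high
#> 3 patient003  91.17311  2.6229801         low
#> 4 patient004  81.81850  2.0326388         low
#> 5 patient005  36.30850 -0.8393595         low
#>   ...
```

`s_value` is each patient's genome-wide sum of squared arm Z-scores and
`score` expresses it in control standard deviations: patient002 deviates
15 control-SDs from healthy plasma (clearly aneuploid, class `high`),
while patient005 is slightly *flatter* than the average control
(negative scores are legal and reported as-is).

The concordance arithmetic on a published 2×2 of dichotomized markers
(cells: both low 73, both high 46, CTC-only high 34, score-only high 21):

```r
concordanceSummary(73, 46, 34, 21)$table
#> Concordance of dichotomized aneuploidy score vs CTC count
#>   both low:        73 (42.0%)
#>   both high:       46 (26.4%)
#>   CTC high only:   34 (19.5%)
#>   score high only: 21 (12.1%)
#>   discordance: 31.6%
```

Real alignments enter through `countReadsPerArm()` (SAM/BAM, leftmost
mapped base, primary non-duplicate alignments only) or pre-computed TSV
count tables through `readCountTable()`. `runPipeline()` orchestrates
simulate/ingest → panel → score → compare → survive from a YAML config
and writes TSV/JSON outputs plus a plain-text report;
`inst/scripts/cfaneuploidy.R` wraps the same functions as shell
sub-commands (`all`, `count`, `panel`, `score`).

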