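---
title: "Genome-wide aneuploidy scoring of cfDNA: models and methods"
author: "cfAneuploidy authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-wide aneuploidy scoring of cfDNA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfAneuploidy)
```

## The problem and the model

Plasma cell-free DNA (cfDNA) of a cancer patient is a mixture of DNA from
normal cells and circulating tumor DNA (ctDNA). Because most solid tumors
are aneuploid, the ctDNA share shifts the relative representation of whole
chromosome arms in the plasma. LINE-1 amplicon shallow sequencing
(mFAST-SeqS) exploits this: ~90,000 single-end reads per sample are
distributed over the genome, counted per chromosome arm, and compared to
healthy controls.

For a sample with per-arm read counts $n_a$, the pipeline computes

1. per-arm read fractions $f_a = n_a / \sum_b n_b$ over the included arm
   set;
2. per-arm Z-scores against the healthy-control panel,
   $z_a = (f_a - \mu_a)/\sigma_a$;
3. the genome-wide statistic $S = \sum_a z_a^2$;
4. the **aneuploidy score** $(S - \mu_S)/\sigma_S$, the number of control
   standard deviations by which the sample's genome-wide deviation
   exceeds that of healthy controls.

The score is dichotomized at the established cut-off of five, with an
inclusive boundary (a score of exactly 5 is *high*). Scores below the
control mean are negative and reported as-is.

The acrocentric short arms 13p, 14p, 15p, 21p and 22p carry too little
LINE-1 signal and are excluded, as is chromosome Y (the assay targets
female patients and controls); 41 arms remain (all other autosomal arms
plus Xp and Xq). Whether the X arms should be dropped for mixed-sex
applications is an open question; a custom arm table can exclude them.

## Arm definitions and read counting

The bundled arm table derives from hg19 cytobands: each p arm runs from
the chromosome start to the centromere gap, each q arm from the gap to
the chromosome end; the gap itself belongs to neither arm since it is
unsequenced. Coordinates are 0-based half-open on disk (BED dialect) and
1-based closed internally (`GRanges`). The genome build is configurable
through `loadArmDefinitions()` because published arm-level analyses do
not depend on fine boundary placement.

Reads are assigned to the arm containing their **leftmost mapped base**.
With 150 bp single-end amplicon reads and arms tens of megabases long,
leftmost-base versus midpoint assignment is immaterial; the leftmost base
is simplest and matches how most per-region counters behave. Secondary,
supplementary, duplicate-flagged and unmapped alignments are never
counted. The default mapping-quality threshold is 0: LINE-1 amplicon
reads are repetitive by design, and a strict MAPQ filter would discard
most of the usable library. Reads on excluded arms, in centromere gaps or
on contigs absent from the arm table go to a per-sample discard tally
that is logged, so the accounting identity *counted + discarded = primary
mapped* always holds.

## The control panel and leave-one-out calibration

The panel stores $\mu_a, \sigma_a$ (per-arm mean and standard deviation
of control fractions, $n-1$ denominator) and $\mu_S, \sigma_S$ (location
and scale of the genome-wide statistic in controls). A subtlety: if each
control's $S$ is computed against a panel that contains the control
itself, the resulting $S$ values are biased low, and patient scores are
inflated. `buildPanel()` therefore defaults to **leave-one-out**
calibration: each control is scored against the panel of the remaining
$n-1$ controls, and $\mu_S, \sigma_S$ are the mean and SD of those
held-out statistics. The plug-in variant (`loo = FALSE`) is retained for
comparison only.

`looControlScores()` makes the calibration check-able: each control is
scored against a panel built entirely without it. For a well-behaved
control set these scores have mean ≈ 0 and SD ≈ 1:

```{r loo}
ctrl <- normalizeToFractions(simulateControls(50, seed = 103))
sc <- looControlScores(ctrl)
round(c(mean = mean(sc), sd = sd(sc)), 3)
```

Panels with any zero per-arm variance fail loudly; no pseudo-variance is
invented, because a floor would silently deflate Z-scores on exactly the
arms where the panel is least informative. At least 3 controls are
required (4 for leave-one-out); realistic panels should be far larger.

## Biomarker-comparison statistics

The validation layer reproduces the conventional marker-comparison
toolkit. Both the aneuploidy score and the CTC count dichotomize at 5
with inclusive boundaries. Choices the literature usually leaves
unstated are fixed as follows:

* **Spearman** correlation mid-ranks ties and uses the t approximation
  for the two-sided p-value.
* **Jonckheere–Terpstra**: ties between groups contribute ½ to the
  statistic; the normal approximation uses the tie-corrected variance
  (no continuity correction); a seeded Monte-Carlo permutation mode is
  available, and refuses to run without a seed so that reported
  p-values are always reproducible. With two groups the test is a
  monotone transform of the Mann–Whitney U.
* **Mann–Whitney** U counts pairs with $x > y$ (ties ½); p-values are by
  exact enumeration when both groups have ≤ 8 untied observations,
  otherwise by tie-corrected normal approximation with continuity
  correction.
* **Chi-square** on the 2×2 concordance table is Pearson's, without the
  Yates correction by default (cohort-sized margins).
* Missing values are excluded pairwise per analysis, with logged
  exclusion counts, which is why denominators may differ between
  analyses of one cohort.

Cell percentages and the discordance rate are reported to one decimal
with standard rounding.

## Survival analysis

Kaplan–Meier estimation, log-rank tests and Cox regression are delegated
to the `survival` package; the trend log-rank and the stepwise procedure
are implemented here.

* **Median survival CI** uses the complementary log-log transform.
* **Log-rank trend** across $k$ ordered strata contrasts observed minus
  expected events with equally spaced scores $c$:
  $\chi^2_1 = (c'(O-E))^2 / (c'Vc)$ with $V$ the hypergeometric
  covariance over the shared risk sets. With two groups it equals the
  ordinary log-rank statistic.
* **Ties** use the Efron approximation by default. Legacy SPSS-style
  analyses default to Breslow, which can produce small numeric
  differences; a `ties` flag switches.
* **Stepwise selection** mirrors the standard biomarker-validation
  recipe: univariable screen admitting candidates at p < 0.1 (lenient,
  to avoid falsely rejecting borderline factors), then backward
  elimination removing the largest-p term while any term has p ≥ 0.05.
  Multi-level factors (e.g. WHO performance status with reference level
  0) are screened and eliminated as whole terms via an aggregate Wald
  test. The full audit trace (admitted set, each elimination with its
  p-value) is returned. An empty admitted set yields a null model, not
  an error, and non-convergence or separation is flagged honestly.
* Whether deaths unrelated to the disease should count as OS events is
  a data-dictionary decision, not a package one; the pipeline takes the
  event indicator as given, and cohorts that prefer censoring such
  deaths should encode that upstream.

## The synthetic cohort generator

No patient-level dataset accompanies the published analyses this package
operationalizes, so validation runs on a generator that reproduces the
statistical structure the pipeline assumes:

* **Baseline arm weights** are proportional to arm length. The real
  assay's weights follow LINE-1 element density, which is unknowable
  without the assay itself; any weight vector can be supplied.
* **Tumor mixture**: expected fractions
  $q_a \propto p_a(1 + \mathrm{tf}\,(c_a-2)/2)$ for tumor copy number
  $c_a$; the default profile carries the alterations most frequently
  seen in HR-positive breast cancer cfDNA — gains on 1q and 8q, losses
  on 8p, 10q, 13q and 17p.
* **Counts** are Dirichlet-multinomial: 90,000 reads at concentration
  50,000, adding ≈ 1.4% per-arm coefficient of variation beyond counting
  noise. This places the score-5 detection threshold at tumor fractions
  around 0.15–0.2, consistent with the assay's reported sensitivity
  range, and yields roughly a third of patients scoring high under the
  default tumor-fraction mixture (40% ctDNA-negative, remainder uniform
  on [0.05, 0.5]).
* **CTC counts** are negative-binomial with log-mean affine in tumor
  fraction. CTC is linked to tumor fraction, *not* to the realized
  score, so marker discordance arises naturally rather than being
  injected.
* **Survival**: exponential event times whose hazard is
  $h_0 e^{\beta\,[\text{true class}]}$, with the true class defined by
  the deterministic excess of the expected composition's squared-Z sum
  over the control calibration; censoring is independent uniform on
  (0, 60] months. Baseline medians default to 12 (PFS) and 40 (OS)
  months.
* All randomness flows from one mandatory master seed through fixed
  sub-streams (controls, tumor fractions, counts, clinical covariates,
  survival), so modules can be regenerated independently and runs are
  byte-reproducible.

What the generator does **not** emulate: LINE-1 density-driven arm
weights, GC or mappability artifacts, focal and sub-arm events,
per-patient copy-number heterogeneity beyond an optional global profile,
fragmentomics, or dependence between PFS and OS within a patient.
Passing tests therefore demonstrate the pipeline's statistical
correctness under its stated assumptions, not assay-level accuracy on
real plasma.

## Problem sizes used for validation

The shipped test-suite checks run at sizes chosen to finish in minutes
on one CPU while keeping Monte-Carlo error well inside the asserted
bands: scoring equivalence against a brute-force oracle on 100 samples
(tolerance 1e-9); control self-calibration at 50 controls; score
monotonicity over tumor fractions {0, 0.1, 0.2, 0.4} with 50 replicates
each; Cox Wald-CI coverage at n = 500 over 300 replicates; stepwise
recovery of a true hazard ratio of 2.5 at n = 130 over 200 replicates;
null calibration of the log-rank p-value over 500 simulated cohorts and
of the Jonckheere–Terpstra test over 2,000 datasets.

## Known limitations

* The score has no tumor-fraction point estimate; it is a relative
  deviation measure (by design — segmentation and focal calling are out
  of scope, and HER2-amplicon assessment is impossible for this assay).
* Arm-level gain/loss calls use a configurable |z| ≥ 3 default; short
  arms with small baseline fractions are noisier and reach the
  threshold later than large arms at the same tumor fraction.
* Panels of real controls should match the assay, sequencer and,
  ideally, demographics of the patient samples; the package checks
  arithmetic, not assay comparability.
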