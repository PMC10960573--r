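---
title: "Methylome-based embryo screening: models and design choices"
author: "methscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylome-based embryo screening: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methscreen)
```

## The screening problem

In assisted reproduction, several euploid embryos of one patient are
often available and conventional aneuploidy testing (PGT-A) cannot rank
them — among all-euploid embryos it amounts to a random pick. This
package ranks euploid preimplantation embryos by features of their DNA
methylome, measured from whole-genome bisulfite sequencing of embryo
biopsies, and evaluates how much a methylome-guided selection would
have changed clinical outcomes.

Two complementary signals are modelled:

* **Whole-genome methylation level (ML).** The mean methylation
  fraction over all sequenced CpGs. Live-birth rates are highest near
  an optimal level of 0.26; the deviation `ML-score = |ML − 0.26|` is
  the embryo-level risk summary. A binomial GLM,
  `logit P(birth) = a + b·MLscore`, converts the score into an
  expected live-birth probability.
* **Promoter methylation signatures.** Mean methylation of 2 kb
  windows centred on each TSS. Embryos that fail to produce a live
  birth carry an excess of promoter *epimutations* — promoters whose
  level deviates from the birth-group baseline by more than 0.1
  absolutely (AM) and more than 3 baseline standard deviations
  relatively (RM). A gradient-boosted tree ensemble trained on these
  promoter features produces the *TSS-score*, a predicted birth
  probability.

The final score mixes the TSS-score with the GLM probability in a 1:2
weight ratio (a convex combination, so the result is again a
probability). Retrospective evaluation uses three statistics: the
per-patient H-index (max − min ML-score: was there any meaningful
choice?), S-index (selected − min: was the selection good?) and, in
simulated selection, the discriminability index
`DI = P(birth embryo) − mean P(failed embryos)`.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `optimum_ml` | 0.26 | methylation level with peak birth rate (imported from prior work, not re-estimated) |
| `threshold` | 0.03 | smallest ML-score difference treated as a real quality difference; drives the similar/superior/inferior grouping. Differences exactly at the threshold count as not meaningful |
| `min_coverage` | 30 | per embryo-promoter cell: summed CpG read coverage below this masks the cell |
| `min_group_fraction` | 0.10 | promoters covered in less than 10% of either outcome group are dropped |
| `am_cutoff`, `rm_cutoff` | 0.1, 3 | absolute / relative epimutation thresholds |
| `feature_alpha` | 0.05 | promoter enters the classifier if ANOVA *or* Wilcoxon p falls below it |
| `max_removals` | 5 | noisy-label cleaning stops after this many removals |
| `weights` | (1, 2) | TSS : GLM mixing weights; the reverse reading (2, 1) is selectable |
| `n_fit`, `n_cv` | 20, 20 | ensemble size and CV repeats; values above 10 are required because single boosted fits are seed-sensitive at these sample sizes |

The 0.03 threshold is exposed as a parameter rather than derived: the
derivation from the GLM confidence band is a judgement call, not an
algorithm, so the package treats it as configuration.

## The synthetic cohort generator

No clinical methylome cohort of this kind is publicly deposited, so the
package ships a simulator whose defaults encode the study conditions
the pipeline assumes, and every statistical claim in the test suite is
made against cohorts drawn from it.

* **Latent levels.** An embryo's whole-genome level is
  `optimum + s·|N(0, ml_scale)|` with a random sign `s`, a half-normal
  deviation (`ml_scale` = 0.05). The clinical distribution's exact
  shape is unknown; the half-normal reproduces a unimodal distribution
  with a tail of large deviations without over-specifying it, and is
  deliberately configurable.
* **Outcomes.** True birth is Bernoulli with
  `logit p = 1.5 − 30·MLscore`, so embryos at the optimum deliver at
  `plogis(1.5) ≈ 0.82` and the rate decays with deviation. Patients
  hold 1–4 embryos and transfer them in sequence until the first live
  birth, which reproduces the clinical structure in which a patient's
  final transfer — and only that one — can be a birth.
* **Promoters.** Baseline promoter levels are drawn from a bimodal
  (hypomethylation-rich) mixture whose mean sits near the optimum; each
  embryo shifts all its promoters by its own global deviation, and
  biological noise of SD 0.03 is added. Failed embryos receive planted
  epimutations (level shifted by 0.3 away from the baseline) on 5% of
  promoters versus 1% in birth embryos. Per-CpG coverage is Poisson
  (mean 3, 12 CpGs per promoter), methylated counts are binomial, and
  cells are aggregated exactly as the i/o layer does, so roughly 15% of
  cells fall below the 30× filter.
* **Label noise.** Recorded outcomes disagree with the truth with
  probability `label_flip_rate` (3% by default); the truth table
  records which labels were flipped so noise-cleaning can be scored.

The generator does **not** simulate read-level bisulfite data,
chromosome structure, imprinted regions, batch effects or
age-dependent aneuploidy. Consequently, green tests show that the
pipeline recovers the signals it models under realistic sampling noise
— they cannot show that real embryo methylomes carry those signals at
the planted effect sizes.

## Numerical and procedural choices

* **Coordinates** are 0-based half-open throughout the text formats,
  matching BED; promoter windows are `[tss − 1000, tss + 1000)` and are
  strand-symmetric (strand only locates the TSS).
* **Coverage filters.** The 30× filter is applied per embryo-promoter
  cell (not globally), and "coverage" is the summed read count over the
  window's CpGs, not the count of distinct covered CpGs. Promoter means
  are unweighted across covered CpGs.
* **Epimutation baselines** are computed over all birth embryos with no
  leave-one-out, including the embryo being called when it is itself a
  birth embryo. A zero-variance baseline makes RM infinite, so the call
  reduces to the absolute criterion; an `sdFloor` is available.
* **Differential promoters** are flagged as "higher in failed" when the
  failed-minus-birth frequency difference is positive and the two-sided
  Fisher p is below 0.05, with no multiple-testing correction by
  default (a Benjamini–Hochberg option exists). This flagging rule is a
  documented default, not a uniquely determined definition.
* **Feature selection runs inside every cross-validation training
  fold.** Selecting promoters once on the full data set leaks held-out
  information; the test suite demonstrates the inflation this produces
  on signal-free data (null AUC rises by well over 0.1). A `features`
  override exists precisely to reproduce that diagnosis.
* **Boosted trees.** Depth-3 trees, learning rate 0.1, 50 rounds, row
  subsampling 0.8, fitted with xgboost. Subsampling gives the
  seed-to-seed variation that prediction averaging (ensembles and CV
  repeats of more than 10) smooths out; all seeds derive from one
  master seed, so runs are bit-reproducible, with a documented knob to
  randomise. Missing promoter values are imputed with the training
  fold's per-feature median, recorded in the scorer for prediction
  time.
* **Noise cleaning** removes, per iteration, the single failed-labelled
  embryo with maximal `N = |label − CV score|`; birth-labelled embryos
  are never removed, ties break towards the lexicographically smallest
  embryo id, and the loop stops after `max_removals` (default 5)
  removals.
* **Degenerate inputs.** The one-sample t-test on DIs reports limiting
  p-values under zero variance (1 when the mean is 0, otherwise 0);
  single-class GLM input and single-class folds are rejected or
  redrawn; empty CpG files parse to empty call sets with a warning.
* **Tie-breaking in selection** is deterministic: higher GLM
  probability, then lower ML-score, then embryo id.

## Problem sizes used in the test suite

Statistical checks run at the smallest sizes at which the tested
property is meaningful: GLM recovery uses 50 cohorts of 160 embryos;
noise-cleaning recovery uses 20 replicates of 126-embryo training sets
with 5 flipped labels over 150-promoter cohorts; null controls use
300–500-promoter cohorts; the end-to-end reproducibility check runs
the full pipeline twice on a ~160-embryo, 2000-promoter cohort with 12
CV/ensemble repeats (the repeat floor of 10 still respected). These
sizes are the package's own choices for a laptop-scale test suite and
are stated here so that readers know exactly what was exercised.

Two statistical subtleties deserve naming. First, noisy labels are
identifiable only when the classes are separable: the noise-cleaning
recovery tests therefore plant a strong signal (failed embryos
epimutated on half their promoters) so that a flipped label is an
unambiguous outlier. At weak planted signal, many genuinely failed
embryos legitimately look birth-like and the maximal-noise ranking
cannot distinguish them from flips — cleaning real clinical data
inherits exactly this caveat. Second, a single null cohort's
cross-validated AUC fluctuates around 0.5 with a standard deviation
near 0.08 at these sample sizes; calibration claims in the tests are
therefore made on means over replicates, not on individual runs.

## Known limitations

* The clinical headline numbers of methylome-based screening (AUCs
  near 0.9, selection accuracy near 0.8) depend on a private clinical
  cohort; nothing in this package reproduces them, and the synthetic
  defaults are not tuned to do so.
* "ANOVA" with two groups is the equal-variance t-test; the package
  implements exactly that and does not support more than two outcome
  groups.
* The GLM treats embryos as independent, ignoring patient-level
  clustering; with 1–4 embryos per patient the effect on standard
  errors is modest but real.
* Promoter windows are fixed 2 kb symmetric intervals; no CpG-island or
  context-aware definitions are offered.

## A minimal run

```{r example, eval = FALSE}
cfg <- pipelineConfig(
  cohort = cohortConfig(n_patients = 60, n_promoters = 300, seed = 1),
  out_dir = tempfile("run_"), n_cv = 12, n_fit = 12, seed = 1)
summary <- runPipeline(cfg, verbose = TRUE)
summary$selection
```
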