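---
title: "Validating toxicity SNP panels with deep sparse autoencoders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating toxicity SNP panels with deep sparse autoencoders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsaeselect)
```

## The problem

Late normal-tissue toxicity after prostate radiotherapy — rectal bleeding,
urinary frequency, haematuria, nocturia, decreased urinary stream — affects
a minority of patients (roughly 4–18% per endpoint), and the genetic risk
factors proposed for it rarely survive independent validation. The classical
validation route, one logistic regression per SNP with Bonferroni control,
loses power exactly where it is needed: rare outcomes, modest effects, many
tests. `dsaeselect` implements an alternative that treats patients *with*
toxicity as outliers relative to the majority: a deep sparse autoencoder
(DSAE) is trained to reconstruct the SNP profiles of patients *without*
toxicity, and the features (SNPs) on which toxicity patients reconstruct
worst are the ones that distinguish the minority class.

## The selection procedure

Let $X$ be the $N \times J$ matrix of additive dosages (each row a patient's
$J$ SNPs) and let the outcome split patients into "healthy" (no toxicity, the
majority) and "unhealthy". One replicate runs four steps:

1. **Sampling.** Draw $S$ healthy patients without replacement, where $S$ is
   the number of unhealthy patients. These plus all unhealthy patients form
   the *test set* ($2S$ rows); every remaining healthy patient forms the
   *training set*.
2. **Training.** Fit the autoencoder on the training set only, so the model
   learns the best representation of normal radiosensitivity.
3. **Testing.** Compute the reconstruction-error matrix
   $R \in \mathbb{R}^{2S \times J}$ on the test set, with
   $r_{ij} = (x_{ij} - \hat{x}_{ij})^2$.
4. **Reduction.** Average $R$ per feature within each class, giving two
   $J$-vectors.

Steps 1–3 are repeated $B$ times (default $B = 50$; the resampling removes
the selection bias of any single healthy subsample). The per-class vectors
are averaged across replicates with equal weight per replicate and
subtracted, giving the selection statistic
$\Delta_j = \overline{RE}^{\,\text{unhealthy}}_j -
\overline{RE}^{\,\text{healthy}}_j$. SNPs with $\Delta$ strictly above the
70th, 80th, 90th and 95th percentiles of the $J$ values form nested tiers,
mapped to the effect-size vocabulary used for the source literature: small
(OR < 2) above the 70th, moderate (OR ≈ 2) above the 80th, large (OR > 2)
above the 90th/95th.

Equal weighting per replicate (rather than pooling all test rows) keeps the
aggregate invariant to per-replicate test-set size; the percentile uses
linear interpolation between order statistics (`stats::quantile` type 7) and
*strict* inequality for membership, so a degenerate constant profile selects
nothing rather than everything.

## The network

The architecture is fixed across endpoints for comparability: input $J$,
encoder layers of 40 and 30 nodes with `tanh` activations, a 20-node
innermost code layer with a sigmoid activation, and a decoder mirroring the
encoder (30, 40, `tanh`) with a linear output. Training minimises

$$\frac{1}{m}\sum_i \lVert x_i - \hat{x}_i \rVert^2
  \;+\; \lambda\,\frac{1}{m}\sum_i \lVert h_i \rVert_1$$

by Adam (learning rate 0.001, conventional moment defaults) for 400 epochs,
where $h_i$ is the code activation. Choices worth spelling out:

* **Loss.** The squared Euclidean norm, not the norm itself — gradients are
  then linear in the residual, and the selection statistic is rank-based so
  the two readings order features identically in practice.
* **Sparsity penalty.** The batch-mean L1 norm of the code activations — the
  standard activity regulariser. The sigmoid code keeps activations in
  $(0,1)$, so the penalty is nonnegative and bounded and drives unused code
  units toward zero.
* **$\lambda$.** Default $10^{-4}$, with $10^{-5}$ equally supported and
  exercised in the test-suite; the tier assignments are insensitive to the
  choice because ranking, not loss magnitude, drives selection.
* **Input scale.** Dosages are divided by 2 into $[0,1]$. The constant is
  fixed rather than estimated, so training and test scaling agree by
  construction and a frozen model's squared residuals scale quadratically
  with the input scale.
* **Initialisation and determinism.** Fan-balanced (Glorot-style) uniform
  weights seeded through R's RNG; full-batch training by default (the
  cohort-sized training sets of ~1,000 rows fit comfortably), so a run is a
  pure function of data, parameters and seed. Mini-batches, if configured,
  shuffle with the same seeded RNG. Replicate seeds are drawn once from the
  master seed, giving independent, reproducible streams.
* **Decoder output.** Linear, compatible with the Euclidean loss on scaled
  dosages; decoder hidden layers use `tanh`, mirroring the encoder.

Training aborts with a diagnostic if the loss leaves the finite range.

## Endpoint derivation

The five shipped endpoints are grade thresholds on ordinal 0–4 symptom
scores at the 12- and 24-month visits: bleeding ≥ 1, urinary frequency ≥ 2,
haematuria ≥ 1, nocturia ≥ 2, decreased stream ≥ 1. Exclusions: collagen
vascular disease always; bladder resection or antimuscarinic use for the
urinary endpoints; baseline haemorrhoids for bleeding; no follow-up grades
at all. Intermediate visits are not consulted — the endpoint definitions
refer only to the 12/24-month grades — and a single missing visit is
tolerated, the case decision using whatever follow-up is available, which
maximises evaluable patients as in observational practice.

Patients already at or above the threshold at baseline are governed by
`baseline_policy`. The narrative definition treats them as "not exhibiting
the endpoint" (our `recode_control`), but the per-endpoint cohort
denominators are only reproduced when they are dropped, so the default is
`exclude`. Under `recode_control` a baseline-prevalent patient whose
follow-up grade *exceeds* the threshold is a case — the literal reading of
"grade ≤ T during follow-up" — which is the one situation where the two
policies can disagree about a case; for every patient below threshold at
baseline the policies agree exactly, and the tests pin this down.

## The synthetic cohort generator

Real genotype-toxicity cohorts in this field sit behind managed access, so
the package generates cohorts with the statistical structure the method
assumes, as first-class tested code:

* **Genotypes.** Per SNP, dosage $\sim$ Binomial(2, MAF) under
  Hardy–Weinberg equilibrium, MAF uniform on $[0.05, 0.5]$ by default;
  integer genotypes by default with an option for jittered "imputed"
  dosages. The six-SNP overall-toxicity group is generated from a shared
  pair of latent haplotypes with per-allele copy probability
  $r_2^{1/4}$, giving pairwise squared correlation ≈ `ld_r2` (default 0.9)
  without any external haplotype reference; `ld_r2 = 1` collapses the block
  to identical columns.
* **Outcomes.** An additive-logistic model with planted log-odds-ratios on a
  chosen SNP subset; the intercept is solved by monotone root search so the
  expected prevalence hits the target (4–18% is the realistic range here)
  to $10^{-6}$, and default planted ORs sit in the panel's printed range.
* **Trajectories.** Grade records are generated to invert exactly through
  the endpoint rules at zero exclusion rates (cases reach the threshold at
  a follow-up visit, controls never do), with optional baseline-prevalent
  non-worsening controls and independent exclusion flags layered on top.

What the generator does **not** emulate: population structure and
relatedness, genotyping error and missingness, LD beyond the one declared
block, non-genetic risk factors (dose, comorbidity) and correlation between
endpoints. Passing tests therefore demonstrate that the pipeline recovers
planted additive signal under clean HWE sampling at realistic imbalance —
not that it would do so against confounded or structured real cohorts.

## Problem sizes and calibration checks

The heavier empirical checks run at deliberately chosen sizes: planted-signal
recovery uses one cohort of $n = 1{,}400$ (prevalence 10%, five planted SNPs
with OR 2.5–3.5) analysed with $B = 20$ replicates under five master seeds —
sharing the cohort across seeds also yields the seed-stability check
(Spearman correlation of $\Delta$ between master seeds ≥ 0.8). Null
calibration permutes the labels 20 times and re-runs the selection with
$B = 5$ per permutation, testing that planted SNPs enter the top (95th
percentile) tier no more often than their share (binomial test at
$\alpha = 0.01$). The univariate arm is calibrated on 500 null replicates of
$n = 5{,}000$ (type-I error ≈ 5% at $\alpha = 0.05$, p-value distribution
uniform by Kolmogorov–Smirnov). $B = 50$ remains the analysis default; the
reduced $B$ in the permutation runs trades replicate averaging for
permutation count, which is the right trade for a calibration check.

## A worked run

```{r example, eval = FALSE}
cfg <- pipeline_config(
  endpoint = "rectal_bleeding",
  output_dir = "dsae_run",
  master_seed = 1,
  B = 20,
  simulation = list(n = 1400, target_prevalence = 0.1,
                    planted_rsids = c("rs17599026", "rs8098701",
                                      "rs7720298", "rs147596965",
                                      "rs4906759"),
                    planted_or = c(2.5, 2.75, 3, 3.25, 3.5))
)
res <- run_pipeline(cfg)
head(res$report[order(-res$report$delta), c("rsid", "delta", "tier")])
```

The output directory receives the genotype and phenotype tables, the
per-SNP selection report and Identified/Not-validated validation matrix,
the univariate association table, the two-panel figure (class-mean
reconstruction errors above, $\Delta$ with percentile lines below) and a
JSON manifest from which every random draw in the run can be reproduced.

## Known limitations

* Tier counts depend on the percentile convention; with 43 features the
  70th-percentile tier holds 13 SNPs whenever the $\Delta$ values are
  distinct, so "identified" is a relative, not absolute, statement.
* The method ranks features; it does not return effect estimates or
  p-values — pair it with the univariate arm for those, remembering the
  power asymmetry that motivates the method.
* Three panel entries' literature effects are hazard ratios carried as
  metadata; no survival modelling is attempted.
* Scaling beyond panel-sized inputs (toward genome-wide feature counts) is
  out of scope.
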