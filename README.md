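# dsaeselect

Minority-class SNP selection with deep sparse autoencoders, for validating
genetic risk factors of late radiotherapy toxicity.

## The problem

Late side effects of prostate radiotherapy (rectal bleeding, urinary
frequency, haematuria, nocturia, decreased urinary stream) affect only
4–18% of patients, and candidate SNPs reported for these endpoints rarely
replicate under the classical single-marker test: a univariate logistic
regression per SNP needs `p < α/J` after Bonferroni correction (`p <
0.0011` for a 43-SNP panel at α = 0.05), which typical cohort sizes cannot
deliver for modest effects.

`dsaeselect` implements an outlier-based alternative. A deep sparse
autoencoder (input J SNPs → 40 → 30 → 20 (sigmoid code) → 30 → 40 → J,
tanh hidden activations) is trained only on patients *without* toxicity, so
it learns the SNP pattern of normal radiosensitivity. On a class-balanced
held-out test set, the per-SNP squared reconstruction errors
`r_ij = (x_ij − x̂_ij)²` are averaged within each outcome class, and the
selection statistic is the per-SNP difference

```
Δ_j = mean RE_j(with toxicity) − mean RE_j(without toxicity)
```

aggregated over B resampled train/test replicates (default B = 50). SNPs
with Δ strictly above the 70th/80th/90th/95th percentiles of the Δ
distribution form nested tiers mapped to small/moderate/large effect sizes.
The package ships the 43-SNP literature panel with per-endpoint effects,
the five endpoint definitions (ordinal grade thresholds with baseline and
confounder exclusion rules), a seeded synthetic cohort generator
(Hardy–Weinberg genotypes with one linkage block, additive-logistic
outcomes, grade trajectories), the univariate comparison arm, and an
end-to-end pipeline with TSV/figure/manifest outputs.

## Worked example

A self-contained run: simulate a 1,400-patient cohort at 10% prevalence
with five planted SNPs (OR 2.5–3.5), then select with B = 20 replicates:

```r
library(dsaeselect)
panel <- load_snp_panel()
planted <- c("rs17599026", "rs8098701", "rs7720298",
             "rs147596965", "rs4906759")
g <- simulate_genotypes(1400, panel, seed = 42)
truth <- simulation_truth(g, panel, planted_rsids = planted,
                          planted_or = seq(2.5, 3.5, length.out = 5),
                          target_prevalence = 0.1)
y <- simulate_outcome(g, truth, seed = 7)
re <- run_replicates(scale_dosages(g), y, network_spec(43),
                     B = 20, master_seed = 11)
report <- tier_select(delta_profile(re), panel = panel)
report[order(-report$delta)[1:6], c("rsid", "delta", "tier", "effect_label")]
```

```
         rsid   delta tier effect_label
1   rs4906759 0.05011  p95        large
2  rs17599026 0.04724  p95        large
3   rs8098701 0.02380  p95        large
4 rs147596965 0.02271  p90        large
5   rs7720298 0.01371  p90        large
6   rs8075565 0.01333  p80     moderate
```

All five planted SNPs head the Δ ranking and sit in the 90th-percentile
tier or above — the autoencoder recovers the planted minority-class signal.
`delta` is the difference in mean squared reconstruction error between the
two classes on the half-scaled dosage scale; `tier` is the highest
percentile threshold the SNP clears. The univariate comparison arm
(`univariate_scan(g$dosages, y)`) on the same cohort flags these five too
(planted ORs of 2.5–3.5 are large); the methods' power difference appears
at the modest effect sizes where Bonferroni-corrected single-marker tests
go quiet while the rank-based Δ statistic still orders signal first.

For a one-command version, `run_pipeline(pipeline_config(...))` (or the
`inst/cli/dsaeselect` wrapper with a YAML config) performs
simulate → label → select → univariate and writes the selection report,
the Identified/Not-validated validation matrix, the univariate table, a
two-panel figure (class-mean REs above, Δ with percentile lines below) and
a JSON manifest.

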