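# agewas

Epigenome-wide association analysis (EWAS) of chronological age on Illumina
450K-like DNA methylation data, with permutation-based family-wise error
control, double replication across independent twin cohorts, genomic
characterization of the replicated CpGs, and gene-set over-representation
analysis. A synthetic-data module generates cohorts with the statistical
structure the analysis assumes, so the entire pipeline is testable without
downloading a single array.

The package is written for methylation analysts who want a tested,
reproducible implementation of the aging-EWAS workflow: discovery in a
repeated-measures elderly cohort, validation in a cross-sectional twin
cohort and a longitudinal twin cohort, and downstream biology.

## The statistics at the core

**Discovery scan.** Methylation fractions (β ∈ [0,1]) are mapped to
M-values by the base-2 logit, M = log₂(β/(1−β)), and each CpG is fitted by
ordinary least squares

&nbsp;&nbsp;&nbsp;&nbsp;M ~ intercept + age + cell composition

where the cell covariates are Houseman-style blood fractions (CD8T, CD4T,
NK, B cell, monocyte, granulocyte; the granulocyte column is dropped to
break the compositional collinearity). Because the discovery cohort has
repeated measures, significance is assessed empirically: K permutations
shuffle age across samples, each permuted scan records its minimum p-value,
and the per-CpG family-wise error rate is the minP estimate

&nbsp;&nbsp;&nbsp;&nbsp;FWER(j) = #{ i : min-p(i) < p(j) } / K.

**Replication.** Every discovery-significant CpG (FWER < 0.05) is refitted
in each validation cohort by a linear mixed model with a random intercept
per cluster (twin pair, or individual for the longitudinal cohort); a CpG
replicates when the validation slope keeps the discovery sign and its Wald
p < 0.05, and *double-replicates* when that holds in both cohorts.

**Characterization.** Double-replicated CpGs are cross-tabulated by
(multi-label) gene region and (single-label) CpG-island relation. The
gain-versus-loss imbalance in each category is the Yates-corrected χ² of
the symmetric 2×2 table, χ² = 8·(max(|k_gain − n/2| − 0.5, 0))²/n; category
proportions are compared against the whole-array background with a
two-sample Yates 2×2 χ².

**Enrichment.** Significant CpGs map to nearest genes and each GMT gene
set is tested with the strictly-greater hypergeometric tail
p(X > k) = 1 − Σ_{r≤k} C(m,r)·C(N−m,n−r)/C(N,n), evaluated in log-space.

## Worked example

```r
library(agewas)

cfg      <- sim_config(n_cpgs = 300, seed = 1)   # planted effects ~ ±0.01 M/yr
manifest <- simulate_manifest(cfg)
presets  <- cohort_presets()

discovery <- simulate_cohort(manifest, presets$discovery_like, cfg)
fit <- run_ewas(discovery$study, manifest, K = 60, seed = 1)
fit
#> <agewas_ewas> 276 CpGs, 400 samples, K = 60 permutations
#>   FWER < 0.05: 19 CpGs (8 gain, 11 loss)

sig   <- significant_cpgs(fit)
cross <- simulate_cohort(manifest, presets$cross_sectional_like, cfg)$study
long  <- simulate_cohort(manifest, presets$longitudinal_like,  cfg)$study
ledger <- replication_ledger(sig,
  replicate_cohort(sig, cross, "pair"),
  replicate_cohort(sig, long,  "subject"))
ledger
#> <agewas_replication> 19 discovery CpGs
#>   cross_sectional: 19 replicated (100.0%); longitudinal: 18 replicated (94.7%)
#>   double-replicated: 18 (overlap rate 100.0%)

dbl <- double_replicate(ledger)
tabulate_by_cgi(dbl, manifest)$direction[, 1:6]
#> # A tibble: 6 × 6
#>   category     n k_gain k_loss prop_gain prop_loss
#> 1 Island       4      2      2     0.5       0.5
#> 2 N_Shore      4      2      2     0.5       0.5
#> ...
```

The 400 discovery samples are 200 subjects measured at two waves; 276 of
the 300 simulated CpGs are autosomal and scanned. 19 CpGs reach FWER <
0.05 under the minP null with K = 60 permutations; 18 of them replicate
with consistent direction in both twin cohorts and form the
double-replicated set that the characterization and enrichment stages
consume. `run_pipeline(pipeline_config(...))` performs the same chain end
to end, writing every stage artifact (TSV/CSV/GMT) and a JSON run report.

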