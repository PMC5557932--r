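---
title: "Methods: EWAS of aging with minP FWER, twin replication and characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EWAS of aging with minP FWER, twin replication and characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agewas)
```

# The analysis model

## Discovery scan

The discovery cohort is a collection of whole-blood 450K-style methylation
profiles from elderly subjects, several of whom are measured at more than
one wave. For each CpG the methylation fraction β is mapped to the M scale
by the base-2 logit, `M = log2(beta / (1 - beta))`, which is close to
normally distributed and variance-stabilized; regression is done entirely
in M units. The per-CpG model is ordinary least squares of M on

* an intercept,
* age at sampling (years) — the coefficient of interest, in M-units/year,
* five of the six blood cell fractions (CD8T, CD4T, NK, B cell, monocyte).

The granulocyte fraction is dropped by design: the six fractions sum to
one, so a full set plus an intercept is exactly collinear. Any *further*
rank deficiency is treated as a data error and reported with the offending
columns, never silently repaired.

Because repeated measures within subject violate the independence
assumption of the OLS t-test, significance is not taken from the model.
Instead, K permutations (default K = 300, with 1/K the resolution of the
resulting error rates) shuffle the age column across samples while leaving
methylation and cell fractions untouched, the entire scan is re-run, and
the minimum p-value of each permuted scan is recorded. The per-CpG
family-wise error rate is the minP estimate

$$\widehat{\mathrm{FWER}}_j = \frac{1}{K}\#\{\,i : \min_p(i) < p_j\,\},$$

with a *strict* inequality. Estimates live on the grid {0, 1/K, …, 1} and
are non-decreasing in the observed p-value. Discovery significance is
FWER < 0.05, again strict: a CpG exactly at the threshold is excluded.
Shuffling at the sample level deliberately destroys the within-subject
correlation; that is what makes the empirical null honest for a
repeated-measures design without modelling the dependence.

## Replication

Validation cohorts are clustered — monozygotic twin pairs in the
cross-sectional cohort, repeated measures per individual in the
longitudinal one — so each discovery-significant CpG is refitted by a
linear mixed model (REML, `lme4`) with the same fixed effects and one
random intercept per cluster. The age p-value is a two-sided Wald test
with a normal reference. Two deliberate simplifications: for the
longitudinal twins the pair-level effect is omitted (one random intercept
per individual) — at ~45 pairs a second variance component buys little and
costs convergence; and if the mixed model cannot be fitted at all the fit
falls back to OLS on cluster means, flagged in the output. With singleton
clusters that fallback coincides with plain OLS, which is the correct
limit.

A CpG *replicates* in a cohort when its validation slope has the
discovery sign **and** p < 0.05 (strict); it *double-replicates* when that
holds in both cohorts. CpGs absent from a validation array are recorded as
not testable and excluded from both numerator and denominator of that
cohort's rate — absence is not evidence of non-replication. Rates follow
the conventions of the aging-EWAS literature: per-cohort replication rate
= replicated / discovery-significant × 100; overlap rate =
double-replicated / the smaller cohort's replicated count × 100. One
documented discrepancy: from the published set sizes 5,168/7,238 =
71.40%, while the source text prints 70.4%; this package reports the ratio
its own arithmetic produces (71.40) since the printed figure cannot be
derived from the printed counts. Undefined rates (zero denominators) are
reported as `NA`, never as 0.

## Characterization

Double-replicated CpGs are characterized along two annotation axes.
Gene-region membership is **multi-label** (a promoter CpG can be both
TSS200 and 1stExon), so a CpG contributes one count to every label it
carries and region totals may exceed the set size; the CGI relation
(Island, N/S shore, N/S shelf, non-CGI) is **single-label** and partitions
the set. Two tests are computed per category:

* **Direction bias** — is the category's gain/loss split unbalanced? The
  statistic is the Yates-continuity-corrected χ² of the symmetric table
  [[gain, loss], [loss, gain]], which reduces to the closed form
  8·(max(|k_gain − n/2| − 0.5, 0))²/n on one degree of freedom. It is
  symmetric in gain/loss and floors at 0 for a perfect 50/50 split. This
  construction reproduces the published table statistics exactly from
  their printed counts (e.g. 374/114 → 274.92; 1,554/128 → 2,414.54), and
  is adopted for that reason.
* **Proportionality** — is the category over- or under-represented in the
  gain (or loss) set relative to the whole array? A two-sample 2×2 Yates
  χ² against the manifest's category counts. Exact reproduction of the
  published proportionality statistics would require the original
  manifest's counts, which are not published; whether those values came
  from a one-sample goodness-of-fit or a two-sample table is not
  determinable from the printed statistics (both give ≈21.3 for the
  plausible backgrounds), so the two-sample form was chosen. Expected
  cells below 1 flag the p-value as unreliable but the statistic is still
  returned.

The region-by-CGI crosstab collapses the island relation to three groups
(CGI, Shore/Shelf, non-CGI); its marginals over the CGI groups reproduce
the per-region direction counts by construction, and that identity is
asserted in the tests. The published crosstab's own percentage column is
internally inconsistent under every parsing we tried, so the crosstab here
reports the gain proportion explicitly and does not attempt to match it.

## Enrichment

Significant CpGs map to distinct nearest genes (CpGs without an annotated
gene map to nothing). With N genes in the universe — by default every
distinct nearest gene in the analysed manifest — m of them significant, a
set of n genes overlapping in k, the over-representation probability is
the hypergeometric tail p(X > k), kept *strictly greater* because that is
how the source formula is printed; the more common inclusive tail
P(X ≥ k) is available via `tail = "ge"`. The sum is evaluated in
log-space over the complementary range (log-binomials combined by
log-sum-exp), so small tails retain full relative accuracy instead of
being computed as 1 minus a number near 1. Results are ordered by p with
ties broken by larger overlap then set name, making the report
deterministic. No multiple-testing correction is applied to enrichment
p-values: the workflow reports ranked tables (top 50 by default), not
significance calls.

# The synthetic-data generator

The generator exists so that every downstream stage can be tested against
known truth. It draws data from exactly the model the analysis assumes:

$$M_{ij} = \mu_j(\mathrm{CGI}) + b_j\,\mathrm{age}_i + \textstyle\sum_c
\gamma_{jc}\,\mathrm{cell}_{ic} + u_{js} + \varepsilon_{ij}$$

with per-CpG slopes `b_j` from a planted truth table, per-subject random
intercepts `u`, Gaussian residuals, Dirichlet cell fractions, and β
recovered by the inverse M transform (so β is strictly inside (0,1)).
Age effects are linear in M-space, matching the fitted model, which makes
parameter recovery well defined.

Key defaults and why:

| parameter | default | rationale |
|---|---|---|
| `cgi_probs` | Island .31, N_Shore .13, S_Shore .10, shelves .05 each, non-CGI .36 | whole-array CGI composition of the 450K platform |
| `region_probs` | Intergenic .25, TSS1500 .17, TSS200 .13, 5'UTR .14, 1stExon .08, Body .36, 3'UTR .04 | whole-array region proportions; they sum past 1 because membership is multi-label |
| `frac_affected` | 0.10 | order of magnitude of genome-wide significant fractions in large aging EWAS |
| `frac_demethylated_among_affected` | 0.61 | demethylation-dominant direction mix of replicated aging CpGs |
| `slope_mean`, `slope_sd` | 0.01, 0.005 M/yr | calibration choice — no published effect-size distribution exists; gives per-decade changes of the size aging EWAS report |
| `baseline_m_by_cgi` | Island −3, shores −1, shelves 1.5, non-CGI 2 | islands are typically unmethylated, open sea methylated |
| `subject_sd`, `noise_sd` | 0.10, 0.15 M | residual scales of well-behaved probes; fixed by a design-time power analysis so that ±0.01 M/yr effects are recoverable at minP stringency with a few hundred subjects |
| `cell_concentration` | (8, 15, 7, 5, 7, 58) | granulocyte-dominated whole-blood profile with realistic dispersion |
| `cell_effect_sd` | 0.5 | per-CpG, per-cell-type effect scale; enabled by default so the cell adjustment is exercised; 0 disables |

Gene-region labels are drawn independently per label (the simplest
generative structure that reproduces multi-membership); CpGs drawing no
label become Intergenic alone. Nearest genes are assigned positionally —
runs of five consecutive CpGs share a symbol — mirroring the locality of
real nearest-gene annotation; Intergenic-only CpGs carry no gene.

Determinism is a contract: a single global seed feeds named substreams
(manifest, truth, per-cohort samples, effects, noise), and per-CpG
quantities are drawn in CpG-contiguous blocks transformed by inverse-CDF,
so the same configuration always reproduces byte-identical data and
*increasing `n_cpgs` never perturbs earlier CpGs*. Both properties are
tested.

Three desk-scale cohort presets mirror the designs an aging EWAS must
handle: a repeated-measures discovery cohort (200 subjects, ages 70–84 at
baseline, second wave six years later), a cross-sectional MZ-twin cohort
(75 pairs in two age clusters, 30–37 and 57–74), and a longitudinal
mixed MZ/DZ twin cohort (90 subjects, ages 73–82 at baseline, a second
wave after a ten-year follow-up). Twins share age and sex; repeated waves
reuse the subject intercept.

What the generator does **not** emulate — and what passing tests can
therefore not show about real arrays: probe-chemistry artifacts (type
I/II differences), batch and plate effects, SNP-under-probe outliers,
cell-composition drift with age (fractions are drawn independently of
age, exactly as the generative model above states, so the cell adjustment
is exercised as variance reduction rather than confounder removal),
non-linear age trajectories, and spatial correlation between neighbouring
CpGs.

# Numerical choices and degenerate inputs

* β ∈ {0, 1} is clamped to [1e-6, 1 − 1e-6] before the logit; synthetic
  data never reaches the clamp, so tests are unaffected by it.
* The logit base is 2, the 450K-literature convention for M-values.
* OLS p-values are floored at the smallest positive double so p stays in
  (0, 1] even for exact fits.
* The OLS scan factorizes the shared design matrix once (QR) and applies
  it to every CpG column; results are identical to CpG-by-CpG `lm()` fits
  (tested to 1e-10) at a fraction of the cost.
* `estimate_fwer()` counts via a sorted `findInterval()`; agreement with
  the naive double loop, including tied values, is tested exhaustively.
* K below 20 is allowed but warns, since FWER resolution is 1/K.
* Open sea is spelled `non-CGI` in every file and output; the Illumina
  `OpenSea` dialect is rejected at read time rather than silently mapped,
  keeping outputs bit-comparable.
* Coordinates are 1-based point positions; strand is not modelled because
  the analysis never uses it.
* Empty characterization inputs produce all-zero count rows with `NA`
  tests; zero-denominator rates are `NA` (undefined), never 0.
* All file readers enforce the container invariants (β range, cell-row
  sums within 1e-6, key alignment, label vocabularies, uniqueness) at
  read time, so violations can never surface downstream.

# Problem sizes in the test suite

The suite regenerates all fixtures in code. The heavier property checks
run at: 200 simulated global-null datasets of 100 CpGs × 60 samples with
K = 100 for FWER calibration; ten seeds of a 300-CpG, 200 + 150 + 90
subject discovery/validation chain with K = 60 for planted-effect
recovery (recovery is scored on CpGs planted at |slope| ≥ 0.015 M/yr, one
SD above the mean planted magnitude); 20 seeds × 500 null CpGs for
p-value uniformity; 500 exact-rational tuples (N ≤ 60) plus randomized
`phyper` comparisons for the hypergeometric tail; and an exhaustive
stride-7 grid over counts up to 2,000 for the direction-bias χ². These
sizes were chosen so the whole suite runs in minutes on one core while
keeping each check's statistical resolution meaningful.

# Known limitations

* The headline dataset-scale results of the motivating analysis (tens of
  thousands of significant CpGs, the specific replicated sets and pathway
  tables) require the original cohorts and manifest and are out of reach
  of synthetic data; the package instead verifies every statistic it
  computes against printed counts, closed forms, independent oracles and
  planted truth.
* The discovery point estimate is OLS; dependence among repeated measures
  is handled entirely by the permutation null rather than model-based
  standard errors. The reported discovery `se` is therefore descriptive,
  not inferential.
* An optional categorical covariate (e.g. birth cohort) is not modelled
  by default; the discovery regression adjusts for age and cell
  composition only.
* Enrichment assumes the gene universe is well-defined by the manifest;
  whether a published analysis counted the full array or the autosomal
  subset as its universe is generally unstated, and the default here is
  the manifest as filtered by the pipeline.
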