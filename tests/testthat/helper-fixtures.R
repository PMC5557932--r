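## Shared fixture builders: everything is generated in code at test time.

# A 10-CpG manifest exercising multi-label regions, all CGI labels and the
# sex chromosomes (2 on X, 1 on Y).
tiny_manifest <- function() {
  as_cpg_manifest(tibble::tibble(
    cpg_id = sprintf("cg%03d", 1:10),
    chromosome = c("1", "2", "3", "4", "5", "6", "7", "X", "X", "Y"),
    position = seq(1000, 10000, by = 1000),
    gene_regions = list("TSS200", c("TSS200", "1stExon"), "Body", "Intergenic",
                        c("5'UTR", "1stExon"), "TSS1500", "3'UTR",
                        "Body", "TSS200", "Intergenic"),
    cgi_relation = c("Island", "Island", "non-CGI", "non-CGI", "N_Shore",
                     "S_Shore", "N_Shelf", "S_Shelf", "Island", "non-CGI"),
    nearest_gene = c("G1", "G1", "G2", "", "G3", "G4", "G5", "G6", "G7", "")
  ))
}

# Valid cell-fraction matrix with mild variation (rows sum to 1).
make_cells <- function(n, seed = 11) {
  set.seed(seed)
  cells <- agewas:::rdirichlet(n, c(8, 15, 7, 5, 7, 58))
  colnames(cells) <- c("CD8T", "CD4T", "NK", "Bcell", "Mono", "Gran")
  rownames(cells) <- sprintf("S%03d", seq_len(n))
  cells
}

# Study whose M-values are an exact linear function of age (zero noise);
# cells vary but do not enter the generative model, so the OLS fit is exact.
exact_study <- function(n = 20, slope = 0.02, intercept = 1, seed = 11) {
  cells <- make_cells(n, seed)
  age <- seq(60, 80, length.out = n)
  M <- matrix(intercept + slope * age, ncol = 1,
              dimnames = list(rownames(cells), "cg001"))
  beta <- m_to_beta(M)
  sheet <- tibble::tibble(
    sample_id = rownames(cells), subject_id = rownames(cells),
    pair_id = "", zygosity = "NA", age = age, sex = "F",
    cohort = "fixture", wave = 1L)
  methylation_study(beta, sheet, cells)
}

# Simulated study triplet (manifest + discovery study + truth) at small scale.
small_sim <- function(n_cpgs = 100, seed = 5, frac_affected = 0.1, ...) {
  cfg <- sim_config(n_cpgs = n_cpgs, seed = seed,
                    frac_affected = frac_affected, ...)
  manifest <- simulate_manifest(cfg)
  cohort <- simulate_cohort(manifest, cohort_presets()$discovery_like, cfg)
  list(cfg = cfg, manifest = manifest, study = cohort$study,
       truth = cohort$truth)
}

# Plain percentage of k out of n.
pct_of_counts <- function(k, n) 100 * k / n

# Naive double-loop minP FWER (the brute-force oracle).
fwer_brute_force <- function(p_obs, min_p) {
  vapply(p_obs, function(p) {
    cnt <- 0L
    for (mp in min_p) if (mp < p) cnt <- cnt + 1L
    cnt / length(min_p)
  }, 0)
}

# Generic Yates-corrected 2x2 chi-square, derived cell-by-cell
# (sum over cells of (|O - E| - 0.5)^2 / E) -- independent of the closed
# form used by direction_bias_chisq().
yates_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  E <- outer(c(a + b, c + d), c(a + c, b + d)) / n
  O <- matrix(c(a, c, b, d), 2)  # rows: (a, b) and (c, d)
  sum(pmax(abs(O - E) - 0.5, 0)^2 / E)
}
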