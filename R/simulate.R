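#' Simulation configuration for synthetic 450K-like methylation data
#'
#' The generator produces data under the same model the analysis assumes:
#' for CpG j, sample i of subject s,
#' \deqn{M_{ij} = \mu_j(\mathrm{CGI}) + b_j\,\mathrm{age}_i +
#'   \sum_c \gamma_{jc}\,\mathrm{cell}_{ic} + u_{js} + \varepsilon_{ij}}
#' with subject effects \eqn{u_{js} \sim N(0, \mathrm{subject\_sd}^2)},
#' residuals \eqn{\varepsilon \sim N(0, \mathrm{noise\_sd}^2)}, and beta-values
#' obtained by the inverse M transform \eqn{\beta = 2^M/(2^M+1)}, so beta
#' stays strictly inside (0,1). Age effects are linear in M-space, matching
#' the analysis model, so parameter recovery is well defined.
#'
#' Defaults encode the whole-array annotation structure of the 450K platform
#' (CGI-relation proportions non-CGI 0.36, N_Shelf 0.05, N_Shore 0.13,
#' Island 0.31, S_Shore 0.10, S_Shelf 0.05; gene-region inclusion
#' probabilities summing past 1 because region membership is multi-label)
#' and a demethylation-dominant direction mix (61% of affected CpGs lose
#' methylation with age). Baseline M levels reflect unmethylated islands and
#' methylated open sea. `slope_mean`/`slope_sd` (0.01/0.005 M-units/year)
#' are calibration choices: no effect-size distribution for age-associated
#' CpGs is established, and these give per-decade changes of the size EWAS
#' of aging typically report. The noise defaults (`subject_sd = 0.10`,
#' `noise_sd = 0.15` M-units) describe well-behaved probes; they were fixed
#' by a design-time power analysis so that effects of that size are
#' recoverable at genome-wide (minP) stringency in cohorts of a few hundred
#' subjects (see the methods vignette).
#'
#' @param n_cpgs number of CpGs to simulate.
#' @param region_probs named per-label inclusion probabilities for the 7
#'   gene-region labels (independent Bernoulli per label; a CpG ending with
#'   no label is assigned Intergenic alone).
#' @param cgi_probs named categorical distribution over the 6 CGI-relation
#'   labels; must sum to 1.
#' @param frac_affected fraction of CpGs with a true age effect.
#' @param frac_demethylated_among_affected fraction of affected CpGs with a
#'   negative slope (age-demethylated).
#' @param slope_mean,slope_sd mean and SD of the absolute true slope,
#'   M-units per year.
#' @param baseline_m_by_cgi named mean baseline M-value per CGI label.
#' @param subject_sd SD of the per-subject, per-CpG random intercept
#'   (M-units).
#' @param noise_sd residual SD (M-units).
#' @param cell_concentration 6-vector of Dirichlet concentration parameters
#'   for the blood cell fractions (CD8T, CD4T, NK, Bcell, Mono, Gran);
#'   defaults centre on a granulocyte-dominated whole-blood profile.
#' @param cell_effect_sd SD of per-CpG, per-cell-type effects on M; 0
#'   disables cell-composition effects.
#' @param seed integer seed; a single global seed feeds named substreams and
#'   per-CpG-contiguous draws so that increasing `n_cpgs` does not perturb
#'   earlier CpGs.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_cpgs = 2000,
                       region_probs = c(Intergenic = 0.25, TSS1500 = 0.17,
                                        TSS200 = 0.13, `5'UTR` = 0.14,
                                        `1stExon` = 0.08, Body = 0.36,
                                        `3'UTR` = 0.04),
                       cgi_probs = c(Island = 0.31, N_Shore = 0.13,
                                     S_Shore = 0.10, N_Shelf = 0.05,
                                     S_Shelf = 0.05, `non-CGI` = 0.36),
                       frac_affected = 0.10,
                       frac_demethylated_among_affected = 0.61,
                       slope_mean = 0.01, slope_sd = 0.005,
                       baseline_m_by_cgi = c(Island = -3, N_Shore = -1,
                                             S_Shore = -1, N_Shelf = 1.5,
                                             S_Shelf = 1.5, `non-CGI` = 2),
                       subject_sd = 0.10, noise_sd = 0.15,
                       cell_concentration = c(CD8T = 8, CD4T = 15, NK = 7,
                                              Bcell = 5, Mono = 7, Gran = 58),
                       cell_effect_sd = 0.5,
                       seed = 1L) {
  cfg <- list(n_cpgs = as.integer(n_cpgs), region_probs = region_probs,
              cgi_probs = cgi_probs, frac_affected = frac_affected,
              frac_demethylated_among_affected = frac_demethylated_among_affected,
              slope_mean = slope_mean, slope_sd = slope_sd,
              baseline_m_by_cgi = baseline_m_by_cgi, subject_sd = subject_sd,
              noise_sd = noise_sd, cell_concentration = cell_concentration,
              cell_effect_sd = cell_effect_sd, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  check_that(cfg$n_cpgs > 0, "n_cpgs must be positive")
  check_that(identical(sort(names(cfg$region_probs)), sort(GENE_REGION_LABELS)),
             "region_probs must be named with the 7 gene-region labels")
  check_that(all(cfg$region_probs >= 0 & cfg$region_probs <= 1),
             "region_probs must lie in [0,1]")
  check_that(identical(sort(names(cfg$cgi_probs)), sort(CGI_LABELS)),
             "cgi_probs must be named with the 6 CGI labels")
  check_that(all(cfg$cgi_probs >= 0 & cfg$cgi_probs <= 1),
             "cgi_probs must lie in [0,1]")
  check_that(abs(sum(cfg$cgi_probs) - 1) <= 1e-9, "cgi_probs must sum to 1")
  check_that(cfg$frac_affected >= 0 && cfg$frac_affected <= 1,
             "frac_affected must lie in [0,1]")
  check_that(all(c(cfg$slope_sd, cfg$subject_sd, cfg$noise_sd,
                   cfg$cell_effect_sd) >= 0), "SDs must be non-negative")
  check_that(identical(sort(names(cfg$baseline_m_by_cgi)), sort(CGI_LABELS)),
             "baseline_m_by_cgi must be named with the 6 CGI labels")
  check_that(length(cfg$cell_concentration) == 6 && all(cfg$cell_concentration > 0),
             "cell_concentration must be 6 positive values")
  invisible(cfg)
}

#' Simulate a CpG annotation manifest
#'
#' Gene-region labels are sampled independently per label with the
#' configured inclusion probabilities (multi-label membership, as on the
#' real array); CpGs drawing no label are assigned Intergenic alone. The
#' CGI relation is drawn categorically. Chromosomes are assigned round-robin
#' over 1..22, X, Y. Nearest genes come from a synthetic symbol pool sized
#' so that several CpGs share a gene; CpGs whose only label is Intergenic
#' carry no nearest gene.
#'
#' @param config a [sim_config()].
#' @return a `cpg_manifest` with `config$n_cpgs` rows.
#' @export
simulate_manifest <- function(config) {
  validate_sim_config(config)
  n <- config$n_cpgs
  set.seed(substream_seed(config$seed, "manifest"))
  ## 8 uniforms per CpG, contiguous per CpG: 7 region labels, 1 CGI
  u <- matrix(runif(8 * n), nrow = 8)

  rp <- config$region_probs[GENE_REGION_LABELS]
  inc <- u[1:7, , drop = FALSE] < rp
  regions <- lapply(seq_len(n), function(j) {
    g <- GENE_REGION_LABELS[inc[, j]]
    if (length(g) == 0) "Intergenic" else g
  })

  cp <- config$cgi_probs[CGI_LABELS]
  cgi <- CGI_LABELS[1L + findInterval(u[8, ], cumsum(cp), left.open = FALSE,
                                      rightmost.closed = TRUE)]
  cgi[u[8, ] >= cumsum(cp)[6]] <- CGI_LABELS[6]  # guard the closed right end

  idx <- seq_len(n)
  ## positional gene pool: runs of 5 consecutive CpGs share a nearest gene,
  ## mirroring the locality of real nearest-gene annotation and keeping the
  ## assignment stable when n_cpgs grows
  gene <- sprintf("GENE%05d", (idx - 1L) %/% 5L + 1L)
  intergenic_only <- vapply(regions, function(g) identical(g, "Intergenic"), TRUE)
  gene[intergenic_only] <- ""

  as_cpg_manifest(tibble::tibble(
    cpg_id = sprintf("cg%07d", idx),
    chromosome = CHROMOSOMES[((idx - 1L) %% 24L) + 1L],
    position = ((idx - 1L) %/% 24L + 1L) * 1000L,
    gene_regions = regions,
    cgi_relation = cgi,
    nearest_gene = gene
  ))
}

#' Ground truth of planted age effects
#'
#' Derived deterministically from the configuration seed, so every cohort
#' simulated from the same configuration shares the same planted effects.
#'
#' @param config a [sim_config()].
#' @return a tibble with `cpg_id`, `true_slope` (M-units/year; 0 for null
#'   CpGs) and `direction` (`gain`/`loss`/`null`, the sign of `true_slope`).
#' @export
simulate_truth <- function(config) {
  validate_sim_config(config)
  n <- config$n_cpgs
  set.seed(substream_seed(config$seed, "truth"))
  u <- matrix(runif(3 * n), nrow = 3)  # affected?, direction?, magnitude
  affected <- u[1, ] < config$frac_affected
  loss <- u[2, ] < config$frac_demethylated_among_affected
  magnitude <- abs(config$slope_mean + config$slope_sd * qnorm(u[3, ]))
  slope <- ifelse(affected, ifelse(loss, -magnitude, magnitude), 0)
  tibble::tibble(
    cpg_id = sprintf("cg%07d", seq_len(n)),
    true_slope = slope,
    direction = dplyr::case_when(slope > 0 ~ "gain", slope < 0 ~ "loss",
                                 TRUE ~ "null")
  )
}

#' Cohort designs at desk scale
#'
#' Three fully specified designs mirroring the structures an aging EWAS
#' must handle, at reduced size:
#' \describe{
#'   \item{discovery_like}{200 subjects, baseline ages 70--84, two waves 6
#'     years apart (repeated measures, no twin structure).}
#'   \item{cross_sectional_like}{150 subjects as 75 monozygotic twin pairs,
#'     one wave, ages in two clusters: 30--37 and 57--74.}
#'   \item{longitudinal_like}{90 subjects in mixed MZ/DZ pairs, baseline
#'     ages 73--82 and a second wave after a ten-year follow-up.}
#' }
#'
#' @return a named list of design lists accepted by [simulate_cohort()].
#' @export
cohort_presets <- function() {
  list(
    discovery_like = list(
      name = "discovery", n_subjects = 200L, age_range = c(70, 84),
      waves = 2L, wave_gap = 6, twin_structure = "none"),
    cross_sectional_like = list(
      name = "cross_sectional", n_subjects = 150L,
      age_clusters = list(c(30, 37), c(57, 74)),
      waves = 1L, wave_gap = 0, twin_structure = "MZ_pairs"),
    longitudinal_like = list(
      name = "longitudinal", n_subjects = 90L, age_range = c(73, 82),
      waves = 2L, wave_gap = 10, twin_structure = "mixed_MZ_DZ")
  )
}

#' Simulate one cohort under a design
#'
#' Sample-level structure (subjects, twin pairs, ages, waves, cell
#' fractions) is drawn first from its own substream; per-CpG quantities
#' (baselines, cell effects, subject intercepts, residual noise) are drawn
#' CpG-contiguously so that the first k CpGs are identical whichever
#' `n_cpgs` is configured. Twins share age and sex; repeated waves reuse
#' the subject intercept and advance age by the wave gap.
#'
#' @param manifest a `cpg_manifest` from [simulate_manifest()] (supplies the
#'   CGI relation that sets each CpG's baseline M).
#' @param design a design list as returned by [cohort_presets()]: fields
#'   `name`, `n_subjects`, `age_range` or `age_clusters`, `waves`,
#'   `wave_gap`, `twin_structure` (`none`, `MZ_pairs`, `mixed_MZ_DZ`).
#' @param config a [sim_config()]; `config$n_cpgs` must match the manifest.
#' @return a list with `study` (a [methylation_study()]) and `truth` (see
#'   [simulate_truth()]).
#' @export
simulate_cohort <- function(manifest, design, config) {
  validate_sim_config(config)
  n_cpg <- nrow(manifest)
  check_that(n_cpg == config$n_cpgs,
             "manifest has %d CpGs but config$n_cpgs is %d", n_cpg, config$n_cpgs)
  check_that(design$waves >= 1L, "waves must be >= 1")
  n_subj <- as.integer(design$n_subjects)
  check_that(n_subj >= 1L, "n_subjects must be >= 1")
  twin <- match.arg(design$twin_structure, c("none", "MZ_pairs", "mixed_MZ_DZ"))
  cohort_name <- design$name %||% "cohort"

  truth <- simulate_truth(config)

  ## ---- sample-level structure -------------------------------------------
  set.seed(substream_seed(config$seed, paste0("samples-", cohort_name)))
  if (twin == "none") {
    pair_of <- rep("", n_subj)
    zygosity <- rep("NA", n_subj)
    unit_of <- seq_len(n_subj)          # age/sex drawn per subject
    n_units <- n_subj
  } else {
    check_that(n_subj %% 2L == 0L, "twin designs need an even n_subjects")
    n_units <- n_subj %/% 2L            # one unit per pair
    unit_of <- rep(seq_len(n_units), each = 2L)
    pair_of <- sprintf("P%04d", unit_of)
    zyg_unit <- if (twin == "MZ_pairs") rep("MZ", n_units) else
      ifelse(runif(n_units) < 18 / 43, "MZ", "DZ")
    zygosity <- zyg_unit[unit_of]
  }

  if (!is.null(design$age_clusters)) {
    cl <- design$age_clusters
    which_cl <- rep(seq_along(cl), length.out = n_units)
    lo <- vapply(cl, `[`, 0, 1)[which_cl]
    hi <- vapply(cl, `[`, 0, 2)[which_cl]
  } else {
    lo <- rep(design$age_range[1], n_units)
    hi <- rep(design$age_range[2], n_units)
  }
  age_unit <- lo + runif(n_units) * (hi - lo)
  sex_unit <- ifelse(runif(n_units) < 0.5, "F", "M")
  age0 <- age_unit[unit_of]
  sex <- sex_unit[unit_of]
  check_that(all(age0 > 0), "ages must be > 0")

  waves <- rep(seq_len(design$waves), times = n_subj)
  subj_idx <- rep(seq_len(n_subj), each = design$waves)
  n_samp <- length(subj_idx)
  age <- age0[subj_idx] + (waves - 1L) * (design$wave_gap %||% 0)
  sheet <- tibble::tibble(
    sample_id = sprintf("%s_S%04d_w%d", cohort_name, subj_idx, waves),
    subject_id = sprintf("%s_S%04d", cohort_name, subj_idx),
    pair_id = pair_of[subj_idx],
    zygosity = zygosity[subj_idx],
    age = age,
    sex = sex[subj_idx],
    cohort = cohort_name,
    wave = waves
  )
  cells <- rdirichlet(n_samp, config$cell_concentration)
  dimnames(cells) <- list(sheet$sample_id, CELL_TYPES)

  ## ---- per-CpG quantities, CpG-contiguous streams -----------------------
  set.seed(substream_seed(config$seed, paste0("cell-effects-", cohort_name)))
  gamma <- matrix(qnorm(runif(6 * n_cpg)) * config$cell_effect_sd, nrow = 6)
  set.seed(substream_seed(config$seed, paste0("subject-effects-", cohort_name)))
  u_sub <- matrix(qnorm(runif(n_subj * n_cpg)) * config$subject_sd, nrow = n_subj)
  set.seed(substream_seed(config$seed, paste0("noise-", cohort_name)))
  eps <- matrix(qnorm(runif(n_samp * n_cpg)) * config$noise_sd, nrow = n_samp)

  mu <- config$baseline_m_by_cgi[manifest$cgi_relation]
  M <- matrix(mu, nrow = n_samp, ncol = n_cpg, byrow = TRUE) +
    outer(sheet$age, truth$true_slope) +
    cells %*% gamma +
    u_sub[subj_idx, , drop = FALSE] +
    eps
  beta <- 1 / (1 + 2^(-M))
  dimnames(beta) <- list(sheet$sample_id, manifest$cpg_id)

  list(study = methylation_study(beta, sheet, cells), truth = truth)
}

#' Simulate a gene-set collection over a manifest's gene pool
#'
#' Draws gene sets from the distinct nearest genes of a manifest, for
#' exercising over-representation analysis without external gene-set
#' databases.
#'
#' @param manifest a `cpg_manifest`.
#' @param n_sets number of sets.
#' @param size_range inclusive range of set sizes.
#' @param seed integer seed.
#' @return a gene-set collection tibble (see [read_gmt()]).
#' @export
simulate_gene_sets <- function(manifest, n_sets = 30, size_range = c(5, 40),
                               seed = 1L) {
  pool <- sort(unique(manifest$nearest_gene[nzchar(manifest$nearest_gene)]))
  check_that(length(pool) >= size_range[2],
             "gene pool (%d) smaller than the largest set size (%d)",
             length(pool), size_range[2])
  set.seed(substream_seed(seed, "gene-sets"))
  sizes <- sample(seq(size_range[1], size_range[2]), n_sets, replace = TRUE)
  tibble::tibble(
    set_name = sprintf("SET%03d", seq_len(n_sets)),
    description = sprintf("synthetic gene set %d", seq_len(n_sets)),
    genes = lapply(sizes, function(s) sort(sample(pool, s)))
  )
}
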