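#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run: simulation scale,
#' significance thresholds, permutation depth, enrichment conventions and
#' the single global seed from which each stage derives its own substream.
#'
#' @param out_dir directory for stage artifacts (created if needed).
#' @param seed global integer seed.
#' @param n_cpgs number of simulated CpGs.
#' @param K permutations for the minP null (>= 20).
#' @param alpha_fwer discovery threshold, FWER < alpha_fwer (strict).
#' @param alpha_replication per-cohort replication threshold, p < alpha
#'   (strict).
#' @param tail hypergeometric tail convention, `"gt"` or `"ge"`.
#' @param top_sets number of top gene sets reported per direction.
#' @param sim optional [sim_config()] overriding the default generator
#'   settings (its `n_cpgs`/`seed` are taken from this configuration).
#' @param gmt_path optional GMT file; when `NULL` a synthetic collection is
#'   generated from the manifest's gene pool.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, n_cpgs = 2000, K = 300,
                            alpha_fwer = 0.05, alpha_replication = 0.05,
                            tail = c("gt", "ge"), top_sets = 50,
                            sim = NULL, gmt_path = NULL) {
  tail <- match.arg(tail)
  check_that(alpha_fwer > 0 && alpha_fwer < 1, "alpha_fwer must lie in (0,1)")
  check_that(alpha_replication > 0 && alpha_replication < 1,
             "alpha_replication must lie in (0,1)")
  check_that(K >= 20, "K must be >= 20 (FWER resolution is 1/K)")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_cpgs = as.integer(n_cpgs), K = as.integer(K),
                 alpha_fwer = alpha_fwer, alpha_replication = alpha_replication,
                 tail = tail, top_sets = top_sets, sim = sim,
                 gmt_path = gmt_path),
            class = "pipeline_config")
}

pipeline_paths <- function(out_dir) {
  file.path(out_dir, c(
    manifest = "manifest.tsv", truth = "truth_table.csv",
    gmt = "gene_sets.gmt",
    ewas = "ewas_results.tsv", null = "null_minp.tsv",
    ledger = "replication_ledger.tsv",
    region = "region_counts.tsv", cgi = "cgi_counts.tsv",
    crosstab = "region_by_cgi.tsv", prop = "proportionality.tsv",
    enrich_gain = "enrichment_gain.tsv", enrich_loss = "enrichment_loss.tsv",
    report = "run_report.json")) |>
    setNames(c("manifest", "truth", "gmt", "ewas", "null", "ledger",
               "region", "cgi", "crosstab", "prop",
               "enrich_gain", "enrich_loss", "report"))
}

study_paths <- function(out_dir, cohort) {
  file.path(out_dir, paste0(cohort, c("_beta.tsv", "_sheet.csv", "_cells.csv"))) |>
    setNames(c("beta", "sheet", "cells"))
}

#' Run the full pipeline: simulate, EWAS, replicate, characterize, enrich
#'
#' Stages run in order, each writing its artifacts under
#' `config$out_dir`; later stages read earlier artifacts from disk, so any
#' suffix of the stage list can be re-run in isolation against an existing
#' run directory. A JSON run report records seeds, artifact checksums and
#' the counts at every stage (discovery-significant, replicated per
#' cohort, double-replicated, gains/losses); every reported count is
#' re-derived from the written TSVs and cross-checked before the report is
#' written. The subset chain (double-replicated within each cohort's
#' replicated set within the discovery set) is asserted on every run.
#'
#' @param config a [pipeline_config()].
#' @param stages character subset of
#'   `c("simulate", "ewas", "replicate", "characterize", "enrich")`
#'   (order fixed); default all.
#' @return invisibly, a list with the stage results and the report.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "ewas", "replicate",
                                    "characterize", "enrich")) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- pipeline_paths(config$out_dir)
  presets <- cohort_presets()
  report <- list(seed = config$seed, n_cpgs = config$n_cpgs, K = config$K,
                 alpha_fwer = config$alpha_fwer,
                 alpha_replication = config$alpha_replication,
                 package_version = as.character(utils::packageVersion("agewas")))

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  ## ---- simulate ---------------------------------------------------------
  if ("simulate" %in% stages) {
    run_stage("simulate", function() {
      sim <- config$sim %||% sim_config()
      sim$n_cpgs <- config$n_cpgs
      sim$seed <- substream_seed(config$seed, "simulate")
      validate_sim_config(sim)
      manifest <- simulate_manifest(sim)
      write_manifest(manifest, paths["manifest"])
      readr::write_csv(simulate_truth(sim), paths["truth"], progress = FALSE)
      for (p in names(presets)) {
        cohort <- simulate_cohort(manifest, presets[[p]], sim)
        sp <- study_paths(config$out_dir, presets[[p]]$name)
        write_study(cohort$study, sp["beta"], sp["sheet"], sp["cells"])
      }
      if (is.null(config$gmt_path)) {
        pool_n <- sum(nzchar(unique(manifest$nearest_gene)))
        size_hi <- max(3, min(25, pool_n %/% 2))
        write_gmt(simulate_gene_sets(manifest, n_sets = 30,
                                     size_range = c(min(3, size_hi), size_hi),
                                     seed = substream_seed(config$seed, "gene-sets")),
                  paths["gmt"])
      } else {
        file.copy(config$gmt_path, paths["gmt"], overwrite = TRUE)
      }
      invisible(NULL)
    })
  }

  manifest <- read_manifest(paths["manifest"])

  ## ---- ewas -------------------------------------------------------------
  if ("ewas" %in% stages) {
    run_stage("ewas", function() {
      sp <- study_paths(config$out_dir, "discovery")
      study <- read_study(sp["beta"], sp["sheet"], sp["cells"])
      fit <- run_ewas(study, manifest, K = config$K,
                      alpha_fwer = config$alpha_fwer,
                      seed = substream_seed(config$seed, "ewas"))
      readr::write_tsv(fit$results, paths["ewas"], progress = FALSE)
      readr::write_tsv(tibble::tibble(perm = seq_along(fit$null$min_p),
                                      min_p = fit$null$min_p),
                       paths["null"], progress = FALSE)
      invisible(NULL)
    })
  }

  ewas_results <- readr::read_tsv(paths["ewas"], show_col_types = FALSE,
                                  progress = FALSE)
  sig <- significant_cpgs(ewas_results, config$alpha_fwer)

  ## ---- replicate --------------------------------------------------------
  if ("replicate" %in% stages) {
    run_stage("replicate", function() {
      if (nrow(sig) == 0) {
        ledger <- tibble::tibble(cpg_id = character(),
                                 discovery_direction = character(),
                                 slope_a = double(), p_a = double(),
                                 replicated_a = logical(),
                                 slope_b = double(), p_b = double(),
                                 replicated_b = logical(),
                                 double_replicated = logical())
      } else {
        spx <- study_paths(config$out_dir, "cross_sectional")
        spl <- study_paths(config$out_dir, "longitudinal")
        cross <- read_study(spx["beta"], spx["sheet"], spx["cells"])
        long <- read_study(spl["beta"], spl["sheet"], spl["cells"])
        rep_a <- replicate_cohort(sig, cross, cluster_by = "pair",
                                  alpha = config$alpha_replication)
        rep_b <- replicate_cohort(sig, long, cluster_by = "subject",
                                  alpha = config$alpha_replication)
        ledger <- replication_ledger(sig, rep_a, rep_b)$ledger
      }
      readr::write_tsv(ledger, paths["ledger"], progress = FALSE)
      invisible(NULL)
    })
  }

  ledger_cols <- readr::cols(
    cpg_id = readr::col_character(), discovery_direction = readr::col_character(),
    slope_a = readr::col_double(), p_a = readr::col_double(),
    replicated_a = readr::col_logical(), slope_b = readr::col_double(),
    p_b = readr::col_double(), replicated_b = readr::col_logical(),
    double_replicated = readr::col_logical())
  ledger <- readr::read_tsv(paths["ledger"], col_types = ledger_cols,
                            progress = FALSE)
  ## subset chain: double-replicated within each replicated set within discovery
  check_that(all(ledger$cpg_id %in% sig$cpg_id),
             "ledger contains CpGs outside the discovery-significant set")
  check_that(all(!ledger$double_replicated |
                   (ledger$replicated_a & ledger$replicated_b)),
             "double-replicated set must lie inside both replicated sets")
  double_set <- ledger |>
    dplyr::filter(.data$double_replicated) |>
    dplyr::transmute(cpg_id = .data$cpg_id, direction = .data$discovery_direction)

  ## ---- characterize -----------------------------------------------------
  if ("characterize" %in% stages) {
    run_stage("characterize", function() {
      by_region <- tabulate_by_region(double_set, manifest)
      by_cgi <- tabulate_by_cgi(double_set, manifest)
      crosstab <- crosstab_region_by_cgi(double_set, manifest)
      readr::write_tsv(by_region$direction, paths["region"], progress = FALSE)
      readr::write_tsv(by_cgi$direction, paths["cgi"], progress = FALSE)
      readr::write_tsv(crosstab, paths["crosstab"], progress = FALSE)
      prop <- dplyr::bind_rows(
        dplyr::mutate(by_region$proportionality, breakdown = "gene_region"),
        dplyr::mutate(by_cgi$proportionality, breakdown = "cgi_relation"))
      readr::write_tsv(prop, paths["prop"], progress = FALSE)
      invisible(NULL)
    })
  }

  ## ---- enrich -----------------------------------------------------------
  if ("enrich" %in% stages) {
    run_stage("enrich", function() {
      collection <- read_gmt(paths["gmt"])
      universe <- sort(unique(manifest$nearest_gene[nzchar(manifest$nearest_gene)]))
      for (dir_label in c("gain", "loss")) {
        ids <- double_set$cpg_id[double_set$direction == dir_label]
        genes <- if (length(ids)) cpgs_to_genes(ids, manifest) else character()
        enr <- run_enrichment(genes, universe, collection, tail = config$tail,
                              top = config$top_sets)
        readr::write_tsv(tidy(enr),
                         paths[paste0("enrich_", dir_label)], progress = FALSE)
      }
      invisible(NULL)
    })
  }

  ## ---- run report, cross-checked against the written TSVs ---------------
  counts <- list(
    n_cpgs_manifest = nrow(manifest),
    n_autosomal = sum(!manifest$chromosome %in% c("X", "Y")),
    n_scanned = nrow(ewas_results),
    n_discovery_significant = nrow(sig),
    n_discovery_gain = sum(sig$direction == "gain"),
    n_discovery_loss = sum(sig$direction == "loss"),
    n_replicated_cross_sectional = sum(ledger$replicated_a, na.rm = TRUE),
    n_replicated_longitudinal = sum(ledger$replicated_b, na.rm = TRUE),
    n_double_replicated = nrow(double_set),
    n_double_gain = sum(double_set$direction == "gain"),
    n_double_loss = sum(double_set$direction == "loss")
  )
  recheck <- readr::read_tsv(paths["ledger"], col_types = ledger_cols,
                             progress = FALSE)
  check_that(sum(recheck$double_replicated, na.rm = TRUE) ==
               counts$n_double_replicated,
             "run report count does not match the written ledger")
  artifacts <- list.files(config$out_dir, pattern = "\\.(tsv|csv|gmt)$",
                          full.names = TRUE)
  report <- c(report, counts,
              list(artifact_md5 = as.list(tools::md5sum(artifacts)),
                   substream_seeds = list(
                     simulate = substream_seed(config$seed, "simulate"),
                     ewas = substream_seed(config$seed, "ewas"))))
  jsonlite::write_json(report, paths["report"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(counts = counts, report = report, paths = paths))
}
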