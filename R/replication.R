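#' Mixed-model fit of methylation on age for one CpG
#'
#' Validation cohorts are clustered -- twin pairs in a cross-sectional
#' design, repeated measures per individual in a longitudinal one -- so the
#' age effect is estimated by a linear mixed model with fixed effects
#' intercept + age + five cell fractions and one random intercept per
#' cluster, fitted by REML ([lme4::lmer()]). The p-value is a two-sided
#' Wald test on the age coefficient (normal reference).
#'
#' If the mixed model fails to converge (or every cluster has a single
#' sample, where the random intercept is unidentifiable), the fit falls
#' back to OLS on cluster-aggregated data (one mean per cluster), flagged
#' in the output.
#'
#' @param m per-sample M-values.
#' @param age per-sample ages (years).
#' @param cells samples x 6 cell-fraction matrix.
#' @param cluster grouping labels (pair id or subject id).
#' @return one-row tibble: `slope`, `se`, `p`, `fallback` (logical).
#' @export
fit_cpg_lmm <- function(m, age, cells, cluster) {
  cluster <- as.character(cluster)
  check_that(dplyr::n_distinct(cluster) >= 2, "need >= 2 clusters")
  check_that(all(table(cluster) >= 1), "every cluster must be non-empty")
  dat <- data.frame(m = m, age = age,
                    cells[, setdiff(CELL_TYPES, "Gran"), drop = FALSE],
                    cluster = cluster)
  cell_terms <- paste(setdiff(CELL_TYPES, "Gran"), collapse = " + ")
  if (max(table(cluster)) == 1L) {
    return(cluster_ols_fallback(dat, cell_terms))
  }
  fml <- stats::as.formula(paste("m ~ age +", cell_terms, "+ (1 | cluster)"))
  fit <- tryCatch(
    suppressMessages(lme4::lmer(fml, data = dat, REML = TRUE,
                                control = lme4::lmerControl(calc.derivs = FALSE,
                                                            check.conv.singular = "ignore"))),
    error = function(e) NULL)
  if (is.null(fit)) return(cluster_ols_fallback(dat, cell_terms))
  cf <- coef(summary(fit))
  slope <- cf["age", "Estimate"]
  se <- cf["age", "Std. Error"]
  p <- 2 * pnorm(-abs(slope / se))
  tibble::tibble(slope = slope, se = se, p = max(p, .Machine$double.xmin),
                 fallback = FALSE)
}

## OLS on one mean per cluster; the stated fallback when the mixed model
## cannot be fitted. With singleton clusters it coincides with plain OLS.
cluster_ols_fallback <- function(dat, cell_terms) {
  agg <- stats::aggregate(dat[setdiff(names(dat), "cluster")],
                          by = list(cluster = dat$cluster), FUN = mean)
  fml <- stats::as.formula(paste("m ~ age +", cell_terms))
  fit <- stats::lm(fml, data = agg)
  cf <- coef(summary(fit))
  tibble::tibble(slope = cf["age", "Estimate"], se = cf["age", "Std. Error"],
                 p = max(cf["age", "Pr(>|t|)"], .Machine$double.xmin),
                 fallback = TRUE)
}

#' Replicate discovery CpGs in one validation cohort
#'
#' Each discovery-significant CpG is refitted in the validation cohort by
#' [fit_cpg_lmm()]; it replicates when the validation slope has the same
#' sign as the discovery slope AND the validation p-value is strictly below
#' `alpha`. CpGs absent from the validation array are recorded as not
#' testable (`testable = FALSE`, excluded from rate denominators), not as
#' failures.
#'
#' @param discovery tibble of discovery-significant CpGs (needs `cpg_id`
#'   and `direction`; see [significant_cpgs()]).
#' @param validation_study a [methylation_study()] for the validation
#'   cohort.
#' @param cluster_by `"pair"` (random intercept per twin pair) or
#'   `"subject"` (per individual, for longitudinal repeated measures).
#' @param alpha replication significance threshold (strict), default 0.05.
#' @return a tibble: `cpg_id`, `discovery_direction`, `slope`, `p`,
#'   `fallback`, `testable`, `replicated`.
#' @export
replicate_cohort <- function(discovery, validation_study,
                             cluster_by = c("pair", "subject"), alpha = 0.05) {
  check_that(nrow(discovery) > 0, "discovery set is empty")
  cluster_by <- match.arg(cluster_by)
  cluster <- switch(cluster_by,
                    pair = validation_study$sheet$pair_id,
                    subject = validation_study$sheet$subject_id)
  check_that(all(nzchar(cluster)), "empty %s ids in validation sheet", cluster_by)
  age <- validation_study$sheet$age
  cells <- validation_study$cells
  present <- discovery$cpg_id %in% colnames(validation_study$beta)
  M <- beta_to_m(validation_study$beta[, discovery$cpg_id[present], drop = FALSE])

  fits <- purrr::map_dfr(seq_len(ncol(M)), function(j) {
    fit_cpg_lmm(M[, j], age, cells, cluster)
  })
  out <- tibble::tibble(cpg_id = discovery$cpg_id,
                        discovery_direction = discovery$direction,
                        slope = NA_real_, p = NA_real_, fallback = NA,
                        testable = present)
  out$slope[present] <- fits$slope
  out$p[present] <- fits$p
  out$fallback[present] <- fits$fallback
  sign_match <- ifelse(out$discovery_direction == "gain",
                       out$slope > 0, out$slope < 0)
  out$replicated <- out$testable & sign_match & out$p < alpha
  out$replicated[!out$testable] <- FALSE
  out
}

#' Combine two cohort replications into a replication ledger
#'
#' @param discovery discovery-significant tibble (see [replicate_cohort()]).
#' @param cohort_a,cohort_b results of [replicate_cohort()] for the two
#'   validation cohorts (conventionally the cross-sectional and the
#'   longitudinal cohort).
#' @param names_ab character(2), labels for the two cohorts.
#' @return an `agewas_replication` object: per-CpG ledger tibble plus the
#'   double-replicated subset. `double_replicated` is the intersection of
#'   the two cohorts' replicated sets; direction is taken from discovery.
#' @export
replication_ledger <- function(discovery, cohort_a, cohort_b,
                               names_ab = c("cross_sectional", "longitudinal")) {
  check_that(identical(cohort_a$cpg_id, discovery$cpg_id) &&
               identical(cohort_b$cpg_id, discovery$cpg_id),
             "cohort results must be aligned with the discovery set")
  ledger <- tibble::tibble(
    cpg_id = discovery$cpg_id,
    discovery_direction = discovery$direction,
    slope_a = cohort_a$slope, p_a = cohort_a$p, replicated_a = cohort_a$replicated,
    slope_b = cohort_b$slope, p_b = cohort_b$p, replicated_b = cohort_b$replicated,
    double_replicated = cohort_a$replicated & cohort_b$replicated
  )
  structure(list(ledger = ledger, cohort_names = names_ab),
            class = "agewas_replication")
}

#' Double-replicated CpGs, split by direction
#'
#' @param x an `agewas_replication` object.
#' @return tibble of double-replicated CpGs with `cpg_id` and `direction`
#'   (from discovery).
#' @export
double_replicate <- function(x) {
  x$ledger |>
    dplyr::filter(.data$double_replicated) |>
    dplyr::transmute(cpg_id = .data$cpg_id,
                     direction = .data$discovery_direction)
}

#' Replication and overlap rates
#'
#' Per-cohort replication rate = replicated / discovery-significant x 100
#' (not-testable CpGs are excluded from both counts). The overlap rate is
#' the double-replicated count divided by the smaller cohort's replicated
#' count, x 100. Zero denominators yield `NA` (undefined), never 0.
#'
#' @param x an `agewas_replication` object.
#' @return one-row tibble: `n_discovery`, `n_replicated_a`,
#'   `n_replicated_b`, `n_double`, `rate_a`, `rate_b`, `overlap_rate` (all
#'   rates in percent).
#' @export
replication_rates <- function(x) {
  l <- x$ledger
  n_disc_a <- sum(!is.na(l$p_a))
  n_disc_b <- sum(!is.na(l$p_b))
  n_a <- sum(l$replicated_a, na.rm = TRUE)
  n_b <- sum(l$replicated_b, na.rm = TRUE)
  n_double <- sum(l$double_replicated, na.rm = TRUE)
  tibble::tibble(
    n_discovery = nrow(l),
    n_replicated_a = n_a, n_replicated_b = n_b, n_double = n_double,
    rate_a = pct_of(n_a, n_disc_a),
    rate_b = pct_of(n_b, n_disc_b),
    overlap_rate = pct_of(n_double, min(n_a, n_b))
  )
}

#' @export
print.agewas_replication <- function(x, ...) {
  r <- replication_rates(x)
  cat(sprintf(paste0("<agewas_replication> %d discovery CpGs\n",
                     "  %s: %d replicated (%.1f%%); %s: %d replicated (%.1f%%)\n",
                     "  double-replicated: %d (overlap rate %.1f%%)\n"),
              r$n_discovery, x$cohort_names[1], r$n_replicated_a, r$rate_a,
              x$cohort_names[2], r$n_replicated_b, r$rate_b,
              r$n_double, r$overlap_rate))
  invisible(x)
}

#' @export
tidy.agewas_replication <- function(x, ...) x$ledger

#' @export
glance.agewas_replication <- function(x, ...) replication_rates(x)

#' Percentage overlap between two CpG (or gene) id sets
#'
#' Counts how many elements of `query` are present in `reference` and
#' reports the percentage of the query covered -- the statistic used to
#' compare a replicated CpG set against published methylation-clock CpG
#' lists.
#'
#' @param query character vector of ids (e.g. a clock's CpG list).
#' @param reference character vector of ids (e.g. the double-replicated
#'   set).
#' @return one-row tibble: `n_query`, `n_overlap`, `pct_overlap`.
#' @export
set_overlap <- function(query, reference) {
  query <- unique(query)
  k <- sum(query %in% reference)
  tibble::tibble(n_query = length(query), n_overlap = k,
                 pct_overlap = pct_of(k, length(query)))
}

#' Discovery-vs-validation effect plot
#'
#' @param object an `agewas_replication` object.
#' @param discovery_slopes optional named vector of discovery slopes
#'   (names = cpg_id) to place on the x axis; when absent, cohort A slopes
#'   are plotted against cohort B slopes.
#' @param ... unused.
#' @return a ggplot highlighting replicated and double-replicated CpGs.
#' @export
autoplot.agewas_replication <- function(object, discovery_slopes = NULL, ...) {
  l <- object$ledger |>
    dplyr::mutate(status = dplyr::case_when(
      .data$double_replicated ~ "double-replicated",
      .data$replicated_a | .data$replicated_b ~ "replicated once",
      TRUE ~ "not replicated"))
  if (!is.null(discovery_slopes)) {
    l$x <- unname(discovery_slopes[l$cpg_id])
    xlab <- "discovery slope (M-units/year)"
  } else {
    l$x <- l$slope_a
    xlab <- sprintf("%s slope (M-units/year)", object$cohort_names[1])
  }
  ggplot2::ggplot(l, ggplot2::aes(x = .data$x, y = .data$slope_b,
                                  colour = .data$status)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_point(alpha = 0.7, size = 0.9) +
    ggplot2::scale_colour_manual(values = c(`double-replicated` = "#d73027",
                                            `replicated once` = "#4575b4",
                                            `not replicated` = "grey70")) +
    ggplot2::labs(x = xlab,
                  y = sprintf("%s slope (M-units/year)", object$cohort_names[2]),
                  colour = NULL) +
    ggplot2::theme_minimal()
}
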