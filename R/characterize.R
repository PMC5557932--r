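#' Gain-versus-loss direction-bias chi-square
#'
#' Tests whether age-methylated (gain) and age-demethylated (loss) CpGs in
#' a category occur equally often. Implemented as the Yates-continuity-
#' corrected chi-square of the symmetric 2x2 table `[[gain, loss], [loss,
#' gain]]`, which has the closed form
#' \deqn{\chi^2 = 8\,(\max(|k_\mathrm{gain} - n/2| - 0.5,\,0))^2 / n}
#' with n = gain + loss, referred to the upper tail of chi-square with one
#' degree of freedom. The statistic is symmetric in (gain, loss) and floors
#' at 0 for a perfectly balanced split.
#'
#' @param k_gain,k_loss counts of gain and loss CpGs (vectorized).
#' @return a tibble with `chisq` and `p`.
#' @export
#' @examples
#' direction_bias_chisq(374, 114)   # chisq 274.92
#' direction_bias_chisq(1554, 128)  # chisq 2414.54
direction_bias_chisq <- function(k_gain, k_loss) {
  n <- k_gain + k_loss
  check_that(all(n >= 1), "need at least one CpG (k_gain + k_loss >= 1)")
  chisq <- 8 * pmax(abs(k_gain - n / 2) - 0.5, 0)^2 / n
  tibble::tibble(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Proportionality test against the whole-array background
#'
#' Compares the proportion of a CpG group falling in a category with the
#' category's whole-array proportion, as a two-sample 2x2 chi-square with
#' Yates continuity correction (upper tail, 1 df). When any expected cell
#' is below 1 the p-value is flagged unreliable but still returned.
#'
#' @param k_group CpGs of the group in the category.
#' @param n_group group size.
#' @param k_array array CpGs in the category.
#' @param n_array array size.
#' @return a tibble with `chisq`, `p` and `reliable`.
#' @export
proportionality_test <- function(k_group, n_group, k_array, n_array) {
  check_that(all(n_group >= 1) && all(n_array >= 1),
             "group and array sizes must be >= 1")
  purrr::pmap_dfr(list(k_group, n_group, k_array, n_array),
                  function(kg, ng, ka, na) {
    tab <- matrix(c(kg, ng - kg, ka, na - ka), nrow = 2, byrow = TRUE)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    tibble::tibble(chisq = unname(ct$statistic), p = unname(ct$p.value),
                   reliable = all(expected >= 1))
  })
}

## Internal shared tabulator: `membership` is a tibble (cpg_id, category)
## possibly with several rows per CpG (multi-label regions) or exactly one
## (CGI relation). `array_membership` is the same for the whole manifest.
tabulate_directions <- function(cpgs, membership, array_membership, categories) {
  joined <- dplyr::inner_join(cpgs, membership, by = "cpg_id")
  counts <- joined |>
    dplyr::count(.data$category, .data$direction) |>
    tidyr::pivot_wider(names_from = "direction", values_from = "n",
                       values_fill = 0L)
  for (col in c("gain", "loss")) if (!col %in% names(counts)) counts[[col]] <- 0L
  counts <- tibble::tibble(category = categories) |>
    dplyr::left_join(counts, by = "category") |>
    dplyr::mutate(k_gain = dplyr::coalesce(.data$gain, 0L),
                  k_loss = dplyr::coalesce(.data$loss, 0L),
                  n = .data$k_gain + .data$k_loss) |>
    dplyr::select("category", "n", "k_gain", "k_loss")

  tested <- counts$n > 0
  counts$prop_gain <- ifelse(tested, counts$k_gain / counts$n, NA_real_)
  counts$prop_loss <- ifelse(tested, counts$k_loss / counts$n, NA_real_)
  counts$chisq <- NA_real_
  counts$p <- NA_real_
  if (any(tested)) {
    db <- direction_bias_chisq(counts$k_gain[tested], counts$k_loss[tested])
    counts$chisq[tested] <- db$chisq
    counts$p[tested] <- db$p
  }

  array_counts <- array_membership |>
    dplyr::count(.data$category, name = "k_array")
  n_array <- dplyr::n_distinct(array_membership$cpg_id)
  n_gain <- sum(cpgs$direction == "gain")
  n_loss <- sum(cpgs$direction == "loss")
  prop <- tidyr::expand_grid(category = categories,
                             group = c("gain", "loss")) |>
    dplyr::left_join(array_counts, by = "category") |>
    dplyr::mutate(k_array = dplyr::coalesce(.data$k_array, 0L)) |>
    dplyr::left_join(dplyr::select(counts, "category", "k_gain", "k_loss"),
                     by = "category") |>
    dplyr::mutate(
      k_group = ifelse(.data$group == "gain", .data$k_gain, .data$k_loss),
      n_group = ifelse(.data$group == "gain", n_gain, n_loss),
      p_group = ifelse(.data$n_group > 0, .data$k_group / .data$n_group, NA_real_),
      p_array = .data$k_array / n_array
    ) |>
    dplyr::select("category", "group", "k_group", "n_group", "k_array",
                  "p_group", "p_array")
  testable <- prop$n_group > 0
  prop$chisq <- NA_real_
  prop$p <- NA_real_
  prop$reliable <- NA
  if (any(testable)) {
    pt_res <- proportionality_test(prop$k_group[testable], prop$n_group[testable],
                                   prop$k_array[testable], n_array)
    prop$chisq[testable] <- pt_res$chisq
    prop$p[testable] <- pt_res$p
    prop$reliable[testable] <- pt_res$reliable
  }
  list(direction = counts, proportionality = prop)
}

check_in_manifest <- function(cpgs, manifest) {
  miss <- setdiff(cpgs$cpg_id, manifest$cpg_id)
  check_that(length(miss) == 0, "CpG(s) absent from manifest: %s",
             paste(head(miss, 5), collapse = ", "))
}

#' Characterize replicated CpGs by gene region
#'
#' Counts gains and losses per gene-region label -- a CpG contributes one
#' count to every label it carries (multi-label membership, so region
#' totals can exceed the set size) -- and runs two tests per region: the
#' gain-vs-loss [direction_bias_chisq()] and, separately for the gain and
#' the loss set, the [proportionality_test()] of the region's share in the
#' set against its whole-array share.
#'
#' @param cpgs tibble with `cpg_id` and `direction` (`gain`/`loss`), e.g.
#'   the double-replicated set from [double_replicate()].
#' @param manifest a `cpg_manifest` containing every CpG of `cpgs`.
#' @return list of two tibbles: `direction` (per region: `n`, `k_gain`,
#'   `k_loss`, proportions, `chisq`, `p`) and `proportionality` (per region
#'   x group: `p_group`, `p_array`, `chisq`, `p`, `reliable`).
#' @export
tabulate_by_region <- function(cpgs, manifest) {
  check_in_manifest(cpgs, manifest)
  membership <- manifest |>
    dplyr::select("cpg_id", "gene_regions") |>
    tidyr::unnest_longer("gene_regions", values_to = "category")
  tabulate_directions(cpgs, membership, membership, GENE_REGION_LABELS)
}

#' Characterize replicated CpGs by CpG-island relation
#'
#' As [tabulate_by_region()] but over the single-label CGI relation
#' (Island, N/S shore, N/S shelf, non-CGI); category totals partition the
#' input set.
#'
#' @inheritParams tabulate_by_region
#' @return list of two tibbles, as in [tabulate_by_region()].
#' @export
tabulate_by_cgi <- function(cpgs, manifest) {
  check_in_manifest(cpgs, manifest)
  membership <- tibble::tibble(cpg_id = manifest$cpg_id,
                               category = manifest$cgi_relation)
  tabulate_directions(cpgs, membership, membership, CGI_LABELS)
}

#' Cross-tabulate gene region by collapsed CGI group
#'
#' CGI relations are collapsed to three groups -- Island to `CGI`, the
#' shores and shelves to `Shore/Shelf`, open sea to `non-CGI` -- and gains
#' and losses are counted in every (region x group) cell with multi-label
#' region counting. The per-cell gain proportion and direction-bias p-value
#' show whether age-related methylation gain concentrates at islands
#' within each gene region.
#'
#' @inheritParams tabulate_by_region
#' @return tibble: `region`, `cgi_group`, `k_gain`, `k_loss`, `prop_gain`,
#'   `p` (direction-bias; `NA` for empty cells).
#' @export
crosstab_region_by_cgi <- function(cpgs, manifest) {
  check_in_manifest(cpgs, manifest)
  cgi_group <- c(Island = "CGI", N_Shore = "Shore/Shelf", S_Shore = "Shore/Shelf",
                 N_Shelf = "Shore/Shelf", S_Shelf = "Shore/Shelf",
                 `non-CGI` = "non-CGI")
  membership <- manifest |>
    dplyr::select("cpg_id", "gene_regions", "cgi_relation") |>
    tidyr::unnest_longer("gene_regions", values_to = "region") |>
    dplyr::mutate(cgi_group = cgi_group[.data$cgi_relation])
  joined <- dplyr::inner_join(cpgs, membership, by = "cpg_id")
  grid <- tidyr::expand_grid(region = GENE_REGION_LABELS,
                             cgi_group = c("non-CGI", "Shore/Shelf", "CGI"))
  out <- joined |>
    dplyr::count(.data$region, .data$cgi_group, .data$direction) |>
    tidyr::pivot_wider(names_from = "direction", values_from = "n",
                       values_fill = 0L)
  for (col in c("gain", "loss")) if (!col %in% names(out)) out[[col]] <- 0L
  out <- grid |>
    dplyr::left_join(out, by = c("region", "cgi_group")) |>
    dplyr::mutate(k_gain = dplyr::coalesce(.data$gain, 0L),
                  k_loss = dplyr::coalesce(.data$loss, 0L),
                  n = .data$k_gain + .data$k_loss,
                  prop_gain = ifelse(.data$n > 0, .data$k_gain / .data$n, NA_real_)) |>
    dplyr::select("region", "cgi_group", "n", "k_gain", "k_loss", "prop_gain")
  out$p <- NA_real_
  tested <- out$n > 0
  if (any(tested)) {
    out$p[tested] <- direction_bias_chisq(out$k_gain[tested], out$k_loss[tested])$p
  }
  out
}

#' Share of all gains (and losses) per category
#'
#' For each category of a direction-count table, the percentage of all gain
#' CpGs and of all loss CpGs falling in that category (e.g. "gains
#' concentrate at 1stExon: 18.44% of gains vs 3.63% of losses"). Zero
#' totals yield `NA` (undefined), never 0.
#'
#' @param counts `direction` tibble from [tabulate_by_region()] or
#'   [tabulate_by_cgi()] (columns `category`, `k_gain`, `k_loss`).
#' @param n_gain_total,n_loss_total total gain and loss CpGs in the
#'   characterized set (category sums cannot be used: region membership is
#'   multi-label).
#' @return tibble: `category`, `share_gain_pct`, `share_loss_pct`.
#' @export
gain_share_summary <- function(counts, n_gain_total, n_loss_total) {
  tibble::tibble(
    category = counts$category,
    share_gain_pct = pct_of(counts$k_gain, n_gain_total),
    share_loss_pct = pct_of(counts$k_loss, n_loss_total)
  )
}

#' Plot direction composition by category
#'
#' @param counts a `direction` tibble from [tabulate_by_region()] or
#'   [tabulate_by_cgi()].
#' @param title plot title.
#' @return a stacked-bar ggplot of gain/loss counts per category.
#' @export
plot_direction_counts <- function(counts, title = NULL) {
  d <- counts |>
    dplyr::select("category", "k_gain", "k_loss") |>
    tidyr::pivot_longer(c("k_gain", "k_loss"), names_to = "direction",
                        values_to = "count") |>
    dplyr::mutate(direction = ifelse(.data$direction == "k_gain",
                                     "gain (age-methylated)",
                                     "loss (age-demethylated)"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$count,
                                  fill = .data$direction)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::scale_fill_manual(values = c(`gain (age-methylated)` = "#d73027",
                                          `loss (age-demethylated)` = "#4575b4")) +
    ggplot2::labs(x = NULL, y = "proportion", fill = NULL, title = title) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
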