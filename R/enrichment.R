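#' Map CpGs to their nearest genes
#'
#' @param cpg_ids character vector of CpG ids, all present in the manifest.
#' @param manifest a `cpg_manifest`.
#' @return sorted character vector of distinct non-empty nearest-gene
#'   symbols (CpGs without an annotated gene map to nothing).
#' @export
cpgs_to_genes <- function(cpg_ids, manifest) {
  idx <- match(cpg_ids, manifest$cpg_id)
  check_that(!anyNA(idx), "CpG(s) absent from manifest: %s",
             paste(head(cpg_ids[is.na(idx)], 5), collapse = ", "))
  sort(unique(manifest$nearest_gene[idx][nzchar(manifest$nearest_gene[idx])]))
}

#' Upper-tail hypergeometric probability for gene-set over-representation
#'
#' With N genes in the universe, m of them significant, and a gene set of
#' size n overlapping the significant genes in k, the over-representation
#' probability is
#' \deqn{p(X > k) = 1 - \sum_{r=0}^{k} \binom{m}{r}\binom{N-m}{n-r} / \binom{N}{n}}
#' i.e. the strictly-greater tail. The default keeps that strict
#' convention; `tail = "ge"` gives the more common `P(X >= k)`. The sum is
#' evaluated in log-space (complementary summation, log-binomials combined
#' by log-sum-exp), so tiny tail probabilities keep full relative accuracy.
#'
#' @param N universe size (genes annotated to CpGs on the array).
#' @param m genes annotated to the significant CpGs.
#' @param n genes in the set.
#' @param k genes both significant and in the set.
#' @param tail `"gt"` for `P(X > k)` (default) or `"ge"` for `P(X >= k)`.
#' @return the tail probability, a number in \[0,1\].
#' @export
#' @examples
#' hypergeom_upper(4, 2, 2, 0)  # 1 - 1/6
hypergeom_upper <- function(N, m, n, k, tail = c("gt", "ge")) {
  tail <- match.arg(tail)
  check_that(all(c(N, m, n, k) >= 0) && m <= N && n <= N,
             "need 0 <= m, n <= N and k >= 0")
  check_that(k <= min(m, n), "k must not exceed min(m, n)")
  lo <- if (tail == "gt") k + 1L else k
  r_max <- min(m, n)
  r_min <- max(lo, 0L, n - (N - m))  # impossible r contribute nothing
  if (r_min > r_max) return(0)
  r <- seq.int(r_min, r_max)
  logterms <- lchoose(m, r) + lchoose(N - m, n - r) - lchoose(N, n)
  mx <- max(logterms)
  min(1, exp(mx + log(sum(exp(logterms - mx)))))
}

#' Hypergeometric over-representation analysis of gene sets
#'
#' For every gene set: intersect with the universe to get n, overlap with
#' the significant gene list to get k, and compute the upper-tail
#' probability of [hypergeom_upper()]. Genes of the list absent from the
#' universe are dropped (with a message). Results are sorted by p, ties
#' broken by larger overlap k then set name, so the ordering is
#' deterministic.
#'
#' @param gene_list character vector of significant genes (e.g. from
#'   [cpgs_to_genes()]).
#' @param universe character vector of all eligible genes (conventionally
#'   every distinct nearest gene of the analysed manifest).
#' @param collection gene-set tibble from [read_gmt()] or
#'   [simulate_gene_sets()].
#' @param tail passed to [hypergeom_upper()].
#' @param top keep only the `top` smallest p-values (default all).
#' @return an `agewas_enrichment` tibble: `set_name`, `N`, `m`, `n`, `k`,
#'   `p_hyper`.
#' @export
run_enrichment <- function(gene_list, universe, collection,
                           tail = c("gt", "ge"), top = Inf) {
  tail <- match.arg(tail)
  universe <- unique(universe)
  check_that(length(universe) > 0, "gene universe is empty")
  gene_list <- unique(gene_list)
  outside <- setdiff(gene_list, universe)
  if (length(outside) > 0) {
    inform(sprintf("dropping %d gene(s) of the list absent from the universe",
                   length(outside)))
    gene_list <- setdiff(gene_list, outside)
  }
  n_universe <- length(universe)
  m_sig <- length(gene_list)
  sets_in_universe <- lapply(collection$genes, intersect, universe)
  n_set <- lengths(sets_in_universe)
  k_overlap <- vapply(sets_in_universe,
                      function(g) length(intersect(g, gene_list)), 0L)
  out <- tibble::tibble(
    set_name = collection$set_name,
    N = n_universe, m = m_sig, n = n_set, k = k_overlap,
    p_hyper = purrr::map2_dbl(n_set, k_overlap, function(n1, k1) {
      hypergeom_upper(n_universe, m_sig, n1, k1, tail = tail)
    })
  ) |>
    dplyr::arrange(.data$p_hyper, dplyr::desc(.data$k), .data$set_name)
  if (is.finite(top)) out <- head(out, top)
  class(out) <- c("agewas_enrichment", class(out))
  out
}

#' @export
tidy.agewas_enrichment <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "agewas_enrichment")
  out
}

#' Dot plot of top over-represented gene sets
#'
#' @param object an `agewas_enrichment` tibble.
#' @param top number of sets to display.
#' @param ... unused.
#' @return a ggplot of -log10 p against set, sized by overlap.
#' @export
autoplot.agewas_enrichment <- function(object, top = 20, ...) {
  d <- head(object, top) |>
    dplyr::mutate(set_name = factor(.data$set_name, levels = rev(.data$set_name)))
  ggplot2::ggplot(d, ggplot2::aes(x = -log10(pmax(.data$p_hyper, 1e-300)),
                                  y = .data$set_name, size = .data$k)) +
    ggplot2::geom_point(colour = "#4575b4") +
    ggplot2::labs(x = expression(-log[10](p[hyper])), y = NULL,
                  size = "overlap k") +
    ggplot2::theme_minimal()
}
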