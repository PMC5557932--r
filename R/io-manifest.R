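#' CpG annotation manifests
#'
#' A CpG manifest is a tibble with one row per CpG and columns
#' `cpg_id`, `chromosome` (`"1"`..`"22"`, `"X"`, `"Y"`), `position`
#' (1-based point position), `gene_regions` (a list-column of one or more
#' labels from `r paste0('\x60', paste(GENE_REGION_LABELS, collapse = '\x60, \x60'), '\x60')`),
#' `cgi_relation` (exactly one of Island, N_Shore, S_Shore, N_Shelf, S_Shelf,
#' non-CGI) and `nearest_gene` (possibly empty). Gene-region membership is
#' multi-label -- a promoter-associated CpG can sit in both TSS200 and
#' 1stExon -- while the CpG-island relation is single-label, a partition of
#' the array.
#'
#' @param x a data frame with the columns above (`gene_regions` may be given
#'   as semicolon-separated strings, which are split).
#' @return a validated `cpg_manifest` tibble.
#' @export
#' @examples
#' as_cpg_manifest(tibble::tibble(
#'   cpg_id = "cg0001", chromosome = "1", position = 1000,
#'   gene_regions = "TSS200;1stExon", cgi_relation = "Island",
#'   nearest_gene = "GENE1"))
as_cpg_manifest <- function(x) {
  required <- c("cpg_id", "chromosome", "position", "gene_regions",
                "cgi_relation", "nearest_gene")
  missing <- setdiff(required, names(x))
  check_that(length(missing) == 0,
             "manifest is missing column(s): %s", paste(missing, collapse = ", "))
  x <- tibble::as_tibble(x)[required]
  if (!is.list(x$gene_regions)) {
    x$gene_regions <- strsplit(as.character(x$gene_regions), ";", fixed = TRUE)
  }
  x$gene_regions <- lapply(x$gene_regions, function(g) unique(as.character(g)))
  x$cpg_id <- as.character(x$cpg_id)
  x$chromosome <- as.character(x$chromosome)
  x$position <- as.integer(x$position)
  x$cgi_relation <- as.character(x$cgi_relation)
  x$nearest_gene <- dplyr::coalesce(as.character(x$nearest_gene), "")
  validate_manifest(x)
  class(x) <- c("cpg_manifest", class(tibble::tibble()))
  x
}

validate_manifest <- function(x) {
  dup <- x$cpg_id[duplicated(x$cpg_id)]
  check_that(length(dup) == 0, "duplicate cpg_id in manifest: %s",
             paste(unique(dup), collapse = ", "))
  bad_chr <- setdiff(unique(x$chromosome), CHROMOSOMES)
  check_that(length(bad_chr) == 0, "unknown chromosome label(s): %s",
             paste(bad_chr, collapse = ", "))
  check_that(all(x$position >= 0 & !is.na(x$position)),
             "positions must be non-negative integers")
  n_lab <- lengths(x$gene_regions)
  check_that(all(n_lab > 0), "empty GENE_REGIONS for cpg_id: %s",
             paste(head(x$cpg_id[n_lab == 0], 5), collapse = ", "))
  bad_region <- setdiff(unique(unlist(x$gene_regions)), GENE_REGION_LABELS)
  check_that(length(bad_region) == 0, "unknown gene-region label(s): %s",
             paste(bad_region, collapse = ", "))
  bad_cgi <- setdiff(unique(x$cgi_relation), CGI_LABELS)
  check_that(length(bad_cgi) == 0,
             "unknown CGI label(s): %s (open sea must be spelled \"non-CGI\")",
             paste(bad_cgi, collapse = ", "))
  invisible(x)
}

#' Read a CpG annotation manifest from TSV
#'
#' The file must carry header columns `CpG_ID`, `CHR`, `POS`,
#' `GENE_REGIONS` (semicolon-separated multi-label), `CGI_RELATION`
#' (single label; open sea spelled `non-CGI`) and `NEAREST_GENE` (may be
#' empty). Any invariant violation -- duplicate ids, unknown labels, empty
#' region sets -- is a hard error at read time, never downstream.
#'
#' @param path path to a tab-separated manifest file.
#' @return a `cpg_manifest` tibble (see [as_cpg_manifest()]).
#' @export
read_manifest <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  required <- c("CpG_ID", "CHR", "POS", "GENE_REGIONS", "CGI_RELATION", "NEAREST_GENE")
  missing <- setdiff(required, names(raw))
  check_that(length(missing) == 0, "manifest %s is missing column(s): %s",
             path, paste(missing, collapse = ", "))
  as_cpg_manifest(tibble::tibble(
    cpg_id = raw$CpG_ID,
    chromosome = raw$CHR,
    position = suppressWarnings(as.integer(raw$POS)),
    gene_regions = raw$GENE_REGIONS,
    cgi_relation = raw$CGI_RELATION,
    nearest_gene = raw$NEAREST_GENE
  ))
}

#' Write a CpG manifest to TSV
#'
#' Inverse of [read_manifest()]: multi-label gene regions are serialized
#' semicolon-separated in one column (the UCSC_RefGene_Group convention).
#' `write_manifest()` then `read_manifest()` is the identity.
#'
#' @param manifest a `cpg_manifest`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  out <- tibble::tibble(
    CpG_ID = manifest$cpg_id,
    CHR = manifest$chromosome,
    POS = manifest$position,
    GENE_REGIONS = vapply(manifest$gene_regions, paste, "", collapse = ";"),
    CGI_RELATION = manifest$cgi_relation,
    NEAREST_GENE = manifest$nearest_gene
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
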