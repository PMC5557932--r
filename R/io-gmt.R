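#' Read a gene-set collection from a GMT file
#'
#' GMT is the tab-separated gene-set interchange format: one set per line,
#' `name TAB description TAB gene TAB gene ...`. Gene symbols are
#' deduplicated per set; duplicate set names and lines with fewer than three
#' fields are hard errors.
#'
#' @param path path to a GMT file.
#' @return a tibble with columns `set_name`, `description` and `genes`
#'   (list-column of unique symbols). An empty file gives a zero-row
#'   collection.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(set_name = character(), description = character(),
                          genes = list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  check_that(length(short) == 0, "GMT line %d has fewer than 3 fields",
             if (length(short)) short[1] else 0L)
  out <- tibble::tibble(
    set_name = vapply(fields, `[[`, "", 1L),
    description = vapply(fields, `[[`, "", 2L),
    genes = lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  )
  dup <- out$set_name[duplicated(out$set_name)]
  check_that(length(dup) == 0, "duplicate gene-set name(s) in GMT: %s",
             paste(unique(dup), collapse = ", "))
  check_that(all(lengths(out$genes) > 0), "empty gene set(s): %s",
             paste(out$set_name[lengths(out$genes) == 0], collapse = ", "))
  out
}

#' Write a gene-set collection to a GMT file
#'
#' @param collection a tibble as returned by [read_gmt()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- purrr::pmap_chr(collection, function(set_name, description, genes) {
    paste(c(set_name, description, genes), collapse = "\t")
  })
  readr::write_lines(lines, path)
  invisible(path)
}
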