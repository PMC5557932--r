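#' Methylation study containers
#'
#' A `methylation_study` bundles, for one cohort, a samples-by-CpGs matrix of
#' beta-values (methylation fractions in \[0,1\]), the sample sheet, and a
#' samples-by-6 matrix of blood cell-composition fractions (CD8T, CD4T, NK,
#' Bcell, Mono, Gran -- Houseman-style estimates, consumed precomputed). The
#' three parts are key-aligned: `rownames(beta)`, `sheet$sample_id` and
#' `rownames(cells)` are identical and identically ordered.
#'
#' The sample sheet is a tibble with columns `sample_id`, `subject_id`,
#' `pair_id` (twin/family cluster, empty when none), `zygosity`
#' (`MZ`/`DZ`/`NA`), `age` (years at sampling, > 0), `sex`, `cohort` and
#' `wave` (observation number within subject, >= 1).
#'
#' @param beta numeric matrix, samples x CpGs, values in \[0,1\], rownames =
#'   sample ids, colnames = CpG ids.
#' @param sheet data frame with the sample-sheet columns above.
#' @param cells numeric matrix, samples x 6, rows summing to 1 (tolerance
#'   1e-6), non-negative, columns named as `CD8T, CD4T, NK, Bcell, Mono, Gran`.
#' @return a `methylation_study` object (a list with elements `beta`,
#'   `sheet`, `cells`).
#' @export
methylation_study <- function(beta, sheet, cells) {
  sheet <- tibble::as_tibble(sheet)
  required <- c("sample_id", "subject_id", "pair_id", "zygosity", "age",
                "sex", "cohort", "wave")
  missing <- setdiff(required, names(sheet))
  check_that(length(missing) == 0, "sample sheet is missing column(s): %s",
             paste(missing, collapse = ", "))
  sheet$sample_id <- as.character(sheet$sample_id)
  sheet$subject_id <- as.character(sheet$subject_id)
  sheet$wave <- as.integer(sheet$wave)

  check_that(!anyDuplicated(sheet$sample_id), "duplicate sample_id in sheet")
  check_that(!anyDuplicated(sheet[c("subject_id", "wave")]),
             "duplicate (subject_id, wave) in sheet")
  check_that(all(sheet$age > 0), "age must be > 0 for every sample")
  check_that(all(sheet$wave >= 1L), "wave must be >= 1")

  check_that(is.matrix(beta) && is.numeric(beta), "beta must be a numeric matrix")
  check_that(identical(rownames(beta), sheet$sample_id),
             "beta rownames and sheet sample_id must be identical and ordered identically")
  bad <- which(beta < 0 | beta > 1 | is.na(beta), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("beta outside [0,1] at sample '%s', CpG '%s' (value %g)",
                  rownames(beta)[bad[1, 1]], colnames(beta)[bad[1, 2]],
                  beta[bad[1, 1], bad[1, 2]]))
  }

  check_that(is.matrix(cells) && ncol(cells) == 6, "cells must be a samples x 6 matrix")
  check_that(identical(rownames(cells), sheet$sample_id),
             "cells rownames and sheet sample_id must be identical and ordered identically")
  if (is.null(colnames(cells))) colnames(cells) <- CELL_TYPES
  check_that(identical(colnames(cells), CELL_TYPES),
             "cell columns must be named %s", paste(CELL_TYPES, collapse = ", "))
  check_that(all(cells >= 0), "cell fractions must be non-negative")
  off <- which(abs(rowSums(cells) - 1) > 1e-6)
  check_that(length(off) == 0,
             "cell-fraction rows must sum to 1 (off for sample '%s': %.8f)",
             if (length(off)) sheet$sample_id[off[1]] else "",
             if (length(off)) rowSums(cells)[off[1]] else 0)

  structure(list(beta = beta, sheet = sheet, cells = cells),
            class = "methylation_study")
}

#' @export
print.methylation_study <- function(x, ...) {
  cat(sprintf("<methylation_study> %d samples x %d CpGs, %d subjects, cohort(s): %s\n",
              nrow(x$beta), ncol(x$beta), dplyr::n_distinct(x$sheet$subject_id),
              paste(unique(x$sheet$cohort), collapse = ", ")))
  invisible(x)
}

#' Read a methylation study from its three on-disk artifacts
#'
#' @param beta_path TSV of beta-values: first column `sample_id`, one column
#'   per CpG.
#' @param sheet_path CSV sample sheet keyed by `sample_id`.
#' @param cells_path CSV of cell fractions keyed by `sample_id`, columns
#'   `CD8T, CD4T, NK, Bcell, Mono, Gran`.
#' @return a [methylation_study()]. Samples present in the beta matrix but
#'   missing from the sheet or the cell table are a hard error; beta values
#'   outside \[0,1\] or cell rows not summing to 1 are hard errors with the
#'   offending cell named.
#' @export
read_study <- function(beta_path, sheet_path, cells_path) {
  bt <- readr::read_tsv(beta_path, col_types = readr::cols(
    sample_id = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  sheet <- readr::read_csv(sheet_path, col_types = readr::cols(
    sample_id = readr::col_character(), subject_id = readr::col_character(),
    pair_id = readr::col_character(), zygosity = readr::col_character(),
    age = readr::col_double(), sex = readr::col_character(),
    cohort = readr::col_character(), wave = readr::col_integer()),
    na = character(), progress = FALSE)
  ct <- readr::read_csv(cells_path, col_types = readr::cols(
    sample_id = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)

  ids <- bt$sample_id
  miss_sheet <- setdiff(ids, sheet$sample_id)
  check_that(length(miss_sheet) == 0, "samples in beta matrix missing from sheet: %s",
             paste(head(miss_sheet, 5), collapse = ", "))
  miss_cells <- setdiff(ids, ct$sample_id)
  check_that(length(miss_cells) == 0, "samples in beta matrix missing from cell table: %s",
             paste(head(miss_cells, 5), collapse = ", "))

  beta <- as.matrix(bt[-1])
  rownames(beta) <- ids
  sheet <- sheet[match(ids, sheet$sample_id), ]
  cells <- as.matrix(ct[match(ids, ct$sample_id), CELL_TYPES])
  rownames(cells) <- ids
  methylation_study(beta, sheet, cells)
}

#' Write a methylation study to its three on-disk artifacts
#'
#' Inverse of [read_study()]; round-trips exactly (beta values are written
#' with full precision).
#'
#' @param study a [methylation_study()].
#' @inheritParams read_study
#' @return the three paths, invisibly.
#' @export
write_study <- function(study, beta_path, sheet_path, cells_path) {
  bt <- tibble::as_tibble(study$beta)
  bt <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(study$beta)), bt)
  readr::write_tsv(bt, beta_path, progress = FALSE)
  readr::write_csv(study$sheet, sheet_path, progress = FALSE)
  ct <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(study$cells)),
                         tibble::as_tibble(study$cells))
  readr::write_csv(ct, cells_path, progress = FALSE)
  invisible(c(beta_path, sheet_path, cells_path))
}
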