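#' Beta/M-value transforms
#'
#' The logit (base-2) transform `M = log2(beta / (1 - beta))` maps
#' methylation fractions to an approximately normal scale suitable for
#' regression. Boundary values are clamped to `[eps, 1 - eps]` with
#' `eps = 1e-6` so M stays finite; `m_to_beta()` is the exact inverse away
#' from the clamp zone.
#'
#' @param beta numeric vector or matrix of beta-values in \[0,1\].
#' @param m numeric vector or matrix of M-values.
#' @param eps clamp width at the boundaries.
#' @return transformed values with the shape of the input.
#' @export
#' @examples
#' beta_to_m(0.5)  # 0
#' beta_to_m(0.8)  # 2
beta_to_m <- function(beta, eps = 1e-6) {
  check_that(all(beta >= 0 & beta <= 1, na.rm = FALSE),
             "beta values must lie in [0,1]")
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' @rdname beta_to_m
#' @export
m_to_beta <- function(m) {
  1 / (1 + 2^(-m))
}

#' Drop sex-chromosome CpGs
#'
#' EWAS of aging is run on autosomal CpGs only; X/Y probes are removed from
#' the manifest and, when supplied, the aligned beta matrix, preserving
#' order.
#'
#' @param manifest a `cpg_manifest`.
#' @param study optionally, a [methylation_study()] whose beta columns cover
#'   the manifest's CpGs.
#' @return the filtered manifest, or `list(manifest =, study =)` when a
#'   study is supplied. Warns if nothing is left.
#' @export
filter_autosomal <- function(manifest, study = NULL) {
  keep <- !(manifest$chromosome %in% c("X", "Y"))
  out_manifest <- manifest[keep, ]
  if (sum(keep) == 0) warn("no autosomal CpGs remain after filtering")
  if (is.null(study)) return(out_manifest)
  keep_ids <- intersect(colnames(study$beta), out_manifest$cpg_id)
  study$beta <- study$beta[, keep_ids, drop = FALSE]
  list(manifest = out_manifest, study = study)
}

## Shared OLS core: one design matrix (intercept + age + 5 cell fractions;
## the granulocyte column is dropped to break the compositional sum-to-one
## collinearity), QR-factored once and applied to every CpG column.
ols_scan_core <- function(M, age, cells) {
  M <- as.matrix(M)
  n <- nrow(M)
  check_that(length(age) == n, "age must have one value per sample")
  check_that(n >= 9, "need >= 9 samples (7 coefficients + 2 residual df), got %d", n)
  X <- cbind(intercept = 1, age = age,
             cells[, setdiff(CELL_TYPES, "Gran"), drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    abort(sprintf("design matrix is rank deficient; collinear column(s): %s",
                  paste(dropped, collapse = ", ")))
  }
  coefs <- qr.coef(qrX, M)
  res <- qr.resid(qrX, M)
  df <- n - ncol(X)
  sigma2 <- colSums(res^2) / df
  ## variance multiplier for the age coefficient from (X'X)^{-1} (pivoted order)
  XtXinv <- chol2inv(qr.R(qrX))
  c_age <- XtXinv[match("age", colnames(X)[qrX$pivot]),
                  match("age", colnames(X)[qrX$pivot])]
  slope <- coefs["age", ]
  se <- sqrt(sigma2 * c_age)
  tval <- slope / se
  p <- 2 * pt(-abs(tval), df)
  p <- pmax(p, .Machine$double.xmin)  # keep p in (0, 1]
  tibble::tibble(slope = unname(slope), se = unname(se), p_obs = unname(p))
}

#' Per-CpG ordinary least squares of methylation on age
#'
#' Fits M ~ intercept + age + cell composition by OLS for one CpG and
#' returns the age coefficient with its standard error and two-sided t-test
#' p-value. One of the six cell fractions (granulocyte, the largest) is
#' dropped from the design: the fractions sum to one, so keeping all six
#' with an intercept would be exactly collinear. Any rank deficiency beyond
#' that planned drop is an error naming the collinear columns.
#'
#' @param m numeric vector of per-sample M-values.
#' @param age numeric vector of ages (years).
#' @param cells samples x 6 matrix of cell fractions (CD8T, CD4T, NK,
#'   Bcell, Mono, Gran).
#' @return a one-row tibble with `slope` (M-units/year), `se` and `p_obs`.
#' @export
fit_cpg_ols <- function(m, age, cells) {
  ols_scan_core(matrix(m, ncol = 1), age, cells)
}

#' Discovery association scan over all CpGs
#'
#' Applies [beta_to_m()] and fits the per-CpG OLS of [fit_cpg_ols()] to
#' every CpG of the study (a single shared design factorization, so results
#' are identical to CpG-by-CpG fits). Direction is the sign of the age
#' slope: `gain` for age-methylated, `loss` for age-demethylated.
#'
#' @param study a [methylation_study()].
#' @param manifest a `cpg_manifest` covering the study's CpGs (used to
#'   restrict and order the scan; pass the autosomally filtered manifest).
#' @return a tibble with one row per CpG: `cpg_id`, `slope`, `se`, `p_obs`,
#'   `direction`.
#' @export
ewas_scan <- function(study, manifest) {
  ids <- manifest$cpg_id
  miss <- setdiff(ids, colnames(study$beta))
  check_that(length(miss) == 0, "CpGs in manifest missing from study: %s",
             paste(head(miss, 5), collapse = ", "))
  M <- beta_to_m(study$beta[, ids, drop = FALSE])
  res <- ols_scan_core(M, study$sheet$age, study$cells)
  dplyr::bind_cols(tibble::tibble(cpg_id = ids), res) |>
    dplyr::mutate(direction = ifelse(.data$slope > 0, "gain", "loss"))
}

#' Permutation null distribution of the minimum p-value
#'
#' For each of K permutations the age column is shuffled uniformly across
#' samples (methylation and cell fractions untouched), the full scan is
#' re-run, and the minimum p-value over CpGs is recorded. Shuffling age at
#' the sample level deliberately breaks within-subject structure; that
#' empirical null is what makes the minP family-wise error estimate valid
#' for a repeated-measures discovery cohort without model-based dependence
#' corrections.
#'
#' @param study a [methylation_study()].
#' @param manifest a `cpg_manifest` (autosomally filtered).
#' @param K number of permutations (default 300). Values below 20 trigger a
#'   warning: FWER resolution is 1/K.
#' @param seed integer seed for the permutation stream.
#' @return a list with `min_p` (length-K vector in (0,1\]), `K` and `seed`.
#' @export
permutation_null <- function(study, manifest, K = 300, seed = 1L) {
  check_that(K >= 1, "K must be >= 1")
  if (K < 20) warn(sprintf("K = %d is low: FWER resolution is 1/K = %.3f", K, 1 / K))
  ids <- manifest$cpg_id
  M <- beta_to_m(study$beta[, ids, drop = FALSE])
  age <- study$sheet$age
  cells <- study$cells
  set.seed(substream_seed(seed, "permutation-null"))
  min_p <- vapply(seq_len(K), function(i) {
    min(ols_scan_core(M, sample(age), cells)$p_obs)
  }, 0)
  list(min_p = min_p, K = as.integer(K), seed = as.integer(seed))
}

#' Estimate the family-wise error rate by the minP method
#'
#' For each CpG the FWER estimate is the fraction of permuted scans whose
#' minimum p-value falls strictly below the CpG's observed p-value:
#' `fwer_j = (1/K) * #\{i : min_p\[i\] < p_obs_j\}`. Estimates take values
#' in \{0, 1/K, ..., 1\} and are non-decreasing in `p_obs`.
#'
#' @param p_obs vector of observed per-CpG p-values.
#' @param null a permutation null from [permutation_null()].
#' @return numeric vector of FWER estimates, aligned with `p_obs`.
#' @export
estimate_fwer <- function(p_obs, null) {
  check_that(length(null$min_p) >= 1, "permutation null is empty")
  s <- sort(null$min_p)
  findInterval(p_obs, s, left.open = TRUE) / length(s)
}

#' Run the full discovery EWAS
#'
#' Autosomal filtering, beta-to-M transform, per-CpG OLS adjusted for cell
#' composition, and minP permutation FWER, bundled into one fitted object.
#'
#' @inheritParams permutation_null
#' @param alpha_fwer significance threshold applied by [significant_cpgs()]
#'   (strict inequality), stored with the fit.
#' @return an `agewas_ewas` object: list with `results` (tibble `cpg_id`,
#'   `slope`, `se`, `p_obs`, `direction`, `fwer`), `null`, `alpha_fwer`,
#'   `n_samples`.
#' @export
run_ewas <- function(study, manifest, K = 300, alpha_fwer = 0.05, seed = 1L) {
  flt <- filter_autosomal(manifest, study)
  res <- ewas_scan(flt$study, flt$manifest)
  null <- permutation_null(flt$study, flt$manifest, K = K, seed = seed)
  res$fwer <- estimate_fwer(res$p_obs, null)
  structure(list(results = res, null = null, alpha_fwer = alpha_fwer,
                 n_samples = nrow(flt$study$beta)),
            class = "agewas_ewas")
}

#' @export
print.agewas_ewas <- function(x, ...) {
  sig <- significant_cpgs(x)
  cat(sprintf(paste0("<agewas_ewas> %d CpGs, %d samples, K = %d permutations\n",
                     "  FWER < %g: %d CpGs (%d gain, %d loss)\n"),
              nrow(x$results), x$n_samples, x$null$K, x$alpha_fwer,
              nrow(sig), sum(sig$direction == "gain"),
              sum(sig$direction == "loss")))
  invisible(x)
}

#' Discovery-significant CpGs at an FWER threshold
#'
#' Strict inequality, matching the genome-wide criterion FWER < 0.05: a CpG
#' with FWER exactly at the threshold is excluded.
#'
#' @param ewas an `agewas_ewas` object or its `results` tibble.
#' @param alpha_fwer threshold; defaults to the value stored in the fit
#'   (0.05 for a plain tibble).
#' @return the significant rows of the results tibble (`direction` splits
#'   the set into age-methylated gains and age-demethylated losses).
#' @export
significant_cpgs <- function(ewas, alpha_fwer = NULL) {
  if (inherits(ewas, "agewas_ewas")) {
    alpha_fwer <- alpha_fwer %||% ewas$alpha_fwer
    ewas <- ewas$results
  }
  alpha_fwer <- alpha_fwer %||% 0.05
  dplyr::filter(ewas, .data$fwer < alpha_fwer)
}

#' @export
tidy.agewas_ewas <- function(x, ...) x$results

#' @export
glance.agewas_ewas <- function(x, ...) {
  sig <- significant_cpgs(x)
  tibble::tibble(
    n_cpgs = nrow(x$results), n_samples = x$n_samples, K = x$null$K,
    alpha_fwer = x$alpha_fwer, n_significant = nrow(sig),
    n_gain = sum(sig$direction == "gain"),
    n_loss = sum(sig$direction == "loss"),
    pct_loss = pct_of(sum(sig$direction == "loss"), nrow(sig))
  )
}

#' Volcano-style plot of a discovery scan
#'
#' @param object an `agewas_ewas` object.
#' @param ... unused.
#' @return a ggplot: age slope against -log10 p, significant CpGs
#'   highlighted by direction.
#' @export
autoplot.agewas_ewas <- function(object, ...) {
  d <- object$results |>
    dplyr::mutate(status = ifelse(.data$fwer < object$alpha_fwer,
                                  .data$direction, "not significant"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$slope,
                                  y = -log10(.data$p_obs),
                                  colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(gain = "#d73027",
                                            loss = "#4575b4",
                                            `not significant` = "grey70")) +
    ggplot2::labs(x = "age slope (M-units/year)",
                  y = expression(-log[10](p)),
                  colour = NULL,
                  title = sprintf("Discovery EWAS (FWER < %g by minP, K = %d)",
                                  object$alpha_fwer, object$null$K)) +
    ggplot2::theme_minimal()
}
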