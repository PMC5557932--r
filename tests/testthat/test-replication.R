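make_long_data <- function(seed, n_subj = 45, cluster_sd = 0.5, noise_sd = 0.1,
                           slope = -0.01) {
  set.seed(seed)
  subj <- rep(seq_len(n_subj), each = 2)
  age0 <- runif(n_subj, 73, 82)
  age <- age0[subj] + (rep(1:2, n_subj) - 1) * 10
  u <- rnorm(n_subj, 0, cluster_sd)[subj]
  m <- 2 + slope * age + u + rnorm(length(age), 0, noise_sd)
  cells <- make_cells(length(age), seed)
  list(m = m, age = age, cells = cells, cluster = subj,
       cluster_sd = cluster_sd, noise_sd = noise_sd)
}

test_that("mixed model recovers a noise-free slope exactly", {
  st <- exact_study(n = 24, slope = -0.01, intercept = 2)
  cluster <- rep(1:12, each = 2)
  fit <- fit_cpg_lmm(beta_to_m(st$beta[, 1]), st$sheet$age, st$cells, cluster)
  expect_equal(fit$slope, -0.01, tolerance = 1e-6)
})

test_that("mixed model matches a known-variance GLS oracle and beats naive OLS", {
  for (seed in c(7, 8, 9)) {
    d <- make_long_data(seed)
    got <- fit_cpg_lmm(d$m, d$age, d$cells, d$cluster)
    expect_false(got$fallback)
    ## GLS with the true variance components as the oracle
    X <- cbind(1, d$age, d$cells[, 1:5])
    V <- diag(d$noise_sd^2, length(d$age)) +
      d$cluster_sd^2 * outer(d$cluster, d$cluster, "==")
    Vi <- solve(V)
    XtVi <- t(X) %*% Vi
    bhat <- solve(XtVi %*% X, XtVi %*% d$m)
    se_gls <- sqrt(diag(solve(XtVi %*% X)))[2]
    expect_lt(abs(got$slope - bhat[2]), 0.1 * se_gls)
    ## with cluster SD >> noise SD and age varying within cluster, the
    ## mixed model is far more powerful than OLS that ignores clustering
    ols <- fit_cpg_ols(d$m, d$age, d$cells)
    expect_lt(got$p, ols$p_obs)
  }
})

test_that("one sample per cluster degenerates to OLS", {
  d <- make_long_data(3)
  keep <- seq(1, length(d$m), by = 2)
  got <- fit_cpg_lmm(d$m[keep], d$age[keep], d$cells[keep, ],
                     cluster = seq_along(keep))
  expect_true(got$fallback)
  ref <- fit_cpg_ols(d$m[keep], d$age[keep], d$cells[keep, ])
  expect_equal(got$slope, ref$slope, tolerance = 1e-8)
  expect_equal(got$p, ref$p_obs, tolerance = 1e-8)
})

test_that("replication requires same direction AND strictly sub-alpha p", {
  sim <- small_sim(n_cpgs = 12, seed = 17, frac_affected = 1,
                   slope_mean = 0.03, slope_sd = 0.005)
  cross <- simulate_cohort(sim$manifest, cohort_presets()$cross_sectional_like,
                           sim$cfg)$study
  truth_dir <- sim$truth$direction

  disc_true <- tibble::tibble(cpg_id = sim$truth$cpg_id, direction = truth_dir)
  rep_true <- replicate_cohort(disc_true, cross, cluster_by = "pair", alpha = 0.05)
  expect_true(all(rep_true$testable))
  expect_gt(mean(rep_true$replicated), 0.8)  # large effects replicate

  ## flipping the claimed discovery direction kills replication
  disc_flip <- dplyr::mutate(disc_true,
                             direction = ifelse(direction == "gain", "loss", "gain"))
  rep_flip <- replicate_cohort(disc_flip, cross, cluster_by = "pair", alpha = 0.05)
  expect_true(!any(rep_flip$replicated & rep_true$replicated))

  ## p exactly equal to alpha is NOT replication (strict inequality)
  p1 <- rep_true$p[1]
  rep_edge <- replicate_cohort(disc_true[1, ], cross, cluster_by = "pair",
                               alpha = p1)
  expect_false(rep_edge$replicated[1])

  ## alpha = 1 reduces to pure direction concordance
  rep_dir <- replicate_cohort(disc_true, cross, cluster_by = "pair", alpha = 1)
  expect_identical(rep_dir$replicated,
                   ifelse(disc_true$direction == "gain",
                          rep_dir$slope > 0, rep_dir$slope < 0))

  ## CpGs absent from the validation array are not testable, not failures
  cross_sub <- cross
  cross_sub$beta <- cross_sub$beta[, -1, drop = FALSE]
  rep_sub <- replicate_cohort(disc_true, cross_sub, cluster_by = "pair")
  expect_false(rep_sub$testable[1])
  expect_false(rep_sub$replicated[1])
  expect_true(all(rep_sub$testable[-1]))
})

test_that("double replication is the intersection, with the subset chain intact", {
  disc <- tibble::tibble(cpg_id = c("c1", "c2", "c3", "c4", "c5"),
                         direction = c("gain", "loss", "gain", "loss", "gain"))
  mk <- function(replicated) tibble::tibble(
    cpg_id = disc$cpg_id, slope = 1, p = 0.01, fallback = FALSE,
    testable = TRUE, replicated = replicated)
  led <- replication_ledger(disc, mk(c(TRUE, TRUE, TRUE, FALSE, FALSE)),
                            mk(c(FALSE, TRUE, TRUE, TRUE, FALSE)))
  dbl <- double_replicate(led)
  expect_identical(dbl$cpg_id, c("c2", "c3"))
  expect_identical(dbl$direction, c("loss", "gain"))
  expect_true(all(dbl$cpg_id %in% disc$cpg_id))

  disjoint <- replication_ledger(disc, mk(c(TRUE, TRUE, FALSE, FALSE, FALSE)),
                                 mk(c(FALSE, FALSE, FALSE, TRUE, TRUE)))
  expect_identical(nrow(double_replicate(disjoint)), 0L)
})

test_that("replication and overlap rates follow the published conventions", {
  ## ledger with the published counts: 67,604 discovery, 19,768 and 7,238
  ## replicated, 5,168 double-replicated
  n <- 67604
  rep_a <- logical(n); rep_a[1:19768] <- TRUE
  rep_b <- logical(n); rep_b[1:5168] <- TRUE; rep_b[19769:21838] <- TRUE
  stopifnot(sum(rep_b) == 7238)
  led <- structure(list(ledger = tibble::tibble(
    cpg_id = sprintf("c%d", 1:n), discovery_direction = "gain",
    slope_a = 1, p_a = 0.01, replicated_a = rep_a,
    slope_b = 1, p_b = 0.01, replicated_b = rep_b,
    double_replicated = rep_a & rep_b),
    cohort_names = c("a", "b")), class = "agewas_replication")
  r <- replication_rates(led)
  expect_equal(round(r$rate_a, 1), 29.2)
  expect_equal(round(r$rate_b, 1), 10.7)
  ## overlap convention: double-replicated over the smaller replicated set
  expect_equal(r$overlap_rate, 100 * 5168 / 7238)
  expect_equal(round(r$overlap_rate, 1), 71.4)

  ## 0 of 100 replicated is 0%, not undefined
  led0 <- led
  led0$ledger <- led0$ledger[1:100, ]
  led0$ledger$replicated_a <- FALSE
  led0$ledger$double_replicated <- FALSE
  expect_equal(replication_rates(led0)$rate_a, 0)
  ## but an empty denominator is NA (undefined marker)
  led0$ledger$p_a <- NA_real_
  expect_true(is.na(replication_rates(led0)$rate_a))
})

test_that("under a global null the per-cohort replication rate is about alpha/2", {
  cfg <- sim_config(n_cpgs = 500, seed = 23, frac_affected = 0)
  man <- simulate_manifest(cfg)
  cross <- simulate_cohort(man, cohort_presets()$cross_sectional_like, cfg)$study
  set.seed(23)
  disc <- tibble::tibble(cpg_id = man$cpg_id,
                         direction = sample(c("gain", "loss"), 500, replace = TRUE))
  rep_null <- replicate_cohort(disc, cross, cluster_by = "pair", alpha = 0.05)
  rate <- mean(rep_null$replicated)
  ## two-sided p < alpha with a random direction agreeing half the time:
  ## expected 2.5%, allow 3 binomial SDs
  se <- sqrt(0.025 * 0.975 / 500)
  expect_lt(abs(rate - 0.025), 3 * se)
})

test_that("set overlap percentages match direct counting", {
  ref <- sprintf("c%d", 1:5168)
  query <- c(sprintf("c%d", 1:54), sprintf("x%d", 1:17))
  ov <- set_overlap(query, ref)
  expect_identical(ov$n_overlap, 54L)
  expect_equal(round(ov$pct_overlap, 2), 76.06)
  expect_true(is.na(set_overlap(character(), ref)$pct_overlap))
})
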