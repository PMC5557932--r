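test_that("direction-bias chi-square equals a generic Yates 2x2 oracle on a grid", {
  ## exhaustive grid over 0..2000 at stride 7 (skipping the empty table)
  g <- seq(0, 2000, by = 7)
  grid <- expand.grid(gain = g, loss = g)
  grid <- grid[grid$gain + grid$loss > 0, ]
  got <- direction_bias_chisq(grid$gain, grid$loss)$chisq
  ## independent cell-by-cell evaluation of the symmetric table [[g,l],[l,g]]
  n <- grid$gain + grid$loss
  E <- n / 2
  oracle <- 4 * pmax(abs(grid$gain - E) - 0.5, 0)^2 / E
  expect_equal(got, oracle, tolerance = 1e-12)

  ## spot-check against stats::chisq.test on random cells with both counts > 0
  set.seed(5)
  idx <- sample(which(grid$gain > 0 & grid$loss > 0), 50)
  for (i in idx) {
    tab <- matrix(c(grid$gain[i], grid$loss[i], grid$loss[i], grid$gain[i]), 2)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    expect_equal(direction_bias_chisq(grid$gain[i], grid$loss[i])$chisq,
                 unname(ref$statistic), tolerance = 1e-10)
  }
})

test_that("direction-bias chi-square is symmetric and floors at perfect balance", {
  set.seed(2)
  g <- sample(0:500, 40); l <- sample(0:500, 40)
  ok <- g + l > 0
  expect_equal(direction_bias_chisq(g[ok], l[ok]), direction_bias_chisq(l[ok], g[ok]))
  expect_equal(direction_bias_chisq(10, 10)$chisq, 0)
  expect_equal(direction_bias_chisq(10, 10)$p, 1)
  expect_error(direction_bias_chisq(0, 0), ">= 1")
})

test_that("published direction-bias statistics reproduce from their printed counts", {
  counts <- list(c(374, 114), c(556, 1197), c(254, 180),
                 c(1554, 128), c(124, 1412), c(196, 673))
  expected <- c(274.92, 467.31, 24.56, 2414.54, 2156.73, 521.46)
  got <- direction_bias_chisq(vapply(counts, `[`, 0, 1),
                              vapply(counts, `[`, 0, 2))$chisq
  expect_equal(round(got, 2), expected)
})

test_that("proportionality test is a Yates 2x2 against the array background", {
  ## equal proportions with large counts: statistic near 0
  near0 <- proportionality_test(250, 1000, 2500, 10000)
  expect_lt(near0$chisq, 0.01)
  expect_true(near0$reliable)

  ## doubling all counts roughly doubles the statistic
  a <- proportionality_test(590, 2028, 117045, 473864)
  b <- proportionality_test(1180, 4056, 234090, 947728)
  expect_equal(b$chisq / a$chisq, 2, tolerance = 0.05)

  ## Intergenic gain row of the published table: 590/2028 vs an array
  ## background near 0.247 gives a statistic in the vicinity of 21.3
  expect_gt(a$chisq, 15); expect_lt(a$chisq, 28)

  ## tiny expected cells flagged unreliable but still computed
  tiny <- proportionality_test(1, 2, 1, 5000)
  expect_false(tiny$reliable)
  expect_true(is.finite(tiny$chisq))
})

test_that("region tabulation counts each CpG in every region label it carries", {
  man <- as_cpg_manifest(tibble::tibble(
    cpg_id = c("c1", "c2", "c3"), chromosome = "1", position = 1:3,
    gene_regions = list(c("TSS200", "1stExon"), "Body", "Body"),
    cgi_relation = c("Island", "non-CGI", "Island"), nearest_gene = ""))
  cpgs <- tibble::tibble(cpg_id = c("c1", "c2"), direction = c("gain", "loss"))
  tab <- tabulate_by_region(cpgs, man)
  d <- tab$direction
  expect_identical(d$k_gain[d$category == "TSS200"], 1L)
  expect_identical(d$k_gain[d$category == "1stExon"], 1L)
  expect_identical(d$k_loss[d$category == "Body"], 1L)
  expect_identical(d$n[d$category == "Intergenic"], 0L)
  expect_true(is.na(d$p[d$category == "Intergenic"]))

  ## proportionality rows use whole-array background from the manifest
  p <- tab$proportionality
  body_gain <- p[p$category == "Body" & p$group == "gain", ]
  expect_equal(body_gain$p_array, 2 / 3)
  expect_equal(body_gain$p_group, 0)

  ## unknown CpG is a hard error naming the id
  expect_error(tabulate_by_region(tibble::tibble(cpg_id = "nope",
                                                 direction = "gain"), man),
               "nope")

  ## empty input: all-zero rows, no tests computed
  empty <- tabulate_by_region(cpgs[0, ], man)
  expect_true(all(empty$direction$n == 0L))
  expect_true(all(is.na(empty$direction$p)))
})

test_that("printed gain/loss proportions arise from tabulated counts", {
  ## 1,062 TSS1500 CpGs split 288 gain / 774 loss, as published
  man <- as_cpg_manifest(tibble::tibble(
    cpg_id = sprintf("c%04d", 1:1062), chromosome = "1", position = 1:1062,
    gene_regions = replicate(1062, "TSS1500", simplify = FALSE),
    cgi_relation = "Island", nearest_gene = ""))
  cpgs <- tibble::tibble(cpg_id = man$cpg_id,
                         direction = rep(c("gain", "loss"), c(288, 774)))
  d <- tabulate_by_region(cpgs, man)$direction
  row <- d[d$category == "TSS1500", ]
  expect_identical(row$k_gain, 288L)
  expect_equal(round(row$prop_gain, 2), 0.27)
  expect_equal(round(row$prop_loss, 2), 0.73)
  expect_equal(round(row$chisq, 2), 442.98)  # as published for this split
})

test_that("CGI tabulation partitions the set and handles degenerate inputs", {
  sim <- small_sim(n_cpgs = 200, seed = 41)
  set.seed(41)
  cpgs <- tibble::tibble(cpg_id = sample(sim$manifest$cpg_id, 80),
                         direction = sample(c("gain", "loss"), 80, replace = TRUE))
  tab <- tabulate_by_cgi(cpgs, sim$manifest)
  expect_identical(sum(tab$direction$n), 80L)  # single-label partition
  expect_setequal(tab$direction$category,
                  c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "non-CGI"))

  ## published N_Shore row: (196, 673) gives 521.46
  expect_equal(round(direction_bias_chisq(196, 673)$chisq, 2), 521.46)

  ## all-Island input leaves the other rows at zero
  island_ids <- sim$manifest$cpg_id[sim$manifest$cgi_relation == "Island"][1:5]
  tab2 <- tabulate_by_cgi(tibble::tibble(cpg_id = island_ids, direction = "gain"),
                          sim$manifest)
  expect_identical(sum(tab2$direction$n), 5L)
  expect_identical(tab2$direction$n[tab2$direction$category == "Island"], 5L)
})

test_that("region x CGI crosstab marginalizes back to the region counts", {
  sim <- small_sim(n_cpgs = 300, seed = 43)
  set.seed(43)
  cpgs <- tibble::tibble(cpg_id = sample(sim$manifest$cpg_id, 120),
                         direction = sample(c("gain", "loss"), 120, replace = TRUE))
  ct <- crosstab_region_by_cgi(cpgs, sim$manifest)
  expect_setequal(unique(ct$cgi_group), c("non-CGI", "Shore/Shelf", "CGI"))
  marg <- ct |>
    dplyr::group_by(region) |>
    dplyr::summarise(k_gain = sum(k_gain), k_loss = sum(k_loss))
  d <- tabulate_by_region(cpgs, sim$manifest)$direction
  for (r in d$category) {
    expect_identical(marg$k_gain[marg$region == r], d$k_gain[d$category == r])
    expect_identical(marg$k_loss[marg$region == r], d$k_loss[d$category == r])
  }

  ## single-cell fixture
  man1 <- as_cpg_manifest(tibble::tibble(
    cpg_id = "c1", chromosome = "1", position = 1,
    gene_regions = list("Body"), cgi_relation = "Island", nearest_gene = ""))
  ct1 <- crosstab_region_by_cgi(tibble::tibble(cpg_id = "c1", direction = "gain"),
                                man1)
  hit <- ct1[ct1$region == "Body" & ct1$cgi_group == "CGI", ]
  expect_identical(hit$k_gain, 1L)
  expect_identical(sum(ct1$k_gain) + sum(ct1$k_loss), 1L)
})

test_that("gains planted only at islands concentrate in every region's CGI cell", {
  cfg <- sim_config(n_cpgs = 400, seed = 47, frac_affected = 0)
  man <- simulate_manifest(cfg)
  ## direction by construction: islands gain, everything else loss
  cpgs <- tibble::tibble(cpg_id = man$cpg_id,
                         direction = ifelse(man$cgi_relation == "Island",
                                            "gain", "loss"))
  ct <- crosstab_region_by_cgi(cpgs, man)
  filled <- ct |>
    tidyr::pivot_wider(id_cols = "region", names_from = "cgi_group",
                       values_from = "prop_gain")
  ok <- !is.na(filled$CGI) & !is.na(filled$`non-CGI`)
  expect_true(all(filled$CGI[ok] > filled$`non-CGI`[ok]))
})

test_that("gain and loss shares are percentages of the direction totals", {
  counts <- tibble::tibble(category = c("1stExon", "Island", "TSS1500"),
                           k_gain = c(374L, 1554L, 288L),
                           k_loss = c(114L, 128L, 774L))
  sh <- gain_share_summary(counts, n_gain_total = 2028, n_loss_total = 3140)
  expect_equal(round(sh$share_gain_pct, 2), c(18.44, 76.63, 14.20))
  expect_equal(round(sh$share_loss_pct[3], 2), 24.65)
  ## zero totals give the undefined marker
  sh0 <- gain_share_summary(counts, 0, 3140)
  expect_true(all(is.na(sh0$share_gain_pct)))
})
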