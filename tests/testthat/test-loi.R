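test_that("degree of LOI is the least/most read ratio with its edge cases", {
  expect_equal(degree_of_loi(15, 15), 1)
  expect_equal(degree_of_loi(30, 0), 0)
  expect_equal(degree_of_loi(3, 9), 1 / 3)
  # symmetric and scale-free
  expect_equal(degree_of_loi(7, 21), degree_of_loi(21, 7))
  expect_equal(degree_of_loi(14, 42), degree_of_loi(7, 21))
  expect_warning(r <- degree_of_loi(0, 0), "undefined")
  expect_true(is.na(r))
  expect_error(degree_of_loi(-1, 3), "ref_count")
})

test_that("LOI regression reduces to its null identity and saturated form", {
  d <- tibble::tibble(least = rep(c(2L, 5L), 10),
                      most = rep(c(28L, 25L), 10),
                      group = rep(c("control", "case"), each = 10))
  # identical profiles in both groups
  d_same <- tibble::tibble(least = rep(3L, 20), most = rep(27L, 20),
                           group = rep(c("control", "case"), each = 10))
  res0 <- loi_regression(d_same, control = "control")
  expect_equal(res0$beta_case, 0, tolerance = 1e-10)
  expect_equal(res0$p_one_sided, 0.5, tolerance = 1e-10)
  # the two-group model is saturated: the case coefficient is exactly the
  # log-odds difference of the pooled least/(least+most) ratios
  res <- loi_regression(d, control = "control")
  pool_ctrl <- res$successes_control / (res$successes_control + res$failures_control)
  pool_case <- res$successes_case / (res$successes_case + res$failures_case)
  expect_equal(res$beta_case, qlogis(pool_case) - qlogis(pool_ctrl),
               tolerance = 1e-8)
})

test_that("LOI regression coefficient matches grid-search maximisation", {
  set.seed(121)
  least <- c(rbinom(5, 30, 0.1), rbinom(5, 30, 0.25))
  most <- 30 - least
  is_case <- rep(c(0, 1), each = 5)
  d <- tibble::tibble(least = least, most = most,
                      group = factor(rep(c("control", "case"), each = 5),
                                     levels = c("control", "case")))
  res <- loi_regression(d)
  expect_equal(res$method, "wald")
  oracle <- grid_logistic(least, most, is_case)
  expect_equal(res$beta_case, unname(oracle["b1"]), tolerance = 1e-4)
})

test_that("separation and degenerate inputs follow their contracts", {
  # controls with zero least reads: strong LOI still detected (LRT fallback)
  d <- tibble::tibble(
    least = c(rep(0L, 128), rep(0L, 168), rep(8L, 72)),
    most = c(rep(30L, 128), rep(30L, 168), rep(22L, 72)),
    group = factor(rep(c("normal", "tumor"), c(128, 240)),
                   levels = c("normal", "tumor")))
  res <- loi_regression(d)
  expect_lt(res$p_one_sided, 1e-4)
  expect_equal(res$method, "lrt")
  expect_gt(res$beta_case, 0)
  # no successes anywhere: p = 0.5, flagged, no crash
  d0 <- tibble::tibble(least = rep(0L, 20), most = rep(30L, 20),
                       group = rep(c("normal", "tumor"), each = 10))
  expect_warning(r0 <- loi_regression(d0), "degenerate")
  expect_equal(r0$p_one_sided, 0.5)
  expect_true(r0$degenerate)
})

test_that("gene-level LOI consensus applies geometric mean and BH", {
  one <- tibble::tibble(gene_id = "G1", p_one_sided = 0.03)
  expect_equal(combine_loi_gene(one)$gene_p, 0.03)
  two <- tibble::tibble(gene_id = c("G1", "G1"),
                        p_one_sided = c(0.04, 0.09))
  expect_equal(combine_loi_gene(two)$gene_p, 0.06)
  three <- tibble::tibble(gene_id = c("G1", "G2", "G3"),
                          p_one_sided = c(0.001, 0.02, 0.8))
  res <- combine_loi_gene(three)
  expect_equal(res$gene_q[match(c("G1", "G2", "G3"), res$gene_id)],
               c(0.003, 0.03, 0.8))
  expect_equal(sum(res$loi_call), 2)
  zero <- tibble::tibble(gene_id = "G1", p_one_sided = 0)
  expect_warning(rz <- combine_loi_gene(zero), "clipped")
  expect_gt(rz$gene_p, 0)
})

test_that("per-sample LOI calls use inclusive count and fraction thresholds", {
  cts <- toy_counts(ref = c(2, 1, 3, 5, 0, 18),
                    alt = c(18, 5, 37, 20, 30, 2),
                    group = rep("tumor", 6))
  calls <- call_loi_samples(cts, imprinted_snps = "rs1")
  expect_equal(nrow(calls), 6)
  expect_equal(calls$is_loi,
               c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE))
  # least exactly 2, fraction exactly 0.10 is LOI (both inclusive)
  expect_true(calls$is_loi[calls$sample_id == "S001"])
  # uncallable samples (no informative SNP) are absent, not FALSE
  cts0 <- toy_counts(ref = c(0, 10), alt = c(0, 10), group = rep("tumor", 2))
  calls0 <- call_loi_samples(cts0, imprinted_snps = "rs1")
  expect_equal(calls0$sample_id, "S002")
})

test_that("no-LOI cohorts stay below the nominal gene-level call rate", {
  set.seed(131)
  n_rep <- 40
  called <- 0; total <- 0
  for (r in seq_len(n_rep)) {
    snp_p <- tibble::tibble(
      gene_id = sprintf("G%d", 1:5),
      p_one_sided = vapply(1:5, function(g) {
        ctrl <- simulate_snp_counts(60, p = 0.5, i = 0.95, seed = NULL)
        case <- simulate_snp_counts(60, p = 0.5, i = 0.95, seed = NULL)
        d <- dplyr::bind_rows(
          dplyr::mutate(ctrl, group = "control"),
          dplyr::mutate(case, group = "case"))
        d <- dplyr::mutate(d, least = pmin(ref_count, alt_count),
                           most = pmax(ref_count, alt_count),
                           group = factor(group, c("control", "case")))
        loi_regression(d)$p_one_sided
      }, numeric(1)))
    res <- combine_loi_gene(snp_p)
    called <- called + sum(res$loi_call)
    total <- total + nrow(res)
  }
  expect_lte(called / total, 0.05)
})
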