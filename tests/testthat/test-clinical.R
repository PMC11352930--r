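make_expr <- function(mat, genes, samples) {
  tibble::as_tibble(cbind(tibble::tibble(gene_id = genes),
                          stats::setNames(as.data.frame(mat), samples)))
}

test_that("differential expression recovers planted shifts on the log2 scale", {
  set.seed(141)
  samples <- sprintf("S%03d", 1:40)
  si <- tibble::tibble(sample_id = samples,
                       group = rep(c("normal", "tumor"), each = 20))
  # identical groups: fc 0, p 1
  l2 <- matrix(rnorm(40, 5, 0.5), 1)
  same <- make_expr(2^cbind(l2[, 1:20, drop = FALSE],
                            l2[, 1:20, drop = FALSE]) - 1, "G1", samples)
  r0 <- differential_expression(same, si)
  expect_equal(r0$log2_fc, 0)
  expect_equal(r0$p_value, 1)
  # planted +0.91 shift, sd 0.5, 20 vs 20
  base <- rnorm(40, 5, 0.5)
  shift <- ifelse(si$group == "tumor", 0.91, 0)
  expr <- make_expr(matrix(2^(base + shift) - 1, 1), "G1", samples)
  r1 <- differential_expression(expr, si)
  expect_lt(abs(r1$log2_fc - 0.91), 0.35)
  expect_lt(r1$p_value, 0.01)
})

test_that("paired differential expression uses the pair structure", {
  set.seed(142)
  samples <- sprintf("S%03d", 1:10)
  si <- tibble::tibble(sample_id = samples,
                       group = rep(c("normal", "tumor"), 5),
                       pair_id = rep(1:5, each = 2))
  subject <- rnorm(5, 5, 2) # large between-pair variance
  l2 <- rep(subject, each = 2) + ifelse(si$group == "tumor", 1.0, 0) +
    rnorm(10, 0, 0.3)
  expr <- make_expr(matrix(2^l2 - 1, 1), "G1", samples)
  rp <- differential_expression(expr, si, paired = TRUE)
  expect_lt(rp$p_value, 0.05)
  expect_equal(rp$n_case, 5)
  # incomplete pairs are dropped with a message
  si_bad <- dplyr::bind_rows(si, tibble::tibble(
    sample_id = "S011", group = "tumor", pair_id = 6L))
  expr2 <- make_expr(matrix(2^c(l2, 5) - 1, 1), "G1", c(samples, "S011"))
  expect_message(differential_expression(expr2, si_bad, paired = TRUE),
                 "incomplete")
})

test_that("SNP-level DE is library-size invariant and detects planted shifts", {
  set.seed(143)
  n <- 50
  mk <- function(mult_case = 1) {
    ids <- sprintf("S%03d", 1:(2 * n))
    grp <- rep(c("normal", "tumor"), each = n)
    base <- rnbinom(2 * n, mu = 50, size = 20)
    tot <- ifelse(grp == "tumor", round(base * mult_case), base)
    dplyr::bind_rows(
      toy_counts(tot, round(tot * 0.1), group = grp, snp_id = "rs1",
                 gene_id = "GA"),
      toy_counts(rnbinom(2 * n, mu = 60, size = 20), rep(5, 2 * n),
                 group = grp, snp_id = "rs2", gene_id = "GB"))
  }
  # doubling all counts of one sample leaves CPM (hence p-values) unchanged
  d <- mk()
  d2 <- d
  one <- d2$sample_id == "S001"
  d2$ref_count[one] <- 2L * d2$ref_count[one]
  d2$alt_count[one] <- 2L * d2$alt_count[one]
  expect_equal(snp_level_de(d)$p_value, snp_level_de(d2)$p_value,
               tolerance = 1e-12)
  # identical groups: p near 1 on average; planted 2x shift: significant
  null_p <- snp_level_de(mk())$p_value
  expect_gt(min(null_p), 0.001)
  shifted <- snp_level_de(mk(mult_case = 2))
  expect_lt(shifted$p_value[shifted$gene_id == "GA"], 0.01)
})

test_that("canonical LOI is the conjunction of the four printed criteria", {
  loi <- tibble::tibble(gene_id = c("HM13", "ZNF331", "RMEG", "ONLYLOI"),
                        gene_q = c(0.003, 0.003, 0.001, 0.02))
  de <- tibble::tibble(gene_id = c("HM13", "ZNF331", "RMEG", "OTHER"),
                       q_value = c(1e-15, 4e-6, 1e-10, 0.5),
                       log2_fc = c(0.60, -1.1, 1.5, 0.2))
  res <- suppressMessages(
    classify_canonical_loi(loi, de, rme_flags = "RMEG"))
  expect_true(res$canonical[res$gene_id == "HM13"])
  expect_false(res$canonical[res$gene_id == "ZNF331"]) # downregulated
  expect_false(res$canonical[res$gene_id == "RMEG"])   # RME-flagged
  expect_false("ONLYLOI" %in% res$gene_id)             # missing from DE
  expect_message(classify_canonical_loi(loi, de), "not classified")
})

test_that("beta/M transforms are exact and invertible", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  b <- seq(0.01, 0.99, by = 0.01)
  expect_equal(m_to_beta(beta_to_m(b)), b, tolerance = 1e-9)
  expect_error(beta_to_m(1.5), "beta")
})

test_that("differential methylation detects planted beta differences", {
  set.seed(151)
  samples <- sprintf("S%03d", 1:60)
  si <- tibble::tibble(sample_id = samples,
                       group = rep(c("normal", "tumor"), each = 30))
  beta <- rbind(
    pmin(pmax(rnorm(60, ifelse(si$group == "tumor", 0.3, 0.5), 0.05), 0), 1),
    pmin(pmax(rnorm(60, 0.4, 0.05), 0), 1))
  tbl <- tibble::as_tibble(cbind(tibble::tibble(probe_id = c("cg1", "cg2")),
                                 stats::setNames(as.data.frame(beta), samples)))
  res <- methylation_dm(tbl, si)
  hit <- res[res$probe_id == "cg1", ]
  expect_lt(hit$q_value, 0.05)
  expect_lt(hit$delta_beta, -0.15) # tumor minus normal
  expect_gt(res$p_value[res$probe_id == "cg2"], 0.05)
})

test_that("CNV association handles planted and degenerate tables", {
  set.seed(152)
  samples <- sprintf("S%03d", 1:240)
  loi_flag <- c(rep(TRUE, 17), rep(FALSE, 223))
  gain <- ifelse(loi_flag, rbinom(240, 1, 0.29), rbinom(240, 1, 0.13))
  cnv <- tibble::as_tibble(cbind(tibble::tibble(gene_id = "HM13"),
                                 stats::setNames(as.data.frame(matrix(gain, 1)),
                                                 samples)))
  l2 <- rnorm(240, 5, 0.5) + 0.67 * gain
  expr <- tibble::as_tibble(cbind(tibble::tibble(gene_id = "HM13"),
                                  stats::setNames(as.data.frame(matrix(2^l2 - 1, 1)),
                                                  samples)))
  loi_calls <- tibble::tibble(sample_id = samples, gene_id = "HM13",
                              is_loi = loi_flag)
  res <- cnv_association(cnv, expr, loi_calls)
  expect_lt(res$expr_p, 1e-4)
  expect_gt(res$expr_log2_fc, 0.3)
  # small LOI subgroup: the gain enrichment is not significant
  expect_gt(res$chisq_p, 0.05)
  # all-zero scores: degenerate margins reported missing
  cnv0 <- cnv; cnv0[1, samples] <- 0L
  res0 <- suppressWarnings(cnv_association(cnv0, expr, loi_calls))
  expect_equal(res0$gain_fraction, 0)
  expect_true(is.na(res0$chisq_p))
  # independence identity: balanced 2x2 gives p = 1
  tab <- matrix(c(10, 10, 10, 10), 2)
  expect_equal(suppressWarnings(chisq.test(tab, correct = TRUE)$p.value), 1)
})

test_that("Cox regression is calibrated at the null and flags degeneracy", {
  set.seed(153)
  samples <- sprintf("S%03d", 1:500)
  l2 <- rnorm(500, 5, 1)
  surv <- simulate_survival(l2, log_hazard_beta = 0, censor_rate = 0.3)
  clin <- tibble::tibble(sample_id = samples, time = surv$time,
                         event = surv$event,
                         age = rnorm(500, 60, 10),
                         sex = sample(c("male", "female"), 500, TRUE))
  ex <- stats::setNames(2^l2 - 1, samples)
  res <- cox_survival(ex, clin, gene_id = "G")
  expect_true(res$converged)
  expect_gt(res$hazard_ratio, 0.9)
  expect_lt(res$hazard_ratio, 1.1)
  # all censored: flagged, no crash
  clin0 <- dplyr::mutate(clin, event = 0L)
  expect_warning(res0 <- cox_survival(ex, clin0, gene_id = "G"), "degenerate")
  expect_false(res0$converged)
})

test_that("KM grouping splits at the mean with ties going above", {
  ex <- stats::setNames(c(1, 2, 3, 4), sprintf("S%d", 1:4))
  g <- km_expression_groups(ex, log2_transform = FALSE)
  expect_equal(as.character(g), c("below", "below", "above", "above"))
  tie <- stats::setNames(rep(2, 3), sprintf("S%d", 1:3))
  expect_true(all(km_expression_groups(tie, log2_transform = FALSE) == "above"))
})

test_that("stage trend ANOVA detects monotone progression and matches t-test", {
  set.seed(154)
  stage <- rep(1:4, each = 60)
  l2 <- rnorm(240, 5 + 0.25 * (stage - 1), 0.5)
  res <- stage_trend(2^l2 - 1, stage)
  expect_lt(res$p_value, 0.001)
  expect_equal(nrow(res$stage_means), 4)
  expect_true(all(diff(res$stage_means$mean_log2_expr) > -0.2))
  # two groups: F-test equals the squared equal-variance t-test
  st2 <- rep(1:2, each = 30)
  x2 <- 2^rnorm(60, 5 + 0.3 * st2, 0.5) - 1
  r2 <- stage_trend(x2, st2)
  tt <- t.test(log2(x2 + 1)[st2 == 1], log2(x2 + 1)[st2 == 2],
               var.equal = TRUE)
  expect_equal(r2$p_value, tt$p.value, tolerance = 1e-10)
  expect_error(stage_trend(x2, rep(1, 60)), "two stages")
})

test_that("cohort balance diagnostics emulate the study design", {
  set.seed(155)
  hits <- replicate(200, {
    clin <- tibble::tibble(
      sample_id = sprintf("S%03d", 1:368),
      group = rep(c("normal", "tumor"), c(128, 240)),
      age = c(rnorm(128, 60.77, 13.28), rnorm(240, 60.00, 12.88)),
      sex = c(sample(c("female", "male"), 128, TRUE, c(0.33, 0.67)),
              sample(c("female", "male"), 240, TRUE, c(0.41, 0.59))))
    res <- cohort_balance_check(clin)
    c(age = res$p_value[res$check == "age t-test"] > 0.05,
      sex = res$p_value[res$check == "sex chi-squared"] > 0.05)
  })
  # the planted group difference leaves ~92% of replicates non-significant;
  # the bound sits 2.4 binomial SEs below that
  expect_gte(mean(hits["age", ]), 0.87)
  expect_gt(mean(hits["sex", ]), 0.5)
  # identical ages: t-test p = 1; missing covariate: warned, skipped
  clin_eq <- tibble::tibble(sample_id = sprintf("S%d", 1:20),
                            group = rep(c("normal", "tumor"), each = 10),
                            age = rep(rnorm(10, 60, 5), 2),
                            sex = rep(c("male", "female"), 10))
  res_eq <- cohort_balance_check(clin_eq)
  expect_equal(res_eq$p_value[res_eq$check == "age t-test"], 1)
  clin_na <- dplyr::select(clin_eq, -"age")
  expect_warning(cohort_balance_check(clin_na), "age")
})
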