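test_that("genotype priors follow the inbreeding-adjusted HWE formula", {
  plain <- genotype_priors(0.5, 0)
  expect_equal(c(plain$p_rr, plain$p_ra, plain$p_aa), c(0.25, 0.5, 0.25))
  mono <- genotype_priors(1.0, 0.0103667)
  expect_equal(c(mono$p_rr, mono$p_ra, mono$p_aa), c(1, 0, 0))
  adj <- genotype_priors(0.5, 0.0103667)
  expect_equal(adj$p_ra, 0.49481665)
  grid <- genotype_priors(seq(0, 1, 0.1), 0.0103667)
  expect_equal(grid$p_rr + grid$p_ra + grid$p_aa, rep(1, 11), tolerance = 1e-12)
  expect_true(all(grid$p_rr >= 0 & grid$p_ra >= 0 & grid$p_aa >= 0))
  expect_error(genotype_priors(1.5), "p")
})

test_that("allele-frequency estimation matches its definitions", {
  d <- toy_counts(rep(60, 10), rep(40, 10))
  est <- estimate_allele_frequencies(d)
  expect_equal(est$p_initial, 0.6)
  expect_equal(rowSums(as.matrix(est$posteriors)), rep(1, 10), tolerance = 1e-12)
  hom <- toy_counts(rep(30, 50), rep(0, 50))
  expect_gt(estimate_allele_frequencies(hom)$p_genotype, 0.99)
  expect_error(estimate_allele_frequencies(toy_counts(0, 0)), "depth")
  sim <- simulate_snp_counts(500, p = 0.4, i = 0, seed = 61)
  est2 <- estimate_allele_frequencies(
    data.frame(ref_count = sim$ref_count, alt_count = sim$alt_count))
  expect_lt(abs(est2$p_genotype - 0.4), 0.05)
})

test_that("heterozygous component fractions hit their limits", {
  expect_equal(unname(loiscan:::het_fractions(1, 0)), c(1, 0))
  expect_equal(unname(loiscan:::het_fractions(0, 0.002)), c(0.5, 0.5))
})

test_that("the fit recovers a strongly imprinted SNP and rejects its null", {
  sim <- simulate_snp_counts(200, p = 0.4, i = 0.95, seed = 71)
  fit <- fit_imprinting(sim[, c("ref_count", "alt_count")])
  expect_lt(abs(fit$i_hat - 0.95), 0.05)
  expect_lt(fit$p_lrt, 1e-10)
  expect_gte(fit$loglik_alt, fit$loglik_null - 1e-8)
  expect_equal(fit$lrt_stat, 2 * (fit$loglik_alt - fit$loglik_null))
  expect_equal(rowSums(as.matrix(fit$posteriors)), rep(1, 200),
               tolerance = 1e-9)
  expect_error(fit_imprinting(toy_counts(c(3, 0), c(0, 0))), "2 samples")
})

test_that("boundary LRT p-values follow the 50:50 chi-squared mixture", {
  expect_equal(lrt_pvalue(list(loglik_alt = 10, loglik_null = 10)), 1)
  expect_equal(lrt_pvalue(list(loglik_alt = 3.841 / 2, loglik_null = 0)),
               0.0250, tolerance = 1e-3)
  # numerical noise below the null is clipped
  expect_equal(lrt_pvalue(list(loglik_alt = -1e-9, loglik_null = 0)), 1)
  expect_error(lrt_pvalue(list(loglik_alt = NaN, loglik_null = 0)), "finite")
})

test_that("goodness of fit is high for self-consistent data, low otherwise", {
  sim <- simulate_snp_counts(1000, p = 0.4, i = 0.9, seed = 81)
  fit <- fit_imprinting(sim[, c("ref_count", "alt_count")])
  expect_gte(fit$gof, 0.9)
  expect_lte(fit$gof, 1)
  tiny <- fake_fit(c(1, 2), c(1, 0), c(2, 2))
  expect_warning(g <- goodness_of_fit(tiny), "depth")
  expect_true(is.na(g))
})

test_that("symmetry test is the exact binomial test of component assignment", {
  f1 <- fake_fit(rep(28, 20), rep(2, 20), c(rep(2, 10), rep(3, 10)))
  expect_equal(symmetry_test(f1), 1)
  f2 <- fake_fit(rep(28, 20), rep(2, 20), c(rep(2, 15), rep(3, 5)))
  expect_equal(symmetry_test(f2), 0.04139, tolerance = 1e-3)
  f3 <- fake_fit(rep(28, 20), rep(2, 20), rep(2, 20))
  expect_lt(symmetry_test(f3), 1e-4)
  f4 <- fake_fit(c(30, 0), c(0, 30), c(1, 4))
  expect_warning(p <- symmetry_test(f4), "heterozygous")
  expect_true(is.na(p))
})

test_that("median imprinting is the median per-sample allelic skew", {
  mono <- fake_fit(c(20, 25), c(0, 0), c(2, 3))
  expect_equal(median_imprinting(mono), 1)
  even <- fake_fit(c(10, 15), c(10, 15), c(2, 3))
  expect_equal(median_imprinting(even), 0)
  mixed <- fake_fit(c(18, 19, 20), c(2, 1, 0), c(2, 2, 3))
  expect_equal(median_imprinting(mixed), 0.9)
})

test_that("adding a perfectly monoallelic heterozygote never decreases i-hat", {
  sim <- simulate_snp_counts(80, p = 0.5, i = 0.9, seed = 91)
  base <- sim[, c("ref_count", "alt_count")]
  fit0 <- fit_imprinting(base)
  fit1 <- fit_imprinting(rbind(base, data.frame(ref_count = 30L, alt_count = 0L)))
  expect_gte(fit1$i_hat, fit0$i_hat - 1e-6)
})

test_that("SNP filters apply the strict printed thresholds", {
  sim <- simulate_snp_counts(200, p = 0.4, i = 0.95, seed = 101)
  cts <- toy_counts(sim$ref_count, sim$alt_count)
  fits <- detect_imprinting(cts, group = NULL)
  filt <- filter_snps(fits)
  expect_true(filt$pass_all[1])
  # strictness: exactly-at-threshold fails
  at4 <- dplyr::mutate(filt, median_coverage = 4)
  expect_false(filter_snps(at4)$pass_coverage[1])
  at30 <- dplyr::mutate(filt, n_samples = 30)
  expect_false(filter_snps(at30)$pass_n_samples[1])
  # switchable symmetry direction
  expect_equal(filter_snps(fits, symmetry_keep = "lt")$pass_symmetry[1],
               !filter_snps(fits, symmetry_keep = "ge")$pass_symmetry[1])
  # missing statistics fail their filter
  na_gof <- dplyr::mutate(fits, gof = NA_real_)
  ff <- filter_snps(na_gof)
  expect_false(ff$pass_gof[1])
  expect_false(ff$pass_all[1])
})

test_that("gene aggregation combines p-values and enforces the two-SNP rule", {
  snp_tbl <- tibble::tibble(
    snp_id = c("s1", "s2", "s3", "s4"),
    gene_id = c("GA", "GA", "GB", "PEG10"),
    p_lrt = c(1e-4, 1e-2, 1e-6, 0.5),
    i_hat = c(0.9, 0.8, 0.95, 0.2),
    pass_all = c(TRUE, TRUE, TRUE, FALSE))
  genes <- aggregate_genes(snp_tbl)
  ga <- genes[genes$gene_id == "GA", ]
  expect_equal(ga$gene_p, 1e-3)
  expect_equal(ga$n_significant_snps, 2L)
  expect_true(ga$imprinted)
  expect_equal(ga$mean_i_hat, 0.85)
  # one significant SNP, not whitelisted: no call even at tiny p
  gb <- genes[genes$gene_id == "GB", ]
  expect_false(gb$imprinted)
  # whitelisted gene: called with manual provenance
  wl <- genes[genes$gene_id == "PEG10", ]
  expect_true(wl$imprinted)
  expect_equal(wl$provenance, "manual")
  # geometric mean invariant under SNP reordering; identity for one SNP
  shuf <- aggregate_genes(snp_tbl[c(3, 1, 4, 2), ])
  expect_equal(dplyr::arrange(genes, gene_id)$gene_p,
               dplyr::arrange(shuf, gene_id)$gene_p)
  expect_equal(gb$gene_p, 1e-6)
})

test_that("mixture log-likelihood matches brute-force enumeration", {
  set.seed(111)
  for (rep in 1:3) {
    s <- sample(4:8, 1)
    n <- sample(1:6, s, replace = TRUE)
    ref <- rbinom(s, n, 0.5)
    for (i in c(0, 0.3, 0.9)) {
      p <- 0.45; f <- 0.0103667; eps <- 0.002
      l_rr <- dbinom(ref, n, 1 - eps, log = TRUE)
      l_aa <- dbinom(ref, n, eps, log = TRUE)
      got <- loiscan:::profile_loglik_i(ref, n, i, f, eps, l_rr, l_aa,
                                        p_start = p, em_iter = 0L)$loglik
      want <- enumerate_loglik(ref, n, p, i, f, eps)
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
})
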