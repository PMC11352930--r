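#' Hardy-Weinberg genotype priors with inbreeding
#'
#' Genotype frequencies under Hardy-Weinberg equilibrium adjusted for excess
#' homozygosity via the inbreeding coefficient F:
#' `P(RR) = p^2 + F p q`, `P(RA) = 2 p q (1 - F)`, `P(AA) = q^2 + F p q`.
#'
#' @param p Reference-allele frequency, vectorised.
#' @param f Inbreeding coefficient in `[0, 1)`. The cohort-level default
#'   used throughout this package is 0.0103667.
#' @return A tibble with columns `p`, `f`, `p_rr`, `p_ra`, `p_aa`.
#' @examples
#' genotype_priors(0.5, 0)          # plain HWE: 0.25 / 0.5 / 0.25
#' genotype_priors(0.5, 0.0103667)  # P(RA) = 0.49481665
#' @export
genotype_priors <- function(p, f = 0.0103667) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("`p` must lie in [0, 1].")
  }
  check_prob(f, "f", upper_open = TRUE)
  q <- 1 - p
  tibble(p = p, f = f,
         p_rr = p^2 + f * p * q,
         p_ra = 2 * p * q * (1 - f),
         p_aa = q^2 + f * p * q)
}

#' Estimate reference-allele frequency from allele counts
#'
#' Two estimates per SNP: `p_initial`, the pooled read proportion
#' `sum(ref) / sum(ref + alt)`, and `p_genotype`, obtained from one E-step of
#' the non-imprinted (i = 0) mixture: posterior genotype probabilities under
#' priors built from `p_initial`, then the posterior-expected allele dosage
#' `sum(2 post_RR + post_RA) / (2 N)`.
#'
#' @param counts Data frame with integer columns `ref_count` and `alt_count`
#'   (one row per sample at one SNP).
#' @param f Inbreeding coefficient.
#' @param eps Per-read miscall probability.
#' @return A list with `p_initial`, `p_genotype`, and `posteriors` (a tibble
#'   with per-sample `post_rr`, `post_ra`, `post_aa` summing to one).
#' @export
estimate_allele_frequencies <- function(counts, f = 0.0103667, eps = 0.002) {
  ref <- counts$ref_count; alt <- counts$alt_count
  check_counts(ref, "ref_count"); check_counts(alt, "alt_count")
  n <- ref + alt
  if (sum(n) == 0) {
    abort("Cannot estimate allele frequencies: total depth is zero.",
          class = "loiscan_estimation_error")
  }
  p_init <- sum(ref) / sum(n)
  w <- genotype_priors(p_init, f)
  # i = 0: both heterozygous components collapse to Binomial(n, 1/2).
  l <- cbind(dbinom(ref, n, 1 - eps, log = TRUE),
             dbinom(ref, n, 0.5, log = TRUE),
             dbinom(ref, n, eps, log = TRUE))
  lw <- sweep(l, 2, log(c(w$p_rr, w$p_ra, w$p_aa)), `+`)
  m <- do.call(pmax, as.data.frame(lw))
  e <- exp(lw - m)
  post <- e / rowSums(e)
  p_geno <- sum(2 * post[, 1] + post[, 2]) / (2 * length(n))
  list(p_initial = p_init, p_genotype = p_geno,
       posteriors = tibble(post_rr = post[, 1], post_ra = post[, 2],
                           post_aa = post[, 3]))
}

# Profile log-likelihood of the four-component mixture at a fixed degree of
# imprinting i, with the allele frequency p re-estimated by EM. The
# homozygous component log-likelihoods (which do not depend on i) are
# precomputed by the caller.
#
# Returns loglik, the profiled p, and the per-sample posterior matrix over
# (RR, het-hi, het-lo, AA).
profile_loglik_i <- function(ref, n, i, f, eps, l_rr, l_aa,
                             p_start, em_iter = 20L) {
  pis <- het_fractions(i, eps)
  lmat <- cbind(l_rr,
                dbinom(ref, n, pis[["hi"]], log = TRUE),
                dbinom(ref, n, pis[["lo"]], log = TRUE),
                l_aa)
  m <- do.call(pmax, as.data.frame(lmat))
  e <- exp(lmat - m)
  p <- p_start
  n_s <- length(ref)
  for (k in seq_len(em_iter)) {
    q <- 1 - p
    w <- c(p^2 + f * p * q, p * q * (1 - f), p * q * (1 - f),
           q^2 + f * p * q) # het prior split half/half over hi & lo
    num <- sweep(e, 2, w, `*`)
    z <- rowSums(num)
    # Posterior-expected reference-allele dosage: 2 for RR, 1 for either het.
    p_new <- sum((2 * num[, 1] + num[, 2] + num[, 3]) / z) / (2 * n_s)
    if (abs(p_new - p) < 1e-10) { p <- p_new; break }
    p <- p_new
  }
  q <- 1 - p
  w <- c(p^2 + f * p * q, p * q * (1 - f), p * q * (1 - f), q^2 + f * p * q)
  num <- sweep(e, 2, w, `*`)
  z <- rowSums(num)
  list(loglik = sum(m + log(z)), p = p, posteriors = num / z)
}

#' Fit the imprinting mixture model at one SNP
#'
#' Maximises the Hardy-Weinberg-conform binomial mixture likelihood over the
#' degree-of-imprinting parameter i in `[0, 1]`. Each sample's likelihood is
#' `P_RR Bin(x; n, 1-eps) + (P_RA/2) Bin(x; n, pi_hi) + (P_RA/2) Bin(x; n,
#' pi_lo) + P_AA Bin(x; n, eps)` with `pi_hi = i (1-eps) + (1-i)/2` and
#' `pi_lo = i eps + (1-i)/2`: at i = 0 the heterozygotes form a single peak
#' at 1/2, at i = 1 they coincide with the homozygous peaks. The allele
#' frequency p is profiled out by EM at each candidate i; i is optimised on a
#' grid (step `grid_step`) followed by local refinement to tolerance 1e-4.
#'
#' @param counts Data frame with columns `ref_count`, `alt_count` and
#'   optionally `sample_id`, `snp_id` (one SNP).
#' @param f Inbreeding coefficient.
#' @param eps Per-read miscall probability.
#' @param grid_step Grid resolution for the i search.
#' @param em_iter EM iterations profiling p at each i.
#' @return An object of class `imprinting_fit`; see [tidy.imprinting_fit()].
#'   Contains `i_hat`, `loglik_alt`, `loglik_null`, `lrt_stat`, `p_lrt`,
#'   allele-frequency estimates, per-sample posteriors, and the quality
#'   statistics `gof`, `p_symmetry`, `median_imprinting`.
#' @export
fit_imprinting <- function(counts, f = 0.0103667, eps = 0.002,
                           grid_step = 0.005, em_iter = 20L) {
  check_prob(f, "f", upper_open = TRUE)
  check_prob(eps, "eps", upper_open = TRUE)
  ref <- counts$ref_count; alt <- counts$alt_count
  check_counts(ref, "ref_count"); check_counts(alt, "alt_count")
  n <- ref + alt
  keep <- n > 0
  if (sum(keep) < 2L) {
    abort("Need at least 2 samples with positive depth to fit.",
          class = "loiscan_fit_error")
  }
  snp_id <- if ("snp_id" %in% names(counts)) counts$snp_id[1] else NA_character_
  sample_id <- if ("sample_id" %in% names(counts)) {
    counts$sample_id[keep]
  } else {
    sprintf("S%04d", which(keep))
  }
  ref_k <- ref[keep]; n_k <- n[keep]

  freqs <- estimate_allele_frequencies(counts[keep, , drop = FALSE], f, eps)
  p0 <- min(max(freqs$p_initial, 1e-6), 1 - 1e-6)

  l_rr <- dbinom(ref_k, n_k, 1 - eps, log = TRUE)
  l_aa <- dbinom(ref_k, n_k, eps, log = TRUE)
  ll_at <- function(i) {
    profile_loglik_i(ref_k, n_k, i, f, eps, l_rr, l_aa, p0, em_iter)$loglik
  }

  i_grid <- seq(0, 1, by = grid_step)
  ll_grid <- vapply(i_grid, ll_at, numeric(1))
  k_best <- which.max(ll_grid)
  lo <- i_grid[max(1L, k_best - 1L)]
  hi <- i_grid[min(length(i_grid), k_best + 1L)]
  if (hi > lo) {
    opt <- optimize(ll_at, interval = c(lo, hi), maximum = TRUE, tol = 1e-4)
    if (opt$objective >= ll_grid[k_best]) {
      i_hat <- opt$maximum; ll_alt <- opt$objective
    } else {
      i_hat <- i_grid[k_best]; ll_alt <- ll_grid[k_best]
    }
  } else {
    i_hat <- i_grid[k_best]; ll_alt <- ll_grid[k_best]
  }
  ll_null <- ll_grid[1] # i = 0

  final <- profile_loglik_i(ref_k, n_k, i_hat, f, eps, l_rr, l_aa, p0, em_iter)
  post <- final$posteriors
  colnames(post) <- c("post_rr", "post_hi", "post_lo", "post_aa")

  fit <- structure(list(
    snp_id = snp_id,
    sample_id = sample_id,
    ref_count = ref_k, alt_count = n_k - ref_k,
    f = f, eps = eps,
    p_initial = freqs$p_initial,
    p_genotype = freqs$p_genotype,
    p_profiled = final$p,
    i_hat = i_hat,
    loglik_alt = ll_alt,
    loglik_null = ll_null,
    posteriors = as_tibble(post),
    n_samples_used = sum(keep),
    median_coverage = median(n_k)
  ), class = "imprinting_fit")
  fit$lrt_stat <- max(0, 2 * (fit$loglik_alt - fit$loglik_null))
  fit$p_lrt <- lrt_pvalue(fit)
  fit$gof <- goodness_of_fit(fit)
  fit$p_symmetry <- symmetry_test(fit)
  fit$median_imprinting <- median_imprinting(fit)
  fit
}

#' Boundary-corrected likelihood-ratio p-value
#'
#' The null hypothesis i = 0 lies on the boundary of the parameter space, so
#' the LRT statistic is asymptotically a 50:50 mixture of a point mass at
#' zero and a chi-squared with one degree of freedom:
#' `p = 0.5 P(chisq_1 > stat)` for positive statistics, 1 otherwise.
#' Negative statistics arising from numerical noise are clipped to zero.
#'
#' @param fit An `imprinting_fit`, or a list with finite `loglik_alt` and
#'   `loglik_null` elements.
#' @return One-sided p-value in `[0, 1]`.
#' @export
lrt_pvalue <- function(fit) {
  la <- fit$loglik_alt; l0 <- fit$loglik_null
  if (!is.finite(la) || !is.finite(l0)) {
    abort("Log-likelihoods must be finite.", class = "loiscan_fit_error")
  }
  stat <- max(0, 2 * (la - l0))
  if (stat <= 0) return(1)
  0.5 * pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Goodness of fit of the imprinting mixture
#'
#' One minus the total-variation distance between the empirical distribution
#' of reference-allele read fractions (20 equal bins on `[0, 1]`, samples
#' with depth >= 5) and the fitted mixture's predictive distribution over
#' the same bins (each sample's exact predictive bin probabilities, averaged
#' across samples). 1 means a perfect match; small values flag SNPs whose
#' count distribution the model cannot explain.
#'
#' @param fit An `imprinting_fit`.
#' @param n_bins Number of allele-fraction bins.
#' @param min_depth Minimum per-sample depth to enter the statistic.
#' @return Value in `[0, 1]`, or `NA` (with a warning) if no sample
#'   reaches `min_depth`.
#' @export
goodness_of_fit <- function(fit, n_bins = 20L, min_depth = 5L) {
  n <- fit$ref_count + fit$alt_count
  keep <- n >= min_depth
  if (!any(keep)) {
    warn("goodness_of_fit undefined: no sample with depth >= 5.")
    return(NA_real_)
  }
  ref <- fit$ref_count[keep]; nn <- n[keep]
  brks <- seq(0, 1, length.out = n_bins + 1L)
  bin_of <- function(fr) pmin(pmax(ceiling(fr * n_bins), 1L), n_bins)
  emp <- tabulate(bin_of(ref / nn), nbins = n_bins) / length(ref)

  p <- fit$p_profiled; f <- fit$f; eps <- fit$eps; i <- fit$i_hat
  w <- genotype_priors(p, f)
  pis <- het_fractions(i, eps)
  pred <- numeric(n_bins)
  for (s in seq_along(nn)) {
    x <- 0:nn[s]
    pmf <- w$p_rr * dbinom(x, nn[s], 1 - eps) +
      w$p_ra / 2 * dbinom(x, nn[s], pis[["hi"]]) +
      w$p_ra / 2 * dbinom(x, nn[s], pis[["lo"]]) +
      w$p_aa * dbinom(x, nn[s], eps)
    bins <- bin_of(x / nn[s])
    pred <- pred + vapply(seq_len(n_bins),
                          function(b) sum(pmf[bins == b]), numeric(1))
  }
  pred <- pred / length(nn)
  1 - 0.5 * sum(abs(emp - pred))
}

#' Symmetry of the heterozygous component assignment
#'
#' With the silenced allele assorting independently of the read-out allele,
#' heterozygotes should split evenly between the high and the low
#' reference-fraction component. Samples are assigned to their
#' maximum-posterior component; the counts assigned to the two heterozygous
#' components are compared by an exact two-sided binomial test at success
#' probability one half. Strong asymmetry points away from imprinting
#' (e.g., towards a cis-eQTL or mapping artefact).
#'
#' @param fit An `imprinting_fit`.
#' @return Two-sided exact binomial p-value, or `NA` (with a warning) if no
#'   sample is assigned to a heterozygous component.
#' @export
symmetry_test <- function(fit) {
  comp <- max.col(as.matrix(fit$posteriors), ties.method = "first")
  k_hi <- sum(comp == 2L); k_lo <- sum(comp == 3L)
  if (k_hi + k_lo == 0L) {
    warn("symmetry_test undefined: no heterozygous-component sample.")
    return(NA_real_)
  }
  binom.test(k_hi, k_hi + k_lo, p = 0.5)$p.value
}

#' Robust median imprinting
#'
#' Per-sample degree of imprinting `(max(ref, alt) - min(ref, alt)) / (ref +
#' alt)` — 1 for fully monoallelic samples, 0 at a 50/50 split — computed
#' over samples whose maximum-posterior component is heterozygous and whose
#' depth is at least `min_depth`; the median is returned.
#'
#' @param fit An `imprinting_fit`.
#' @param min_depth Minimum per-sample depth.
#' @return Median per-sample imprinting degree, or `NA` with a warning when
#'   no sample qualifies.
#' @export
median_imprinting <- function(fit, min_depth = 5L) {
  comp <- max.col(as.matrix(fit$posteriors), ties.method = "first")
  n <- fit$ref_count + fit$alt_count
  keep <- comp %in% c(2L, 3L) & n >= min_depth
  if (!any(keep)) {
    warn("median_imprinting undefined: no heterozygous sample with depth >= 5.")
    return(NA_real_)
  }
  d <- abs(fit$ref_count[keep] - fit$alt_count[keep]) / n[keep]
  median(d)
}

#' @export
print.imprinting_fit <- function(x, ...) {
  cat("<imprinting_fit>", if (!is.na(x$snp_id)) x$snp_id else "", "\n")
  cat(sprintf("  samples: %d  median coverage: %g\n",
              x$n_samples_used, x$median_coverage))
  cat(sprintf("  p_initial: %.4f  p_genotype: %.4f\n",
              x$p_initial, x$p_genotype))
  cat(sprintf("  i_hat: %.4f  LRT p: %.3g  GOF: %.3f  p_symmetry: %.3g  median imprinting: %.3f\n",
              x$i_hat, x$p_lrt, x$gof, x$p_symmetry, x$median_imprinting))
  invisible(x)
}
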