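# broom-style tidiers.

#' Tidy an imprinting mixture fit
#'
#' @param x An `imprinting_fit`.
#' @param ... Unused.
#' @return One-row tibble with every per-SNP scalar: identifiers, sample
#'   tallies, allele-frequency estimates, `i_hat`, log-likelihoods, the
#'   boundary LRT statistic and p-value, and the quality statistics.
#' @export
tidy.imprinting_fit <- function(x, ...) {
  tibble(
    snp_id = x$snp_id,
    n_samples = x$n_samples_used,
    median_coverage = x$median_coverage,
    p_initial = x$p_initial,
    p_genotype = x$p_genotype,
    i_hat = x$i_hat,
    eps = x$eps,
    loglik_alt = x$loglik_alt,
    loglik_null = x$loglik_null,
    lrt_stat = x$lrt_stat,
    p_lrt = x$p_lrt,
    gof = x$gof,
    p_symmetry = x$p_symmetry,
    median_imprinting = x$median_imprinting
  )
}

#' @rdname tidy.imprinting_fit
#' @export
glance.imprinting_fit <- function(x, ...) {
  tibble(n_samples = x$n_samples_used,
         i_hat = x$i_hat,
         lrt_stat = x$lrt_stat,
         p_lrt = x$p_lrt,
         loglik = x$loglik_alt)
}

#' Tidy a pipeline report
#'
#' @param x A `loi_pipeline_report`.
#' @param ... Unused.
#' @return The per-gene summary table (gene, number of significant SNPs,
#'   mean degree of imprinting, LOI and DE FDR, log2 fold change).
#' @export
tidy.loi_pipeline_report <- function(x, ...) {
  x$gene_table
}

#' @rdname tidy.loi_pipeline_report
#' @export
glance.loi_pipeline_report <- function(x, ...) {
  as_tibble(x$counts[c("snps_tested", "snps_pass", "genes_tested",
                       "genes_imprinted", "genes_loi", "genes_canonical")])
}
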