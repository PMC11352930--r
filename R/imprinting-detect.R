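#' Default imprinted-gene whitelist
#'
#' Known imprinted loci that the two-significant-SNP rule tends to drop
#' (each typically carries a single informative SNP); genes on this list are
#' retained in the gene-level table with provenance `"manual"`.
#'
#' @return Character vector of gene identifiers.
#' @export
imprinting_whitelist <- function() {
  c("SLC9A3R2", "PEG10", "NDN", "GNAS", "RPH3AL")
}

#' SNP filter thresholds for imprinting detection
#'
#' The screening thresholds applied to every fitted SNP, all strict
#' inequalities: median coverage > 4, number of samples > 30, initial minor
#' allele frequency > 0.1, genotype-estimate minor allele frequency > 0.15,
#' goodness of fit > 0.80, degree of imprinting > 0.60, robust median
#' imprinting > 0.80, SNP-level FDR < 0.05, plus the heterozygous-symmetry
#' screen at 0.05 (see [filter_snps()] for its direction).
#'
#' @param median_coverage,n_samples,maf_initial,maf_genotype,gof,i_hat,median_imprinting,symmetry_alpha,fdr Individual thresholds.
#' @return Named list of thresholds.
#' @export
imprinting_filter_thresholds <- function(median_coverage = 4,
                                         n_samples = 30,
                                         maf_initial = 0.1,
                                         maf_genotype = 0.15,
                                         gof = 0.80,
                                         i_hat = 0.60,
                                         median_imprinting = 0.80,
                                         symmetry_alpha = 0.05,
                                         fdr = 0.05) {
  as.list(environment())
}

#' Fit the imprinting model across all SNPs of a count table
#'
#' Runs [fit_imprinting()] per SNP on an allele-count table (normally the
#' solid-tissue-normal subpopulation) and collects every per-SNP scalar into
#' one tibble. SNPs whose fit fails its preconditions (fewer than two
#' samples with reads) are dropped with a message.
#'
#' @param allele_counts Data frame with columns `snp_id`, `ref_count`,
#'   `alt_count`, optionally `gene_id`, `sample_id`, `group`.
#' @param f Inbreeding coefficient.
#' @param eps Per-read miscall probability.
#' @param group If the table has a `group` column, restrict to this group
#'   (default `"normal"`; use `NULL` to keep all rows).
#' @param ... Passed on to [fit_imprinting()].
#' @return A tibble, one row per SNP, with the fitted parameters and quality
#'   statistics; the full `imprinting_fit` objects are attached as the
#'   `"fits"` attribute (named by SNP).
#' @export
detect_imprinting <- function(allele_counts, f = 0.0103667, eps = 0.002,
                              group = "normal", ...) {
  stopifnot(is.data.frame(allele_counts))
  if (!is.null(group) && "group" %in% names(allele_counts)) {
    allele_counts <- allele_counts[allele_counts$group %in% group, ,
                                   drop = FALSE]
  }
  need <- c("snp_id", "ref_count", "alt_count")
  miss <- setdiff(need, names(allele_counts))
  if (length(miss)) {
    abort(sprintf("`allele_counts` is missing column(s): %s.",
                  paste(miss, collapse = ", ")))
  }
  gene_map <- if ("gene_id" %in% names(allele_counts)) {
    distinct(allele_counts, .data$snp_id, .data$gene_id)
  } else {
    NULL
  }
  split_counts <- split(allele_counts, allele_counts$snp_id)
  fits <- list()
  rows <- purrr::map(split_counts, function(d) {
    fit <- tryCatch(
      suppressWarnings(fit_imprinting(d, f = f, eps = eps, ...)),
      loiscan_fit_error = function(e) NULL)
    if (is.null(fit)) {
      inform(sprintf("SNP %s skipped: too few samples with reads.",
                     d$snp_id[1]))
      return(NULL)
    }
    fits[[d$snp_id[1]]] <<- fit
    tidy(fit)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    abort("No SNP could be fitted.", class = "loiscan_fit_error")
  }
  if (!is.null(gene_map)) {
    out <- left_join(out, gene_map, by = "snp_id") |>
      relocate("gene_id", .after = "snp_id")
  }
  attr(out, "fits") <- fits
  out
}

#' Apply the SNP-level imprinting filters
#'
#' Applies the screening filters of [imprinting_filter_thresholds()] to a
#' per-SNP fit table, records every observed value next to its threshold,
#' and combines them into an overall pass flag. Missing statistics fail
#' their filter. The SNP-level FDR filter is Benjamini-Hochberg over all
#' SNPs in `fits`.
#'
#' The direction of the heterozygous-symmetry screen is switchable:
#' `symmetry_keep = "ge"` (default) keeps SNPs whose heterozygote assignment
#' is consistent with symmetry (p >= alpha), which is the direction under
#' which a symmetric imprinting signal survives; `"lt"` keeps SNPs where
#' symmetry is rejected.
#'
#' @param fits Tibble from [detect_imprinting()].
#' @param thresholds List from [imprinting_filter_thresholds()].
#' @param symmetry_keep `"ge"` or `"lt"`, see above.
#' @return The input tibble augmented with `q_snp`, one `pass_*` logical
#'   per filter, and `pass_all`.
#' @export
filter_snps <- function(fits, thresholds = imprinting_filter_thresholds(),
                        symmetry_keep = c("ge", "lt")) {
  symmetry_keep <- match.arg(symmetry_keep)
  th <- thresholds
  out <- fits[setdiff(names(fits), grep("^pass_", names(fits), value = TRUE))]
  out$maf_initial <- pmin(out$p_initial, 1 - out$p_initial)
  out$maf_genotype <- pmin(out$p_genotype, 1 - out$p_genotype)
  out$q_snp <- p.adjust(out$p_lrt, method = "BH")
  pass <- function(x) !is.na(x) & x
  out$pass_coverage <- pass(out$median_coverage > th$median_coverage)
  out$pass_n_samples <- pass(out$n_samples > th$n_samples)
  out$pass_maf_initial <- pass(out$maf_initial > th$maf_initial)
  out$pass_maf_genotype <- pass(out$maf_genotype > th$maf_genotype)
  out$pass_symmetry <- if (symmetry_keep == "ge") {
    pass(out$p_symmetry >= th$symmetry_alpha)
  } else {
    pass(out$p_symmetry < th$symmetry_alpha)
  }
  out$pass_gof <- pass(out$gof > th$gof)
  out$pass_i_hat <- pass(out$i_hat > th$i_hat)
  out$pass_median_imprinting <-
    pass(out$median_imprinting > th$median_imprinting)
  out$pass_fdr <- pass(out$q_snp < th$fdr)
  flag_cols <- grep("^pass_", names(out), value = TRUE)
  out$pass_all <- Reduce(`&`, out[flag_cols])
  attr(out, "thresholds") <- th
  attr(out, "symmetry_keep") <- symmetry_keep
  out
}

#' Gene-level imprinting consensus
#'
#' Combines SNP-level likelihood-ratio p-values into a gene-level consensus
#' by the geometric mean, adjusts across genes by Benjamini-Hochberg, and
#' calls a gene imprinted when its FDR is below `fdr` and at least
#' `min_significant_snps` of its SNPs pass all filters — or when the gene is
#' on the manual whitelist of known imprinted loci.
#'
#' @param snp_results Tibble from [filter_snps()] with columns `snp_id`,
#'   `gene_id`, `p_lrt`, `i_hat`, `pass_all`.
#' @param whitelist Character vector of genes kept with provenance
#'   `"manual"` (default [imprinting_whitelist()]).
#' @param fdr Gene-level FDR threshold.
#' @param min_significant_snps Minimum number of filter-passing SNPs.
#' @return Tibble with one row per gene: `gene_id`, `snp_ids`, `n_snps`,
#'   `gene_p`, `gene_q`, `n_significant_snps`, `mean_i_hat` (over
#'   significant SNPs), `whitelisted`, `provenance`, `imprinted`.
#' @export
aggregate_genes <- function(snp_results, whitelist = imprinting_whitelist(),
                            fdr = 0.05, min_significant_snps = 2L) {
  if (!"gene_id" %in% names(snp_results)) {
    abort("`snp_results` needs a `gene_id` column for gene aggregation.")
  }
  snp_results <- snp_results[!is.na(snp_results$gene_id), , drop = FALSE]
  dropped <- setdiff(unique(snp_results$gene_id[is.na(snp_results$p_lrt)]),
                     unique(snp_results$gene_id[!is.na(snp_results$p_lrt)]))
  if (length(dropped)) {
    inform(sprintf("Gene(s) without any tested SNP excluded: %s.",
                   paste(dropped, collapse = ", ")))
  }
  out <- snp_results |>
    filter(!is.na(.data$p_lrt)) |>
    group_by(.data$gene_id) |>
    summarise(
      snp_ids = paste(.data$snp_id, collapse = ","),
      n_snps = n(),
      gene_p = geometric_mean_p(.data$p_lrt),
      n_significant_snps = sum(.data$pass_all),
      mean_i_hat = if (any(.data$pass_all)) {
        mean(.data$i_hat[.data$pass_all])
      } else {
        NA_real_
      },
      .groups = "drop"
    )
  out$gene_q <- p.adjust(out$gene_p, method = "BH")
  out$whitelisted <- out$gene_id %in% whitelist
  out$provenance <- if_else(out$whitelisted, "manual", "statistical")
  out$imprinted <- (out$gene_q < fdr &
                      out$n_significant_snps >= min_significant_snps) |
    out$whitelisted
  out |>
    relocate("gene_q", .after = "gene_p") |>
    arrange(.data$gene_q)
}
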