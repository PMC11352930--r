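# Differential expression and canonical-LOI classification.

# Pivot a genes-x-samples wide tibble (gene_id + one column per sample)
# into long form.
expr_long <- function(expr) {
  if (!"gene_id" %in% names(expr)) {
    abort("Expression table needs a `gene_id` column.")
  }
  tidyr::pivot_longer(expr, -"gene_id",
                      names_to = "sample_id", values_to = "rpkm")
}

welch_or_paired_t <- function(x, y, paired) {
  if (paired && length(x) != length(y)) {
    abort("Paired comparison requires equal group sizes in matched order.")
  }
  vx <- if (paired) sd(x - y) else max(sd(x), sd(y))
  if (!is.finite(vx) || vx == 0) {
    warn("Zero variance; p-value set to 1.")
    return(list(p = 1, fc = mean(x) - mean(y)))
  }
  tt <- t.test(x, y, paired = paired)
  list(p = tt$p.value, fc = mean(x) - mean(y))
}

#' Gene-level differential expression
#'
#' Welch two-sample (or paired) t-tests on `log2(RPKM + 1)` per gene; the
#' effect size is the case-minus-control mean difference on that scale
#' (log2 fold change), and p-values are Benjamini-Hochberg adjusted across
#' genes.
#'
#' @param expr Wide expression tibble: `gene_id` plus one column per sample
#'   (RPKM scale).
#' @param sample_info Data frame with `sample_id`, a two-level `group`
#'   column, and (for paired tests) `pair_id`.
#' @param control,case Group labels; `log2_fc` is case minus control.
#' @param paired Use a paired t-test; pairs are matched through `pair_id`,
#'   and incomplete pairs are dropped with a message.
#' @param comparison Label stored in the output.
#' @return Tibble: `gene_id`, `log2_fc`, `p_value`, `q_value`,
#'   `comparison`, `paired`, `n_control`, `n_case`.
#' @export
differential_expression <- function(expr, sample_info,
                                    control = "normal", case = "tumor",
                                    paired = FALSE,
                                    comparison = paste(case, "vs", control)) {
  si <- sample_info[sample_info$group %in% c(control, case), , drop = FALSE]
  if (paired) {
    if (!"pair_id" %in% names(si)) {
      abort("Paired analysis requires a `pair_id` column in `sample_info`.")
    }
    complete <- si |>
      group_by(.data$pair_id) |>
      filter(n() == 2L, length(unique(.data$group)) == 2L) |>
      ungroup()
    dropped <- dplyr::n_distinct(si$pair_id) - dplyr::n_distinct(complete$pair_id)
    if (dropped > 0) {
      inform(sprintf("%d incomplete pair(s) dropped from the paired analysis.",
                     dropped))
    }
    si <- arrange(complete, .data$pair_id, .data$group)
  }
  ctrl_ids <- si$sample_id[si$group == control]
  case_ids <- si$sample_id[si$group == case]
  if (length(ctrl_ids) < 2 || length(case_ids) < 2) {
    abort("Need at least 2 samples (or pairs) per group.")
  }
  long <- expr_long(expr) |>
    filter(.data$sample_id %in% c(ctrl_ids, case_ids)) |>
    mutate(l2 = log2(.data$rpkm + 1))
  out <- long |>
    group_by(.data$gene_id) |>
    summarise(res = {
      xs <- .data$l2[match(case_ids, .data$sample_id)]
      ys <- .data$l2[match(ctrl_ids, .data$sample_id)]
      list(welch_or_paired_t(xs, ys, paired))
    }, .groups = "drop") |>
    mutate(log2_fc = purrr::map_dbl(.data$res, "fc"),
           p_value = purrr::map_dbl(.data$res, "p")) |>
    select(-"res")
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out$comparison <- comparison
  out$paired <- paired
  out$n_control <- length(ctrl_ids)
  out$n_case <- length(case_ids)
  out
}

#' SNP-level differential expression combined per gene
#'
#' For genes without an expression matrix entry, total allelic coverage acts
#' as an expression proxy: per-sample SNP totals are library-size corrected
#' to counts per million, log2(x + 1) transformed, compared by Welch t-test
#' per SNP, and combined per gene by the geometric mean.
#'
#' @param allele_counts Allele-count table with `sample_id`, `snp_id`,
#'   `gene_id`, `ref_count`, `alt_count`, `group`.
#' @param control,case Group labels.
#' @return Tibble: `gene_id`, `n_snps`, `p_value`, `q_value`.
#' @export
snp_level_de <- function(allele_counts, control = "normal", case = "tumor") {
  d <- allele_counts[allele_counts$group %in% c(control, case), , drop = FALSE]
  d$total <- d$ref_count + d$alt_count
  libs <- d |>
    group_by(.data$sample_id) |>
    summarise(lib = sum(.data$total), .groups = "drop")
  zero <- libs$sample_id[libs$lib == 0]
  if (length(zero)) {
    warn(sprintf("%d sample(s) with zero library size excluded.", length(zero)))
    d <- d[!d$sample_id %in% zero, , drop = FALSE]
    libs <- libs[libs$lib > 0, , drop = FALSE]
  }
  d <- left_join(d, libs, by = "sample_id") |>
    mutate(log_cpm = log2(.data$total / .data$lib * 1e6 + 1))
  snp_p <- d |>
    group_by(.data$snp_id, .data$gene_id) |>
    summarise(p_value = {
      xs <- .data$log_cpm[.data$group == case]
      ys <- .data$log_cpm[.data$group == control]
      welch_or_paired_t(xs, ys, paired = FALSE)$p
    }, .groups = "drop")
  out <- snp_p |>
    group_by(.data$gene_id) |>
    summarise(n_snps = n(),
              p_value = geometric_mean_p(.data$p_value), .groups = "drop")
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out
}

#' Classify canonical LOI
#'
#' Canonical LOI combines loss-of-imprinting with expression upregulation:
#' a gene is canonical when its LOI FDR and its differential-expression FDR
#' are both below 0.05, its log2 fold change (tumor over normal) exceeds
#' 0.5, and it is not flagged as a random monoallelic expression (RME)
#' locus.
#'
#' @param loi_genes Tibble from [combine_loi_gene()] (`gene_id`, `gene_q`).
#' @param de_genes Tibble from [differential_expression()] or
#'   [snp_level_de()] (`gene_id`, `q_value`, `log2_fc`; a missing
#'   `log2_fc` fails the fold-change criterion).
#' @param rme_flags Character vector of genes flagged as RME.
#' @param loi_fdr,de_fdr,min_log2_fc Classification thresholds.
#' @return Tibble: `gene_id`, `loi_q`, `de_q`, `log2_fc`, `rme`,
#'   `canonical`. Genes missing from either input are omitted with a
#'   message.
#' @export
classify_canonical_loi <- function(loi_genes, de_genes,
                                   rme_flags = character(),
                                   loi_fdr = 0.05, de_fdr = 0.05,
                                   min_log2_fc = 0.5) {
  if (!"log2_fc" %in% names(de_genes)) de_genes$log2_fc <- NA_real_
  joined <- inner_join(
    select(loi_genes, "gene_id", loi_q = "gene_q"),
    select(de_genes, "gene_id", de_q = "q_value", "log2_fc"),
    by = "gene_id")
  missing <- setdiff(union(loi_genes$gene_id, de_genes$gene_id),
                     joined$gene_id)
  if (length(missing)) {
    inform(sprintf("Gene(s) missing from one input, not classified: %s.",
                   paste(missing, collapse = ", ")))
  }
  joined$rme <- joined$gene_id %in% rme_flags
  joined$canonical <- joined$loi_q < loi_fdr & joined$de_q < de_fdr &
    !is.na(joined$log2_fc) & joined$log2_fc > min_log2_fc & !joined$rme
  arrange(joined, dplyr::desc(.data$canonical), .data$loi_q)
}
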