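# Methylation contrasts and copy-number association.

#' Beta/M-value transforms
#'
#' Methylation beta values (fraction methylated, in `[0, 1]`) are clipped to
#' the open interval and logit-2 transformed for testing:
#' `M = log2(beta / (1 - beta))`; `m_to_beta()` inverts the transform.
#'
#' @param beta Numeric vector in `[0, 1]`.
#' @param m Numeric vector of M-values.
#' @param clip Clipping margin before the transform.
#' @return Numeric vector.
#' @export
beta_to_m <- function(beta, clip = 1e-6) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    abort("`beta` must lie in [0, 1].")
  }
  b <- pmin(pmax(beta, clip), 1 - clip)
  log2(b / (1 - b))
}

#' @rdname beta_to_m
#' @export
m_to_beta <- function(m) {
  2^m / (1 + 2^m)
}

#' Differential methylation on M-values
#'
#' Per-probe Welch t-tests on M-values for every pairwise contrast of the
#' sample groups (e.g., stage 1 LOI tumor vs stage 1 non-LOI tumor vs solid
#' tissue normal), Benjamini-Hochberg adjusted within each contrast. Effect
#' sizes are reported back on the beta scale as group-mean differences.
#'
#' @param beta Wide methylation tibble: `probe_id` (and optional extra
#'   annotation columns) plus one column per sample, beta scale.
#' @param sample_info Data frame with `sample_id` and `group`.
#' @param contrasts Optional list of length-2 character vectors
#'   `c(case, control)`; default: all pairwise combinations.
#' @return Tibble: `probe_id`, `contrast`, `mean_beta_case`,
#'   `mean_beta_control`, `delta_beta`, `p_value`, `q_value`.
#' @export
methylation_dm <- function(beta, sample_info, contrasts = NULL) {
  if (!"probe_id" %in% names(beta)) {
    abort("Methylation table needs a `probe_id` column.")
  }
  anno <- intersect(names(beta), c("probe_id", "gene_id"))
  long <- tidyr::pivot_longer(beta, -all_of(anno),
                              names_to = "sample_id", values_to = "beta") |>
    inner_join(sample_info[, c("sample_id", "group")], by = "sample_id") |>
    mutate(m = beta_to_m(.data$beta))
  groups <- sort(unique(long$group))
  if (length(groups) < 2) abort("Need at least two sample groups.")
  if (is.null(contrasts)) {
    contrasts <- utils::combn(groups, 2, function(g) c(g[2], g[1]),
                              simplify = FALSE)
  }
  purrr::map_dfr(contrasts, function(ct) {
    case <- ct[1]; control <- ct[2]
    sub <- long[long$group %in% ct, , drop = FALSE]
    res <- sub |>
      group_by(.data$probe_id) |>
      summarise(
        mean_beta_case = mean(.data$beta[.data$group == case]),
        mean_beta_control = mean(.data$beta[.data$group == control]),
        p_value = {
          xs <- .data$m[.data$group == case]
          ys <- .data$m[.data$group == control]
          welch_or_paired_t(xs, ys, paired = FALSE)$p
        },
        .groups = "drop") |>
      mutate(delta_beta = .data$mean_beta_case - .data$mean_beta_control,
             contrast = paste(case, "vs", control))
    res$q_value <- p.adjust(res$p_value, method = "BH")
    relocate(res, "contrast", .after = "probe_id")
  })
}

#' Copy-number association with expression and LOI
#'
#' Per gene: the copy-number gain fraction (GISTIC-like score > 0), a Welch
#' t-test comparing `log2(RPKM + 1)` between gain and no-gain samples, a
#' continuity-corrected chi-squared test on the 2x2 gain-by-LOI table, and
#' the cohort mutation count.
#'
#' @param cnv Wide CNV tibble: `gene_id` plus one integer score column per
#'   sample (scores in -2..2).
#' @param expr Wide expression tibble (RPKM scale).
#' @param loi_calls Tibble from [call_loi_samples()] (`sample_id`,
#'   `gene_id`, `is_loi`).
#' @param mutations Optional tibble of mutation records (`gene_id`,
#'   `sample_id`).
#' @param samples Optional sample ids to restrict to (e.g. stage 1 tumors).
#' @return Tibble: `gene_id`, `n`, `gain_fraction`, `expr_log2_fc`,
#'   `expr_p`, `loi_gain_fraction`, `chisq_p`, `n_mutations`.
#' @export
cnv_association <- function(cnv, expr, loi_calls,
                            mutations = NULL, samples = NULL) {
  score_long <- tidyr::pivot_longer(cnv, -"gene_id",
                                    names_to = "sample_id",
                                    values_to = "score")
  if (any(!score_long$score %in% -2:2)) {
    abort("CNV scores must be integers in -2..2.")
  }
  if (!is.null(samples)) {
    score_long <- score_long[score_long$sample_id %in% samples, , drop = FALSE]
  }
  el <- expr_long(expr) |> mutate(l2 = log2(.data$rpkm + 1))
  d <- score_long |>
    mutate(gain = .data$score > 0) |>
    left_join(el, by = c("gene_id", "sample_id")) |>
    left_join(loi_calls[, c("sample_id", "gene_id", "is_loi")],
              by = c("gene_id", "sample_id"))
  d |>
    group_by(.data$gene_id) |>
    summarise(
      n = n(),
      gain_fraction = mean(.data$gain),
      expr_log2_fc = if (sum(.data$gain) >= 2 && sum(!.data$gain) >= 2 &&
                           !all(is.na(.data$l2))) {
        mean(.data$l2[.data$gain], na.rm = TRUE) -
          mean(.data$l2[!.data$gain], na.rm = TRUE)
      } else {
        NA_real_
      },
      expr_p = if (sum(.data$gain) >= 2 && sum(!.data$gain) >= 2 &&
                     !all(is.na(.data$l2))) {
        welch_or_paired_t(.data$l2[.data$gain & !is.na(.data$l2)],
                          .data$l2[!.data$gain & !is.na(.data$l2)],
                          paired = FALSE)$p
      } else {
        NA_real_
      },
      loi_gain_fraction = if (any(!is.na(.data$is_loi) & .data$is_loi)) {
        mean(.data$gain[!is.na(.data$is_loi) & .data$is_loi])
      } else {
        NA_real_
      },
      chisq_p = {
        ok <- !is.na(.data$is_loi)
        tab <- table(gain = .data$gain[ok], loi = .data$is_loi[ok])
        if (all(dim(tab) == c(2L, 2L)) && all(rowSums(tab) > 0) &&
              all(colSums(tab) > 0)) {
          suppressWarnings(chisq.test(tab, correct = TRUE)$p.value)
        } else {
          warn(sprintf("Gene %s: empty margin in the gain-by-LOI table.",
                       .data$gene_id[1]))
          NA_real_
        }
      },
      .groups = "drop"
    ) |>
    left_join(
      if (is.null(mutations) || nrow(mutations) == 0) {
        tibble(gene_id = character(), n_mutations = integer())
      } else {
        mutations |> group_by(.data$gene_id) |>
          summarise(n_mutations = n(), .groups = "drop")
      },
      by = "gene_id") |>
    mutate(n_mutations = dplyr::coalesce(.data$n_mutations, 0L))
}
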