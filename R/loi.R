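#' Per-sample degree of LOI
#'
#' The read coverage of the least- over the most-expressed allele: 1 for a
#' perfect heterozygote (equal counts), 0 for a perfect homozygote (all
#' reads on one allele). Vectorised; a sample with zero reads on both
#' alleles has an undefined ratio and returns `NA`.
#'
#' @param ref_count,alt_count Non-negative integer read counts.
#' @return Numeric vector of ratios in `[0, 1]`.
#' @examples
#' degree_of_loi(15, 15) # 1
#' degree_of_loi(30, 0)  # 0
#' @export
degree_of_loi <- function(ref_count, alt_count) {
  check_counts(ref_count, "ref_count")
  check_counts(alt_count, "alt_count")
  least <- pmin(ref_count, alt_count)
  most <- pmax(ref_count, alt_count)
  out <- ifelse(most == 0, NA_real_, least / most)
  if (any(is.na(out))) {
    warn("degree_of_loi undefined (NA) for samples with zero total depth.")
  }
  out
}

#' Binomial logistic LOI test at one SNP
#'
#' Models each sample's least-expressed allele reads as binomial successes
#' (most-expressed reads as failures) and regresses on case status:
#' `logit(pi_s) = b0 + b1 * 1[case]`. Re-expression of the silenced allele
#' in cases gives a positive `b1`; the reported p-value is the one-sided
#' Wald test of `b1 > 0`.
#'
#' When one group has no successes (or no failures) at all, the Wald
#' standard error diverges and its p-value is uninformative; the one-sided
#' p is then derived from the signed likelihood-ratio statistic instead and
#' the result is flagged `method = "lrt"`. With no successes anywhere the
#' fit is degenerate and `p_one_sided = 0.5` is reported with
#' `degenerate = TRUE`.
#'
#' @param data Data frame with integer columns `least` and `most` and a
#'   two-level `group` column; the first factor level (or the
#'   alphabetically first value) is the control group.
#' @param control Optional explicit control-group label.
#' @return One-row tibble: `beta_case`, `se_beta`, `z`, `p_one_sided`,
#'   `n_control`, `n_case`, `successes_control`, `failures_control`,
#'   `successes_case`, `failures_case`, `method`, `degenerate`.
#' @export
loi_regression <- function(data, control = NULL) {
  need <- c("least", "most", "group")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(sprintf("`data` is missing column(s): %s.",
                  paste(miss, collapse = ", ")))
  }
  check_counts(data$least, "least"); check_counts(data$most, "most")
  grp <- as.factor(data$group)
  if (nlevels(grp) != 2L) abort("`group` must have exactly two levels.")
  if (!is.null(control)) grp <- stats::relevel(grp, ref = control)
  keep <- data$least + data$most > 0
  least <- data$least[keep]; most <- data$most[keep]; grp <- droplevels(grp[keep])
  if (nlevels(grp) != 2L) {
    abort("Both groups need at least one sample with positive depth.")
  }
  is_case <- as.integer(grp) == 2L
  sc <- sum(least[!is_case]); fc <- sum(most[!is_case])
  sk <- sum(least[is_case]); fk <- sum(most[is_case])

  base <- tibble(beta_case = NA_real_, se_beta = NA_real_, z = NA_real_,
                 p_one_sided = 0.5,
                 n_control = sum(!is_case), n_case = sum(is_case),
                 successes_control = sc, failures_control = fc,
                 successes_case = sk, failures_case = fk,
                 method = "degenerate", degenerate = TRUE)
  if (sc + sk == 0) {
    warn("LOI regression degenerate: no successes in either group.")
    return(base)
  }
  fit <- suppressWarnings(
    glm(cbind(least, most) ~ is_case, family = binomial()))
  beta <- unname(coef(fit)[2])
  se <- unname(sqrt(diag(vcov(fit)))[2])
  separated <- (sc == 0 || fc == 0 || sk == 0 || fk == 0)
  if (separated) {
    fit0 <- suppressWarnings(glm(cbind(least, most) ~ 1, family = binomial()))
    stat <- max(0, fit0$deviance - fit$deviance)
    p_two <- pchisq(stat, df = 1, lower.tail = FALSE)
    p <- if (beta > 0) p_two / 2 else 1 - p_two / 2
    method <- "lrt"
  } else {
    p <- pnorm(beta / se, lower.tail = FALSE)
    method <- "wald"
  }
  tibble(beta_case = beta, se_beta = unname(se), z = unname(beta / se),
         p_one_sided = p,
         n_control = sum(!is_case), n_case = sum(is_case),
         successes_control = sc, failures_control = fc,
         successes_case = sk, failures_case = fk,
         method = method, degenerate = FALSE)
}

#' LOI screen across imprinted SNPs
#'
#' Runs [loi_regression()] for every SNP in `imprinted_snps`, contrasting
#' the control group (`"normal"`) against the case group (`"tumor"`,
#' typically restricted to stage 1 by the caller).
#'
#' @param allele_counts Allele-count table with `sample_id`, `snp_id`,
#'   `gene_id`, `ref_count`, `alt_count`, `group`.
#' @param imprinted_snps Character vector of SNP ids to test.
#' @param control,case Group labels.
#' @return Tibble with one row per SNP (`snp_id`, `gene_id`, the
#'   [loi_regression()] columns).
#' @export
detect_loi <- function(allele_counts, imprinted_snps,
                       control = "normal", case = "tumor") {
  d <- allele_counts |>
    filter(.data$snp_id %in% imprinted_snps,
           .data$group %in% c(control, case)) |>
    mutate(least = pmin(.data$ref_count, .data$alt_count),
           most = pmax(.data$ref_count, .data$alt_count),
           group = factor(.data$group, levels = c(control, case)))
  if (nrow(d) == 0) abort("No rows at the requested SNPs/groups.")
  if (!"gene_id" %in% names(d)) d$gene_id <- NA_character_
  d |>
    group_by(.data$snp_id, .data$gene_id) |>
    dplyr::group_modify(~ loi_regression(.x)) |>
    ungroup()
}

#' Gene-level LOI consensus
#'
#' Combines per-SNP one-sided LOI p-values into a consensus p-value per
#' gene by the geometric mean, adjusts across genes by Benjamini-Hochberg,
#' and calls LOI at `gene_q < fdr`.
#'
#' @param snp_results Tibble with columns `gene_id` and a p-value column
#'   (`p_one_sided` or `p_value`).
#' @param fdr FDR threshold for the LOI call.
#' @return Tibble: `gene_id`, `n_snps`, `gene_p`, `gene_q`, `loi_call`.
#' @export
combine_loi_gene <- function(snp_results, fdr = 0.05) {
  pcol <- intersect(c("p_one_sided", "p_value"), names(snp_results))[1]
  if (is.na(pcol)) abort("`snp_results` needs a p-value column.")
  out <- snp_results |>
    filter(!is.na(.data[[pcol]])) |>
    group_by(.data$gene_id) |>
    summarise(n_snps = n(),
              gene_p = geometric_mean_p(.data[[pcol]]),
              .groups = "drop")
  out$gene_q <- p.adjust(out$gene_p, method = "BH")
  out$loi_call <- out$gene_q < fdr
  arrange(out, .data$gene_q)
}

#' Call per-sample LOI status
#'
#' A tumor sample shows LOI at a gene when, at any informative imprinted
#' SNP (positive depth), its least-expressed allele has at least
#' `min_count` reads and makes up at least `min_fraction` of the total
#' (both thresholds inclusive). Samples with no informative SNP at a gene
#' are uncallable and are omitted (missing, not `FALSE`).
#'
#' @param allele_counts Allele-count table (`sample_id`, `snp_id`,
#'   `gene_id`, `ref_count`, `alt_count`, optionally `group`).
#' @param imprinted_snps SNP ids considered imprinted, with their gene.
#' @param min_count Minimum least-expressed allele read count.
#' @param min_fraction Minimum least-expressed allele fraction.
#' @param group Restrict to this group if a `group` column exists (default
#'   `"tumor"`; `NULL` keeps all samples).
#' @return Tibble with one row per callable (sample, gene):
#'   `sample_id`, `gene_id`, `n_informative_snps`, `least_count`,
#'   `least_fraction`, `degree_of_loi`, `is_loi`. The reported counts come
#'   from the sample's SNP with the highest least-allele fraction.
#' @export
call_loi_samples <- function(allele_counts, imprinted_snps,
                             min_count = 2L, min_fraction = 0.10,
                             group = "tumor") {
  if (!is.null(group) && "group" %in% names(allele_counts)) {
    allele_counts <- allele_counts[allele_counts$group %in% group, ,
                                   drop = FALSE]
  }
  d <- allele_counts |>
    filter(.data$snp_id %in% imprinted_snps,
           .data$ref_count + .data$alt_count > 0) |>
    mutate(least = pmin(.data$ref_count, .data$alt_count),
           most = pmax(.data$ref_count, .data$alt_count),
           fraction = .data$least / (.data$least + .data$most),
           snp_pass = .data$least >= min_count & .data$fraction >= min_fraction)
  d |>
    group_by(.data$sample_id, .data$gene_id) |>
    summarise(
      n_informative_snps = n(),
      least_count = .data$least[which.max(.data$fraction)],
      least_fraction = max(.data$fraction),
      degree_of_loi = {
        k <- which.max(.data$fraction)
        if (.data$most[k] == 0) NA_real_ else .data$least[k] / .data$most[k]
      },
      is_loi = any(.data$snp_pass),
      .groups = "drop"
    )
}
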