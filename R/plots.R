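# ggplot2 figure helpers for the three canonical result displays.

#' Allele-fraction histogram per SNP
#'
#' The diagnostic display for imprinting and LOI: per-sample reference-allele
#' read fractions at a SNP, faceted by sample group. Under imprinting the
#' heterozygous peak at 1/2 is missing in normals; LOI shows up as tumor
#' samples re-populating intermediate fractions.
#'
#' @param allele_counts Allele-count tibble.
#' @param snp Single SNP id to plot.
#' @param min_depth Minimum per-sample depth to include.
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_allele_fractions <- function(allele_counts, snp, min_depth = 5L,
                                  bins = 40L) {
  d <- allele_counts |>
    filter(.data$snp_id == snp,
           .data$ref_count + .data$alt_count >= min_depth) |>
    mutate(fraction = .data$ref_count / (.data$ref_count + .data$alt_count))
  if (nrow(d) == 0) abort(sprintf("No samples with depth >= %d at %s.",
                                  min_depth, snp))
  gg <- ggplot2::ggplot(d, ggplot2::aes(x = .data$fraction)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0,
                            fill = "grey35", colour = "white") +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(x = "reference-allele read fraction", y = "samples",
                  title = snp) +
    ggplot2::theme_minimal()
  if ("group" %in% names(d)) {
    gg <- gg + ggplot2::facet_wrap(~group)
  }
  gg
}

#' @export
autoplot.imprinting_fit <- function(object, bins = 20L, ...) {
  n <- object$ref_count + object$alt_count
  keep <- n >= 5
  d <- tibble(fraction = object$ref_count[keep] / n[keep])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fraction)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0,
                            fill = "grey35", colour = "white") +
    ggplot2::geom_vline(xintercept = het_fractions(object$i_hat, object$eps),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(x = "reference-allele read fraction", y = "samples",
                  subtitle = sprintf("i = %.2f, LRT p = %.2g",
                                     object$i_hat, object$p_lrt)) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier plot by expression group
#'
#' Step-function survival curves for tumor samples split above/below mean
#' expression (see [km_expression_groups()]).
#'
#' @param clinical Data frame with `sample_id`, `time`, `event`.
#' @param groups Factor from [km_expression_groups()], named by sample.
#' @return A ggplot object.
#' @export
plot_km <- function(clinical, groups) {
  d <- clinical[!is.na(clinical$time) & !is.na(clinical$event), , drop = FALSE]
  d$expr_group <- groups[d$sample_id]
  d <- d[!is.na(d$expr_group), , drop = FALSE]
  fit <- survival::survfit(survival::Surv(time, event) ~ expr_group, data = d)
  strata <- rep(names(fit$strata), fit$strata)
  km <- tibble(time = fit$time, surv = fit$surv,
               group = sub("^expr_group=", "", strata))
  km <- bind_rows(tibble(time = 0, surv = 1, group = unique(km$group)), km)
  ggplot2::ggplot(km, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability",
                  colour = "expression") +
    ggplot2::theme_minimal()
}

#' Violin plot of expression by tumor stage
#'
#' @param expression Named numeric RPKM vector.
#' @param stage Stage labels aligned with `expression`.
#' @param log2_transform Plot `log2(RPKM + 1)`.
#' @return A ggplot object.
#' @export
plot_stage_violin <- function(expression, stage, log2_transform = TRUE) {
  keep <- !is.na(expression) & !is.na(stage)
  d <- tibble(stage = factor(stage[keep]),
              expr = if (log2_transform) {
                log2(expression[keep] + 1)
              } else {
                expression[keep]
              })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stage, y = .data$expr)) +
    ggplot2::geom_violin(fill = "grey80") +
    ggplot2::geom_boxplot(width = 0.1, outlier.shape = NA) +
    ggplot2::labs(x = "tumor stage", y = "log2(RPKM + 1)") +
    ggplot2::theme_minimal()
}
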