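# Survival and stage-trend analyses for canonical-LOI genes.

#' Cox regression of survival on gene expression
#'
#' Proportional-hazards fit of survival on continuous gene expression
#' (default scale `log2(RPKM + 1)`), adjusted for the requested clinical
#' covariates. Non-convergence or an all-censored input is flagged rather
#' than raised.
#'
#' @param expr Wide expression tibble (RPKM scale) or a named numeric
#'   vector of per-sample expression values.
#' @param clinical Data frame with `sample_id`, `time`, `event` and the
#'   adjustment covariates (`age`, `sex`, `stage`).
#' @param gene_id Gene to model when `expr` is a table.
#' @param adjust_for Covariates to adjust for; any of `"age"`, `"sex"`,
#'   `"stage"`.
#' @param log2_transform Model `log2(RPKM + 1)` (default) or the raw scale.
#' @return One-row tibble: `gene_id`, `hazard_ratio`, `ci_low`, `ci_high`,
#'   `wald_p`, `n`, `n_events`, `covariates`, `converged`.
#' @export
cox_survival <- function(expr, clinical, gene_id = NULL,
                         adjust_for = c("age", "sex"),
                         log2_transform = TRUE) {
  if (is.data.frame(expr)) {
    if (is.null(gene_id)) gene_id <- expr$gene_id[1]
    ex <- as.numeric(expr[expr$gene_id == gene_id, setdiff(names(expr), "gene_id")])
    names(ex) <- setdiff(names(expr), "gene_id")
  } else {
    ex <- expr
    gene_id <- gene_id %||% NA_character_
  }
  d <- clinical[!is.na(clinical$time) & !is.na(clinical$event), , drop = FALSE]
  d$expression <- ex[d$sample_id]
  if (log2_transform) d$expression <- log2(d$expression + 1)
  covs <- intersect(adjust_for, names(d))
  d <- d[complete.cases(d[, c("time", "event", "expression", covs)]), ,
         drop = FALSE]
  if (any(d$time <= 0)) abort("Survival times must be positive.")
  base <- tibble(gene_id = gene_id, hazard_ratio = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_, wald_p = NA_real_,
                 n = nrow(d), n_events = sum(d$event),
                 covariates = paste(covs, collapse = "+"),
                 converged = FALSE)
  if (nrow(d) < 3 || sum(d$event) == 0) {
    warn("Cox fit degenerate: too few samples or no events.")
    return(base)
  }
  fml <- stats::reformulate(c("expression", covs),
                            response = "survival::Surv(time, event)")
  fit <- tryCatch(
    withCallingHandlers(
      survival::coxph(fml, data = d),
      warning = function(w) {
        if (grepl("converge|infinite|singular", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }),
    error = function(e) NULL)
  if (is.null(fit)) {
    warn("Cox fit failed to converge.")
    return(base)
  }
  sm <- summary(fit)
  co <- sm$coefficients["expression", ]
  converged <- all(is.finite(co)) && unname(co["se(coef)"]) < 50
  tibble(gene_id = gene_id,
         hazard_ratio = unname(exp(co["coef"])),
         ci_low = unname(exp(co["coef"] - 1.96 * co["se(coef)"])),
         ci_high = unname(exp(co["coef"] + 1.96 * co["se(coef)"])),
         wald_p = unname(co["Pr(>|z|)"]),
         n = nrow(d), n_events = sum(d$event),
         covariates = paste(covs, collapse = "+"),
         converged = converged)
}

#' Kaplan-Meier expression grouping
#'
#' Splits tumor samples into `"above"` and `"below"` groups at the
#' tumor-sample mean of `log2(RPKM + 1)`; ties at the mean go to the
#' `"above"` group.
#'
#' @param expression Named numeric vector of RPKM values (tumor samples).
#' @param log2_transform Apply the log2(RPKM + 1) transform first.
#' @return Factor with levels `"below"`, `"above"`, named by sample.
#' @export
km_expression_groups <- function(expression, log2_transform = TRUE) {
  x <- if (log2_transform) log2(expression + 1) else expression
  factor(ifelse(x >= mean(x), "above", "below"), levels = c("below", "above"))
}

#' Stage-trend ANOVA
#'
#' One-way ANOVA of `log2(RPKM + 1)` across tumor stages, with per-stage
#' summaries for violin-style plotting.
#'
#' @param expression Named numeric vector of RPKM values.
#' @param stage Integer/factor vector of tumor stages, aligned with
#'   `expression`.
#' @param log2_transform Apply the log2(RPKM + 1) transform first.
#' @return List with `p_value` (ANOVA F-test) and `stage_means`, a tibble
#'   of `stage`, `n`, `mean_log2_expr`, `sd_log2_expr`.
#' @export
stage_trend <- function(expression, stage, log2_transform = TRUE) {
  keep <- !is.na(expression) & !is.na(stage)
  x <- expression[keep]; st <- factor(stage[keep])
  if (log2_transform) x <- log2(x + 1)
  used <- names(table(st))[table(st) >= 2]
  x <- x[st %in% used]; st <- droplevels(st[st %in% used])
  if (nlevels(st) < 2) {
    abort("stage_trend requires at least two stages with >= 2 samples each.")
  }
  fit <- aov(x ~ st)
  p <- summary(fit)[[1]][["Pr(>F)"]][1]
  means <- tibble(stage = levels(st)) |>
    mutate(n = as.integer(table(st)[.data$stage]),
           mean_log2_expr = vapply(.data$stage,
                                   function(s) mean(x[st == s]), numeric(1)),
           sd_log2_expr = vapply(.data$stage,
                                 function(s) sd(x[st == s]), numeric(1)))
  list(p_value = p, stage_means = means)
}

#' Cohort balance diagnostics
#'
#' Reports (never gates on) group comparability for the major confounders:
#' independent-samples t-test on age, F-test for equality of age variances,
#' and a chi-squared test on sex.
#'
#' @param clinical Data frame with `sample_id`, `group`, and `age`/`sex`.
#' @param control,case Group labels.
#' @return Tibble: `check`, `statistic`, `p_value`. Checks with a missing
#'   covariate are skipped with a warning.
#' @export
cohort_balance_check <- function(clinical, control = "normal", case = "tumor") {
  d <- clinical[clinical$group %in% c(control, case), , drop = FALSE]
  out <- list()
  if ("age" %in% names(d) && !all(is.na(d$age))) {
    a1 <- d$age[d$group == control]; a2 <- d$age[d$group == case]
    if (isTRUE(all.equal(a1, a2))) {
      out$age_t <- tibble(check = "age t-test", statistic = 0, p_value = 1)
    } else {
      tt <- t.test(a1, a2)
      out$age_t <- tibble(check = "age t-test",
                          statistic = unname(tt$statistic),
                          p_value = tt$p.value)
    }
    vt <- tryCatch(var.test(a1, a2), error = function(e) NULL)
    if (!is.null(vt)) {
      out$age_f <- tibble(check = "age variance F-test",
                          statistic = unname(vt$statistic),
                          p_value = vt$p.value)
    }
  } else {
    warn("Balance check on age skipped: covariate missing.")
  }
  if ("sex" %in% names(d) && !all(is.na(d$sex))) {
    tab <- table(d$group, d$sex)
    if (all(dim(tab) >= 2)) {
      ct <- suppressWarnings(chisq.test(tab))
      out$sex <- tibble(check = "sex chi-squared",
                        statistic = unname(ct$statistic),
                        p_value = ct$p.value)
    }
  } else {
    warn("Balance check on sex skipped: covariate missing.")
  }
  bind_rows(out)
}
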