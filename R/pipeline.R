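# End-to-end orchestration: simulate/load -> imprinting in normals ->
# LOI in stage-1 tumors -> canonical-LOI classification -> clinical stats.

#' Run the full imprinting / LOI pipeline
#'
#' Executes the analysis end to end with the package defaults: imprinting
#' is detected in the normal-tissue population, loss-of-imprinting is
#' tested in stage 1 tumors versus normals at the SNPs detected as
#' imprinted, per-sample LOI status is called, gene-level differential
#' expression classifies canonical LOI, and (when the inputs carry them)
#' the clinical analyses are run for canonical genes. All stage outputs
#' are collected into a machine-readable report; given the same cohort (or
#' simulation seed) the run is deterministic.
#'
#' @param input A `synthetic_cohort`, a `loi_sim_config` (simulated on the
#'   fly), or a named list of tables (`allele_counts` required;
#'   `expression`, `methylation`, `cnv`, `mutations`, `clinical` optional).
#' @param out_dir Optional output directory for the per-stage TSV files,
#'   the JSON report and a plain-text log.
#' @param thresholds SNP filter thresholds,
#'   see [imprinting_filter_thresholds()].
#' @param whitelist Manually retained imprinted genes.
#' @param symmetry_keep Direction of the symmetry screen,
#'   see [filter_snps()].
#' @param rme_flags Genes flagged as random monoallelic expression.
#' @param f,eps Mixture-model parameters.
#' @param min_count,min_fraction Per-sample LOI-call thresholds.
#' @param loi_stage Tumor stage(s) used for the LOI contrast (default 1).
#' @return An object of class `loi_pipeline_report`: a list with the
#'   per-stage tibbles (`snp_fits`, `snp_filters`, `gene_imprinting`,
#'   `loi_snps`, `loi_genes`, `sample_loi`, `de_genes`, `canonical`,
#'   `balance`, optional `survival` and `stage_trend`), a `counts` record
#'   keeping per-stage tallies, and `seed`/`config_hash` metadata.
#' @export
run_pipeline <- function(input,
                         out_dir = NULL,
                         thresholds = imprinting_filter_thresholds(),
                         whitelist = imprinting_whitelist(),
                         symmetry_keep = "ge",
                         rme_flags = character(),
                         f = 0.0103667, eps = 0.002,
                         min_count = 2L, min_fraction = 0.10,
                         loi_stage = 1L) {
  log_lines <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    inform(msg)
  }
  stage_wrap <- function(stage_name, code) {
    tryCatch(code, error = function(e) {
      if (!is.null(out_dir)) {
        dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
        writeLines(c(stage_name, conditionMessage(e)),
                   file.path(out_dir, "FAILED"))
      }
      abort(sprintf("Pipeline stage `%s` failed: %s",
                    stage_name, conditionMessage(e)))
    })
  }

  if (inherits(input, "loi_sim_config")) {
    say("Simulating cohort (seed %d).", input$rng_seed)
    input <- simulate_cohort(input)
  }
  seed <- if (inherits(input, "synthetic_cohort")) {
    input$config$rng_seed
  } else {
    NA_integer_
  }
  counts <- input$allele_counts
  if (is.null(counts)) abort("`input` must provide an allele_counts table.")

  # Stage 1: imprinting detection in the normal population.
  normals <- counts[counts$group == "normal", , drop = FALSE]
  fits <- stage_wrap("imprinting_detection",
                     detect_imprinting(normals, f = f, eps = eps, group = NULL))
  say("Imprinting: fitted %d SNPs on %d normal samples.",
      nrow(fits), dplyr::n_distinct(normals$sample_id))
  filt <- filter_snps(fits, thresholds, symmetry_keep = symmetry_keep)
  filter_cols <- grep("^pass_(?!all)", names(filt), value = TRUE, perl = TRUE)
  filter_tally <- vapply(filter_cols, function(cl) sum(!filt[[cl]]),
                         integer(1))
  genes <- stage_wrap("gene_aggregation",
                      aggregate_genes(filt, whitelist = whitelist,
                                      fdr = thresholds$fdr))
  imprinted_genes <- genes$gene_id[genes$imprinted]
  imprinted_snps <- filt$snp_id[filt$pass_all &
                                  filt$gene_id %in% imprinted_genes]
  say("Imprinting: %d/%d genes called imprinted (%d SNPs).",
      length(imprinted_genes), nrow(genes), length(imprinted_snps))

  # Stage 2: LOI in stage-restricted tumors vs normals.
  loi_counts <- counts[counts$group == "normal" |
                         (counts$group == "tumor" &
                            counts$stage %in% loi_stage), , drop = FALSE]
  loi_snps <- loi_genes <- sample_loi <- NULL
  if (length(imprinted_snps)) {
    loi_snps <- stage_wrap("loi_detection",
                           detect_loi(loi_counts, imprinted_snps))
    loi_genes <- combine_loi_gene(loi_snps)
    sample_loi <- suppressWarnings(
      call_loi_samples(loi_counts, imprinted_snps,
                       min_count = min_count, min_fraction = min_fraction))
    say("LOI: %d genes tested, %d called; %d/%d callable samples show LOI.",
        nrow(loi_genes), sum(loi_genes$loi_call),
        sum(sample_loi$is_loi), nrow(sample_loi))
  } else {
    say("LOI: no imprinted SNPs; stage skipped.")
    loi_genes <- tibble(gene_id = character(), n_snps = integer(),
                        gene_p = numeric(), gene_q = numeric(),
                        loi_call = logical())
  }

  # Stage 3: differential expression and canonical-LOI classification.
  de_genes <- canonical <- NULL
  if (!is.null(input$expression) && !is.null(input$clinical)) {
    si <- input$clinical[, intersect(names(input$clinical),
                                     c("sample_id", "group", "stage"))]
    de_genes <- stage_wrap("differential_expression",
                           suppressWarnings(
                             differential_expression(input$expression, si)))
    if (nrow(loi_genes)) {
      canonical <- suppressMessages(
        classify_canonical_loi(loi_genes, de_genes, rme_flags = rme_flags))
      say("Canonical LOI: %d gene(s): %s.",
          sum(canonical$canonical),
          paste(canonical$gene_id[canonical$canonical], collapse = ", ") %||% "")
    }
  }

  # Stage 4: clinical analyses for canonical genes.
  balance <- survival_res <- trend_res <- NULL
  if (!is.null(input$clinical)) {
    balance <- suppressWarnings(cohort_balance_check(input$clinical))
    canon_genes <- if (!is.null(canonical)) {
      canonical$gene_id[canonical$canonical]
    } else {
      character()
    }
    if (length(canon_genes) && !is.null(input$expression) &&
          "time" %in% names(input$clinical)) {
      survival_res <- bind_rows(lapply(canon_genes, function(g) {
        suppressWarnings(
          cox_survival(input$expression, input$clinical, gene_id = g))
      }))
      tum <- input$clinical[input$clinical$group == "tumor", , drop = FALSE]
      trend_res <- purrr::map(setNames(canon_genes, canon_genes), function(g) {
        ex <- as.numeric(input$expression[
          input$expression$gene_id == g, tum$sample_id, drop = TRUE])
        tryCatch(stage_trend(ex, tum$stage), error = function(e) NULL)
      })
    }
  }

  report <- structure(list(
    snp_fits = fits,
    snp_filters = filt,
    gene_imprinting = genes,
    imprinted_genes = imprinted_genes,
    imprinted_snps = imprinted_snps,
    loi_snps = loi_snps,
    loi_genes = loi_genes,
    sample_loi = sample_loi,
    de_genes = de_genes,
    canonical = canonical,
    balance = balance,
    survival = survival_res,
    stage_trend = trend_res,
    gene_table = build_gene_table(genes, loi_genes, de_genes),
    counts = list(
      samples_in = dplyr::n_distinct(counts$sample_id),
      snps_in = dplyr::n_distinct(counts$snp_id),
      snps_tested = nrow(fits),
      snps_pass = sum(filt$pass_all),
      snps_failed = sum(!filt$pass_all),
      filter_tally = as.list(filter_tally),
      genes_tested = nrow(genes),
      genes_imprinted = length(imprinted_genes),
      genes_loi = sum(loi_genes$loi_call),
      genes_canonical = if (is.null(canonical)) 0L else sum(canonical$canonical)
    ),
    seed = seed,
    config_hash = rlang::hash(if (inherits(input, "synthetic_cohort")) {
      input$config
    } else {
      lapply(input, dim)
    }),
    package_version = as.character(packageVersion("loiscan")),
    log = log_lines
  ), class = "loi_pipeline_report")

  stopifnot(report$counts$snps_tested ==
              report$counts$snps_pass + report$counts$snps_failed)

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# Table-1-like per-gene summary: gene, #significant SNPs, mean i-hat,
# LOI q, DE q, log2FC.
build_gene_table <- function(genes, loi_genes, de_genes) {
  tbl <- genes |>
    select("gene_id", n = "n_significant_snps", i_hat = "mean_i_hat",
           "imprinted", "provenance")
  if (!is.null(loi_genes) && nrow(loi_genes)) {
    tbl <- left_join(tbl, select(loi_genes, "gene_id", p_loi = "gene_q"),
                     by = "gene_id")
  } else {
    tbl$p_loi <- NA_real_
  }
  if (!is.null(de_genes)) {
    tbl <- left_join(tbl,
                     select(de_genes, "gene_id", p_de = "q_value", "log2_fc"),
                     by = "gene_id")
  } else {
    tbl$p_de <- NA_real_; tbl$log2_fc <- NA_real_
  }
  arrange(tbl, dplyr::desc(.data$imprinted), .data$p_loi)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(tbl, name) {
    if (!is.null(tbl) && is.data.frame(tbl)) {
      readr::write_tsv(tbl, file.path(out_dir, paste0(name, ".tsv")),
                       progress = FALSE)
    }
  }
  wr(report$snp_fits, "snp_fits")
  wr(report$snp_filters, "snp_filters")
  wr(report$gene_imprinting, "gene_imprinting")
  wr(report$loi_snps, "loi_snps")
  wr(report$loi_genes, "loi_genes")
  wr(report$sample_loi, "sample_loi")
  wr(report$de_genes, "de_genes")
  wr(report$canonical, "canonical")
  wr(report$gene_table, "gene_table")
  jsonlite::write_json(report_summary(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(report$log, file.path(out_dir, "pipeline.log"))
  invisible(out_dir)
}

# The JSON-serialisable heart of a report (used for hashing/determinism).
report_summary <- function(report) {
  list(
    seed = report$seed,
    config_hash = report$config_hash,
    package_version = report$package_version,
    counts = report$counts,
    imprinted_genes = report$imprinted_genes,
    canonical_genes = if (is.null(report$canonical)) {
      character()
    } else {
      report$canonical$gene_id[report$canonical$canonical]
    },
    gene_table = as.data.frame(report$gene_table)
  )
}

#' @export
print.loi_pipeline_report <- function(x, ...) {
  cat("<loi_pipeline_report>\n")
  cat(sprintf("  SNPs: %d tested, %d pass filters\n",
              x$counts$snps_tested, x$counts$snps_pass))
  cat(sprintf("  genes: %d tested, %d imprinted, %d LOI, %d canonical\n",
              x$counts$genes_tested, x$counts$genes_imprinted,
              x$counts$genes_loi, x$counts$genes_canonical))
  if (length(x$imprinted_genes)) {
    cat("  imprinted:", paste(x$imprinted_genes, collapse = ", "), "\n")
  }
  cg <- if (!is.null(x$canonical)) x$canonical$gene_id[x$canonical$canonical]
  if (length(cg)) cat("  canonical LOI:", paste(cg, collapse = ", "), "\n")
  invisible(x)
}
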