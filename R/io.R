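# Tab-separated I/O with schema validation.

allele_count_columns <- c("sample_id", "snp_id", "chrom", "pos", "ref",
                          "alt", "gene_id", "ref_count", "alt_count",
                          "group", "stage")

#' Read and validate an allele-count table
#'
#' Reads the tab-separated allele-count dialect (header line; columns
#' `sample_id, snp_id, chrom, pos, ref, alt, gene_id, ref_count, alt_count,
#' group, stage`; positions 1-based). Counts must be non-negative integers,
#' `group` must be `normal` or `tumor`, `stage` 1-4 or missing. Duplicate
#' `(sample_id, snp_id)` rows are rejected unless an optional `timestamp`
#' column is present, in which case the most recent row is retained
#' (keep-last deduplication).
#'
#' @param path Path to a TSV file.
#' @return A validated tibble.
#' @export
read_allele_counts <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(allele_count_columns, names(d))
  if (length(miss)) {
    abort(sprintf("%s: missing column(s) %s.", path,
                  paste(miss, collapse = ", ")))
  }
  for (col in c("ref_count", "alt_count")) {
    bad <- which(is.na(d[[col]]) | d[[col]] < 0 | d[[col]] != floor(d[[col]]))
    if (length(bad)) {
      abort(sprintf("%s: column `%s` has invalid count at line %d.",
                    path, col, bad[1] + 1L))
    }
  }
  bad_grp <- which(!d$group %in% c("normal", "tumor"))
  if (length(bad_grp)) {
    abort(sprintf("%s: column `group` has unknown value %s at line %d.",
                  path, deparse(d$group[bad_grp[1]]), bad_grp[1] + 1L))
  }
  bad_st <- which(!is.na(d$stage) & !d$stage %in% 1:4)
  if (length(bad_st)) {
    abort(sprintf("%s: column `stage` must be 1-4 or NA (line %d).",
                  path, bad_st[1] + 1L))
  }
  key <- paste(d$sample_id, d$snp_id)
  if (anyDuplicated(key)) {
    if ("timestamp" %in% names(d)) {
      d <- d |>
        group_by(.data$sample_id, .data$snp_id) |>
        filter(row_number() ==
                 which.max(as.numeric(as.POSIXct(.data$timestamp)))) |>
        ungroup()
      inform("Duplicate (sample, SNP) rows deduplicated: most recent timestamp retained.")
    } else {
      dup <- key[duplicated(key)][1]
      abort(sprintf("%s: duplicate (sample_id, snp_id) rows for %s and no timestamp column.",
                    path, dup))
    }
  }
  d
}

read_matrix_table <- function(path, id_col) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!id_col %in% names(d)) {
    abort(sprintf("%s: missing column `%s`.", path, id_col))
  }
  d
}

#' Read auxiliary pipeline tables
#'
#' Light schema checks for the remaining tab-separated inputs: expression
#' (`gene_id` x samples, RPKM), methylation (`probe_id` x samples, beta),
#' CNV (`gene_id` x samples, scores -2..2) and clinical
#' (`sample_id, group, age, sex, stage, time, event`).
#'
#' @param path Path to a TSV file.
#' @return A validated tibble.
#' @export
read_expression <- function(path) read_matrix_table(path, "gene_id")

#' @rdname read_expression
#' @export
read_methylation <- function(path) {
  d <- read_matrix_table(path, "probe_id")
  vals <- unlist(d[setdiff(names(d), c("probe_id", "gene_id"))])
  if (any(vals < 0 | vals > 1, na.rm = TRUE)) {
    abort(sprintf("%s: beta values must lie in [0, 1].", path))
  }
  d
}

#' @rdname read_expression
#' @export
read_cnv <- function(path) {
  d <- read_matrix_table(path, "gene_id")
  vals <- unlist(d[setdiff(names(d), "gene_id")])
  if (any(!vals %in% -2:2, na.rm = TRUE)) {
    abort(sprintf("%s: CNV scores must be integers in -2..2.", path))
  }
  d
}

#' @rdname read_expression
#' @export
read_clinical <- function(path) {
  d <- read_matrix_table(path, "sample_id")
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    abort(sprintf("%s: missing column(s) %s.", path,
                  paste(miss, collapse = ", ")))
  }
  d
}

#' Write a synthetic cohort to tab-separated files
#'
#' Writes every table of a cohort (allele counts, expression, methylation,
#' CNV, mutations, clinical) plus the planted-truth tables as TSV files
#' under `dir`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  wr <- function(tbl, name) {
    p <- file.path(dir, paste0(name, ".tsv"))
    readr::write_tsv(tbl, p, progress = FALSE)
    paths <<- c(paths, p)
  }
  wr(cohort$allele_counts, "allele_counts")
  wr(cohort$expression, "expression")
  wr(cohort$methylation, "methylation")
  wr(cohort$cnv, "cnv")
  wr(cohort$mutations, "mutations")
  wr(cohort$clinical, "clinical")
  wr(cohort$truth$genotypes, "truth_genotypes")
  wr(cohort$truth$loi, "truth_loi")
  wr(cohort$truth$gene_i, "truth_gene_i")
  invisible(paths)
}

#' Export allele counts as a VCF with per-sample allelic depths
#'
#' Writes a minimal VCF 4.2 file with one record per SNP and a per-sample
#' `AD` (allelic depth) FORMAT field, the standard interchange form for
#' allele-specific counts.
#'
#' @param allele_counts Allele-count tibble.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_allele_counts_vcf <- function(allele_counts, path) {
  d <- allele_counts
  samples <- sort(unique(d$sample_id))
  wide <- d |>
    mutate(ad = paste0(.data$ref_count, ",", .data$alt_count)) |>
    select("snp_id", "chrom", "pos", "ref", "alt", "sample_id", "ad") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "ad",
                       values_fill = ".") |>
    arrange(.data$chrom, .data$pos)
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- apply(wide, 1, function(r) {
    paste(c(r[["chrom"]], r[["pos"]], r[["snp_id"]], r[["ref"]], r[["alt"]],
            ".", ".", ".", "AD", r[samples]), collapse = "\t")
  })
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read allele counts from a VCF with AD fields
#'
#' Minimal adapter for VCFs carrying per-sample `AD` allelic depths (as
#' written by [write_allele_counts_vcf()] or standard variant callers).
#' Gene and group annotations are not part of VCF and must be joined on
#' afterwards.
#'
#' @param path VCF file path.
#' @return Tibble with `sample_id`, `snp_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `ref_count`, `alt_count`.
#' @export
read_allele_counts_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) abort(sprintf("%s: no #CHROM header line.", path))
  cols <- strsplit(sub("^#", "", lines[hdr]), "\t")[[1]]
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  purrr::map_dfr(body, function(ln) {
    fld <- strsplit(ln, "\t")[[1]]
    fmt <- strsplit(fld[9], ":")[[1]]
    ad_i <- match("AD", fmt)
    if (is.na(ad_i)) abort(sprintf("%s: record without AD field.", path))
    ads <- vapply(fld[-(1:9)],
                  function(s) strsplit(s, ":")[[1]][ad_i], character(1))
    keep <- ads != "."
    counts <- strsplit(ads[keep], ",")
    tibble(sample_id = samples[keep],
           snp_id = fld[3], chrom = fld[1], pos = as.integer(fld[2]),
           ref = fld[4], alt = fld[5],
           ref_count = as.integer(vapply(counts, `[`, character(1), 1)),
           alt_count = as.integer(vapply(counts, `[`, character(1), 2)))
  })
}
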