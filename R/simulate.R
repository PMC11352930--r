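#' Build a SNP panel for simulation
#'
#' Helper constructing the per-SNP table a [simulation_config()] needs:
#' one row per SNP with its gene, reference-allele population frequency and
#' (synthetic) coordinates.
#'
#' @param gene_ids Character vector of gene identifiers.
#' @param snps_per_gene Number of SNPs per gene.
#' @param ref_allele_freq Reference-allele frequency, recycled across SNPs.
#' @return A tibble with columns `snp_id`, `gene_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `ref_allele_freq`.
#' @export
snp_panel <- function(gene_ids, snps_per_gene = 2L, ref_allele_freq = 0.5) {
  n <- length(gene_ids) * snps_per_gene
  freq <- rep_len(ref_allele_freq, n)
  if (any(freq <= 0 | freq >= 1)) {
    abort("`ref_allele_freq` must lie strictly in (0, 1).")
  }
  tibble(
    snp_id = sprintf("rs%05d", seq_len(n)),
    gene_id = rep(gene_ids, each = snps_per_gene),
    chrom = "chr20",
    pos = 1000L + 500L * seq_len(n),
    ref = rep_len(c("A", "G", "C", "T"), n),
    alt = rep_len(c("G", "A", "T", "C"), n),
    ref_allele_freq = freq
  )
}

default_snp_panel <- function() {
  snp_panel(sprintf("GENE%02d", 1:10), snps_per_gene = 2L,
            ref_allele_freq = rep(c(0.5, 0.45, 0.4, 0.45, 0.5), each = 4))
}

default_imprinting_degrees <- function(panel) {
  genes <- unique(panel$gene_id)
  i <- setNames(rep(0, length(genes)), genes)
  # A realistic mixed panel: five imprinted genes spanning the degree range
  # seen at known imprinted loci, the rest biallelic.
  imp <- c(0.97, 0.95, 0.9, 0.99, 0.8)
  i[seq_len(min(5L, length(genes)))] <- imp[seq_len(min(5L, length(genes)))]
  i
}

#' Simulation configuration for a synthetic cohort
#'
#' Assembles and validates every parameter the cohort generator uses. The
#' defaults emulate the TCGA kidney design the package targets: 128 solid
#' tissue normal and 240 stage 1 tumor samples, Hardy-Weinberg genotypes with
#' inbreeding coefficient 0.0103667, near-complete monoallelic expression at
#' imprinted SNPs, re-expression of the silenced allele in a subset of tumors,
#' log-normal RPKM-scale expression, beta-distributed methylation and
#' expression-dependent exponential survival.
#'
#' @param n_normal,n_tumor Sample counts for the normal and tumor groups.
#' @param panel SNP panel tibble, see [snp_panel()].
#' @param inbreeding_f Inbreeding coefficient F on the probability scale.
#' @param seq_error_eps Per-read allele-miscall probability.
#' @param coverage_mean,coverage_dispersion Negative-binomial read-depth mean
#'   and size (dispersion) parameters.
#' @param imprinting_degree Named numeric vector, degree of imprinting
#'   `i` in `[0, 1]` per gene; genes absent from the vector get 0.
#' @param loi_genes Genes whose silenced allele is re-expressed in a subset
#'   of tumor samples.
#' @param loi_case_fraction Fraction of tumor samples with re-expression.
#' @param loi_reexpression_delta Expected silenced-allele read fraction in
#'   LOI samples, in `(0, 0.5]`.
#' @param expr_log2_mean,expr_log2_sd Baseline mean and SD of log2(RPKM + 1).
#' @param tumor_shift Named per-gene additive tumor effect on the log2 scale
#'   (default: +0.60 for the first LOI gene, 0 elsewhere).
#' @param loi_shift Named per-gene additional shift in LOI samples
#'   (default: +0.37 for the first LOI gene).
#' @param survival_log_hazard Log hazard ratio per unit of centred
#'   log2(RPKM + 1) of `hazard_gene` (default `log(1.68)`).
#' @param hazard_gene Gene driving survival (default: first LOI gene).
#' @param baseline_hazard Baseline exponential event rate (per year).
#' @param censor_rate Expected fraction of censored tumor samples, in `[0, 1)`.
#' @param age_normal_mean,age_normal_sd,age_tumor_mean,age_tumor_sd Age
#'   distributions per group (years).
#' @param female_frac_normal,female_frac_tumor Female fractions per group.
#' @param stage_probs Probabilities of tumor stages 1-4 (default: all stage 1).
#' @param n_pairs Number of tumor samples given a matched normal.
#' @param cnv_gain_rate Per-gene probability of a copy-number gain (score +1)
#'   in a tumor sample.
#' @param meth_concentration Beta-distribution concentration for methylation.
#' @param rng_seed Integer seed making the whole cohort reproducible.
#' @return An object of class `loi_sim_config` (a validated list).
#' @export
simulation_config <- function(n_normal = 128L,
                              n_tumor = 240L,
                              panel = default_snp_panel(),
                              inbreeding_f = 0.0103667,
                              seq_error_eps = 0.002,
                              coverage_mean = 30,
                              coverage_dispersion = 10,
                              imprinting_degree = default_imprinting_degrees(panel),
                              loi_genes = names(imprinting_degree)[imprinting_degree > 0][1],
                              loi_case_fraction = 0.3,
                              loi_reexpression_delta = 0.25,
                              expr_log2_mean = 5,
                              expr_log2_sd = 1,
                              tumor_shift = NULL,
                              loi_shift = NULL,
                              survival_log_hazard = log(1.68),
                              hazard_gene = loi_genes[1],
                              baseline_hazard = 0.08,
                              censor_rate = 0.65,
                              age_normal_mean = 60.77, age_normal_sd = 13.28,
                              age_tumor_mean = 60.00, age_tumor_sd = 12.88,
                              female_frac_normal = 0.33,
                              female_frac_tumor = 0.41,
                              stage_probs = c(1, 0, 0, 0),
                              n_pairs = 20L,
                              cnv_gain_rate = 0.132,
                              meth_concentration = 100,
                              rng_seed = 1L) {
  bad <- function(field, msg) {
    abort(sprintf("Invalid simulation config: `%s` %s", field, msg),
          class = "loiscan_config_error")
  }
  if (!is.numeric(n_normal) || n_normal < 1) bad("n_normal", "must be >= 1.")
  if (!is.numeric(n_tumor) || n_tumor < 1) bad("n_tumor", "must be >= 1.")
  if (!is.data.frame(panel) ||
      !all(c("snp_id", "gene_id", "ref_allele_freq") %in% names(panel))) {
    bad("panel", "must have columns snp_id, gene_id, ref_allele_freq.")
  }
  if (any(panel$ref_allele_freq <= 0 | panel$ref_allele_freq >= 1)) {
    bad("panel", "has ref_allele_freq outside (0, 1).")
  }
  if (inbreeding_f < 0 || inbreeding_f >= 1) bad("inbreeding_f", "must be in [0, 1).")
  if (seq_error_eps < 0 || seq_error_eps >= 0.5) bad("seq_error_eps", "must be in [0, 0.5).")
  if (coverage_mean <= 0) bad("coverage_mean", "must be > 0.")
  if (coverage_dispersion <= 0) bad("coverage_dispersion", "must be > 0.")
  if (any(imprinting_degree < 0 | imprinting_degree > 1)) {
    bad("imprinting_degree", "must lie in [0, 1].")
  }
  loi_genes <- loi_genes[!is.na(loi_genes)]
  if (loi_case_fraction < 0 || loi_case_fraction > 1) {
    bad("loi_case_fraction", "must be in [0, 1].")
  }
  if (loi_reexpression_delta <= 0 || loi_reexpression_delta > 0.5) {
    bad("loi_reexpression_delta", "must be in (0, 0.5].")
  }
  if (censor_rate < 0 || censor_rate >= 1) bad("censor_rate", "must be in [0, 1).")
  if (length(stage_probs) != 4 || any(stage_probs < 0) || sum(stage_probs) <= 0) {
    bad("stage_probs", "must be 4 non-negative weights with positive sum.")
  }
  genes <- unique(panel$gene_id)
  full <- function(x, default = 0) {
    out <- setNames(rep(default, length(genes)), genes)
    if (!is.null(x)) out[names(x)] <- x
    out
  }
  degree <- full(imprinting_degree)
  if (is.null(tumor_shift) && length(loi_genes)) {
    tumor_shift <- setNames(rep(0.60, length(loi_genes)), loi_genes)
  }
  if (is.null(loi_shift) && length(loi_genes)) {
    loi_shift <- setNames(rep(0.37, length(loi_genes)), loi_genes)
  }
  structure(list(
    n_normal = as.integer(n_normal), n_tumor = as.integer(n_tumor),
    panel = as_tibble(panel),
    inbreeding_f = inbreeding_f, seq_error_eps = seq_error_eps,
    coverage_mean = coverage_mean, coverage_dispersion = coverage_dispersion,
    imprinting_degree = degree,
    loi_genes = intersect(loi_genes, genes),
    loi_case_fraction = loi_case_fraction,
    loi_reexpression_delta = loi_reexpression_delta,
    expr_log2_mean = expr_log2_mean, expr_log2_sd = expr_log2_sd,
    tumor_shift = full(tumor_shift), loi_shift = full(loi_shift),
    survival_log_hazard = survival_log_hazard,
    hazard_gene = hazard_gene, baseline_hazard = baseline_hazard,
    censor_rate = censor_rate,
    age_normal_mean = age_normal_mean, age_normal_sd = age_normal_sd,
    age_tumor_mean = age_tumor_mean, age_tumor_sd = age_tumor_sd,
    female_frac_normal = female_frac_normal,
    female_frac_tumor = female_frac_tumor,
    stage_probs = stage_probs / sum(stage_probs),
    n_pairs = as.integer(min(n_pairs, n_normal, n_tumor)),
    cnv_gain_rate = cnv_gain_rate,
    meth_concentration = meth_concentration,
    rng_seed = as.integer(rng_seed)
  ), class = "loi_sim_config")
}

#' Simulate allele-specific read counts for a single SNP
#'
#' Generates the mixture model forward: genotypes from Hardy-Weinberg
#' frequencies adjusted for inbreeding, negative-binomial depth, and binomial
#' reference-read counts whose success probability depends on genotype,
#' degree of imprinting and (for LOI samples) the re-expression fraction.
#'
#' @param n_samples Number of samples.
#' @param p Reference-allele population frequency.
#' @param i Degree of imprinting in `[0, 1]`.
#' @param f Inbreeding coefficient.
#' @param eps Per-read miscall probability.
#' @param coverage_mean,coverage_dispersion Negative-binomial depth parameters.
#' @param n_loi Number of samples (drawn from the heterozygotes where
#'   possible) whose silenced allele is re-expressed.
#' @param delta Expected silenced-allele read fraction in LOI samples.
#' @param seed Optional integer seed.
#' @return Tibble with columns `sample_id`, `genotype`, `silenced_allele`,
#'   `is_loi`, `ref_count`, `alt_count`.
#' @export
simulate_snp_counts <- function(n_samples, p = 0.5, i = 0,
                                f = 0.0103667, eps = 0.002,
                                coverage_mean = 30, coverage_dispersion = 10,
                                n_loi = 0L, delta = 0.25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  check_prob(p, "p"); check_prob(i, "i"); check_prob(f, "f", upper_open = TRUE)
  pr <- hwe_frequencies(p, f)
  geno <- sample(c("RR", "RA", "AA"), n_samples, replace = TRUE, prob = pr)
  depth <- rnbinom(n_samples, mu = coverage_mean, size = coverage_dispersion)
  silenced <- ifelse(geno == "RA",
                     sample(c("ref", "alt"), n_samples, replace = TRUE), NA)
  is_loi <- rep(FALSE, n_samples)
  if (n_loi > 0) {
    het <- which(geno == "RA")
    pick <- het[seq_len(min(n_loi, length(het)))]
    if (length(pick) < n_loi) {
      pick <- c(pick, setdiff(seq_len(n_samples), pick)[seq_len(n_loi - length(pick))])
    }
    is_loi[pick] <- TRUE
  }
  pi_ref <- ref_read_prob(geno, silenced, i, eps, is_loi, delta)
  ref_count <- rbinom(n_samples, depth, pi_ref)
  tibble(
    sample_id = sprintf("S%04d", seq_len(n_samples)),
    genotype = geno, silenced_allele = silenced, is_loi = is_loi,
    ref_count = ref_count, alt_count = depth - ref_count
  )
}

# Genotype frequencies under HWE with inbreeding.
hwe_frequencies <- function(p, f) {
  q <- 1 - p
  c(RR = p^2 + f * p * q, RA = 2 * p * q * (1 - f), AA = q^2 + f * p * q)
}

# Per-sample reference-read success probability given genotype and
# imprinting/LOI state.
ref_read_prob <- function(geno, silenced, i, eps, is_loi, delta) {
  pis <- het_fractions(i, eps)
  pi_ref <- ifelse(geno == "RR", 1 - eps, ifelse(geno == "AA", eps, NA))
  het <- geno == "RA"
  pi_ref[het & silenced == "alt"] <- pis["hi"]
  pi_ref[het & silenced == "ref"] <- pis["lo"]
  hl <- het & is_loi
  pi_ref[hl & silenced == "alt"] <- 1 - delta
  pi_ref[hl & silenced == "ref"] <- delta
  pi_ref
}

#' Simulate a complete synthetic cohort
#'
#' Runs the allele-count mixture model forward for every SNP of the panel and
#' adds matched expression, methylation, copy-number, mutation and clinical
#' tables, together with the planted ground truth.
#'
#' @param config A [simulation_config()].
#' @return An object of class `synthetic_cohort`: a list with tibbles
#'   `allele_counts`, `expression`, `methylation`, `cnv`, `mutations`,
#'   `clinical`, and a `truth` list (`genotypes`, `loi`, `gene_i`, `hazard`),
#'   plus the `config` used.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  if (!inherits(config, "loi_sim_config")) {
    abort("`config` must be created by simulation_config().")
  }
  set.seed(config$rng_seed)
  cfg <- config
  genes <- unique(cfg$panel$gene_id)

  samples <- tibble(
    sample_id = c(sprintf("N%04d", seq_len(cfg$n_normal)),
                  sprintf("T%04d", seq_len(cfg$n_tumor))),
    group = rep(c("normal", "tumor"), c(cfg$n_normal, cfg$n_tumor))
  )
  tum <- samples$group == "tumor"
  samples$stage <- NA_integer_
  samples$stage[tum] <- sample(1:4, cfg$n_tumor, replace = TRUE,
                               prob = cfg$stage_probs)
  samples$age <- ifelse(tum,
                        rnorm(nrow(samples), cfg$age_tumor_mean, cfg$age_tumor_sd),
                        rnorm(nrow(samples), cfg$age_normal_mean, cfg$age_normal_sd))
  samples$sex <- ifelse(
    runif(nrow(samples)) < ifelse(tum, cfg$female_frac_tumor, cfg$female_frac_normal),
    "female", "male")
  samples$matched_normal <- NA_character_
  if (cfg$n_pairs > 0) {
    samples$matched_normal[which(tum)[seq_len(cfg$n_pairs)]] <-
      samples$sample_id[seq_len(cfg$n_pairs)]
  }

  # Per-gene LOI sample assignment (tumor samples only).
  loi_truth <- tibble(gene_id = character(), sample_id = character(),
                      is_loi = logical())
  if (length(cfg$loi_genes)) {
    loi_truth <- purrr::map_dfr(cfg$loi_genes, function(g) {
      n_loi <- round(cfg$loi_case_fraction * cfg$n_tumor)
      picked <- sample(samples$sample_id[tum], n_loi)
      tibble(gene_id = g, sample_id = samples$sample_id[tum],
             is_loi = samples$sample_id[tum] %in% picked)
    })
  }

  # Allele counts: one genotype per (sample, SNP), then forward binomials.
  grid <- tidyr::crossing(samples[, c("sample_id", "group", "stage")], cfg$panel)
  grid <- grid |>
    left_join(tibble(gene_id = names(cfg$imprinting_degree),
                     i = unname(cfg$imprinting_degree)), by = "gene_id")
  u <- runif(nrow(grid))
  p <- grid$ref_allele_freq
  f <- cfg$inbreeding_f
  p_rr <- p^2 + f * p * (1 - p)
  p_ra <- 2 * p * (1 - p) * (1 - f)
  grid$genotype <- ifelse(u < p_rr, "RR", ifelse(u < p_rr + p_ra, "RA", "AA"))
  grid$silenced_allele <- ifelse(
    grid$genotype == "RA",
    ifelse(runif(nrow(grid)) < 0.5, "ref", "alt"), NA_character_)
  grid <- grid |>
    left_join(loi_truth, by = c("gene_id", "sample_id")) |>
    mutate(is_loi = !is.na(.data$is_loi) & .data$is_loi)
  depth <- rnbinom(nrow(grid), mu = cfg$coverage_mean,
                   size = cfg$coverage_dispersion)
  eps <- cfg$seq_error_eps
  pis_hi <- grid$i * (1 - eps) + (1 - grid$i) / 2
  pis_lo <- grid$i * eps + (1 - grid$i) / 2
  pi_ref <- ifelse(grid$genotype == "RR", 1 - eps,
            ifelse(grid$genotype == "AA", eps,
            ifelse(grid$is_loi,
                   ifelse(grid$silenced_allele == "alt",
                          1 - cfg$loi_reexpression_delta,
                          cfg$loi_reexpression_delta),
                   ifelse(grid$silenced_allele == "alt", pis_hi, pis_lo))))
  grid$ref_count <- rbinom(nrow(grid), depth, pi_ref)
  grid$alt_count <- depth - grid$ref_count
  allele_counts <- grid |>
    select("sample_id", "snp_id", "chrom", "pos", "ref", "alt", "gene_id",
           "ref_count", "alt_count", "group", "stage") |>
    arrange(.data$snp_id, .data$sample_id)

  # Expression: log2(RPKM + 1) normal with additive tumor / LOI shifts.
  eg <- tidyr::crossing(gene_id = genes, samples[, c("sample_id", "group")]) |>
    left_join(loi_truth, by = c("gene_id", "sample_id")) |>
    mutate(is_loi = !is.na(.data$is_loi) & .data$is_loi)
  log2e <- rnorm(nrow(eg), cfg$expr_log2_mean, cfg$expr_log2_sd) +
    ifelse(eg$group == "tumor", cfg$tumor_shift[eg$gene_id], 0) +
    ifelse(eg$is_loi, cfg$loi_shift[eg$gene_id], 0)
  eg$rpkm <- pmax(2^log2e - 1, 0)
  expression <- eg |>
    select("gene_id", "sample_id", "rpkm") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "rpkm") |>
    arrange(.data$gene_id)

  # Methylation: two probes per gene; the first sits at ~50% methylation for
  # imprinted genes (an imprinting-regulatory site), others at ~30%.
  probes <- tidyr::crossing(gene_id = genes, probe_idx = 1:2) |>
    mutate(probe_id = sprintf("%s_cg%d", .data$gene_id, .data$probe_idx),
           target = ifelse(.data$probe_idx == 1 &
                             cfg$imprinting_degree[.data$gene_id] > 0, 0.5, 0.3))
  mg <- tidyr::crossing(probes, sample_id = samples$sample_id)
  conc <- cfg$meth_concentration
  mg$beta <- rbeta(nrow(mg), mg$target * conc, (1 - mg$target) * conc)
  methylation <- mg |>
    select("probe_id", "gene_id", "sample_id", "beta") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "beta") |>
    arrange(.data$probe_id)

  # CNV: GISTIC-like scores; gains (score 1) only in tumors.
  cg <- tidyr::crossing(gene_id = genes, samples[, c("sample_id", "group")])
  cg$score <- ifelse(cg$group == "tumor",
                     rbinom(nrow(cg), 1L, cfg$cnv_gain_rate), 0L)
  cnv <- cg |>
    select("gene_id", "sample_id", "score") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "score") |>
    arrange(.data$gene_id)

  mutations <- tibble(gene_id = character(), sample_id = character(),
                      effect = character())

  # Survival: exponential hazard scaling with the hazard gene's expression.
  clinical <- samples
  clinical$time <- NA_real_
  clinical$event <- NA_integer_
  hz <- cfg$hazard_gene
  if (!is.na(hz) && length(hz) && hz %in% genes && cfg$n_tumor > 1) {
    ex <- as.numeric(expression[expression$gene_id == hz,
                                samples$sample_id[tum], drop = TRUE])
    surv <- simulate_survival(log2(ex + 1), cfg$survival_log_hazard,
                              censor_rate = cfg$censor_rate,
                              baseline_hazard = cfg$baseline_hazard)
    clinical$time[tum] <- surv$time
    clinical$event[tum] <- surv$event
  }

  structure(list(
    allele_counts = allele_counts,
    expression = expression,
    methylation = methylation,
    cnv = cnv,
    mutations = mutations,
    clinical = clinical,
    truth = list(
      genotypes = grid |>
        select("sample_id", "snp_id", "gene_id", "genotype",
               "silenced_allele", "is_loi"),
      loi = loi_truth,
      gene_i = tibble(gene_id = names(cfg$imprinting_degree),
                      i = unname(cfg$imprinting_degree)),
      hazard = list(gene_id = hz, log_hazard = cfg$survival_log_hazard)
    ),
    config = cfg
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>\n")
  cat(sprintf("  samples: %d normal, %d tumor\n",
              sum(x$clinical$group == "normal"),
              sum(x$clinical$group == "tumor")))
  cat(sprintf("  SNPs: %d across %d genes\n",
              dplyr::n_distinct(x$allele_counts$snp_id),
              dplyr::n_distinct(x$allele_counts$gene_id)))
  cat(sprintf("  imprinted genes (true i > 0): %s\n",
              paste(x$truth$gene_i$gene_id[x$truth$gene_i$i > 0],
                    collapse = ", ")))
  invisible(x)
}

#' Simulate survival times driven by expression
#'
#' Exponential proportional-hazards event times with hazard
#' `baseline_hazard * exp(log_hazard_beta * (x - mean(x)))` and independent
#' exponential censoring calibrated so that roughly `censor_rate` of samples
#' are censored under the null.
#'
#' @param expression Numeric vector of (log-scale) expression values.
#' @param log_hazard_beta Log hazard ratio per unit expression.
#' @param censor_rate Expected censored fraction, in `[0, 1)`.
#' @param baseline_hazard Baseline event rate.
#' @param seed Optional integer seed.
#' @return Tibble with columns `time` and `event` (1 = event, 0 = censored).
#' @export
simulate_survival <- function(expression, log_hazard_beta,
                              censor_rate = 0.65, baseline_hazard = 0.08,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(!is.finite(expression))) {
    abort("`expression` must be finite.")
  }
  if (censor_rate < 0 || censor_rate >= 1) {
    abort("`censor_rate` must be in [0, 1).")
  }
  n <- length(expression)
  rate <- baseline_hazard * exp(log_hazard_beta * (expression - mean(expression)))
  t_event <- rexp(n, rate)
  if (censor_rate > 0) {
    t_cens <- rexp(n, baseline_hazard * censor_rate / (1 - censor_rate))
  } else {
    t_cens <- rep(Inf, n)
  }
  tibble(time = pmin(t_event, t_cens),
         event = as.integer(t_event <= t_cens))
}

#' Packaged small cohorts with known truth
#'
#' Deterministic fixtures (at most 40 samples, 6 SNPs) used throughout the
#' test-suite and documentation:
#' \describe{
#'   \item{`tiny-null`}{no gene imprinted (all true i = 0), no LOI.}
#'   \item{`tiny-imprinted`}{GENE1 imprinted at i = 0.97 with two SNPs;
#'     the other genes biallelic.}
#'   \item{`tiny-loi`}{GENE1 imprinted with strong re-expression and
#'     overexpression in tumors (the planted canonical-LOI gene); GENE2
#'     imprinted without LOI; GENE3 biallelic.}
#' }
#'
#' @param name One of `"tiny-null"`, `"tiny-imprinted"`, `"tiny-loi"`.
#' @return A `synthetic_cohort`.
#' @export
make_fixture <- function(name) {
  fixtures <- c("tiny-null", "tiny-imprinted", "tiny-loi")
  if (!is.character(name) || length(name) != 1L || !name %in% fixtures) {
    abort(sprintf("Unknown fixture %s. Valid fixtures: %s.",
                  deparse(name), paste(fixtures, collapse = ", ")),
          class = "loiscan_lookup_error")
  }
  panel <- snp_panel(c("GENE1", "GENE2", "GENE3"), snps_per_gene = 2L,
                     ref_allele_freq = 0.5)
  base <- list(n_normal = 32L, n_tumor = 8L, panel = panel,
               coverage_mean = 40, n_pairs = 4L)
  cfg <- switch(
    name,
    "tiny-null" = simulation_config(
      n_normal = base$n_normal, n_tumor = base$n_tumor, panel = panel,
      coverage_mean = base$coverage_mean, n_pairs = base$n_pairs,
      imprinting_degree = c(GENE1 = 0, GENE2 = 0, GENE3 = 0),
      loi_genes = character(), hazard_gene = NA_character_,
      rng_seed = 101L),
    "tiny-imprinted" = simulation_config(
      n_normal = base$n_normal, n_tumor = base$n_tumor, panel = panel,
      coverage_mean = base$coverage_mean, n_pairs = base$n_pairs,
      imprinting_degree = c(GENE1 = 0.97, GENE2 = 0, GENE3 = 0),
      loi_genes = character(), hazard_gene = NA_character_,
      rng_seed = 102L),
    "tiny-loi" = simulation_config(
      n_normal = base$n_normal, n_tumor = base$n_tumor, panel = panel,
      coverage_mean = base$coverage_mean, n_pairs = base$n_pairs,
      imprinting_degree = c(GENE1 = 0.97, GENE2 = 0.95, GENE3 = 0),
      loi_genes = "GENE1", loi_case_fraction = 0.75,
      loi_reexpression_delta = 0.35,
      tumor_shift = c(GENE1 = 1.0), loi_shift = c(GENE1 = 0.4),
      expr_log2_sd = 0.5,
      rng_seed = 103L)
  )
  simulate_cohort(cfg)
}
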