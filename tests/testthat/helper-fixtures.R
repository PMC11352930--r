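# In-code fixtures shared across test files.

# A minimal allele-count table: one SNP, explicit per-sample counts.
toy_counts <- function(ref, alt, group = NULL, snp_id = "rs1",
                       gene_id = "GENEA") {
  n <- length(ref)
  rc <- as.integer(round(ref)); ac <- as.integer(round(alt))
  out <- tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    snp_id = snp_id, chrom = "chr1", pos = 100L, ref = "A", alt = "G",
    gene_id = gene_id, ref_count = rc, alt_count = ac)
  if (!is.null(group)) {
    out$group <- group
    out$stage <- ifelse(group == "tumor", 1L, NA_integer_)
  }
  out
}

# A hand-built imprinting_fit carrying only what the quality statistics
# need (counts + posterior component assignments).
fake_fit <- function(ref, alt, component) {
  n <- length(ref)
  post <- matrix(0, n, 4)
  post[cbind(seq_len(n), component)] <- 1
  colnames(post) <- c("post_rr", "post_hi", "post_lo", "post_aa")
  structure(list(ref_count = as.integer(ref), alt_count = as.integer(alt),
                 posteriors = tibble::as_tibble(post),
                 f = 0.0103667, eps = 0.002,
                 p_profiled = 0.5, i_hat = 0.9),
            class = "imprinting_fit")
}

# Brute-force mixture log-likelihood: sums over every genotype assignment
# (RR, het-high, het-low, AA per sample), independent of the package's
# vectorised per-sample mixture computation.
enumerate_loglik <- function(ref, n, p, i, f, eps) {
  w <- c(p^2 + f * p * (1 - p),
         p * (1 - p) * (1 - f),
         p * (1 - p) * (1 - f),
         (1 - p)^2 + f * p * (1 - p))
  pis <- c(1 - eps,
           i * (1 - eps) + (1 - i) / 2,
           i * eps + (1 - i) / 2,
           eps)
  s <- length(ref)
  combos <- as.matrix(expand.grid(rep(list(1:4), s)))
  total <- 0
  for (r in seq_len(nrow(combos))) {
    g <- combos[r, ]
    total <- total + prod(w[g] * dbinom(ref, n, pis[g]))
  }
  log(total)
}

# Grid-search maximiser of the two-group binomial log-likelihood in
# (b0, b1), zooming in around the optimum; independent oracle for glm.
grid_logistic <- function(least, most, is_case, span = 8, steps = 41,
                          rounds = 6) {
  ll <- function(b0, b1) {
    eta <- b0 + b1 * is_case
    pi <- 1 / (1 + exp(-eta))
    sum(least * log(pi) + most * log(1 - pi))
  }
  c0 <- 0; c1 <- 0; half <- span
  for (r in seq_len(rounds)) {
    b0s <- seq(c0 - half, c0 + half, length.out = steps)
    b1s <- seq(c1 - half, c1 + half, length.out = steps)
    vals <- outer(b0s, b1s, Vectorize(ll))
    k <- arrayInd(which.max(vals), dim(vals))
    c0 <- b0s[k[1]]; c1 <- b1s[k[2]]
    half <- half * 2 / (steps - 1) * 2 # keep a neighbourhood around the best cell
  }
  c(b0 = c0, b1 = c1)
}
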