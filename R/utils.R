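# Small shared numerics. These are deliberately dependency-free.

#' Geometric mean of p-values
#'
#' Consensus p-value used for gene-level aggregation: `exp(mean(log(p)))`.
#' Zero p-values are clipped to the smallest positive double with a warning,
#' since `log(0)` would collapse the whole gene to zero.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return A single numeric value in `[0, 1]`.
#' @examples
#' geometric_mean_p(c(1e-4, 1e-2)) # 1e-3
#' @export
geometric_mean_p <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0L) return(NA_real_)
  if (any(p < 0 | p > 1)) abort("p-values must lie in [0, 1].")
  if (any(p == 0)) {
    warn("Zero p-values clipped to .Machine$double.xmin before log.")
    p <- pmax(p, .Machine$double.xmin)
  }
  exp(mean(log(p)))
}

# Row-wise log-sum-exp for an n x k matrix of log-likelihood terms.
logsumexp_rows <- function(lmat) {
  m <- do.call(pmax, c(as.data.frame(lmat), na.rm = FALSE))
  m + log(rowSums(exp(lmat - m)))
}

# Reference-allele success probabilities of the two heterozygous mixture
# components at degree of imprinting i and per-read miscall rate eps:
# the silenced allele contributes only through sequencing error.
het_fractions <- function(i, eps) {
  c(hi = i * (1 - eps) + (1 - i) / 2,
    lo = i * eps + (1 - i) / 2)
}

# Argument check helper: probability-scale scalar.
check_prob <- function(x, name, upper_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      x < 0 || x > 1 || (upper_open && x == 1)) {
    abort(sprintf("`%s` must be a single number in [0, 1%s].",
                  name, if (upper_open) ")" else "]"))
  }
  invisible(x)
}

check_counts <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x != floor(x))) {
    abort(sprintf("`%s` must contain non-negative integer counts.", name))
  }
  invisible(x)
}
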