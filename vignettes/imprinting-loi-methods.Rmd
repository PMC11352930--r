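---
title: "Detecting imprinting and loss-of-imprinting from allele-specific expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting imprinting and loss-of-imprinting from allele-specific expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loiscan)
library(dplyr)
```

## The problem

Genomic imprinting silences one parental allele of a gene, so in a
heterozygous individual essentially all RNA-seq reads at an exonic SNP come
from a single allele. Loss-of-imprinting (LOI) — re-expression of the
normally silenced allele — is a candidate early event in oncogenesis, and in
its *canonical* form is accompanied by overexpression of the gene. loiscan
detects imprinted SNPs and genes in a normal-tissue population from allelic
read-count tables, screens them for LOI in a tumor population, and runs the
downstream clinical statistics (differential expression, methylation
contrasts, copy-number association, survival), all on plain tabular inputs.

Because no individual-level genotype truth is available in public cohorts,
the package ships a first-class synthetic-cohort generator with planted
ground truth; every statistical guarantee in the test-suite is demonstrated
against cohorts that generator produces.

## The mixture model

At a biallelic SNP with reference-allele population frequency $p$, sample
genotypes follow Hardy–Weinberg proportions adjusted for excess homozygosity
through an inbreeding coefficient $F$:

$$P(RR) = p^2 + Fpq,\quad P(RA) = 2pq(1-F),\quad P(AA) = q^2 + Fpq .$$

Given a genotype and a per-read miscall probability $\varepsilon$, the
reference-read count $x$ out of depth $n$ is binomial. Homozygotes have
success probability $1-\varepsilon$ (RR) or $\varepsilon$ (AA). The
heterozygous class is split into two components by the degree-of-imprinting
parameter $i \in [0, 1]$:

$$\pi_\text{hi} = i(1-\varepsilon) + \tfrac{1-i}{2}, \qquad
  \pi_\text{lo} = i\varepsilon + \tfrac{1-i}{2},$$

each carrying half of the heterozygous prior mass (which parental allele is
silenced is unobservable and assorts independently of the read-out allele,
so the population pattern is symmetric). At $i = 0$ both components collapse
to a single peak at $1/2$ (no imprinting); at $i = 1$ they coincide with the
homozygous peaks (complete imprinting). The per-sample likelihood is the
four-component binomial mixture; samples are independent.

### Estimation

`fit_imprinting()` maximises the total log-likelihood over $i$. The allele
frequency is profiled out: at each candidate $i$, $p$ is re-estimated by 20
EM iterations started from the pooled read proportion (the posterior
expected allele dosage update). The profile likelihood in $i$ can be
multimodal at low depth, so the maximiser uses a full grid (step 0.005)
followed by local refinement (`optimize()`, golden-section with parabolic
interpolation) to a tolerance of $10^{-4}$. The homozygous component
densities do not depend on $i$ and are computed once per SNP; per-sample
mixture terms use log-sum-exp, so deep samples cannot underflow.

Two allele-frequency estimates are kept deliberately distinct, because two
of the screening filters refer to different estimation stages:
`p_initial` is the pooled read proportion, and `p_genotype` results from one
E-step of the non-imprinted ($i=0$) mixture, counting posterior genotypes
rather than reads — robust to the strong read imbalance that imprinting
itself induces.

### Testing

The null hypothesis $i = 0$ sits on the boundary of the parameter space, so
twice the log-likelihood-ratio is asymptotically a 50:50 mixture of a point
mass at zero and $\chi^2_1$; `lrt_pvalue()` applies that correction
($p = \tfrac12 P(\chi^2_1 > \Lambda)$, $p = 1$ at $\Lambda = 0$, negative
statistics from numerical noise clipped to zero). Calibration under the null
is demonstrated in the test-suite: across 1,000 simulated null SNPs the
rejection rate at $\alpha = 0.05$ stays within $[0.03, 0.07]$.

## Quality statistics and filters

Beyond the LRT, each SNP is screened by statistics designed to be
deterministic, bounded and threshold-compatible:

* **Goodness of fit** (`goodness_of_fit()`): one minus the total-variation
  distance between the empirical distribution of reference-read fractions
  (20 equal bins, samples with depth ≥ 5) and the fitted mixture's
  predictive distribution over the same bins (each sample's exact predictive
  bin probabilities, averaged). This choice is bounded in $[0,1]$ and equals
  1 exactly when the empirical histogram matches the predictive one.
* **Heterozygote symmetry** (`symmetry_test()`): among samples whose
  maximum-posterior component is heterozygous, the counts assigned to the
  high and low component are compared by an exact two-sided binomial test at
  $\tfrac12$. Under genuine imprinting the split is even; strong asymmetry
  points towards a cis-eQTL or mapping artefact rather than imprinting. Note
  that when $\hat i \approx 0$ the two heterozygous components coincide and
  the assignment is an arbitrary tie-break, so this statistic is only
  interpretable jointly with the effect-size filter.
* **Robust median imprinting** (`median_imprinting()`): the median of the
  per-sample allelic skew $(\max - \min)/n$ over posterior-heterozygous
  samples with depth ≥ 5 — an estimator of $i$ that no single outlying
  sample can move.

`filter_snps()` applies the screening thresholds as strict inequalities:
median coverage > 4, #samples > 30 (samples with any reads at the SNP),
initial MAF > 0.1, genotype-estimate MAF > 0.15, GOF > 0.80, $\hat i$ >
0.60, robust median imprinting > 0.80, SNP-level Benjamini–Hochberg FDR <
0.05, and the symmetry screen at 0.05. Missing statistics fail their filter.

**The symmetry direction is switchable.** `symmetry_keep = "ge"` (default)
keeps SNPs whose heterozygote assignment is *consistent* with symmetry
($p \ge 0.05$); `"lt"` keeps SNPs where symmetry is *rejected*. The default
follows from the model's own structure: the silenced-allele side assorts
independently of the allele identity, so a genuinely imprinted SNP produces
a balanced split and a large symmetry p-value — a keep-if-rejected rule
would discard every true positive the generator can produce. The opposite
direction remains available for data in which the statistic is defined with
the opposite polarity.

### Gene-level consensus

`aggregate_genes()` combines SNP-level LRT p-values per gene by the
geometric mean, adjusts across genes by Benjamini–Hochberg, and calls a gene
imprinted when the FDR is below 0.05 **and** at least two of its SNPs pass
all filters. The two-SNP rule protects against single-SNP artefacts but also
drops known imprinted loci that carry a single informative SNP; a manual
whitelist (`imprinting_whitelist()`: SLC9A3R2, PEG10, NDN, GNAS, RPH3AL)
retains those with provenance `"manual"`.

## The LOI test

For each imprinted SNP, every sample contributes its least-expressed allele
reads as binomial successes and its most-expressed allele reads as failures;
`loi_regression()` fits

$$\operatorname{logit}(\pi_s) = \beta_0 + \beta_1\,\mathbb{1}[\text{case}],$$

and reports the one-sided Wald p-value for $\beta_1 > 0$ (more "success"
means more biallelic expression in cases, i.e. LOI). Homozygous samples are
retained — the degree-of-LOI definition assigns them 0, and they dilute both
groups identically. Two degenerate regimes are handled explicitly:

* one group entirely without successes (or failures): the Wald standard
  error diverges under quasi-separation and its p-value loses all power, so
  the one-sided p is taken from the signed likelihood-ratio statistic
  instead and the row is flagged `method = "lrt"`;
* no successes in either group: the fit is meaningless; `p = 0.5` is
  reported with `degenerate = TRUE`.

Gene-level consensus (`combine_loi_gene()`) is again the geometric mean over
the gene's imprinted SNPs with BH across genes; `gene_q < 0.05` calls LOI.

Per-sample LOI status (`call_loi_samples()`) uses inclusive thresholds: a
tumor sample shows LOI at a gene when at any informative SNP its
least-expressed allele has ≥ 2 reads **and** ≥ 10% of the total. A sample
heterozygous at none of the gene's SNPs is uncallable (missing, not
`FALSE`). Aggregation across a gene's SNPs is by "any SNP passes": samples
are typically informative at only a subset of SNPs, and requiring a pooled
count would conflate missingness with absence of re-expression.

The per-sample **degree of LOI** is `degree_of_loi()` = least/most read
coverage: 1 for a perfect heterozygote, 0 for a perfect homozygote,
undefined (NA) without reads.

## Downstream clinical statistics

* **Differential expression**: Welch (or paired) t-tests on
  $\log_2(\text{RPKM}+1)$; the log2 scale is used throughout so the tested
  scale and the reported fold change coincide. For genes without an
  expression matrix entry, `snp_level_de()` uses total allelic coverage,
  library-size corrected to CPM, as an expression proxy.
* **Canonical LOI** (`classify_canonical_loi()`): LOI FDR < 0.05, DE FDR <
  0.05, log2 fold change > 0.5, and no RME (random monoallelic expression)
  flag — all four as a conjunction.
* **Methylation**: beta values clipped to $[10^{-6}, 1-10^{-6}]$ and
  logit-2 transformed to M-values; per-probe Welch t-tests per pairwise
  group contrast with BH within contrast, effects reported back on the beta
  scale. Per-probe moderated (empirical-Bayes) statistics are deliberately
  not used; plain Welch t keeps the per-probe tests independent and
  transparent at the cohort sizes simulated here.
* **Copy number**: gain is score > 0 (the conventional reading of
  GISTIC-like calls); Welch t on expression gain vs no-gain; gain × LOI 2×2
  association by chi-squared with Yates continuity correction (LOI counts
  are small); per-gene mutation record counts.
* **Survival**: `cox_survival()` fits proportional hazards on continuous
  $\log_2(\text{RPKM}+1)$ (a raw-scale flag exists; the log scale matches
  the expression tests), adjusted for age/sex(/stage); Kaplan–Meier display
  groups split at the tumor-mean expression with ties assigned "above".
* **Stage trend**: one-way ANOVA of expression across tumor stages.

## The synthetic cohort generator

`simulate_cohort()` runs the mixture model *forward* and is therefore the
exact generative complement of the detector: genotypes from the
inbreeding-adjusted HWE frequencies; read depth negative-binomial
(overdispersed RNA-seq coverage; mean 30, size 10 by default); heterozygote
reference-read counts binomial with $\pi_\text{hi}$ or $\pi_\text{lo}$
(silenced side uniform per sample); LOI heterozygotes re-express the
silenced allele at fraction $\delta$ instead.

Defaults encode the targeted cohort design: 128 normal and 240 stage 1
tumor samples; $F = 0.0103667$; $\varepsilon = 0.002$ (a free parameter —
no error rate is identifiable from the count tables themselves);
$\delta = 0.25$ in 30% of tumors at the LOI gene; log-normal RPKM
(baseline mean 5, SD 1 on the log2 scale) with a +0.60 tumor shift and a
further +0.37 LOI-sample shift at the LOI gene; beta-distributed
methylation with the first probe of an imprinted gene at ~50% methylation
(an imprinting-regulatory site); 13.2% copy-number gain rate in tumors;
ages N(60.77, 13.28²) / N(60.00, 12.88²) and 33%/41% female fractions;
exponential survival with hazard ratio 1.68 per unit of the hazard gene's
log2 expression and ~65% independent exponential censoring; 20 matched
tumor–normal pairs.

What the generator does *not* emulate: tumor purity and subclonal
structure, allele-specific methylation mechanisms, isoform-specific
imprinting, mapping bias, and cis-eQTL-driven allelic imbalance. Passing
tests therefore demonstrate statistical correctness of the estimators and
decision rules under the stated model, not robustness to those real-data
artefacts.

`make_fixture()` packages three deterministic miniature cohorts
(32 normals + 8 tumors, 3 genes × 2 SNPs, fixed seeds): `tiny-null`
(nothing planted), `tiny-imprinted` (one gene at $i = 0.97$) and `tiny-loi`
(a canonical-LOI gene with re-expression at $\delta = 0.35$ in 75% of
tumors and a +1.0 log2 expression shift — effects strong enough to be
unambiguous at 8 tumor samples).

## Worked example

```{r example, eval = FALSE}
cohort <- simulate_cohort(simulation_config(rng_seed = 1))
report <- run_pipeline(cohort)
tidy(report)     # per-gene table: N, i-hat, LOI q, DE q, log2FC
glance(report)   # stage tallies
```

## Numerical choices and edge cases

* Zero p-values entering a geometric mean are clipped to the smallest
  positive double with a warning.
* Allele-fraction binning assigns fraction $f$ to bin
  $\lceil 20f \rceil$ (clamped to $[1, 20]$), so $f = 0$ joins the first
  and $f = 1$ the last bin.
* Samples with zero depth are dropped before fitting; a SNP needs at least
  two samples with reads.
* Posterior component ties (possible only when components coincide) break
  towards the first component, which is why the symmetry statistic is
  uninformative at $\hat i \approx 0$ (see above).
* `t.test` guards: identical groups return $p = 1$ with a warning instead
  of erroring on zero variance.
* Cox fits that fail or lose all events return a flagged row
  (`converged = FALSE`), never an error.
* All tables are written as TSV with headers; the report JSON is written
  with `auto_unbox` and full precision, making end-to-end determinism
  checkable by file hash.

## Problem sizes used in validation

The test-suite validates the statistical guarantees at these simulation
sizes, chosen to bound Monte-Carlo noise while keeping a laptop run short:
estimator bias on a grid $i \in \{0.2, 0.5, 0.8, 0.95\}$ with 200 samples ×
50 replicates per point; LRT calibration on 1,000 null SNPs of 100 samples;
LOI power/specificity at the full cohort design (128/240) × 100 replicates;
Cox coverage at $n = 500$ × 50 replicates; brute-force oracle equivalence
(likelihood enumeration over all genotype assignments) at ≤ 8 samples and
depth ≤ 6, and a zooming grid search for the logistic coefficient.

## Known limitations

Parent-of-origin assignment is impossible without trio data; the package
flags but cannot distinguish random monoallelic expression from imprinting;
overdispersion beyond binomial (e.g. beta-binomial allelic noise) is not
modelled in the LOI regression; and the inbreeding coefficient is consumed
as a fixed constant rather than estimated from the cohort.
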