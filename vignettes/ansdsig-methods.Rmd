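---
title: "Methods: ANSD signature derivation, prediction and subtyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ANSD signature derivation, prediction and subtyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ansdsig)
```

This vignette documents the models and procedures the package implements,
the tunable parameters and their defaults, what the synthetic-data
generators do and do not emulate, and the numerical and design choices
that were genuinely open.

## The statistical kernel

All stages route through one kernel (`spearman_corr`, `rank_sum_test`,
`bh_adjust`, `auc_score`, `log_rank_test`, `fit_cox`) so tie handling and
missing-value conventions are identical everywhere: midranks for ties,
pairwise deletion in correlations, and listwise deletion (with a logged
count) for survival rows. The kernel is deliberately self-contained and is
verified in the test suite against enumeration oracles and independent
reference implementations.

Choices the underlying literature leaves open, and what this package does:

* **Spearman p-values.** t approximation with `n - 2` df for `n >= 10`;
  exact permutation enumeration below that. Exactness where it is cheap,
  standard practice elsewhere.
* **Mann-Whitney.** Exact enumeration of all group assignments when the
  pooled size is at most 12 and tie-free; otherwise the normal
  approximation with tie correction and continuity correction. All group
  comparisons are two-sided: the source analyses never state sidedness,
  and two-sided is the conservative default.
* **Cox ties.** Breslow approximation, Newton-Raphson with step halving,
  convergence at max |score| < 1e-8 or 50 iterations. Monotone likelihood
  (a diverging coefficient, i.e. complete separation) is reported as
  `converged = FALSE` with a diagnostic rather than an error, because the
  risk-model stage wants to surface the problem, not crash.

## ssGSEA scoring

Genes are ranked per unit by decreasing expression; the score is the
summed difference between the rank-weighted in-set cumulative fraction
(weights `rank^alpha`) and the uniform out-of-set cumulative fraction.

* `alpha = 0.75`: the conventional default for this method; the source
  description says only "default parameters".
* **Tie-break**: ties in expression are broken by gene-name lexicographic
  order, making scores bit-reproducible across platforms. Scores are
  invariant to strictly monotone transforms of a unit's expression, which
  is the property that makes the method usable on differently normalized
  inputs.
* **Normalization**: when requested, every score is divided by the global
  `max - min` of the score matrix *of that call*. Normalized scores are
  therefore comparable only within a call; this is flagged in the output
  attributes. Whether single-cell scores should be normalized per dataset
  or globally is not specified anywhere; per-call normalization was chosen
  and recorded.
* `kcdf = "Gaussian"` exists in the common bulk implementation but is
  inert for this scoring method; the argument is accepted and recorded for
  provenance only.
* Set members absent from the matrix are dropped with a warning as long as
  one member remains; a fully absent set is an error naming the set.

## Signature derivation (Gx / Gy / Gn)

Per dataset: QC keeps cells with >= 300 detected genes and mitochondrial
fraction <= 0.20 (strict reading: "less than 300" and "more than 20%"
fail). Normalization is library-size scaling to 10,000 followed by
`log2(x + 1)`; the upstream description of per-sample normalization is
garbled in the source (it names PCA, a dimensionality reduction), so
standard library-size + log normalization is used and documented here.

The DE screen tests each gene malignant-vs-rest with the rank-sum test;
`logFC` is computed on back-transformed means with a pseudocount of 1 (the
pseudocount is configurable; the source is silent). BH is applied within
each dataset independently, because datasets are screened separately
before intersecting. `Gy` keeps only the positive direction despite the
generic `|logFC| >= 0.30` phrasing, because the candidate set is defined
as genes *higher* in malignant cells. The correlation screen uses raw
p-values exactly as printed (a flag enables BH). `Gn = Gx ∩ Gy` per
dataset; the signature is the sorted deduplicated union with per-gene
provenance. Tightening any threshold can only shrink the result, and the
union is invariant to dataset order; both are asserted as properties in
the tests.

## CRISPR z-score integration

The printed standardization formula is self-contradictory: taken per gene
across datasets it makes every gene's mean z identically zero, which is
incompatible with a nonzero mean-z ranking and with the stated goal of
removing batch effects between screens. The package therefore standardizes
**within each dataset across genes** (`mu_d`, `sigma_d` are the dataset's
logFC mean and SD), which makes the integration invariant to per-screen
affine transforms. The literal per-gene reading remains available as
`mode = "per_gene"` for audit; the tests demonstrate its degeneracy.

Ranking is ascending in mean z (rank 1 = most resistance-like), ties
broken by gene name. Top-fraction sizes use `floor(fraction * n_ranked)`,
which reproduces the published counts 450/900/1350 at the 22,505-gene
scale (round-to-nearest would too; floor is the conservative rule). Genes
need only be observed in `min_datasets = 1` screens by default, matching
the published ranking that tolerates missing entries.

## ICI response prediction

RECIST CR/PR encode to 1 and SD/PD to 0; anything else is a hard error.
Pooled cohorts are batch-corrected by a per-gene location/scale method:
within each batch, center to the pooled gene mean and rescale so the
pooled per-gene SD is preserved exactly (the rescaling factor
`sqrt((N-1)/(N-B))` makes the preservation exact, and the transform
idempotent). An empirical-Bayes variant (ComBat) is selectable. Whether
response should be protected as a covariate during correction is unstated
upstream; the default method is covariate-free.

The 80/20 split takes `round(0.8 n)` training samples (772 -> 618/154,
matching the published sizes) with largest-remainder stratification.
Training uses 5-fold CV repeated 10 times over small documented grids (RF
`mtry` in {sqrt(p), p/3} with 500 trees; SVM cost {1, 10}; KNN k {5, 11,
21}; boosting rounds {50, 100}; NB Laplace {0, 1}) — no grids are given
upstream, so these are deliberately minimal. AdaBoost and LogitBoost are
decision-stump boosters implemented in-package; "cancerclass" is
instantiated as a standardized nearest-centroid classifier whose
continuous score is the distance difference to the two class centroids,
fit without CV — an explicit approximation, since only the algorithm name
is given. All algorithms expose probability-like continuous scores, and
the evaluation AUC is exactly `auc_score` on those scores. The published
validation AUC (0.675, "low accuracy" band) depends on the eight external
cohorts and is not reproducible here; planted-effect synthetic AUC
thresholds stand in for it.

## Hub selection, risk score and cut-point

The consensus RULE — a gene must be picked by at least 3 of 5 selectors —
is the contract. Two of the five named selectors ("Bayesian", "LQV") are
not specified anywhere; they are instantiated as (a) a per-feature
class-conditional Gaussian log-evidence-ratio filter with BH, and (b) a
per-feature AUC filter at 0.6, both clearly labelled stand-ins behind
pluggable interfaces. Boruta is implemented as shadow-feature permutation
against RF permutation importance with binomial confirmation (up to 100
iterations). The selector target defaults to response labels; survival
can be used instead by passing any binary target, since the upstream
description is ambiguous about which was used.

The RiskScore is the linear Cox form over hub genes. The cut-point scan
evaluates every distinct observed score inside the 10-90% quantile band
and maximizes the log-rank chi-square (ties to the lower cutoff), which is
the maximally-selected-rank-statistics practice behind the named
`surv_categorize` behaviour. No multiplicity correction is applied to the
selected statistic — the upstream analysis reports the plain KM p — so the
reported p-value is optimistic; this caveat is deliberate and documented.

## Consensus subtyping

For each k in 2..6: 80% of samples are subsampled, k-means (Euclidean,
k-means++ initialization, seeded) clusters the subsample, and co-cluster
counts accumulate over 1,000 repetitions (the package default mirrors the
published configuration; scaled-down repetitions are used in the test
suite). The consensus matrix divides co-clustered counts by co-sampled
counts; assignments come from an average-linkage cut of `1 - M`. The
upstream analysis shows a consensus CDF but never states the k-selection
criterion; the package uses the classic relative delta-area of the CDF and
reports PAC (0.1-0.9 band) alongside. Dysfunction, TMB and MSI scores are
consumed as input columns — their generating algorithms are out of scope.
Mutation frequencies count a sample at most once per gene and exclude
Silent variants by default (the upstream variant-class filter is unstated;
the exclusion list is configurable).

## Synthetic data: what it does and does not emulate

All generators are pure functions of (config, seed) and emit ground truth
sufficient to score recovery. Expression is additive Gaussian noise on a
log2-like scale rather than counts: every downstream statistic in scope is
rank- or mean-based and operates on normalized matrices, so a count model
would add realism the pipeline never exploits. Consequences: passing tests
demonstrate correct recovery of planted rank/mean structure, not
robustness to UMI sampling noise, doublets, ambient RNA, or nonlinear
batch effects (only location/scale shifts are modelled). QC metadata
(detected genes, mitochondrial fraction) is simulated independently of the
matrix so the QC filter is tested as a pure filter.

Defaults mirror the study conditions: ICI batches of 181/348/243 samples
(n = 772), a 30% responder rate (a typical ICI objective-response rate),
CRISPR screens of 22,505 genes in 17 datasets with 50 planted resistance
genes at shift -3 and 10% missingness. Planted correlations are calibrated
through the bivariate-normal relation `r_pearson = 2 sin(pi rho_s / 6)` so
the realized Spearman correlation lands on target. RECIST labels split
CR/PR and SD/PD 50/50 within their response class, since only the binary
encoding matters downstream.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` run, as the package's own
choices: signature recovery on three datasets of 2,000 genes x 600 cells
with a 15-gene planted truth; response prediction on n = 600 cohorts
(planted effect d = 1.5 on 20 genes; 20 null seeds); CRISPR recovery on
5,000 genes x 10 screens (plus the full 22,505 x 17 scale for the
top-fraction sizes); consensus clustering on two 50-sample blobs at 200
repetitions; Cox recovery at n = 400 with a planted hazard ratio of 2.

## Known limitations

Single-cell batch integration (Harmony-style), doublet detection,
deconvolution algorithms, TIDE, pseudotime and network lookups are out of
scope; their outputs are consumed as inputs where relevant. The Cox fit is
unpenalized and unstratified; BH is the only multiplicity method; the
maximally selected cut-point p-value is uncorrected. Normalized ssGSEA
scores are comparable only within one call.
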