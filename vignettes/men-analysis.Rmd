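---
title: "Molecular ecological network analysis: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular ecological network analysis: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(menet)
```

## The problem

Longitudinal amplicon surveys of the gut microbiome — for example a
two-arm mouse experiment in which one arm receives an antibiotic pulse and
both arms are then sampled monthly for over a year — produce ASV-by-sample
count tables. Beyond diversity summaries, the ecological question is how
the *association structure* of the community responds and recovers: which
taxa co-occur, how modular the co-occurrence network is, which taxa act as
keystones, and how fragile the network is to species loss. `menet`
implements that analysis chain end to end: preprocessing, diversity and
permutation tests, correlation-network construction with a random-matrix-
theory (RMT) threshold, a full topological index panel with null-model
comparison, robustness/vulnerability simulation, time-trend regression,
and pathway-level functional networks with dense-core extraction.

## Preprocessing model

Counts are filtered in two stages. The low-abundance filter drops an ASV
when, in **every** month stratum, its summed count is below `min_total`
(default 10) or it occurs in fewer than `min_samples` samples (default 3).
The stratified reading matters for longitudinal data: a taxon absent early
but abundant late is biologically informative and is retained because it
passes in at least one stratum. Rarefaction (optional, default depth
37,800 reads — the conventional depth for this design) subsamples without
replacement, preserving exact depth and unbiased relative abundances.
Before any correlation is computed, the half-prevalence filter keeps only
ASVs present in at least `ceiling(0.5 * n)` of the samples entering that
network; correlations estimated from mostly-zero vectors are dominated by
the zero pattern and are not trustworthy. Prevalence filtering is applied
*per network* (per group-month cell), not globally: each monthly network
should be built from taxa observable in that cell.

Abundances are `log10(x + 1)`-transformed before Pearson correlation. The
base and pseudocount are exposed (`log_transform()`), since only
"log-transformed" is conventionally specified in this field.

## RMT thresholding

An arbitrary correlation cutoff is the weakest point of co-occurrence
analysis. The RMT approach chooses it from the spectrum of the thresholded
absolute correlation matrix: while noise correlations remain, the
eigenvalue nearest-neighbour spacing distribution (NNSD) shows
Gaussian-orthogonal-ensemble (GOE) level repulsion; once only modular
signal survives, independent blocks superpose into Poisson statistics
`P(d) = e^{-d}`.

`nnsd()` implements the spectral test:

* eigenvalues are **de-duplicated** first. Thresholded matrices contain
  exactly degenerate eigenvalues (isolated rows all contribute 1); their
  zero spacings form an atom that has nothing to do with either universal
  law and would corrupt the fit.
* unfolding maps each eigenvalue to its fitted rank under a cubic
  smoothing spline (default `df = 10`) fit to the empirical cumulative
  spectral density, and spacings are rescaled to mean 1. A low `df`
  deliberately captures only the smooth part of the density; fitting too
  closely would whiten the very fluctuations being tested.
* the goodness-of-fit statistic is a chi-squared over
  `floor(sqrt(n))` equal-probability exponential bins, compared to
  `chisq(df = bins - 1)`. The same machinery evaluates the Wigner surmise
  `P(d) = (pi d / 2) e^{-pi d^2/4}` so both universal laws are available.

`scan_threshold()` walks the cutoff grid (0.30–0.99, step 0.01) and
chooses the **smallest** threshold whose NNSD conforms to Poisson at
`p > 0.001` *provided* every larger testable threshold remains on the
Poisson side of the two laws (`chi2_Poisson < chi2_Wigner`). Requiring
strict conformity at every larger threshold turned out to be fragile: near
total breakup of the matrix, a handful of surviving dyads and triangles
produce clustered, near-degenerate spacings that reject Poisson through
level *attraction* — not a GOE signature, and not a reason to discard a
lower, well-supported transition point. The two-sided comparison encodes
"has crossed away from GOE" directly. All knobs (`alpha`, `min_eigs`,
binning, spline df) are exposed because the exact GOF machinery varies
between published implementations of the method.

Thresholds where fewer than `min_eigs` (default 100) unique eigenvalues
remain are excluded from the decision; with very small ASV panels the scan
errors out and the pipeline falls back to a fixed threshold (default 0.75,
recorded in the output).

## Index panel and null models

All structural indices are computed on the unsigned skeleton; signs are
kept only for positive/negative link accounting (P/N is `NA`, never
infinity, when no negative links exist). Geodesic distance averages over
*reachable* pairs only, and connectedness is the fraction of reachable
pairs — monthly networks routinely have several components, and averaging
infinite distances would be meaningless.

Module detection uses deterministic fast-greedy modularity maximization on
the unweighted skeleton (reproducibility over the last percent of
modularity; the algorithm is pluggable). One guard is applied: the
returned partition is never worse than one-module-per-connected-component,
which protects against floating-point tie artifacts in the greedy
dendrogram cut on symmetric graphs. Relative modularity
`RM = (M - mean(M_null)) / mean(M_null)` and the avgCC/GD/modularity
z-scores come from Maslov–Sneppen degree-preserving rewiring
(`null_ensemble()`, 10 swap attempts per edge, ensemble size
config-exposed).

Zi–Pi roles use the conventional cutoffs `Zi > 2.5` (module hub) and
`Pi > 0.62` (connector), both exposed as parameters since published
pipelines cite them without printing values; zero-variance modules give
`Zi = 0`. Keystones are connectors, module hubs and network hubs.

## Stability

Global efficiency is the mean inverse shortest-path length;
vulnerability is the worst relative efficiency drop over single-node
deletions. Robustness removes either `ceiling(0.5 n)` random nodes
(averaged over `n_reps`, default 100) or all module hubs (network hubs
included — they exceed the same Zi cutoff), then **prunes survivors left
with zero links**: a species with no remaining association is not part of
the network. A single pruning pass suffices because pruning removes only
degree-zero vertices and cannot create new ones. A `prune = FALSE` flag
supports sensitivity analysis. Abundance-weighted extinction cascades are
an explicit extension point, not implemented.

## Statistical tests

ANOSIM, one-factor PERMANOVA (adonis) and MRPP are permutation tests with
`p = (1 + #(perm >= obs)) / (n_perm + 1)` (`<=` for the MRPP delta). The
MRPP chance-corrected `A` uses the permutation mean as its expectation.
Group contrasts follow the field's reporting rule: Shapiro–Wilk on both
groups, t-test when both pass (Student or Welch by an F-test on the
variances), Wilcoxon rank-sum otherwise, with the branch recorded.
Dominance is Simpson's concentration `sum p_i^2` — the usual "dominance"
of QIIME-style outputs; the exact definition used by any given upstream
toolchain is not standardized, so the index is documented rather than
assumed. PCoA drops negative eigenvalues from the variance-explained
denominator (no Lingoes correction). Trend correlation defaults to
Spearman with a Pearson switch and optional Benjamini–Hochberg adjustment
(off by default, matching the raw-P convention of the heatmaps this
reproduces).

## Synthetic community generator

`generate_counts()` states the world the tests assume: two groups, 14
monthly time points, 8 subjects per group-month, 200 ASVs of which 120 sit
in 12 planted blocks of 10. Latent log-abundances are multivariate normal
— baseline means `N(0, 1.5^2)` for a realistically uneven log-normal
community, exchangeable within-block correlation `rho_within = 0.9`, and
independent background — and counts are multinomial draws of `depth`
(default 10,000) reads from the softmax composition. The group-A effect at
month `m` is scaled by `w = 2^{-(m-1)/3}` (half-life 3 months, reflecting
gradual, incomplete recovery): 30% of ASVs depleted by 6 latent log-units,
the top 5% of taxa boosted `3^w`-fold, and block correlation reduced to
`rho_within * (1 - 0.7 w)`. Where the emulated design leaves a value
unstated (per-cell sample count, depth, latent scale) the default is a
single, fixed choice a practitioner would call realistic, and it is not
tuned against test outcomes.

What the generator does **not** emulate: read-level sequencing error and
chimeras, taxonomy, phylogenetic signal, overdispersion beyond the
log-normal latent, and non-exchangeable (e.g. hub-and-spoke) correlation
inside modules. A green recovery test therefore establishes that the
pipeline detects block-structured compositional signal of the stated
strength — not that it would detect every real ecological structure.

## Numerical and design choices

* Rarefaction and all stochastic stages restore the caller's RNG state;
  per-stage sub-seeds derive from the one pipeline seed, so any stage is
  independently reproducible and two runs with the same config are
  byte-identical.
* Pearson values are clamped to [-1, 1] before thresholding to absorb
  floating-point overshoot.
* MCODE follows the published molecular-complex-detection scheme: vertex
  weight = highest-core density x core level of the closed neighbourhood,
  greedy seeded expansion admitting vertices within `node_score_cutoff`
  (default 0.2) of the seed weight, then reduction of each cluster to its
  `k_core`-core (default 2), which subsumes the haircut; score = density x
  size. Pathway-network edge cutoffs default to `|r| >= 0.8`, `p < 0.05`
  and are recorded in the graph attributes because published functional
  networks rarely print them.
* The low-abundance filter keeps an ASV that passes in *any* stratum;
  the alternative reading (drop per stratum, analyze strata separately)
  is recovered by filtering after subsetting to one month.

## Known limitations

* Fast-greedy modularity can be a few hundredths below the exhaustive
  optimum on small graphs (the test suite bounds the gap at 0.05); module
  *counts* may differ slightly from annealing-based pipelines.
* The RMT scan needs on the order of 100 ASVs after prevalence filtering;
  small panels must use a fixed threshold.
* PERMANOVA is restricted to the one-factor design used here (no strata,
  no repeated-measure correction); with monthly repeated measures on the
  same subjects, p-values for whole-series contrasts are anti-conservative
  and should be read as descriptive.
* Bray–Curtis on unrarefied counts conflates depth with composition; the
  pipeline filters but does not force rarefaction — enable it when depths
  vary materially.
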