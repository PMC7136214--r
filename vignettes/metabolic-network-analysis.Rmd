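---
title: "Reporter metabolites and metabolic co-expression modules: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reporter metabolites and metabolic co-expression modules: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metrep)
```

## The problem

Tumors rewire metabolism, and the rewiring differs between histological
subtypes of the same cancer. Individual differentially expressed enzymes
are a noisy readout of that rewiring: a metabolite's production or
consumption is typically controlled by several enzymes, and coordinated
moderate shifts across an enzyme neighborhood are stronger evidence of
metabolic change than one large shift in isolation. `metrep` implements
two complementary ways of reading coordinated change off a genome-scale
metabolic model (GEM):

1. **Reporter metabolites and pathways** — integrate per-gene
   differential-expression evidence over each metabolite's enzyme
   neighborhood in the GEM, with an empirical background correction, then
   aggregate metabolite evidence into pathway evidence; and
2. **Signed co-expression modules** — group metabolic genes into modules by
   signed weighted correlation networks across all samples, summarize each
   module by an SVD eigengene, and relate modules to clinical traits
   (disease status, stage, survival time) and to GEM pathways.

The first arm asks *where in the network does expression shift between
matched tumor and normal samples*; the second asks *how does metabolic
expression covary across tumors and what does that covariation track
clinically*.

## The metabolic model layer

The GEM enters only through two derived maps. Each metabolite's
**neighborhood** is the union of the gene sets of all reactions in which it
participates; each **pathway** (reaction subsystem) owns the union of its
reactions' metabolites and genes. Gene-reaction associations are flattened
to plain gene sets — boolean AND/OR enzyme logic is never evaluated,
because neighborhood scoring only uses the union. Metabolite identity is
compartmented: the same chemical in cytosol (`_c`), mitochondria (`_m`) or
the extracellular space (`_s`) is a distinct network node, so compartment-
specific regulation stays visible. Currency metabolites (ATP, H2O, ...)
connect large swaths of the network and can be excluded through an optional
list; the default excludes nothing, keeping the statistic faithful to the
raw network.

## The reporter statistic

Given a per-gene p-value \(p_i\), the gene score is the upper-tail normal
quantile \(Z_i = \Phi^{-1}(1 - p_i)\), clamped to
\(p \in [10^{-15}, 1 - 10^{-15}]\) so that upstream tools reporting
\(p = 0\) give a large finite score. A metabolite with neighborhood size
\(k\) scores

\[ Z_\mathrm{met} = \frac{1}{\sqrt{k}} \sum_{i = 1}^{k} Z_i . \]

Under independent standard-normal gene scores this is again standard
normal for any \(k\); in real data gene scores are neither centered nor
independent, so the score is standardized empirically: draw `n_sets`
(default 100000) random gene sets of size \(k\) from the full scored pool
(without replacement within a set), score each like a neighborhood, and
form

\[ Z^\mathrm{corr}_\mathrm{met} = \frac{Z_\mathrm{met} - \mu_k}{\sigma_k}, \qquad
   p_\mathrm{met} = 1 - \Phi(Z^\mathrm{corr}_\mathrm{met}), \]

with \(\mu_k, \sigma_k\) the mean and population SD of the sampled scores.
Pathways aggregate the corrected metabolite scores the same way
(\(\sum Z^\mathrm{corr} / \sqrt{n}\) over the \(n\) scored member
metabolites) and are standardized against random *metabolite* sets of size
\(n\) drawn from the corrected-score pool. Directional runs restrict the
gene universe to positive (or negative) log2 fold changes — optionally also
requiring adjusted \(p \le \alpha\), default 0.05 — and rerun the entire
cascade, including the background draws, inside the restricted universe.

Choices worth knowing about:

* **Raw vs adjusted p-values for scoring.** The default scores genes by raw
  p-values: BH adjustment truncates and ties p-values, which distorts the
  inverse-normal transform. Scoring from adjusted p-values is available via
  `p_source = "adjusted"` for compatibility with workflows that integrate
  adjusted evidence.
* **Degenerate backgrounds.** If a requested set size equals the pool size
  there is exactly one subset and \(\sigma_k = 0\). At the metabolite level
  this is an error unless the raw score equals the null mean exactly (a
  completely flat score pool), in which case the corrected score is 0. At
  the pathway level a pathway spanning every scored metabolite keeps its
  raw aggregated score — it is already on the corrected-Z scale — because
  no background spread exists to standardize against. This matters for
  directional runs over small restricted universes.
* **Determinism and tie-breaks.** All background draws are driven by a
  user seed through fixed per-size substreams, so identical inputs and
  seed give bit-identical tables. Ranked output sorts by p-value, then
  |corrected Z| descending, then id.
* **No multiplicity correction of reporter p-values.** The reporter p-value
  is reported raw; the null is over random gene sets, not over sample
  labels, and ranking is the primary use.

## Expression preprocessing

Counts are normalized by **median-of-ratios** size factors: per-gene
geometric means over samples define ratios, and each sample's factor is
the median ratio over genes with nonzero counts in every sample. A paired
differential-expression stage — a two-sided paired t-test on
\(\log_2(\mathrm{normalized} + 1)\) across matched tumor/normal pairs,
BH-adjusted — is built in so the network statistics are runnable from raw
counts; externally produced DE tables (e.g. from a negative-binomial GLM)
are accepted anywhere and are the primary input path for real studies.
Genes whose paired differences have exactly zero variance get \(p = 1\).
The pseudocount (default 1) and the log base are deliberate, documented
constants rather than hidden choices.

For cross-sample structure, the matched-pair log2 fold-change matrix
(tumor minus normal per pair, after normalization) feeds a PCA of the
top-variance genes (default top 10%), centering genes but not rescaling
them — the variance filter already treats magnitude as meaningful.

## The co-expression arm

Pairwise Pearson correlations of metabolic-gene expression map to the
signed similarity \(S_{ij} = (1 + \mathrm{cor}(x_i, x_j))/2\): perfectly
anticorrelated genes get similarity 0, not 1, so modules never mix
opposing profiles. Adjacency is \(S_{ij}^\beta\); topological overlap

\[ \mathrm{TOM}_{ij} = \frac{\sum_u A_{iu}A_{uj} + A_{ij}}
   {\min(k_i, k_j) + 1 - A_{ij}} \]

rewards shared neighborhoods, and \(1 - \mathrm{TOM}\) is the distance for
average-linkage hierarchical clustering. Modules come from a **static cut**
at a fraction (default 0.99) of the maximum merge height, with clusters
below `min_size` (default 100; lower it for small gene sets) relabeled
`M0`. The hybrid dynamic tree-cut algorithm is deliberately not
re-implemented: for the block-structured recovery this package validates,
the static cut is sufficient and fully transparent; the cut height is
configurable. Module merging by eigengene similarity is likewise not
performed. Each module's **eigengene** is the first right singular vector
of the standardized member submatrix (unit norm, oriented so its mean
correlation with member profiles is positive). Eigengene-trait association
is plain Pearson correlation with the two-sided t-transform p-value;
survival is correlated as raw time, ignoring censoring — a documented
limitation, not an oversight. Pathway enrichment of modules is the
upper-tail hypergeometric test over the universe of model genes present in
the data.

### Choosing the power \(\beta\)

`pick_soft_threshold()` implements the scale-free topology criterion: for
each candidate power, connectivities \(k_i = \sum_j S_{ij}^\beta\) are
binned (10 equal-width bins; empty bins dropped), and
\(\log_{10}\) frequency is regressed on \(\log_{10}\) mean connectivity.
The signed fit index is \(-\mathrm{sign}(\mathrm{slope}) \cdot R^2\); the
smallest power reaching the cut (default 0.8) wins, otherwise the power
with the maximal index. Two caveats. First, equal-width binning is
essential — equal-count bins would make the frequency constant and the
regression meaningless. Second, the criterion presumes approximately
scale-free connectivity; data with a few equally sized, equally dense
modules (exactly what a block factor model produces) are *not* scale-free,
the index stays low for every power, and the fallback can land on an
uninformatively small power. For such data the analyses in this package
fix \(\beta = 12\), the conventional default for signed networks; the
criterion remains the right tool for genome-wide expression whose
connectivity is heavy-tailed.

## What the synthetic data does and does not show

The generators produce exactly the structure the statistics assume:

* `synth_model()` — pathway-blocked bipartite networks where each
  metabolite draws \(k \sim U(k_\min, k_\max)\) neighbors, preferentially
  (mixing fraction, default 0.1) from its own pathway's gene block;
* `synth_counts()` — negative-binomial matched-pair counts
  (variance \(\mu + \alpha\mu^2\), default dispersion \(\alpha = 0.1\),
  log-normal baselines and per-sample depths, sd 0.3 on the log scale)
  with chosen metabolite neighborhoods shifted by a planted log2 fold
  change (default 2, i.e. 4-fold), round-robin tumor stages, and
  exponential survival times whose rate increases with the planted
  up-signature — higher signature, shorter survival;
* `synth_coexpression()` — latent-factor expression (per-gene loadings
  near 1, noise sd 0.5, a 4:1 signal-to-noise variance ratio) with traits
  tied to designated factors: disease is a thresholded noisy factor copy,
  stage is a within-disease quartile code 0-4, survival is exponential in
  the designated aggressive factor.

All generators are pure functions of their parameters and a seed. Passing
the recovery tests shows the statistics do what they claim *under their
own assumptions* — coordinated neighborhoods, block pathway structure,
factor-driven modules. It does not show robustness to what real RNA-seq
adds: batch effects, GC and length bias, gene-gene correlation beyond the
planted factors, GPR logic, isoform effects, or censored survival. Those
belong to the upstream tools this package deliberately defers to.

## Problem sizes and runtime choices

The test and acceptance workloads use desk-scale versions of the study
design: models of 90-300 genes and 36-500 metabolites, 12-25 matched
pairs, 100000 background sets where calibration is measured (20000 where
only ranking matters), 200-gene/100-sample factor models, and exhaustive
oracles (subset enumeration, triple-loop TOM, hypergeometric tail sums,
longhand BH) wherever the instance is small enough to enumerate. These
sizes are the package's own choice of smallest-instance-that-exercises-
every-code-path; every quantity they produce is recomputed at run time by
`scripts/acceptance.R` and the analysis scripts, never stored.

## Known limitations

* Flat gene sets only; GPR boolean logic is out of scope.
* The paired t-test is a pragmatic built-in, not a replacement for a
  negative-binomial GLM at small counts; feed in external DE tables for
  real studies.
* Static-cut module detection under-splits nested or unevenly dense
  modules compared to hybrid dynamic tree cut.
* Survival correlation ignores censoring and treats time linearly.
* The scale-free criterion is uninformative on non-scale-free expression;
  inspect the fit profile (`pick_soft_threshold()$fits`) before trusting
  an automatic power.
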