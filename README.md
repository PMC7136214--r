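# metrep

Reporter metabolite and metabolic co-expression module analysis in R.

Tumors reprogram metabolism, and the reprogramming differs between
histological subtypes of the same cancer. `metrep` is for computational
biologists who want to read those shifts off a genome-scale metabolic
model (GEM) integrated with RNA-seq differential expression, the way
renal-cell-carcinoma subtypes (clear cell, papillary, chromophobe) have
been contrasted against matched tumor-adjacent normal tissue. It
implements two arms:

**Reporter metabolites and pathways.** Per-gene p-values become
inverse-normal scores Z_i = Φ⁻¹(1 − p_i). A metabolite whose enzyme
neighborhood in the GEM has k genes scores

    Z_met = (1/√k) Σ Z_i ,

standardized against 100000 random gene sets of size k drawn from the
scored pool:

    Z_met_corrected = (Z_met − μ_k) / σ_k ,   p = 1 − Φ(Z_met_corrected),

and pathways aggregate their n member metabolites' corrected scores the
same way (Σ Z_corrected / √n, with its own random-set standardization).
Directional runs rerun the full cascade on only up- or down-regulated
genes, so each pathway's direction of change is identified.

**Signed co-expression modules.** Metabolic-gene expression across all
samples enters a signed weighted network: similarity
S_ij = (1 + cor(x_i, x_j))/2, adjacency S_ij^β (β by the scale-free
topology criterion or fixed), topological overlap TOM, average-linkage
clustering on 1 − TOM with a minimum module size, SVD eigengenes,
Pearson correlation of eigengenes with disease/stage/survival traits,
and hypergeometric enrichment of GEM pathways in each module.

Everything runs end-to-end on built-in synthetic generators (planted
reporter metabolites, planted modules, planted trait effects), so each
claim the package makes is checkable against a known truth without any
download. See the methods vignette
(`vignettes/metabolic-network-analysis.Rmd`) for the model, parameter,
and design details.

## Worked example

Plant three up-regulated metabolites in a toy model, simulate matched
tumor/normal counts, and run the reporter cascade:

```r
library(metrep)
sm <- synth_model(n_genes = 120, n_metabolites = 40, n_pathways = 5,
                  k_range = c(3, 5), seed = 7)
planted <- data.frame(metabolite = names(sm$model$neighbor_map)[1:3],
                      direction = "up")
sc  <- synth_counts(sm$model, planted = planted, n_pairs = 20, seed = 8)
dge <- simple_paired_dge(sc$counts)
res <- reporter_analysis(sm$model, dge, n_sets = 1e5, seed = 9)
head(res$metabolites, 5)
#>   metabolite k z_raw z_corrected        p
#> 1    m0003_s 5 13.96        6.11 5.08e-10
#> 2    m0001_c 4 12.42        5.41 3.09e-08
#> 3    m0002_m 4 12.28        5.34 4.63e-08
#> 4    m0004_c 5  6.11        2.12 1.71e-02
#> 5    m0005_m 4  4.74        1.52 6.42e-02
head(res$pathways, 3)
#>   pathway n  z_raw      z        p direction
#> 1     P01 8  8.296  4.860 5.86e-07       all
#> 2     P05 8 -0.618 -0.600 7.26e-01       all
#> 3     P02 8 -0.670 -0.632 7.36e-01       all
```

The three planted metabolites (`m0001_c`, `m0002_m`, `m0003_s`) head the
ranking: their raw neighborhood scores (12-14) sit 5-6 background
standard deviations above random gene sets of the same size, giving
reporter p-values below 5e-8, while unplanted metabolites hover near the
null. Their pathway `P01` aggregates the corrected scores of its 8
scored metabolites into z = 4.86 (p ≈ 6e-7); the remaining pathways are
background. The `analysis/` scripts walk the same two arms (plus module
detection and trait correlation) as a narrated workflow, writing tables
under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_reporter.R
Rscript analysis/03_coexpression.R
```

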