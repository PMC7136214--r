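#!/usr/bin/env Rscript
# Step 1 — build the synthetic study.
#
# A real study of this kind starts from a genome-scale metabolic model and
# tumor/normal RNA-seq. Here we simulate both so every downstream claim can
# be checked against a known truth: a toy metabolic network whose pathways
# are gene blocks, matched-pair NB counts in which the enzyme neighborhoods
# of four chosen metabolites are shifted (two up, two down), and a separate
# factor-model expression set with four planted co-expression modules tied
# to disease, stage and survival traits.

suppressPackageStartupMessages(library(metrep))
seed <- 20260923L
out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sm <- synth_model(n_genes = 300, n_metabolites = 120, n_pathways = 8,
                  k_range = c(3, 6), mixing = 0.1, seed = seed)
write_model(sm$model, file.path(out, "model.json"))
message(sprintf("model: %d genes, %d metabolites, %d pathways",
                length(sm$model$genes), nrow(sm$model$metabolites),
                length(sm$model$pathway_map)))

mets <- names(sm$model$neighbor_map)
by_pw <- split(mets, sm$truth$metabolite_pathway[mets])
planted <- rbind(
  data.frame(metabolite = by_pw[["P01"]][1:4], direction = "up"),
  data.frame(metabolite = by_pw[["P02"]][1:4], direction = "down"))
sc <- synth_counts(sm$model, planted = planted, n_pairs = 25,
                   nb_dispersion = 0.1, effect_log2fc = 2, seed = seed + 1L)
write_counts(sc$counts, file.path(out, "counts.tsv"),
             file.path(out, "meta.tsv"))
write.table(planted, file.path(out, "planted_metabolites.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(sc$truth$planted_genes, file.path(out, "planted_genes.txt"))
message(sprintf("counts: %d genes x %d samples (%d matched pairs), %d planted genes",
                nrow(sc$counts$counts), ncol(sc$counts$counts), 25,
                length(sc$truth$planted_genes)))

sx <- synth_coexpression(n_modules = 4, genes_per_module = 50,
                         n_samples = 100, noise_sd = 0.5, seed = seed + 2L)
write.table(data.frame(gene = rownames(sx$expr), sx$expr,
                       check.names = FALSE),
            file.path(out, "coexpr_expression.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sx$traits, file.path(out, "coexpr_traits.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(gene = names(sx$truth$module_of),
                       module = unname(sx$truth$module_of)),
            file.path(out, "coexpr_truth_modules.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("co-expression set: 200 genes x 100 samples, 4 planted modules")
message("wrote ", out)
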