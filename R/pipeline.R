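#' Assemble and validate a run configuration
#'
#' One configuration drives both analysis arms. Defaults match the study
#' conditions of the method: 100000 random sets for the background, minimum
#' module size 100, adjusted p <= 0.05 for the directional gene selection.
#'
#' @param model path to the model JSON (or a \code{MetabolicModel}).
#' @param counts,meta paths to a counts TSV and a metadata TSV (or a
#'   \code{CountMatrix} as \code{counts} with \code{meta = NULL}).
#' @param dge path to a differential-expression TSV (or a \code{DgeTable});
#'   overrides the built-in paired test when given.
#' @param out_dir output directory for report bundles.
#' @param n_sets background random sets; default 100000.
#' @param seed top-level integer seed; each stage derives a named substream.
#' @param alpha adjusted-p cutoff for directional gene selection; default
#'   0.05.
#' @param p_source "raw" or "adjusted" gene p-values for scoring.
#' @param pathway_background standardize pathway scores against random
#'   metabolite sets; default TRUE.
#' @param exclude_metabolites optional currency-metabolite exclusion list.
#' @param min_size minimum module size; default 100.
#' @param beta "auto" (scale-free criterion) or a fixed power.
#' @param beta_grid candidate powers for the criterion; default 1:20.
#' @param r2_cut signed R-squared threshold; default 0.8.
#' @param cut_height dendrogram cut as a fraction of the maximum merge
#'   height; default 0.99.
#' @return A validated \code{RunConfig} list.
#' @export
run_config <- function(model, counts = NULL, meta = NULL, dge = NULL,
                       out_dir = tempfile("metrep_run_"),
                       n_sets = 1e5, seed = 1, alpha = 0.05,
                       p_source = "raw", pathway_background = TRUE,
                       exclude_metabolites = character(),
                       min_size = 100, beta = "auto", beta_grid = 1:20,
                       r2_cut = 0.8, cut_height = 0.99) {
  if (is.character(model) && !file.exists(model)) {
    stop(sprintf("model file not found: %s", model))
  }
  for (nm in c("counts", "meta", "dge")) {
    v <- get(nm)
    if (is.character(v) && !file.exists(v)) {
      stop(sprintf("%s file not found: %s", nm, v))
    }
  }
  if (is.null(dge) && is.null(counts)) {
    stop("configuration needs either a DGE table or a count matrix")
  }
  structure(list(model = model, counts = counts, meta = meta, dge = dge,
                 out_dir = out_dir, n_sets = n_sets, seed = as.integer(seed),
                 alpha = alpha, p_source = p_source,
                 pathway_background = pathway_background,
                 exclude_metabolites = exclude_metabolites,
                 min_size = min_size, beta = beta, beta_grid = beta_grid,
                 r2_cut = r2_cut, cut_height = cut_height),
            class = "RunConfig")
}

resolve_model <- function(config) {
  if (inherits(config$model, "MetabolicModel")) return(config$model)
  load_model(config$model, exclude_metabolites = config$exclude_metabolites)
}

resolve_counts <- function(config) {
  if (is.null(config$counts)) return(NULL)
  if (inherits(config$counts, "CountMatrix")) return(config$counts)
  read_counts(config$counts, config$meta)
}

resolve_dge <- function(config) {
  if (!is.null(config$dge)) {
    if (inherits(config$dge, "DgeTable")) return(config$dge)
    return(read_dge(config$dge))
  }
  simple_paired_dge(resolve_counts(config))
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_manifest <- function(out_dir, config, stage, files, extra = list()) {
  manifest <- c(list(
    package = "metrep",
    version = as.character(utils::packageVersion("metrep")),
    stage = stage,
    seed = config$seed,
    n_sets = config$n_sets,
    parameters = list(alpha = config$alpha, p_source = config$p_source,
                      pathway_background = config$pathway_background,
                      min_size = config$min_size, beta = config$beta,
                      r2_cut = config$r2_cut, cut_height = config$cut_height),
    outputs = as.list(stats::setNames(unname(tools::md5sum(files)),
                                      basename(files)))
  ), extra)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Run the reporter arm end-to-end
#'
#' Loads the model and expression evidence, runs the undirected reporter
#' cascade plus the up- and down-restricted runs, and writes the report
#' bundle: \code{reporter_metabolites.tsv}, one
#' \code{reporter_pathways_<direction>.tsv} per direction,
#' \code{background_cache.json}, \code{excluded.tsv} and a
#' \code{manifest.json} with parameters, the seed and output checksums.
#' Rerunning with an identical configuration reproduces the bundle
#' byte-for-byte.
#'
#' @param config a \code{RunConfig} from \code{\link{run_config}}.
#' @return Invisibly, a list with the in-memory results per direction and
#'   the bundle file paths.
#' @export
run_reporter <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  model <- resolve_model(config)
  dge <- resolve_dge(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  results <- list()
  files <- character()
  excluded <- list()
  for (dir_tag in c("all", "up", "down")) {
    res <- tryCatch(
      reporter_analysis(model, dge, direction = dir_tag,
                        alpha = if (dir_tag == "all") NULL else config$alpha,
                        n_sets = config$n_sets, seed = config$seed,
                        p_source = config$p_source,
                        pathway_background = config$pathway_background),
      error = function(e) stop(sprintf("reporter stage '%s': %s", dir_tag,
                                       conditionMessage(e)), call. = FALSE))
    results[[dir_tag]] <- res
    if (dir_tag == "all") {
      files <- c(files, write_tsv(res$metabolites,
                                  file.path(config$out_dir,
                                            "reporter_metabolites.tsv")))
    }
    files <- c(files, write_tsv(
      res$pathways,
      file.path(config$out_dir,
                sprintf("reporter_pathways_%s.tsv", dir_tag))))
    ex <- attr(res$pathways, "excluded")
    if (!is.null(ex) && nrow(ex)) {
      ex$direction <- dir_tag
      excluded[[dir_tag]] <- ex
    }
  }
  bg <- attr(results$all$metabolites, "background")
  bg_path <- file.path(config$out_dir, "background_cache.json")
  jsonlite::write_json(bg, bg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, bg_path)
  ex_tab <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(type = character(), id = character(), reason = character(),
               direction = character())
  files <- c(files, write_tsv(ex_tab, file.path(config$out_dir,
                                                "excluded.tsv")))
  manifest <- write_manifest(config$out_dir, config, "reporter", files)
  invisible(list(results = results, files = c(files, manifest)))
}

#' Run the co-expression arm end-to-end
#'
#' Builds the expression matrix (log2 of median-of-ratios-normalized counts
#' plus one) restricted to model genes present in the data, then runs the
#' signed-network cascade: similarity, soft-threshold selection, adjacency,
#' topological overlap, module detection, SVD eigengenes, module-trait
#' correlation and hypergeometric pathway enrichment. Writes
#' \code{modules.tsv}, \code{eigengenes.tsv}, \code{module_traits.tsv},
#' \code{module_pathways.tsv} and a \code{manifest.json} recording the
#' chosen power and its fit profile.
#'
#' @param config a \code{RunConfig} with counts and metadata.
#' @return Invisibly, a list with the network, module labels, eigengenes,
#'   trait correlations, enrichment table and bundle paths.
#' @export
run_coexpression <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  model <- resolve_model(config)
  counts <- resolve_counts(config)
  if (is.null(counts)) stop("co-expression stage needs a count matrix")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  expr <- log2(normalize_counts(counts) + 1)
  shared <- intersect(rownames(expr), model$genes)
  if (length(shared) < 2L) stop("fewer than 2 model genes in the data")
  expr <- expr[shared, , drop = FALSE]

  S <- signed_similarity(expr)
  expr <- expr[rownames(S), , drop = FALSE]   # constant genes dropped
  if (identical(config$beta, "auto")) {
    pick <- pick_soft_threshold(S, candidates = config$beta_grid,
                                r2_cut = config$r2_cut)
    beta <- pick$beta
    fits <- pick$fits
  } else {
    beta <- config$beta
    fits <- NULL
  }
  A <- adjacency_matrix(S, beta)
  tom <- topological_overlap(A)
  modules <- detect_modules(tom, min_size = config$min_size,
                            cut_height = config$cut_height)
  me <- module_eigengenes(expr, modules)

  meta <- counts$meta
  traits <- data.frame(sample_id = meta$sample_id,
                       disease = as.integer(meta$condition == "tumor"),
                       stringsAsFactors = FALSE)
  if (!is.null(meta$stage)) traits$stage <- meta$stage
  if (!is.null(meta$survival_days)) traits$survival_days <- meta$survival_days
  mt <- module_trait_correlation(me, traits)
  enr <- module_pathway_enrichment(modules, model)

  files <- c(
    write_tsv(data.frame(gene = names(modules), module = unname(modules)),
              file.path(config$out_dir, "modules.tsv")),
    write_tsv(data.frame(module = rownames(me), me, check.names = FALSE),
              file.path(config$out_dir, "eigengenes.tsv")),
    write_tsv(mt, file.path(config$out_dir, "module_traits.tsv")),
    write_tsv(enr, file.path(config$out_dir, "module_pathways.tsv")))
  manifest <- write_manifest(
    config$out_dir, config, "coexpression", files,
    extra = list(beta = beta,
                 beta_fits = if (is.null(fits)) NULL else
                   as.list(stats::setNames(fits$signed_r2, fits$beta))))
  invisible(list(beta = beta, similarity = S, tom = tom, modules = modules,
                 eigengenes = me, module_traits = mt, enrichment = enr,
                 files = c(files, manifest)))
}
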