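#' Construct a genome-scale metabolic model object
#'
#' Builds the bipartite gene-metabolite view of a metabolic network that the
#' reporter statistics consume: for every metabolite, the set of genes whose
#' reactions it participates in (its enzyme neighborhood), and for every
#' pathway (subsystem), the metabolites and genes of its reactions.
#'
#' Metabolite identity is the compartmented id: the same chemical species in
#' cytosol and mitochondria is two distinct network nodes. Gene-reaction
#' associations are flat gene sets; no boolean (AND/OR) gene-protein-reaction
#' logic is evaluated, because neighborhood scoring only needs the union of
#' genes attached to each metabolite's reactions.
#'
#' @param genes character vector of gene ids known to the model.
#' @param metabolites data.frame with columns \code{id} (unique compartmented
#'   metabolite id) and \code{compartment} (single-token compartment code,
#'   e.g. \code{c}, \code{m}, \code{s}).
#' @param reactions list of reaction records; each a list with elements
#'   \code{id}, \code{genes} (character, possibly empty), \code{metabolites}
#'   (character, metabolite ids), \code{pathway} (single label).
#' @param exclude_metabolites optional character vector of metabolite ids
#'   (e.g. currency metabolites such as ATP or H2O) removed from the network
#'   before neighborhoods are derived. Default: none.
#'
#' @return An object of class \code{MetabolicModel}: a list with the inputs
#'   plus derived \code{neighbor_map} (metabolite id -> character vector of
#'   gene ids), \code{pathway_map} (pathway label -> metabolite ids) and
#'   \code{pathway_genes} (pathway label -> gene ids).
#' @export
metabolic_model <- function(genes, metabolites, reactions,
                            exclude_metabolites = character()) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("duplicated gene ids in model")
  if (!is.data.frame(metabolites) ||
      !all(c("id", "compartment") %in% names(metabolites))) {
    stop("metabolites must be a data.frame with columns 'id' and 'compartment'")
  }
  metabolites$id <- as.character(metabolites$id)
  metabolites$compartment <- as.character(metabolites$compartment)
  if (anyDuplicated(metabolites$id)) stop("duplicated metabolite ids in model")
  if (any(grepl("\\s", metabolites$compartment))) {
    stop("compartment codes must be single tokens")
  }

  met_ids <- metabolites$id
  for (r in reactions) {
    if (is.null(r$id)) stop("reaction without an id")
    bad_g <- setdiff(as.character(r$genes), genes)
    if (length(bad_g)) {
      stop(sprintf("reaction '%s' references undeclared gene(s): %s",
                   r$id, paste(bad_g, collapse = ", ")))
    }
    bad_m <- setdiff(as.character(r$metabolites), met_ids)
    if (length(bad_m)) {
      stop(sprintf("reaction '%s' references undeclared metabolite(s): %s",
                   r$id, paste(bad_m, collapse = ", ")))
    }
  }

  keep <- !(met_ids %in% exclude_metabolites)
  metabolites <- metabolites[keep, , drop = FALSE]
  met_ids <- metabolites$id

  neighbor_map <- new.env(parent = emptyenv())
  pathway_map <- list()
  pathway_genes <- list()
  for (r in reactions) {
    rg <- as.character(r$genes)
    rm <- intersect(as.character(r$metabolites), met_ids)
    for (m in rm) {
      neighbor_map[[m]] <- union(get0(m, envir = neighbor_map,
                                      ifnotfound = character()), rg)
    }
    pw <- as.character(r$pathway)
    if (length(pw) == 1L && nzchar(pw)) {
      pathway_map[[pw]] <- union(pathway_map[[pw]], rm)
      pathway_genes[[pw]] <- union(pathway_genes[[pw]], rg)
    }
  }
  nm <- as.list(neighbor_map)
  nm <- lapply(nm, function(g) sort(g))
  nm <- nm[vapply(nm, length, 1L) > 0L]   # gene-less reactions add no edges
  nm <- nm[order(names(nm))]
  pathway_map <- lapply(pathway_map, sort)[order(names(pathway_map))]
  pathway_genes <- lapply(pathway_genes, sort)[order(names(pathway_genes))]

  structure(
    list(genes = sort(genes),
         metabolites = metabolites,
         reactions = reactions,
         neighbor_map = nm,
         pathway_map = pathway_map,
         pathway_genes = pathway_genes),
    class = "MetabolicModel"
  )
}

#' Load a metabolic model from its JSON representation
#'
#' Canonical on-disk form: a JSON object with keys \code{genes} (array of
#' strings), \code{metabolites} (array of \code{{"id","compartment"}}) and
#' \code{reactions} (array of \code{{"id","genes","metabolites","pathway"}}).
#'
#' @param path path to the JSON file.
#' @inheritParams metabolic_model
#' @return A validated \code{MetabolicModel}.
#' @export
load_model <- function(path, exclude_metabolites = character()) {
  if (!file.exists(path)) stop(sprintf("model file not found: %s", path))
  obj <- tryCatch(
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE, simplifyVector = TRUE),
    error = function(e) stop(sprintf("cannot parse model file '%s': %s",
                                     path, conditionMessage(e)))
  )
  for (key in c("genes", "metabolites", "reactions")) {
    if (is.null(obj[[key]])) {
      stop(sprintf("model file '%s' lacks top-level key '%s'", path, key))
    }
  }
  rx <- obj$reactions
  if (is.data.frame(rx)) {
    reactions <- lapply(seq_len(nrow(rx)), function(i) {
      list(id = rx$id[i],
           genes = unlist(rx$genes[i], use.names = FALSE),
           metabolites = unlist(rx$metabolites[i], use.names = FALSE),
           pathway = rx$pathway[i])
    })
  } else {
    reactions <- rx
  }
  mets <- obj$metabolites
  if (!is.data.frame(mets)) mets <- do.call(rbind.data.frame, mets)
  metabolic_model(obj$genes, mets, reactions,
                  exclude_metabolites = exclude_metabolites)
}

#' Read a metabolic model from a reaction table (TSV)
#'
#' Hand-editable alternative to the JSON form: one row per reaction with
#' columns \code{reaction}, \code{genes}, \code{metabolites}, \code{pathway};
#' gene and metabolite lists are semicolon-joined. Compartment codes are the
#' suffix after the final underscore of each metabolite id (e.g.
#' \code{akg_m} is in compartment \code{m}).
#'
#' @param path path to the TSV file.
#' @inheritParams metabolic_model
#' @return A validated \code{MetabolicModel}.
#' @export
read_reaction_table <- function(path, exclude_metabolites = character()) {
  if (!file.exists(path)) stop(sprintf("reaction table not found: %s", path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("reaction", "genes", "metabolites", "pathway")
  if (!all(need %in% names(tab))) {
    stop(sprintf("reaction table must have columns: %s",
                 paste(need, collapse = ", ")))
  }
  split_field <- function(x) {
    v <- strsplit(x, ";", fixed = TRUE)[[1]]
    v <- trimws(v)
    v[nzchar(v)]
  }
  reactions <- lapply(seq_len(nrow(tab)), function(i) {
    list(id = tab$reaction[i],
         genes = split_field(tab$genes[i]),
         metabolites = split_field(tab$metabolites[i]),
         pathway = tab$pathway[i])
  })
  genes <- sort(unique(unlist(lapply(reactions, `[[`, "genes"))))
  met_ids <- sort(unique(unlist(lapply(reactions, `[[`, "metabolites"))))
  comp <- sub("^.*_", "", met_ids)
  comp[comp == met_ids] <- "c"
  mets <- data.frame(id = met_ids, compartment = comp,
                     stringsAsFactors = FALSE)
  metabolic_model(genes, mets, reactions,
                  exclude_metabolites = exclude_metabolites)
}

#' Write a metabolic model to its canonical JSON form
#'
#' @param model a \code{MetabolicModel}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "MetabolicModel"))
  obj <- list(
    genes = model$genes,
    metabolites = model$metabolites,
    reactions = lapply(model$reactions, function(r) {
      list(id = r$id, genes = as.character(r$genes),
           metabolites = as.character(r$metabolites),
           pathway = as.character(r$pathway))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Restrict a metabolic model to a gene universe
#'
#' Intersects every metabolite's enzyme neighborhood with \code{universe};
#' metabolites whose neighborhood becomes empty are dropped from the
#' neighborhood and pathway maps. Used to align the model with the measured
#' genes, and for directional runs that keep only up- or down-regulated
#' genes. The input model is not modified.
#'
#' @param model a \code{MetabolicModel}.
#' @param universe non-empty character vector of gene ids to keep.
#' @return A new \code{MetabolicModel} restricted to \code{universe}.
#' @export
restrict_to_genes <- function(model, universe) {
  stopifnot(inherits(model, "MetabolicModel"))
  universe <- as.character(universe)
  if (length(universe) == 0L) stop("gene universe must be non-empty")
  nm <- lapply(model$neighbor_map, intersect, y = universe)
  nm <- nm[vapply(nm, length, 1L) > 0L]
  kept_mets <- names(nm)
  pm <- lapply(model$pathway_map, intersect, y = kept_mets)
  pm <- pm[vapply(pm, length, 1L) > 0L]
  pg <- lapply(model$pathway_genes, intersect, y = universe)
  pg <- pg[vapply(pg, length, 1L) > 0L]
  out <- model
  out$genes <- intersect(model$genes, universe)
  out$metabolites <- model$metabolites[model$metabolites$id %in% kept_mets, ,
                                       drop = FALSE]
  out$neighbor_map <- nm
  out$pathway_map <- pm
  out$pathway_genes <- pg
  out
}

#' @export
print.MetabolicModel <- function(x, ...) {
  cat(sprintf(
    "MetabolicModel: %d genes, %d metabolites, %d reactions, %d pathways\n",
    length(x$genes), nrow(x$metabolites), length(x$reactions),
    length(x$pathway_map)))
  k <- vapply(x$neighbor_map, length, 1L)
  if (length(k)) {
    cat(sprintf("  neighborhood size k: min %d, median %g, max %d\n",
                min(k), stats::median(k), max(k)))
  }
  invisible(x)
}
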