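#' Inverse-normal transform of p-values to Z-scores
#'
#' Maps a p-value to the upper-tail standard-normal quantile,
#' \code{Z = qnorm(1 - p)}. Small p-values give large positive Z. P-values
#' are clamped to \code{[1e-15, 1 - 1e-15]} so that p = 0 (common in the
#' output of upstream differential-expression tools) yields a large finite
#' score rather than infinity.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Numeric vector of Z-scores, strictly decreasing in p.
#' @export
p_to_z <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  stats::qnorm(1 - p)
}

#' Build a gene score table from a differential-expression table
#'
#' @param dge a \code{DgeTable} (see \code{\link{simple_paired_dge}},
#'   \code{\link{read_dge}}).
#' @param p_source which p-value feeds the inverse-normal transform:
#'   \code{"raw"} (default; the aggregation's normal theory assumes
#'   untruncated p-values) or \code{"adjusted"} (BH-adjusted).
#' @return data.frame with columns \code{gene}, \code{p}, \code{z}.
#' @export
gene_scores <- function(dge, p_source = c("raw", "adjusted")) {
  p_source <- match.arg(p_source)
  p <- if (p_source == "raw") dge$pvalue else dge$padj
  data.frame(gene = dge$gene, p = p, z = p_to_z(p),
             stringsAsFactors = FALSE)
}

#' Raw reporter score of one metabolite
#'
#' Aggregates the Z-scores of the k genes in a metabolite's enzyme
#' neighborhood: \code{Z = sum(Z_i) / sqrt(k)}. Under independent
#' standard-normal gene scores this preserves the N(0,1) scale for any k.
#'
#' @param z named numeric vector of gene Z-scores.
#' @param neighbors non-empty character vector of gene ids, all present in
#'   \code{names(z)}.
#' @return The raw metabolite Z-score.
#' @export
metabolite_raw_score <- function(z, neighbors) {
  if (length(neighbors) == 0L) stop("empty neighborhood")
  missing <- setdiff(neighbors, names(z))
  if (length(missing)) {
    stop(sprintf("neighbor gene(s) without scores: %s",
                 paste(missing, collapse = ", ")))
  }
  sum(z[neighbors]) / sqrt(length(neighbors))
}

sample_set_scores <- function(pool, k, n_sets) {
  n <- length(pool)
  if (k == n) return(rep(sum(pool) / sqrt(k), n_sets))
  idx <- vapply(seq_len(n_sets), function(i) sample.int(n, k),
                integer(k))
  if (k == 1L) {
    pool[idx] / sqrt(k)
  } else {
    colSums(matrix(pool[idx], nrow = k)) / sqrt(k)
  }
}

#' Background distribution of the reporter score for neighborhood size k
#'
#' Draws \code{n_sets} random gene sets of size k (without replacement
#' within a set, independently across sets) from the full pool of gene
#' Z-scores, scores each set like a metabolite neighborhood, and returns the
#' mean and population standard deviation of those scores. These are the
#' null parameters used to standardize raw metabolite scores, removing the
#' dependence of the score distribution on k and on the overall shift of
#' the gene-score pool.
#'
#' @param pool numeric vector of all gene Z-scores in the analysis universe.
#' @param k neighborhood size, 1 <= k <= length(pool).
#' @param n_sets number of random sets; default 100000.
#' @param seed integer seed making the draw reproducible.
#' @return List with \code{mu}, \code{sigma} (population SD), \code{k},
#'   \code{n_sets}, \code{seed}.
#' @export
background_stats <- function(pool, k, n_sets = 1e5, seed = 1) {
  n <- length(pool)
  if (k > n) stop(sprintf("k = %d exceeds pool size %d", k, n))
  if (n_sets < 1) stop("n_sets must be >= 1")
  set.seed(seed)
  s <- sample_set_scores(pool, k, n_sets)
  mu <- mean(s)
  sigma <- sqrt(mean((s - mu)^2))
  list(mu = mu, sigma = sigma, k = as.integer(k),
       n_sets = as.integer(n_sets), seed = as.integer(seed))
}

#' Background table for a set of neighborhood sizes
#'
#' @inheritParams background_stats
#' @param ks integer vector of distinct neighborhood sizes.
#' @return data.frame with columns \code{k}, \code{mu}, \code{sigma},
#'   \code{n_sets}, \code{seed}; one row per distinct k. Each k uses a seed
#'   derived deterministically from \code{seed} so the table does not depend
#'   on which other sizes are requested.
#' @export
background_table <- function(pool, ks, n_sets = 1e5, seed = 1) {
  ks <- sort(unique(as.integer(ks)))
  rows <- lapply(ks, function(k) {
    sk <- k_substream_seed(seed, k)
    bg <- background_stats(pool, k, n_sets = n_sets, seed = sk)
    data.frame(k = k, mu = bg$mu, sigma = bg$sigma,
               n_sets = as.integer(n_sets), seed = sk)
  })
  do.call(rbind, rows)
}

# deterministic per-k substream seed, kept inside 32-bit integer range
k_substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 10007 + as.numeric(k) * 7919) %%
               .Machine$integer.max)
}

#' Background-corrected reporter metabolite scores
#'
#' For every metabolite in the model (restricted to the scored genes), the
#' raw neighborhood score is standardized against the random-gene-set
#' background of matching size k: \code{Z_corrected = (Z_raw - mu_k) /
#' sigma_k}, and the reporter p-value is the upper normal tail
#' \code{1 - pnorm(Z_corrected)}. Output is sorted by p-value (ties broken
#' by |corrected Z| descending, then metabolite id).
#'
#' @param model a \code{MetabolicModel}.
#' @param scores gene score table from \code{\link{gene_scores}} (columns
#'   \code{gene}, \code{z}).
#' @param n_sets random sets per neighborhood size; default 100000.
#' @param seed integer seed for the background draws.
#' @return A \code{ReporterTable}: data.frame with columns
#'   \code{metabolite}, \code{k}, \code{z_raw}, \code{z_corrected},
#'   \code{p}. The background table used is attached as attribute
#'   \code{"background"}.
#' @export
corrected_scores <- function(model, scores, n_sets = 1e5, seed = 1) {
  stopifnot(inherits(model, "MetabolicModel"))
  model <- restrict_to_genes(model, scores$gene)
  if (length(model$neighbor_map) == 0L) {
    stop("no metabolite has a scored neighbor gene")
  }
  z <- stats::setNames(scores$z, scores$gene)[model$genes]
  nm <- model$neighbor_map
  kvec <- vapply(nm, length, 1L)
  zraw <- vapply(nm, function(g) sum(z[g]) / sqrt(length(g)), numeric(1))
  bg <- background_table(z, unique(kvec), n_sets = n_sets, seed = seed)
  i <- match(kvec, bg$k)
  num <- zraw - bg$mu[i]
  sig <- bg$sigma[i]
  # zero background spread: a score exactly at the null mean is null (0);
  # any other score cannot be standardized
  if (any(sig == 0 & abs(num) > 1e-12)) {
    stop(sprintf("degenerate background (sigma = 0) for k = %s",
                 paste(unique(kvec[sig == 0 & abs(num) > 1e-12]),
                       collapse = ", ")))
  }
  zc <- ifelse(sig == 0, 0, num / sig)
  p <- stats::pnorm(zc, lower.tail = FALSE)
  out <- data.frame(metabolite = names(nm), k = kvec, z_raw = zraw,
                    z_corrected = zc, p = p,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$p, -abs(out$z_corrected), out$metabolite), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "background") <- bg
  class(out) <- c("ReporterTable", "data.frame")
  out
}

#' Reporter pathway scores from corrected metabolite scores
#'
#' A pathway with n scored member metabolites gets
#' \code{Z_pathway = sum(Z_corrected) / sqrt(n)}. By default the pathway
#' score is itself standardized against random metabolite sets of size n
#' drawn from the pool of corrected metabolite scores (the same background
#' machinery used at the gene level), and the pathway p-value is the upper
#' normal tail of the standardized score. With \code{background = FALSE}
#' the raw pathway score is converted directly, relying on corrected
#' metabolite scores being approximately standard normal under the null.
#' Pathways with no scored metabolite are excluded and recorded in the
#' \code{"excluded"} attribute.
#'
#' @param reporters a \code{ReporterTable} from \code{\link{corrected_scores}}.
#' @param model the \code{MetabolicModel} supplying pathway membership.
#' @param n_sets random sets per pathway size; default 100000.
#' @param seed integer seed.
#' @param background standardize against random metabolite sets (default
#'   TRUE).
#' @param direction tag recorded in the output ("all", "up" or "down").
#' @return A \code{PathwayTable}: data.frame with columns \code{pathway},
#'   \code{n}, \code{z_raw}, \code{z}, \code{p}, \code{direction}, sorted by
#'   p with deterministic tie-breaks.
#' @export
pathway_scores <- function(reporters, model, n_sets = 1e5, seed = 1,
                           background = TRUE, direction = "all") {
  stopifnot(inherits(model, "MetabolicModel"))
  pool <- stats::setNames(reporters$z_corrected, reporters$metabolite)
  members <- lapply(model$pathway_map, intersect, y = names(pool))
  n_mem <- vapply(members, length, 1L)
  empty_pw <- names(members)[n_mem == 0L]
  excluded <- data.frame(type = rep("pathway", length(empty_pw)),
                         id = empty_pw,
                         reason = rep("no_scored_metabolite", length(empty_pw)),
                         stringsAsFactors = FALSE)
  members <- members[n_mem > 0L]
  if (length(members) == 0L) stop("no pathway has a scored metabolite")
  nvec <- vapply(members, length, 1L)
  zraw <- vapply(members, function(m) sum(pool[m]) / sqrt(length(m)),
                 numeric(1))
  if (background) {
    # a pathway spanning every scored metabolite admits a single subset:
    # there is no background spread to correct against, so its raw score
    # (already on the corrected-Z scale) is used directly
    correctable <- unique(nvec[nvec < length(pool)])
    zc <- zraw
    if (length(correctable)) {
      bg <- background_table(pool, correctable, n_sets = n_sets, seed = seed)
      if (any(bg$sigma == 0)) {
        stop(sprintf(
          "degenerate pathway background (sigma = 0) for n = %s",
          paste(bg$k[bg$sigma == 0], collapse = ", ")))
      }
      i <- match(nvec, bg$k)
      ok <- !is.na(i)
      zc[ok] <- (zraw[ok] - bg$mu[i[ok]]) / bg$sigma[i[ok]]
    }
  } else {
    zc <- zraw
  }
  p <- stats::pnorm(zc, lower.tail = FALSE)
  out <- data.frame(pathway = names(members), n = nvec, z_raw = zraw,
                    z = zc, p = p, direction = direction,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$p, -abs(out$z), out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  class(out) <- c("PathwayTable", "data.frame")
  out
}

#' Full reporter analysis: metabolites and pathways in one call
#'
#' Runs the complete cascade — inverse-normal gene scores, neighborhood
#' aggregation, background correction, pathway aggregation — for one
#' direction. With \code{direction = "up"} (\code{"down"}) the gene universe
#' is first restricted to genes with positive (negative) log2 fold change
#' (optionally also requiring adjusted p below \code{alpha}), the model is
#' restricted accordingly, and the background pools are drawn from the
#' restricted universe, so directional runs are self-contained reruns of the
#' whole statistic.
#'
#' @param model a \code{MetabolicModel}.
#' @param dge a \code{DgeTable}.
#' @param direction "all" (default), "up" or "down".
#' @param alpha optional adjusted-p cutoff applied to the directional gene
#'   selection (default NULL: select by fold-change sign only).
#' @param n_sets,seed background sampling parameters.
#' @param p_source "raw" (default) or "adjusted": which p-value feeds the
#'   inverse-normal gene scores.
#' @param pathway_background standardize pathway scores against random
#'   metabolite sets (default TRUE).
#' @return List with elements \code{metabolites} (a \code{ReporterTable}),
#'   \code{pathways} (a \code{PathwayTable}) and \code{universe} (the gene
#'   ids used).
#' @export
reporter_analysis <- function(model, dge, direction = c("all", "up", "down"),
                              alpha = NULL, n_sets = 1e5, seed = 1,
                              p_source = c("raw", "adjusted"),
                              pathway_background = TRUE) {
  direction <- match.arg(direction)
  p_source <- match.arg(p_source)
  keep <- rep(TRUE, nrow(dge))
  if (direction == "up") keep <- dge$log2fc > 0
  if (direction == "down") keep <- dge$log2fc < 0
  if (!is.null(alpha) && direction != "all") keep <- keep & dge$padj <= alpha
  if (!any(keep)) {
    stop(sprintf("empty gene universe for direction '%s'", direction))
  }
  sub <- dge[keep, , drop = FALSE]
  scores <- gene_scores(sub, p_source = p_source)
  restricted <- restrict_to_genes(model, scores$gene)
  mets <- corrected_scores(restricted, scores, n_sets = n_sets, seed = seed)
  pws <- pathway_scores(mets, restricted, n_sets = n_sets,
                        seed = k_substream_seed(seed, 999983L),
                        background = pathway_background,
                        direction = direction)
  list(metabolites = mets, pathways = pws, universe = scores$gene)
}

#' Directional reporter pathway analysis
#'
#' Convenience wrapper around \code{\link{reporter_analysis}} for up- or
#' down-restricted runs; returns the pathway table tagged with the
#' direction.
#'
#' @inheritParams reporter_analysis
#' @param direction "up" or "down".
#' @return A \code{PathwayTable}.
#' @export
directional_analysis <- function(dge, model, direction = c("up", "down"),
                                 alpha = NULL, n_sets = 1e5, seed = 1,
                                 p_source = c("raw", "adjusted"),
                                 pathway_background = TRUE) {
  direction <- match.arg(direction)
  reporter_analysis(model, dge, direction = direction, alpha = alpha,
                    n_sets = n_sets, seed = seed, p_source = p_source,
                    pathway_background = pathway_background)$pathways
}
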