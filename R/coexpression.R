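#' Signed co-expression similarity
#'
#' Maps Pearson correlations between gene expression profiles into [0, 1]
#' while retaining their sign: \code{S_ij = (1 + cor(x_i, x_j)) / 2}.
#' Anticorrelated genes get similarity near 0 rather than near 1, so a
#' signed network never groups opposing profiles into one module.
#'
#' @param expr genes x samples numeric matrix with at least 3 samples.
#'   Genes constant across samples are dropped with a warning.
#' @return Symmetric similarity matrix with unit diagonal, entries in [0,1].
#' @export
signed_similarity <- function(expr) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3L) stop("need at least 3 samples")
  v <- apply(expr, 1, stats::var)
  if (any(v == 0)) {
    warning(sprintf("dropping %d constant gene(s)", sum(v == 0)))
    expr <- expr[v > 0, , drop = FALSE]
  }
  if (nrow(expr) < 2L) stop("need at least 2 non-constant genes")
  s <- (1 + stats::cor(t(expr))) / 2
  diag(s) <- 1
  s
}

#' Soft-threshold adjacency
#'
#' Raises the signed similarity elementwise to the power beta. The diagonal
#' is set to zero (self-connections carry no information for connectivity or
#' topological overlap).
#'
#' @param S similarity matrix in [0,1].
#' @param beta soft-threshold power, >= 1.
#' @return Adjacency matrix, zero diagonal.
#' @export
adjacency_matrix <- function(S, beta) {
  if (beta < 1) stop("beta must be >= 1")
  a <- S^beta
  diag(a) <- 0
  a
}

scale_free_fit <- function(k, n_bins = 10) {
  if (max(k) == min(k)) stop("degenerate connectivity: all values identical")
  bins <- cut(k, breaks = n_bins, include.lowest = TRUE)
  freq <- tabulate(bins, nbins = n_bins) / length(k)
  km <- tapply(k, bins, mean)
  keep <- freq > 0 & !is.na(km) & km > 0
  if (sum(keep) < 2L) stop("degenerate connectivity binning")
  fit <- stats::lm(log10(freq[keep]) ~ log10(km[keep]))
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[2]
  -sign(slope) * r2
}

#' Choose the soft-threshold power by the scale-free topology criterion
#'
#' For each candidate power, computes the connectivity
#' \code{k_i = sum_j S_ij^beta} (j != i), bins the connectivities, and fits
#' log10(frequency) against log10(mean connectivity per bin). The signed fit
#' index is R-squared with the sign of the slope reversed, so only
#' decreasing (scale-free-like) connectivity distributions score high. The
#' chosen power is the smallest candidate whose signed index reaches
#' \code{r2_cut}; if none does, the candidate with the largest index.
#'
#' @param S similarity matrix in [0,1].
#' @param candidates candidate powers; default 1:20.
#' @param r2_cut signed R-squared threshold in (0,1); default 0.8.
#' @param n_bins connectivity bins for the fit; default 10.
#' @return List with \code{beta} (the chosen power) and \code{fits}
#'   (data.frame of candidate, signed R-squared, mean connectivity).
#' @export
pick_soft_threshold <- function(S, candidates = 1:20, r2_cut = 0.8,
                                n_bins = 10) {
  if (length(candidates) == 0L) stop("no candidate powers")
  if (r2_cut <= 0 || r2_cut >= 1) stop("r2_cut must lie in (0,1)")
  fits <- lapply(candidates, function(b) {
    a <- adjacency_matrix(S, b)
    k <- rowSums(a)
    data.frame(beta = b, signed_r2 = scale_free_fit(k, n_bins = n_bins),
               mean_k = mean(k))
  })
  fits <- do.call(rbind, fits)
  hit <- which(fits$signed_r2 >= r2_cut)
  beta <- if (length(hit)) fits$beta[hit[1]] else fits$beta[which.max(fits$signed_r2)]
  list(beta = beta, fits = fits)
}

#' Topological overlap matrix
#'
#' For adjacency A (symmetric, zero diagonal, entries in [0,1]) and
#' connectivities \code{k_i = sum_u A_iu}:
#' \deqn{TOM_{ij} = \frac{\sum_{u} A_{iu} A_{uj} + A_{ij}}
#'                       {\min(k_i, k_j) + 1 - A_{ij}}}
#' for i != j, and 1 on the diagonal. Gene pairs that share strong
#' neighbors score high even when their direct adjacency is moderate;
#' \code{1 - TOM} is the clustering distance for module detection.
#'
#' @param A adjacency matrix.
#' @return TOM matrix, symmetric, entries in [0,1], unit diagonal.
#' @export
topological_overlap <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A) || max(abs(A - t(A))) > 1e-8) {
    stop("adjacency must be a symmetric square matrix")
  }
  if (any(diag(A) != 0)) stop("adjacency must have zero diagonal")
  if (any(A < 0 | A > 1)) stop("adjacency entries must lie in [0,1]")
  k <- rowSums(A)
  shared <- A %*% A            # diagonal of A is zero, so u = i, j drop out
  denom <- outer(k, k, pmin) + 1 - A
  tom <- (shared + A) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(A)
  tom
}

#' Detect co-expression modules from a topological overlap matrix
#'
#' Average-linkage hierarchical clustering on \code{1 - TOM}, cut at a fixed
#' fraction of the maximum merge height. Clusters smaller than
#' \code{min_size} are relabeled \code{M0} (unassigned); the rest are named
#' \code{M1}, \code{M2}, ... in order of decreasing size.
#'
#' @param TOM topological overlap matrix with gene dimnames.
#' @param min_size minimum module size (>= 2); default 100, matching the
#'   scale of genome-wide metabolic gene sets (lower it for small studies).
#' @param cut_height fraction of the maximum merge height at which the tree
#'   is cut; default 0.99.
#' @return Named character vector: gene id -> module label.
#' @export
detect_modules <- function(TOM, min_size = 100, cut_height = 0.99) {
  if (min_size < 2) stop("min_size must be >= 2")
  genes <- rownames(TOM)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(TOM)))
  if (nrow(TOM) < min_size) {
    warning("fewer genes than min_size: all genes unassigned (M0)")
    return(stats::setNames(rep("M0", nrow(TOM)), genes))
  }
  h <- stats::hclust(stats::as.dist(1 - TOM), method = "average")
  # ties can leave numerically non-monotone merge heights; cutree needs order
  h$height <- cummax(h$height)
  cl <- stats::cutree(h, h = cut_height * max(h$height))
  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_size]
  labels <- rep("M0", length(cl))
  if (length(big)) {
    big <- big[order(-sizes[big], as.integer(big))]
    for (i in seq_along(big)) labels[cl == as.integer(big[i])] <- paste0("M", i)
  }
  stats::setNames(labels, genes)
}

#' Module eigengenes by singular value decomposition
#'
#' For each assigned module, member gene profiles are standardized across
#' samples and the first right singular vector of the standardized
#' submatrix is taken as the module eigengene: a unit-norm, one-per-module
#' summary expression profile over samples. Each eigengene is oriented so
#' that its mean correlation with the member gene profiles is positive.
#'
#' @param expr genes x samples matrix covering all module members.
#' @param modules named character vector from \code{\link{detect_modules}};
#'   label \code{M0} is skipped.
#' @return Matrix, one row per module (sorted by label), one column per
#'   sample; rows have unit Euclidean norm.
#' @export
module_eigengenes <- function(expr, modules) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 2L) stop("need at least 2 samples")
  labels <- setdiff(sort(unique(modules)), "M0")
  labels <- labels[order(as.integer(sub("^M", "", labels)))]
  if (length(labels) == 0L) stop("no assigned modules")
  me <- matrix(NA_real_, nrow = length(labels), ncol = ncol(expr),
               dimnames = list(labels, colnames(expr)))
  for (lab in labels) {
    members <- names(modules)[modules == lab]
    x <- expr[members, , drop = FALSE]
    v <- apply(x, 1, stats::var)
    if (all(v == 0)) {
      stop(sprintf("module %s contains only constant genes", lab))
    }
    if (any(v == 0)) {
      warning(sprintf("module %s: dropping %d constant gene(s)",
                      lab, sum(v == 0)))
      x <- x[v > 0, , drop = FALSE]
    }
    xs <- t(scale(t(x)))
    sv <- svd(xs, nu = 0, nv = 1)
    e <- sv$v[, 1]
    orient <- mean(stats::cor(e, t(xs)))
    if (!is.na(orient) && orient < 0) e <- -e
    me[lab, ] <- e
  }
  me
}

#' Correlate module eigengenes with clinical traits
#'
#' Pearson correlation between each eigengene and each numeric trait column
#' (e.g. disease 0/1, stage 0-4, overall survival time), with the two-sided
#' p-value from the t transform \code{t = r sqrt((n-2)/(1-r^2))} on n-2
#' degrees of freedom. Missing trait values are dropped pairwise; survival
#' is correlated as raw time among samples with a recorded time. A constant
#' trait yields NA with a warning.
#'
#' @param ME modules x samples eigengene matrix.
#' @param traits data.frame with \code{sample_id} plus numeric trait
#'   columns, one row per sample.
#' @return data.frame with columns \code{module}, \code{trait}, \code{r},
#'   \code{p}, \code{n}.
#' @export
module_trait_correlation <- function(ME, traits) {
  if (!"sample_id" %in% names(traits)) stop("traits needs a sample_id column")
  idx <- match(colnames(ME), traits$sample_id)
  if (any(is.na(idx))) {
    stop(sprintf("samples without trait rows: %s",
                 paste(colnames(ME)[is.na(idx)], collapse = ", ")))
  }
  traits <- traits[idx, , drop = FALSE]
  trait_cols <- setdiff(names(traits), "sample_id")
  trait_cols <- trait_cols[vapply(traits[trait_cols], is.numeric, TRUE)]
  rows <- list()
  for (m in rownames(ME)) {
    for (tr in trait_cols) {
      y <- traits[[tr]]
      ok <- !is.na(y)
      n <- sum(ok)
      if (n < 3L) {
        rows[[length(rows) + 1L]] <- data.frame(
          module = m, trait = tr, r = NA_real_, p = NA_real_, n = n)
        next
      }
      if (stats::var(y[ok]) == 0) {
        warning(sprintf("trait '%s' constant over non-missing samples", tr))
        rows[[length(rows) + 1L]] <- data.frame(
          module = m, trait = tr, r = NA_real_, p = NA_real_, n = n)
        next
      }
      r <- stats::cor(ME[m, ok], y[ok])
      tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
      p <- 2 * stats::pt(-abs(tt), df = n - 2)
      p <- max(p, .Machine$double.xmin)
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, trait = tr, r = r, p = p, n = n)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Upper-tail hypergeometric p-value
#'
#' \code{P(X >= overlap)} when drawing \code{draws} genes from a universe of
#' \code{universe_size} genes of which \code{successes} belong to the
#' pathway.
#'
#' @param overlap observed overlap count.
#' @param successes pathway genes in the universe.
#' @param universe_size size of the gene universe.
#' @param draws module size.
#' @return The tail probability, in (0, 1].
#' @export
hyper_tail_p <- function(overlap, successes, universe_size, draws) {
  if (overlap > min(draws, successes)) stop("overlap exceeds set sizes")
  stats::phyper(overlap - 1, successes, universe_size - successes, draws,
                lower.tail = FALSE)
}

#' Pathway over-representation within co-expression modules
#'
#' For each assigned module and each pathway with at least one gene in the
#' universe, the upper-tail hypergeometric probability of the observed
#' overlap. The universe is the intersection of the model's genes with the
#' analyzed genes.
#'
#' @param modules named character vector (gene -> module label); M0 skipped.
#' @param model a \code{MetabolicModel} (supplies pathway gene sets).
#' @param universe optional gene universe; default
#'   \code{intersect(model$genes, names(modules))}.
#' @return data.frame with columns \code{module}, \code{pathway},
#'   \code{overlap}, \code{module_size}, \code{pathway_size},
#'   \code{universe_size}, \code{p}, sorted by module then p.
#' @export
module_pathway_enrichment <- function(modules, model, universe = NULL) {
  stopifnot(inherits(model, "MetabolicModel"))
  if (is.null(universe)) universe <- intersect(model$genes, names(modules))
  universe <- unique(as.character(universe))
  u <- length(universe)
  if (u == 0L) stop("empty gene universe")
  pw_genes <- lapply(model$pathway_genes, intersect, y = universe)
  pw_genes <- pw_genes[vapply(pw_genes, length, 1L) > 0L]
  labels <- setdiff(sort(unique(modules)), "M0")
  rows <- list()
  for (m in labels) {
    mg <- intersect(names(modules)[modules == m], universe)
    for (pw in names(pw_genes)) {
      ov <- length(intersect(mg, pw_genes[[pw]]))
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, pathway = pw, overlap = ov,
        module_size = length(mg), pathway_size = length(pw_genes[[pw]]),
        universe_size = u,
        p = hyper_tail_p(ov, length(pw_genes[[pw]]), u, length(mg)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$module, out$p, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}
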