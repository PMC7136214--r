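#' Bundle a count matrix with its sample metadata
#'
#' @param counts numeric matrix of non-negative counts, genes as rows
#'   (rownames = gene ids), samples as columns (colnames = sample ids).
#' @param meta data.frame with one row per sample: \code{sample_id},
#'   \code{condition} ("normal"/"tumor"), optional \code{pair_id} (matched
#'   normal/tumor pair key), optional \code{stage} (integer 0-4; 0 = normal,
#'   1-4 = tumor stages I-IV), optional \code{survival_days}.
#' @return A \code{CountMatrix}: list with elements \code{counts}, \code{meta}.
#' @export
count_matrix <- function(counts, meta) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene rownames and sample colnames")
  }
  if (!is.data.frame(meta) ||
      !all(c("sample_id", "condition") %in% names(meta))) {
    stop("meta must be a data.frame with columns sample_id and condition")
  }
  meta$sample_id <- as.character(meta$sample_id)
  missing_meta <- setdiff(colnames(counts), meta$sample_id)
  if (length(missing_meta)) {
    stop(sprintf("samples without metadata: %s",
                 paste(missing_meta, collapse = ", ")))
  }
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  if (!all(meta$condition %in% c("normal", "tumor"))) {
    stop("condition must be 'normal' or 'tumor'")
  }
  if (!is.null(meta$stage) &&
      !all(is.na(meta$stage) | meta$stage %in% 0:4)) {
    stop("stage codes must be 0 (normal) through 4 (stage IV)")
  }
  if (!is.null(meta$pair_id)) {
    pid <- meta$pair_id[!is.na(meta$pair_id) & nzchar(meta$pair_id)]
    if (length(pid)) {
      tab <- table(meta$pair_id,
                   factor(meta$condition, levels = c("normal", "tumor")))
      bad <- rownames(tab)[tab[, "normal"] != 1L | tab[, "tumor"] != 1L]
      if (length(bad)) {
        stop(sprintf(
          "pair id(s) without exactly one normal and one tumor sample: %s",
          paste(bad, collapse = ", ")))
      }
    }
  }
  structure(list(counts = counts, meta = meta), class = "CountMatrix")
}

#' Read counts and sample metadata from TSV files
#'
#' Counts: genes as rows, first column the gene id, one column per sample.
#' Metadata: columns \code{sample_id}, \code{condition}, and optionally
#' \code{pair_id}, \code{stage}, \code{survival_days}.
#'
#' @param counts_path,meta_path file paths.
#' @return A \code{CountMatrix}.
#' @export
read_counts <- function(counts_path, meta_path) {
  tab <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab[[1]]
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  count_matrix(counts, meta)
}

#' Write a CountMatrix to TSV files
#' @param x a \code{CountMatrix}.
#' @param counts_path,meta_path output paths.
#' @return invisibly, a list of the two paths.
#' @export
write_counts <- function(x, counts_path, meta_path) {
  stopifnot(inherits(x, "CountMatrix"))
  tab <- data.frame(gene = rownames(x$counts), x$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(counts = counts_path, meta = meta_path))
}

as_count_mat <- function(counts) {
  if (inherits(counts, "CountMatrix")) counts$counts else as.matrix(counts)
}

#' Median-of-ratios size factors
#'
#' Per-sample scale factors from the median ratio of each sample's counts to
#' the per-gene geometric mean across samples. Only genes with nonzero counts
#' in every sample (the reference-positive set) enter the medians, so single
#' zero counts do not break the geometric means.
#'
#' @param counts a \code{CountMatrix} or a genes x samples count matrix.
#' @return Named positive numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  m <- as_count_mat(counts)
  ref <- rowSums(m > 0) == ncol(m)
  if (!any(ref)) {
    stop("median-of-ratios normalization needs a gene with nonzero counts in every sample")
  }
  logm <- log(m[ref, , drop = FALSE])
  loggeo <- rowMeans(logm)
  apply(exp(logm - loggeo), 2, stats::median)
}

#' Normalize counts by median-of-ratios size factors
#'
#' @param counts a \code{CountMatrix} or count matrix.
#' @param factors optional precomputed size factors; computed if missing.
#' @return Matrix of normalized counts (counts divided by the sample factor).
#' @export
normalize_counts <- function(counts, factors = NULL) {
  m <- as_count_mat(counts)
  if (is.null(factors)) factors <- size_factors(m)
  sweep(m, 2, factors, "/")
}

pair_index <- function(x) {
  stopifnot(inherits(x, "CountMatrix"))
  meta <- x$meta
  if (is.null(meta$pair_id)) stop("metadata has no pair_id column")
  usable <- !is.na(meta$pair_id) & nzchar(as.character(meta$pair_id))
  unpaired <- meta$sample_id[!usable]
  if (length(unpaired)) {
    stop(sprintf("sample(s) without a pair id: %s",
                 paste(unpaired, collapse = ", ")))
  }
  pairs <- sort(unique(meta$pair_id))
  normal <- vapply(pairs, function(p) {
    meta$sample_id[meta$pair_id == p & meta$condition == "normal"]
  }, character(1))
  tumor <- vapply(pairs, function(p) {
    meta$sample_id[meta$pair_id == p & meta$condition == "tumor"]
  }, character(1))
  list(pairs = pairs, normal = normal, tumor = tumor)
}

#' Matched-pair log2 fold-change matrix
#'
#' For each gene and matched normal/tumor pair, the difference
#' \code{log2(normalized tumor + pc) - log2(normalized normal + pc)}.
#' This per-pair fold change removes tissue-of-origin baseline differences,
#' which is what makes cross-cancer-type comparison of metabolic shifts
#' meaningful.
#'
#' @param counts a \code{CountMatrix} with matched pairs in its metadata.
#' @param pseudocount added before the log; default 1.
#' @return genes x pairs numeric matrix, columns named by pair id.
#' @export
paired_logfc_matrix <- function(counts, pseudocount = 1) {
  px <- pair_index(counts)
  norm <- normalize_counts(counts)
  fc <- log2(norm[, px$tumor, drop = FALSE] + pseudocount) -
    log2(norm[, px$normal, drop = FALSE] + pseudocount)
  colnames(fc) <- px$pairs
  fc
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; input order preserved, values
#' capped at 1.
#'
#' @param pvals numeric vector of p-values in [0,1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Paired differential expression on log-transformed normalized counts
#'
#' A light-weight paired test for matched normal/tumor designs: per gene, a
#' two-sided paired t-test on \code{log2(normalized + pseudocount)} across
#' pairs. The log2 fold change is the mean paired difference. Genes whose
#' paired differences have exactly zero variance get p = 1. P-values are
#' BH-adjusted across tested genes. Externally produced differential
#' expression tables (e.g. from a negative-binomial GLM) can be used
#' anywhere a \code{DgeTable} is accepted; this built-in stage exists so the
#' downstream network statistics are runnable from raw counts alone.
#'
#' @param counts a \code{CountMatrix} with at least 3 matched pairs.
#' @param pseudocount added before the log; default 1.
#' @return A \code{DgeTable}: data.frame with columns \code{gene},
#'   \code{log2fc}, \code{pvalue}, \code{padj}, \code{direction} (+1/-1/0,
#'   the sign of \code{log2fc}).
#' @export
simple_paired_dge <- function(counts, pseudocount = 1) {
  px <- pair_index(counts)
  n <- length(px$pairs)
  if (n < 3L) stop("paired differential expression requires at least 3 pairs")
  d <- paired_logfc_matrix(counts, pseudocount = pseudocount)
  log2fc <- rowMeans(d)
  sd_d <- apply(d, 1, stats::sd)
  tstat <- ifelse(sd_d > 0, log2fc / (sd_d / sqrt(n)), 0)
  pvalue <- ifelse(sd_d > 0, 2 * stats::pt(-abs(tstat), df = n - 1), 1)
  out <- data.frame(
    gene = rownames(d),
    log2fc = log2fc,
    pvalue = pvalue,
    padj = bh_adjust(pvalue),
    direction = sign(log2fc),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  class(out) <- c("DgeTable", "data.frame")
  out
}

#' Read / write a differential-expression table
#'
#' TSV with columns \code{gene}, \code{log2fc}, \code{pvalue}, \code{padj}.
#'
#' @param path file path.
#' @return \code{read_dge}: a \code{DgeTable} data.frame (with a derived
#'   \code{direction} column).
#' @export
read_dge <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "log2fc", "pvalue", "padj")
  if (!all(need %in% names(tab))) {
    stop(sprintf("DGE table must have columns: %s", paste(need, collapse = ", ")))
  }
  if (any(tab$pvalue < 0 | tab$pvalue > 1) || any(tab$padj < 0 | tab$padj > 1)) {
    stop("DGE table p-values must lie in [0, 1]")
  }
  tab$direction <- sign(tab$log2fc)
  class(tab) <- c("DgeTable", "data.frame")
  tab
}

#' @rdname read_dge
#' @param dge a \code{DgeTable}.
#' @export
write_dge <- function(dge, path) {
  utils::write.table(dge[, c("gene", "log2fc", "pvalue", "padj")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' PCA of the top-variance genes of a fold-change matrix
#'
#' Selects \code{ceiling(fraction * n_genes)} genes with the highest variance
#' across samples, centers each gene, and computes sample scores by SVD.
#' Centering only, no unit-variance scaling: the variance filter already
#' treats magnitude as meaningful.
#'
#' @param fc genes x samples numeric matrix (e.g. from
#'   \code{\link{paired_logfc_matrix}}).
#' @param fraction proportion of genes to keep, in (0, 1]; default 0.1.
#' @param n_components maximum number of components returned; default 10.
#' @return List with \code{scores} (samples x components), \code{explained}
#'   (explained-variance ratios, non-increasing, summing to <= 1), and
#'   \code{genes} (the selected gene ids).
#' @export
top_variance_pca <- function(fc, fraction = 0.1, n_components = 10) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  fc <- as.matrix(fc)
  if (nrow(fc) < 2L || ncol(fc) < 2L) stop("need at least 2 genes and 2 samples")
  v <- apply(fc, 1, stats::var)
  n_keep <- ceiling(fraction * nrow(fc))
  sel <- order(v, decreasing = TRUE)[seq_len(n_keep)]
  x <- t(fc[sel, , drop = FALSE])          # samples x genes
  x <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(x)
  total_var <- sum(sv$d^2)
  rank <- sum(sv$d > max(sv$d) * 1e-12)
  ncomp <- min(n_components, rank)
  scores <- sv$u[, seq_len(ncomp), drop = FALSE] %*%
    diag(sv$d[seq_len(ncomp)], ncomp)
  rownames(scores) <- rownames(x)
  colnames(scores) <- paste0("PC", seq_len(ncomp))
  list(scores = scores,
       explained = sv$d[seq_len(ncomp)]^2 / total_var,
       genes = rownames(fc)[sel])
}
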