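#' Generate a toy genome-scale metabolic model with planted structure
#'
#' Builds a random bipartite gene-metabolite network with pathway blocks:
#' metabolites are assigned to pathways in contiguous blocks, genes are
#' partitioned into matching blocks, and each metabolite draws its k
#' neighbor genes preferentially from its own pathway's gene block. This
#' reproduces the structural assumption behind reporter scoring — genes
#' attached to the same metabolite/pathway respond together — in a form
#' where the truth is known.
#'
#' @param n_genes number of genes (>= max(k_range)).
#' @param n_metabolites number of metabolites.
#' @param n_pathways number of pathways (<= n_metabolites).
#' @param k_range integer range (min, max) of neighborhood sizes; each
#'   metabolite draws k uniformly from this range. Default c(2, 6).
#' @param mixing fraction of neighbor mass placed outside the metabolite's
#'   own pathway block; 0 = perfectly block-pure. Default 0.1.
#' @param seed integer seed.
#' @return List with \code{model} (a \code{MetabolicModel}) and
#'   \code{truth} (pathway block assignments and the seed).
#' @export
synth_model <- function(n_genes, n_metabolites, n_pathways,
                        k_range = c(2, 6), mixing = 0.1, seed = 1) {
  k_range <- as.integer(k_range)
  if (length(k_range) != 2L || k_range[1] < 1L || k_range[2] < k_range[1]) {
    stop("k_range must be an increasing pair of positive integers")
  }
  if (n_genes < k_range[2]) stop("n_genes must be >= max(k_range)")
  if (n_pathways > n_metabolites) stop("n_pathways must be <= n_metabolites")
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  gene_block <- sort(rep_len(seq_len(n_pathways), n_genes))
  if (mixing == 0 && min(table(gene_block)) < k_range[2]) {
    stop("with mixing = 0 every pathway gene block must hold max(k_range) genes")
  }
  met_block <- sort(rep_len(seq_len(n_pathways), n_metabolites))
  comp <- rep_len(c("c", "m", "s"), n_metabolites)
  met_ids <- sprintf("m%04d_%s", seq_len(n_metabolites), comp)
  pathways <- sprintf("P%02d", met_block)

  reactions <- vector("list", n_metabolites)
  k_choices <- k_range[1]:k_range[2]
  for (i in seq_len(n_metabolites)) {
    k <- if (length(k_choices) == 1L) k_choices else sample(k_choices, 1)
    in_block <- gene_block == met_block[i]
    w <- ifelse(in_block, (1 - mixing) / sum(in_block), 0) + mixing / n_genes
    nb <- sample(genes, k, prob = w)
    reactions[[i]] <- list(id = sprintf("r%04d", i), genes = sort(nb),
                           metabolites = met_ids[i], pathway = pathways[i])
  }
  model <- metabolic_model(
    genes,
    data.frame(id = met_ids, compartment = comp, stringsAsFactors = FALSE),
    reactions)
  truth <- structure(
    list(gene_block = stats::setNames(gene_block, genes),
         metabolite_pathway = stats::setNames(pathways, met_ids),
         k_range = k_range, mixing = mixing, seed = seed),
    class = "SyntheticTruth")
  list(model = model, truth = truth)
}

#' Generate matched-pair RNA-seq-like counts with planted regulation
#'
#' Negative-binomial counts (variance mu + dispersion * mu^2) for matched
#' normal/tumor pairs, with a planted set of regulated genes: the enzyme
#' neighborhoods of chosen metabolites are shifted by \code{effect_log2fc}
#' in tumor samples (up or down per metabolite). Per-sample sequencing
#' depth varies log-normally so the median-of-ratios normalization has real
#' work to do. Tumor stages are assigned round-robin 1-4; survival times
#' are exponential with a rate increasing in the mean expression of the
#' planted up-regulated genes (the "aggressive" signature), so higher
#' signature expression means shorter survival.
#'
#' @param model a \code{MetabolicModel}.
#' @param planted data.frame with columns \code{metabolite}, \code{direction}
#'   ("up"/"down"), or a character vector of metabolite ids (all "up"), or
#'   NULL for a null data set.
#' @param n_pairs matched pairs; default 20.
#' @param nb_dispersion negative-binomial dispersion; 0 gives Poisson.
#'   Default 0.1.
#' @param effect_log2fc planted log2 fold change magnitude; default 2.
#' @param survival_gamma strength of the survival-signature dependence;
#'   default 1.
#' @param seed integer seed.
#' @return List with \code{counts} (a \code{CountMatrix}) and \code{truth}
#'   (planted metabolites, planted genes with true log2 fold changes, seed).
#' @export
synth_counts <- function(model, planted = NULL, n_pairs = 20,
                         nb_dispersion = 0.1, effect_log2fc = 2,
                         survival_gamma = 1, seed = 1) {
  stopifnot(inherits(model, "MetabolicModel"))
  if (is.character(planted)) {
    planted <- data.frame(metabolite = planted, direction = "up",
                          stringsAsFactors = FALSE)
  }
  if (!is.null(planted)) {
    bad <- setdiff(planted$metabolite, names(model$neighbor_map))
    if (length(bad)) {
      stop(sprintf("planted metabolite(s) not in model: %s",
                   paste(bad, collapse = ", ")))
    }
    if (effect_log2fc == 0) warning("planted genes with zero effect size")
  }
  set.seed(seed)
  genes <- model$genes
  n_genes <- length(genes)
  true_lfc <- stats::setNames(numeric(n_genes), genes)
  if (!is.null(planted)) {
    for (i in seq_len(nrow(planted))) {
      sgn <- if (planted$direction[i] == "down") -1 else 1
      nb <- model$neighbor_map[[planted$metabolite[i]]]
      nb <- nb[true_lfc[nb] == 0]            # first plant wins on overlap
      true_lfc[nb] <- sgn * effect_log2fc
    }
  }
  base_mu <- stats::rlnorm(n_genes, meanlog = log(100), sdlog = 1)
  normal_ids <- sprintf("N%03d", seq_len(n_pairs))
  tumor_ids <- sprintf("T%03d", seq_len(n_pairs))
  depth <- stats::rlnorm(2 * n_pairs, meanlog = 0, sdlog = 0.3)
  names(depth) <- c(normal_ids, tumor_ids)

  draw <- function(mu) {
    if (nb_dispersion > 0) {
      stats::rnbinom(length(mu), mu = mu, size = 1 / nb_dispersion)
    } else {
      stats::rpois(length(mu), lambda = mu)
    }
  }
  counts <- matrix(0L, nrow = n_genes, ncol = 2 * n_pairs,
                   dimnames = list(genes, c(normal_ids, tumor_ids)))
  for (s in normal_ids) counts[, s] <- draw(base_mu * depth[s])
  tumor_mu <- base_mu * 2^true_lfc
  for (s in tumor_ids) counts[, s] <- draw(tumor_mu * depth[s])

  stage <- rep_len(1:4, n_pairs)
  up_genes <- names(true_lfc)[true_lfc > 0]
  if (length(up_genes) == 0L) up_genes <- genes[seq_len(min(10, n_genes))]
  sig <- colMeans(log2(counts[up_genes, tumor_ids, drop = FALSE] + 1))
  zsig <- if (stats::sd(sig) > 0) (sig - mean(sig)) / stats::sd(sig) else sig * 0
  survival <- round(stats::rexp(n_pairs, rate = exp(survival_gamma * zsig)) * 1000)

  meta <- data.frame(
    sample_id = c(normal_ids, tumor_ids),
    condition = rep(c("normal", "tumor"), each = n_pairs),
    pair_id = rep(sprintf("p%03d", seq_len(n_pairs)), 2),
    stage = c(rep(0L, n_pairs), stage),
    survival_days = c(rep(NA_real_, n_pairs), survival),
    stringsAsFactors = FALSE)
  truth <- structure(
    list(planted_metabolites = planted,
         true_log2fc = true_lfc,
         planted_genes = names(true_lfc)[true_lfc != 0],
         seed = seed),
    class = "SyntheticTruth")
  list(counts = count_matrix(counts, meta), truth = truth)
}

#' Generate factor-model expression with planted co-expression modules
#'
#' Each module m has a latent factor f_m ~ N(0,1) over samples; member gene
#' profiles are loading * f_m plus independent Gaussian noise. Default
#' loadings near 1 with \code{noise_sd = 0.5} give a 4:1 signal-to-noise
#' variance ratio. Clinical traits are tied to designated factors: disease
#' is a thresholded noisy copy of its factor (binary 0/1), stage is 0 for
#' non-disease samples and a quartile code 1-4 of its factor among disease
#' samples, and survival time is exponential with rate increasing in the
#' designated "aggressive" factor (higher factor, shorter survival).
#'
#' @param n_modules number of planted modules; default 4.
#' @param genes_per_module genes per module; default 50.
#' @param n_samples number of samples (>= 10); default 100.
#' @param noise_sd per-gene noise standard deviation; default 0.5.
#' @param trait_effects list with optional elements \code{disease},
#'   \code{stage}, \code{survival}, each a list \code{(module, coef,
#'   noise)}; defaults tie disease to module 1 (coef 0.9, noise 0.2),
#'   stage to module 1 (coef 0.8, noise 0.3) and survival to module 2
#'   (coef 0.7).
#' @param seed integer seed.
#' @return List with \code{expr} (genes x samples), \code{traits}
#'   (data.frame sample_id/disease/stage/survival_days) and \code{truth}
#'   (module label per gene, factor matrix, the effects, seed).
#' @export
synth_coexpression <- function(n_modules = 4, genes_per_module = 50,
                               n_samples = 100, noise_sd = 0.5,
                               trait_effects = list(
                                 disease = list(module = 1, coef = 0.9, noise = 0.2),
                                 stage = list(module = 1, coef = 0.8, noise = 0.3),
                                 survival = list(module = 2, coef = 0.7)),
                               seed = 1) {
  if (n_modules < 1) stop("n_modules must be >= 1")
  if (n_samples < 10) stop("n_samples must be >= 10")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  set.seed(seed)
  samples <- sprintf("s%03d", seq_len(n_samples))
  f <- matrix(stats::rnorm(n_modules * n_samples), nrow = n_modules,
              dimnames = list(paste0("F", seq_len(n_modules)), samples))
  n_genes <- n_modules * genes_per_module
  genes <- sprintf("g%04d", seq_len(n_genes))
  module_of <- stats::setNames(rep(seq_len(n_modules), each = genes_per_module),
                               genes)
  loading <- stats::runif(n_genes, 0.8, 1.2)
  expr <- f[module_of, , drop = FALSE] * loading +
    matrix(stats::rnorm(n_genes * n_samples, sd = noise_sd), nrow = n_genes)
  dimnames(expr) <- list(genes, samples)

  get_eff <- function(name) {
    e <- trait_effects[[name]]
    if (!is.null(e) && e$module > n_modules) return(NULL)
    e
  }
  de <- get_eff("disease")
  disease <- if (!is.null(de)) {
    as.integer(de$coef * f[de$module, ] +
                 stats::rnorm(n_samples, sd = de$noise %||% 0.2) > 0)
  } else {
    rep(NA_integer_, n_samples)
  }
  se <- get_eff("stage")
  stage <- rep(NA_integer_, n_samples)
  if (!is.null(se)) {
    score <- se$coef * f[se$module, ] +
      stats::rnorm(n_samples, sd = se$noise %||% 0.3)
    if (!is.null(de)) {
      stage[disease == 0] <- 0L
      tum <- which(disease == 1)
      if (length(tum) >= 4) {
        q <- stats::quantile(score[tum], probs = c(0.25, 0.5, 0.75))
        stage[tum] <- 1L + findInterval(score[tum], q)
      } else {
        stage[tum] <- 1L
      }
    } else {
      q <- stats::quantile(score, probs = seq(0.2, 0.8, by = 0.2))
      stage[] <- findInterval(score, q)
    }
  }
  ve <- get_eff("survival")
  survival <- if (!is.null(ve)) {
    round(stats::rexp(n_samples, rate = exp(ve$coef * f[ve$module, ])) * 1000)
  } else {
    rep(NA_real_, n_samples)
  }
  traits <- data.frame(sample_id = samples, disease = disease,
                       stage = stage, survival_days = survival,
                       stringsAsFactors = FALSE)
  truth <- structure(
    list(module_of = stats::setNames(paste0("M", module_of), genes),
         factors = f, loading = stats::setNames(loading, genes),
         trait_effects = trait_effects, noise_sd = noise_sd, seed = seed),
    class = "SyntheticTruth")
  list(expr = expr, traits = traits, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
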