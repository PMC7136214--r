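test_that("inverse-normal transform maps p-values to upper-tail quantiles", {
  expect_equal(p_to_z(0.5), 0)
  expect_equal(p_to_z(0.0228), 2.00, tolerance = 0.005)
  expect_true(is.finite(p_to_z(0)))
  expect_equal(p_to_z(0), qnorm(1 - 1e-15))
  expect_true(is.finite(p_to_z(1)))
  expect_error(p_to_z(-0.1), "\\[0, 1\\]")
  expect_error(p_to_z(1.1), "\\[0, 1\\]")
  p <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(p_to_z(p)) < 0))
})

test_that("raw metabolite score aggregates neighbor Z-scores by 1/sqrt(k)", {
  z <- c(a = 2, b = -1, c = 1, d = 1, e = 1, f = 1)
  expect_equal(metabolite_raw_score(z, "a"), 2)
  expect_equal(metabolite_raw_score(z, c("c", "d", "e", "f")), 2)
  expect_equal(metabolite_raw_score(z, c("a", "b")), 1 / sqrt(2))
  expect_error(metabolite_raw_score(z, character()), "empty")
  expect_error(metabolite_raw_score(z, "zz"), "zz")
})

test_that("sampled background matches exhaustive enumeration on a small pool", {
  pool <- c(3, 1, -1, -3)
  ex <- enum_background(pool, 2)
  expect_equal(ex$mu, 0)
  expect_equal(ex$sigma^2, 20 / 6, tolerance = 1e-12)
  bg <- background_stats(pool, 2, n_sets = 2e5, seed = 31)
  expect_lt(abs(bg$sigma - ex$sigma) / ex$sigma, 0.01)
  expect_lt(abs(bg$mu - ex$mu), 0.03)
  # exhaustion degeneracy: k = pool size leaves a single possible set
  bgN <- background_stats(pool, 4, n_sets = 100, seed = 1)
  expect_equal(bgN$sigma, 0)
  expect_equal(bgN$mu, sum(pool) / 2)
  expect_error(background_stats(pool, 5, n_sets = 10), "exceeds")
})

test_that("background follows the without-replacement closed form", {
  set.seed(55)
  pool <- rnorm(300, mean = 0.3)
  n <- length(pool)
  mu_p <- mean(pool)
  sd_p <- sqrt(mean((pool - mu_p)^2))
  for (k in c(5, 20)) {
    bg <- background_stats(pool, k, n_sets = 1e5, seed = 100 + k)
    expect_lt(abs(bg$mu - sqrt(k) * mu_p), 0.02)
    sigma_expect <- sd_p * sqrt((n - k) / (n - 1))
    expect_lt(abs(bg$sigma - sigma_expect) / sigma_expect, 0.02)
  }
})

test_that("corrected scores are centered under a flat global null", {
  sm <- synth_model(n_genes = 60, n_metabolites = 20, n_pathways = 4,
                    k_range = c(2, 5), seed = 61)
  scores <- data.frame(gene = sm$model$genes, p = 0.5,
                       z = p_to_z(rep(0.5, 60)))
  rt <- corrected_scores(sm$model, scores, n_sets = 2000, seed = 62)
  expect_true(all(rt$z_raw == 0))
  expect_true(all(abs(rt$z_corrected) < 0.2))
  expect_true(all(abs(rt$p - 0.5) < 0.1))
})

test_that("reporter tables are deterministic given the seed", {
  sm <- synth_model(n_genes = 80, n_metabolites = 30, n_pathways = 5,
                    k_range = c(2, 6), seed = 71)
  set.seed(72)
  scores <- data.frame(gene = sm$model$genes, p = runif(80))
  scores$z <- p_to_z(scores$p)
  a <- corrected_scores(sm$model, scores, n_sets = 3000, seed = 73)
  b <- corrected_scores(sm$model, scores, n_sets = 3000, seed = 73)
  expect_identical(a, b)
  pa <- pathway_scores(a, sm$model, n_sets = 3000, seed = 74)
  pb <- pathway_scores(b, sm$model, n_sets = 3000, seed = 74)
  expect_identical(pa, pb)
  # a different seed perturbs the background draw
  c_ <- corrected_scores(sm$model, scores, n_sets = 3000, seed = 99)
  expect_false(identical(a$z_corrected, c_$z_corrected))
})

test_that("lowering a neighbor gene's p never lowers the corrected score", {
  z_others <- c(g2 = 0.3, g3 = -0.8)
  bg <- list(mu = 0.1, sigma = 1.2)   # background held fixed
  p_grid <- seq(0.9, 0.01, by = -0.05)
  zc <- vapply(p_grid, function(p) {
    z <- c(g1 = p_to_z(p), z_others)
    (metabolite_raw_score(z, names(z)) - bg$mu) / bg$sigma
  }, numeric(1))
  expect_true(all(diff(zc) > 0))
})

test_that("pathway aggregation follows the 1/sqrt(n) rule", {
  sm <- synth_model(n_genes = 40, n_metabolites = 10, n_pathways = 2,
                    k_range = c(2, 4), seed = 81)
  set.seed(82)
  scores <- data.frame(gene = sm$model$genes, p = runif(40))
  scores$z <- p_to_z(scores$p)
  rt <- corrected_scores(sm$model, scores, n_sets = 2000, seed = 83)
  pw <- pathway_scores(rt, sm$model, n_sets = 2000, seed = 84,
                       background = FALSE)
  zc <- setNames(rt$z_corrected, rt$metabolite)
  for (i in seq_len(nrow(pw))) {
    members <- intersect(sm$model$pathway_map[[pw$pathway[i]]], rt$metabolite)
    expect_equal(pw$z_raw[i], sum(zc[members]) / sqrt(length(members)),
                 tolerance = 1e-12)
    expect_equal(pw$p[i], pnorm(pw$z[i], lower.tail = FALSE))
  }
  # n = 1 identity and the two-metabolite hand case, on constructed tables
  fake <- data.frame(metabolite = c("m1_c", "m2_m"), k = c(1, 1),
                     z_raw = c(1.7, 2), z_corrected = c(1.7, 2),
                     p = pnorm(c(1.7, 2), lower.tail = FALSE))
  class(fake) <- c("ReporterTable", "data.frame")
  one <- metabolic_model(
    genes = "g1",
    metabolites = data.frame(id = c("m1_c", "m2_m"),
                             compartment = c("c", "m")),
    reactions = list(
      list(id = "r1", genes = "g1", metabolites = "m1_c", pathway = "solo"),
      list(id = "r2", genes = "g1", metabolites = "m2_m", pathway = "duo"),
      list(id = "r3", genes = "g1", metabolites = "m1_c", pathway = "duo")))
  fake2 <- fake
  fake2$z_corrected <- c(2, 2)
  pw1 <- pathway_scores(fake2, one, background = FALSE)
  expect_equal(pw1$z_raw[pw1$pathway == "duo"], 2 * sqrt(2))
  fake$z_corrected <- c(1.7, 0)
  pw2 <- pathway_scores(fake, one, background = FALSE)
  expect_equal(pw2$z_raw[pw2$pathway == "solo"], 1.7)
})

test_that("pathway p-values are near-uniform under a corrected-score null", {
  sm <- synth_model(n_genes = 150, n_metabolites = 120, n_pathways = 30,
                    k_range = c(2, 5), seed = 91)
  set.seed(92)
  scores <- data.frame(gene = sm$model$genes, p = runif(150))
  scores$z <- p_to_z(scores$p)
  rt <- corrected_scores(sm$model, scores, n_sets = 5000, seed = 93)
  pw <- pathway_scores(rt, sm$model, n_sets = 5000, seed = 94)
  frac <- mean(pw$p < 0.05)
  expect_lt(abs(frac - 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / nrow(pw)))
})

test_that("directional runs restrict the universe correctly", {
  sm <- synth_model(n_genes = 50, n_metabolites = 20, n_pathways = 4,
                    k_range = c(2, 4), seed = 111)
  set.seed(112)
  dge <- data.frame(gene = sm$model$genes,
                    log2fc = abs(rnorm(50)) + 0.1,   # all upregulated
                    pvalue = runif(50))
  dge$padj <- bh_adjust(dge$pvalue)
  dge$direction <- sign(dge$log2fc)
  class(dge) <- c("DgeTable", "data.frame")
  expect_error(directional_analysis(dge, sm$model, "down", n_sets = 500,
                                    seed = 5),
               "empty gene universe")
  up <- reporter_analysis(sm$model, dge, direction = "up", n_sets = 2000,
                          seed = 6)
  all_run <- reporter_analysis(sm$model, dge, direction = "all",
                               n_sets = 2000, seed = 6)
  expect_equal(up$metabolites$z_corrected, all_run$metabolites$z_corrected)
  expect_equal(up$pathways$p, all_run$pathways$p)
  expect_equal(up$pathways$direction, rep("up", nrow(up$pathways)))
})

test_that("planted directional pathways are found only by the matching run", {
  sm <- synth_model(n_genes = 160, n_metabolites = 64, n_pathways = 8,
                    k_range = c(3, 5), mixing = 0, seed = 121)
  mets <- names(sm$model$neighbor_map)
  up_mets <- mets[sm$truth$metabolite_pathway[mets] == "P01"]
  down_mets <- mets[sm$truth$metabolite_pathway[mets] == "P02"]
  planted <- rbind(
    data.frame(metabolite = up_mets, direction = "up"),
    data.frame(metabolite = down_mets, direction = "down"))
  sc <- synth_counts(sm$model, planted = planted, n_pairs = 20,
                     effect_log2fc = 2, seed = 122)
  dge <- simple_paired_dge(sc$counts)
  up_run <- directional_analysis(dge, sm$model, "up", alpha = 0.05,
                                 n_sets = 5000, seed = 123)
  down_run <- directional_analysis(dge, sm$model, "down", alpha = 0.05,
                                   n_sets = 5000, seed = 123)
  rank_of <- function(tab, pw) {
    r <- match(pw, tab$pathway)
    if (is.na(r)) nrow(tab) + 1L else r
  }
  expect_lte(rank_of(up_run, "P01"), 3L)
  expect_gt(rank_of(up_run, "P02"), nrow(up_run) / 2)
  expect_lte(rank_of(down_run, "P02"), 3L)
  expect_gt(rank_of(down_run, "P01"), nrow(down_run) / 2)
})

test_that("gene scores can be driven by raw or adjusted p-values", {
  dge <- data.frame(gene = c("a", "b"), log2fc = c(1, -1),
                    pvalue = c(0.01, 0.5), padj = c(0.02, 0.5))
  raw <- gene_scores(dge, "raw")
  adj <- gene_scores(dge, "adjusted")
  expect_equal(raw$z, p_to_z(c(0.01, 0.5)))
  expect_equal(adj$z, p_to_z(c(0.02, 0.5)))
  expect_gt(raw$z[1], adj$z[1])
})
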