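test_that("signed similarity preserves correlation sign on [0,1]", {
  x <- c(1, 2, 3, 4)
  expr <- rbind(g1 = x, g2 = 2 * x + 1, g3 = -x, g4 = c(1, 3, 2, 4))
  S <- signed_similarity(expr)
  expect_equal(S["g1", "g2"], 1)
  expect_equal(S["g1", "g3"], 0)
  expect_true(isSymmetric(S))
  expect_true(all(S >= 0 & S <= 1))
  # cor((1,2,3),(1,3,2)) = 0.5 -> similarity 0.75
  S2 <- signed_similarity(rbind(a = c(1, 2, 3), b = c(1, 3, 2)))
  expect_equal(S2["a", "b"], 0.75)
  expect_error(signed_similarity(rbind(a = 1:2, b = 2:1)), "3 samples")
  expect_warning(signed_similarity(rbind(a = 1:4, b = 4:1, c = rep(1, 4))),
                 "constant")
})

test_that("soft-threshold choice follows the smallest-power-past-cut rule", {
  sx <- synth_coexpression(n_modules = 3, genes_per_module = 30,
                           n_samples = 60, seed = 201)
  S <- signed_similarity(sx$expr)
  pick <- pick_soft_threshold(S, candidates = 1:12, r2_cut = 0.8)
  fits <- pick$fits
  hit <- which(fits$signed_r2 >= 0.8)
  expected <- if (length(hit)) fits$beta[hit[1]] else
    fits$beta[which.max(fits$signed_r2)]
  expect_equal(pick$beta, expected)
  # the choice must follow the rule at any cut level
  for (cut in c(0.05, 0.5, 0.95)) {
    pk <- pick_soft_threshold(S, candidates = 1:12, r2_cut = cut)
    h <- which(pk$fits$signed_r2 >= cut)
    want <- if (length(h)) pk$fits$beta[h[1]] else
      pk$fits$beta[which.max(pk$fits$signed_r2)]
    expect_equal(pk$beta, want)
  }
  # determinism: same input, same choice
  expect_equal(pick$beta, pick_soft_threshold(S, 1:12, 0.8)$beta)
  expect_error(pick_soft_threshold(S, integer(), 0.8), "candidate")
  expect_error(pick_soft_threshold(S, 1:5, 1.2), "r2_cut")
  # identical connectivities cannot be binned
  S_flat <- matrix(0.5, 10, 10); diag(S_flat) <- 1
  expect_error(pick_soft_threshold(S_flat, 1:3, 0.8), "degenerate")
})

test_that("raising the power weakly shrinks every adjacency entry", {
  set.seed(211)
  S <- signed_similarity(matrix(rnorm(30 * 20), 30,
                                dimnames = list(paste0("g", 1:30), NULL)))
  a2 <- adjacency_matrix(S, 2)
  a5 <- adjacency_matrix(S, 5)
  expect_true(all(a5 <= a2 + 1e-12))
  expect_true(all(diag(a2) == 0))
  expect_error(adjacency_matrix(S, 0.5), "beta")
})

test_that("topological overlap matches its hand-worked and brute-force values", {
  A_tri <- matrix(0.5, 3, 3); diag(A_tri) <- 0
  expect_equal(topological_overlap(A_tri)[1, 2], 0.5)
  A0 <- matrix(0, 4, 4)
  t0 <- topological_overlap(A0)
  expect_equal(t0, diag(4))
  set.seed(221)
  for (rep in 1:5) {
    n <- sample(20:50, 1)
    A <- matrix(runif(n * n), n)
    A <- (A + t(A)) / 2
    diag(A) <- 0
    tom <- topological_overlap(A)
    expect_lt(max(abs(tom - brute_tom(A))), 1e-10)
    expect_true(isSymmetric(tom))
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_true(all(diag(tom) == 1))
  }
  bad <- matrix(runif(9), 3); diag(bad) <- 0
  expect_error(topological_overlap(bad), "symmetric")
  A1 <- diag(3)
  expect_error(topological_overlap(A1), "zero diagonal")
})

test_that("module detection recovers planted blocks exactly", {
  n <- 60
  tom <- matrix(0.05, n, n)
  tom[1:30, 1:30] <- 0.8
  tom[31:60, 31:60] <- 0.8
  diag(tom) <- 1
  rownames(tom) <- colnames(tom) <- paste0("g", 1:n)
  mods <- detect_modules(tom, min_size = 10)
  expect_equal(length(unique(mods)), 2L)
  expect_equal(length(unique(mods[1:30])), 1L)
  expect_equal(length(unique(mods[31:60])), 1L)
  expect_false(mods[1] == mods[31])
  # no structure: everything merges into one module
  flat <- matrix(0.5, n, n); diag(flat) <- 1
  rownames(flat) <- colnames(flat) <- paste0("g", 1:n)
  expect_equal(length(unique(detect_modules(flat, min_size = 10))), 1L)
  expect_warning(m0 <- detect_modules(flat, min_size = 100),
                 "min_size")
  expect_true(all(m0 == "M0"))
  expect_error(detect_modules(flat, min_size = 1), "min_size")
})

test_that("module labels are ordered by decreasing size", {
  n <- 50
  tom <- matrix(0.02, n, n)
  tom[1:15, 1:15] <- 0.9
  tom[16:50, 16:50] <- 0.9
  diag(tom) <- 1
  rownames(tom) <- colnames(tom) <- paste0("g", 1:n)
  mods <- detect_modules(tom, min_size = 5)
  expect_equal(unname(mods[20]), "M1")   # the 35-gene block is M1
  expect_equal(unname(mods[1]), "M2")
})

test_that("eigengenes summarize modules and resist duplication/reordering", {
  set.seed(231)
  shared <- rnorm(40)
  expr <- rbind(g1 = 3 * shared + 2, g2 = shared - 1, g3 = 0.5 * shared)
  colnames(expr) <- paste0("s", 1:40)
  mods <- setNames(rep("M1", 3), rownames(expr))
  me <- module_eigengenes(expr, mods)
  expect_equal(sum(me["M1", ]^2), 1, tolerance = 1e-10)
  zs <- scale(shared)[, 1]
  expect_equal(unname(me["M1", ]), zs / sqrt(sum(zs^2)), tolerance = 1e-10)
  # duplicating a member leaves the eigengene unchanged
  expr2 <- rbind(expr, g4 = expr["g2", ])
  mods2 <- setNames(rep("M1", 4), rownames(expr2))
  me2 <- module_eigengenes(expr2, mods2)
  expect_equal(me2["M1", ], me["M1", ], tolerance = 1e-10)
  # sample reordering permutes the eigengene consistently
  perm <- sample(ncol(expr))
  me3 <- module_eigengenes(expr[, perm], mods)
  expect_equal(unname(me3["M1", ]), unname(me["M1", perm]), tolerance = 1e-10)
  # gene reordering within the module has no effect
  me4 <- module_eigengenes(expr[c(3, 1, 2), ], mods)
  expect_equal(me4["M1", ], me["M1", ], tolerance = 1e-10)
  # constant module is degenerate
  const <- matrix(1, 2, 5, dimnames = list(c("a", "b"), paste0("s", 1:5)))
  expect_error(module_eigengenes(const, setNames(c("M1", "M1"), c("a", "b"))),
               "constant")
})

test_that("eigengene recovers the latent factor at the stated noise level", {
  sx <- synth_coexpression(n_modules = 1, genes_per_module = 50,
                           n_samples = 100, noise_sd = 0.5, seed = 241)
  mods <- setNames(rep("M1", nrow(sx$expr)), rownames(sx$expr))
  me <- module_eigengenes(sx$expr, mods)
  expect_gte(abs(cor(me["M1", ], sx$truth$factors["F1", ])), 0.95)
})

test_that("module-trait correlation matches cor.test and a permutation null", {
  set.seed(251)
  n <- 30
  me <- matrix(rnorm(2 * n), 2, n,
               dimnames = list(c("M1", "M2"), paste0("s", 1:n)))
  traits <- data.frame(sample_id = paste0("s", 1:n),
                       disease = rbinom(n, 1, 0.5),
                       stage = sample(0:4, n, TRUE),
                       survival_days = ifelse(runif(n) < 0.3, NA,
                                              rexp(n, 1 / 500)))
  res <- module_trait_correlation(me, traits)
  for (i in seq_len(nrow(res))) {
    y <- traits[[res$trait[i]]]
    ok <- !is.na(y)
    ct <- cor.test(me[res$module[i], ok], y[ok])
    expect_equal(res$r[i], unname(ct$estimate), tolerance = 1e-10)
    expect_equal(res$p[i], ct$p.value, tolerance = 1e-8)
    expect_equal(res$n[i], sum(ok))
  }
  # self-correlation and exact-zero cases
  me_id <- rbind(M1 = traits$stage)
  colnames(me_id) <- traits$sample_id
  r1 <- module_trait_correlation(me_id, traits)
  expect_equal(r1$r[r1$trait == "stage"], 1)
  me0 <- rbind(M1 = c(1, 1, -1, -1))
  colnames(me0) <- paste0("s", 1:4)
  t0 <- data.frame(sample_id = paste0("s", 1:4), x = c(1, -1, -1, 1))
  r0 <- module_trait_correlation(me0, t0)
  expect_equal(r0$r, 0)
  expect_equal(r0$p, 1)
  # constant trait is reported missing with a warning
  tc <- data.frame(sample_id = paste0("s", 1:4), x = rep(2, 4))
  expect_warning(rc <- module_trait_correlation(me0, tc), "constant")
  expect_true(is.na(rc$r))
})

test_that("t-transform p-value agrees with a permutation oracle", {
  set.seed(261)
  n <- 20
  f <- rnorm(n)
  y <- 0.6 * f + rnorm(n, sd = 0.8)
  me <- rbind(M1 = f)
  colnames(me) <- paste0("s", 1:n)
  traits <- data.frame(sample_id = paste0("s", 1:n), y = y)
  res <- module_trait_correlation(me, traits)
  r_obs <- abs(res$r[1])
  n_perm <- 40000
  perm <- replicate(n_perm, abs(cor(f, sample(y))))
  p_perm <- (1 + sum(perm >= r_obs)) / (1 + n_perm)
  mc_err <- 4 * sqrt(p_perm * (1 - p_perm) / n_perm)
  expect_lt(abs(res$p[1] - p_perm), mc_err + 0.005)
})

test_that("hypergeometric enrichment equals exact tail enumeration", {
  expect_equal(hyper_tail_p(3, 4, 10, 5), 66 / 252, tolerance = 1e-12)
  expect_equal(hyper_tail_p(0, 4, 10, 5), 1)
  expect_equal(hyper_tail_p(5, 5, 5, 5), 1)  # saturated draw
  for (U in c(6, 10, 15)) {
    for (K in 1:U) {
      for (n in 1:U) {
        for (q in 0:min(K, n)) {
          expect_equal(hyper_tail_p(q, K, U, n), enum_hyper_tail(q, K, U, n),
                       tolerance = 1e-12)
        }
      }
    }
  }
  expect_error(hyper_tail_p(6, 5, 10, 5), "overlap")
})

test_that("module enrichment flags the pathway concentrated in a module", {
  sm <- synth_model(n_genes = 60, n_metabolites = 30, n_pathways = 3,
                    k_range = c(3, 5), mixing = 0, seed = 271)
  truth_block <- sm$truth$gene_block
  modules <- setNames(ifelse(truth_block == 1, "M1", "M0"),
                      names(truth_block))
  res <- module_pathway_enrichment(modules, sm$model)
  res1 <- res[res$module == "M1", ]
  expect_equal(res1$pathway[which.min(res1$p)], "P01")
  expect_true(all(res$overlap <= pmin(res$module_size, res$pathway_size)))
  expect_true(all(res$p > 0 & res$p <= 1))
})
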