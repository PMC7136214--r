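# Independent brute-force oracles used to validate the package's statistics.

# exact background of the set score over all C(N, k) subsets
enum_background <- function(pool, k) {
  sets <- utils::combn(length(pool), k)
  scores <- apply(sets, 2, function(i) sum(pool[i]) / sqrt(k))
  mu <- mean(scores)
  list(mu = mu, sigma = sqrt(mean((scores - mu)^2)), scores = scores)
}

# step-up FDR adjustment written out longhand
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# triple-loop topological overlap
brute_tom <- function(A) {
  n <- nrow(A)
  k <- rowSums(A)
  tom <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      s <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) s <- s + A[i, u] * A[u, j]
      }
      tom[i, j] <- (s + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
    }
  }
  dimnames(tom) <- dimnames(A)
  tom
}

# exact hypergeometric upper tail by direct summation of the pmf
enum_hyper_tail <- function(q, K, U, n) {
  i <- q:min(n, K)
  sum(choose(K, i) * choose(U - K, n - i)) / choose(U, n)
}

# small handmade model shared across tests
tiny_model <- function() {
  metabolic_model(
    genes = c("g1", "g2", "g3", "g4"),
    metabolites = data.frame(id = c("m1_c", "m2_m", "m3_s"),
                             compartment = c("c", "m", "s")),
    reactions = list(
      list(id = "r1", genes = c("g1", "g2"), metabolites = "m1_c",
           pathway = "PW_A"),
      list(id = "r2", genes = "g3", metabolites = c("m1_c", "m2_m"),
           pathway = "PW_A"),
      list(id = "r3", genes = c("g3", "g4"), metabolites = "m3_s",
           pathway = "PW_B")))
}
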