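# Shared fixtures and independent oracles for the test suite. Everything
# is generated in code; no stored data.

# smaller grids than the defaults: fast, adequate for the small fixtures
quick_ctrl <- function(...) {
  dagmm_control(nlambda1 = 25L, nlambda2 = 25L, lambda_min_ratio = 1e-5, ...)
}

# all permutations of 1..k (k <= 7), as a list of integer vectors
all_perms <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (sub in all_perms(k - 1L)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(sub, k, after = pos - 1L)
    }
  }
  out
}

# independent acyclicity oracle: a directed graph is acyclic iff some
# vertex ordering places every parent before its child
brute_force_acyclic <- function(support, p) {
  if (NROW(support) == 0L) return(TRUE)
  for (perm in all_perms(p)) {
    pos <- order(perm)  # pos[v] = position of vertex v
    if (all(pos[support[, 2L]] < pos[support[, 1L]])) return(TRUE)
  }
  FALSE
}

# random directed graph (child, parent), possibly cyclic, no self-loops
random_digraph <- function(p, n_edges, seed) {
  set.seed(seed)
  all_pairs <- expand.grid(child = seq_len(p), parent = seq_len(p))
  all_pairs <- all_pairs[all_pairs$child != all_pairs$parent, ]
  idx <- sample.int(nrow(all_pairs), min(n_edges, nrow(all_pairs)))
  as.matrix(all_pairs[idx, ])
}

# random DAG support: orient random pairs along a random permutation
random_dag_support <- function(p, n_edges, seed) {
  g <- random_digraph(p, n_edges, seed)
  set.seed(seed + 1L)
  ord <- sample.int(p)
  pos <- order(ord)
  flip <- pos[g[, 2L]] > pos[g[, 1L]]
  tmp <- g[flip, 1L]
  g[flip, 1L] <- g[flip, 2L]
  g[flip, 2L] <- tmp
  unique(g)
}

# a two-node truth with heterogeneous covariate effects (2 -> 1)
two_node_truth <- function(n, seed, beta = c(1.0, -0.8, 0.6), sigma2 = 0.4) {
  make_truth(p = 2, edges = cbind(1L, 2L), beta = list(beta),
             sigma2 = sigma2, error_vars = c(1.0, 0.5),
             covariate_spec = c("normal", "normal", "bernoulli"),
             n = n, seed = seed)
}

# Eq-style node objective computed directly in R (independent of the
# package's own evaluator): parents pa, beta d x k, sigma2 k
node_objective_direct <- function(M, X, j, pa, beta, sigma2, ev) {
  y <- M[, j]
  if (length(pa) == 0L) return(sum(y^2) / ev + length(y) * log(ev))
  Mp <- M[, pa, drop = FALSE]
  r <- y - rowSums((X %*% beta) * Mp)
  w <- drop(Mp^2 %*% sigma2) + ev
  sum(r^2 / w + log(w))
}
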