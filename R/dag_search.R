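# Stages 2-3 of DAG-MM: edge orientation by relative strength and
# iterative hard-thresholding with acyclicity checking and BIC selection.

#' Strength of a directed edge
#'
#' The pruning criterion of the DAG search: the average squared
#' fixed-effect coefficient plus the random-effect variance,
#' `sum(beta^2) / d_norm + sigma2`.
#'
#' @param beta Numeric fixed-effect vector of the edge.
#' @param sigma2 Random-effect variance of the edge.
#' @param d_norm Divisor for the squared-norm term; defaults to the length
#'   of `beta` so the term is an average squared coefficient whether or not
#'   an intercept column is present.
#' @return A non-negative number.
#' @examples
#' edge_strength(c(-0.5, 1, -1.5), 0.5)  # 3.5/3 + 0.5
#' @export
edge_strength <- function(beta, sigma2, d_norm = length(beta)) {
  stopifnot(d_norm >= 1)
  sum(beta^2) / d_norm + sigma2
}

# Internal: strengths for every support edge of a model; returns a data
# frame (child, parent, strength) in support order.
edge_strengths <- function(fit) {
  sup <- fit$support
  if (NROW(sup) == 0L)
    return(data.frame(child = integer(0), parent = integer(0),
                      strength = numeric(0)))
  s <- numeric(nrow(sup))
  for (i in seq_len(nrow(sup))) {
    j <- sup[i, 1L]; k <- sup[i, 2L]
    t <- match(k, fit$parents[[j]])
    s[i] <- edge_strength(fit$beta[[j]][, t], fit$sigma2[[j]][t])
  }
  data.frame(child = sup[, 1L], parent = sup[, 2L], strength = s)
}

#' Check a directed graph for acyclicity
#'
#' Kahn's algorithm on the `parent -> child` digraph: vertices without
#' remaining parents are peeled off iteratively. Acyclic graphs yield a
#' topological order (parents before children); otherwise a witnessing
#' directed cycle is extracted from the residual graph.
#'
#' @param support Integer matrix with columns `(child, parent)`; no
#'   self-loops.
#' @param p Number of nodes.
#' @return List with `acyclic` (logical), `order` (topological order of all
#'   p nodes, or `NULL`), `cycle` (vertex sequence of a directed cycle, or
#'   `NULL`).
#' @examples
#' is_dag(rbind(c(1, 2), c(2, 1)), 2)$acyclic
#' @export
is_dag <- function(support, p) {
  support <- as_support(support)
  check_support(support, p)
  if (nrow(support) == 0L)
    return(list(acyclic = TRUE, order = seq_len(p), cycle = NULL))
  # indeg[j]: number of (unprocessed) parents of j
  indeg <- tabulate(support[, 1L], nbins = p)
  children <- split(support[, 1L], factor(support[, 2L], levels = seq_len(p)))
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) == p)
    return(list(acyclic = TRUE, order = ord, cycle = NULL))
  # extract a cycle from the residual graph by walking parent pointers
  remaining <- setdiff(seq_len(p), ord)
  par_of <- function(v) {
    pa <- support[support[, 1L] == v, 2L]
    intersect(pa, remaining)[1L]
  }
  path <- remaining[1L]
  repeat {
    nxt <- par_of(path[length(path)])
    if (nxt %in% path) {
      start <- match(nxt, path)
      cycle <- rev(path[start:length(path)])
      break
    }
    path <- c(path, nxt)
  }
  list(acyclic = FALSE, order = NULL, cycle = cycle)
}

#' Orient bidirected skeleton edges by relative strength
#'
#' While the support contains any pair present in both directions, computes
#' the strength ratio `r_jk = c_jk / c_kj` for every such directed edge,
#' removes the single direction with the smallest ratio (ties broken by
#' smallest `(child, parent)`), and refits the affected child node.
#'
#' @param fit A `dagmm_model` refit on the skeleton support.
#' @param M,X Node and covariate matrices.
#' @param control A [dagmm_control()] object.
#' @return The model with no bidirected pairs remaining.
#' @examples
#' truth <- make_setting(1, n = 200, p = 15, seed = 3)
#' dat <- simulate_data(truth)
#' sk <- initial_skeleton(dat$M, dat$X,
#'                        dagmm_control(nlambda1 = 10, nlambda2 = 10))
#' or <- orient_edges(sk$fit, dat$M, dat$X)
#' @export
orient_edges <- function(fit, M, X, control = dagmm_control()) {
  repeat {
    sup <- fit$support
    if (nrow(sup) == 0L) break
    key <- paste(sup[, 1L], sup[, 2L])
    rev_key <- paste(sup[, 2L], sup[, 1L])
    bid <- which(rev_key %in% key)
    if (length(bid) == 0L) break
    es <- edge_strengths(fit)
    strength_of <- structure(es$strength, names = paste(es$child, es$parent))
    ratio <- strength_of[key[bid]] /
      pmax(strength_of[rev_key[bid]], .Machine$double.xmin)
    cand <- data.frame(child = sup[bid, 1L], parent = sup[bid, 2L],
                       ratio = as.numeric(ratio))
    cand <- cand[order(cand$ratio, cand$child, cand$parent), , drop = FALSE]
    j <- cand$child[1L]; k <- cand$parent[1L]
    if (control$verbose)
      message(sprintf("orienting: dropping %d -> %d (ratio %.3g)",
                      k, j, cand$ratio[1L]))
    fit <- refit_node_in_model(fit, j, setdiff(fit$parents[[j]], k),
                               M, X, control)
  }
  fit
}

#' Iterative DAG building by hard-thresholding
#'
#' Starting from an oriented support, repeatedly records the current model
#' (computing BIC whenever the support is acyclic), removes the edge with
#' the smallest strength (ties broken by smallest `(child, parent)`), and
#' refits the affected child node. The search is deletion-only and ends at
#' the empty graph, which is always a DAG, so at least one candidate DAG is
#' recorded. Returns the recorded DAG with minimum BIC.
#'
#' @param fit A `dagmm_model` with no bidirected pairs.
#' @param M,X Node and covariate matrices.
#' @param control A [dagmm_control()] object.
#' @return List with `fit` (BIC-optimal DAG model), `trace` (class
#'   `dagmm_trace`: one row per visited support with edge count, nll,
#'   n_params, bic (NA when cyclic) and an acyclicity flag, plus the
#'   visited supports as an attribute), and `best_index` into the trace.
#' @export
build_dag <- function(fit, M, X, control = dagmm_control()) {
  p <- fit$p; n <- nrow(M)
  snapshots <- list(); supports <- list()
  best <- NULL; best_index <- NA_integer_
  max_steps <- p * (p - 1L) + 1L
  step <- 0L
  repeat {
    step <- step + 1L
    if (step > max_steps)
      stop("internal error: DAG search exceeded the maximum step count")
    chk <- is_dag(fit$support, p)
    bicv <- if (chk$acyclic) dagmm_bic(fit, n) else NA_real_
    snapshots[[step]] <- data.frame(
      n_edges = NROW(fit$support), nll = fit$nll,
      n_params = fit$n_params, bic = bicv, is_dag = chk$acyclic)
    supports[[step]] <- fit$support
    if (chk$acyclic && (is.null(best) || bicv < best$bic)) {
      best <- list(fit = fit, bic = bicv)
      best_index <- step
    }
    if (NROW(fit$support) == 0L) break
    es <- edge_strengths(fit)
    es <- es[order(es$strength, es$child, es$parent), , drop = FALSE]
    j <- es$child[1L]; k <- es$parent[1L]
    if (control$verbose)
      message(sprintf("pruning: dropping %d -> %d (strength %.3g)",
                      k, j, es$strength[1L]))
    fit <- refit_node_in_model(fit, j, setdiff(fit$parents[[j]], k),
                               M, X, control)
  }
  trace <- do.call(rbind, snapshots)
  attr(trace, "supports") <- supports
  attr(trace, "best_index") <- best_index
  class(trace) <- c("dagmm_trace", class(trace))
  list(fit = best$fit, trace = trace, best_index = best_index)
}

#' Fit a subject-specific DAG with DAG-MM
#'
#' The full three-step procedure: penalized sparse skeleton
#' ([initial_skeleton()]), orientation of bidirected pairs by relative
#' strength ([orient_edges()]), then iterative hard-thresholding with
#' acyclicity checking and BIC selection ([build_dag()]). The result is
#' always a DAG whose support is contained in the initial skeleton.
#'
#' @param M Node matrix (n subjects x p nodes), assumed centered.
#' @param X Covariate matrix (n x d); prepend an intercept column with
#'   [covariate_matrix()] if a covariate-free baseline effect is wanted.
#' @param control A [dagmm_control()] object.
#' @return An object of class `dagmm`: list with `fit` (the selected
#'   `dagmm_model`), `trace`, `skeleton`, `lambda1`, `lambda2`.
#' @examples
#' truth <- make_setting(1, n = 200, p = 15, seed = 11)
#' dat <- simulate_data(truth)
#' res <- dagmm_fit(dat$M, dat$X,
#'                  dagmm_control(nlambda1 = 10, nlambda2 = 10))
#' res$fit$support
#' @export
dagmm_fit <- function(M, X, control = dagmm_control()) {
  M <- node_matrix(M)
  X <- covariate_matrix(X)
  check_data_pair(M, X)
  sk <- initial_skeleton(M, X, control)
  oriented <- orient_edges(sk$fit, M, X, control)
  bd <- build_dag(oriented, M, X, control)
  structure(list(fit = bd$fit, trace = bd$trace,
                 best_index = bd$best_index, skeleton = sk,
                 oriented_support = oriented$support,
                 lambda1 = sk$lambda1, lambda2 = sk$lambda2),
            class = "dagmm")
}

#' @export
print.dagmm <- function(x, ...) {
  cat("DAG-MM fit\n")
  cat("  skeleton edges:", NROW(x$skeleton$support),
      " oriented:", NROW(x$oriented_support),
      " selected DAG:", NROW(x$fit$support), "edges\n")
  cat(sprintf("  BIC: %.4f  (lambda1 = %.4g, lambda2 = %.4g)\n",
              x$fit$bic, x$lambda1, x$lambda2))
  invisible(x)
}

#' Number of possible directed edges among p nodes
#'
#' @param p Number of nodes.
#' @return `p * (p - 1)`.
#' @examples
#' n_possible_edges(100)  # 9900
#' @export
n_possible_edges <- function(p) as.integer(p) * (as.integer(p) - 1L)
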