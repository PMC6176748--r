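# Synthetic benchmark generator: heterogeneous-network data from known
# mixed-effects SEM truths, including the five standard benchmark settings
# on a fixed 12-edge DAG.

#' The fixed 12-edge benchmark truth graph
#'
#' Ordered `(child, parent)` pairs of the benchmark DAG used by the five
#' simulation settings; nodes beyond 15 are independent noise.
#'
#' @return A 12 x 2 integer matrix with columns `child`, `parent`.
#' @examples
#' nrow(truth_graph12())
#' @export
truth_graph12 <- function() {
  e <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(4, 5), c(6, 7),
             c(7, 8), c(8, 9), c(8, 10), c(11, 12), c(12, 13), c(14, 15))
  storage.mode(e) <- "integer"
  colnames(e) <- c("child", "parent")
  e
}

#' Construct an arbitrary simulation truth
#'
#' @param p Number of nodes.
#' @param edges Integer matrix `(child, parent)`; must be acyclic.
#' @param beta List of fixed-effect vectors (length d), one per edge row.
#' @param sigma2 Random-effect variances, one per edge row.
#' @param error_vars Length-p positive error variances.
#' @param covariate_spec Character vector of per-covariate distribution
#'   tags: `"normal"` (standard normal), `"bernoulli"` (Bernoulli(0.5)),
#'   `"constant"` (all ones, an intercept).
#' @param n Number of subjects to generate.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return An object of class `dagmm_truth`.
#' @examples
#' tr <- make_truth(2, cbind(1L, 2L), list(c(1, -1)), 0.3, c(1, 0.5),
#'                  c("normal", "bernoulli"), n = 100, seed = 1)
#' tr$p
#' @export
make_truth <- function(p, edges, beta, sigma2, error_vars, covariate_spec,
                       n, seed) {
  edges <- as_support(edges)
  check_support(edges, p)
  chk <- is_dag(edges, p)
  if (!chk$acyclic) stop("truth edge set contains a directed cycle")
  d <- length(covariate_spec)
  if (!all(covariate_spec %in% c("normal", "bernoulli", "constant")))
    stop("unknown covariate_spec tag")
  if (length(beta) != NROW(edges) || length(sigma2) != NROW(edges))
    stop("beta and sigma2 must have one entry per edge")
  if (!all(vapply(beta, length, 0L) == d))
    stop("every beta vector must match the covariate dimension")
  if (length(error_vars) != p || any(error_vars <= 0))
    stop("error_vars must be p positive values")
  if (any(sigma2 < 0)) stop("sigma2 must be non-negative")
  structure(list(p = as.integer(p), d = d, n = as.integer(n),
                 edges = edges, beta = beta, sigma2 = as.numeric(sigma2),
                 error_vars = as.numeric(error_vars),
                 covariate_spec = covariate_spec,
                 seed = as.integer(seed)),
            class = "dagmm_truth")
}

#' Benchmark simulation settings on the 12-edge truth graph
#'
#' Builds the truth object for one of five benchmark designs on the
#' 12-edge DAG of [truth_graph12()]. Settings 1-4 use three covariates
#' (two standard normal, one Bernoulli(0.5)) and no intercept column;
#' Setting 5 prepends a constant column and puts all effect in it. Error
#' variances alternate 1.0 (odd nodes) / 0.5 (even nodes). Edge effects:
#' \describe{
#'   \item{1 (fixed only)}{`beta = (-0.5, 1.0, -1.5)`, `sigma2 = 0`.}
#'   \item{2 (random only)}{`beta = 0`, `sigma2 = 0.5`.}
#'   \item{3 (mixed 1)}{`beta = (-0.5, 1.0, -1.5)` and `sigma2 = 0.5`.}
#'   \item{4 (mixed 2)}{fixed effects on one 8-edge subset, random-effect
#'     variances on another 8-edge subset (union = all 12 edges).}
#'   \item{5 (homogeneous)}{intercept-only effects of +1 or -1 on two
#'     6-edge subsets; no covariate or random effects.}
#' }
#'
#' @param setting Integer 1-5.
#' @param n Number of subjects.
#' @param p Number of nodes (>= 15; nodes beyond 15 are independent noise).
#' @param seed Integer seed.
#' @return A `dagmm_truth` object.
#' @examples
#' tr <- make_setting(3, n = 100, p = 20, seed = 1)
#' tr$sigma2
#' @export
make_setting <- function(setting, n, p, seed) {
  setting <- as.integer(setting)
  if (!setting %in% 1:5) stop("setting must be in 1..5")
  if (p < 15) stop("p must be at least 15 (the truth graph uses nodes 1-15)")
  edges <- truth_graph12()
  m <- nrow(edges)
  key <- paste(edges[, 1L], edges[, 2L])
  error_vars <- ifelse(seq_len(p) %% 2 == 1, 1.0, 0.5)
  if (setting == 5L) {
    spec <- c("constant", "normal", "normal", "bernoulli")
    plus <- paste(c(1, 1, 4, 7, 8, 12), c(2, 4, 5, 8, 10, 13))
    minus <- paste(c(1, 2, 6, 8, 11, 14), c(3, 3, 7, 9, 12, 15))
    beta <- lapply(key, function(k)
      c(if (k %in% plus) 1 else if (k %in% minus) -1 else 0, 0, 0, 0))
    sigma2 <- rep(0, m)
  } else {
    spec <- c("normal", "normal", "bernoulli")
    b_full <- c(-0.5, 1.0, -1.5)
    if (setting == 1L) {
      beta <- rep(list(b_full), m); sigma2 <- rep(0, m)
    } else if (setting == 2L) {
      beta <- rep(list(c(0, 0, 0)), m); sigma2 <- rep(0.5, m)
    } else if (setting == 3L) {
      beta <- rep(list(b_full), m); sigma2 <- rep(0.5, m)
    } else {
      fixed <- paste(c(1, 1, 4, 7, 8, 11, 12, 14),
                     c(2, 4, 5, 8, 10, 12, 13, 15))
      random <- paste(c(1, 1, 1, 2, 6, 8, 8, 12),
                      c(2, 3, 4, 3, 7, 9, 10, 13))
      beta <- lapply(key, function(k)
        if (k %in% fixed) b_full else c(0, 0, 0))
      sigma2 <- ifelse(key %in% random, 0.5, 0)
    }
  }
  make_truth(p, edges, beta, sigma2, error_vars, spec, n, seed)
}

#' Generate data from a simulation truth
#'
#' Draws covariates per their distribution tags, then generates nodes in a
#' topological order of the truth DAG: each child equals the sum over its
#' parents of `(beta' x_i + gamma_ijk) * m_ik` plus Gaussian error, with
#' `gamma_ijk ~ N(0, sigma2_jk)` drawn independently per subject and edge.
#' Nodes outside the truth subgraph are independent Gaussian noise.
#' Fully reproducible from `truth$seed`.
#'
#' @param truth A `dagmm_truth` object.
#' @param return_latent Logical; also return the random-effect draws
#'   (`gamma`, one n-vector per edge) and error draws (`eps`).
#' @return List with `M` (node matrix) and `X` (covariate matrix); with
#'   `return_latent`, also `gamma` and `eps`.
#' @examples
#' dat <- simulate_data(make_setting(1, n = 50, p = 15, seed = 2))
#' dim(dat$M)
#' @export
simulate_data <- function(truth, return_latent = FALSE) {
  stopifnot(inherits(truth, "dagmm_truth"))
  set.seed(truth$seed)
  n <- truth$n; p <- truth$p; d <- truth$d
  X <- vapply(truth$covariate_spec, function(tag)
    switch(tag,
           normal = rnorm(n),
           bernoulli = as.numeric(rbinom(n, 1L, 0.5)),
           constant = rep(1, n)),
    numeric(n))
  X <- matrix(X, nrow = n, ncol = d)
  colnames(X) <- names_for_spec(truth$covariate_spec)
  ord <- is_dag(truth$edges, p)$order
  M <- matrix(0, n, p)
  colnames(M) <- paste0("M", seq_len(p))
  key <- paste(truth$edges[, 1L], truth$edges[, 2L])
  gamma <- vector("list", nrow(truth$edges))
  names(gamma) <- key
  eps <- matrix(0, n, p)
  for (j in ord) {
    e_j <- rnorm(n, 0, sqrt(truth$error_vars[j]))
    eps[, j] <- e_j
    rows <- which(truth$edges[, 1L] == j)
    val <- e_j
    for (i in rows) {
      k <- truth$edges[i, 2L]
      g <- if (truth$sigma2[i] > 0) rnorm(n, 0, sqrt(truth$sigma2[i]))
           else rep(0, n)
      gamma[[i]] <- g
      val <- val + (drop(X %*% truth$beta[[i]]) + g) * M[, k]
    }
    M[, j] <- val
  }
  out <- list(M = M, X = structure(X, has_intercept =
                                     truth$covariate_spec[1] == "constant"))
  if (return_latent) {
    out$gamma <- gamma
    out$eps <- eps
  }
  out
}

names_for_spec <- function(spec) {
  nm <- character(length(spec))
  ix <- 0L
  for (i in seq_along(spec)) {
    if (spec[i] == "constant") nm[i] <- "intercept"
    else { ix <- ix + 1L; nm[i] <- paste0("X", ix) }
  }
  nm
}

#' Run a simulation study over settings, sample sizes and node counts
#'
#' For each `(setting, n, p)` cell, generates `replicates` independent data
#' sets, runs the full DAG-MM procedure on each, scores the selected graph
#' and parameters against the generating truth, and averages. Per-replicate
#' seeds are spawned from the master seed, so results are reproducible.
#'
#' @param settings Integer vector of benchmark settings (1-5).
#' @param n_list,p_list Sample sizes and node counts to cross.
#' @param replicates Replicates per cell.
#' @param seed Master seed.
#' @param control A [dagmm_control()] object.
#' @param verbose Print per-cell progress.
#' @return A data frame of class `dagmm_study`, one row per cell, with
#'   means and Monte-Carlo standard errors of TP/FP/FN counts and the three
#'   RSS error metrics, and the per-replicate results as attribute
#'   `"details"`.
#' @examples
#' \donttest{
#' tab <- run_study(1, n_list = 200, p_list = 15, replicates = 2, seed = 1)
#' tab$tp_mean
#' }
#' @export
run_study <- function(settings, n_list, p_list, replicates = 100L,
                      seed = 1L, control = dagmm_control(),
                      verbose = FALSE) {
  stopifnot(replicates >= 1)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, replicates)
  cells <- expand.grid(setting = settings, n = n_list, p = p_list,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- list(); details <- list()
  for (ci in seq_len(nrow(cells))) {
    s <- cells$setting[ci]; n <- cells$n[ci]; p <- cells$p[ci]
    res <- vector("list", replicates)
    for (r in seq_len(replicates)) {
      res[[r]] <- tryCatch({
        truth <- make_setting(s, n = n, p = p, seed = rep_seeds[r])
        dat <- simulate_data(truth)
        ans <- dagmm_fit(dat$M, dat$X, control)
        conf <- edge_confusion(ans$fit$support, truth)
        rss <- rss_metrics(ans$fit, truth)
        data.frame(setting = s, n = n, p = p, replicate = r,
                   tp = conf$tp, fp = conf$fp, fn = conf$fn,
                   rss_beta = rss$rss_beta, rss_sigma2 = rss$rss_sigma2,
                   rss_error = rss$rss_error)
      }, error = function(e) {
        warning(sprintf("replicate %d of cell (setting %d, n %d, p %d) failed: %s",
                        r, s, n, p, conditionMessage(e)))
        NULL
      })
      if (verbose && r %% 10 == 0)
        message(sprintf("setting %d n=%d p=%d: %d/%d replicates",
                        s, n, p, r, replicates))
    }
    ok <- !vapply(res, is.null, TRUE)
    det <- do.call(rbind, res[ok])
    details[[ci]] <- det
    mstat <- function(v) c(mean(v), if (sum(ok) > 1) sd(v) / sqrt(sum(ok)) else NA_real_)
    stats <- vapply(det[, c("tp", "fp", "fn", "rss_beta", "rss_sigma2",
                            "rss_error")], mstat, numeric(2))
    rows[[ci]] <- data.frame(
      setting = s, n = n, p = p, replicates = sum(ok),
      failed = replicates - sum(ok),
      tp_mean = stats[1, "tp"], tp_se = stats[2, "tp"],
      fp_mean = stats[1, "fp"], fp_se = stats[2, "fp"],
      fn_mean = stats[1, "fn"], fn_se = stats[2, "fn"],
      rss_beta_mean = stats[1, "rss_beta"], rss_beta_se = stats[2, "rss_beta"],
      rss_sigma2_mean = stats[1, "rss_sigma2"],
      rss_sigma2_se = stats[2, "rss_sigma2"],
      rss_error_mean = stats[1, "rss_error"],
      rss_error_se = stats[2, "rss_error"])
    if (verbose)
      message(sprintf("setting %d n=%d p=%d done: TP %.2f FP %.2f FN %.2f",
                      s, n, p, stats[1, "tp"], stats[1, "fp"], stats[1, "fn"]))
  }
  out <- do.call(rbind, rows)
  attr(out, "details") <- do.call(rbind, details)
  class(out) <- c("dagmm_study", class(out))
  out
}
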