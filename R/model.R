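#' Construct a mixed-effects SEM model fit object
#'
#' Assembles the parameters of a mixed-effects structural equation model on a
#' given graph support into the object used throughout the package. Each
#' directed edge `parent -> child` (stored as an ordered `(child, parent)`
#' pair) carries a fixed-effect coefficient vector `beta` of length d (one
#' entry per covariate column) and a random-effect variance `sigma2 >= 0`;
#' each node carries an error variance.
#'
#' @param support Integer matrix with columns `child`, `parent`.
#' @param beta List of numeric vectors (length d), one per support row.
#' @param sigma2 Numeric vector of random-effect variances, one per support
#'   row.
#' @param error_vars Numeric vector of p positive error variances.
#' @param d Number of covariate columns the betas refer to.
#' @param node_names,covariate_names Optional identifiers.
#' @return An object of class `dagmm_model`.
#' @examples
#' fit <- model_fit(cbind(child = 1L, parent = 2L),
#'                  beta = list(c(0.5, -1)), sigma2 = 0.25,
#'                  error_vars = c(1, 1), d = 2)
#' fit$parents
#' @export
model_fit <- function(support, beta, sigma2, error_vars, d,
                      node_names = NULL, covariate_names = NULL) {
  p <- length(error_vars)
  support <- as_support(support)
  check_support(support, p)
  m <- NROW(support)
  if (length(beta) != m || length(sigma2) != m)
    stop("beta and sigma2 must have one entry per support edge")
  if (any(sigma2 < 0)) stop("sigma2 must be non-negative")
  if (any(error_vars <= 0)) stop("error variances must be positive")
  parents <- rep(list(integer(0)), p)
  beta_m <- lapply(seq_len(p), function(j) matrix(0, d, 0))
  sig_m <- rep(list(numeric(0)), p)
  if (m > 0L) {
    for (i in seq_len(m)) {
      j <- support[i, 1L]; k <- support[i, 2L]
      bv <- as.numeric(beta[[i]])
      if (length(bv) != d) stop("each beta vector must have length d")
      parents[[j]] <- c(parents[[j]], k)
      beta_m[[j]] <- cbind(beta_m[[j]], bv)
      sig_m[[j]] <- c(sig_m[[j]], sigma2[i])
    }
    for (j in seq_len(p)) {
      o <- order(parents[[j]])
      parents[[j]] <- as.integer(parents[[j]][o])
      beta_m[[j]] <- beta_m[[j]][, o, drop = FALSE]
      dimnames(beta_m[[j]]) <- NULL
      sig_m[[j]] <- unname(sig_m[[j]][o])
    }
  }
  new_dagmm_model(parents, beta_m, sig_m, error_vars, node_nll = NULL,
                  d = d, n = NA_integer_, node_names = node_names,
                  covariate_names = covariate_names)
}

# Internal constructor from per-node pieces.
new_dagmm_model <- function(parents, beta, sigma2, error_vars, node_nll,
                            d, n, node_names = NULL, covariate_names = NULL) {
  p <- length(parents)
  support <- support_from_parents(parents)
  n_edges <- NROW(support)
  n_params <- n_edges * d + n_edges + p
  nll <- if (is.null(node_nll)) NA_real_ else sum(node_nll)
  fit <- structure(list(
    p = p, d = d, n = n,
    node_names = node_names %||% paste0("M", seq_len(p)),
    covariate_names = covariate_names %||% paste0("X", seq_len(d)),
    parents = parents, beta = beta, sigma2 = sigma2,
    error_vars = as.numeric(error_vars),
    node_nll = node_nll, nll = nll, n_params = n_params,
    support = support), class = "dagmm_model")
  fit$bic <- if (!is.na(nll) && !is.na(n)) dagmm_bic(fit, n) else NA_real_
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_support <- function(support) {
  if (NROW(support) == 0L) return(empty_support())
  support <- as.matrix(support)
  storage.mode(support) <- "integer"
  colnames(support) <- c("child", "parent")
  support
}

#' @export
print.dagmm_model <- function(x, ...) {
  cat("Mixed-effects SEM fit:", x$p, "nodes,", NROW(x$support),
      "directed edges,", x$d, "covariate columns\n")
  if (!is.na(x$nll))
    cat(sprintf("  -log-likelihood (constant-free): %.4f  BIC: %.4f  params: %d\n",
                x$nll, x$bic, x$n_params))
  invisible(x)
}

#' Marginal negative log-likelihood of the mixed-effects SEM
#'
#' Evaluates, for data `(M, X)` and a fitted model, the constant-free
#' marginal negative log-likelihood
#' \deqn{\sum_{i,j} \left[ \frac{(M_{ij} - \sum_k (\beta_{jk}'X_i) M_{ik})^2}
#'   {\sum_k \sigma^2_{jk} M_{ik}^2 + \sigma^2_{\epsilon j}} +
#'   \log\left(\sum_k \sigma^2_{jk} M_{ik}^2 + \sigma^2_{\epsilon j}\right)
#'   \right],}
#' where sums over k run over the parents of node j in the fit's support
#' (coefficients outside the support are zero). Additive `2*pi` constants
#' are omitted; see [marginal_density_oracle()] for the exact relation to
#' the integrated density.
#'
#' @param M Node matrix (n x p).
#' @param X Covariate matrix (n x d).
#' @param fit A `dagmm_model`.
#' @return A single number, the summed negative log-likelihood.
#' @examples
#' fit <- model_fit(matrix(integer(0), 0, 2), list(), numeric(0),
#'                  error_vars = c(2), d = 1)
#' m <- matrix(c(1, -1, 0.5), 3, 1)
#' neg_log_likelihood(m, matrix(1, 3, 1), fit)  # sum(m^2/2 + log 2)
#' @export
neg_log_likelihood <- function(M, X, fit) {
  check_data_pair(M, X)
  if (ncol(M) != fit$p) stop("M has wrong number of columns for this fit")
  if (ncol(X) != fit$d) stop("X has wrong number of columns for this fit")
  if (any(fit$error_vars <= 0)) stop("error variances must be positive")
  total <- 0
  for (j in seq_len(fit$p)) {
    total <- total + node_nll_value(M, X, fit, j)
  }
  total
}

# Internal: Eq.-style node term for one node under the fit's parameters.
node_nll_value <- function(M, X, fit, j) {
  pa <- fit$parents[[j]]
  y <- M[, j]
  if (length(pa) == 0L) {
    w <- fit$error_vars[j]
    return(sum(y^2) / w + length(y) * log(w))
  }
  Mp <- M[, pa, drop = FALSE]
  mean_part <- rowSums((X %*% fit$beta[[j]]) * Mp)
  w <- drop(Mp^2 %*% fit$sigma2[[j]]) + fit$error_vars[j]
  r <- y - mean_part
  sum(r^2 / w + log(w))
}

#' Fit one node of the mixed-effects SEM for a fixed parent set
#'
#' Minimises the node's marginal negative log-likelihood term by
#' alternating weighted least squares for the stacked fixed-effect
#' coefficients (weights equal to the inverse conditional variance) with
#' Newton-Raphson updates of the log random-effect and error variances,
#' with backtracking and a variance floor, until the relative change in the
#' node objective falls below `control$rel_tol`.
#'
#' @param j Node index (column of `M`) to fit.
#' @param parents Integer vector of parent node indices (may be empty).
#' @param M,X Node and covariate matrices.
#' @param init Optional warm start: list with elements `beta` (d x k matrix),
#'   `sigma2` (length k), `error_var`.
#' @param control A [dagmm_control()] object.
#' @return List with `beta` (d x k matrix, one column per parent), `sigma2`,
#'   `error_var`, `nll` (minimised node objective), `converged`,
#'   `iterations`.
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(40), 20, 2)
#' f <- fit_node(1, integer(0), m, matrix(rnorm(20), 20, 1))
#' all.equal(f$error_var, mean(m[, 1]^2))
#' @export
fit_node <- function(j, parents, M, X, init = NULL,
                     control = dagmm_control()) {
  check_data_pair(M, X)
  parents <- sort(unique(as.integer(parents)))
  if (j %in% parents) stop("a node cannot be its own parent")
  n <- nrow(M); d <- ncol(X); k <- length(parents)
  if (k > 0L && n <= k * d + k + 1L)
    warning("fewer subjects than free parameters for node ", j,
            "; fit is not identified")
  Mp <- M[, parents, drop = FALSE]
  y <- M[, j]
  if (is.null(init)) {
    beta0 <- rep(0, k * d)
    v <- max(var(y) * (n - 1) / n, control$variance_floor)
    logv0 <- c(rep(log(max(0.1, control$variance_floor)), k), log(v))
  } else {
    beta0 <- as.numeric(init$beta)
    if (length(beta0) != k * d) stop("init beta has wrong dimension")
    logv0 <- log(pmax(c(init$sigma2, init$error_var),
                      control$variance_floor))
  }
  res <- fit_node_cpp(y, Mp, X, beta0, logv0, control$variance_floor,
                      control$rel_tol, control$max_iter)
  if (!res$converged && k > 0L)
    warning("node ", j, " fit did not converge in ", control$max_iter,
            " iterations; returning best iterate")
  res$parents <- parents
  res$sigma2 <- as.numeric(res$sigma2)
  res
}

# Internal: fit every node for a given parents list; returns a dagmm_model.
fit_support_model <- function(M, X, parents, control = dagmm_control(),
                              warm = NULL, node_names = NULL,
                              covariate_names = NULL) {
  p <- ncol(M); d <- ncol(X)
  beta <- vector("list", p); sig <- vector("list", p)
  evars <- numeric(p); nnll <- numeric(p)
  for (j in seq_len(p)) {
    init <- if (!is.null(warm)) warm_init(warm, j, parents[[j]]) else NULL
    f <- fit_node(j, parents[[j]], M, X, init = init, control = control)
    beta[[j]] <- f$beta; sig[[j]] <- f$sigma2
    evars[j] <- f$error_var; nnll[j] <- f$nll
  }
  new_dagmm_model(parents, beta, sig, evars, nnll, d = d, n = nrow(M),
                  node_names = node_names %||% colnames(M),
                  covariate_names = covariate_names %||% colnames(X))
}

# Internal: warm start for node j restricted to a (possibly reduced)
# parent set, taken from an existing dagmm_model.
warm_init <- function(fit, j, parents) {
  old <- fit$parents[[j]]
  if (length(parents) == 0L) return(NULL)
  idx <- match(parents, old)
  if (anyNA(idx)) return(NULL)
  list(beta = fit$beta[[j]][, idx, drop = FALSE],
       sigma2 = fit$sigma2[[j]][idx],
       error_var = fit$error_vars[j])
}

# Internal: refit a single node inside an existing model, reusing all other
# node fits (the likelihood is separable across nodes).
refit_node_in_model <- function(fit, j, parents, M, X, control) {
  init <- warm_init(fit, j, parents)
  f <- fit_node(j, parents, M, X, init = init, control = control)
  fit$parents[[j]] <- f$parents
  fit$beta[[j]] <- f$beta
  fit$sigma2[[j]] <- f$sigma2
  fit$error_vars[j] <- f$error_var
  fit$node_nll[j] <- f$nll
  fit$support <- support_from_parents(fit$parents)
  n_edges <- NROW(fit$support)
  fit$n_params <- n_edges * fit$d + n_edges + fit$p
  fit$nll <- sum(fit$node_nll)
  fit$bic <- dagmm_bic(fit, fit$n)
  fit
}

#' Bayesian information criterion for a model fit
#'
#' `nll + n_params * log(n)`, with `nll` the constant-free objective of
#' [neg_log_likelihood()] and `n_params` the number of free parameters
#' (d coefficients plus one random-effect variance per edge, plus p error
#' variances). The stored objective is already on the deviance scale
#' (`-2 * log-likelihood` up to an additive constant; each observation
#' contributes `r^2/w + log(w)`), so it enters the criterion unscaled.
#'
#' @param fit A `dagmm_model` with `nll` and `n_params` set.
#' @param n Number of subjects the likelihood was computed on.
#' @return The BIC value.
#' @examples
#' f <- list(nll = 10, n_params = 3)
#' dagmm_bic(f, exp(2))  # 10 + 6
#' @export
dagmm_bic <- function(fit, n) {
  if (is.na(n) || n <= 1) stop("n must exceed 1")
  fit$nll + fit$n_params * log(n)
}

#' Quadrature oracle for the integrated subject density
#'
#' Computes the marginal density of one subject's node vector by numerical
#' integration of the conditional Gaussian density over the random effects,
#' using tensor-product Gauss-Hermite quadrature. Intended purely as an
#' independent check of the closed-form likelihood: for a model with
#' support edges `(j, k)` the relation
#' `neg_log_likelihood = -2 * sum_i log f_i - n * p * log(2*pi)`
#' holds, where `f_i` is this density for subject i.
#'
#' The determinant of `I - B(X) - Gamma` is computed numerically (it equals
#' one for any DAG-compatible support).
#'
#' @param row_m Numeric vector of one subject's p node values.
#' @param row_x Numeric vector of the subject's d covariates.
#' @param fit A `dagmm_model`; at most 3 support edges may have
#'   `sigma2 > 0` (the dimension of the integral).
#' @param quad_points Gauss-Hermite points per dimension.
#' @return The marginal density (a positive number).
#' @examples
#' fit <- model_fit(cbind(1L, 2L), beta = list(0.5), sigma2 = 0,
#'                  error_vars = c(1, 1), d = 1)
#' marginal_density_oracle(c(0.2, -0.1), 1, fit)
#' @export
marginal_density_oracle <- function(row_m, row_x, fit, quad_points = 32L) {
  p <- fit$p; d <- fit$d
  if (length(row_m) != p || length(row_x) != d)
    stop("row_m / row_x dimensions do not match the fit")
  support <- fit$support
  chk <- is_dag(support, p)
  if (!chk$acyclic) stop("oracle requires a DAG-compatible support")
  # fixed-effect adjacency for this subject
  B <- matrix(0, p, p)
  re_edges <- NULL; re_sd <- NULL
  if (NROW(support) > 0L) {
    for (j in seq_len(p)) {
      pa <- fit$parents[[j]]
      if (length(pa) == 0L) next
      B[j, pa] <- drop(crossprod(fit$beta[[j]], row_x))
      pos <- fit$sigma2[[j]] > 0
      if (any(pos)) {
        re_edges <- rbind(re_edges, cbind(j, pa[pos]))
        re_sd <- c(re_sd, sqrt(fit$sigma2[[j]][pos]))
      }
    }
  }
  r <- NROW(re_edges)
  if (r > 3L) stop("oracle supports at most 3 random-effect edges")
  sde <- sqrt(fit$error_vars)
  cond_dens <- function(gam) {
    G <- matrix(0, p, p)
    if (r > 0L)
      for (e in seq_len(r)) G[re_edges[e, 1L], re_edges[e, 2L]] <- gam[e]
    A <- diag(p) - B - G
    resid <- drop(A %*% row_m)
    abs(det(A)) * prod(dnorm(resid, mean = 0, sd = sde))
  }
  if (r == 0L) return(cond_dens(numeric(0)))
  gh <- pracma::gaussHermite(quad_points)
  grids <- rep(list(seq_len(quad_points)), r)
  idx <- as.matrix(expand.grid(grids))
  total <- 0
  for (i in seq_len(nrow(idx))) {
    t_i <- gh$x[idx[i, ]]
    w_i <- prod(gh$w[idx[i, ]])
    gam <- sqrt(2) * re_sd * t_i
    total <- total + w_i * cond_dens(gam)
  }
  total / pi^(r / 2)
}
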