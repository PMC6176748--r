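# Stage 1 of DAG-MM: the sparse initial skeleton from two l1-penalized
# moment objectives, with BIC selection of the penalties.

# Internal: stacked interaction design for node j, columns grouped per
# candidate parent k != j: (X[,1]*M[,k], ..., X[,d]*M[,k]).
node_design <- function(M, X, j) {
  p <- ncol(M); d <- ncol(X)
  ks <- setdiff(seq_len(p), j)
  Z <- X[, rep.int(seq_len(d), length(ks)), drop = FALSE] *
    M[, rep(ks, each = d), drop = FALSE]
  attr(Z, "parents") <- ks
  Z
}

#' Penalized fixed-effect estimates for one node
#'
#' Solves the lasso problem of the first skeleton objective for node `j`:
#' the node column is regressed on the interaction features
#' `X[, l] * M[, k]` for every candidate parent `k != j`, with an l1
#' penalty `lambda1` on all coefficients. Coordinate descent with
#' soft-thresholding yields exact zeros.
#'
#' @param j Node index.
#' @param M,X Node and covariate matrices.
#' @param lambda1 Positive penalty (may be a decreasing vector; the path is
#'   computed with warm starts).
#' @param control A [dagmm_control()] object.
#' @return A list with `beta` (d x (p-1) x nlambda array of coefficients,
#'   candidate parents in column order `setdiff(1:p, j)`), `parents`
#'   (candidate parent indices), and `lambda1`.
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(60), 20, 3); x <- matrix(rnorm(20), 20, 1)
#' big <- max(abs(2 * crossprod(cbind(x * m[, 2], x * m[, 3]), m[, 1])))
#' f <- fit_beta_penalized(1, m, x, big * 1.01)
#' all(f$beta == 0)
#' @export
fit_beta_penalized <- function(j, M, X, lambda1,
                               control = dagmm_control()) {
  check_data_pair(M, X)
  stopifnot(all(lambda1 > 0))
  Z <- node_design(M, X, j)
  zero_cols <- colSums(Z^2) == 0
  if (any(zero_cols))
    warning("dropping ", sum(zero_cols), " all-zero feature column(s) for node ", j)
  lam <- sort(as.numeric(lambda1), decreasing = TRUE)
  B <- lasso_path_cpp(Z, M[, j], lam,
                      control$cd_tol * max(lam[1], 1),
                      control$cd_max_sweeps, numeric(0))
  d <- ncol(X)
  beta <- array(B, dim = c(d, ncol(M) - 1L, length(lam)))
  list(beta = beta, parents = attr(Z, "parents"), lambda1 = lam)
}

#' Penalized random-effect variance estimates for one node
#'
#' Solves the non-negative penalized least-squares problem of the second
#' skeleton objective: squared residuals are regressed on the squared
#' candidate-parent columns `M[, k]^2` plus an unpenalized positive
#' intercept (the error variance), with penalty `lambda2 * sum(sigma2)`
#' (the l1 penalty is linear under the non-negativity constraint).
#' Projected coordinate descent returns exact zeros at the boundary.
#'
#' @param j Node index.
#' @param r_tilde Residual vector for node `j` (from the current penalized
#'   fixed-effect estimates).
#' @param M Node matrix.
#' @param lambda2 Positive penalty (may be a decreasing vector).
#' @param control A [dagmm_control()] object.
#' @return A list with `sigma2` ((p-1) x nlambda matrix, candidate parents
#'   in order `setdiff(1:p, j)`), `error_var` (length nlambda), `parents`,
#'   `lambda2`.
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(200), 100, 2)
#' f <- fit_sigma_penalized(1, rnorm(100), m, 1e6)
#' all(f$sigma2 == 0)
#' @export
fit_sigma_penalized <- function(j, r_tilde, M, lambda2,
                                control = dagmm_control()) {
  stopifnot(length(r_tilde) == nrow(M), all(lambda2 > 0))
  ks <- setdiff(seq_len(ncol(M)), j)
  A <- M[, ks, drop = FALSE]^2
  lam <- sort(as.numeric(lambda2), decreasing = TRUE)
  res <- nn_path_cpp(A, r_tilde^2, lam, control$variance_floor,
                     control$cd_tol * max(lam[1], 1),
                     control$cd_max_sweeps)
  list(sigma2 = res$coef, error_var = as.numeric(res$intercept),
       parents = ks, lambda2 = lam)
}

# Internal: BIC-scored lambda search shared by select_lambdas() and
# initial_skeleton(). Runs the full two-stage path computation and returns
# everything downstream consumers need.
#
# Tuning scores each penalty by the BIC of the penalized estimates
# themselves, with degrees of freedom equal to the number of nonzero
# coefficients (the standard lasso df): stage A uses the Gaussian
# profile-variance form n*log(RSS/n) + df*log(n) per node, stage B plugs
# the moment estimates into the marginal likelihood's variance term. This
# deliberately tunes on the liberal side: the skeleton only needs to
# contain the truth (the DAG search deletes, never adds), and shrunken
# penalized estimates do not overfit the way refits on the same support
# would.
skeleton_search <- function(M, X, control = dagmm_control()) {
  check_data_pair(M, X)
  n <- nrow(M); p <- ncol(M); d <- ncol(X)
  floor_ <- control$variance_floor

  # scan a penalty grid from most to least penalized, stopping once BIC
  # has worsened for `patience` consecutive grid points (supports only
  # grow as the penalty decreases, so the expensive dense end is skipped
  # once the criterion has clearly turned)
  scan_grid <- function(grid, bic_at, patience = 8L) {
    bics <- rep(NA_real_, length(grid))
    best <- Inf; worse <- 0L
    for (li in seq_along(grid)) {
      bics[li] <- bic_at(li)
      if (bics[li] < best) { best <- bics[li]; worse <- 0L }
      else worse <- worse + 1L
      if (worse >= patience) break
    }
    bics
  }

  # ---- stage A: lasso path over lambda1 ----
  Zs <- lapply(seq_len(p), function(j) node_design(M, X, j))
  if (is.null(control$lambda1_grid)) {
    lam1_max <- max(vapply(seq_len(p), function(j)
      max(abs(2 * crossprod(Zs[[j]], M[, j]))), 0))
    lam1_max <- max(lam1_max, .Machine$double.eps)
    grid1 <- exp(seq(log(lam1_max), log(lam1_max * control$lambda_min_ratio),
                     length.out = control$nlambda1))
  } else grid1 <- sort(control$lambda1_grid, decreasing = TRUE)

  kkt1 <- control$cd_tol * max(grid1[1], 1)
  # lasso paths are computed lazily in warm-started chunks so the grid
  # scan's early stop also skips the (slow) dense end of the path;
  # per-column RSS and df are accumulated alongside
  paths1 <- vector("list", p)
  rss1 <- vector("list", p)
  df1 <- vector("list", p)
  done1 <- 0L
  ensure_path1 <- function(li) {
    while (done1 < li) {
      hi <- min(done1 + 6L, length(grid1))
      idx <- (done1 + 1L):hi
      for (j in seq_len(p)) {
        b0 <- if (done1 > 0L) paths1[[j]][, done1] else numeric(0)
        seg <- lasso_path_cpp(Zs[[j]], M[, j], grid1[idx], kkt1,
                              control$cd_max_sweeps, b0)
        paths1[[j]] <<- cbind(paths1[[j]], seg)
        resid <- M[, j] - Zs[[j]] %*% seg
        rss1[[j]] <<- c(rss1[[j]], pmax(colSums(resid^2), 1e-300))
        df1[[j]] <<- c(df1[[j]], colSums(seg != 0))
      }
      done1 <<- hi
    }
  }

  beta_support <- function(j, li) {
    # parents whose d-block has any nonzero coefficient at grid index li
    ks <- setdiff(seq_len(p), j)
    bz <- matrix(paths1[[j]][, li], nrow = d)
    ks[colSums(bz != 0) > 0]
  }
  bic1 <- scan_grid(grid1, function(li) {
    ensure_path1(li)
    tot <- 0
    for (j in seq_len(p))
      tot <- tot + n * log(rss1[[j]][li] / n) + df1[[j]][li] * log(n)
    tot
  })
  li1 <- which.min(bic1)
  lambda1_star <- grid1[li1]

  # penalized beta estimates and residuals at lambda1*
  beta_tilde <- lapply(seq_len(p), function(j)
    matrix(paths1[[j]][, li1], nrow = d))
  r_tilde <- vapply(seq_len(p), function(j)
    M[, j] - drop(Zs[[j]] %*% paths1[[j]][, li1]), numeric(n))

  # ---- stage B: non-negative path over lambda2 given the residuals ----
  A2 <- lapply(seq_len(p), function(j) M[, setdiff(seq_len(p), j),
                                         drop = FALSE]^2)
  b2 <- lapply(seq_len(p), function(j) r_tilde[, j]^2)
  if (is.null(control$lambda2_grid)) {
    lam2_max <- max(vapply(seq_len(p), function(j) {
      g <- 2 * crossprod(A2[[j]], b2[[j]] - mean(b2[[j]]))
      max(c(g, 0))
    }, 0))
    lam2_max <- max(lam2_max, .Machine$double.eps)
    grid2 <- exp(seq(log(lam2_max), log(lam2_max * control$lambda_min_ratio),
                     length.out = control$nlambda2))
  } else grid2 <- sort(control$lambda2_grid, decreasing = TRUE)

  kkt2 <- control$cd_tol * max(grid2[1], 1)
  paths2 <- lapply(seq_len(p), function(j)
    nn_path_cpp(A2[[j]], b2[[j]], grid2, floor_, kkt2,
                control$cd_max_sweeps))

  # Gaussian profile BIC of the squared-residual regression itself,
  # mirroring stage A: n*log(RSS/n) + df*log(n) per node, df = number of
  # nonzero variance coefficients
  bic2 <- scan_grid(grid2, function(li) {
    tot <- 0
    for (j in seq_len(p)) {
      pred <- drop(A2[[j]] %*% paths2[[j]]$coef[, li]) +
        paths2[[j]]$intercept[li]
      rss2 <- max(sum((b2[[j]] - pred)^2), 1e-300)
      tot <- tot + n * log(rss2 / n) +
        sum(paths2[[j]]$coef[, li] > 0) * log(n)
    }
    tot
  }, patience = length(grid2))
  li2 <- which.min(bic2)
  lambda2_star <- grid2[li2]

  sup_union <- function(j, li) {
    ks <- setdiff(seq_len(p), j)
    sort(unique(c(beta_support(j, li1), ks[paths2[[j]]$coef[, li] > 0])))
  }

  parents <- lapply(seq_len(p), function(j) sup_union(j, li2))
  sigma2_tilde <- lapply(seq_len(p), function(j) paths2[[j]]$coef[, li2])
  sigma2_eps_tilde <- vapply(seq_len(p), function(j)
    paths2[[j]]$intercept[li2], 0)

  list(lambda1 = lambda1_star, lambda2 = lambda2_star,
       grid1 = grid1, grid2 = grid2, bic1 = bic1, bic2 = bic2,
       parents = parents, beta_tilde = beta_tilde,
       sigma2_tilde = sigma2_tilde, sigma2_eps_tilde = sigma2_eps_tilde)
}

#' Select the skeleton penalties by BIC
#'
#' Computes the two regularization paths (shared across nodes) and picks
#' the penalties minimising a BIC score of the penalized estimates, with
#' degrees of freedom equal to the nonzero-coefficient count: `lambda1` is
#' chosen along the fixed-effect lasso path first; the residuals at the
#' selected `lambda1` define the squared-residual regression whose path
#' selects `lambda2`. Tuning is deliberately on the liberal side: the
#' skeleton only needs to contain the true graph, since the subsequent
#' search deletes edges and never adds them.
#'
#' @param M,X Node and covariate matrices.
#' @param control A [dagmm_control()] object.
#' @return List with `lambda1`, `lambda2` and the searched grids.
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(200), 50, 4); x <- matrix(rnorm(100), 50, 2)
#' sel <- select_lambdas(m, x, dagmm_control(nlambda1 = 8, nlambda2 = 8))
#' sel$lambda1 > 0
#' @export
select_lambdas <- function(M, X, control = dagmm_control()) {
  s <- skeleton_search(M, X, control)
  list(lambda1 = s$lambda1, lambda2 = s$lambda2,
       grid1 = s$grid1, grid2 = s$grid2)
}

#' Initial sparse skeleton
#'
#' Runs the penalized moment stage of DAG-MM: fixed-effect lasso and
#' non-negative variance regression per node at BIC-selected penalties,
#' then refits the unpenalized likelihood on the union support (an edge
#' `(j, k)` enters the skeleton when its penalized fixed-effect block or
#' its penalized random-effect variance is nonzero).
#'
#' @param M,X Node and covariate matrices.
#' @param control A [dagmm_control()] object.
#' @return An object of class `dagmm_skeleton`: list with `fit` (the
#'   refitted `dagmm_model` on the skeleton support), `support`,
#'   `beta_tilde`, `sigma2_tilde`, `sigma2_eps_tilde` (penalized
#'   estimates), `lambda1`, `lambda2`.
#' @examples
#' truth <- make_setting(1, n = 150, p = 15, seed = 7)
#' dat <- simulate_data(truth)
#' sk <- initial_skeleton(dat$M, dat$X,
#'                        dagmm_control(nlambda1 = 10, nlambda2 = 10))
#' nrow(sk$support) >= 0
#' @export
initial_skeleton <- function(M, X, control = dagmm_control()) {
  s <- skeleton_search(M, X, control)
  fit <- fit_support_model(M, X, s$parents, control = control)
  structure(list(fit = fit, support = fit$support,
                 beta_tilde = s$beta_tilde, sigma2_tilde = s$sigma2_tilde,
                 sigma2_eps_tilde = s$sigma2_eps_tilde,
                 lambda1 = s$lambda1, lambda2 = s$lambda2,
                 grid1 = s$grid1, grid2 = s$grid2),
            class = "dagmm_skeleton")
}

#' @export
print.dagmm_skeleton <- function(x, ...) {
  cat("DAG-MM initial skeleton:", NROW(x$support), "directed edges",
      sprintf("(lambda1 = %.4g, lambda2 = %.4g)\n", x$lambda1, x$lambda2))
  invisible(x)
}
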