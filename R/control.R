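#' Tuning and convergence settings for DAG-MM
#'
#' Collects every numerical knob used across the skeleton, model-fitting and
#' search stages. Defaults follow standard penalized-regression practice and
#' are adequate for the benchmark designs shipped with the package.
#'
#' @param max_iter Maximum outer iterations (WLS/Newton-Raphson alternations)
#'   per node fit.
#' @param rel_tol Relative tolerance on the per-node objective for declaring
#'   convergence.
#' @param variance_floor Lower bound applied to every variance parameter;
#'   keeps the log-likelihood finite and gradients stable.
#' @param lambda1_grid,lambda2_grid Optional explicit penalty grids (decreasing
#'   positive vectors) for the fixed-effect lasso and the non-negative
#'   variance regression. When `NULL`, `nlambda` log-spaced values from the
#'   smallest penalty that zeroes all coefficients (computed from the KKT
#'   conditions at the origin) down to `lambda_min_ratio` times it.
#' @param nlambda1,nlambda2 Grid sizes when grids are auto-generated.
#' @param lambda_min_ratio Ratio of smallest to largest auto-generated penalty.
#' @param cd_tol Coordinate-descent KKT tolerance (relative to the largest
#'   penalty on each path).
#' @param cd_max_sweeps Maximum coordinate-descent sweeps per penalty value.
#' @param sweeps Number of beta/sigma alternations in the skeleton stage. The
#'   first moment objective does not depend on the variance estimates, so
#'   values above 1 re-solve an identical problem; the knob exists for
#'   completeness.
#' @param seed Optional integer seed recorded in results for provenance.
#' @param verbose Logical; print progress messages.
#'
#' @return An object of class `dagmm_control` (a named list).
#' @examples
#' ctrl <- dagmm_control(nlambda1 = 20, verbose = FALSE)
#' ctrl$rel_tol
#' @export
dagmm_control <- function(max_iter = 100L, rel_tol = 1e-6,
                          variance_floor = 1e-8,
                          lambda1_grid = NULL, lambda2_grid = NULL,
                          nlambda1 = 50L, nlambda2 = 50L,
                          lambda_min_ratio = 1e-6,
                          cd_tol = 1e-7, cd_max_sweeps = 1000L,
                          sweeps = 1L, seed = NULL, verbose = FALSE) {
  stopifnot(max_iter >= 1, rel_tol > 0, variance_floor > 0,
            nlambda1 >= 1, nlambda2 >= 1,
            lambda_min_ratio > 0, lambda_min_ratio < 1,
            cd_tol > 0, cd_max_sweeps >= 1, sweeps >= 1)
  for (g in list(lambda1_grid, lambda2_grid)) {
    if (!is.null(g)) {
      stopifnot(length(g) >= 1, all(g > 0), !is.unsorted(rev(g)))
    }
  }
  structure(list(max_iter = as.integer(max_iter), rel_tol = rel_tol,
                 variance_floor = variance_floor,
                 lambda1_grid = lambda1_grid, lambda2_grid = lambda2_grid,
                 nlambda1 = as.integer(nlambda1),
                 nlambda2 = as.integer(nlambda2),
                 lambda_min_ratio = lambda_min_ratio,
                 cd_tol = cd_tol, cd_max_sweeps = as.integer(cd_max_sweeps),
                 sweeps = as.integer(sweeps), seed = seed,
                 verbose = isTRUE(verbose)),
            class = "dagmm_control")
}
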