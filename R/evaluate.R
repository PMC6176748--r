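# Scoring of estimated graphs and parameters against a simulation truth.

#' Directed edge confusion counts
#'
#' Compares an estimated directed edge set with the truth, taking direction
#' into account: a reversed edge contributes one false positive and one
#' false negative.
#'
#' @param estimated Integer matrix `(child, parent)` of estimated edges.
#' @param truth A `dagmm_truth` object (or a `(child, parent)` matrix).
#' @return List with integer counts `tp`, `fp`, `fn`.
#' @examples
#' tr <- make_setting(1, 100, 15, 1)
#' edge_confusion(truth_graph12(), tr)  # tp = 12, fp = 0, fn = 0
#' @export
edge_confusion <- function(estimated, truth) {
  true_edges <- if (inherits(truth, "dagmm_truth")) truth$edges else
    as_support(truth)
  estimated <- as_support(estimated)
  est_key <- paste(estimated[, 1L], estimated[, 2L])
  true_key <- paste(true_edges[, 1L], true_edges[, 2L])
  tp <- sum(est_key %in% true_key)
  list(tp = tp, fp = length(est_key) - tp, fn = length(true_key) - tp)
}

#' Root-sum-squared parameter errors
#'
#' Computes the three estimation-error summaries over all ordered node
#' pairs (parameters absent from one side are treated as zero):
#' `rss_beta = sqrt(sum_jk ||beta_hat_jk - beta_jk||^2)`,
#' `rss_sigma2 = sqrt(sum_jk (sigma2_hat_jk - sigma2_jk)^2)`, and
#' `rss_error = sqrt(sum_j (sigma2_eps_hat_j - sigma2_eps_j)^2)`.
#'
#' @param fit A `dagmm_model`.
#' @param truth A `dagmm_truth` with the same node universe and covariate
#'   dimension.
#' @return List with `rss_beta`, `rss_sigma2`, `rss_error`.
#' @examples
#' tr <- make_setting(1, 100, 15, 1)
#' fit <- model_fit(tr$edges, tr$beta, tr$sigma2, tr$error_vars, tr$d)
#' unlist(rss_metrics(fit, tr))  # all zero
#' @export
rss_metrics <- function(fit, truth) {
  stopifnot(inherits(truth, "dagmm_truth"))
  if (fit$d != truth$d)
    stop("covariate dimension of fit and truth differ")
  true_key <- paste(truth$edges[, 1L], truth$edges[, 2L])
  fit_beta <- list(); fit_sig <- list()
  sup <- fit$support
  if (NROW(sup) > 0L) {
    for (i in seq_len(nrow(sup))) {
      j <- sup[i, 1L]; k <- sup[i, 2L]
      t <- match(k, fit$parents[[j]])
      fit_beta[[paste(j, k)]] <- fit$beta[[j]][, t]
      fit_sig[[paste(j, k)]] <- fit$sigma2[[j]][t]
    }
  }
  keys <- union(true_key, names(fit_beta))
  zb <- rep(0, truth$d)
  ss_beta <- 0; ss_sig <- 0
  for (kk in keys) {
    ti <- match(kk, true_key)
    tb <- if (is.na(ti)) zb else truth$beta[[ti]]
    ts <- if (is.na(ti)) 0 else truth$sigma2[ti]
    fb <- fit_beta[[kk]] %||% zb
    fs <- fit_sig[[kk]] %||% 0
    ss_beta <- ss_beta + sum((fb - tb)^2)
    ss_sig <- ss_sig + (fs - ts)^2
  }
  ev <- fit$error_vars
  if (length(ev) != truth$p) stop("node universes differ")
  list(rss_beta = sqrt(ss_beta), rss_sigma2 = sqrt(ss_sig),
       rss_error = sqrt(sum((ev - truth$error_vars)^2)))
}
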