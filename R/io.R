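# Delimited-text I/O for data matrices, and fit/truth serialization.

detect_sep <- function(path) {
  if (grepl("\\.tsv$|\\.tab$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a node or covariate matrix from delimited text
#'
#' CSV or TSV (auto-detected from the extension), first row headers, one
#' row per subject. Every cell must be a finite number; offending cells are
#' reported by row and column.
#'
#' @param path File path.
#' @param role `"nodes"` or `"covariates"`; controls validation and the
#'   returned class of matrix.
#' @param intercept For `role = "covariates"`, prepend a constant column.
#' @return A validated numeric matrix (see [node_matrix()],
#'   [covariate_matrix()]).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(a = 1:3, b = 4:6), f, row.names = FALSE)
#' read_matrix(f, "nodes")
#' @export
read_matrix <- function(path, role = c("nodes", "covariates"),
                        intercept = FALSE) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    read.csv(path, sep = detect_sep(path), check.names = FALSE,
             colClasses = NA, stringsAsFactors = FALSE),
    error = function(e) stop("could not parse ", path, ": ",
                             conditionMessage(e)))
  if (nrow(df) == 0L || ncol(df) == 0L) stop("empty file: ", path)
  vals <- suppressWarnings(
    vapply(df, function(col) as.numeric(as.character(col)),
           numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(NULL, colnames(df)))
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric or missing cell at row %d, column '%s' in %s",
                 bad[1, 1], colnames(vals)[bad[1, 2]], path))
  if (role == "nodes") node_matrix(vals)
  else covariate_matrix(vals, intercept = intercept)
}

#' Write a matrix as delimited text
#'
#' @param mat Numeric matrix with column names.
#' @param path Output path; `.tsv` extension selects tab separation.
#' @return The path, invisibly.
#' @export
write_matrix <- function(mat, path) {
  utils::write.table(as.data.frame(mat), path, sep = detect_sep(path),
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Internal: plain-list serialization of a dagmm_model (JSON-ready).
fit_to_list <- function(fit) {
  sup <- fit$support
  edges <- list()
  if (NROW(sup) > 0L) {
    for (i in seq_len(nrow(sup))) {
      j <- sup[i, 1L]; k <- sup[i, 2L]
      t <- match(k, fit$parents[[j]])
      edges[[i]] <- list(child = j, parent = k,
                         beta = as.numeric(fit$beta[[j]][, t]),
                         sigma2 = fit$sigma2[[j]][t])
    }
  }
  list(nodes = fit$node_names, covariates = fit$covariate_names,
       edges = edges, error_vars = as.numeric(fit$error_vars),
       nll = fit$nll, bic = fit$bic)
}

list_to_fit <- function(x) {
  p <- length(x$error_vars); d <- length(x$covariates)
  m <- length(x$edges)
  sup <- if (m > 0L)
    cbind(child = vapply(x$edges, function(e) as.integer(e$child), 0L),
          parent = vapply(x$edges, function(e) as.integer(e$parent), 0L))
  else empty_support()
  fit <- model_fit(sup,
                   beta = lapply(x$edges, function(e) as.numeric(e$beta)),
                   sigma2 = vapply(x$edges, function(e) as.numeric(e$sigma2), 0),
                   error_vars = as.numeric(x$error_vars), d = d,
                   node_names = as.character(x$nodes),
                   covariate_names = as.character(x$covariates))
  fit$nll <- x$nll %||% NA_real_
  fit$bic <- x$bic %||% NA_real_
  fit
}

#' Write a fitted model to a directory
#'
#' Emits four artifacts: `edges.tsv` (child, parent, one `beta_` column per
#' covariate, `sigma2`, and the edge `strength`), `error_vars.tsv`,
#' `model.json` (full serialization, read back with [read_fit()]), and
#' `graph.dot` (Graphviz, arrows drawn parent to child). Node indices are
#' 1-based and pairs are ordered `(child, parent)` throughout.
#'
#' @param fit A `dagmm_model`.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_fit <- function(fit, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sup <- fit$support
  d <- fit$d
  bcols <- matrix(numeric(0), 0, d)
  sig <- numeric(0); strengths <- numeric(0)
  if (NROW(sup) > 0L) {
    bcols <- matrix(0, nrow(sup), d)
    sig <- numeric(nrow(sup)); strengths <- numeric(nrow(sup))
    for (i in seq_len(nrow(sup))) {
      j <- sup[i, 1L]; k <- sup[i, 2L]
      t <- match(k, fit$parents[[j]])
      bcols[i, ] <- fit$beta[[j]][, t]
      sig[i] <- fit$sigma2[[j]][t]
      strengths[i] <- edge_strength(bcols[i, ], sig[i])
    }
  }
  edf <- data.frame(child = sup[, 1L], parent = sup[, 2L])
  for (l in seq_len(d))
    edf[[paste0("beta_", fit$covariate_names[l])]] <- bcols[, l]
  edf$sigma2 <- sig
  edf$strength <- strengths
  utils::write.table(edf, file.path(outdir, "edges.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(node = seq_len(fit$p), name = fit$node_names,
               error_var = fit$error_vars),
    file.path(outdir, "error_vars.tsv"), sep = "\t",
    row.names = FALSE, quote = FALSE)
  jsonlite::write_json(fit_to_list(fit), file.path(outdir, "model.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  dot <- c("digraph dagmm {",
           sprintf('  %d [label="%s"];', seq_len(fit$p), fit$node_names),
           if (NROW(sup) > 0L)
             sprintf("  %d -> %d;", sup[, 2L], sup[, 1L]),
           "}")
  writeLines(dot, file.path(outdir, "graph.dot"))
  invisible(outdir)
}

#' Read a fitted model from `model.json`
#'
#' @param path Path to a `model.json` written by [write_fit()].
#' @return A `dagmm_model`.
#' @export
read_fit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  x$error_vars <- as.numeric(unlist(x$error_vars))
  x$nodes <- unlist(x$nodes)
  x$covariates <- unlist(x$covariates)
  list_to_fit(x)
}

#' Write / read a simulation truth as JSON
#'
#' @param truth A `dagmm_truth`.
#' @param path Output path.
#' @return `path` invisibly (`write_truth`); a `dagmm_truth` (`read_truth`).
#' @export
write_truth <- function(truth, path) {
  x <- list(p = truth$p, n = truth$n, seed = truth$seed,
            covariate_spec = truth$covariate_spec,
            error_vars = truth$error_vars,
            edges = lapply(seq_len(NROW(truth$edges)), function(i)
              list(child = truth$edges[i, 1L], parent = truth$edges[i, 2L],
                   beta = truth$beta[[i]], sigma2 = truth$sigma2[i])))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  m <- length(x$edges)
  edges <- if (m > 0L)
    cbind(child = vapply(x$edges, function(e) as.integer(e$child), 0L),
          parent = vapply(x$edges, function(e) as.integer(e$parent), 0L))
  else empty_support()
  make_truth(p = as.integer(x$p), edges = edges,
             beta = lapply(x$edges, function(e) as.numeric(unlist(e$beta))),
             sigma2 = vapply(x$edges, function(e) as.numeric(e$sigma2), 0),
             error_vars = as.numeric(unlist(x$error_vars)),
             covariate_spec = unlist(x$covariate_spec),
             n = as.integer(x$n), seed = as.integer(x$seed))
}
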