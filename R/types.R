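#' Validate a node-data matrix
#'
#' Checks an n-subjects by p-nodes numeric matrix (assumed centered) and
#' attaches node names.
#'
#' @param values Numeric matrix, one row per subject, one column per node.
#' @param node_names Optional character vector of p node identifiers;
#'   defaults to existing column names or `M1..Mp`.
#' @return The validated matrix with column names set.
#' @examples
#' m <- node_matrix(matrix(rnorm(20), 5, 4))
#' colnames(m)
#' @export
node_matrix <- function(values, node_names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("node matrix must have at least one row and one column")
  if (!all(is.finite(values)))
    stop("node matrix contains non-finite entries")
  if (is.null(node_names))
    node_names <- colnames(values)
  if (is.null(node_names))
    node_names <- paste0("M", seq_len(ncol(values)))
  if (length(node_names) != ncol(values))
    stop("length of node_names must equal the number of columns")
  colnames(values) <- node_names
  values
}

#' Validate an exogenous covariate matrix
#'
#' Checks an n by d numeric covariate matrix and optionally prepends a
#' constant intercept column (named `intercept`).
#'
#' @param values Numeric matrix of covariates, one row per subject.
#' @param covariate_names Optional character vector of column identifiers.
#' @param intercept Logical; prepend a column of ones.
#' @return The validated matrix, with attribute `has_intercept`.
#' @examples
#' x <- covariate_matrix(matrix(rnorm(10), 5, 2), intercept = TRUE)
#' attr(x, "has_intercept")
#' @export
covariate_matrix <- function(values, covariate_names = NULL,
                             intercept = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(is.finite(values)))
    stop("covariate matrix contains non-finite entries")
  if (is.null(covariate_names))
    covariate_names <- colnames(values)
  if (is.null(covariate_names))
    covariate_names <- paste0("X", seq_len(ncol(values)))
  if (length(covariate_names) != ncol(values))
    stop("length of covariate_names must equal the number of columns")
  colnames(values) <- covariate_names
  if (isTRUE(intercept)) {
    values <- cbind(intercept = 1, values)
  }
  has_int <- ncol(values) >= 1 && all(values[, 1] == 1)
  structure(values, has_intercept = has_int)
}

# Internal: joint validation of a node/covariate pair.
check_data_pair <- function(M, X) {
  if (!is.matrix(M) || !is.matrix(X))
    stop("M and X must be matrices")
  if (nrow(M) != nrow(X))
    stop("M and X must have the same number of rows (subjects)")
  if (!all(is.finite(M)) || !all(is.finite(X)))
    stop("M and X must contain only finite values")
  invisible(TRUE)
}

# Internal: canonical empty support matrix.
empty_support <- function() {
  matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("child", "parent")))
}

# Internal: support matrix from a parents list.
support_from_parents <- function(parents) {
  rows <- lapply(seq_along(parents), function(j) {
    pa <- parents[[j]]
    if (length(pa) == 0L) return(NULL)
    cbind(child = rep.int(j, length(pa)), parent = as.integer(pa))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty_support())
  storage.mode(out) <- "integer"
  out
}

# Internal: parents list (length p) from a support matrix.
parents_from_support <- function(support, p) {
  parents <- rep(list(integer(0)), p)
  if (NROW(support) > 0L) {
    for (i in seq_len(nrow(support))) {
      j <- support[i, 1L]
      parents[[j]] <- c(parents[[j]], support[i, 2L])
    }
    parents <- lapply(parents, function(v) sort(unique(as.integer(v))))
  }
  parents
}

# Internal: validate a support matrix (child, parent), no self-loops.
check_support <- function(support, p) {
  if (NROW(support) == 0L) return(invisible(TRUE))
  if (ncol(support) != 2L) stop("support must have two columns")
  if (any(support < 1L) || any(support > p))
    stop("support indices out of range")
  if (any(support[, 1L] == support[, 2L]))
    stop("support contains self-loops")
  invisible(TRUE)
}
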