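#' Spearman correlation matrix of an item-response table
#'
#' Pairwise Spearman rank correlations with average ranks under ties (the
#' appropriate convention for heavily tied Likert codes). The result is the
#' input to the regularized network estimator.
#'
#' @param table an `item_response_table` (or plain numeric matrix) with at
#'   least 3 rows and no zero-variance column.
#' @return An object of class `correlation_matrix`: list with `S` (p x p,
#'   symmetric, unit diagonal), `method = "spearman"`, `pd_adjusted`
#'   (logical), `n`.
#' @export
spearman_matrix <- function(table) {
  X <- if (inherits(table, "item_response_table")) table$responses else as.matrix(table)
  if (nrow(X) < 3) stopf("need at least 3 respondents for correlations")
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stopf("zero-variance item(s): %s — Spearman's rho is undefined",
          paste(colnames(X)[sds == 0], collapse = ", "))
  S <- cor(X, method = "spearman")
  S <- (S + t(S)) / 2
  diag(S) <- 1
  structure(list(S = S, method = "spearman", pd_adjusted = FALSE, n = nrow(X)),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("correlation_matrix (%s): %d x %d, n = %d%s\n", x$method,
              nrow(x$S), ncol(x$S), x$n,
              if (x$pd_adjusted) ", PSD-adjusted" else ""))
  invisible(x)
}

#' Repair a correlation matrix to positive semidefiniteness
#'
#' Rank-based correlation matrices need not be positive semidefinite, but
#' the graphical lasso requires a PSD input. Eigenvalues below a small
#' floor are clipped, the matrix is reconstructed and rescaled back to unit
#' diagonal. A matrix that is already PSD is returned unchanged.
#'
#' @param cm a `correlation_matrix` (or plain symmetric matrix).
#' @param floor eigenvalue floor used for clipping, default `1e-8`.
#' @return The input object with `S` repaired and `pd_adjusted` set when a
#'   repair actually happened.
#' @export
nearest_positive_semidefinite <- function(cm, floor = 1e-8) {
  plain <- !inherits(cm, "correlation_matrix")
  S <- if (plain) as.matrix(cm) else cm$S
  if (max(abs(S - t(S))) > 1e-12) stopf("input must be symmetric")
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) >= 0) return(cm)
  vals <- pmax(e$values, floor)
  R <- e$vectors %*% (vals * t(e$vectors))
  d <- 1 / sqrt(diag(R))
  R <- R * tcrossprod(d)
  R <- (R + t(R)) / 2
  diag(R) <- 1
  dimnames(R) <- dimnames(S)
  if (plain) return(R)
  cm$S <- R
  cm$pd_adjusted <- TRUE
  cm
}

#' Write / read a correlation matrix as CSV
#'
#' Round-trips exactly at full double precision (values serialized with 17
#' significant digits).
#'
#' @param cm a `correlation_matrix`.
#' @param path CSV path; the header row and first column carry item ids.
#' @return `write_correlation` invisibly returns `path`;
#'   `read_correlation` returns a `correlation_matrix`.
#' @export
write_correlation <- function(cm, path) {
  df <- data.frame(item = colnames(cm$S) %||% paste0("V", seq_len(ncol(cm$S))),
                   cm$S, check.names = FALSE)
  old <- options(digits = 17)
  on.exit(options(old))
  write.csv(format(df, digits = 17, trim = TRUE), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' @rdname write_correlation
#' @param n sample size to record on the read-back object.
#' @export
read_correlation <- function(path, n = NA_integer_) {
  df <- read.csv(path, check.names = FALSE)
  S <- as.matrix(df[, -1, drop = FALSE])
  rownames(S) <- df[[1]]
  S <- (S + t(S)) / 2
  structure(list(S = S, method = "spearman", pd_adjusted = FALSE, n = n),
            class = "correlation_matrix")
}
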