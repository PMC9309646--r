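#' Construct an item-response table
#'
#' The basic data container of the package: an `n x p` integer matrix of
#' 5-point Likert codes (1--5) together with an item-to-cluster assignment.
#' Downstream network analysis expects exactly two clusters (for example an
#' intolerance-of-uncertainty cluster and a problematic-smartphone-use
#' symptom cluster), but the container itself accepts any number.
#'
#' @param responses integer matrix or data frame, respondents in rows, items
#'   in columns; every cell must be an integer code in `1:5`. Column names
#'   are used as item ids.
#' @param cluster_of named character vector mapping every item id to a
#'   cluster label.
#' @return An object of class `item_response_table` with elements
#'   `responses`, `item_ids`, `cluster_of`, `n`, `p`.
#' @export
item_response_table <- function(responses, cluster_of) {
  responses <- as.matrix(responses)
  if (is.null(colnames(responses)))
    stopf("responses must have column names (item ids)")
  item_ids <- colnames(responses)
  if (!all(item_ids %in% names(cluster_of)))
    stopf("cluster map is missing items: %s",
          paste(setdiff(item_ids, names(cluster_of)), collapse = ", "))
  cluster_of <- cluster_of[item_ids]
  storage <- suppressWarnings(as.numeric(responses))
  if (anyNA(storage))
    stopf("missing or non-numeric cells are not allowed")
  bad <- which(storage != round(storage) | storage < 1 | storage > 5)
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(responses))
    stopf("cell at row %d, item '%s' is not an integer code in 1..5 (value: %s)",
          rc[1], item_ids[rc[2]], format(responses[bad[1]]))
  }
  mode(responses) <- "integer"
  structure(
    list(responses = responses, item_ids = item_ids,
         cluster_of = cluster_of, n = nrow(responses), p = ncol(responses)),
    class = "item_response_table")
}

#' @export
print.item_response_table <- function(x, ...) {
  cat(sprintf("item_response_table: %d respondents x %d items\n", x$n, x$p))
  tab <- table(x$cluster_of)
  cat("clusters:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Read an item-response CSV
#'
#' Reads a delimited file whose header names the items and validates every
#' cell against the 1--5 Likert range. Columns not named in the cluster map
#' (for example attention-check columns) are carried along unchanged in the
#' `extra` attribute so that [apply_attention_filter()] can use them.
#'
#' @param path path to a CSV file with a header row of item ids.
#' @param cluster_of named character vector mapping item id to cluster
#'   label; all mapped items must be present in the file.
#' @param sep field separator, default comma.
#' @return An `item_response_table`; unmapped columns are kept in
#'   `attr(, "extra")` as a data frame.
#' @export
read_responses <- function(path, cluster_of, sep = ",") {
  raw <- read.csv(path, sep = sep, check.names = FALSE)
  missing <- setdiff(names(cluster_of), names(raw))
  if (length(missing))
    stopf("input file lacks mapped item column(s): %s",
          paste(missing, collapse = ", "))
  items <- names(cluster_of)
  tab <- item_response_table(as.matrix(raw[items]), cluster_of)
  extra_cols <- setdiff(names(raw), items)
  attr(tab, "extra") <- if (length(extra_cols)) raw[extra_cols] else NULL
  tab
}

#' Filter respondents by attention-check items
#'
#' Retains only rows whose check columns equal the required code; the
#' classic survey honesty device ("please choose the second option"). Check
#' columns live in the table's `extra` attribute (see [read_responses()]) or
#' in the response matrix itself, and are never part of the analyzed items.
#'
#' @param table an `item_response_table`, typically with an `extra`
#'   attribute holding the check columns.
#' @param checks named integer vector: names are check column names, values
#'   the required codes. Empty or `NULL` means no filtering.
#' @return A list with `table` (filtered) and `n_excluded`.
#' @export
apply_attention_filter <- function(table, checks = NULL) {
  if (is.null(checks) || length(checks) == 0)
    return(list(table = table, n_excluded = 0L))
  extra <- attr(table, "extra")
  keep <- rep(TRUE, table$n)
  for (col in names(checks)) {
    if (!is.null(extra) && col %in% names(extra)) {
      vals <- extra[[col]]
    } else if (col %in% table$item_ids) {
      vals <- table$responses[, col]
    } else {
      stopf("attention-check column '%s' not found", col)
    }
    keep <- keep & (vals == checks[[col]])
  }
  n_excluded <- sum(!keep)
  if (n_excluded == table$n)
    stopf("attention filter excluded every respondent")
  out <- item_response_table(table$responses[keep, , drop = FALSE],
                             table$cluster_of)
  if (!is.null(extra)) attr(out, "extra") <- extra[keep, , drop = FALSE]
  list(table = out, n_excluded = n_excluded)
}

# moment skewness g1 and excess kurtosis g2 (bias-uncorrected)
moment_shape <- function(x) {
  n <- length(x)
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  if (m2 == 0) return(c(skewness = NA_real_, kurtosis = NA_real_))
  c(skewness = mean(d^3) / m2^1.5, kurtosis = mean(d^4) / m2^2 - 3)
}

#' Per-item and per-cluster descriptive statistics
#'
#' Mean, standard deviation (n-1 denominator), moment skewness g1 and excess
#' kurtosis g2 for every item, plus summed-score mean/SD and McDonald's
#' omega for every cluster. A constant item gets `NA` shape statistics
#' rather than an error.
#'
#' @param table an `item_response_table` with `n >= 2`.
#' @return A list with data frames `items` (item, cluster, mean, sd,
#'   skewness, kurtosis) and `clusters` (cluster, n_items, total_mean,
#'   total_sd, omega).
#' @export
descriptives <- function(table) {
  if (table$n < 2) stopf("need at least 2 respondents")
  X <- table$responses
  shape <- t(apply(X, 2, moment_shape))
  items <- data.frame(
    item = table$item_ids,
    cluster = unname(table$cluster_of),
    mean = colMeans(X),
    sd = apply(X, 2, sd),
    skewness = shape[, "skewness"],
    kurtosis = shape[, "kurtosis"],
    row.names = NULL)
  clusters <- lapply(unique(table$cluster_of), function(cl) {
    members <- table$item_ids[table$cluster_of == cl]
    total <- rowSums(X[, members, drop = FALSE])
    omega <- if (length(members) >= 3)
      mcdonalds_omega(table, items = members) else NA_real_
    data.frame(cluster = cl, n_items = length(members),
               total_mean = mean(total), total_sd = sd(total), omega = omega)
  })
  list(items = items, clusters = do.call(rbind, clusters))
}

# iterated principal-factor extraction of a single factor from a
# covariance matrix; returns loadings and uniquenesses
one_factor_fit <- function(C, tol = 1e-8, maxit = 10000) {
  p <- nrow(C)
  v <- diag(C)
  # initial communalities: squared multiple correlations when C invertible
  h <- tryCatch(v - 1 / diag(solve(C)), error = function(e) 0.5 * v)
  if (any(!is.finite(h)) || any(h < 0)) h <- 0.5 * v
  for (it in seq_len(maxit)) {
    Cr <- C
    diag(Cr) <- h
    e <- eigen(Cr, symmetric = TRUE)
    lam <- e$vectors[, 1] * sqrt(max(e$values[1], 0))
    if (sum(lam) < 0) lam <- -lam
    h_new <- pmin(lam^2, v * (1 - 1e-6))
    if (max(abs(h_new - h)) < tol) { h <- h_new; break }
    h <- h_new
  }
  theta <- v - lam^2
  if (any(theta <= 0)) {
    warnf("Heywood case: %d uniqueness(es) clamped to a small positive value",
          sum(theta <= 0))
    theta <- pmax(theta, 1e-6 * v)
  }
  list(loadings = lam, uniquenesses = theta, iterations = it)
}

#' McDonald's omega (omega-total, single factor)
#'
#' Internal-consistency reliability from a one-factor model of the item
#' covariance matrix: omega = (sum lambda)^2 / ((sum lambda)^2 + sum theta)
#' with loadings lambda and uniquenesses theta estimated by iterated
#' principal-factor extraction (tolerance 1e-8). Negative uniquenesses
#' (Heywood cases) are clamped to a small positive value with a warning.
#'
#' @param table an `item_response_table`.
#' @param items character vector of item ids to include (default: all);
#'   at least 3 items are required.
#' @return Omega as a single number in (0, 1].
#' @export
mcdonalds_omega <- function(table, items = table$item_ids) {
  if (length(items) < 3) stopf("omega needs at least 3 items")
  X <- table$responses[, items, drop = FALSE]
  C <- cov(X)
  fit <- one_factor_fit(C)
  s <- sum(fit$loadings)
  s^2 / (s^2 + sum(fit$uniquenesses))
}

#' Write a descriptive-statistics table to CSV
#'
#' @param desc result of [descriptives()].
#' @param path output file path for the per-item table; the per-cluster
#'   table goes to the same path with a `_clusters` suffix.
#' @return Invisibly, the two paths written.
#' @export
write_descriptives <- function(desc, path) {
  write.csv(desc$items, path, row.names = FALSE)
  cpath <- sub("(\\.[^.]+)?$", "_clusters\\1", path)
  write.csv(desc$clusters, cpath, row.names = FALSE)
  invisible(c(path, cpath))
}
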