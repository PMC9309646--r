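#' Penalty path for the graphical lasso
#'
#' Log-spaced sequence of `n_lambdas` penalties from `lambda_max` (the
#' largest absolute off-diagonal correlation, at which the estimated
#' network is empty) down to `min_ratio * lambda_max`.
#'
#' @param cm a `correlation_matrix` or plain matrix.
#' @param n_lambdas number of penalties, default 100.
#' @param min_ratio ratio of the smallest to the largest penalty, default
#'   0.01.
#' @return List of class `lambda_path` with `lambdas` (strictly
#'   decreasing), `n_lambdas`, `min_ratio`.
#' @export
lambda_path <- function(cm, n_lambdas = 100, min_ratio = 0.01) {
  S <- if (inherits(cm, "correlation_matrix")) cm$S else as.matrix(cm)
  if (n_lambdas < 2) stopf("n_lambdas must be >= 2")
  if (min_ratio <= 0 || min_ratio >= 1) stopf("min_ratio must be in (0, 1)")
  off <- S[upper.tri(S)]
  lmax <- max(abs(off))
  if (lmax == 0) {
    warnf("all off-diagonal correlations are zero; degenerate path at 0")
    return(structure(list(lambdas = 0, n_lambdas = 1L, min_ratio = min_ratio),
                     class = "lambda_path"))
  }
  lams <- exp(seq(log(lmax), log(min_ratio * lmax), length.out = n_lambdas))
  structure(list(lambdas = lams, n_lambdas = as.integer(n_lambdas),
                 min_ratio = min_ratio),
            class = "lambda_path")
}

#' Graphical lasso at a single penalty
#'
#' L1-penalized maximum-likelihood estimate of the precision (inverse
#' covariance) matrix: maximizes
#' `log det(Theta) - trace(S Theta) - lambda * sum_{i != j} |Theta_ij|`
#' with the diagonal unpenalized, by block coordinate descent on the
#' covariance with an exact soft-thresholding inner solver (so small
#' partial covariances are estimated as exact zeros). At `lambda = 0` the
#' solution is `solve(S)`; at `lambda >= max|S_ij|` it is diagonal.
#'
#' @param cm a `correlation_matrix` (PSD; see
#'   [nearest_positive_semidefinite()]) or plain symmetric matrix.
#' @param lambda penalty, `>= 0`.
#' @param tol convergence tolerance on the maximum absolute change of the
#'   working covariance per sweep, default 1e-6.
#' @param maxit maximum outer sweeps, default 1000.
#' @return List of class `precision_matrix`: `Theta` (symmetric positive
#'   definite), `lambda`, `iterations`, `converged`.
#' @export
graphical_lasso <- function(cm, lambda, tol = 1e-6, maxit = 1000) {
  S <- if (inherits(cm, "correlation_matrix")) cm$S else as.matrix(cm)
  if (lambda < 0) stopf("lambda must be non-negative")
  fit <- glasso_cpp(S, lambda, NULL, NULL, tol, maxit)
  if (!fit$converged)
    stopf("graphical lasso did not converge at lambda = %g (last change %g)",
          lambda, fit$max_delta)
  Theta <- fit$Theta
  dimnames(Theta) <- dimnames(S)
  structure(list(Theta = Theta, lambda = lambda,
                 iterations = fit$iterations, converged = fit$converged),
            class = "precision_matrix")
}

#' Precision matrix to partial-correlation network
#'
#' `rho_ij = -Theta_ij / sqrt(Theta_ii * Theta_jj)`, diagonal set to zero.
#' Exact zeros of `Theta` map to exact zeros of `rho`, so the sparsity
#' pattern is preserved.
#'
#' @param pm a `precision_matrix` (or plain SPD matrix).
#' @return Object of class `pcor_network`: `weights` (symmetric, zero
#'   diagonal), `node_ids`, and (when produced by [estimate_network()])
#'   `selected_lambda`, `gamma`, `n_edges`, `path_summary`.
#' @export
to_partial_correlations <- function(pm) {
  Theta <- if (inherits(pm, "precision_matrix")) pm$Theta else as.matrix(pm)
  d <- diag(Theta)
  if (any(d <= 0)) stopf("precision matrix has a non-positive diagonal")
  isd <- 1 / sqrt(d)
  W <- -Theta * tcrossprod(isd)
  diag(W) <- 0
  W <- (W + t(W)) / 2
  structure(list(weights = W,
                 node_ids = colnames(W) %||% paste0("V", seq_len(ncol(W))),
                 selected_lambda = if (inherits(pm, "precision_matrix")) pm$lambda else NA_real_,
                 gamma = NA_real_,
                 n_edges = sum(W[upper.tri(W)] != 0),
                 path_summary = NULL),
            class = "pcor_network")
}

#' @export
print.pcor_network <- function(x, ...) {
  p <- ncol(x$weights)
  cat(sprintf("pcor_network: %d nodes, %d / %d edges", p, x$n_edges,
              p * (p - 1) / 2))
  if (!is.na(x$selected_lambda))
    cat(sprintf(" (lambda = %.4g)", x$selected_lambda))
  cat("\n")
  invisible(x)
}

#' Gaussian log-likelihood of a precision matrix
#'
#' `L = (n/2) * (log det Theta - trace(S Theta))`, the multivariate-normal
#' log-likelihood up to an additive constant that is the same for every
#' model on a path (and therefore cancels in information criteria).
#'
#' @param cm sample correlation/covariance (`correlation_matrix` or matrix).
#' @param pm `precision_matrix` or SPD matrix.
#' @param n sample size.
#' @return Log-likelihood (single number).
#' @export
gaussian_loglik <- function(cm, pm, n) {
  S <- if (inherits(cm, "correlation_matrix")) cm$S else as.matrix(cm)
  Theta <- if (inherits(pm, "precision_matrix")) pm$Theta else as.matrix(pm)
  ch <- chol(Theta)
  (n / 2) * (2 * sum(log(diag(ch))) - sum(S * Theta))
}

#' Extended Bayesian information criterion
#'
#' `EBIC = -2 L + E log(n) + 4 gamma E log(p)` for a Gaussian graphical
#' model with `E` edges among `p` nodes fitted to `n` observations. The
#' hyperparameter `gamma` in `[0, 1]` trades sensitivity (0, plain BIC)
#' against specificity (larger values select sparser networks).
#'
#' @param L log-likelihood.
#' @param E edge count (non-zero upper-triangle entries).
#' @param n sample size.
#' @param p node count.
#' @param gamma sparsity hyperparameter, default 0.5.
#' @return EBIC value (smaller is better).
#' @export
ebic <- function(L, E, n, p, gamma = 0.5) {
  if (E < 0 || n < 1 || p < 1 || gamma < 0) stopf("invalid EBIC arguments")
  -2 * L + E * log(n) + 4 * gamma * E * log(p)
}

#' Estimate a regularized partial-correlation network
#'
#' The package's central estimator: fits the graphical lasso at every
#' penalty on a log-spaced path, scores each fit by EBIC (edges counted
#' from the exact zeros of the partial-correlation matrix; no post-hoc
#' thresholding), and returns the network at the EBIC-minimizing penalty.
#' Ties prefer the sparser (larger-penalty) fit.
#'
#' @param x an `item_response_table` (Spearman correlations are computed,
#'   PSD-repaired if needed) or a `correlation_matrix`.
#' @param gamma EBIC hyperparameter, default 0.5.
#' @param n sample size; taken from `x` when omitted.
#' @param n_lambdas,min_ratio path parameters, see [lambda_path()].
#' @param tol,maxit solver controls, see [graphical_lasso()].
#' @return A `pcor_network` with `selected_lambda`, `gamma`, `n_edges` and
#'   a `path_summary` data frame (lambda, loglik, n_edges, ebic).
#' @export
estimate_network <- function(x, gamma = 0.5, n = NULL,
                             n_lambdas = 100, min_ratio = 0.01,
                             tol = 1e-6, maxit = 1000) {
  if (inherits(x, "item_response_table")) {
    cm <- nearest_positive_semidefinite(spearman_matrix(x))
  } else if (inherits(x, "correlation_matrix")) {
    cm <- x
  } else {
    stopf("x must be an item_response_table or correlation_matrix")
  }
  n <- n %||% cm$n
  if (is.null(n) || is.na(n)) stopf("sample size n is required")
  S <- cm$S
  p <- ncol(S)
  path <- lambda_path(cm, n_lambdas = n_lambdas, min_ratio = min_ratio)
  fits <- glasso_path_cpp(S, path$lambdas, tol, maxit)
  if (!all(fits$converged)) {
    bad <- which(!fits$converged)[1]
    stopf("graphical lasso did not converge at lambda = %g",
          path$lambdas[bad])
  }
  nl <- length(path$lambdas)
  logliks <- edges <- numeric(nl)
  pcors <- vector("list", nl)
  ut <- upper.tri(S)
  for (l in seq_len(nl)) {
    Theta <- fits$thetas[[l]]
    isd <- 1 / sqrt(diag(Theta))
    W <- -Theta * tcrossprod(isd)
    diag(W) <- 0
    W <- (W + t(W)) / 2
    pcors[[l]] <- W
    edges[l] <- sum(W[ut] != 0)
    ch <- chol(Theta)
    logliks[l] <- (n / 2) * (2 * sum(log(diag(ch))) - sum(S * Theta))
  }
  ebics <- -2 * logliks + edges * log(n) + 4 * gamma * edges * log(p)
  summary <- data.frame(lambda = path$lambdas, loglik = logliks,
                        n_edges = edges, ebic = ebics)
  best <- which.min(ebics)  # first minimum = largest lambda = sparsest
  W <- pcors[[best]]
  dimnames(W) <- dimnames(S)
  structure(list(weights = W,
                 node_ids = colnames(S) %||% paste0("V", seq_len(p)),
                 selected_lambda = path$lambdas[best], gamma = gamma,
                 n_edges = as.integer(edges[best]), path_summary = summary,
                 n = n, pd_adjusted = cm$pd_adjusted),
            class = "pcor_network")
}

#' Write a network as edge list and matrix CSVs
#'
#' @param net a `pcor_network`.
#' @param prefix file-path prefix; writes `<prefix>_edges.csv`,
#'   `<prefix>_matrix.csv` and, when present, `<prefix>_path.csv`.
#' @param cluster_of optional named cluster map to annotate the edge list.
#' @return Invisibly, the paths written.
#' @export
write_network <- function(net, prefix, cluster_of = NULL) {
  W <- net$weights
  pairs <- upper_pairs(ncol(W), net$node_ids)
  edges <- data.frame(node_a = pairs$node_a, node_b = pairs$node_b,
                      weight = W[cbind(pairs$i, pairs$j)])
  if (!is.null(cluster_of)) {
    edges$cluster_a <- unname(cluster_of[edges$node_a])
    edges$cluster_b <- unname(cluster_of[edges$node_b])
  }
  paths <- c(paste0(prefix, "_edges.csv"), paste0(prefix, "_matrix.csv"))
  write.csv(edges, paths[1], row.names = FALSE)
  write.csv(data.frame(node = net$node_ids, W, check.names = FALSE),
            paths[2], row.names = FALSE)
  if (!is.null(net$path_summary)) {
    paths <- c(paths, paste0(prefix, "_path.csv"))
    write.csv(net$path_summary, paths[3], row.names = FALSE)
  }
  invisible(paths)
}
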