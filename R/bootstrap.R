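#' Bootstrap specification
#'
#' Bundles every knob of the accuracy/stability machinery: replicate count,
#' master seed, significance level, the case-dropping grid, and the
#' CS-coefficient rule (probability `cs_probability` of correlating at
#' least `cs_threshold` with the full-sample statistic).
#'
#' @param B replicate count, default 2000.
#' @param seed master RNG seed; child seeds for replicates are derived
#'   deterministically from it, so results do not depend on worker count.
#' @param alpha significance level for CIs and difference tests, default 0.05.
#' @param drop_proportions case-dropping grid, default `seq(0.05, 0.75, 0.05)`.
#' @param cs_threshold correlation threshold of the CS rule, default 0.7.
#' @param cs_probability required probability of the CS rule, default 0.95.
#' @return List of class `bootstrap_spec`.
#' @export
bootstrap_spec <- function(B = 2000, seed = 1, alpha = 0.05,
                           drop_proportions = seq(0.05, 0.75, by = 0.05),
                           cs_threshold = 0.7, cs_probability = 0.95) {
  if (B < 1) stopf("B must be >= 1")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  if (any(drop_proportions <= 0 | drop_proportions >= 1))
    stopf("drop proportions must lie strictly in (0, 1)")
  structure(list(B = as.integer(B), seed = as.integer(seed), alpha = alpha,
                 drop_proportions = drop_proportions,
                 cs_threshold = cs_threshold, cs_probability = cs_probability),
            class = "bootstrap_spec")
}

# run the full estimation pipeline on a response matrix; estimator is a
# list of estimate_network settings
estimate_from_rows <- function(X, cluster_of, estimator) {
  tab <- item_response_table(X, cluster_of)
  do.call(estimate_network, c(list(x = tab), estimator))
}

#' Nonparametric bootstrap of the network estimator
#'
#' Draws `B` n-out-of-n resamples of the respondents (rows, with
#' replacement) and re-runs the entire estimation — Spearman correlation,
#' PSD repair if needed, graphical-lasso path, EBIC selection — on each.
#' Replicates are seeded individually from the master seed, so results are
#' reproducible and independent of any parallel scheduling. Replicates
#' whose estimation fails are recorded and skipped; more than 5% failures
#' is an error.
#'
#' @param table an `item_response_table`.
#' @param spec a `bootstrap_spec`.
#' @param estimator list of settings passed to [estimate_network()]
#'   (gamma, n_lambdas, min_ratio, ...).
#' @return Object of class `network_boot`: `point` (the full-sample
#'   network), `edge_weights` (B x n_pairs matrix of upper-triangle
#'   weights), `ei`, `bei` (`NULL` unless clusters given), `pairs`,
#'   `failed`, `spec`.
#' @param cluster_of optional cluster map; when supplied, per-replicate
#'   expected influence and bridge expected influence are stored too.
#' @export
nonparametric_boot <- function(table, spec = bootstrap_spec(),
                               estimator = list(), cluster_of = NULL) {
  point <- do.call(estimate_network, c(list(x = table), estimator))
  p <- table$p
  pairs <- upper_pairs(p, table$item_ids)
  ut <- cbind(pairs$i, pairs$j)
  edge_weights <- matrix(NA_real_, spec$B, nrow(pairs))
  colnames(edge_weights) <- paste(pairs$node_a, pairs$node_b, sep = "--")
  ei <- matrix(NA_real_, spec$B, p, dimnames = list(NULL, table$item_ids))
  bei <- if (!is.null(cluster_of)) ei else NULL
  failed <- integer(0)
  for (b in seq_len(spec$B)) {
    set.seed(child_seed(spec$seed, b))
    rows <- sample.int(table$n, table$n, replace = TRUE)
    net <- tryCatch(
      estimate_from_rows(table$responses[rows, , drop = FALSE],
                         table$cluster_of, estimator),
      error = function(e) NULL)
    if (is.null(net)) { failed <- c(failed, b); next }
    edge_weights[b, ] <- net$weights[ut]
    ei[b, ] <- expected_influence(net)
    if (!is.null(bei)) bei[b, ] <- bridge_expected_influence(net, cluster_of)
  }
  if (length(failed) > 0.05 * spec$B)
    stopf("%d of %d bootstrap replicates failed", length(failed), spec$B)
  if (length(failed))
    warnf("%d bootstrap replicate(s) failed and were skipped", length(failed))
  structure(list(point = point, edge_weights = edge_weights, ei = ei,
                 bei = bei, pairs = pairs, failed = failed, spec = spec),
            class = "network_boot")
}

#' Bootstrap confidence intervals of the edge weights
#'
#' Per-edge empirical quantiles at `alpha/2` and `1 - alpha/2` of the
#' replicate edge weights, alongside the full-sample point estimate and
#' the bootstrap mean.
#'
#' @param boot a `network_boot`.
#' @param spec optionally override the spec stored in `boot`.
#' @return Data frame: node_a, node_b, estimate, boot_mean, lower, upper.
#' @export
edge_cis <- function(boot, spec = boot$spec) {
  ok <- setdiff(seq_len(spec$B), boot$failed)
  W <- boot$edge_weights[ok, , drop = FALSE]
  qs <- apply(W, 2, quantile, probs = c(spec$alpha / 2, 1 - spec$alpha / 2),
              names = FALSE)
  ut <- cbind(boot$pairs$i, boot$pairs$j)
  data.frame(node_a = boot$pairs$node_a, node_b = boot$pairs$node_b,
             estimate = boot$point$weights[ut],
             boot_mean = colMeans(W), lower = qs[1, ], upper = qs[2, ],
             row.names = NULL)
}

#' Bootstrapped difference tests
#'
#' For every pair of edges (or of node centralities), the bootstrap CI of
#' the replicate-wise difference; a pair differs significantly when that
#' CI excludes zero at `alpha`. No multiplicity correction is applied by
#' default, matching common practice; `p_adjust = "bonferroni"` tightens
#' alpha family-wise.
#'
#' @param boot a `network_boot`.
#' @param kind `"edges"`, `"ei"` or `"bei"`.
#' @param spec optionally override the stored spec.
#' @param p_adjust `"none"` (default) or `"bonferroni"`.
#' @return List of class `difference_test`: `significant` (symmetric
#'   logical matrix, `FALSE` diagonal), `lower`, `upper`, `labels`, `kind`.
#' @export
difference_test <- function(boot, kind = c("edges", "ei", "bei"),
                            spec = boot$spec, p_adjust = c("none", "bonferroni")) {
  kind <- match.arg(kind)
  p_adjust <- match.arg(p_adjust)
  M <- switch(kind, edges = boot$edge_weights, ei = boot$ei, bei = boot$bei)
  if (is.null(M)) stopf("replicate store lacks '%s' statistics", kind)
  ok <- setdiff(seq_len(spec$B), boot$failed)
  M <- M[ok, , drop = FALSE]
  m <- ncol(M)
  alpha <- spec$alpha
  if (p_adjust == "bonferroni") alpha <- alpha / (m * (m - 1) / 2)
  lower <- upper <- matrix(0, m, m, dimnames = list(colnames(M), colnames(M)))
  for (a in seq_len(m - 1)) {
    d <- M[, (a + 1):m, drop = FALSE] - M[, a]
    qs <- apply(d, 2, quantile, probs = c(alpha / 2, 1 - alpha / 2),
                names = FALSE)
    lower[a, (a + 1):m] <- qs[1, ]
    upper[a, (a + 1):m] <- qs[2, ]
    lower[(a + 1):m, a] <- qs[1, ]
    upper[(a + 1):m, a] <- qs[2, ]
  }
  sig <- lower > 0 | upper < 0
  diag(sig) <- FALSE
  structure(list(significant = sig, lower = lower, upper = upper,
                 labels = colnames(M), kind = kind, alpha = alpha),
            class = "difference_test")
}

#' Case-dropping bootstrap for centrality stability
#'
#' For each proportion `q` in the drop grid, draws `B` subsamples of
#' `round((1 - q) n)` respondents without replacement, re-runs the entire
#' estimation on each, and correlates (Pearson) the subsample centrality
#' vector with the full-sample one. Proportions whose retained sample
#' would have fewer than `p + 1` rows are skipped with a warning.
#'
#' @param table an `item_response_table`.
#' @param spec a `bootstrap_spec` (`B`, `seed`, grid, CS rule).
#' @param statistic which centralities to track: any of `"ei"`, `"bei"`.
#' @param estimator settings for [estimate_network()].
#' @param cluster_of cluster map (required for `"bei"`); defaults to the
#'   table's own map.
#' @return Object of class `stability_result`: `correlations` (long data
#'   frame: statistic, proportion, replicate, correlation), `full` (the
#'   full-sample centralities), `spec`.
#' @export
case_dropping_boot <- function(table, spec = bootstrap_spec(),
                               statistic = c("ei", "bei"),
                               estimator = list(),
                               cluster_of = table$cluster_of) {
  statistic <- match.arg(statistic, several.ok = TRUE)
  point <- do.call(estimate_network, c(list(x = table), estimator))
  full <- list()
  if ("ei" %in% statistic) full$ei <- expected_influence(point)
  if ("bei" %in% statistic)
    full$bei <- bridge_expected_influence(point, cluster_of)
  rows <- list()
  for (qi in seq_along(spec$drop_proportions)) {
    q <- spec$drop_proportions[qi]
    m <- round((1 - q) * table$n)
    if (m < table$p + 1) {
      warnf("drop proportion %.2f leaves only %d rows; skipped", q, m)
      next
    }
    for (b in seq_len(spec$B)) {
      set.seed(child_seed(spec$seed, qi * 1000000L + b))
      keep <- sample.int(table$n, m, replace = FALSE)
      net <- tryCatch(
        estimate_from_rows(table$responses[keep, , drop = FALSE],
                           table$cluster_of, estimator),
        error = function(e) NULL)
      for (st in statistic) {
        val <- if (is.null(net)) NA_real_ else {
          sub <- if (st == "ei") expected_influence(net)
                 else bridge_expected_influence(net, cluster_of)
          if (sd(sub) == 0 || sd(full[[st]]) == 0) NA_real_
          else cor(full[[st]], sub)
        }
        rows[[length(rows) + 1L]] <-
          data.frame(statistic = st, proportion = q, replicate = b,
                     correlation = val)
      }
    }
  }
  corrs <- do.call(rbind, rows)
  # monotonicity sanity check on the mean correlation
  for (st in statistic) {
    sub <- corrs[corrs$statistic == st, ]
    mu <- tapply(sub$correlation, sub$proportion, mean, na.rm = TRUE)
    if (any(diff(mu) > 0.05, na.rm = TRUE))
      warnf("mean %s stability correlation is not non-increasing in the drop proportion", st)
  }
  structure(list(correlations = corrs, full = full, spec = spec),
            class = "stability_result")
}

#' Correlation-stability (CS) coefficient
#'
#' The largest drop proportion `q` such that at least `cs_probability` of
#' the replicates at `q` correlate at least `cs_threshold` with the
#' full-sample statistic; 0 when no grid point qualifies. Values of 0.25
#' and 0.5 are the conventional acceptable/ideal benchmarks.
#'
#' @param result a `stability_result`.
#' @param statistic `"ei"` or `"bei"`.
#' @param spec optionally override the stored spec.
#' @return CS-coefficient (a proportion from the grid, or 0).
#' @export
cs_coefficient <- function(result, statistic = "ei", spec = result$spec) {
  sub <- result$correlations[result$correlations$statistic == statistic, ]
  if (nrow(sub) == 0) stopf("no stability replicates for '%s'", statistic)
  qs <- sort(unique(sub$proportion))
  qualifies <- vapply(qs, function(q) {
    r <- sub$correlation[sub$proportion == q]
    # missing correlations (failed replicates, undefined correlation) count
    # against the rule rather than being dropped
    mean(!is.na(r) & r >= spec$cs_threshold) >= spec$cs_probability
  }, logical(1))
  if (any(qualifies)) max(qs[qualifies]) else 0
}

#' Write bootstrap outputs as CSV/JSON
#'
#' @param cis result of [edge_cis()].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_edge_cis <- function(cis, path) {
  write.csv(cis, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_cis
#' @param stab a `stability_result`; written long-format plus a JSON
#'   summary of CS values.
#' @param prefix path prefix for `<prefix>_stability.csv` and
#'   `<prefix>_cs.json`.
#' @export
write_stability <- function(stab, prefix) {
  paths <- c(paste0(prefix, "_stability.csv"), paste0(prefix, "_cs.json"))
  write.csv(stab$correlations, paths[1], row.names = FALSE)
  cs <- lapply(names(stab$full), function(st) cs_coefficient(stab, st))
  names(cs) <- names(stab$full)
  jsonlite::write_json(cs, paths[2], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
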