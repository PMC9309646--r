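#' One-step expected influence
#'
#' The signed sum of a node's edge weights, `ei_i = sum_{j != i} rho_ij`.
#' Unlike strength centrality this keeps the sign of negative edges, which
#' matters in networks that contain them.
#'
#' @param net a `pcor_network` (or plain symmetric zero-diagonal matrix).
#' @return Named numeric vector of expected influence per node.
#' @export
expected_influence <- function(net) {
  W <- if (inherits(net, "pcor_network")) net$weights else as.matrix(net)
  out <- rowSums(W)
  names(out) <- colnames(W) %||% paste0("V", seq_len(ncol(W)))
  out
}

#' Bridge expected influence over two pre-defined clusters
#'
#' The sum of a node's edge weights to nodes of the other cluster,
#' `bei_i = sum_{j : cluster(j) != cluster(i)} rho_ij`. Requires exactly
#' two non-empty clusters covering all nodes.
#'
#' @param net a `pcor_network` or matrix.
#' @param cluster_of named character vector mapping every node to one of
#'   two cluster labels.
#' @return Named numeric vector of bridge expected influence per node.
#' @export
bridge_expected_influence <- function(net, cluster_of) {
  W <- if (inherits(net, "pcor_network")) net$weights else as.matrix(net)
  ids <- colnames(W) %||% paste0("V", seq_len(ncol(W)))
  if (!all(ids %in% names(cluster_of)))
    stopf("cluster map is missing node(s): %s",
          paste(setdiff(ids, names(cluster_of)), collapse = ", "))
  cl <- cluster_of[ids]
  labs <- unique(cl)
  if (length(labs) != 2) stopf("exactly two clusters are required, got %d",
                               length(labs))
  other <- outer(cl, cl, FUN = "!=")
  out <- rowSums(W * other)
  names(out) <- ids
  out
}

#' Standardize a vector of centrality values
#'
#' `(x - mean) / sd` with the n-1 standard deviation. A constant input
#' yields all zeros with a warning instead of NaN.
#'
#' @param values numeric vector, length at least 2.
#' @return z-scores, same names as input.
#' @export
standardize <- function(values) {
  if (length(values) < 2) stopf("need at least 2 values to standardize")
  s <- sd(values)
  if (s == 0) {
    warnf("constant centrality values; z-scores set to 0")
    return(values * 0)
  }
  (values - mean(values)) / s
}

#' Blind percentile cutoff for node selection
#'
#' Selects the `floor(p * (1 - percentile/100))` highest-valued nodes —
#' with 21 nodes at the 85th percentile, exactly 3. Ties at the boundary
#' are broken by stable input order with a warning.
#'
#' @param values named numeric vector (one value per node).
#' @param percentile cutoff percentile in (0, 100), default 85.
#' @return Character vector of selected node names (in input order).
#' @export
select_top_percentile <- function(values, percentile = 85) {
  if (percentile <= 0 || percentile >= 100)
    stopf("percentile must be in (0, 100)")
  p <- length(values)
  k <- floor(p * (1 - percentile / 100))
  if (k == 0) return(character(0))
  ord <- order(values, decreasing = TRUE)  # stable: ties keep input order
  cutoff <- values[ord[k]]
  if (k < p && values[ord[k + 1]] == cutoff)
    warnf("tie at the %g-th percentile boundary (value %g); broken by node order",
          percentile, cutoff)
  selected <- sort(ord[seq_len(k)])
  names(values)[selected] %||% as.character(selected)
}

#' Centrality table with percentile-based selection flags
#'
#' Combines raw and standardized expected influence and bridge expected
#' influence with `is_central` / `is_bridge` flags from the blind
#' percentile cutoff.
#'
#' @param net a `pcor_network`.
#' @param cluster_of named two-cluster map over the nodes.
#' @param percentile selection percentile, default 85.
#' @return A data frame of class `centrality_table`: node, cluster, ei,
#'   ei_z, bei, bei_z, is_central, is_bridge.
#' @export
centrality_table <- function(net, cluster_of, percentile = 85) {
  ei <- expected_influence(net)
  bei <- bridge_expected_influence(net, cluster_of)
  central <- select_top_percentile(ei, percentile)
  bridge <- select_top_percentile(bei, percentile)
  out <- data.frame(
    node = names(ei),
    cluster = unname(cluster_of[names(ei)]),
    ei = unname(ei), ei_z = unname(standardize(ei)),
    bei = unname(bei), bei_z = unname(standardize(bei)),
    is_central = names(ei) %in% central,
    is_bridge = names(ei) %in% bridge,
    row.names = NULL)
  class(out) <- c("centrality_table", "data.frame")
  out
}
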