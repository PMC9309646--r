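#' Configuration for a full analysis run
#'
#' Validates and freezes every setting of an end-to-end run so the run can
#' be reproduced from its serialized config alone.
#'
#' @param input path to a response CSV, or `NULL` to use the synthetic
#'   profile.
#' @param cluster_of named cluster map (required with `input`).
#' @param checks attention-check spec (named codes) or `NULL`.
#' @param profile `"iu_psu"` to simulate the default two-cluster profile
#'   when no input file is given.
#' @param n synthetic sample size (profile runs only).
#' @param gamma EBIC hyperparameter, default 0.5.
#' @param n_lambdas,min_ratio penalty-path settings.
#' @param percentile node-selection percentile, default 85.
#' @param boot a `bootstrap_spec` or `NULL` to skip bootstraps.
#' @param layout_seed,layout_iterations force-directed layout settings.
#' @param cut_value display-only cut for the figure, default 0.03.
#' @param seed master seed of the run.
#' @param out output directory, or `NULL` to write nothing.
#' @return List of class `run_config`.
#' @export
run_config <- function(input = NULL, cluster_of = NULL, checks = NULL,
                       profile = "iu_psu", n = 1849, gamma = 0.5,
                       n_lambdas = 100, min_ratio = 0.01, percentile = 85,
                       boot = bootstrap_spec(B = 2000),
                       layout_seed = 42, layout_iterations = 500,
                       cut_value = 0.03, seed = 1, out = NULL) {
  if (is.null(input) && !identical(profile, "iu_psu"))
    stopf("unknown synthetic profile '%s'", profile)
  if (!is.null(input) && is.null(cluster_of))
    stopf("cluster_of is required when reading an input file")
  if (gamma < 0) stopf("gamma must be non-negative")
  if (percentile <= 0 || percentile >= 100) stopf("percentile must be in (0, 100)")
  structure(list(input = input, cluster_of = cluster_of, checks = checks,
                 profile = profile, n = n, gamma = gamma,
                 n_lambdas = n_lambdas, min_ratio = min_ratio,
                 percentile = percentile, boot = boot,
                 layout_seed = layout_seed,
                 layout_iterations = layout_iterations,
                 cut_value = cut_value, seed = seed, out = out),
            class = "run_config")
}

#' Structural summary of a network
#'
#' Edge count, possible edges `p(p-1)/2`, density, positive/negative
#' counts, weight range, and the strongest within- and between-cluster
#' edges.
#'
#' @param net a `pcor_network`.
#' @param cluster_of named two-cluster map.
#' @param top_k how many strongest edges to list per group, default 3.
#' @return List of class `network_summary` with fields `n_nodes`,
#'   `n_edges`, `possible_edges`, `density`, `n_positive`, `n_negative`,
#'   `min_weight`, `max_weight`, `top_within`, `top_between`.
#' @export
network_summary <- function(net, cluster_of, top_k = 3) {
  W <- net$weights
  p <- ncol(W)
  pairs <- upper_pairs(p, net$node_ids)
  w <- W[cbind(pairs$i, pairs$j)]
  pairs$weight <- w
  pairs$between <- cluster_of[pairs$node_a] != cluster_of[pairs$node_b]
  nz <- pairs[pairs$weight != 0, ]
  top <- function(sub) {
    sub <- sub[order(-abs(sub$weight)), c("node_a", "node_b", "weight")]
    utils::head(sub, top_k)
  }
  structure(list(
    n_nodes = p,
    n_edges = nrow(nz),
    possible_edges = p * (p - 1) / 2,
    density = nrow(nz) / (p * (p - 1) / 2),
    n_positive = sum(nz$weight > 0),
    n_negative = sum(nz$weight < 0),
    min_weight = if (nrow(nz)) min(nz$weight) else 0,
    max_weight = if (nrow(nz)) max(nz$weight) else 0,
    top_within = top(nz[!nz$between, ]),
    top_between = top(nz[nz$between, ])),
    class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("%d nodes; %d of %d possible edges (%.0f%%); %d positive, %d negative\n",
              x$n_nodes, x$n_edges, x$possible_edges, 100 * x$density,
              x$n_positive, x$n_negative))
  cat(sprintf("weights in [%.3f, %.3f]\n", x$min_weight, x$max_weight))
  if (nrow(x$top_within)) {
    cat("strongest within-cluster edges:\n")
    print(x$top_within, row.names = FALSE, digits = 3)
  }
  if (nrow(x$top_between)) {
    cat("strongest between-cluster edges:\n")
    print(x$top_between, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Force-directed node layout
#'
#' Fruchterman-Reingold layout on the absolute edge weights (stronger
#' edges attract harder), with a seeded random initial placement so a
#' given seed always reproduces the same coordinates. Coordinates are
#' centered on the origin; a single node sits exactly at the origin.
#'
#' @param net a `pcor_network`.
#' @param seed layout seed, default 42.
#' @param iterations iteration count of the cooling schedule, default 500.
#' @return p x 2 matrix of coordinates, rows named by node.
#' @export
fruchterman_reingold <- function(net, seed = 42, iterations = 500) {
  W <- net$weights
  p <- ncol(W)
  if (p == 1)
    return(matrix(0, 1, 2, dimnames = list(net$node_ids, c("x", "y"))))
  g <- igraph::graph_from_adjacency_matrix(abs(W), mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(seed)
  coords <- igraph::layout_with_fr(g, niter = iterations,
                                   weights = igraph::E(g)$weight %||% numeric(0))
  coords <- scale(coords, scale = FALSE)  # center on the origin
  dimnames(coords) <- list(net$node_ids, c("x", "y"))
  attr(coords, "scaled:center") <- NULL
  coords
}

#' Render the network figure
#'
#' Display layer only: edges with |weight| below `cut_value` are hidden,
#' sign maps to color (blue positive, red negative), magnitude to line
#' width, cluster to node color. The network itself is never modified.
#'
#' @param net a `pcor_network`.
#' @param coords coordinates from [fruchterman_reingold()].
#' @param cluster_of named cluster map (node fill color).
#' @param cut_value smallest |weight| drawn, default 0.03.
#' @param file output file (`.png` or `.svg`); `NULL` draws on the active
#'   device.
#' @return Invisibly, `file`.
#' @export
render_network_plot <- function(net, coords, cluster_of, cut_value = 0.03,
                                file = NULL) {
  if (!is.null(file)) {
    if (grepl("\\.svg$", file)) grDevices::svg(file, width = 7, height = 7)
    else grDevices::png(file, width = 1400, height = 1400, res = 200)
    on.exit(grDevices::dev.off())
  }
  W <- net$weights
  p <- ncol(W)
  graphics::par(mar = c(1, 1, 1, 1))
  graphics::plot(coords, type = "n", axes = FALSE, xlab = "", ylab = "",
                 asp = 1)
  pairs <- upper_pairs(p, net$node_ids)
  w <- W[cbind(pairs$i, pairs$j)]
  show <- abs(w) >= cut_value & w != 0
  if (any(show)) {
    graphics::segments(coords[pairs$i[show], 1], coords[pairs$i[show], 2],
                       coords[pairs$j[show], 1], coords[pairs$j[show], 2],
                       col = ifelse(w[show] > 0, "#3366CCAA", "#CC3333AA"),
                       lwd = 0.5 + 8 * abs(w[show]))
  }
  cl <- factor(cluster_of[net$node_ids])
  graphics::points(coords, pch = 21, cex = 3,
                   bg = c("#F3C300", "#8DB600")[as.integer(cl)])
  graphics::text(coords, labels = net$node_ids, cex = 0.55)
  invisible(file)
}

#' Run the full analysis pipeline
#'
#' Read (or simulate) and filter the data, compute descriptives, the
#' Spearman matrix (PSD-repaired if necessary), the EBIC graphical-lasso
#' network, centrality with percentile selection, the bootstrap machinery,
#' the layout and the figure, and write every artifact plus a JSON run
#' manifest into the output directory.
#'
#' @param config a `run_config`.
#' @return List of class `report_bundle` with `table`, `descriptives`,
#'   `network`, `summary`, `centrality`, `boot`, `edge_cis`, `stability`,
#'   `cs`, `coords`, `config`, `log`.
#' @export
run_pipeline <- function(config) {
  log <- list()
  note <- function(stage, msg) log[[length(log) + 1]] <<- list(stage = stage, message = msg)

  # --- data ---
  if (!is.null(config$input)) {
    tab <- read_responses(config$input, config$cluster_of)
    note("read", sprintf("read %d rows x %d items from %s", tab$n, tab$p,
                         config$input))
  } else {
    ds <- simulate_survey(n = config$n, seed = config$seed)
    tab <- ds$table
    note("simulate", sprintf("simulated %d rows under profile '%s' (seed %d)",
                             tab$n, config$profile, config$seed))
  }
  if (!is.null(config$checks)) {
    flt <- apply_attention_filter(tab, config$checks)
    tab <- flt$table
    note("filter", sprintf("%d respondent(s) excluded by attention checks",
                           flt$n_excluded))
  }

  desc <- descriptives(tab)
  cm <- spearman_matrix(tab)
  cm2 <- nearest_positive_semidefinite(cm)
  if (cm2$pd_adjusted) note("correlation", "Spearman matrix repaired to PSD")
  estimator <- list(gamma = config$gamma, n_lambdas = config$n_lambdas,
                    min_ratio = config$min_ratio)
  net <- do.call(estimate_network, c(list(x = cm2), estimator))
  note("ggm", sprintf("selected lambda %.5f with %d edges (gamma %.2f)",
                      net$selected_lambda, net$n_edges, config$gamma))
  summ <- network_summary(net, tab$cluster_of)
  cent <- centrality_table(net, tab$cluster_of, percentile = config$percentile)

  boot <- cis <- stab <- cs <- NULL
  if (!is.null(config$boot)) {
    spec <- config$boot
    spec$seed <- as.integer(config$seed)
    boot <- nonparametric_boot(tab, spec, estimator = estimator,
                               cluster_of = tab$cluster_of)
    cis <- edge_cis(boot)
    stab <- case_dropping_boot(tab, spec, statistic = c("ei", "bei"),
                               estimator = estimator)
    cs <- list(ei = cs_coefficient(stab, "ei"),
               bei = cs_coefficient(stab, "bei"))
    note("bootstrap", sprintf("B = %d; CS(ei) = %.2f, CS(bei) = %.2f",
                              spec$B, cs$ei, cs$bei))
  }

  coords <- fruchterman_reingold(net, seed = config$layout_seed,
                                 iterations = config$layout_iterations)

  bundle <- structure(list(table = tab, descriptives = desc, network = net,
                           summary = summ, centrality = cent, boot = boot,
                           edge_cis = cis, stability = stab, cs = cs,
                           coords = coords, config = config, log = log),
                      class = "report_bundle")
  if (!is.null(config$out)) write_bundle(bundle, config$out)
  bundle
}

#' Write a report bundle to a directory
#'
#' @param bundle a `report_bundle`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- bundle$table
  write_descriptives(bundle$descriptives, file.path(dir, "descriptives.csv"))
  write_network(bundle$network, file.path(dir, "network"), tab$cluster_of)
  write.csv(as.data.frame(bundle$centrality),
            file.path(dir, "centrality.csv"), row.names = FALSE)
  if (!is.null(bundle$edge_cis))
    write_edge_cis(bundle$edge_cis, file.path(dir, "edge_cis.csv"))
  if (!is.null(bundle$stability))
    write_stability(bundle$stability, file.path(dir, "bootstrap"))
  write.csv(data.frame(node = rownames(bundle$coords), bundle$coords),
            file.path(dir, "layout.csv"), row.names = FALSE)
  s <- bundle$summary
  manifest <- list(
    seed = bundle$config$seed, gamma = bundle$config$gamma,
    percentile = bundle$config$percentile,
    n = tab$n, p = tab$p,
    n_edges = s$n_edges, possible_edges = s$possible_edges,
    density = s$density, n_positive = s$n_positive,
    n_negative = s$n_negative,
    selected_lambda = bundle$network$selected_lambda,
    cs = bundle$cs,
    log = bundle$log)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  render_network_plot(bundle$network, bundle$coords, tab$cluster_of,
                      cut_value = bundle$config$cut_value,
                      file = file.path(dir, "network.png"))
  invisible(dir)
}
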