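#' Default two-cluster emulation profile
#'
#' The package's reference simulation profile: a 21-node network of 12
#' intolerance-of-uncertainty (IU) items and 9 problematic-smartphone-use
#' (PSU) items with the marginal moments of a large published university
#' sample (n = 1,849), about two thirds of all possible edges present,
#' mostly positive weights with a handful of small negative ones, the
#' strongest within-cluster edge near 0.43 (IU1--IU2), the strongest
#' within-PSU edge 0.31 (PSU2--PSU3), and a planted strongest bridge edge
#' of 0.11 between IU2 and PSU8.
#'
#' @return Data frame with columns item, cluster, mean, sd: the per-item
#'   marginal targets used to calibrate the Likert thresholds.
#' @export
iu_psu_moments <- function() {
  data.frame(
    item = c(paste0("IU", 1:12), paste0("PSU", 1:9)),
    cluster = c(rep("IU", 12), rep("PSU", 9)),
    mean = c(3.0, 3.0, 3.8, 3.4, 3.5, 2.9, 3.3, 2.6, 2.8, 2.8, 2.5, 2.3,
             2.7, 1.6, 1.8, 2.2, 1.6, 1.8, 1.7, 2.2, 1.5),
    sd = c(1.1, 1.1, 0.9, 1.0, 1.1, 1.1, 0.9, 1.1, 1.1, 1.1, 1.1, 1.1,
           1.0, 0.8, 0.9, 1.0, 0.8, 1.0, 0.8, 1.1, 0.8))
}

default_fixed_edges <- function() {
  data.frame(
    a = c("IU1", "PSU2", "IU2", "IU1", "IU7", "IU9", "IU4", "PSU5", "PSU1", "IU6"),
    b = c("IU2", "PSU3", "PSU8", "PSU8", "PSU1", "IU10", "IU5", "PSU6", "PSU9", "IU8"),
    weight = c(0.43, 0.31, 0.11, 0.08, -0.05, 0.25, 0.20, 0.22, 0.18, 0.16))
}

#' Construct a ground-truth partial-correlation network
#'
#' Builds a sparse two-cluster partial-correlation matrix with planted
#' "anchor" edges plus randomly placed filler edges, then verifies the
#' implied precision matrix (unit diagonal, off-diagonal `-rho`) is
#' positive definite, proportionally shrinking all weights if necessary
#' until the smallest eigenvalue exceeds `pd_margin`. The recorded
#' `shrink_factor` is 1 when no shrinking was needed.
#'
#' @param cluster_sizes named integer vector of the two cluster sizes;
#'   node ids are `<label><index>`.
#' @param within_density,between_density fraction of within-/between-
#'   cluster pairs carrying an edge.
#' @param within_range,between_range magnitude range of random filler
#'   edges, drawn uniformly.
#' @param fixed_edges data frame (a, b, weight) of planted edges; the
#'   defaults reproduce the profile described in [iu_psu_moments()].
#' @param n_negative total number of negative edges aimed for (filler
#'   edges outside the second cluster are flipped to small negatives).
#' @param negative_range magnitude range for negative filler edges.
#' @param pd_margin required smallest eigenvalue of the implied precision.
#' @param seed RNG seed for edge placement.
#' @return Object of class `ground_truth_network`: `true_pcors`,
#'   `node_ids`, `cluster_of`, `shrink_factor`, `seed`.
#' @export
make_ground_truth <- function(cluster_sizes = c(IU = 12, PSU = 9),
                              within_density = 0.76,
                              between_density = 0.56,
                              within_range = c(0.015, 0.10),
                              between_range = c(0.015, 0.06),
                              fixed_edges = default_fixed_edges(),
                              n_negative = 15,
                              negative_range = c(0.02, 0.06),
                              pd_margin = 1e-3, seed = 101) {
  if (length(cluster_sizes) != 2) stopf("exactly two clusters are required")
  labels <- names(cluster_sizes)
  node_ids <- unlist(lapply(labels, function(l)
    paste0(l, seq_len(cluster_sizes[[l]]))))
  cluster_of <- stats::setNames(rep(labels, cluster_sizes), node_ids)
  p <- length(node_ids)
  P <- matrix(0, p, p, dimnames = list(node_ids, node_ids))
  set.seed(seed)
  pairs <- upper_pairs(p, node_ids)
  pairs$type <- ifelse(cluster_of[pairs$node_a] != cluster_of[pairs$node_b],
                       "between",
                       ifelse(cluster_of[pairs$node_a] == labels[1],
                              "within1", "within2"))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  pairs$key <- key(pairs$node_a, pairs$node_b)
  fixed <- fixed_edges
  if (!is.null(fixed) && nrow(fixed)) {
    if (!all(c(fixed$a, fixed$b) %in% node_ids))
      stopf("fixed edge endpoint not among the nodes")
    fixed$key <- key(fixed$a, fixed$b)
    for (r in seq_len(nrow(fixed)))
      P[fixed$a[r], fixed$b[r]] <- P[fixed$b[r], fixed$a[r]] <- fixed$weight[r]
  }
  fill <- function(type, density, range) {
    cand <- pairs[pairs$type == type, ]
    n_target <- round(density * nrow(cand))
    have <- if (is.null(fixed)) character(0) else intersect(fixed$key, cand$key)
    free <- cand[!(cand$key %in% have), ]
    n_new <- max(0, n_target - length(have))
    if (n_new > nrow(free)) n_new <- nrow(free)
    pick <- free[sample.int(nrow(free), n_new), ]
    w <- stats::runif(n_new, range[1], range[2])
    for (r in seq_len(n_new))
      P[pick$node_a[r], pick$node_b[r]] <<- P[pick$node_b[r], pick$node_a[r]] <<- w[r]
  }
  fill("within1", within_density, within_range)
  fill("within2", within_density, within_range)
  fill("between", between_density, between_range)
  # flip small filler edges to negatives; keep the second cluster all
  # positive and never touch planted edges
  n_neg_fixed <- if (is.null(fixed)) 0L else sum(fixed$weight < 0)
  n_flip <- max(0, n_negative - n_neg_fixed)
  if (n_flip > 0) {
    cand <- pairs[pairs$type %in% c("within1", "between"), ]
    cand <- cand[!(cand$key %in% (if (is.null(fixed)) character(0) else fixed$key)), ]
    cand <- cand[P[cbind(cand$i, cand$j)] != 0, ]
    n_flip <- min(n_flip, nrow(cand))
    pick <- cand[sample.int(nrow(cand), n_flip), ]
    w <- -stats::runif(n_flip, negative_range[1], negative_range[2])
    for (r in seq_len(n_flip))
      P[pick$node_a[r], pick$node_b[r]] <- P[pick$node_b[r], pick$node_a[r]] <- w[r]
  }
  # proportional shrink until the implied precision is comfortably PD
  shrink <- 1
  for (it in 1:200) {
    Theta <- diag(p) - shrink * P
    if (min(eigen(Theta, symmetric = TRUE, only.values = TRUE)$values) >=
        pd_margin) break
    shrink <- shrink * 0.95
    if (it == 200) stopf("could not reach positive definiteness by shrinking")
  }
  if (shrink < 1)
    warnf("ground-truth weights shrunk by factor %.3f for positive definiteness", shrink)
  structure(list(true_pcors = shrink * P, node_ids = node_ids,
                 cluster_of = cluster_of, shrink_factor = shrink,
                 seed = seed),
            class = "ground_truth_network")
}

#' Covariance matrix implied by a ground-truth network
#'
#' Assembles the precision matrix with unit diagonal and off-diagonal
#' `-rho_ij`, inverts it, and rescales to unit variances. Feeding the
#' result back through [to_partial_correlations()] of its inverse recovers
#' the true partial correlations (round-trip identity).
#'
#' @param truth a `ground_truth_network`.
#' @return Correlation-scale covariance matrix (p x p).
#' @export
truth_to_covariance <- function(truth) {
  P <- truth$true_pcors
  Theta <- diag(nrow(P)) - P
  ev <- eigen(Theta, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stopf("ground truth implies a non-PD precision matrix")
  Sigma <- solve(Theta)
  d <- 1 / sqrt(diag(Sigma))
  Sigma <- Sigma * tcrossprod(d)
  Sigma <- (Sigma + t(Sigma)) / 2
  dimnames(Sigma) <- dimnames(P)
  Sigma
}

# moments of the 5-category distribution implied by cuts on a standard
# normal latent variable
threshold_moments <- function(cuts, categories = 5) {
  probs <- diff(c(0, pnorm(cuts), 1))
  k <- seq_len(categories)
  m <- sum(k * probs)
  s <- sqrt(sum(k^2 * probs) - m^2)
  list(mean = m, sd = s, probs = probs)
}

#' Likert thresholds matching target moments
#'
#' Solves a two-parameter (location, log-spacing) family of four latent
#' cut-points, `cuts = location + spacing * (-1.5, -0.5, 0.5, 1.5)`, so
#' that discretizing a standard normal yields the target mean (within
#' 0.01) and SD (within 0.05) on the 1--5 code scale. Skew then emerges
#' from the location shift rather than being fitted separately.
#'
#' @param target_mean target mean in (1, 5).
#' @param target_sd target standard deviation (population form).
#' @param categories number of categories (currently 5).
#' @param item optional item label used in error messages.
#' @return Numeric vector of 4 strictly increasing cut-points, class
#'   `likert_thresholds`, with achieved moments in attributes.
#' @export
thresholds_from_target_moments <- function(target_mean, target_sd,
                                           categories = 5, item = NULL) {
  if (categories != 5) stopf("only 5-category items are supported")
  if (target_mean <= 1 || target_mean >= 5)
    stopf("target mean must be in (1, 5)")
  if (target_sd <= 0) stopf("target sd must be positive")
  base <- c(-1.5, -0.5, 0.5, 1.5)
  obj <- function(par) {
    cuts <- par[1] + exp(par[2]) * base
    mm <- threshold_moments(cuts, categories)
    (mm$mean - target_mean)^2 + (mm$sd - target_sd)^2
  }
  best <- NULL
  for (start in list(c(0, 0), c(1, 0), c(-1, 0), c(0, -0.7))) {
    fit <- optim(start, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  cuts <- best$par[1] + exp(best$par[2]) * base
  mm <- threshold_moments(cuts, categories)
  lab <- if (is.null(item)) "" else sprintf(" for item '%s'", item)
  if (abs(mm$mean - target_mean) > 0.01)
    stopf("infeasible target mean %.2f%s (achieved %.3f)", target_mean, lab, mm$mean)
  if (abs(mm$sd - target_sd) > 0.05)
    stopf("infeasible target sd %.2f%s (achieved %.3f)", target_sd, lab, mm$sd)
  if (min(mm$probs) < 0 || mm$sd == 0)
    stopf("degenerate thresholds%s: a category has collapsed", lab)
  structure(cuts, class = "likert_thresholds",
            mean = mm$mean, sd = mm$sd, probs = mm$probs)
}

#' Sample ordinal responses from a latent Gaussian
#'
#' Draws `n` multivariate-normal latent vectors with the given covariance
#' and discretizes each item by its thresholds into codes 1--5.
#'
#' @param covariance p x p positive-definite latent covariance with item
#'   ids as dimnames.
#' @param thresholds list of `likert_thresholds` (or 4-vectors), one per
#'   item, in column order.
#' @param n sample size.
#' @param cluster_of named cluster map over the items.
#' @param seed RNG seed.
#' @return An `item_response_table`.
#' @export
sample_likert <- function(covariance, thresholds, n, cluster_of, seed = 1) {
  p <- ncol(covariance)
  if (length(thresholds) != p) stopf("need one threshold set per item")
  set.seed(seed)
  Z <- matrix(rnorm(n * p), n, p) %*% chol(covariance)
  X <- matrix(1L, n, p, dimnames = list(NULL, colnames(covariance)))
  for (j in seq_len(p))
    X[, j] <- findInterval(Z[, j], as.numeric(thresholds[[j]])) + 1L
  item_response_table(X, cluster_of)
}

#' Append attention-check columns with seeded failures
#'
#' Adds two honesty-check columns ("please choose option k") whose
#' required codes are met except in a random fraction of rows. Each check
#' fails independently with probability `1 - sqrt(1 - fail_rate)`, so the
#' probability that a row fails at least one check is exactly
#' `fail_rate`. Filtering the result with [apply_attention_filter()]
#' recovers the failing-free subset of the original table.
#'
#' @param table an `item_response_table`.
#' @param fail_rate probability that a row fails at least one check,
#'   in `[0, 1)`.
#' @param seed RNG seed.
#' @param checks named integer vector of check columns and required codes.
#' @return The table with the check columns in `attr(, "extra")` and the
#'   check spec in `attr(, "checks")`.
#' @export
inject_attention_failures <- function(table, fail_rate, seed = 1,
                                      checks = c(check_1 = 2L, check_2 = 4L)) {
  if (fail_rate < 0 || fail_rate >= 1) stopf("fail_rate must be in [0, 1)")
  set.seed(seed)
  pr <- 1 - sqrt(1 - fail_rate)
  extra <- as.data.frame(lapply(checks, function(code) {
    v <- rep(as.integer(code), table$n)
    bad <- stats::runif(table$n) < pr
    wrong <- sample(setdiff(1:5, code), sum(bad), replace = TRUE)
    v[bad] <- wrong
    v
  }))
  names(extra) <- names(checks)
  attr(table, "extra") <- extra
  attr(table, "checks") <- checks
  table
}

#' Simulate a full synthetic survey
#'
#' End-to-end generator: ground-truth network, per-item thresholds
#' calibrated to the profile's marginal moments, latent-Gaussian sampling,
#' and (optionally) injected attention-check failures. With all defaults
#' this emulates the reference study conditions: 21 items in two clusters,
#' n = 1,849 retained respondents, Table-style marginals, and a known
#' sparse two-cluster partial-correlation truth.
#'
#' @param n sample size, default 1849.
#' @param seed master seed (drives edge placement jitter only through
#'   `truth`; sampling and failure injection use it directly).
#' @param truth a `ground_truth_network`, default [make_ground_truth()].
#' @param moments data frame (item, cluster, mean, sd) aligned with the
#'   truth's nodes, default [iu_psu_moments()].
#' @param fail_rate attention-failure rate, default 0 (no check columns).
#' @return List of class `synthetic_dataset`: `table`
#'   (`item_response_table`), `truth`, `thresholds`, `covariance`, `n`,
#'   `seed`.
#' @export
simulate_survey <- function(n = 1849, seed = 1,
                            truth = make_ground_truth(),
                            moments = iu_psu_moments(),
                            fail_rate = 0) {
  if (!identical(moments$item, truth$node_ids))
    stopf("moments table must list exactly the truth's nodes, in order")
  Sigma <- truth_to_covariance(truth)
  thresholds <- lapply(seq_len(nrow(moments)), function(i)
    thresholds_from_target_moments(moments$mean[i], moments$sd[i],
                                   item = moments$item[i]))
  names(thresholds) <- moments$item
  tab <- sample_likert(Sigma, thresholds, n, truth$cluster_of, seed = seed)
  if (fail_rate > 0)
    tab <- inject_attention_failures(tab, fail_rate, seed = seed + 1)
  structure(list(table = tab, truth = truth, thresholds = thresholds,
                 covariance = Sigma, n = n, seed = seed),
            class = "synthetic_dataset")
}

#' Write a synthetic dataset to disk
#'
#' Emits the response CSV in the same dialect [read_responses()] reads,
#' the true partial-correlation matrix as CSV, and a JSON manifest with
#' the seed and generation parameters.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_synthetic <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("responses.csv", "true_pcors.csv", "manifest.json"))
  df <- as.data.frame(dataset$table$responses)
  extra <- attr(dataset$table, "extra")
  if (!is.null(extra)) df <- cbind(df, extra)
  write.csv(df, paths[1], row.names = FALSE)
  write.csv(data.frame(node = dataset$truth$node_ids,
                       dataset$truth$true_pcors, check.names = FALSE),
            paths[2], row.names = FALSE)
  jsonlite::write_json(
    list(n = dataset$n, seed = dataset$seed,
         truth_seed = dataset$truth$seed,
         shrink_factor = dataset$truth$shrink_factor,
         cluster_of = as.list(dataset$truth$cluster_of)),
    paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
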