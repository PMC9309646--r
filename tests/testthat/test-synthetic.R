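test_that("ground truth respects requested structure and is PD", {
  truth <- make_ground_truth()
  P <- truth$true_pcors
  ut <- upper.tri(P)
  expect_equal(P, t(P))
  expect_equal(unname(diag(P)), rep(0, 21))
  expect_equal(length(truth$node_ids), 21L)
  ev <- eigen(diag(21) - P, only.values = TRUE)$values
  expect_gte(min(ev), 1e-3)
  # density near two thirds, a handful of negative edges, anchors in place
  expect_gt(sum(P[ut] != 0) / 210, 0.6)
  expect_equal(sum(P[ut] < 0), 15L)
  expect_equal(P["IU1", "IU2"], 0.43 * truth$shrink_factor)
  expect_equal(P["IU2", "PSU8"], 0.11 * truth$shrink_factor)
  expect_equal(P["IU7", "PSU1"], -0.05 * truth$shrink_factor)
  # the second cluster stays all-positive inside
  psu <- grep("^PSU", truth$node_ids, value = TRUE)
  expect_true(all(P[psu, psu] >= 0))

  empty <- make_ground_truth(within_density = 0, between_density = 0,
                             fixed_edges = NULL, n_negative = 0)
  expect_true(all(empty$true_pcors == 0))
})

test_that("covariance round-trips to the true partial correlations", {
  truth <- make_ground_truth()
  Sigma <- truth_to_covariance(truth)
  expect_equal(unname(diag(Sigma)), rep(1, 21))
  Theta <- solve(Sigma)
  P <- -Theta / sqrt(tcrossprod(diag(Theta)))
  diag(P) <- 0
  expect_equal(P, truth$true_pcors, tolerance = 1e-10)

  # p = 2 closed form: partial correlation equals marginal correlation
  t2 <- make_ground_truth(cluster_sizes = c(A = 1, B = 1),
                          within_density = 0, between_density = 0,
                          fixed_edges = data.frame(a = "A1", b = "B1",
                                                   weight = 0.5),
                          n_negative = 0)
  expect_equal(truth_to_covariance(t2)["A1", "B1"], 0.5, tolerance = 1e-12)

  # empty truth -> identity covariance
  e <- make_ground_truth(within_density = 0, between_density = 0,
                         fixed_edges = NULL, n_negative = 0)
  expect_equal(unname(truth_to_covariance(e)), diag(21))
})

test_that("threshold calibration hits target moments", {
  # symmetric targets give exactly symmetric thresholds -> mean 3
  th <- thresholds_from_target_moments(3.0, 1.1)
  expect_equal(attr(th, "mean"), 3.0, tolerance = 0.01)
  expect_equal(attr(th, "sd"), 1.1, tolerance = 0.05)
  expect_equal(as.numeric(th)[1], -as.numeric(th)[4], tolerance = 1e-4)

  # the left-skewed profile item: mean 3.8, sd 0.9 -> negative skew
  th2 <- thresholds_from_target_moments(3.8, 0.9)
  probs <- attr(th2, "probs")
  k <- 1:5
  m <- sum(k * probs)
  s <- sqrt(sum(k^2 * probs) - m^2)
  skew <- sum((k - m)^3 * probs) / s^3
  expect_equal(m, 3.8, tolerance = 0.01)
  expect_equal(s, 0.9, tolerance = 0.05)
  expect_lt(skew, -0.3)

  expect_error(thresholds_from_target_moments(0.9, 1), "in \\(1, 5\\)")
  expect_error(thresholds_from_target_moments(3, 2.5), "infeasible")
})

test_that("every default profile item is calibratable", {
  mom <- iu_psu_moments()
  for (i in seq_len(nrow(mom))) {
    th <- thresholds_from_target_moments(mom$mean[i], mom$sd[i],
                                         item = mom$item[i])
    expect_true(all(diff(as.numeric(th)) > 0))
  }
})

test_that("likert sampling is seeded, in range, and respects structure", {
  truth <- make_ground_truth()
  ds1 <- simulate_survey(n = 300, seed = 5, truth = truth)
  ds2 <- simulate_survey(n = 300, seed = 5, truth = truth)
  expect_identical(ds1$table$responses, ds2$table$responses)
  expect_true(all(ds1$table$responses %in% 1:5))

  # independent items: sample Spearman off-diagonals stay small
  e <- make_ground_truth(within_density = 0, between_density = 0,
                         fixed_edges = NULL, n_negative = 0)
  mom <- iu_psu_moments()
  di <- simulate_survey(n = 2500, seed = 6, truth = e)
  S <- spearman_matrix(di$table)$S
  expect_lt(max(abs(S[upper.tri(S)])), 3 / sqrt(2500))

  # (numerically) perfectly correlated pair with identical thresholds ->
  # identical columns
  Sig <- matrix(c(1, 1 - 1e-12, 1 - 1e-12, 1), 2, 2,
                dimnames = list(c("A1", "B1"), c("A1", "B1")))
  th <- thresholds_from_target_moments(3, 1.1)
  tab <- sample_likert(Sig, list(th, th), 500,
                       c(A1 = "A", B1 = "B"), seed = 9)
  expect_equal(tab$responses[, 1], tab$responses[, 2])
})

test_that("sample moments track the profile's Table-style targets", {
  ds <- simulate_survey(n = 4000, seed = 12)
  d <- descriptives(ds$table)
  mom <- iu_psu_moments()
  expect_lt(max(abs(d$items$mean - mom$mean)), 0.08)
  expect_lt(max(abs(d$items$sd - mom$sd)), 0.1)
  # the strongly shifted item is left-skewed in the sample too
  expect_lt(d$items$skewness[d$items$item == "IU3"], -0.2)
})

test_that("attention-failure injection round-trips through the filter", {
  ds <- simulate_survey(n = 500, seed = 15)
  clean <- ds$table

  none <- inject_attention_failures(clean, 0, seed = 1)
  flt0 <- apply_attention_filter(none, attr(none, "checks"))
  expect_equal(flt0$n_excluded, 0L)
  expect_identical(flt0$table$responses, clean$responses)

  raw <- inject_attention_failures(clean, 0.087, seed = 2)
  flt <- apply_attention_filter(raw, attr(raw, "checks"))
  expect_gt(flt$n_excluded, 0L)
  expect_lt(flt$n_excluded / clean$n, 0.2)
  kept <- apply(attr(raw, "extra"), 1, function(r)
    all(r == attr(raw, "checks")))
  expect_identical(flt$table$responses,
                   clean$responses[kept, , drop = FALSE])
})

test_that("continuous-sample round-trip converges to the truth at large n", {
  truth <- make_ground_truth()
  ch <- chol(truth_to_covariance(truth))
  set.seed(33)
  Z <- matrix(rnorm(20000 * 21), 20000, 21) %*% ch
  colnames(Z) <- truth$node_ids
  S <- nearest_positive_semidefinite(spearman_matrix(Z))$S
  Theta <- solve(S)
  P <- -Theta / sqrt(tcrossprod(diag(Theta)))
  diag(P) <- 0
  expect_lte(max(abs(P - truth$true_pcors)), 0.05)
})

test_that("estimated edge signs match planted signs for clear edges", {
  truth <- make_ground_truth()
  P <- truth$true_pcors
  clear <- upper.tri(P) & abs(P) >= 0.15
  hits <- sapply(1:5, function(s) {
    ds <- simulate_survey(n = 2000, seed = 800 + s, truth = truth)
    W <- estimate_network(ds$table)$weights
    mean(sign(W[clear]) == sign(P[clear]))
  })
  expect_gte(mean(hits), 0.95)
})

test_that("synthetic datasets serialize and re-read identically", {
  ds <- simulate_survey(n = 60, seed = 21, fail_rate = 0.1)
  dir <- tempfile()
  paths <- write_synthetic(ds, dir)
  expect_true(all(file.exists(paths)))
  back <- read_responses(paths[1], ds$truth$cluster_of)
  expect_equal(back$responses, ds$table$responses)
  flt <- apply_attention_filter(back, attr(ds$table, "checks"))
  expect_lt(flt$table$n, back$n + 1)
})
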