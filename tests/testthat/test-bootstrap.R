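small_ds <- function(n = 250, seed = 3) {
  truth <- make_ground_truth(
    cluster_sizes = c(A = 3, B = 2),
    within_density = 0, between_density = 0,
    within_range = c(0, 0), between_range = c(0, 0),
    fixed_edges = data.frame(a = c("A1", "A2", "A3"),
                             b = c("A2", "A3", "B1"),
                             weight = c(0.35, 0.3, 0.25)),
    n_negative = 0, seed = 5)
  mom <- data.frame(item = truth$node_ids, cluster = unname(truth$cluster_of),
                    mean = 3.0, sd = 1.1)
  simulate_survey(n = n, seed = seed, truth = truth, moments = mom)
}

est <- list(n_lambdas = 30)

test_that("bootstrap replicates are bit-identical for a fixed seed", {
  ds <- small_ds()
  spec <- bootstrap_spec(B = 10, seed = 7)
  b1 <- nonparametric_boot(ds$table, spec, estimator = est)
  b2 <- nonparametric_boot(ds$table, spec, estimator = est)
  expect_identical(b1$edge_weights, b2$edge_weights)
  b3 <- nonparametric_boot(ds$table, bootstrap_spec(B = 10, seed = 8),
                           estimator = est)
  expect_false(identical(b1$edge_weights, b3$edge_weights))
})

test_that("a constant replicate store yields zero-width CIs", {
  boot <- list(point = list(weights = matrix(0, 2, 2,
                                             dimnames = list(c("a", "b"), c("a", "b")))),
               edge_weights = matrix(0.42, 50, 1,
                                     dimnames = list(NULL, "a--b")),
               pairs = data.frame(i = 1, j = 2, node_a = "a", node_b = "b"),
               failed = integer(0),
               spec = bootstrap_spec(B = 50))
  class(boot) <- "network_boot"
  ci <- edge_cis(boot)
  expect_equal(ci$lower, 0.42)
  expect_equal(ci$upper, 0.42)
})

test_that("edge CI quantiles match a sorted-array oracle", {
  ds <- small_ds()
  spec <- bootstrap_spec(B = 40, seed = 11)
  b <- nonparametric_boot(ds$table, spec, estimator = est)
  ci <- edge_cis(b)
  for (k in c(1, 4, 7)) {
    xs <- sort(b$edge_weights[, k])
    expect_equal(ci$lower[k],
                 unname(quantile(xs, 0.025, names = FALSE)))
    expect_equal(ci$upper[k],
                 unname(quantile(xs, 0.975, names = FALSE)))
    expect_lte(ci$lower[k], ci$upper[k])
  }
})

test_that("difference tests match a brute-force pairwise loop", {
  ds <- small_ds()
  spec <- bootstrap_spec(B = 50, seed = 13)
  b <- nonparametric_boot(ds$table, spec, estimator = est,
                          cluster_of = ds$table$cluster_of)
  dt <- difference_test(b, "edges")
  m <- ncol(b$edge_weights)
  for (a in seq_len(m - 1)) {
    for (bb in (a + 1):m) {
      d <- b$edge_weights[, bb] - b$edge_weights[, a]
      qs <- quantile(d, c(0.025, 0.975), names = FALSE)
      expect_equal(dt$lower[a, bb], qs[1])
      expect_equal(dt$upper[a, bb], qs[2])
      expect_identical(dt$significant[a, bb], qs[1] > 0 || qs[2] < 0)
      expect_identical(dt$significant[a, bb], dt$significant[bb, a])
    }
  }
  # a statistic against itself is never significant
  expect_false(any(diag(dt$significant)))
  dtei <- difference_test(b, "ei")
  expect_false(any(diag(dtei$significant)))

  # two statistics with disjoint replicate ranges are significant
  fake <- b
  fake$edge_weights[, 1] <- seq(0.5, 0.6, length.out = spec$B)
  fake$edge_weights[, 2] <- seq(-0.2, -0.1, length.out = spec$B)
  dt2 <- difference_test(fake, "edges")
  expect_true(dt2$significant[1, 2])
})

test_that("case-dropping correlations approach 1 at tiny drop proportions", {
  ds <- small_ds(n = 400)
  spec <- bootstrap_spec(B = 15, seed = 17, drop_proportions = c(0.05, 0.5))
  stab <- case_dropping_boot(ds$table, spec, statistic = "ei",
                             estimator = est)
  r05 <- stab$correlations$correlation[stab$correlations$proportion == 0.05]
  expect_gt(mean(r05, na.rm = TRUE), 0.9)
  long <- stab$correlations
  expect_named(long, c("statistic", "proportion", "replicate", "correlation"))
  expect_equal(nrow(long), 2 * 15)
})

test_that("drop proportions leaving too few rows are skipped with a warning", {
  ds <- small_ds(n = 30)
  spec <- bootstrap_spec(B = 4, seed = 19, drop_proportions = c(0.2, 0.9))
  expect_error(bootstrap_spec(drop_proportions = c(0, 0.5)), "strictly")
  expect_warning(
    stab <- case_dropping_boot(ds$table, spec, statistic = "ei",
                               estimator = est),
    "skipped")
  expect_false(0.9 %in% stab$correlations$proportion)
})

test_that("CS-coefficient follows its definition on hand-built results", {
  mk <- function(vals_by_q) {
    rows <- do.call(rbind, lapply(names(vals_by_q), function(q)
      data.frame(statistic = "ei", proportion = as.numeric(q),
                 replicate = seq_along(vals_by_q[[q]]),
                 correlation = vals_by_q[[q]])))
    structure(list(correlations = rows, full = list(ei = 1:5),
                   spec = bootstrap_spec(B = 20)),
              class = "stability_result")
  }
  grid <- seq(0.05, 0.75, 0.05)
  perfect <- mk(stats::setNames(lapply(grid, function(q) rep(1, 20)),
                                grid))
  expect_equal(cs_coefficient(perfect, "ei"), 0.75)

  none <- mk(stats::setNames(lapply(grid, function(q) rep(0, 20)), grid))
  expect_equal(cs_coefficient(none, "ei"), 0)

  # 0.25 passes (19/20 >= 0.7), 0.30 and beyond fail
  mixed <- mk(stats::setNames(lapply(grid, function(q) {
    if (q <= 0.25) c(rep(0.9, 19), 0.1) else rep(0.5, 20)
  }), grid))
  expect_equal(cs_coefficient(mixed, "ei"), 0.25)

  # relaxing the threshold can only raise CS
  spec_low <- bootstrap_spec(B = 20, cs_threshold = 0.4)
  expect_gte(cs_coefficient(mixed, "ei", spec_low),
             cs_coefficient(mixed, "ei"))
})

test_that("stability outputs serialize to CSV and JSON", {
  ds <- small_ds(n = 200)
  spec <- bootstrap_spec(B = 5, seed = 23, drop_proportions = c(0.1, 0.3))
  stab <- case_dropping_boot(ds$table, spec, statistic = c("ei", "bei"),
                             estimator = est)
  prefix <- tempfile()
  paths <- write_stability(stab, prefix)
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(paths[2])
  expect_named(js, c("ei", "bei"))
})

test_that("pipeline CI coverage matches a package-independent bootstrap oracle", {
  # same datasets, two routes: the package pipeline's percentile CI for the
  # single edge vs a plain-R percentile bootstrap of the Spearman
  # correlation itself (for p = 2 the partial equals the marginal, so the
  # two routes estimate the same quantity)
  Sig <- matrix(c(1, 0.3, 0.3, 1), 2, 2,
                dimnames = list(c("A1", "B1"), c("A1", "B1")))
  cl <- c(A1 = "A", B1 = "B")
  th <- list(thresholds_from_target_moments(3.0, 1.1),
             thresholds_from_target_moments(3.0, 1.1))
  big <- sample_likert(Sig, th, 200000, cl, seed = 900)
  pt <- cor(big$responses[, 1], big$responses[, 2], method = "spearman")
  res <- vapply(1:50, function(d) {
    tab <- sample_likert(Sig, th, 400, cl, seed = 901 + d)
    b <- nonparametric_boot(tab, bootstrap_spec(B = 200, seed = 20000 + d))
    ci <- edge_cis(b)
    mine <- ci$lower[1] <= pt && pt <= ci$upper[1]
    set.seed(30000 + d)
    reps <- replicate(200, {
      i <- sample(400, 400, TRUE)
      cor(tab$responses[i, 1], tab$responses[i, 2], method = "spearman")
    })
    q <- quantile(reps, c(0.025, 0.975), names = FALSE)
    c(mine = mine, oracle = q[1] <= pt && pt <= q[2])
  }, logical(2))
  expect_lte(abs(mean(res["mine", ]) - mean(res["oracle", ])), 0.08)
})
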