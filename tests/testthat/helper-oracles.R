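# Independent oracles used across the suite. None of these share code with
# the package's own estimation path.

# ADMM solver of the penalized Gaussian likelihood
#   max log det Theta - tr(S Theta) - lambda * sum_{i!=j} |Theta_ij|
# (diagonal unpenalized). Different algorithm family from the package's
# block coordinate descent; used as the convex-solver oracle.
admm_glasso <- function(S, lambda, rho = 1, maxit = 20000, tol = 1e-9) {
  p <- nrow(S)
  Z <- diag(p)
  U <- matrix(0, p, p)
  for (it in seq_len(maxit)) {
    e <- eigen(rho * (Z - U) - S, symmetric = TRUE)
    d <- (e$values + sqrt(e$values^2 + 4 * rho)) / (2 * rho)
    Theta <- e$vectors %*% (d * t(e$vectors))
    Zold <- Z
    M <- Theta + U
    Z <- sign(M) * pmax(abs(M) - lambda / rho, 0)
    diag(Z) <- diag(M)
    U <- U + Theta - Z
    if (norm(Theta - Z, "F") < tol * p && rho * norm(Z - Zold, "F") < tol * p)
      break
  }
  (Z + t(Z)) / 2
}

# brute-force expected influence / bridge expected influence by explicit
# double loops over node pairs
brute_ei <- function(W) {
  p <- ncol(W)
  out <- numeric(p)
  for (i in seq_len(p))
    for (j in seq_len(p))
      if (i != j) out[i] <- out[i] + W[i, j]
  names(out) <- colnames(W)
  out
}

brute_bei <- function(W, cl) {
  p <- ncol(W)
  out <- numeric(p)
  ids <- colnames(W)
  for (i in seq_len(p))
    for (j in seq_len(p))
      if (i != j && cl[ids[i]] != cl[ids[j]])
        out[i] <- out[i] + W[i, j]
  names(out) <- ids
  out
}

# brute-force network summary counts by looping over the upper triangle
brute_summary_counts <- function(W, cl) {
  ids <- colnames(W)
  p <- ncol(W)
  n_edges <- n_pos <- n_neg <- 0L
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      w <- W[i, j]
      if (w != 0) {
        n_edges <- n_edges + 1L
        if (w > 0) n_pos <- n_pos + 1L else n_neg <- n_neg + 1L
      }
    }
  }
  list(n_edges = n_edges, possible = p * (p - 1) / 2,
       n_positive = n_pos, n_negative = n_neg)
}

# a small random weighted network with exact zeros
random_network <- function(p, density = 0.4, seed = 1) {
  set.seed(seed)
  W <- matrix(0, p, p)
  ut <- which(upper.tri(W))
  on <- sample(ut, round(density * length(ut)))
  W[on] <- runif(length(on), -0.3, 0.4)
  W <- W + t(W)
  colnames(W) <- rownames(W) <- paste0("n", seq_len(p))
  W
}

# cluster map helper: first k nodes cluster "A", rest "B"
split_clusters <- function(ids, k) {
  stats::setNames(c(rep("A", k), rep("B", length(ids) - k)), ids)
}

# small valid Likert table
tiny_table <- function(n = 12, p = 4, seed = 1) {
  set.seed(seed)
  X <- matrix(sample(1:5, n * p, replace = TRUE), n, p,
              dimnames = list(NULL, paste0("it", seq_len(p))))
  item_response_table(X, split_clusters(colnames(X), ceiling(p / 2)))
}

# write a temporary CSV and return its path
write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}
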