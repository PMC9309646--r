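#' @useDynLib ordinet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor cov optim pnorm dnorm qnorm quantile rnorm sd var
#' @importFrom utils read.csv write.csv head
NULL

# indices of the strict upper triangle, column-major, as a two-column matrix
upper_pairs <- function(p, labels = NULL) {
  ut <- which(upper.tri(diag(p)), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  out <- data.frame(i = ut[, 1], j = ut[, 2])
  if (!is.null(labels)) {
    out$node_a <- labels[out$i]
    out$node_b <- labels[out$j]
  }
  out
}

# deterministic child seed for replicate b under a master seed; stays
# within the 32-bit integer range R requires
child_seed <- function(master, b) {
  as.integer((as.double(master) * 48271 + b * 1009) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
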