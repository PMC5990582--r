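#' Split-chain Gelman-Rubin convergence diagnostic
#'
#' Compares between-chain to within-chain variability on split chains: each
#' chain is halved, then `R-hat = sqrt(((n-1)/n * W + B/n) / W)` where `W`
#' is the mean within-chain variance and `B/n` the variance of chain means.
#' Values near 1 indicate convergence; the conventional acceptance rule used
#' throughout this package is `R-hat < 1.05`, with 1.1 as the rule-of-thumb
#' upper bound. Chains with zero within-chain variance make the diagnostic
#' undefined and return `NA` (flagged, never silently accepted).
#'
#' @param x draws: a matrix (iterations x chains), or a 3-d array
#'   (chain, iteration, parameter) as produced by the fitting functions.
#' @return a single `R-hat` for a matrix; a named vector (one per parameter)
#'   for a 3-d array.
#' @export
gelman_rubin <- function(x) {
  if (is.matrix(x)) return(rhat_matrix(x))
  if (length(dim(x)) == 3) {
    p <- dim(x)[3]
    out <- vapply(seq_len(p), function(j) rhat_matrix(t(x[, , j, drop = TRUE])),
                  numeric(1))
    names(out) <- dimnames(x)[[3]]
    return(out)
  }
  stop("x must be an iterations x chains matrix or a (chain, iter, param) array")
}

# x: iterations x chains
rhat_matrix <- function(x) {
  n_it <- nrow(x)
  m <- ncol(x)
  if (m < 2) stop("at least 2 chains are required")
  if (n_it < 8) stop("at least 4 draws per split chain are required")
  half <- n_it %/% 2
  splits <- cbind(x[seq_len(half), , drop = FALSE],
                  x[(n_it - half + 1):n_it, , drop = FALSE])
  n <- nrow(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2, stats::var)
  W <- mean(vars)
  B_over_n <- stats::var(means)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B_over_n) / W)
}
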