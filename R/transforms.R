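#' Probit transform of PVL-Delta parameters
#'
#' Parameters are rescaled to the unit interval (`w` and `c` divided by 5)
#' and mapped through the standard normal quantile function, so group-level
#' distributions can be normal on the probit scale. Values at or beyond the
#' boundaries are clipped into `[eps, 1 - eps]` with a warning, since the
#' quantile function diverges there.
#'
#' @param params a `pvl_params` vector (or coercible).
#' @param eps boundary clipping tolerance on the unit scale (default 1e-6).
#' @return named numeric vector `c(A, w, a, c)` of probit-scale values,
#'   class `pvl_probit`.
#' @seealso [to_natural()]
#' @export
to_probit <- function(params, eps = 1e-6) {
  params <- as_pvl_params(params)
  unit <- c(params[["A"]], params[["w"]] / 5, params[["a"]], params[["c"]] / 5)
  if (any(unit <= 0 | unit >= 1)) {
    warning("parameter(s) at the range boundary clipped by eps = ", eps)
    unit <- pmin(pmax(unit, eps), 1 - eps)
  }
  structure(stats::qnorm(unit), names = c("A", "w", "a", "c"),
            class = "pvl_probit")
}

#' Inverse probit transform
#'
#' Maps probit-scale values back to the natural parameter ranges:
#' `A = pnorm(A')`, `w = 5 pnorm(w')`, `a = pnorm(a')`, `c = 5 pnorm(c')`.
#' Round-trips with [to_probit()] on the open ranges.
#'
#' @param z named numeric vector (A, w, a, c) on the probit scale.
#' @return a `pvl_params` vector.
#' @export
to_natural <- function(z) {
  z <- unlist(z)
  if (length(z) != 4) stop("expected 4 probit-scale values (A, w, a, c)")
  if (is.null(names(z))) names(z) <- c("A", "w", "a", "c")
  u <- stats::pnorm(z[c("A", "w", "a", "c")])
  pvl_params(A = u[["A"]], w = 5 * u[["w"]], a = u[["a"]], c = 5 * u[["c"]])
}

# Vectorized natural-scale transform for a matrix of probit draws
# (columns A, w, a, c) -- used by the fitting and posthoc code paths.
probit_matrix_to_natural <- function(zm) {
  u <- stats::pnorm(zm)
  u[, c(2, 4)] <- 5 * u[, c(2, 4)]
  colnames(u) <- c("A", "w", "a", "c")
  u
}
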