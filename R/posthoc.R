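#' One-step-ahead ("postdiction") choice probabilities
#'
#' For fitted parameters and an observed sequence, row `t` gives the
#' softmax probabilities of each deck on trial `t` conditioned on the
#' observed choices and payoffs of trials `1..t-1` (row 1 is uniform, since
#' initial expectancies are zero). Predictions condition on the *observed*
#' history, never on model-generated choices.
#'
#' @param p an `igt_participant`.
#' @param params a `pvl_params` vector (or coercible).
#' @param outcome_scale utility scaling divisor (default 100).
#' @return trials x 4 matrix of probabilities (rows sum to 1).
#' @export
one_step_ahead_probs <- function(p, params, outcome_scale = 100) {
  stopifnot(inherits(p, "igt_participant"))
  if (length(p$deck) < 1) stop("empty trial sequence")
  params <- as_pvl_params(params)
  P <- one_step_probs_cpp(p$deck, net_outcomes(p), params[["A"]],
                          params[["w"]], params[["a"]], params[["c"]],
                          outcome_scale)
  colnames(P) <- c("A", "B", "C", "D")
  P
}

#' Post hoc absolute-fit block curves
#'
#' Aggregates one-step-ahead predictions into block-wise mean choice
#' probabilities across participants, alongside the observed block-wise
#' choice proportions, for model-adequacy checks (deck-wise and aggregated
#' into good decks C + D versus bad decks A + B).
#'
#' @param dataset an `igt_dataset`.
#' @param params fitted individual parameters: a participants x 4 matrix
#'   (rows in dataset order or named by participant id; columns A, w, a, c
#'   on the natural scale, e.g. from [individual_posterior_params()]), or a
#'   list of `pvl_params`.
#' @param block_size trials per block (default 10).
#' @param outcome_scale utility scaling divisor (default 100).
#' @return object of class `igt_posthoc`: `predicted` and `observed`
#'   (blocks x 4 matrices of means across participants), `predicted_good`
#'   and `observed_good` (decks C + D), and `n_participants`.
#' @export
posthoc_block_curves <- function(dataset, params, block_size = 10,
                                 outcome_scale = 100) {
  stopifnot(inherits(dataset, "igt_dataset"))
  n <- length(dataset)
  if (is.list(params) && !is.matrix(params)) {
    params <- do.call(rbind, lapply(params, function(p) as_pvl_params(p)[1:4]))
  }
  if (!is.matrix(params) || ncol(params) != 4)
    stop("params must be a participants x 4 matrix or list of pvl_params")
  ids <- vapply(dataset$participants, `[[`, character(1), "id")
  if (!is.null(rownames(params))) {
    if (!all(ids %in% rownames(params)))
      stop("params rows do not cover all participants")
    params <- params[ids, , drop = FALSE]
  } else if (nrow(params) != n) {
    stop("one parameter set per participant is required (got ", nrow(params),
         " for ", n, " participants)")
  }
  per_pred <- vector("list", n)
  per_obs <- vector("list", n)
  for (i in seq_len(n)) {
    p <- dataset$participants[[i]]
    P <- one_step_ahead_probs(p, params[i, ], outcome_scale)
    block <- (seq_len(nrow(P)) - 1L) %/% block_size + 1L
    per_pred[[i]] <- apply(P, 2, function(col) tapply(col, block, mean))
    per_obs[[i]] <- block_proportions(p, block_size)$proportions
  }
  nb <- max(vapply(per_pred, NROW, integer(1)))
  acc <- function(lst) {
    out <- matrix(0, nb, 4, dimnames = list(NULL, c("A", "B", "C", "D")))
    cnt <- numeric(nb)
    for (m in lst) {
      m <- rbind(m)  # 1-block participants come back as vectors
      idx <- seq_len(nrow(m))
      out[idx, ] <- out[idx, ] + m
      cnt[idx] <- cnt[idx] + 1
    }
    out / cnt
  }
  predicted <- acc(per_pred)
  observed <- acc(per_obs)
  structure(
    list(predicted = predicted, observed = observed,
         predicted_good = predicted[, "C"] + predicted[, "D"],
         observed_good = observed[, "C"] + observed[, "D"],
         n_participants = n, block_size = block_size),
    class = "igt_posthoc"
  )
}

#' @export
print.igt_posthoc <- function(x, ...) {
  cat("Post hoc absolute fit over", nrow(x$predicted), "blocks of",
      x$block_size, "trials (", x$n_participants, "participants)\n")
  cat("good-deck proportion (observed vs predicted):\n")
  print(round(cbind(observed = x$observed_good,
                    predicted = x$predicted_good), 3))
  invisible(x)
}

#' Export post hoc curves as CSV
#'
#' Long format: one row per (block, deck) with observed and predicted
#' proportions.
#'
#' @param x an `igt_posthoc`.
#' @param path output path.
#' @param group optional group label column.
#' @return `path`, invisibly.
#' @export
export_posthoc_csv <- function(x, path, group = NA) {
  stopifnot(inherits(x, "igt_posthoc"))
  nb <- nrow(x$predicted)
  df <- data.frame(
    group = group,
    block = rep(seq_len(nb), times = 4),
    deck = rep(c("A", "B", "C", "D"), each = nb),
    observed = as.vector(x$observed),
    predicted = as.vector(x$predicted))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Plot post hoc absolute-fit curves
#'
#' Two panels: observed and one-step-ahead predicted mean choice
#' proportions per deck across blocks, plus the good-deck aggregates.
#'
#' @param x an `igt_posthoc`.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.igt_posthoc <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  blocks <- seq_len(nrow(x$predicted))
  for (panel in c("observed", "predicted")) {
    m <- x[[panel]]
    graphics::matplot(blocks, m, type = "b", pch = 1:4, lty = 1,
                      ylim = c(0, 1), xlab = "block",
                      ylab = "choice proportion", main = panel)
    graphics::lines(blocks, x[[paste0(panel, "_good")]], lwd = 2, lty = 2)
    graphics::legend("topleft", bty = "n", cex = 0.7,
                     legend = c("A", "B", "C", "D", "good (C+D)"),
                     pch = c(1:4, NA), lty = c(rep(1, 4), 2),
                     col = c(1:4, 1), lwd = c(rep(1, 4), 2))
  }
  invisible(x)
}
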