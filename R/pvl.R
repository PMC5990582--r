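#' PVL-Delta parameters
#'
#' The PVL-Delta model has four parameters: outcome sensitivity
#' `A` in \[0,1\] (curvature of the prospect utility), loss aversion
#' `w` in \[0,5\] (weight on negative net outcomes), updating rate
#' `a` in \[0,1\] (delta-rule learning rate; large `a` = strong recency),
#' and response consistency `c` in \[0,5\], which sets the softmax
#' sensitivity `theta = 3^c - 1` (so `c = 0` gives uniform random choice).
#'
#' @param A outcome sensitivity, in \[0,1\].
#' @param w loss aversion, in \[0,5\].
#' @param a updating rate, in \[0,1\].
#' @param c response consistency, in \[0,5\].
#' @return named numeric vector of class `pvl_params`.
#' @examples
#' pvl_params(A = 0.5, w = 2.5, a = 0.3, c = 1)
#' @export
pvl_params <- function(A, w, a, c) {
  check_range <- function(x, nm, hi) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > hi)
      stop("parameter '", nm, "' must be a single value in [0, ", hi, "]")
  }
  check_range(A, "A", 1)
  check_range(w, "w", 5)
  check_range(a, "a", 1)
  check_range(c, "c", 5)
  structure(c(A = unname(A), w = unname(w), a = unname(a), c = unname(c)),
            class = "pvl_params")
}

#' @export
print.pvl_params <- function(x, ...) {
  cat(sprintf("PVL-Delta parameters: A = %.3f, w = %.3f, a = %.3f, c = %.3f (theta = %.3f)\n",
              x["A"], x["w"], x["a"], x["c"], pvl_sensitivity(x["c"])))
  invisible(x)
}

as_pvl_params <- function(x) {
  if (inherits(x, "pvl_params")) return(x)
  x <- unlist(x)
  if (!all(c("A", "w", "a", "c") %in% names(x)))
    stop("parameters must be named A, w, a, c")
  pvl_params(x[["A"]], x[["w"]], x[["a"]], x[["c"]])
}

#' Prospect utility of a net outcome
#'
#' `u(x) = x^A` for gains and `u(x) = -w * |x|^A` for losses; both branches
#' vanish at `x = 0`, where `u` is defined to be exactly 0 (covering the
#' `0^0` case at `A = 0`).
#'
#' @param x net outcome(s), already on the modeling scale (see
#'   `outcome_scale` in [pvl_log_likelihood()]).
#' @param A outcome sensitivity, in \[0,1\].
#' @param w loss aversion, in \[0,5\].
#' @return subjective utilities, same length as `x`.
#' @export
pvl_utility <- function(x, A, w) {
  if (A < 0 || A > 1) stop("A must be in [0,1]")
  if (w < 0 || w > 5) stop("w must be in [0,5]")
  ifelse(x == 0, 0, ifelse(x > 0, x^A, -w * abs(x)^A))
}

#' Delta-rule expectancy update
#'
#' Only the just-chosen deck's expectancy moves:
#' `Ev_k <- Ev_k + a * (u - Ev_k)`; the other decks are untouched.
#'
#' @param ev length-4 numeric vector of current expected utilities.
#' @param deck chosen deck (1-4 or letter).
#' @param u experienced utility of the chosen card.
#' @param a updating rate, in \[0,1\].
#' @return updated length-4 expectancy vector.
#' @export
update_expectancies <- function(ev, deck, u, a) {
  stopifnot(length(ev) == 4, is.finite(ev))
  if (a < 0 || a > 1) stop("a must be in [0,1]")
  k <- deck_index(deck)
  ev[k] <- ev[k] + a * (u - ev[k])
  ev
}

#' Softmax sensitivity
#'
#' `theta = 3^c - 1`, monotone in the response consistency `c`; ranges from
#' 0 (`c = 0`, uniform random choice) to 242 (`c = 5`).
#'
#' @param c response consistency, in \[0,5\].
#' @return sensitivity `theta`.
#' @export
pvl_sensitivity <- function(c) {
  if (any(c < 0 | c > 5)) stop("c must be in [0,5]")
  3^c - 1
}

#' Softmax choice probabilities
#'
#' `P(k)` proportional to `exp(theta * Ev_k)`, computed with max-subtraction
#' so it cannot overflow even at `theta = 242`.
#'
#' @param ev length-4 numeric vector of expected utilities (finite).
#' @param c response consistency, in \[0,5\].
#' @return length-4 probability vector summing to 1.
#' @export
choice_probabilities <- function(ev, c) {
  if (length(ev) != 4 || !all(is.finite(ev))) stop("ev must be 4 finite values")
  theta <- pvl_sensitivity(c)
  e <- exp(theta * (ev - max(ev)))
  e / sum(e)
}

#' PVL-Delta sequence log-likelihood
#'
#' Sum over trials of the log-probability of the observed choice given the
#' expectancies built from the history up to the previous trial. Initial
#' expectancies are zero, so the first trial always has probability 1/4.
#' Net outcomes are divided by `outcome_scale` before entering the utility
#' function (default 100; the raw scale is available with
#' `outcome_scale = 1`). The scaling constant is part of the model
#' configuration and must match between simulation and fitting.
#'
#' @param p an `igt_participant`.
#' @param params a `pvl_params` vector (or coercible named vector/list).
#' @param outcome_scale divisor applied to net outcomes (default 100).
#' @return scalar log-likelihood (finite for all in-range parameters).
#' @export
pvl_log_likelihood <- function(p, params, outcome_scale = 100) {
  stopifnot(inherits(p, "igt_participant"))
  if (length(p$deck) < 1) stop("empty trial sequence")
  params <- as_pvl_params(params)
  pvl_loglik_cpp(p$deck, net_outcomes(p), params[["A"]], params[["w"]],
                 params[["a"]], params[["c"]], outcome_scale)
}

#' Simulate a PVL-Delta agent on the IGT
#'
#' Plays `n_trials` of the task: on each trial a deck is sampled from the
#' softmax probabilities, the payoff is drawn from the scheme (per-deck draw
#' counters drive the loss schedule), and expectancies are updated by the
#' delta rule. Reproducible under [set.seed()].
#'
#' @param params a `pvl_params` vector.
#' @param scheme an `igt_scheme` (default: traditional scheme).
#' @param n_trials number of trials (default: the scheme's default, 100).
#' @param id participant identifier.
#' @param outcome_scale utility scaling divisor (default 100); must match
#'   the value used when fitting.
#' @param forced_choices optional integer vector of deck choices; when
#'   supplied (length `n_trials`) the agent is forced through this sequence
#'   and only payoffs/expectancies are computed.
#' @param group optional group label attached to the output.
#' @return an `igt_participant`.
#' @examples
#' set.seed(1)
#' ag <- simulate_pvl_agent(pvl_params(0.6, 1, 0.2, 2), n_trials = 20)
#' @export
simulate_pvl_agent <- function(params, scheme = traditional_scheme(),
                               n_trials = NULL, id = "sim",
                               outcome_scale = 100, forced_choices = NULL,
                               group = NULL) {
  params <- as_pvl_params(params)
  stopifnot(inherits(scheme, "igt_scheme"))
  if (is.null(n_trials)) n_trials <- scheme$n_trials_default
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (!is.null(forced_choices)) {
    forced_choices <- deck_index(forced_choices)
    if (length(forced_choices) != n_trials)
      stop("forced_choices must have length n_trials")
  }
  bl <- scheme$block_length
  # pre-realize each deck's loss schedule for the maximum possible draws
  n_blocks <- ceiling(n_trials / bl)
  loss_seq <- lapply(scheme$decks, function(d) {
    unlist(lapply(seq_len(n_blocks), function(b) {
      if (isTRUE(scheme$shuffle_within_block)) d$losses[sample.int(bl)]
      else d$losses
    }))
  })
  ev <- numeric(4)
  draws <- integer(4)
  deck <- integer(n_trials)
  reward <- numeric(n_trials)
  loss <- numeric(n_trials)
  a <- params[["a"]]
  for (t in seq_len(n_trials)) {
    k <- if (is.null(forced_choices)) {
      sample.int(4, 1, prob = choice_probabilities(ev, params[["c"]]))
    } else forced_choices[t]
    draws[k] <- draws[k] + 1L
    deck[t] <- k
    reward[t] <- scheme$decks[[k]]$reward
    loss[t] <- loss_seq[[k]][draws[k]]
    u <- pvl_utility((reward[t] + loss[t]) / outcome_scale,
                     params[["A"]], params[["w"]])
    ev[k] <- ev[k] + a * (u - ev[k])
  }
  participant_data(id, deck, reward, loss, group = group)
}
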