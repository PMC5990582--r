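#' Payoff scheme for the Iowa Gambling Task
#'
#' An `igt_scheme` describes the four decks of the IGT: a constant reward per
#' draw and a schedule of losses applied within each block of
#' `block_length` consecutive draws *from that deck*. Losses are stored as
#' non-positive numbers at fixed within-block positions; an optional
#' seed-controlled shuffle permutes the positions (never the magnitudes)
#' block by block.
#'
#' @param decks named list (`A`..`D`), each element a list with `reward`
#'   (constant reward per draw) and `losses` (numeric vector of length
#'   `block_length`, entries `<= 0`, the loss applied at each within-block
#'   position).
#' @param block_length number of draws per deck block (default 10).
#' @param endowment hypothetical starting capital (default 2000).
#' @param n_trials_default default task length (default 100).
#' @param shuffle_within_block if `TRUE`, loss positions are permuted within
#'   each block when payoffs are drawn (magnitudes, and hence all block
#'   totals, are unchanged).
#' @return an object of class `igt_scheme`.
#' @seealso [traditional_scheme()], [draw_payoff()]
#' @export
igt_scheme <- function(decks, block_length = 10, endowment = 2000,
                       n_trials_default = 100, shuffle_within_block = FALSE) {
  stopifnot(is.list(decks), length(decks) == 4)
  if (is.null(names(decks))) names(decks) <- c("A", "B", "C", "D")
  for (nm in names(decks)) {
    d <- decks[[nm]]
    if (!is.numeric(d$reward) || length(d$reward) != 1 || d$reward < 0)
      stop("deck ", nm, ": 'reward' must be a single non-negative number")
    if (!is.numeric(d$losses) || length(d$losses) != block_length)
      stop("deck ", nm, ": 'losses' must have length block_length (",
           block_length, ")")
    if (any(d$losses > 0))
      stop("deck ", nm, ": losses must be stored as non-positive numbers")
  }
  structure(
    list(decks = decks, block_length = block_length, endowment = endowment,
         n_trials_default = n_trials_default,
         shuffle_within_block = shuffle_within_block),
    class = "igt_scheme"
  )
}

#' The traditional IGT payoff scheme
#'
#' Builds the classic Bechara et al. payoff structure: decks A and B pay 100
#' per draw but lose 1250 per 10 cards (A in five losses, B in one), decks C
#' and D pay 50 per draw and lose 250 per 10 cards (C in five losses, D in
#' one). Net outcome per 10-card block is therefore -250 for the bad decks
#' (A, B) and +250 for the good decks (C, D). The within-block loss
#' magnitudes for deck A follow the classic administration
#' (-150, -200, -250, -300, -350); positions are fixed by default.
#'
#' @param shuffle_within_block permute loss positions within each block when
#'   drawing (default `FALSE`: deterministic schedule).
#' @return an `igt_scheme`.
#' @examples
#' sch <- traditional_scheme()
#' scheme_summary(sch)
#' @export
traditional_scheme <- function(shuffle_within_block = FALSE) {
  at <- function(block_length, pos, val) {
    x <- numeric(block_length)
    x[pos] <- val
    x
  }
  igt_scheme(
    decks = list(
      A = list(reward = 100,
               losses = at(10, c(3, 5, 7, 9, 10),
                           c(-150, -200, -250, -300, -350))),
      B = list(reward = 100, losses = at(10, 9, -1250)),
      C = list(reward = 50, losses = at(10, c(3, 5, 7, 9, 10), rep(-50, 5))),
      D = list(reward = 50, losses = at(10, 10, -250))
    ),
    shuffle_within_block = shuffle_within_block
  )
}

#' Summarize a payoff scheme per deck
#'
#' @param scheme an `igt_scheme`.
#' @return data frame with one row per deck: reward per trial, number of
#'   losses per block, total loss per block, and net outcome per block.
#' @export
scheme_summary <- function(scheme) {
  stopifnot(inherits(scheme, "igt_scheme"))
  bl <- scheme$block_length
  do.call(rbind, lapply(names(scheme$decks), function(nm) {
    d <- scheme$decks[[nm]]
    data.frame(deck = nm,
               reward_per_trial = d$reward,
               n_losses_per_block = sum(d$losses < 0),
               loss_per_block = sum(d$losses),
               net_per_block = bl * d$reward + sum(d$losses))
  }))
}

#' @export
print.igt_scheme <- function(x, ...) {
  cat("IGT payoff scheme (block length ", x$block_length,
      ", endowment ", x$endowment, ")\n", sep = "")
  print(scheme_summary(x), row.names = FALSE)
  invisible(x)
}

deck_index <- function(deck) {
  if (is.character(deck)) deck <- match(deck, c("A", "B", "C", "D"))
  deck <- as.integer(deck)
  if (any(is.na(deck)) || any(deck < 1L | deck > 4L))
    stop("unknown deck id; decks are 1-4 (A-D)")
  deck
}

#' Draw payoffs from a deck
#'
#' Returns the reward and loss experienced on given draws from one deck.
#' `draws` are 1-based per-deck draw counters (the k-th time this deck is
#' chosen), not global trial indices: the loss schedule restarts every
#' `block_length` draws from the deck. With `shuffle_within_block` off the
#' schedule is fully deterministic; with it on, each block's loss positions
#' are permuted using the current RNG state (so results are reproducible
#' under [set.seed()]), leaving the multiset of losses per block unchanged.
#'
#' @param scheme an `igt_scheme`.
#' @param deck deck id, integer 1-4 or letter "A"-"D".
#' @param draws vector of positive integers: per-deck draw counters.
#' @return data frame with columns `draw`, `reward`, `loss` (`loss <= 0`).
#' @examples
#' draw_payoff(traditional_scheme(), "A", 1:10)
#' @export
draw_payoff <- function(scheme, deck, draws) {
  stopifnot(inherits(scheme, "igt_scheme"))
  k <- deck_index(deck)
  stopifnot(length(k) == 1)
  draws <- as.integer(draws)
  if (any(draws < 1L)) stop("draw counters must be >= 1")
  d <- scheme$decks[[k]]
  bl <- scheme$block_length
  block <- (draws - 1L) %/% bl + 1L
  pos <- (draws - 1L) %% bl + 1L
  losses <- numeric(length(draws))
  for (b in unique(block)) {
    sched <- d$losses
    if (isTRUE(scheme$shuffle_within_block)) sched <- sched[sample.int(bl)]
    sel <- block == b
    losses[sel] <- sched[pos[sel]]
  }
  data.frame(draw = draws, reward = rep(d$reward, length(draws)),
             loss = losses)
}

#' Read or write a payoff-scheme configuration as JSON
#'
#' The JSON object mirrors the `igt_scheme` fields: per-deck `reward` and
#' `losses` (length `block_length`), plus `block_length`, `endowment`,
#' `n_trials_default`, `shuffle_within_block`.
#'
#' @param scheme an `igt_scheme`.
#' @param path file path.
#' @return `write_scheme_json()` returns `path` invisibly;
#'   `read_scheme_json()` returns an `igt_scheme`.
#' @export
write_scheme_json <- function(scheme, path) {
  stopifnot(inherits(scheme, "igt_scheme"))
  jsonlite::write_json(unclass(scheme), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scheme_json
#' @export
read_scheme_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  decks <- lapply(x$decks, function(d)
    list(reward = d$reward, losses = as.numeric(d$losses)))
  igt_scheme(decks, block_length = x$block_length, endowment = x$endowment,
             n_trials_default = x$n_trials_default,
             shuffle_within_block = isTRUE(x$shuffle_within_block))
}
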