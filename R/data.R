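#' Per-participant IGT trial records
#'
#' Stores one participant's ordered trial sequence: deck chosen (1-4),
#' reward `W(t) >= 0` and loss `L(t) <= 0` per trial. The net outcome
#' `X(t) = W(t) + L(t)` (equivalently `W(t) - |L(t)|`) is derived, never
#' stored, so the likelihood is invariant to the loss sign convention at
#' the file boundary.
#'
#' @param id participant identifier (coerced to character).
#' @param deck integer vector of chosen decks (1-4).
#' @param reward numeric vector of rewards (`>= 0`).
#' @param loss numeric vector of losses (`<= 0`; positive values are
#'   interpreted as magnitudes and negated with a warning).
#' @param group optional group label.
#' @return an object of class `igt_participant`.
#' @export
participant_data <- function(id, deck, reward, loss, group = NULL) {
  deck <- deck_index(deck)
  n <- length(deck)
  if (n < 1) stop("empty trial sequence")
  if (length(reward) != n || length(loss) != n)
    stop("deck, reward and loss must have equal length")
  if (any(reward < 0)) stop("rewards must be non-negative")
  if (any(loss > 0)) {
    warning("positive loss values supplied; interpreting as magnitudes")
    loss <- -abs(loss)
  }
  structure(
    list(id = as.character(id), deck = deck,
         reward = as.numeric(reward), loss = as.numeric(loss),
         group = group),
    class = "igt_participant"
  )
}

#' Net outcomes of a participant's trials
#'
#' @param p an `igt_participant`.
#' @return numeric vector `X(t) = W(t) + L(t)` with losses stored `<= 0`.
#' @export
net_outcomes <- function(p) {
  stopifnot(inherits(p, "igt_participant"))
  p$reward + p$loss
}

#' @export
print.igt_participant <- function(x, ...) {
  cat("IGT participant ", x$id, ": ", length(x$deck), " trials",
      if (!is.null(x$group)) paste0(" (group ", x$group, ")"), "\n", sep = "")
  invisible(x)
}

#' A named collection of participants
#'
#' @param participants list of `igt_participant` objects.
#' @param name group name.
#' @return an object of class `igt_dataset`.
#' @export
group_dataset <- function(participants, name = "group") {
  if (!length(participants)) stop("a dataset must contain >= 1 participant")
  ok <- vapply(participants, inherits, logical(1), what = "igt_participant")
  if (!all(ok)) stop("all elements must be igt_participant objects")
  ids <- vapply(participants, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicated participant ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(list(participants = participants, name = name),
            class = "igt_dataset")
}

#' @export
print.igt_dataset <- function(x, ...) {
  nt <- vapply(x$participants, function(p) length(p$deck), integer(1))
  cat("IGT dataset '", x$name, "': ", length(x$participants),
      " participants, ", sum(nt), " trials\n", sep = "")
  invisible(x)
}

#' @export
length.igt_dataset <- function(x) length(x$participants)

#' Block-wise choice proportions
#'
#' Splits a participant's choice sequence into blocks of `block_size` trials
#' and tabulates the proportion of choices from each deck per block, plus the
#' good-deck proportion (decks C + D). Proportions are exact rationals
#' (counts over block size).
#'
#' @param p an `igt_participant`.
#' @param block_size trials per block (default 10).
#' @return list of class `igt_block_props` with elements `proportions`
#'   (blocks x 4 matrix, rows summing to 1), `good` (per-block proportion of
#'   C/D choices), `block_size`, and `partial_final` (`TRUE` when the trial
#'   count is not divisible by `block_size`, in which case the final,
#'   shorter block is normalized by its own length).
#' @export
block_proportions <- function(p, block_size = 10) {
  stopifnot(inherits(p, "igt_participant"))
  n <- length(p$deck)
  if (n < 1) stop("empty trial sequence")
  block <- (seq_len(n) - 1L) %/% block_size + 1L
  nb <- max(block)
  counts <- matrix(0L, nb, 4, dimnames = list(NULL, c("A", "B", "C", "D")))
  for (b in seq_len(nb)) {
    tb <- tabulate(p$deck[block == b], nbins = 4)
    counts[b, ] <- tb
  }
  props <- counts / rowSums(counts)
  structure(
    list(proportions = props, good = props[, "C"] + props[, "D"],
         block_size = block_size, partial_final = (n %% block_size) != 0),
    class = "igt_block_props"
  )
}

#' @export
print.igt_block_props <- function(x, ...) {
  m <- cbind(x$proportions, good = x$good)
  cat("Choice proportions per block of ", x$block_size, " trials",
      if (x$partial_final) " (final block partial)", ":\n", sep = "")
  print(round(m, 3))
  invisible(x)
}

igt_csv_columns <- c("subject", "trial", "deck", "reward", "loss")

#' Read an IGT dataset from CSV
#'
#' Expects a header with columns `subject`, `trial` (1-based, contiguous per
#' subject), `deck` (1-4), `reward` (`>= 0`), `loss` (`<= 0`). Parse errors
#' cite the offending column or data row.
#'
#' @param path CSV file path.
#' @param name dataset name (default: file name without extension).
#' @return an `igt_dataset`.
#' @export
read_igt_csv <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(igt_csv_columns, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  bad_deck <- which(!(df$deck %in% 1:4))
  if (length(bad_deck))
    stop("deck value ", df$deck[bad_deck[1]], " outside 1-4 at row ",
         bad_deck[1])
  bad_reward <- which(df$reward < 0)
  if (length(bad_reward))
    stop("negative reward at row ", bad_reward[1])
  bad_loss <- which(df$loss > 0)
  if (length(bad_loss))
    stop("positive loss at row ", bad_loss[1], " (losses are stored <= 0)")
  subjects <- unique(df$subject)
  parts <- lapply(subjects, function(s) {
    rows <- df[df$subject == s, , drop = FALSE]
    rows <- rows[order(rows$trial), , drop = FALSE]
    if (!identical(as.integer(rows$trial), seq_len(nrow(rows))))
      stop("non-contiguous trial indices for subject ", s,
           " (expected 1..", nrow(rows), ")")
    grp <- if ("group" %in% names(rows)) rows$group[1] else NULL
    participant_data(s, rows$deck, rows$reward, rows$loss, group = grp)
  })
  if (is.null(name)) name <- sub("\\.[Cc][Ss][Vv]$", "", basename(path))
  group_dataset(parts, name = name)
}

#' Write an IGT dataset to CSV
#'
#' Inverse of [read_igt_csv()]: the write -> read roundtrip is the identity
#' on trial records. Group labels are included as a `group` column when any
#' participant carries one.
#'
#' @param dataset an `igt_dataset`.
#' @param path output CSV path.
#' @param include_group write the `group` column (default: only when labels
#'   are present).
#' @return `path`, invisibly.
#' @export
write_igt_csv <- function(dataset, path, include_group = NULL) {
  stopifnot(inherits(dataset, "igt_dataset"))
  has_grp <- any(vapply(dataset$participants,
                        function(p) !is.null(p$group), logical(1)))
  if (is.null(include_group)) include_group <- has_grp
  rows <- lapply(dataset$participants, function(p) {
    out <- data.frame(subject = p$id, trial = seq_along(p$deck),
                      deck = p$deck, reward = p$reward, loss = p$loss)
    if (include_group) out$group <- if (is.null(p$group)) NA else p$group
    out
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
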