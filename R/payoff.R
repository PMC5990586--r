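#' Traditional Iowa Gambling Task payoff schedule
#'
#' Builds the deterministic four-deck payoff schedule of the traditional
#' (Bechara-style) Iowa Gambling Task. Decks A and B pay a win of 100 currency
#' units on every draw, decks C and D pay 50. Losses are arranged so that over
#' every consecutive block of ten draws the net outcome totals -250 for the
#' disadvantageous decks A and B and +250 for the advantageous decks C and D;
#' deck A and C spread their losses over five positions per block, decks B and
#' D take a single large loss. The block pattern repeats cyclically so that any
#' number of draws that is a multiple of ten can be dealt from a single deck.
#'
#' The exact within-block loss positions follow the canonical fixed schedule
#' (deck A: -150, -300, -200, -250, -350 at positions 3, 5, 7, 9, 10; deck B:
#' -1250 at position 9; deck C: small unpredictable losses -25, -75, -50,
#' -25, -75 at positions 3, 5, 7, 9, 10, mean 50; deck D: -250 at position
#' 10). Any schedule satisfying the block-sum and loss-count invariants is a
#' conforming "traditional" dialect; deck C's losses are varied (not five
#' flat -50s) so that its loss draws do not all net exactly zero, which
#' would make outcomes from the most-preferred deck carry no utility
#' information.
#'
#' @param max_draws Maximum number of draws dealable from each deck; must be a
#'   positive multiple of 10 (the schedule is defined in 10-draw blocks).
#' @param initial_credit Starting credit of the task (recorded as metadata;
#'   plays no role in the model equations).
#' @return An object of class `igt_schedule`: a list with `wins` and `losses`
#'   (`max_draws` x 4 matrices, columns = decks A-D), `max_draws` and
#'   `initial_credit`.
#' @examples
#' sch <- igt_payoff_schedule(20)
#' colSums(sch$wins[1:10, ] + sch$losses[1:10, ]) # -250 -250 250 250
#' @export
igt_payoff_schedule <- function(max_draws = 200L, initial_credit = 2000) {
  if (length(max_draws) != 1L || !is.finite(max_draws) || max_draws < 10 ||
      max_draws %% 10 != 0)
    stop("`max_draws` must be a positive multiple of 10", call. = FALSE)
  max_draws <- as.integer(max_draws)
  block_win <- cbind(A = rep(100, 10), B = rep(100, 10),
                     C = rep(50, 10), D = rep(50, 10))
  block_loss <- matrix(0, 10, 4, dimnames = list(NULL, c("A", "B", "C", "D")))
  block_loss[c(3, 5, 7, 9, 10), "A"] <- c(-150, -300, -200, -250, -350)
  block_loss[9, "B"] <- -1250
  block_loss[c(3, 5, 7, 9, 10), "C"] <- c(-25, -75, -50, -25, -75)
  block_loss[10, "D"] <- -250
  reps <- max_draws %/% 10L
  out <- list(
    wins = block_win[rep(seq_len(10), reps), , drop = FALSE],
    losses = block_loss[rep(seq_len(10), reps), , drop = FALSE],
    max_draws = max_draws,
    initial_credit = initial_credit
  )
  class(out) <- "igt_schedule"
  out
}

#' Deal one card from a deck
#'
#' Returns the scheduled (win, loss) pair for the `position`-th draw from a
#' deck. Pure and deterministic.
#'
#' @param schedule An `igt_schedule`.
#' @param deck Deck index in 1..4 (A-D).
#' @param position Draw position, 1-based; must not exceed
#'   `schedule$max_draws`.
#' @return Named numeric vector with elements `win`, `loss` and `net`.
#' @export
igt_deal <- function(schedule, deck, position) {
  stopifnot(inherits(schedule, "igt_schedule"))
  if (length(deck) != 1L || !deck %in% 1:4)
    stop("`deck` must be a single index in 1..4", call. = FALSE)
  if (length(position) != 1L || position < 1 || position > schedule$max_draws)
    stop("`position` out of range 1..", schedule$max_draws, call. = FALSE)
  w <- unname(schedule$wins[position, deck])
  l <- unname(schedule$losses[position, deck])
  c(win = w, loss = l, net = w + l)
}

#' Validate a trial-level IGT dataset
#'
#' Checks the long-format trial table contract: required columns, deck indices
#' in 1..4, non-negative wins, non-positive losses, and trial indices running
#' contiguously from 1 within every participant.
#'
#' @param data A data.frame with columns `participant`, `trial`, `choice`,
#'   `win`, `loss`.
#' @return The validated data.frame (invisibly classed `igt_data`), ordered by
#'   participant and trial.
#' @export
validate_igt_data <- function(data) {
  req <- c("participant", "trial", "choice", "win", "loss")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(data) == 0L) stop("empty dataset: no trial records", call. = FALSE)
  bad <- which(!data$choice %in% 1:4)
  if (length(bad))
    stop("invalid deck index at row ", bad[1], " (choice = ",
         data$choice[bad[1]], ")", call. = FALSE)
  bad <- which(data$win < 0)
  if (length(bad)) stop("negative win at row ", bad[1], call. = FALSE)
  bad <- which(data$loss > 0)
  if (length(bad)) stop("positive loss at row ", bad[1], call. = FALSE)
  data <- data[order(data$participant, data$trial), , drop = FALSE]
  for (id in unique(data$participant)) {
    tr <- data$trial[data$participant == id]
    if (!identical(as.integer(tr), seq_len(length(tr))))
      stop("non-contiguous trial indices for participant ", id, call. = FALSE)
  }
  rownames(data) <- NULL
  class(data) <- c("igt_data", "data.frame")
  invisible(data)
}

#' Read / write trial-level IGT data
#'
#' Delimited-text round trip for the trial table (columns `participant`,
#' `trial`, `choice`, `win`, `loss`; losses stored as non-positive numbers).
#' Reading validates the dataset; writing then reading reproduces it exactly.
#'
#' @param path File path of a delimited text file with a header row.
#' @param sep Field separator (default comma).
#' @return `read_igt_trials` returns a validated `igt_data` data.frame.
#' @export
read_igt_trials <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  data <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
  if (nrow(data) == 0L) stop("empty dataset: ", path, call. = FALSE)
  data <- validate_igt_data(data)
  class(data) <- c("igt_data", "data.frame")
  data
}

#' @rdname read_igt_trials
#' @param data An `igt_data` data.frame (or coercible; validated before
#'   writing).
#' @export
write_igt_trials <- function(data, path, sep = ",") {
  data <- validate_igt_data(as.data.frame(data))
  utils::write.table(data, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Reshape a validated long trial table into T x N choice and net matrices
# (columns ordered by unique(participant)); internal plumbing for the
# likelihood and sampler.
igt_matrices <- function(data) {
  data <- validate_igt_data(as.data.frame(data))
  ids <- unique(data$participant)
  Ts <- table(factor(data$participant, levels = ids))
  if (length(unique(as.integer(Ts))) != 1L)
    stop("all participants must have the same number of trials", call. = FALSE)
  T <- as.integer(Ts[1])
  N <- length(ids)
  choice <- matrix(0L, T, N)
  net <- matrix(0, T, N)
  for (j in seq_along(ids)) {
    rows <- data$participant == ids[j]
    choice[, j] <- as.integer(data$choice[rows])
    net[, j] <- data$win[rows] + data$loss[rows]
  }
  list(choice = choice, net = net, ids = ids, n_trials = T, n_participants = N)
}
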