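#' Deck payoff schedule for the Iowa Gambling Task
#'
#' Returns the deck schedule as a data frame with one row per deck and
#' block, columns `deck`, `block`, `reward`, `loss`, `loss_probability`.
#' Every pick from a deck pays `reward` points; with probability
#' `loss_probability` it additionally incurs `loss` points (`loss <= 0`).
#'
#' The bundled default follows the canonical task structure: decks A and B
#' pay 100 per pick but lose 25 per pick in expectation (A through frequent
#' moderate losses, B through a rare large loss of 1250), while decks C and
#' D pay 50 and gain 25 per pick in expectation.  A and B are therefore
#' disadvantageous (negative expected value) and C and D advantageous.
#'
#' @param file optional CSV path with the columns above to load an
#'   alternative schedule; `NULL` loads the bundled default.
#' @return a data frame of class `deck_schedule`.
#' @export
deck_schedule <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "deck_schedule.csv", package = "bgstim",
                        mustWork = TRUE)
  s <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("deck", "block", "reward", "loss", "loss_probability")
  if (!all(need %in% names(s)))
    stop("deck schedule must have columns: ", paste(need, collapse = ", "))
  if (any(s$loss > 0)) stop("losses must be <= 0 (sign convention)")
  if (any(s$loss_probability < 0 | s$loss_probability > 1))
    stop("loss_probability must lie in [0, 1]")
  if (!all(c("A", "B", "C", "D") %in% s$deck))
    stop("schedule must cover decks A, B, C, D")
  class(s) <- c("deck_schedule", "data.frame")
  s
}

#' Expected value per pick for each deck
#'
#' @param schedule a [deck_schedule()].
#' @return named numeric vector (decks A-D), expected net points per pick
#'   averaged over blocks.
#' @export
deck_expected_value <- function(schedule) {
  ev <- sapply(c("A", "B", "C", "D"), function(d) {
    rows <- schedule[schedule$deck == d, ]
    mean(rows$reward + rows$loss_probability * rows$loss)
  })
  ev
}

# Schedule row applying to a given deck and trial (1..100): the row whose
# block is the largest block <= the trial's 20-trial block, so a
# single-block schedule applies throughout.
schedule_row <- function(schedule, deck, trial) {
  rows <- schedule[schedule$deck == deck, ]
  if (nrow(rows) == 0) stop("unknown deck: ", deck)
  blk <- ceiling(trial / 20)
  rows <- rows[rows$block <= blk, ]
  rows[which.max(rows$block), ]
}

#' Draw one card from a deck
#'
#' Samples the outcome of picking `deck` on trial `trial`: the deck's fixed
#' reward plus, with the deck's loss probability, its loss.  Uses the R
#' session RNG; seed with [set.seed()] for reproducible sequences.
#'
#' @param schedule a [deck_schedule()].
#' @param deck one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param trial trial index (>= 1), used for block-dependent schedules.
#' @return list with `reward` (>= 0), `loss` (<= 0) and `net`
#'   (reward + loss).
#' @export
draw_card <- function(schedule, deck, trial = 1) {
  stopifnot(trial >= 1)
  if (!deck %in% c("A", "B", "C", "D")) stop("unknown deck: ", deck)
  row <- schedule_row(schedule, deck, trial)
  loss <- if (runif(1) < row$loss_probability) row$loss else 0
  list(reward = row$reward, loss = loss, net = row$reward + loss)
}

#' Score an IGT session
#'
#' The total score is the number of advantageous picks (decks C, D) minus
#' the number of disadvantageous picks (decks A, B); bin scores apply the
#' same statistic to the five consecutive 20-trial bins, so the total always
#' equals the sum of the bins.
#'
#' @param selections character vector of exactly 100 deck labels.
#' @return list with `total` (in `[-100, 100]`) and `bins` (length 5,
#'   each in `[-20, 20]`).
#' @export
igt_score <- function(selections) {
  if (length(selections) != 100)
    stop("an IGT session has exactly 100 selections, got ", length(selections))
  if (!all(selections %in% c("A", "B", "C", "D")))
    stop("selections must be deck labels A-D")
  sgn <- ifelse(selections %in% c("C", "D"), 1, -1)
  bins <- vapply(1:5, function(b) sum(sgn[(20 * b - 19):(20 * b)]), numeric(1))
  list(total = sum(sgn), bins = bins)
}

#' Write a deck schedule to CSV
#'
#' @param schedule a [deck_schedule()].
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_deck_schedule <- function(schedule, file) {
  write.csv(as.data.frame(schedule), file, row.names = FALSE)
  invisible(file)
}
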