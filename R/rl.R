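#' Dopamine / learning parameters for a simulated condition
#'
#' The temporal-difference error delta stands in for phasic dopamine.  In
#' the untreated parkinsonian condition the loss of dopamine neurons is
#' modelled by clamping delta from above, `min(delta, da_ceil)`; dopaminergic
#' medication adds a positive `delta_med` term to the clamped error.  A
#' dopamine agonist (DAA) is modelled as medication whose plasticity effect
#' is restricted to the D2 pathway: only `w_D2` is updated, `w_D1` is frozen.
#'
#' @param condition `"HC"` (healthy control), `"PD_OFF"` (untreated),
#'   `"PD_ON_LDOPA"` or `"PD_ON_DAA"`.
#' @param eta learning rate, default 0.1.
#' @param da_ceil upper clamp on delta in PD conditions, default 0.05 (on
#'   the learning scale, see `outcome_scale` in [bg_network_config()]).
#' @param delta_med additive medication term in PD-ON conditions; the
#'   default 13 exceeds the largest scaled penalty, so every medicated
#'   outcome - including net losses - reinforces the selected deck.
#' @return an object of class `dopamine_params`.
#' @export
dopamine_params <- function(condition = c("HC", "PD_OFF", "PD_ON_LDOPA",
                                          "PD_ON_DAA"),
                            eta = 0.1, da_ceil = 0.05, delta_med = 13) {
  condition <- match.arg(condition)
  stopifnot(eta > 0)
  structure(list(condition = condition, eta = eta, da_ceil = da_ceil,
                 delta_med = delta_med),
            class = "dopamine_params")
}

#' Initialise cortico-striatal weights
#'
#' Each deck carries two cortico-striatal weights, `w_D1` (direct pathway,
#' selection) and `w_D2` (indirect pathway, avoidance), initialised
#' uniformly at random on (0, 1).
#'
#' @return list of class `cs_weights` with numeric 4-vectors `d1` and `d2`
#'   named by deck.
#' @export
init_weights <- function() {
  decks <- c("A", "B", "C", "D")
  structure(list(d1 = stats::setNames(runif(4), decks),
                 d2 = stats::setNames(runif(4), decks)),
            class = "cs_weights")
}

# one-hot selection vector from a deck label
selection_vector <- function(deck) {
  decks <- c("A", "B", "C", "D")
  if (is.character(deck)) {
    stopifnot(deck %in% decks)
    as.numeric(decks == deck)
  } else {
    x <- as.numeric(deck)
    if (length(x) != 4 || sum(x == 1) != 1 || any(!x %in% c(0, 1)))
      stop("selection must be a one-hot 4-vector or a deck label")
    x
  }
}

#' Expected value of the selected deck
#'
#' `V_k = sum_i w_D1[i] * x_sel[i]`: the D1 cortico-striatal weight of the
#' selected deck.
#'
#' @param weights a `cs_weights` object (or a plain numeric 4-vector taken
#'   as `w_D1`).
#' @param selection deck label or one-hot 4-vector.
#' @return scalar value estimate.
#' @export
compute_value <- function(weights, selection) {
  w1 <- if (inherits(weights, "cs_weights")) weights$d1 else as.numeric(weights)
  stopifnot(length(w1) == 4)
  sum(w1 * selection_vector(selection))
}

#' Temporal-difference error
#'
#' `delta_k = Re_k + L_k - V_k`, where `Re_k` and `L_k` are the reward and
#' loss of the selected card and `V_k` the current value estimate.
#'
#' @param reward reward of the selected card (>= 0).
#' @param loss loss of the selected card (<= 0).
#' @param value current value `V_k` of the selected deck.
#' @return scalar delta.
#' @export
compute_delta <- function(reward, loss, value) {
  if (loss > 0) stop("loss must be <= 0 (sign convention)")
  reward + loss - value
}

#' Condition-dependent transform of the TD error
#'
#' Healthy: delta unchanged.  Untreated PD: `min(delta, da_ceil)` (the clamp
#' only cuts positive surprises; negative errors pass).  Medicated PD
#' (either drug): `min(delta, da_ceil) + delta_med`.
#'
#' @param delta raw TD error.
#' @param params a [dopamine_params()] object.
#' @return effective delta used for the weight update.
#' @export
condition_transform <- function(delta, params) {
  stopifnot(inherits(params, "dopamine_params"))
  switch(params$condition,
    HC = delta,
    PD_OFF = min(delta, params$da_ceil),
    PD_ON_LDOPA = ,
    PD_ON_DAA = min(delta, params$da_ceil) + params$delta_med)
}

#' Update cortico-striatal weights from the effective TD error
#'
#' Opposed plasticity on the selected deck:
#' `w_D1 <- w_D1 + eta * delta` and `w_D2 <- w_D2 - eta * delta`.  Under the
#' dopamine-agonist condition only `w_D2` is updated (`w_D1` frozen).
#' Weights are clipped to `[0, w_max]` to prevent unbounded drift; the
#' striatal rate map saturates in that range anyway.
#'
#' By default the update is gated by the selected deck only (the outcome of
#' an unchosen deck is never observed).  `literal_input = TRUE` restores the
#' variant in which the same delta updates all presented decks (the
#' all-ones input vector), for comparison.
#'
#' @param weights a `cs_weights` object.
#' @param delta_eff effective (condition-transformed) TD error.
#' @param selection deck label or one-hot 4-vector.
#' @param params a [dopamine_params()] object.
#' @param w_max weight clip, default 2.
#' @param literal_input update all presented decks instead of the selected
#'   one (default `FALSE`).
#' @return the updated `cs_weights`.
#' @export
update_weights <- function(weights, delta_eff, selection, params,
                           w_max = 2, literal_input = FALSE) {
  stopifnot(inherits(weights, "cs_weights"),
            inherits(params, "dopamine_params"))
  x <- if (literal_input) rep(1, 4) else selection_vector(selection)
  eta <- params$eta
  if (params$condition != "PD_ON_DAA")
    weights$d1 <- pmin(pmax(weights$d1 + eta * delta_eff * x, 0), w_max)
  weights$d2 <- pmin(pmax(weights$d2 - eta * delta_eff * x, 0), w_max)
  if (any(!is.finite(weights$d1)) || any(!is.finite(weights$d2)))
    stop("non-finite cortico-striatal weight after update")
  weights
}
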