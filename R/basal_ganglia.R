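# Basal-ganglia readout: per-(column, category) recommendation weights.
# A decision sums spike-count-weighted recommendations per category; the
# only learning is consequence feedback on these weights (teacher signal or
# bare correct/incorrect). Cortical synapses are never touched by feedback.

#' Initialise recommendation weights
#'
#' Every layer-3 output (one per column) starts with the same low
#' recommendation weight in favour of every category.
#'
#' @param n_columns Number of cortical columns.
#' @param n_categories Number of categories.
#' @param w0 Common positive initial weight.
#' @return `n_columns x n_categories` matrix of class `ra_weights`.
#' @export
init_weights <- function(n_columns, n_categories, w0) {
  stopifnot(n_columns >= 1, n_categories >= 1)
  if (length(w0) != 1L || is.na(w0) || w0 <= 0)
    stop("`w0` must be a positive scalar")
  structure(matrix(as.numeric(w0), n_columns, n_categories),
            w0 = as.numeric(w0),
            class = c("ra_weights", "matrix", "array"))
}

#' Decide the category for one working-memory segment
#'
#' Accumulates, for every category, the recommendation weights of all
#' layer-3 outputs multiplied by the column's spike count over the segment,
#' and ranks categories by total (ties broken by lowest category index).
#'
#' @param weights An `ra_weights` matrix.
#' @param counts Non-negative integer vector of per-column layer-3 spike
#'   counts for one category segment.
#' @return Object of class `ra_decision`: `totals`, `ranking` (best first)
#'   and `chosen` (`ranking[1]`).
#' @export
decide <- function(weights, counts) {
  stopifnot(inherits(weights, "ra_weights"))
  counts <- as.numeric(counts)
  if (length(counts) != nrow(weights))
    stop("`counts` length must equal the number of columns")
  if (any(counts < 0)) stop("`counts` must be non-negative")
  totals <- as.vector(crossprod(weights, counts))
  ranking <- order(-totals, seq_along(totals))
  structure(list(totals = totals, ranking = as.integer(ranking),
                 chosen = as.integer(ranking[1L])),
            class = "ra_decision")
}

#' Teacher-signal weight update
#'
#' The weights in favour of the correct category are increased for every
#' column in proportion to the column's spike count during the segment
#' (`+ alpha_up * counts`), saturating at the ceiling `w_cap`. If the
#' top-ranked category was incorrect, the weights in favour of that chosen
#' category are additionally reduced by the standard proportion
#' `delta_down` for every column that produced output. The ceiling anchors
#' every category's weights at the same scale no matter when it was
#' trained, which is what lets earlier learning survive later learning.
#'
#' @param weights An `ra_weights` matrix.
#' @param counts Per-column spike counts the decision was computed from.
#' @param decision The `ra_decision` for these counts.
#' @param correct Correct category id.
#' @param alpha_up Increment rate per spike.
#' @param delta_down Proportional reduction in `[0, 1)` for an incorrect
#'   top choice.
#' @param w_cap Saturation ceiling on recommendation weights. Increments
#'   never push a weight above `w_cap`, so every category's weights level
#'   off at the same scale no matter when it was trained (default `Inf`,
#'   no ceiling).
#' @return The updated `ra_weights`.
#' @export
learn_teacher <- function(weights, counts, decision, correct,
                          alpha_up, delta_down, w_cap = Inf) {
  stopifnot(inherits(weights, "ra_weights"), inherits(decision, "ra_decision"))
  if (delta_down < 0 || delta_down >= 1)
    stop("`delta_down` must lie in [0, 1)")
  if (w_cap <= 0) stop("`w_cap` must be positive")
  counts <- as.numeric(counts)
  weights[, correct] <- pmin(weights[, correct] + alpha_up * counts, w_cap)
  if (decision$chosen != correct) {
    active <- counts > 0
    weights[active, decision$chosen] <-
      weights[active, decision$chosen] * (1 - delta_down)
  }
  weights
}

#' Correct/incorrect-only weight update
#'
#' Low-information consequence feedback: the basal ganglia is only told
#' whether its selection was right. On incorrect feedback the weights of
#' active columns toward the chosen category are reduced by `delta_down`;
#' nothing is increased because the correct category is unknown. On correct
#' feedback the default is no change (an optional small multiplicative
#' boost of the chosen category can be enabled with `correct_boost`).
#'
#' @inheritParams learn_teacher
#' @param is_correct Logical (or 0/1): was the chosen category correct?
#' @param correct_boost Optional proportional increase applied to active
#'   columns' weights toward a correctly chosen category (default 0, off).
#' @return The updated `ra_weights`.
#' @export
learn_feedback_only <- function(weights, counts, decision, is_correct,
                                delta_down, correct_boost = 0) {
  stopifnot(inherits(weights, "ra_weights"), inherits(decision, "ra_decision"))
  if (delta_down < 0 || delta_down >= 1)
    stop("`delta_down` must lie in [0, 1)")
  counts <- as.numeric(counts)
  active <- counts > 0
  if (isTRUE(as.logical(is_correct))) {
    if (correct_boost > 0)
      weights[active, decision$chosen] <-
        weights[active, decision$chosen] * (1 + correct_boost)
  } else {
    weights[active, decision$chosen] <-
      weights[active, decision$chosen] * (1 - delta_down)
  }
  weights
}
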