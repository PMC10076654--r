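# Accuracy metrics over decision logs.

#' Top-k accuracy
#'
#' Fraction of decisions whose top-k ranking contains the true label.
#' Accepts either a decision log data frame (with a `rank_of_true` column,
#' as produced by the experiment runners) or a list of `ra_decision`
#' objects with a parallel `labels` vector.
#'
#' @param decisions Decision log data frame, or list of `ra_decision`.
#' @param labels True category ids (ignored for a log data frame, which
#'   already carries them).
#' @param k Ranking depth, `1 <= k <= n_categories`.
#' @return Accuracy in `[0, 1]`.
#' @export
topk_accuracy <- function(decisions, labels = NULL, k = 1L) {
  if (is.data.frame(decisions)) {
    rank_of_true <- decisions$rank_of_true
    n_categories <- attr(decisions, "n_categories")
  } else {
    if (length(decisions) != length(labels))
      stop("`decisions` and `labels` lengths differ")
    rank_of_true <- mapply(function(d, l) match(l, d$ranking),
                           decisions, labels)
    n_categories <- if (length(decisions)) length(decisions[[1L]]$ranking)
                    else NA_integer_
  }
  if (length(rank_of_true) == 0L) stop("empty decision log")
  if (k < 1L) stop("`k` must be at least 1")
  if (!is.null(n_categories) && !is.na(n_categories) && k > n_categories)
    stop("`k` exceeds the number of categories")
  mean(rank_of_true <= k)
}

#' Set-balance ratio
#'
#' Accuracy on the first-learned category set divided by accuracy on the
#' second-learned set; 1 indicates balanced retention.
#'
#' @param acc_first,acc_second Per-set accuracies.
#' @return The ratio, or `NA` with a warning when the denominator is zero.
#' @export
set_balance_ratio <- function(acc_first, acc_second) {
  if (acc_second == 0) {
    warning("second-set accuracy is zero; ratio undefined")
    return(NA_real_)
  }
  acc_first / acc_second
}

# Accuracy summary of one stage's decision log.
stage_metrics <- function(log, set_a = NULL) {
  acc <- vapply(1:3, function(k) topk_accuracy(log, k = k), numeric(1L))
  names(acc) <- paste0("top", 1:3)
  out <- list(overall = acc, n_decisions = nrow(log))
  if (!is.null(set_a)) {
    la <- log[log$label %in% set_a, , drop = FALSE]
    lb <- log[!log$label %in% set_a, , drop = FALSE]
    attr(la, "n_categories") <- attr(log, "n_categories")
    attr(lb, "n_categories") <- attr(log, "n_categories")
    out$set_a <- vapply(1:3, function(k) topk_accuracy(la, k = k), numeric(1L))
    out$set_b <- vapply(1:3, function(k) topk_accuracy(lb, k = k), numeric(1L))
    names(out$set_a) <- names(out$set_b) <- paste0("top", 1:3)
    out$set_balance_ratio <- suppressWarnings(
      set_balance_ratio(out$set_a[["top1"]], out$set_b[["top1"]]))
  }
  out
}
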