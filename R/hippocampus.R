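# Hippocampal connectivity bias ("dream sleep"): from an unprocessed sample of
# presentations, group the 400 input components into per-column sets of inputs
# that tend to be active at the same time. The groups bias initial layer-1
# wiring; nothing else of the hippocampus is modelled.

#' Derive co-activation input groups
#'
#' Pools a sample of presentations, counts for every input pair the number of
#' timeslots on which both spiked, and clusters the inputs on this
#' co-occurrence into exactly `n_columns` groups of roughly equal size
#' (greedy average-linkage agglomeration on cosine-normalised co-occurrence,
#' with a group-size cap; deterministic, ties broken by lowest index).
#' Inputs that never spiked in the sample carry no co-occurrence signal and
#' are placed into the smallest groups at the end.
#'
#' @param sample List of `ra_presentation` objects covering all categories.
#' @param n_columns Number of groups, one per cortical column.
#' @return Object of class `ra_groups`: `groups` (list of `n_columns`
#'   disjoint integer index sets) and the symmetric `cooccurrence` count
#'   matrix they were formed from.
#' @export
derive_coactivation_groups <- function(sample, n_columns) {
  if (length(sample) == 0L) stop("`sample` must contain presentations")
  stopifnot(n_columns >= 1)
  n_in <- ncol(sample[[1L]]$spikes)
  co <- matrix(0, n_in, n_in)
  for (p in sample) {
    stopifnot(inherits(p, "ra_presentation"))
    co <- co + crossprod(p$spikes)
  }
  d <- diag(co)
  active <- which(d > 0)
  inert <- which(d == 0)
  if (length(active) < n_columns)
    stop("fewer active inputs than requested groups")
  s <- co[active, active, drop = FALSE] /
    sqrt(outer(d[active], d[active]))
  groups <- greedy_equal_groups(s, n_columns,
                                cap = ceiling(n_in / n_columns))
  groups <- lapply(groups, function(g) active[g])
  for (i in inert) {
    j <- which.min(lengths(groups))
    groups[[j]] <- c(groups[[j]], i)
  }
  groups <- lapply(groups, function(g) sort(as.integer(g)))
  structure(list(groups = groups, cooccurrence = co), class = "ra_groups")
}

# Greedy size-capped average-linkage agglomeration into exactly k clusters.
# Deterministic: the best pair is the first maximum in column-major order.
# If no pair can merge under the cap while more than k clusters remain, the
# cap is relaxed by one.
greedy_equal_groups <- function(s, k, cap) {
  n <- nrow(s)
  if (k > n) stop("more groups than items")
  members <- as.list(seq_len(n))
  cross_sum <- s            # total inter-cluster similarity
  sizes <- rep(1L, n)
  alive <- rep(TRUE, n)
  n_alive <- n
  while (n_alive > k) {
    avg <- cross_sum / outer(sizes, sizes)
    avg[outer(sizes, sizes, "+") > cap] <- -Inf
    avg[!alive, ] <- -Inf
    avg[, !alive] <- -Inf
    diag(avg) <- -Inf
    best <- which.max(avg)
    if (!is.finite(avg[best])) {
      cap <- cap + 1L
      next
    }
    j <- (best - 1L) %/% n + 1L
    i <- (best - 1L) %% n + 1L
    a <- min(i, j); b <- max(i, j)
    members[[a]] <- c(members[[a]], members[[b]])
    cross_sum[a, ] <- cross_sum[a, ] + cross_sum[b, ]
    cross_sum[, a] <- cross_sum[, a] + cross_sum[, b]
    sizes[a] <- sizes[a] + sizes[b]
    alive[b] <- FALSE
    n_alive <- n_alive - 1L
  }
  members[alive]
}
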