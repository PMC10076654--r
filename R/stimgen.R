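# Stimulus generation: never-identical categorical spike streams.
#
# Each of the 30 categories is a fixed 400-component propensity profile.
# A presentation renders the active profile through a 40 Hz gamma envelope
# and an integer chance draw (1..10,000), so no two renderings are ever
# identical even within a category.

#' Propensity level pool with decaying repetition
#'
#' Builds the multiset of propensity levels from which category profiles are
#' drawn. Levels run `0..max_level`; the multiplicity of a level decays
#' linearly (rounded to nearest integer) from `max_repeat` at level 0 down to
#' 1 at `max_level`, so a uniform draw from the pool favours small
#' propensities and keeps input spiking sparse.
#'
#' @param max_level Largest propensity level (default 200).
#' @param max_repeat Multiplicity of level 0 (default 5).
#' @return An object of class `ra_level_pool` with fields `levels`,
#'   `multiplicity`, and `draws` (the expanded multiset that is sampled).
#' @export
make_level_pool <- function(max_level = 200L, max_repeat = 5L) {
  if (length(max_level) != 1L || is.na(max_level) || max_level < 1)
    stop("`max_level` must be a positive integer")
  if (length(max_repeat) != 1L || is.na(max_repeat) || max_repeat < 1)
    stop("`max_repeat` must be a positive integer")
  levels <- 0:max_level
  mult <- as.integer(round(max_repeat - (max_repeat - 1) * levels / max_level))
  mult <- pmax(mult, 1L)
  structure(list(levels = levels, multiplicity = mult,
                 draws = rep(levels, mult)),
            class = "ra_level_pool")
}

#' Draw one category propensity profile
#'
#' A profile is `n_components` i.i.d. uniform draws from the level pool. It is
#' fixed for the lifetime of a model instantiation; only its renderings vary.
#' Uses the current R random stream (seed at the call site for
#' reproducibility).
#'
#' @param pool An `ra_level_pool`.
#' @param n_components Profile length (default 400, the number of cortical
#'   input sources).
#' @return Integer vector of length `n_components` with values in
#'   `[0, max_level]`.
#' @export
make_category_profile <- function(pool, n_components = 400L) {
  stopifnot(inherits(pool, "ra_level_pool"))
  pool$draws[sample.int(length(pool$draws), n_components, replace = TRUE)]
}

#' Draw a full set of category profiles
#'
#' @param n_categories Number of categories (rows).
#' @param pool An `ra_level_pool`.
#' @param n_components Profile length (default 400).
#' @return Integer matrix `n_categories x n_components`, class `ra_profiles`;
#'   row `i` is the propensity profile of category `i`.
#' @export
make_category_profiles <- function(n_categories, pool, n_components = 400L) {
  stopifnot(n_categories >= 1)
  m <- t(vapply(seq_len(n_categories),
                function(i) make_category_profile(pool, n_components),
                integer(n_components)))
  structure(m, class = c("ra_profiles", class(m)))
}

#' Gamma modulation envelope
#'
#' The thalamic 40 Hz modulation is modelled as a half-wave duty-cycle
#' envelope: within each `period_timeslots`-slot gamma period the first half
#' of the slots carry factor `f_hi` and the second half `f_lo`. With 1/3 ms
#' timeslots an 8-slot period is one 40 Hz cycle, and 75 periods make one
#' 200 ms (600-slot) presentation.
#'
#' @param n_periods Number of gamma periods (75 for triple working-memory
#'   mode, 25 for single-category mode).
#' @param period_timeslots Timeslots per gamma period (default 8).
#' @param f_hi,f_lo Modulation factors for the high and low half-periods.
#'   `f_hi * max_level` may not exceed 10,000 so spike probability stays at
#'   or below 1.
#' @param max_level Largest propensity level the envelope will meet.
#' @return Object of class `ra_envelope` with the per-timeslot `factor`.
#' @export
make_modulation_envelope <- function(n_periods = 75L, period_timeslots = 8L,
                                     f_hi = 50, f_lo = 5, max_level = 200L) {
  stopifnot(n_periods >= 1, period_timeslots >= 2)
  if (f_hi < 0 || f_lo < 0) stop("modulation factors must be non-negative")
  if (f_hi * max_level > 10000)
    stop("`f_hi * max_level` must not exceed 10,000 (spike probability cap)")
  half <- period_timeslots %/% 2L
  cycle <- c(rep(f_hi, half), rep(f_lo, period_timeslots - half))
  structure(list(factor = rep(cycle, n_periods),
                 period_timeslots = as.integer(period_timeslots),
                 n_periods = as.integer(n_periods),
                 f_hi = f_hi, f_lo = f_lo),
            class = "ra_envelope")
}

#' Chance draw for a spike
#'
#' A spike occurs iff the product of propensity and modulation factor exceeds
#' an integer drawn uniformly from 1..10,000, i.e.
#' `P(spike) = clamp(ceiling(product) - 1, 0, 10000) / 10000`.
#' Vectorised over `product`; uses the current R random stream.
#'
#' @param product Non-negative propensity x modulation products.
#' @return Integer 0/1 vector of the same length.
#' @export
spike_draw <- function(product) {
  if (any(product < 0)) stop("`product` must be non-negative")
  r <- sample.int(10000L, length(product), replace = TRUE)
  as.integer(product > r)
}

# exact spike probability of the chance draw for a given product
chance_probability <- function(product) {
  pmin(pmax(ceiling(product) - 1, 0), 10000) / 10000
}

#' Render one presentation
#'
#' Renders one 200 ms stimulus window. In triple (working-memory) mode three
#' category profiles are interleaved round-robin across successive gamma
#' periods (25 periods each of the 75); in single mode one profile occupies
#' every period. Each cell is an independent chance draw, so two renderings
#' of the same profiles are never identical in practice.
#'
#' @param profiles Matrix with 1 or 3 rows (profiles in presentation order),
#'   or a single profile vector.
#' @param envelope An `ra_envelope` whose period count matches the mode
#'   (divisible by 3 in triple mode).
#' @param labels Category ids of the rows (default `1:nrow`).
#' @return Object of class `ra_presentation`: binary `spikes` matrix
#'   (`timeslots x components`), `labels`, per-timeslot `segments` (slot
#'   position 1..3 within the working-memory triple), and `seg_labels`
#'   (`labels[segments]`).
#' @export
render_presentation <- function(profiles, envelope, labels = NULL) {
  stopifnot(inherits(envelope, "ra_envelope"))
  if (is.null(dim(profiles))) profiles <- matrix(profiles, nrow = 1L)
  k <- nrow(profiles)
  if (!k %in% c(1L, 3L))
    stop("`profiles` must have 1 (single mode) or 3 (triple mode) rows")
  if (is.null(labels)) labels <- seq_len(k)
  if (length(labels) != k) stop("`labels` length must match profile count")
  if (k == 3L && envelope$n_periods %% 3L != 0L)
    stop("triple mode needs an envelope with a period count divisible by 3")
  n_slots <- envelope$n_periods * envelope$period_timeslots
  seg_period <- if (k == 3L) rep_len(1:3, envelope$n_periods)
                else rep(1L, envelope$n_periods)
  segments <- rep(seg_period, each = envelope$period_timeslots)
  # one probability row per (profile row, modulation level) combination;
  # each cell then takes one uniform draw at the exact chance probability
  half <- envelope$period_timeslots %/% 2L
  hi_slot <- rep(rep(c(TRUE, FALSE),
                     c(half, envelope$period_timeslots - half)),
                 envelope$n_periods)
  prob <- rbind(chance_probability(envelope$f_hi * profiles),
                chance_probability(envelope$f_lo * profiles))
  row_of_slot <- segments + ifelse(hi_slot, 0L, k)
  spikes <- render_spikes_cpp(prob, as.integer(row_of_slot))
  structure(list(spikes = spikes, labels = as.integer(labels),
                 segments = segments,
                 seg_labels = as.integer(labels)[segments]),
            class = "ra_presentation")
}

#' Build a presentation curriculum
#'
#' Lays out the fixed-order presentation schedule of an experiment. The
#' category order is a fixed cycle that never changes across epochs;
#' presentation `p` carries the working-memory triple of three consecutive
#' categories of the cycle, so over `n` presentations each category leads
#' `n / n_categories` of them. Stimulus instances themselves are rendered
#' later, one fresh rendering per row, and are never reused.
#'
#' Experiment one is the novelty run: `n_warmup` cortex-only presentations,
#' `n_teacher` teacher-feedback presentations, `n_test` test presentations.
#' Experiment two is the split-training run: a cortex-only warm-up on the
#' first category set, teacher training of set A (categories
#' `1..n_categories/2`) then set B, an all-category test (`after_split`),
#' optionally a correct/incorrect-only pass and retest (`after_feedback`),
#' and optionally a short teacher relearn pass and retest (`after_relearn`).
#'
#' @param experiment `"one"` or `"two"`.
#' @param n_categories Number of categories (default 30; even for
#'   experiment two).
#' @param n_warmup,n_teacher,n_test,n_feedback,n_relearn Phase lengths in
#'   presentations. `n_teacher` applies per category set in experiment two.
#' @param include_feedback_pass,include_relearn Include the recovery stages
#'   of experiment two.
#' @return Data frame of class `ra_curriculum` with columns `phase`
#'   (`cortex_only` / `teacher` / `feedback_only` / `test`), `stage`, and the
#'   triple `c1` (lead), `c2`, `c3`.
#' @export
build_curriculum <- function(experiment = c("one", "two"),
                             n_categories = 30L,
                             n_warmup = 300L, n_teacher = 600L, n_test = 300L,
                             n_feedback = 300L, n_relearn = 30L,
                             include_feedback_pass = TRUE,
                             include_relearn = TRUE) {
  experiment <- match.arg(experiment)
  counts <- c(n_warmup, n_teacher, n_test, n_feedback, n_relearn)
  if (any(counts < 0) || n_test < 1)
    stop("phase presentation counts are inconsistent")
  triple_block <- function(n, cats, phase, stage, offset = 0L) {
    if (n == 0L) return(NULL)
    k <- length(cats)
    i <- offset + seq_len(n) - 1L
    data.frame(phase = phase, stage = stage,
               c1 = cats[(i %% k) + 1L],
               c2 = cats[((i + 1L) %% k) + 1L],
               c3 = cats[((i + 2L) %% k) + 1L])
  }
  all_cats <- seq_len(n_categories)
  if (experiment == "one") {
    cur <- rbind(
      triple_block(n_warmup, all_cats, "cortex_only", "warmup"),
      triple_block(n_teacher, all_cats, "teacher", "train",
                   offset = n_warmup),
      triple_block(n_test, all_cats, "test", "test",
                   offset = n_warmup + n_teacher))
  } else {
    if (n_categories %% 2L != 0L)
      stop("experiment two needs an even number of categories")
    set_a <- seq_len(n_categories %/% 2L)
    set_b <- setdiff(all_cats, set_a)
    cur <- rbind(
      triple_block(n_warmup, set_a, "cortex_only", "warmup"),
      triple_block(n_teacher, set_a, "teacher", "train_a"),
      triple_block(n_teacher, set_b, "teacher", "train_b"),
      triple_block(n_test, all_cats, "test", "after_split"))
    if (include_feedback_pass)
      cur <- rbind(cur,
        triple_block(n_feedback, all_cats, "feedback_only", "feedback"),
        triple_block(n_test, all_cats, "test", "after_feedback"))
    if (include_relearn)
      cur <- rbind(cur,
        triple_block(n_relearn, all_cats, "teacher", "relearn"),
        triple_block(n_test, all_cats, "test", "after_relearn"))
  }
  rownames(cur) <- NULL
  structure(cur, n_categories = as.integer(n_categories),
            experiment = experiment,
            class = c("ra_curriculum", class(cur)))
}
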