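# Shared fixtures, built in code at test time.

# Micro cortex on a dyadic parameter grid: every weight is a dyadic rational
# with a short significand, so branch-potential sums are exact in floating
# point and independent of summation order. Used wherever the compiled
# engine is compared bit-for-bit against the per-synapse reference engine.
dyadic_cortex_config <- function(...) {
  cortex_config(neurons = c(4L, 3L, 1L), branches = c(2L, 2L, 2L),
                syn_per_branch = c(30L, 2L, 2L),
                theta_branch = c(8, 1, 1), theta_neuron = c(1L, 1L, 1L),
                w_init = 1, w_max = 4, d_pot = 0.25, d_dep = 0.25,
                m_miss = c(10L, 50L, 50L), rho_max = c(60L, 60L, 60L),
                s_homeo = 0.5, p_bias = 0.5, ...)
}

# One-neuron cortex for hand-verifiable threshold and plasticity arithmetic:
# a single layer-1 neuron with one branch of `n_syn` synapses wired to
# inputs 1..n_syn in order; layers 2-3 are single neurons that never fire.
micro_cortex <- function(n_syn = 2L, theta = 2, w_init = 1,
                         d_pot = 0.25, d_dep = 0.25,
                         m_miss = 3L, rho_max = 1000L) {
  cfg <- cortex_config(n_inputs = as.integer(n_syn),
                       neurons = c(1L, 1L, 1L), branches = c(1L, 1L, 1L),
                       syn_per_branch = c(as.integer(n_syn), 1L, 1L),
                       theta_branch = c(theta, 99, 99),
                       theta_neuron = c(1L, 1L, 1L),
                       w_init = w_init, w_max = 100,
                       d_pot = d_pot, d_dep = d_dep,
                       m_miss = c(m_miss, 999L, 999L),
                       rho_max = c(rho_max, 999L, 999L),
                       s_homeo = 0.5, p_bias = 0)
  state <- init_cortex(1L, list(seq_len(n_syn)), cfg)
  state$src[[1L]] <- seq_len(n_syn)   # deterministic wiring for arithmetic
  state
}

# Feed a raw spike matrix through the reference engine step by step and
# apply end-of-window plasticity; returns state and per-slot layer-1 fires.
drive_window <- function(state, spikes) {
  fires <- integer(nrow(spikes))
  for (t in seq_len(nrow(spikes))) {
    st <- step_timeslot(state, spikes[t, ])
    state <- st$state
    fires[t] <- sum(st$fired[[1L]])
  }
  list(state = end_window_plasticity(state), l1_fires = fires)
}

# Profiles with planted correlation blocks: inputs inside a block share one
# propensity value in every category, so block members are maximally
# co-active; block boundaries define the ground-truth partition.
planted_profiles <- function(n_categories, n_blocks, n_inputs = 400L,
                             levels = c(30L, 190L)) {
  block_of <- rep(seq_len(n_blocks), length.out = n_inputs)
  block_of <- sort(block_of)
  prof <- matrix(0L, n_categories, n_inputs)
  for (cat in seq_len(n_categories)) {
    block_levels <- sample(levels, n_blocks, replace = TRUE)
    prof[cat, ] <- block_levels[block_of]
  }
  list(profiles = structure(prof, class = c("ra_profiles", "matrix", "array")),
       block_of = block_of)
}

# Render a small sample of triple presentations covering all categories.
render_sample <- function(profiles, n_pres, envelope = NULL) {
  n_cat <- nrow(profiles)
  if (is.null(envelope))
    envelope <- make_modulation_envelope(n_periods = 15L)
  lapply(seq_len(n_pres), function(p) {
    trip <- ((p + 0:2 - 1L) %% n_cat) + 1L
    render_presentation(profiles[trip, , drop = FALSE], envelope, trip)
  })
}

# Flatten an ra_groups object into a per-input group id vector.
group_assignment <- function(groups, n_inputs) {
  a <- integer(n_inputs)
  for (g in seq_along(groups$groups)) a[groups$groups[[g]]] <- g
  a
}

# Adjusted Rand index between two partitions (independent of the grouping
# code; used to score planted-partition recovery).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Small experiment configuration for orchestration tests: full model
# wiring but a short curriculum so a run takes a few seconds.
tiny_exp_config <- function(experiment = "one", seed = 1L, ...) {
  args <- list(experiment, n_columns = 4L, n_categories = 6L, seed = seed,
               n_warmup = 6L, n_teacher = 30L, n_test = 12L,
               n_feedback = 12L, n_relearn = 6L, n_bias_sample = 6L,
               stim = stim_config(n_periods = 15L))
  override <- list(...)
  args[names(override)] <- override
  do.call(ra_config, args)
}
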