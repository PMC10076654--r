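# Cortical integration and temporal-correlation plasticity.

test_that("initialisation builds the columnar topology", {
  set.seed(71)
  groups <- split(sample(1:400), rep(1:15, length.out = 400))
  ctx <- init_cortex(15L, groups, cortex_config())
  # 15 columns x (10 + 10 + 1) neurons
  expect_equal(sum(lengths(ctx$fires)), 315L)
  expect_length(ctx$src[[1L]], 15L * 10L * 10L * 120L)
  # about 1,200 synapses per layer-1 neuron
  expect_equal(length(ctx$src[[1L]]) / (15L * 10L), 1200L)
  # all weights start equal
  for (L in 1:3) expect_true(all(ctx$w[[L]] == ctx$cfg$w_init[L]))
  # within-column wiring for layers 2-3
  col_of_l2 <- rep(1:15, each = 10L * 10L)   # per synapse
  expect_true(all(ceiling(ctx$src[[2L]] / 10L) == col_of_l2))
  expect_error(init_cortex(2L, list(1:10), cortex_config()), "one bias group")
  expect_error(init_cortex(1L, list(integer(0L)), cortex_config()),
               "non-empty")
})

test_that("connectivity bias follows p_bias", {
  groups <- split(1:400, rep(1:4, each = 100L))
  set.seed(72)
  all_in <- init_cortex(4L, groups, cortex_config(p_bias = 1))
  per_col <- length(all_in$src[[1L]]) / 4L
  for (col in 1:4) {
    s <- all_in$src[[1L]][(col - 1L) * per_col + seq_len(per_col)]
    expect_true(all(s %in% groups[[col]]))
  }
  set.seed(73)
  unbiased <- init_cortex(1L, list(1:40), cortex_config(p_bias = 0))
  # sources approximately uniform over all 400 inputs
  counts <- tabulate(unbiased$src[[1L]], 400L)
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)
})

test_that("two-stage integration thresholds behave as specified", {
  state <- micro_cortex(n_syn = 2L, theta = 2)
  # both inputs spike: branch potential 2 >= 2, neuron fires
  st <- step_timeslot(state, c(1L, 1L))
  expect_equal(st$fired[[1L]], 1L)
  # one input: potential 1 < 2
  st <- step_timeslot(state, c(1L, 0L))
  expect_equal(st$fired[[1L]], 0L)
  # no input, or zero weights: silence
  st <- step_timeslot(state, c(0L, 0L))
  expect_equal(st$fired[[1L]], 0L)
  z <- micro_cortex(n_syn = 2L, theta = 2, w_init = 0)
  st <- step_timeslot(z, c(1L, 1L))
  expect_equal(st$fired[[1L]], 0L)
  expect_error(step_timeslot(state, c(1L, 1L, 1L)), "length")
})

test_that("signals propagate one layer per timeslot", {
  cfg <- cortex_config(n_inputs = 2L, neurons = c(1L, 1L, 1L),
                       branches = c(1L, 1L, 1L),
                       syn_per_branch = c(2L, 1L, 1L),
                       theta_branch = c(2, 1, 1), theta_neuron = c(1L, 1L, 1L),
                       p_bias = 0)
  set.seed(74)
  state <- init_cortex(1L, list(1:2), cfg)
  state$src[[1L]] <- 1:2
  fired <- list()
  for (t in 1:4) {
    st <- step_timeslot(state, c(1L, 1L))
    state <- st$state
    fired[[t]] <- vapply(st$fired, sum, integer(1L))
  }
  expect_equal(fired[[1L]], c(1L, 0L, 0L))  # layer 1 immediately
  expect_equal(fired[[2L]], c(1L, 1L, 0L))  # layer 2 one slot later
  expect_equal(fired[[3L]], c(1L, 1L, 1L))  # layer 3 after two slots
})

test_that("tentative potentiation reverses below three pairings", {
  # two pairings in the window: exact net-zero reversal
  state <- micro_cortex(n_syn = 2L, theta = 2, m_miss = 999L)
  w0 <- state$w[[1L]]
  spikes <- matrix(0L, 8L, 2L)
  spikes[c(1L, 5L), ] <- 1L                # neuron fires at slots 1 and 5
  res <- drive_window(state, spikes)
  expect_equal(sum(res$l1_fires), 2L)
  expect_identical(res$state$w[[1L]], w0)

  # three pairings: the increase becomes permanent, exactly +d_pot
  state <- micro_cortex(n_syn = 2L, theta = 2, m_miss = 999L, d_pot = 0.25)
  spikes <- matrix(0L, 8L, 2L)
  spikes[c(1L, 4L, 7L), ] <- 1L
  res <- drive_window(state, spikes)
  expect_equal(sum(res$l1_fires), 3L)
  expect_identical(res$state$w[[1L]], w0 + 0.25)

  # an input on the slot just before the fire also counts as a pairing
  state <- micro_cortex(n_syn = 3L, theta = 2, m_miss = 999L, d_pot = 0.25)
  spikes <- matrix(0L, 9L, 3L)
  spikes[c(2L, 5L, 8L), 1:2] <- 1L         # drive the neuron via synapses 1-2
  spikes[c(1L, 4L, 7L), 3L] <- 1L          # synapse 3 spikes one slot before
  res <- drive_window(state, spikes)
  expect_identical(res$state$w[[1L]], rep(1.25, 3L))
})

test_that("contribution misses depress synapses down to zero", {
  # synapse 3 never contributes while the branch fires m_miss times
  state <- micro_cortex(n_syn = 3L, theta = 2, m_miss = 3L,
                        d_dep = 0.25, d_pot = 0.25)
  spikes <- matrix(0L, 8L, 3L)
  spikes[c(1L, 4L, 7L), 1:2] <- 1L
  res <- drive_window(state, spikes)
  # synapses 1-2 potentiate (3 pairings), synapse 3 is depressed
  expect_identical(res$state$w[[1L]], c(1.25, 1.25, 0.75))

  # repeated windows floor the weight at zero
  state <- micro_cortex(n_syn = 3L, theta = 2, m_miss = 3L,
                        d_dep = 0.5, d_pot = 0)
  for (i in 1:4) {
    res <- drive_window(state, spikes)
    state <- res$state
  }
  expect_equal(state$w[[1L]][3L], 0)
  expect_true(all(state$w[[1L]] >= 0))
})

test_that("homeostatic scaling preserves weight ratios exactly", {
  state <- micro_cortex(n_syn = 3L, theta = 1, rho_max = 2L, d_pot = 0,
                        m_miss = 999L)
  state$w[[1L]] <- c(2, 4, 6)
  spikes <- matrix(1L, 5L, 3L)             # fires 5 > rho_max = 2
  res <- drive_window(state, spikes)
  expect_identical(res$state$w[[1L]], c(2, 4, 6) * 0.5)
  expect_identical(res$state$w[[1L]] / min(res$state$w[[1L]]), c(1, 2, 3))
})

test_that("mid-window plasticity calls are rejected", {
  state <- micro_cortex()
  expect_error(end_window_plasticity(state), "no timeslots")
  st <- step_timeslot(state, c(1L, 1L))
  expect_silent(end_window_plasticity(st$state))
})

test_that("compiled engine equals the per-synapse reference engine", {
  # dyadic parameters: branch-potential sums are exact in floating point,
  # so the two engines must agree bit for bit
  set.seed(75)
  pool <- make_level_pool()
  prof <- make_category_profiles(3L, pool)
  env <- make_modulation_envelope(9L)      # 72 timeslots
  groups <- split(1:400, rep(1:3, length.out = 400))
  set.seed(76)
  state_a <- init_cortex(3L, groups, dyadic_cortex_config())
  state_b <- state_a
  for (i in 1:3) {                         # several windows incl. plasticity
    pres <- render_presentation(prof, env)
    ra <- run_presentation(state_a, pres, engine = "cpp", record = TRUE)
    rb <- run_presentation(state_b, pres, engine = "r", record = TRUE)
    expect_identical(ra$counts, rb$counts)
    expect_identical(ra$state$w, rb$state$w)
    expect_identical(lapply(ra$rasters, unname), lapply(rb$rasters, unname))
    expect_identical(ra$l2_window_fires, rb$l2_window_fires)
    state_a <- ra$state
    state_b <- rb$state
  }
  expect_gt(sum(unlist(state_a$w[[1L]])), 0)
})

test_that("weights stay within bounds and change even during test phases", {
  set.seed(77)
  pool <- make_level_pool()
  prof <- make_category_profiles(3L, pool)
  env <- make_modulation_envelope(15L)
  groups <- split(1:400, rep(1:3, length.out = 400))
  set.seed(78)
  state <- init_cortex(3L, groups, cortex_config())
  w_before <- state$w
  for (i in 1:3) {
    pres <- render_presentation(prof, env)
    res <- run_presentation(state, pres)
    state <- res$state
    for (L in 1:3) {
      expect_true(all(state$w[[L]] >= 0))
      expect_true(all(state$w[[L]] <= state$cfg$w_max[L]))
    }
    # counts bounded by the timeslots available per segment
    expect_true(all(res$counts <= nrow(pres$spikes)))
  }
  # plasticity is always on: no feedback was involved, weights moved anyway
  expect_false(identical(w_before, state$w))
})

test_that("cortex checkpoints round-trip", {
  state <- micro_cortex()
  path <- tempfile(fileext = ".rds")
  save_cortex(state, path)
  expect_identical(load_cortex(path), state)
  saveRDS(list(format = "other"), path)
  expect_error(load_cortex(path), "checkpoint")
})
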