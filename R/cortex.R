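# Columnar three-layer cortex. Per column: 10 layer-1 neurons (10 branches x
# 120 synapses onto the 400 external inputs), 10 layer-2 neurons and one
# layer-3 neuron wired within the column. Integration is two-stage per
# timeslot (branch potential, then count of firing branches), with a
# one-timeslot transmission delay between layers. Plasticity is purely
# temporal-correlation driven: tentative potentiation that is reversed unless
# the input-before-fire pairing recurs at least `pair_min` times within the
# 200 ms window, contribution-miss depression, and homeostatic proportional
# scaling of neurons that fire too often. No consequence feedback ever
# touches these weights.

#' Cortex configuration
#'
#' All free constants of the cortical component. Layer-indexed arguments are
#' length-3 vectors `(layer 1, layer 2, layer 3)`. The defaults are the
#' package's frozen calibration (see the methods vignette).
#'
#' @param n_inputs Number of external input components (default 400).
#' @param neurons Neurons per column and layer (default `c(10, 10, 1)`).
#' @param branches Dendritic branches per neuron.
#' @param syn_per_branch Synapses per branch (layer 1 default `10 x 120`,
#'   about 1,200 synapses per layer-1 neuron).
#' @param theta_branch Branch firing threshold on the branch potential.
#' @param theta_neuron Neuron firing threshold on the count of firing
#'   branches.
#' @param w_init Initial synaptic weight (all synapses of a layer start
#'   equal).
#' @param w_max Weight ceiling.
#' @param d_pot Permanent potentiation per qualifying window.
#' @param d_dep Depression per window for contribution-missing synapses.
#' @param pair_min Minimum input-before-fire pairings within a window for a
#'   tentative potentiation to become permanent (default 3).
#' @param m_miss Branch-fires-without-contribution count at which a synapse
#'   is depressed.
#' @param rho_max Window firing count above which a neuron is
#'   homeostatically scaled.
#' @param s_homeo Homeostatic scaling factor (< 1), applied to all of the
#'   neuron's weights.
#' @param p_bias Probability that a layer-1 synapse source is drawn from the
#'   column's co-activation bias group rather than uniformly from all inputs.
#' @param l3_gate Minimum layer-2 fires per column and window before the
#'   column's layer-3 output is forwarded to the basal ganglia (0 disables
#'   the gate).
#' @return List of class `ra_cortex_config`.
#' @export
cortex_config <- function(n_inputs = 400L,
                          neurons = c(10L, 10L, 1L),
                          branches = c(10L, 2L, 2L),
                          syn_per_branch = c(120L, 5L, 5L),
                          theta_branch = c(40, 2, 2),
                          theta_neuron = c(3L, 2L, 2L),
                          w_init = c(1, 1, 1),
                          w_max = c(4, 4, 4),
                          d_pot = c(0.0625, 0.0625, 0.0625),
                          d_dep = c(0.0625, 0.0625, 0.0625),
                          pair_min = 3L,
                          m_miss = c(25L, 200L, 200L),
                          rho_max = c(90L, 60L, 10L),
                          s_homeo = c(0.875, 0.875, 0.875),
                          p_bias = 0.7,
                          l3_gate = 0L) {
  as3 <- function(x) {
    if (length(x) == 1L) rep(x, 3L) else {
      stopifnot(length(x) == 3L); x
    }
  }
  cfg <- list(n_inputs = as.integer(n_inputs),
              neurons = as.integer(as3(neurons)),
              branches = as.integer(as3(branches)),
              syn_per_branch = as.integer(as3(syn_per_branch)),
              theta_branch = as.numeric(as3(theta_branch)),
              theta_neuron = as.integer(as3(theta_neuron)),
              w_init = as.numeric(as3(w_init)),
              w_max = as.numeric(as3(w_max)),
              d_pot = as.numeric(as3(d_pot)),
              d_dep = as.numeric(as3(d_dep)),
              pair_min = as.integer(pair_min),
              m_miss = as.integer(as3(m_miss)),
              rho_max = as.integer(as3(rho_max)),
              s_homeo = as.numeric(as3(s_homeo)),
              p_bias = as.numeric(p_bias),
              l3_gate = as.integer(l3_gate))
  if (cfg$n_inputs < 1 || any(cfg$neurons < 1) || any(cfg$branches < 1) ||
      any(cfg$syn_per_branch < 1))
    stop("cortex topology counts must be positive")
  if (cfg$p_bias < 0 || cfg$p_bias > 1) stop("`p_bias` must lie in [0, 1]")
  if (any(cfg$s_homeo <= 0 | cfg$s_homeo >= 1))
    stop("`s_homeo` must lie in (0, 1)")
  if (any(cfg$w_init < 0) || any(cfg$w_max < cfg$w_init))
    stop("weights must satisfy 0 <= w_init <= w_max")
  structure(cfg, class = "ra_cortex_config")
}

#' Initialise a cortex
#'
#' Builds the immutable wiring and the initial synaptic state. Layer-1
#' synapse sources are drawn with probability `p_bias` from the column's
#' co-activation bias group and uniformly from all inputs otherwise; layers
#' 2 and 3 are wired within the column, covering the previous layer's
#' neurons evenly. All weights of a layer start at `w_init`. Uses the
#' current R random stream.
#'
#' @param n_columns Number of cortical columns.
#' @param bias_groups An `ra_groups` object or a list of `n_columns` input
#'   index groups.
#' @param cfg A [cortex_config()].
#' @return Object of class `ra_cortex` holding wiring (`src`, global source
#'   indices per layer), weights (`w`), within-window plasticity counters,
#'   firing history and the window clock.
#' @export
init_cortex <- function(n_columns, bias_groups, cfg = cortex_config()) {
  stopifnot(n_columns >= 1)
  groups <- if (inherits(bias_groups, "ra_groups")) bias_groups$groups
            else bias_groups
  if (length(groups) != n_columns)
    stop("need exactly one bias group per column")
  if (any(lengths(groups) == 0L)) stop("bias groups must be non-empty")
  nn <- cfg$neurons * n_columns          # neurons per layer, total
  syn_per_neuron <- cfg$branches * cfg$syn_per_branch
  src <- vector("list", 3L)
  # layer 1: external input sources, bias-weighted
  per_col <- cfg$neurons[1L] * syn_per_neuron[1L]
  s1 <- integer(n_columns * per_col)
  for (col in seq_len(n_columns)) {
    g <- groups[[col]]
    if (any(g < 1L | g > cfg$n_inputs)) stop("bias group index out of range")
    use_bias <- if (cfg$p_bias >= 1) rep(TRUE, per_col)
                else if (cfg$p_bias <= 0) rep(FALSE, per_col)
                else stats::runif(per_col) < cfg$p_bias
    v <- integer(per_col)
    v[use_bias] <- g[sample.int(length(g), sum(use_bias), replace = TRUE)]
    v[!use_bias] <- sample.int(cfg$n_inputs, sum(!use_bias), replace = TRUE)
    s1[(col - 1L) * per_col + seq_len(per_col)] <- v
  }
  src[[1L]] <- s1
  # layers 2-3: within-column sources into the previous layer (global ids)
  for (L in 2:3) {
    n_prev <- cfg$neurons[L - 1L]
    spn <- syn_per_neuron[L]
    s <- integer(nn[L] * spn)
    for (col in seq_len(n_columns)) {
      base_prev <- (col - 1L) * n_prev
      for (ni in seq_len(cfg$neurons[L])) {
        pick <- if (spn == n_prev) sample.int(n_prev)   # exact cover
                else sample.int(n_prev, spn, replace = spn > n_prev)
        at <- ((col - 1L) * cfg$neurons[L] + ni - 1L) * spn
        s[at + seq_len(spn)] <- base_prev + pick
      }
    }
    src[[L]] <- s
  }
  w <- lapply(1:3, function(L) rep(cfg$w_init[L], length(src[[L]])))
  zeros_syn <- lapply(src, function(x) integer(length(x)))
  structure(list(cfg = cfg, n_columns = as.integer(n_columns),
                 groups = groups, src = src, w = w,
                 pair = zeros_syn, miss = zeros_syn,
                 fires = lapply(nn, integer),
                 hist = empty_hist(cfg, n_columns),
                 clock = 0L, window_len = NA_integer_),
            class = "ra_cortex")
}

empty_hist <- function(cfg, n_columns) {
  nn <- cfg$neurons * n_columns
  list(x_prev = integer(cfg$n_inputs),
       y1_prev1 = integer(nn[1L]), y1_prev2 = integer(nn[1L]),
       y2_prev1 = integer(nn[2L]), y2_prev2 = integer(nn[2L]))
}

#' Advance the cortex by one timeslot (reference engine)
#'
#' Straightforward per-branch/per-synapse implementation of one integration
#' step: branch potential = sum of weight x source spike, branch fires at
#' `theta_branch`, neuron fires when at least `theta_neuron` branches fire.
#' Layer L at timeslot t integrates layer L-1 fires of timeslot t-1.
#' Updates the within-window plasticity counters (pairings, contribution
#' misses, firing counts). This engine is the slow, transparent counterpart
#' of the compiled window engine and serves as its oracle in the tests.
#'
#' @param state An `ra_cortex`.
#' @param input_spikes Length-`n_inputs` 0/1 vector.
#' @return List with the updated `state` and `fired`, a list of per-layer
#'   0/1 firing vectors for this timeslot.
#' @export
step_timeslot <- function(state, input_spikes) {
  cfg <- state$cfg
  x <- as.integer(input_spikes)
  if (length(x) != cfg$n_inputs) stop("input vector has wrong length")
  inputs_now <- list(x, state$hist$y1_prev1, state$hist$y2_prev1)
  inputs_before <- list(state$hist$x_prev, state$hist$y1_prev2,
                        state$hist$y2_prev2)
  fired <- vector("list", 3L)
  for (L in 1:3) {
    nb <- cfg$branches[L]; ns <- cfg$syn_per_branch[L]
    n_neurons <- cfg$neurons[L] * state$n_columns
    spn <- nb * ns
    xin <- inputs_now[[L]]
    xbefore <- inputs_before[[L]]
    src <- state$src[[L]]; w <- state$w[[L]]
    y <- integer(n_neurons)
    for (ni in seq_len(n_neurons)) {
      base <- (ni - 1L) * spn
      n_fired_branches <- 0L
      for (bi in seq_len(nb)) {
        idx <- base + (bi - 1L) * ns + seq_len(ns)
        sx <- xin[src[idx]]
        if (sum(w[idx] * sx) >= cfg$theta_branch[L]) {
          n_fired_branches <- n_fired_branches + 1L
          mi <- idx[sx == 0L]
          state$miss[[L]][mi] <- state$miss[[L]][mi] + 1L
        }
      }
      if (n_fired_branches >= cfg$theta_neuron[L]) {
        y[ni] <- 1L
        state$fires[[L]][ni] <- state$fires[[L]][ni] + 1L
        idx <- base + seq_len(spn)
        paired <- idx[xin[src[idx]] == 1L | xbefore[src[idx]] == 1L]
        state$pair[[L]][paired] <- state$pair[[L]][paired] + 1L
      }
    }
    fired[[L]] <- y
  }
  state$hist$x_prev <- x
  state$hist$y1_prev2 <- state$hist$y1_prev1
  state$hist$y1_prev1 <- fired[[1L]]
  state$hist$y2_prev2 <- state$hist$y2_prev1
  state$hist$y2_prev1 <- fired[[2L]]
  state$clock <- state$clock + 1L
  list(state = state, fired = fired)
}

#' Apply end-of-window plasticity
#'
#' At the end of a 200 ms presentation window, in order: (a) tentative
#' potentiations with at least `pair_min` input-before-fire pairings become
#' permanent (`+d_pot`, capped at `w_max`); all others are reversed, i.e.
#' the weight stays at its window-start value; (b) synapses whose branch
#' fired at least `m_miss` times without their contribution are depressed
#' by `d_dep`, floored at 0; (c) neurons that fired more than `rho_max`
#' times have all synaptic weights scaled by `s_homeo`, preserving their
#' ratios. Counters, clock and firing history are then reset.
#'
#' @param state An `ra_cortex` at the end of a window.
#' @return The updated `ra_cortex`.
#' @export
end_window_plasticity <- function(state) {
  cfg <- state$cfg
  if (state$clock == 0L)
    stop("no timeslots have been stepped in the current window")
  if (!is.na(state$window_len) && state$clock < state$window_len)
    stop("end_window_plasticity called mid-window")
  for (L in 1:3) {
    w <- state$w[[L]]
    w <- w + cfg$d_pot[L] * (state$pair[[L]] >= cfg$pair_min)
    w <- pmin(w, cfg$w_max[L])
    w <- w - cfg$d_dep[L] * (state$miss[[L]] >= cfg$m_miss[L])
    w <- pmax(w, 0)
    over <- which(state$fires[[L]] > cfg$rho_max[L])
    if (length(over)) {
      spn <- cfg$branches[L] * cfg$syn_per_branch[L]
      for (ni in over) {
        idx <- (ni - 1L) * spn + seq_len(spn)
        w[idx] <- w[idx] * cfg$s_homeo[L]
      }
    }
    state$w[[L]] <- w
    state$pair[[L]][] <- 0L
    state$miss[[L]][] <- 0L
    state$fires[[L]][] <- 0L
  }
  state$hist <- empty_hist(cfg, state$n_columns)
  state$clock <- 0L
  state$window_len <- NA_integer_
  state
}

#' Run one presentation through the cortex
#'
#' Steps every timeslot of the presentation, applies end-of-window
#' plasticity once, and returns the layer-3 spike counts per column,
#' accumulated separately for each working-memory segment so the basal
#' ganglia can decide each category separately. A layer-3 fire at timeslot
#' t is attributed to the segment of timeslot t-2, the input timeslot it
#' derives from through the two interlayer delays.
#'
#' @param state An `ra_cortex`.
#' @param pres An `ra_presentation`.
#' @param engine `"cpp"` (compiled window engine, default) or `"r"`
#'   (reference per-synapse engine).
#' @param record If `TRUE`, also return per-layer firing rasters
#'   (`timeslots x neurons`).
#' @return List: updated `state`, integer `counts` matrix
#'   (`n_columns x n_segments`), `l2_window_fires` per column, and
#'   optionally `rasters`.
#' @export
run_presentation <- function(state, pres, engine = c("cpp", "r"),
                             record = FALSE) {
  engine <- match.arg(engine)
  stopifnot(inherits(state, "ra_cortex"), inherits(pres, "ra_presentation"))
  cfg <- state$cfg
  if (ncol(pres$spikes) != cfg$n_inputs)
    stop("presentation width does not match cortex input count")
  n_slots <- nrow(pres$spikes)
  n_seg <- max(pres$segments)
  if (engine == "cpp") {
    res <- cortex_window_cpp(
      state$n_columns, cfg$n_inputs, cfg$neurons, cfg$branches,
      cfg$syn_per_branch, cfg$theta_branch, cfg$theta_neuron,
      cfg$d_pot, cfg$d_dep, cfg$pair_min, cfg$m_miss, cfg$rho_max,
      cfg$s_homeo, cfg$w_max,
      state$src, state$w,
      t(pres$spikes), as.integer(pres$segments), n_seg, record)
    state$w <- res$w
    counts <- res$counts
    l2f <- res$fires[[2L]]
    rasters <- if (record) res$rasters else NULL
  } else {
    state$window_len <- n_slots
    counts <- matrix(0L, state$n_columns, n_seg)
    rasters <- if (record)
      lapply(cfg$neurons * state$n_columns,
             function(n) matrix(0L, n_slots, n)) else NULL
    l2f <- NULL
    for (t in seq_len(n_slots)) {
      st <- step_timeslot(state, pres$spikes[t, ])
      state <- st$state
      if (record)
        for (L in 1:3) rasters[[L]][t, ] <- st$fired[[L]]
      f3 <- st$fired[[3L]]
      if (any(f3 == 1L)) {
        seg <- pres$segments[max(t - 2L, 1L)]
        per_col <- colSums(matrix(f3, nrow = cfg$neurons[3L]))
        counts[, seg] <- counts[, seg] + as.integer(per_col)
      }
    }
    l2f <- colSums(matrix(state$fires[[2L]], nrow = cfg$neurons[2L]))
    state <- end_window_plasticity(state)
  }
  if (engine == "cpp")
    l2f <- colSums(matrix(l2f, nrow = cfg$neurons[2L]))
  if (cfg$l3_gate > 0L)
    counts[l2f < cfg$l3_gate, ] <- 0L
  out <- list(state = state, counts = counts, l2_window_fires = l2f)
  if (record) out$rasters <- rasters
  out
}

#' Save / load a cortex checkpoint
#'
#' Checkpoints let one cortex run be replayed against different
#' basal-ganglia settings. The file is an RDS container with a version tag.
#'
#' @param state An `ra_cortex`.
#' @param path File path.
#' @return `save_cortex` returns `path` invisibly; `load_cortex` returns
#'   the `ra_cortex`.
#' @export
save_cortex <- function(state, path) {
  stopifnot(inherits(state, "ra_cortex"))
  saveRDS(list(format = "rasim-cortex", version = 1L, state = state), path)
  invisible(path)
}

#' @rdname save_cortex
#' @export
load_cortex <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "rasim-cortex"))
    stop("not a rasim cortex checkpoint")
  obj$state
}
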