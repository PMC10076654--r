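# Experiment orchestration: build stimuli, derive the hippocampal bias,
# initialise cortex and basal ganglia, and drive the curriculum. Cortical
# plasticity runs continuously through every phase, including tests; only
# the basal-ganglia updates depend on the phase.

# Derive independent child seeds from the master seed so that profiles,
# the bias sample, wiring and presentation draws come from separable
# streams (a cortex run can then be replayed against different
# basal-ganglia settings).
derive_seeds <- function(seed) {
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 4L)
  names(s) <- c("profiles", "bias", "wiring", "presentations")
  s
}

# Shared setup: profiles, bias groups, cortex, weights, envelope.
setup_model <- function(cfg) {
  seeds <- derive_seeds(cfg$seed)
  set.seed(seeds[["profiles"]])
  pool <- make_level_pool(cfg$stim$max_level, cfg$stim$max_repeat)
  profiles <- make_category_profiles(cfg$n_categories, pool,
                                     cfg$stim$n_inputs)
  envelope <- make_modulation_envelope(cfg$stim$n_periods,
                                       cfg$stim$period_timeslots,
                                       cfg$stim$f_hi, cfg$stim$f_lo,
                                       cfg$stim$max_level)
  # unprocessed sample across all categories for the connectivity bias
  set.seed(seeds[["bias"]])
  lead <- rep_len(seq_len(cfg$n_categories), cfg$n_bias_sample)
  sample_pres <- lapply(lead, function(c1) {
    trip <- ((c(c1, c1 + 1L, c1 + 2L) - 1L) %% cfg$n_categories) + 1L
    render_presentation(profiles[trip, , drop = FALSE], envelope, trip)
  })
  groups <- derive_coactivation_groups(sample_pres, cfg$n_columns)
  set.seed(seeds[["wiring"]])
  cortex <- init_cortex(cfg$n_columns, groups, cfg$cortex)
  weights <- init_weights(cfg$n_columns, cfg$n_categories, cfg$w0)
  set.seed(seeds[["presentations"]])
  list(pool = pool, profiles = profiles, envelope = envelope,
       groups = groups, cortex = cortex, weights = weights, seeds = seeds)
}

# Drive one curriculum through the model. Returns the updated model, the
# full decision log and per-presentation layer-3 count totals.
run_curriculum <- function(model, cur, cfg, progress = FALSE) {
  n_pres <- nrow(cur)
  logs <- vector("list", n_pres)
  cortex <- model$cortex
  weights <- model$weights
  for (p in seq_len(n_pres)) {
    trip <- c(cur$c1[p], cur$c2[p], cur$c3[p])
    pres <- render_presentation(model$profiles[trip, , drop = FALSE],
                                model$envelope, trip)
    res <- run_presentation(cortex, pres)
    cortex <- res$state
    phase <- cur$phase[p]
    if (phase != "cortex_only") {
      rows <- vector("list", length(trip))
      for (s in seq_along(trip)) {
        label <- trip[s]
        d <- decide(weights, res$counts[, s])
        if (phase == "teacher") {
          weights <- learn_teacher(weights, res$counts[, s], d, label,
                                   cfg$alpha_up, cfg$delta_down, cfg$w_cap)
        } else if (phase == "feedback_only") {
          weights <- learn_feedback_only(weights, res$counts[, s], d,
                                         d$chosen == label,
                                         cfg$delta_feedback,
                                         cfg$correct_boost)
        }
        rows[[s]] <- data.frame(
          presentation = p, slot = s, phase = phase, stage = cur$stage[p],
          label = label, chosen = d$chosen,
          rank_of_true = match(label, d$ranking),
          total_spikes = sum(res$counts[, s]))
      }
      logs[[p]] <- do.call(rbind, rows)
    }
    if (progress && p %% 100L == 0L)
      message(sprintf("  presentation %d / %d", p, n_pres))
  }
  log <- do.call(rbind, logs[!vapply(logs, is.null, logical(1L))])
  attr(log, "n_categories") <- cfg$n_categories
  model$cortex <- cortex
  model$weights <- weights
  list(model = model, log = log)
}

subset_log <- function(log, stage_name) {
  out <- log[log$stage == stage_name, , drop = FALSE]
  attr(out, "n_categories") <- attr(log, "n_categories")
  out
}

#' Run experiment one (novelty learning)
#'
#' The full 30-category novelty run: `n_warmup` presentations of
#' cortex-only plasticity, `n_teacher` presentations with teacher-signal
#' learning in the basal ganglia, and `n_test` test presentations in which
#' decisions are recorded without weight updates while cortical plasticity
#' continues. Metrics are computed over the test phase.
#'
#' @param cfg An [ra_config()] with `experiment = "one"`.
#' @param progress Print progress messages.
#' @return Object of class `ra_metrics`: test-phase top-1/2/3 accuracies,
#'   a teacher-phase learning curve, the decision log, the final
#'   recommendation matrix and the configuration.
#' @export
run_experiment_one <- function(cfg = ra_config("one"), progress = FALSE) {
  stopifnot(inherits(cfg, "ra_config"))
  if (cfg$experiment != "one") stop("`cfg$experiment` must be \"one\"")
  model <- setup_model(cfg)
  cur <- build_curriculum("one", cfg$n_categories, cfg$n_warmup,
                          cfg$n_teacher, cfg$n_test)
  res <- run_curriculum(model, cur, cfg, progress)
  test_log <- subset_log(res$log, "test")
  train_log <- subset_log(res$log, "train")
  structure(list(experiment = "one",
                 accuracy = stage_metrics(test_log)$overall,
                 curve = learning_curve(train_log),
                 log = res$log,
                 weights = res$model$weights,
                 groups = res$model$groups,
                 cfg = cfg, config_hash = config_hash(cfg)),
            class = "ra_metrics")
}

#' Run experiment two (split training, interference, recovery)
#'
#' Teacher-trains the first half of the categories, then the second half,
#' then tests all categories without weight updates (`after_split`).
#' Optionally follows with a correct/incorrect-only feedback pass of
#' `n_feedback` presentations and a retest (`after_feedback`), and a short
#' teacher relearn pass and retest (`after_relearn`). Cortical plasticity
#' runs continuously throughout.
#'
#' @param cfg An [ra_config()] with `experiment = "two"`.
#' @param progress Print progress messages.
#' @return Object of class `ra_metrics` with per-stage overall and per-set
#'   top-1/2/3 accuracies and set-balance ratios.
#' @export
run_experiment_two <- function(cfg = ra_config("two"), progress = FALSE) {
  stopifnot(inherits(cfg, "ra_config"))
  if (cfg$experiment != "two") stop("`cfg$experiment` must be \"two\"")
  model <- setup_model(cfg)
  cur <- build_curriculum("two", cfg$n_categories, cfg$n_warmup,
                          cfg$n_teacher, cfg$n_test, cfg$n_feedback,
                          cfg$n_relearn, cfg$include_feedback_pass,
                          cfg$include_relearn)
  res <- run_curriculum(model, cur, cfg, progress)
  set_a <- seq_len(cfg$n_categories %/% 2L)
  stage_names <- intersect(c("after_split", "after_feedback",
                             "after_relearn"), unique(res$log$stage))
  stages <- lapply(stage_names, function(sn)
    stage_metrics(subset_log(res$log, sn), set_a = set_a))
  names(stages) <- stage_names
  structure(list(experiment = "two",
                 stages = stages,
                 log = res$log,
                 weights = res$model$weights,
                 groups = res$model$groups,
                 cfg = cfg, config_hash = config_hash(cfg)),
            class = "ra_metrics")
}

# Rolling top-1 accuracy over the teacher phase (window of 90 decisions).
learning_curve <- function(train_log, window = 90L) {
  hit <- as.integer(train_log$rank_of_true == 1L)
  n <- length(hit)
  if (n == 0L) return(data.frame(decision = integer(), top1 = numeric()))
  if (n < window) window <- n
  cs <- cumsum(hit)
  at <- seq(window, n, by = window %/% 3L + 1L)
  before <- at - window
  cs_before <- ifelse(before >= 1L, cs[pmax(before, 1L)], 0)
  data.frame(decision = at, top1 = (cs[at] - cs_before) / window)
}

#' @export
print.ra_metrics <- function(x, ...) {
  cat("rasim metrics (experiment", x$experiment, ")\n")
  if (x$experiment == "one") {
    cat(sprintf("  test accuracy: top-1 %.3f  top-2 %.3f  top-3 %.3f\n",
                x$accuracy[["top1"]], x$accuracy[["top2"]],
                x$accuracy[["top3"]]))
  } else {
    for (sn in names(x$stages)) {
      st <- x$stages[[sn]]
      cat(sprintf(
        "  %-15s top-1 %.3f top-3 %.3f | set A top-1 %.3f | set B top-1 %.3f | ratio %.2f\n",
        sn, st$overall[["top1"]], st$overall[["top3"]],
        st$set_a[["top1"]], st$set_b[["top1"]], st$set_balance_ratio))
    }
  }
  invisible(x)
}
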