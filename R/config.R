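# Experiment configuration.

#' Stimulus configuration
#'
#' @param n_inputs Input components per timeslot (default 400).
#' @param max_level,max_repeat Level-pool parameters (see
#'   [make_level_pool()]).
#' @param period_timeslots Timeslots per gamma period (default 8,
#'   one 40 Hz cycle at 1/3 ms resolution).
#' @param n_periods Gamma periods per presentation (default 75; 600
#'   timeslots = 200 ms).
#' @param f_hi,f_lo Modulation factors (see [make_modulation_envelope()]).
#' @return List of class `ra_stim_config`.
#' @export
stim_config <- function(n_inputs = 400L, max_level = 200L, max_repeat = 5L,
                        period_timeslots = 8L, n_periods = 75L,
                        f_hi = 50, f_lo = 5) {
  structure(list(n_inputs = as.integer(n_inputs),
                 max_level = as.integer(max_level),
                 max_repeat = as.integer(max_repeat),
                 period_timeslots = as.integer(period_timeslots),
                 n_periods = as.integer(n_periods),
                 f_hi = f_hi, f_lo = f_lo),
            class = "ra_stim_config")
}

#' Experiment configuration
#'
#' Bundles every tunable of a simulation run. Defaults reproduce the
#' 15-column novelty-learning run; see the methods vignette for what each
#' constant means and how the defaults were chosen.
#'
#' @param experiment `"one"` (novelty learning) or `"two"`
#'   (split-training interference and recovery).
#' @param n_columns Number of cortical columns.
#' @param n_categories Number of categories (default 30).
#' @param seed Master seed; child streams for profiles, the bias sample,
#'   wiring and presentation draws are derived from it so a cortex run can
#'   be replayed against different basal-ganglia settings.
#' @param n_warmup,n_teacher,n_test,n_feedback,n_relearn Phase lengths in
#'   presentations (see [build_curriculum()]).
#' @param include_feedback_pass,include_relearn Experiment-two recovery
#'   stages.
#' @param alpha_up Teacher increment rate per spike.
#' @param delta_down Proportional punishment of an incorrectly chosen
#'   category under teacher feedback. Kept small: repeated one-sided
#'   punishment of earlier-learned categories during later learning is the
#'   main mechanism of catastrophic interference in this readout.
#' @param delta_feedback Proportional punishment used by the
#'   correct/incorrect-only recovery pass.
#' @param w_cap Saturation ceiling on recommendation weights (see
#'   [learn_teacher()]).
#' @param w0 Initial recommendation weight.
#' @param correct_boost Optional boost on correct-only feedback (default 0).
#' @param n_bias_sample Presentations in the unprocessed sample used to
#'   derive the hippocampal co-activation groups.
#' @param cortex A [cortex_config()].
#' @param stim A [stim_config()].
#' @return List of class `ra_config`.
#' @export
ra_config <- function(experiment = c("one", "two"),
                      n_columns = 15L, n_categories = 30L, seed = 1L,
                      n_warmup = 300L, n_teacher = 600L, n_test = 300L,
                      n_feedback = 300L, n_relearn = 30L,
                      include_feedback_pass = TRUE, include_relearn = TRUE,
                      alpha_up = 0.02, delta_down = 0.0015,
                      delta_feedback = 0.375, w_cap = Inf, w0 = 1,
                      correct_boost = 0,
                      n_bias_sample = 30L,
                      cortex = cortex_config(),
                      stim = stim_config()) {
  experiment <- match.arg(experiment)
  stopifnot(n_columns >= 1, n_categories >= 2)
  if (n_teacher < 0 || n_test < 1 || n_warmup < 0)
    stop("phase counts are inconsistent")
  if (stim$n_inputs != cortex$n_inputs)
    stop("stimulus and cortex input counts disagree")
  structure(list(experiment = experiment,
                 n_columns = as.integer(n_columns),
                 n_categories = as.integer(n_categories),
                 seed = as.integer(seed),
                 n_warmup = as.integer(n_warmup),
                 n_teacher = as.integer(n_teacher),
                 n_test = as.integer(n_test),
                 n_feedback = as.integer(n_feedback),
                 n_relearn = as.integer(n_relearn),
                 include_feedback_pass = isTRUE(include_feedback_pass),
                 include_relearn = isTRUE(include_relearn),
                 alpha_up = alpha_up, delta_down = delta_down,
                 delta_feedback = delta_feedback, w_cap = w_cap, w0 = w0,
                 correct_boost = correct_boost,
                 n_bias_sample = as.integer(n_bias_sample),
                 cortex = cortex, stim = stim),
            class = "ra_config")
}

# Stable config hash (FNV-1a over the serialised JSON), recorded in outputs.
config_hash <- function(cfg) {
  txt <- jsonlite::toJSON(unclass_deep(cfg), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(txt))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30), as.integer(b))
    # keep arithmetic in double to avoid integer overflow
    h <- (abs(h) * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}
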