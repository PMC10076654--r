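# Result export: CSV summary, JSONL decision log, learning curve and a
# config snapshot, each carrying the config hash.

#' Write experiment results to disk
#'
#' Writes `summary.csv` (per-stage top-1/2/3 accuracies and, for the split
#' experiment, per-set accuracies and the set-balance ratio),
#' `decisions.jsonl` (one JSON object per decision), `curve.csv` (the
#' teacher-phase learning curve, experiment one) and `config.json`. Every
#' file records the configuration hash so reruns can be matched to their
#' settings.
#'
#' @param metrics An `ra_metrics` from [run_experiment_one()] or
#'   [run_experiment_two()].
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_results <- function(metrics, dir) {
  stopifnot(inherits(metrics, "ra_metrics"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  h <- metrics$config_hash
  if (metrics$experiment == "one") {
    summary_df <- data.frame(config_hash = h, stage = "test",
                             acc_top1 = metrics$accuracy[["top1"]],
                             acc_top2 = metrics$accuracy[["top2"]],
                             acc_top3 = metrics$accuracy[["top3"]])
    curve <- metrics$curve
    curve$config_hash <- h
    utils::write.csv(curve, file.path(dir, "curve.csv"), row.names = FALSE)
  } else {
    summary_df <- do.call(rbind, lapply(names(metrics$stages), function(sn) {
      st <- metrics$stages[[sn]]
      data.frame(config_hash = h, stage = sn,
                 acc_top1 = st$overall[["top1"]],
                 acc_top2 = st$overall[["top2"]],
                 acc_top3 = st$overall[["top3"]],
                 set_a_top1 = st$set_a[["top1"]],
                 set_a_top3 = st$set_a[["top3"]],
                 set_b_top1 = st$set_b[["top1"]],
                 set_b_top3 = st$set_b[["top3"]],
                 set_balance_ratio = st$set_balance_ratio)
    }))
  }
  utils::write.csv(summary_df, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  log <- metrics$log
  log$config_hash <- h
  con <- file(file.path(dir, "decisions.jsonl"), open = "w")
  on.exit(close(con))
  jsonlite::stream_out(log, con, verbose = FALSE)
  jsonlite::write_json(c(list(config_hash = h),
                         unclass_deep(metrics$cfg)),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
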