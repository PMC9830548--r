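#' Run the full quantification pipeline on one record
#'
#' Preprocess (filter, artifact-mask, resample to the analysis rate),
#' stage, detect SWD/SSWD/spindles, and summarise state and incidence
#' metrics.
#'
#' @param record raw [signal_record()].
#' @param config a [swd_config()].
#' @return list of class `swd_pipeline_result`: `record` (preprocessed),
#'   `hypnogram`, `events`, `state_metrics`, `incidence` (per-state SWD
#'   metrics tibble), `spindle_density_hz`.
#' @export
run_pipeline <- function(record, config = swd_config()) {
  pre <- preprocess_record(record, config)
  hyp <- stage_record(pre, config)
  ev <- detect_events(pre, hyp, config)
  sm <- summarize_states(hyp)
  inc <- incidence_metrics(ev, sm)
  sdens <- if (sm$durations$seconds[sm$durations$state == "NREM"] > 0)
    spindle_density(ev, sm) else NA_real_
  structure(list(record = pre, hypnogram = hyp, events = ev,
                 state_metrics = sm, incidence = inc,
                 spindle_density_hz = sdens),
            class = "swd_pipeline_result")
}

#' @export
print.swd_pipeline_result <- function(x, ...) {
  cat("<swd_pipeline_result>\n")
  print(x$hypnogram)
  cat(sprintf("%d event(s); spindle density %.4g Hz\n",
              nrow(x$events), x$spindle_density_hz))
  print(x$incidence)
  invisible(x)
}

#' Per-animal metric row from a pipeline result
#'
#' Flattens a pipeline result into the one-row-per-animal shape used by
#' [cohort_report()].
#'
#' @param res a `swd_pipeline_result`.
#' @param states states to report SWD incidence for.
#' @return one-row tibble of metrics (NREM/REM/wake SWD rates, durations,
#'   percentages, spindle density).
#' @export
animal_metrics_row <- function(res, states = c("NREM", "REM", "wake")) {
  inc <- res$incidence
  out <- tibble(.rows = 1)
  for (st in states) {
    r <- inc[inc$state == st, ]
    out[[paste0("swd_per_hr_", st)]] <- r$events_per_hr
    out[[paste0("swd_dur_s_per_hr_", st)]] <- r$event_dur_s_per_hr
    out[[paste0("swd_pct_", st)]] <- r$event_pct_of_state
    out[[paste0("duration_h_", st)]] <- r$duration_h
  }
  out$spindle_density_hz <- res$spindle_density_hz
  out
}
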