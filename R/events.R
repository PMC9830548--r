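## Spike-wave discharge (SWD 6-12 Hz, SSWD 3-6 Hz) and sleep-spindle
## (10-15 Hz) detection.
##
## Amplitude is the analytic-signal envelope of the band-passed channel.
## Detection thresholds are multiples of a state-conditioned baseline:
## during wake/REM the baseline is the median broadband (0.5-30 Hz)
## envelope of the preceding event-free seconds; during NREM, because
## delta amplitude is itself large, the baseline is the median delta-band
## (0.5-4 Hz) envelope and the multiplier drops from 2.0 to 1.5.

## per-second median envelope track (n_sec values, 0-based seconds)
sec_median_track <- function(env, rate, n_sec) {
  apply(matrix(env[seq_len(n_sec * rate)], nrow = rate), 2, median)
}

## seconds (0-based logical vector) that overlap any interval in `iv`;
## accepts either start_s/end_s or onset_s/offset_s columns
sec_overlap_flags <- function(iv, n_sec) {
  f <- logical(n_sec)
  if (is.null(iv) || nrow(iv) == 0) return(f)
  if (!"start_s" %in% names(iv))
    iv <- tibble(start_s = iv$onset_s, end_s = iv$offset_s)
  for (i in seq_len(nrow(iv))) {
    a <- max(0L, floor(iv$start_s[i]))
    b <- min(n_sec - 1L, ceiling(iv$end_s[i]) - 1L)
    if (b >= a) f[(a:b) + 1L] <- TRUE
  }
  f
}

## Baseline value for every second: median of per-second median envelopes
## over the same-state, event-free, artifact-free seconds in the preceding
## `window_s` seconds, expanding the lookback to `max_window_s` when
## needed. NA when no eligible second exists within the maximum lookback.
baseline_per_second <- function(sec_med, sec_state, eligible, window_s,
                                max_window_s) {
  n <- length(sec_med)
  out <- rep(NA_real_, n)
  for (s in seq_len(n)) {
    w <- window_s
    repeat {
      lo <- max(1L, s - w)
      idx <- lo:(s - 1L)
      idx <- if (s == 1L) integer(0) else
        idx[eligible[idx] & sec_state[idx] == sec_state[s]]
      if (length(idx) >= min(window_s, s - 1L) || w >= max_window_s) break
      w <- min(max_window_s, w * 2L)
    }
    if (length(idx)) out[s] <- median(sec_med[idx])
  }
  out
}

#' Estimate the pre-event baseline amplitude at a time point
#'
#' For wake/REM comparisons the baseline is the median analytic-signal
#' envelope of the broadband (0.5-30 Hz) signal over the lookback; for NREM
#' it is the median envelope of the delta-band (0.5-4 Hz) signal. The
#' lookback uses only seconds in the same vigilance state that are free of
#' artifacts and previously detected events, expanding from `window_s` up
#' to `max_window_s` when too few are eligible.
#'
#' @param signal one channel at the analysis rate.
#' @param rate sampling rate in Hz.
#' @param t time point in seconds.
#' @param hyp the record's [hypnogram].
#' @param events tibble of previously detected events to exclude (or NULL).
#' @param artifacts artifact intervals tibble (or NULL).
#' @param window_s,max_window_s lookback and maximum lookback in seconds.
#' @return list of class `baseline_estimate` with `value`, `window_s`,
#'   `band`, `state`, `n_seconds`; or NULL when no eligible baseline window
#'   exists within `max_window_s` (the candidate is then rejected).
#' @export
estimate_baseline <- function(signal, rate, t, hyp, events = NULL,
                              artifacts = NULL, window_s = 10,
                              max_window_s = 60) {
  st <- state_at(hyp, t)
  band <- if (st == "NREM") c(0.5, 4) else c(0.5, 30)
  n_sec <- floor(length(signal) / rate)
  env <- band_envelope(signal, rate, band[1], band[2])
  sec_med <- sec_median_track(env, rate, n_sec)
  sec_state <- hyp$sub$state[seq_len(n_sec)]
  busy <- sec_overlap_flags(events, n_sec) | sec_overlap_flags(artifacts, n_sec)
  s <- floor(t) + 1L
  w <- window_s
  idx <- integer(0)
  repeat {
    lo <- max(1L, s - as.integer(w))
    cand <- if (s == 1L) integer(0) else lo:(s - 1L)
    idx <- cand[!busy[cand] & sec_state[cand] == st]
    if (length(idx) >= min(window_s, s - 1L) || w >= max_window_s) break
    w <- min(max_window_s, w * 2)
  }
  if (!length(idx)) return(NULL)
  structure(list(value = median(sec_med[idx]), window_s = w, band = band,
                 state = st, n_seconds = length(idx)),
            class = "baseline_estimate")
}

#' Threshold-crossing candidate detection in one band
#'
#' Computes the band-limited analytic-signal envelope (see
#' [band_envelope()]), marks samples at or above
#' `threshold_mult * baseline`, closes gaps shorter than `merge_gap_s`,
#' keeps runs of at least `min_dur_s`, and discards candidates overlapping
#' the artifact mask. Baselines (and multipliers) may vary per second;
#' seconds with no valid baseline (NA) detect nothing.
#'
#' @param signal one channel.
#' @param rate sampling rate in Hz.
#' @param band two-element band in Hz.
#' @param threshold_mult scalar or per-second multiplier vector.
#' @param baseline scalar, per-second vector, or function(second) -> value.
#' @param min_dur_s minimum candidate duration.
#' @param merge_gap_s close sub-threshold gaps shorter than this.
#' @param artifacts artifact intervals tibble (or NULL).
#' @return tibble of candidate intervals (`onset_s`, `offset_s`).
#' @export
detect_band_events <- function(signal, rate, band, threshold_mult, baseline,
                               min_dur_s = 1, merge_gap_s = 0.3,
                               artifacts = NULL) {
  env <- band_envelope(signal, rate, band[1], band[2])
  n <- length(env)
  n_sec <- ceiling(n / rate)
  base_sec <- if (is.function(baseline)) {
    vapply(0:(n_sec - 1L), function(s) baseline(s) %||% NA_real_, numeric(1))
  } else if (length(baseline) == 1L) {
    rep(as.numeric(baseline), n_sec)
  } else {
    c(as.numeric(baseline), rep(NA_real_, max(0L, n_sec - length(baseline))))
  }
  mult_sec <- if (length(threshold_mult) == 1L) rep(threshold_mult, n_sec) else
    c(threshold_mult, rep(NA_real_, max(0L, n_sec - length(threshold_mult))))
  thr <- rep(mult_sec * base_sec, each = rate)[seq_len(n)]
  above <- is.finite(thr) & env >= thr
  runs_to_events(above, rate, min_dur_s, merge_gap_s, artifacts)
}

## shared run/merge/min-duration logic on a logical per-sample vector
runs_to_events <- function(above, rate, min_dur_s, merge_gap_s,
                           artifacts = NULL, max_dur_s = Inf) {
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ## close short sub-threshold gaps (strictly interior gaps only)
  if (merge_gap_s > 0 && length(r$values) > 2) {
    gap_idx <- which(!r$values & r$lengths < merge_gap_s * rate)
    gap_idx <- gap_idx[gap_idx > 1 & gap_idx < length(r$values)]
    for (g in gap_idx) above[starts[g]:ends[g]] <- TRUE
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
  }
  keep <- r$values & r$lengths >= min_dur_s * rate &
    r$lengths <= max_dur_s * rate
  ev <- tibble(onset_s = (starts[keep] - 1L) / rate,
               offset_s = ends[keep] / rate)
  if (nrow(ev) && !is.null(artifacts) && nrow(artifacts)) {
    hit <- vapply(seq_len(nrow(ev)), function(i)
      intersects_any(artifacts, ev$onset_s[i], ev$offset_s[i]), logical(1))
    ev <- ev[!hit, ]
  }
  ev
}

#' Refine candidate boundaries by baseline crossing
#'
#' Moves the onset backward to the last sample before the candidate whose
#' absolute broadband value is at or below the baseline (the leading edge's
#' crossing of the precedent baseline) and the offset forward to the first
#' such sample after the candidate; the search is bounded to one second
#' beyond the candidate on each side. The refined interval always contains
#' the candidate.
#'
#' @param onset_s,offset_s candidate interval.
#' @param signal broadband channel signal.
#' @param rate sampling rate.
#' @param baseline_value baseline amplitude (mV).
#' @return list with refined `onset_s`, `offset_s`.
#' @export
refine_onset_offset <- function(onset_s, offset_s, signal, rate,
                                baseline_value) {
  n <- length(signal)
  i_on <- as.integer(round(onset_s * rate)) + 1L
  i_off <- as.integer(round(offset_s * rate))
  lo <- max(1L, i_on - as.integer(rate))
  j <- i_on - 1L
  while (j >= lo && abs(signal[j]) > baseline_value) j <- j - 1L
  new_on <- if (j >= lo) j else lo
  hi <- min(n, i_off + as.integer(rate))
  k <- i_off + 1L
  while (k <= hi && abs(signal[k]) > baseline_value) k <- k + 1L
  new_off <- if (k <= hi) k else hi
  list(onset_s = (new_on - 1L) / rate, offset_s = new_off / rate)
}

#' Merge per-channel detections into bilateral/unilateral events
#'
#' Pairs of same-kind events on the two EEG channels whose temporal
#' intersection is at least `overlap_frac` of the shorter event are merged
#' into one bilateral event spanning their union; unmatched events keep
#' their side.
#'
#' @param events_left,events_right tibbles of events from each channel.
#' @param overlap_frac required overlap fraction of the shorter event.
#' @return one tibble with a `laterality` column.
#' @export
classify_laterality <- function(events_left, events_right,
                                overlap_frac = 0.5) {
  nl <- nrow(events_left); nr <- nrow(events_right)
  used_r <- logical(nr)
  out <- list()
  for (i in seq_len(nl)) {
    li <- events_left[i, ]
    best <- 0; best_j <- 0L
    for (j in seq_len(nr)) {
      if (used_r[j]) next
      rj <- events_right[j, ]
      ov <- interval_overlap_s(li$onset_s, li$offset_s, rj$onset_s, rj$offset_s)
      mind <- min(li$offset_s - li$onset_s, rj$offset_s - rj$onset_s)
      if (ov >= overlap_frac * mind && ov > best) { best <- ov; best_j <- j }
    }
    if (best_j > 0L) {
      rj <- events_right[best_j, ]
      used_r[best_j] <- TRUE
      merged <- li
      merged$onset_s <- min(li$onset_s, rj$onset_s)
      merged$offset_s <- max(li$offset_s, rj$offset_s)
      merged$laterality <- "bilateral"
      out[[length(out) + 1L]] <- merged
    } else {
      li$laterality <- "left"
      out[[length(out) + 1L]] <- li
    }
  }
  for (j in which(!used_r)) {
    rj <- events_right[j, ]
    rj$laterality <- "right"
    out[[length(out) + 1L]] <- rj
  }
  res <- bind_rows(out)
  if (nrow(res)) res[order(res$onset_s), ] else res
}

## dominant frequency within a band, zero-padded periodogram
peak_freq_in_band <- function(x, rate, band) {
  n <- length(x)
  nfft <- 2^ceiling(log2(max(4 * rate, n)))
  X <- Mod(fft(c(x - mean(x), numeric(nfft - n))))^2
  freqs <- (0:(nfft - 1)) * rate / nfft
  sel <- which(freqs >= band[1] & freqs <= band[2])
  freqs[sel[which.max(X[sel])]]
}

## fraction of broadband (0.5-30 Hz) power that lies in `band` over a
## span: Hann-tapered periodogram, so band-edge components keep full
## credit (no filter roll-off inside the band)
inband_power_frac <- function(signal, rate, i0, i1, band) {
  span <- signal[i0:i1]
  n <- length(span)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  P <- Mod(fft((span - mean(span)) * w))^2
  f <- (0:(n - 1)) * rate / n
  tot <- sum(P[f >= 0.5 & f <= 30])
  bnd <- sum(P[f >= band[1] & f <= band[2]])
  if (tot <= 0) 0 else bnd / tot
}

## internal single-channel SWD/SSWD detection; returns tibble with
## per-event envelope ratio for later conflict resolution
detect_swd_channel <- function(x, rate, hyp, artifacts, config) {
  det <- config$detect
  n_sec <- floor(length(x) / rate)
  sec_state <- hyp$sub$state[seq_len(n_sec)]
  env_delta <- band_envelope(x, rate, 0.5, 4)
  env_broad <- band_envelope(x, rate, 0.5, 30)
  med_delta <- sec_median_track(env_delta, rate, n_sec)
  med_broad <- sec_median_track(env_broad, rate, n_sec)
  art_busy <- sec_overlap_flags(artifacts, n_sec)
  mult_sec <- ifelse(sec_state == "NREM", det$mult_nrem, det$mult_wake_rem)
  kinds <- list(SWD = config$bands$swd, SSWD = config$bands$sswd)

  prior_events <- empty_intervals()
  cand <- NULL
  for (pass in 1:2) {
    busy <- art_busy | sec_overlap_flags(prior_events, n_sec)
    b_delta <- baseline_per_second(med_delta, sec_state, !busy,
                                   det$baseline_window_s,
                                   det$baseline_max_window_s)
    b_broad <- baseline_per_second(med_broad, sec_state, !busy,
                                   det$baseline_window_s,
                                   det$baseline_max_window_s)
    base_sec <- ifelse(sec_state == "NREM", b_delta, b_broad)
    cand <- purrr::imap(kinds, function(band, kind) {
      ev <- detect_band_events(x, rate, band, mult_sec, base_sec,
                               min_dur_s = det$min_dur_s,
                               merge_gap_s = det$merge_gap_s,
                               artifacts = artifacts)
      if (nrow(ev)) ev$kind <- kind else ev$kind <- character(0)
      ev
    })
    prior_events <- bind_rows(cand)[, c("onset_s", "offset_s")]
    if (!nrow(prior_events)) break
  }
  out <- list()
  for (kind in names(cand)) {
    band <- kinds[[kind]]
    ev <- cand[[kind]]
    if (!nrow(ev)) next
    env_band <- band_envelope(x, rate, band[1], band[2])
    for (i in seq_len(nrow(ev))) {
      s0 <- floor(ev$onset_s[i]) + 1L
      base <- base_sec[min(s0, n_sec)]
      if (!is.finite(base)) next
      ref <- refine_onset_offset(ev$onset_s[i], ev$offset_s[i], x, rate, base)
      i0 <- as.integer(round(ref$onset_s * rate)) + 1L
      i1 <- max(i0 + 1L, as.integer(round(ref$offset_s * rate)))
      i1 <- min(i1, length(x))
      if (inband_power_frac(x, rate, i0, i1, band) < det$inband_frac) next
      ratio <- mean(env_band[i0:i1]) / base
      out[[length(out) + 1L]] <- tibble(
        onset_s = ref$onset_s, offset_s = ref$offset_s, kind = kind,
        band_lo_hz = band[1], band_hi_hz = band[2],
        peak_freq_hz = peak_freq_in_band(x[i0:i1], rate, band),
        env_ratio = ratio)
    }
  }
  ev <- bind_rows(out)
  if (!nrow(ev)) return(ev)
  ev <- ev[order(ev$onset_s), ]
  ## overlapping SWD/SSWD detections: keep the kind with the higher
  ## envelope ratio
  drop <- logical(nrow(ev))
  for (i in seq_len(nrow(ev) - 1L)) {
    if (drop[i]) next
    for (j in (i + 1L):nrow(ev)) {
      if (drop[j]) next
      if (ev$onset_s[j] >= ev$offset_s[i]) break
      if (ev$kind[j] != ev$kind[i]) {
        if (ev$env_ratio[j] > ev$env_ratio[i]) drop[i] <- TRUE else drop[j] <- TRUE
      }
    }
  }
  ev[!drop, ]
}

#' Detect spike-wave discharges and slow spike-wave discharges
#'
#' Runs band-limited envelope detection per EEG channel in the 6-12 Hz
#' (SWD) and 3-6 Hz (SSWD) bands with the state-dependent amplitude rule
#' (2x the preceding broadband baseline in wake/REM; 1.5x the preceding
#' delta-band baseline in NREM), refines onsets/offsets by baseline
#' crossing of the broadband trace, requires in-band rhythmicity, resolves
#' SWD/SSWD overlaps in favour of the stronger envelope ratio, merges the
#' two channels into bilateral/unilateral events, and assigns each event
#' the vigilance state at its onset. Baselines are estimated twice: a
#' second pass excludes the first pass's detections from the lookbacks.
#'
#' @param record preprocessed, staged [signal_record()].
#' @param hyp the record's [hypnogram].
#' @param config a [swd_config()].
#' @return event tibble ([empty_events()] schema), sorted by onset.
#' @export
detect_swd <- function(record, hyp, config = swd_config()) {
  if (is.null(hyp) || !inherits(hyp, "hypnogram"))
    abort("detect_swd requires a staged record (hypnogram)",
          class = "swd_precondition_error")
  require_roles(record, c("eeg_left", "eeg_right"))
  rate <- record$rate
  evl <- detect_swd_channel(channel_by_role(record, "eeg_left"), rate, hyp,
                            record$artifacts, config)
  evr <- detect_swd_channel(channel_by_role(record, "eeg_right"), rate, hyp,
                            record$artifacts, config)
  out <- list()
  for (kind in c("SWD", "SSWD")) {
    l <- evl[evl$kind == kind, , drop = FALSE]
    r <- evr[evr$kind == kind, , drop = FALSE]
    if (nrow(l) + nrow(r) == 0) next
    m <- classify_laterality(l, r, config$detect$overlap_frac)
    out[[kind]] <- m
  }
  ev <- bind_rows(out)
  if (!nrow(ev)) return(empty_events())
  ev$duration_s <- ev$offset_s - ev$onset_s
  ev <- ev[order(ev$onset_s), ]
  ev <- assign_state(ev, hyp)
  ev$env_ratio <- NULL
  ev[, event_columns]
}

#' Detect sleep spindles
#'
#' 10-15 Hz envelope events whose amplitude reaches the baseline mean plus
#' `spindle_sd_mult` (default 1.5) baseline standard deviations, with
#' durations between 0.5 and 5 s; the baseline is the preceding 10 s of
#' same-state, event-free spindle-band envelope. Spindles overlapping a
#' detected SWD/SSWD are discarded (the 10-12 Hz bands overlap; epileptic
#' events take precedence).
#'
#' @param record preprocessed, staged [signal_record()] (conventionally at
#'   200 Hz).
#' @param hyp the record's [hypnogram].
#' @param swd_events previously detected SWD/SSWD events to exclude.
#' @param config a [swd_config()].
#' @return event tibble ([empty_events()] schema).
#' @export
detect_spindles <- function(record, hyp, swd_events = NULL,
                            config = swd_config()) {
  if (is.null(hyp) || !inherits(hyp, "hypnogram"))
    abort("detect_spindles requires a staged record",
          class = "swd_precondition_error")
  det <- config$detect
  band <- config$bands$spindle
  rate <- record$rate
  chans <- list(left = channel_by_role(record, "eeg_left"),
                right = channel_by_role(record, "eeg_right"))
  n_sec <- floor(length(chans$left) / rate)
  sec_state <- hyp$sub$state[seq_len(n_sec)]
  art_busy <- sec_overlap_flags(record$artifacts, n_sec) |
    sec_overlap_flags(swd_events, n_sec)
  per_side <- lapply(chans, function(x) {
    env_raw <- band_envelope(x, rate, band[1], band[2])
    ## detection runs on a 0.25-s-smoothed envelope (suppresses the fast
    ## stochastic envelope fluctuations of band-limited noise) while the
    ## baseline SD -- "the SD of the preceding baseline amplitudes" -- is
    ## taken from the raw envelope
    k <- max(1L, as.integer(round(0.25 * rate)))
    env <- as.numeric(stats::filter(env_raw, rep(1 / k, k), sides = 2))
    env[is.na(env)] <- env_raw[is.na(env)]
    m <- matrix(env_raw[seq_len(n_sec * rate)], nrow = rate)
    sec_mean <- colMeans(m)
    sec_sd <- apply(m, 2, sd)
    busy <- art_busy
    mu <- baseline_per_second(sec_mean, sec_state, !busy,
                              det$baseline_window_s, det$baseline_max_window_s)
    sg <- baseline_per_second(sec_sd, sec_state, !busy,
                              det$baseline_window_s, det$baseline_max_window_s)
    thr_sec <- mu + det$spindle_sd_mult * sg
    thr_sec[!sec_state %in% det$spindle_states] <- NA_real_
    thr <- rep(thr_sec, each = rate)[seq_len(length(env))]
    above <- is.finite(thr) & env >= thr
    ev <- runs_to_events(above, rate, det$spindle_min_s,
                         det$spindle_merge_gap_s,
                         record$artifacts, max_dur_s = det$spindle_max_s)
    if (!nrow(ev)) return(ev)
    ev$kind <- "spindle"
    ev$band_lo_hz <- band[1]; ev$band_hi_hz <- band[2]
    ev$peak_freq_hz <- vapply(seq_len(nrow(ev)), function(i) {
      i0 <- as.integer(round(ev$onset_s[i] * rate)) + 1L
      i1 <- min(length(x), as.integer(round(ev$offset_s[i] * rate)))
      peak_freq_in_band(x[i0:i1], rate, band)
    }, numeric(1))
    ev
  })
  ev <- classify_laterality(per_side$left, per_side$right,
                            det$overlap_frac)
  if (!nrow(ev)) return(empty_events())
  ## spindles are bilaterally synchronous thalamocortical events; requiring
  ## concordance across the two EEG channels suppresses chance
  ## threshold-grazing runs of the stochastic background
  if (isTRUE(det$spindle_bilateral_only))
    ev <- ev[ev$laterality == "bilateral", , drop = FALSE]
  if (!nrow(ev)) return(empty_events())
  ev$duration_s <- ev$offset_s - ev$onset_s
  ev <- ev[ev$duration_s >= det$spindle_min_s &
             ev$duration_s <= det$spindle_max_s, ]
  if (!is.null(swd_events) && nrow(swd_events) && nrow(ev)) {
    hit <- vapply(seq_len(nrow(ev)), function(i)
      any(swd_events$onset_s < ev$offset_s[i] &
            swd_events$offset_s > ev$onset_s[i]), logical(1))
    ev <- ev[!hit, ]
  }
  if (!nrow(ev)) return(empty_events())
  ev <- assign_state(ev, hyp)
  ev[, event_columns]
}

#' Assign each event the vigilance state at its onset
#'
#' Events straddling a state boundary take the state of their onset
#' sub-epoch (incidence is counted by state at onset).
#'
#' @param events event tibble.
#' @param hyp a [hypnogram] covering all event onsets.
#' @return the events with a `state` column.
#' @export
assign_state <- function(events, hyp) {
  if (!nrow(events)) { events$state <- character(0); return(events) }
  span_end <- max(hyp$sub$second) + 1
  if (any(events$onset_s < 0 | events$onset_s >= span_end))
    abort("event onset outside hypnogram span", class = "swd_input_error")
  events$state <- hyp$sub$state[floor(events$onset_s) + 1L]
  events
}

#' Detect all event classes of a staged record
#'
#' SWD/SSWD first, then spindles with SWD exclusion.
#' @param record preprocessed, staged record.
#' @param hyp its [hypnogram].
#' @param config a [swd_config()].
#' @return combined event tibble sorted by onset.
#' @export
detect_events <- function(record, hyp, config = swd_config()) {
  swd <- detect_swd(record, hyp, config)
  sp <- detect_spindles(record, hyp, swd_events = swd, config = config)
  ev <- bind_rows(swd, sp)
  if (nrow(ev)) ev[order(ev$onset_s), ] else ev
}
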