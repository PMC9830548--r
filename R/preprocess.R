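#' Band-pass filter one channel of a record
#'
#' Zero-phase (forward-backward) Butterworth band-pass applied to the named
#' role's channel only; all other channels are untouched. The band is
#' realised as cascaded high-pass + low-pass sections, which is numerically
#' stable even for the 0.1 Hz EEG high-pass edge at kHz rates.
#'
#' @param record a [signal_record()].
#' @param role channel role to filter.
#' @param low_hz,high_hz band edges in Hz, `0 <= low_hz < high_hz < rate/2`.
#' @param order Butterworth order per section (default 4).
#' @return the record with that channel filtered.
#' @export
bandpass <- function(record, role, low_hz, high_hz, order = 4L) {
  nm <- names(record$roles)[record$roles == role]
  if (length(nm) != 1L)
    abort(sprintf("no channel with role '%s'", role), class = "swd_config_error")
  record$channels[[nm]] <-
    bandpass_vector(record$channels[[nm]], record$rate, low_hz, high_hz, order)
  record
}

#' Resample a record to the analysis rate
#'
#' Anti-alias filtered, then decimated (integer ratios) or polyphase
#' resampled. Duration is preserved to within one sample period; the
#' artifact mask (in seconds) is unchanged.
#'
#' @param record a [signal_record()].
#' @param target_rate new rate in Hz, at most the current rate. 200 Hz is
#'   the conventional analysis rate for rodent EEG scoring.
#' @return resampled [signal_record()].
#' @export
resample_to <- function(record, target_rate = 200) {
  if (target_rate > record$rate)
    abort(sprintf("target rate %g Hz exceeds native rate %g Hz",
                  target_rate, record$rate), class = "swd_parameter_error")
  if (target_rate == record$rate) return(record)
  record$channels <- lapply(record$channels, resample_vector,
                            rate = record$rate, target = target_rate)
  nmin <- min(vapply(record$channels, length, integer(1)))
  record$channels <- lapply(record$channels, function(x) x[seq_len(nmin)])
  record$rate <- target_rate
  record
}

#' Flag movement artifacts from EMG power
#'
#' The source recordings in this field are typically cleaned with the help
#' of video; as a reproducible stand-in this detector flags intervals where
#' 1-s EMG RMS exceeds a robust threshold `center + k_sd * spread` for at
#' least `min_dur_s`, and merges adjacent intervals. Because EMG RMS is
#' bimodal across the sleep/wake cycle (atonia vs muscle tone), the center
#' is the median of the upper mode (seconds at or above the overall
#' median) and the spread is the quantile-based robust SD
#' `(q90 - q50) / z_0.90`; ordinary waking muscle tone is therefore not
#' flagged while genuine movement bursts -- an order of magnitude above
#' it -- are.
#' Idempotent for fixed parameters: the mask is recomputed from the EMG
#' signal, not accumulated blindly.
#'
#' @param record a [signal_record()] with an EMG channel.
#' @param k_sd threshold in robust SDs above the median (default 5).
#' @param min_dur_s minimum artifact duration in seconds (default 0.5).
#' @param merge_gap_s merge intervals closer than this (default 1).
#' @return the record with artifact intervals added to its mask.
#' @export
mask_artifacts <- function(record, k_sd = 5, min_dur_s = 0.5, merge_gap_s = 1) {
  emg <- channel_by_role(record, "emg")
  rate <- record$rate
  n_sec <- floor(length(emg) / rate)
  if (n_sec < 1) return(record)
  m <- matrix(emg[seq_len(n_sec * rate)], nrow = rate)
  sec_rms <- sqrt(colMeans(m^2))
  med_upper <- median(sec_rms[sec_rms >= median(sec_rms)])
  rsd <- (quantile(sec_rms, 0.9, names = FALSE) - median(sec_rms)) /
    qnorm(0.9)
  if (rsd == 0) rsd <- .Machine$double.eps
  hot <- sec_rms > med_upper + k_sd * rsd
  runs <- rle(hot)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths
  iv <- tibble(start_s = as.numeric(starts[runs$values]),
               end_s = as.numeric(ends[runs$values]))
  iv <- iv[iv$end_s - iv$start_s >= min_dur_s, ]
  new_mask <- normalize_intervals(bind_rows(record$artifacts, iv),
                                  gap = merge_gap_s)
  record$artifacts <- new_mask
  record
}

#' Standard preprocessing chain
#'
#' Band-filters EEG (0.1-100 Hz) and EMG (0.1-400 Hz, capped below Nyquist
#' when the native rate is too low), masks EMG artifacts at the native rate,
#' then resamples to the analysis rate.
#'
#' @param record a raw [signal_record()].
#' @param config a [swd_config()] list.
#' @return preprocessed [signal_record()] at `config$analysis_rate`.
#' @export
preprocess_record <- function(record, config = swd_config()) {
  nyq <- record$rate / 2
  eeg_hi <- min(config$eeg_band[2], 0.99 * nyq)
  emg_hi <- min(config$emg_band[2], 0.99 * nyq)
  record <- bandpass(record, "eeg_left", config$eeg_band[1], eeg_hi)
  record <- bandpass(record, "eeg_right", config$eeg_band[1], eeg_hi)
  record <- bandpass(record, "emg", config$emg_band[1], emg_hi)
  record <- mask_artifacts(record, k_sd = config$artifact$k_sd,
                           min_dur_s = config$artifact$min_dur_s)
  resample_to(record, config$analysis_rate)
}

#' Pipeline configuration
#'
#' All tunable parameters of the pipeline with their defaults. Values mirror
#' standard rodent polysomnography practice: acquisition bands 0.1-100 Hz
#' (EEG) and 0.1-400 Hz (EMG), 200 Hz analysis rate, 10-s scoring epochs.
#' Two delta bands are kept distinct on purpose: staging uses 0.5-4 Hz, the
#' NREM delta-power statistic uses 0.1-4 Hz.
#'
#' @param ... named overrides, e.g. `swd_config(analysis_rate = 250)`.
#'   Nested lists are replaced wholesale.
#' @return named list of configuration values.
#' @export
swd_config <- function(...) {
  cfg <- list(
    eeg_band = c(0.1, 100),
    emg_band = c(0.1, 400),
    analysis_rate = 200,
    epoch_len_s = 10,
    artifact = list(k_sd = 5, min_dur_s = 0.5),
    bands = list(delta_power = c(0.1, 4), delta_staging = c(0.5, 4),
                 theta = c(6, 10), total = c(0.5, 30), swd = c(6, 12),
                 sswd = c(3, 6), spindle = c(10, 15)),
    staging = list(delta_frac_cut = 0.5, theta_ratio_cut = 1.5,
                   emg_wake_cut = NULL, eeg_amp_cut = NULL),
    spectral = list(nw = 4, n_tapers = 7, window_s = 10),
    detect = list(mult_wake_rem = 2.0, mult_nrem = 1.5, min_dur_s = 1.0,
                  merge_gap_s = 0.3, baseline_window_s = 10,
                  baseline_max_window_s = 60, overlap_frac = 0.5,
                  spindle_sd_mult = 1.5, spindle_min_s = 0.5,
                  spindle_max_s = 5, spindle_merge_gap_s = 0.1,
                  spindle_states = "NREM",
                  spindle_bilateral_only = TRUE, inband_frac = 0.6)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      for (k in names(dots[[nm]])) cfg[[nm]][[k]] <- dots[[nm]][[k]]
    } else cfg[[nm]] <- dots[[nm]]
  }
  cfg
}
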