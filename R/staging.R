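## Vigilance-state scoring on a 10-s epoch grid with 1-s sub-epochs.
##
## The field's criteria are qualitative (wake: low EEG amplitude + high EMG
## tone; NREM: high EEG amplitude, dominant frequency < 4 Hz; REM: uniform
## low-amplitude EEG with dominant 6-10 Hz theta); this module turns them
## into a deterministic classifier with per-record calibrated cuts.

states3 <- c("wake", "NREM", "REM")

new_hypnogram <- function(epochs, sub, epoch_len_s = 10) {
  structure(list(epochs = epochs, sub = sub, epoch_len_s = epoch_len_s),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$epochs$state, levels = c(states3, "artifact")))
  cat(sprintf("<hypnogram> %d epochs x %g s: %s\n", nrow(x$epochs),
              x$epoch_len_s,
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @method as_tibble hypnogram
#' @export
as_tibble.hypnogram <- function(x, ...) x$epochs

## state of the 1-s sub-label containing time t (half-open grid)
state_at <- function(hyp, t) {
  i <- findInterval(t, hyp$sub$second)
  if (any(i < 1 | t >= max(hyp$sub$second) + 1))
    abort("time outside hypnogram span", class = "swd_input_error")
  hyp$sub$state[i]
}

#' Per-second staging features
#'
#' For every 1-s sub-epoch: mean broadband (0.5-30 Hz) EEG envelope, delta
#' (0.5-4 Hz), theta (6-10 Hz) and total (0.5-30 Hz) band power from a
#' short-window multitaper estimate, delta fraction, theta/delta ratio, and
#' EMG RMS. EEG features are averaged over the two EEG channels. Band
#' powers of an identically zero signal are zero and the derived ratios are
#' defined as zero.
#'
#' @param record preprocessed [signal_record()] at the analysis rate.
#' @param config a [swd_config()].
#' @return tibble, one row per second, with an `epoch` column (0-based).
#' @export
compute_epoch_features <- function(record, config = swd_config()) {
  rate <- record$rate
  epoch_len <- config$epoch_len_s
  if (record_duration(record) < epoch_len)
    abort("record shorter than one epoch", class = "swd_input_error")
  n_sec <- floor(length(record$channels[[1]]) / rate)
  nuse <- n_sec * rate
  bands <- config$bands

  band_power_tracks <- function(x) {
    segs <- matrix(x[seq_len(nuse)], nrow = rate)
    m <- mt_psd_matrix(segs, rate, nw = 2, k = 3)
    df <- m$freqs[2] - m$freqs[1]
    bp <- function(b) {
      sel <- m$freqs >= b[1] & m$freqs <= b[2]
      colSums(m$psd[sel, , drop = FALSE]) * df
    }
    env <- envelope(bandpass_vector(x[seq_len(nuse)], rate,
                                    bands$total[1], bands$total[2]))
    list(delta = bp(bands$delta_staging), theta = bp(bands$theta),
         total = bp(bands$total),
         env = colMeans(matrix(env, nrow = rate)))
  }
  l <- band_power_tracks(channel_by_role(record, "eeg_left"))
  r <- band_power_tracks(channel_by_role(record, "eeg_right"))
  delta <- (l$delta + r$delta) / 2
  theta <- (l$theta + r$theta) / 2
  total <- (l$total + r$total) / 2
  env <- (l$env + r$env) / 2
  emg <- channel_by_role(record, "emg")
  emg_rms <- sqrt(colMeans(matrix(emg[seq_len(nuse)]^2, nrow = rate)))

  sec0 <- 0:(n_sec - 1)
  art_frac <- vapply(sec0, function(s)
    covered_seconds(record$artifacts, s, s + 1), numeric(1))
  tibble(
    second = sec0,
    epoch = sec0 %/% epoch_len,
    eeg_env = env,
    delta_pow = delta, theta_pow = theta, total_pow = total,
    delta_frac = ifelse(total > 0, delta / total, 0),
    theta_ratio = ifelse(delta > 0, theta / delta, 0),
    emg_rms = emg_rms,
    artifact_frac = art_frac)
}

#' Calibrate per-record staging thresholds
#'
#' The EMG wake cut is the midpoint (in log space) between the two modes of
#' the log EMG RMS distribution -- sleep atonia and waking muscle tone are
#' bimodal; if no clear bimodality is found the 60th percentile is used.
#' The EEG amplitude cut is the median broadband envelope. Delta-fraction
#' and theta/delta cuts are fixed defaults (0.5 and 1.5), overridable
#' through `config$staging`.
#'
#' @param features output of [compute_epoch_features()], >= 30 min.
#' @param config a [swd_config()]; `config$staging` entries override the
#'   calibrated values when non-NULL.
#' @return list of class `staging_thresholds`.
#' @export
calibrate_thresholds <- function(features, config = swd_config()) {
  if (nrow(features) < 1800)
    warn("fewer than 30 min of features; calibration may be unstable")
  if (sd(features$emg_rms) == 0 || sd(features$eeg_env) == 0)
    abort("degenerate (constant) features; cannot calibrate",
          class = "swd_calibration_error")
  lemg <- log(pmax(features$emg_rms, .Machine$double.xmin))
  d <- density(lemg, n = 512)
  ispeak <- which(diff(sign(diff(d$y))) == -2) + 1
  peaks <- ispeak[order(d$y[ispeak], decreasing = TRUE)]
  emg_cut <- if (length(peaks) >= 2) {
    two <- sort(d$x[peaks[1:2]])
    exp(mean(two))
  } else exp(quantile(lemg, 0.6, names = FALSE))
  th <- list(
    emg_wake_cut = config$staging$emg_wake_cut %||% emg_cut,
    eeg_amp_cut = config$staging$eeg_amp_cut %||% median(features$eeg_env),
    delta_frac_cut = config$staging$delta_frac_cut %||% 0.5,
    theta_ratio_cut = config$staging$theta_ratio_cut %||% 1.5)
  structure(th, class = "staging_thresholds")
}

## decision rule for one feature row -> sub-epoch state
score_sub_epochs <- function(features, th) {
  emg <- features$emg_rms; env <- features$eeg_env
  dfrac <- features$delta_frac; ratio <- features$theta_ratio
  is_wake <- emg > th$emg_wake_cut
  is_nrem <- !is_wake & dfrac > th$delta_frac_cut & env > th$eeg_amp_cut
  is_rem <- !is_wake & !is_nrem & ratio > th$theta_ratio_cut &
    env <= th$eeg_amp_cut
  lab <- ifelse(is_wake, "wake", ifelse(is_nrem, "NREM",
                ifelse(is_rem, "REM", NA_character_)))
  und <- which(is.na(lab))
  if (length(und)) {
    ## EMG tone is bimodal on the log scale (atonia vs muscle tone), so its
    ## distance is measured in octaves below the cut; spectral-shape and
    ## envelope terms are relative linear distances
    d_wake <- pmax(0, log2(th$emg_wake_cut /
                             pmax(emg[und], .Machine$double.xmin)))
    d_nrem <- pmax(0, (th$delta_frac_cut - dfrac[und]) / th$delta_frac_cut) +
      pmax(0, (th$eeg_amp_cut - env[und]) / th$eeg_amp_cut)
    d_rem <- pmax(0, (th$theta_ratio_cut - ratio[und]) / th$theta_ratio_cut) +
      pmax(0, (env[und] - th$eeg_amp_cut) / th$eeg_amp_cut)
    pick <- max.col(-cbind(d_wake, d_nrem, d_rem), ties.method = "first")
    lab[und] <- states3[pick]
  }
  lab
}

#' Score a record into a hypnogram
#'
#' Each 1-s sub-epoch is labeled by the decision rule (wake if EMG RMS
#' exceeds the wake cut; else NREM if delta fraction and EEG envelope exceed
#' their cuts; else REM if theta/delta exceeds its cut at low envelope; else
#' the nearest state by normalised distance to the cuts). Each 10-s epoch
#' takes the state occupying more than 5 of its 10 seconds; an exact 5 s/5 s
#' split keeps the previous epoch's state (hysteresis). Epochs overlapping
#' the artifact mask by more than 50% are labeled `artifact`.
#'
#' @param features output of [compute_epoch_features()].
#' @param thresholds a `staging_thresholds` object.
#' @param config a [swd_config()].
#' @return a `hypnogram`.
#' @export
score_epochs <- function(features, thresholds, config = swd_config()) {
  epoch_len <- config$epoch_len_s
  sub_state <- score_sub_epochs(features, thresholds)
  epochs_idx <- sort(unique(features$epoch))
  prev <- "wake"
  lab <- character(length(epochs_idx))
  art <- numeric(length(epochs_idx))
  for (j in seq_along(epochs_idx)) {
    rows <- features$epoch == epochs_idx[j]
    art[j] <- sum(features$artifact_frac[rows]) / sum(rows)
    cnt <- table(factor(sub_state[rows], levels = states3))
    if (art[j] > 0.5) {
      lab[j] <- "artifact"
      next
    }
    mx <- max(cnt)
    winners <- names(cnt)[cnt == mx]
    if (mx > epoch_len / 2) {
      lab[j] <- winners[1]
    } else if (prev %in% winners) {
      lab[j] <- prev
    } else {
      lab[j] <- winners[1]
    }
    prev <- lab[j]
  }
  epochs <- tibble(epoch = epochs_idx,
                   start_s = epochs_idx * epoch_len,
                   end_s = (epochs_idx + 1) * epoch_len,
                   state = lab, artifact_frac = art)
  ## the epoch grid is the staging unit: downstream state conditioning
  ## (event baselines, incidence) uses epoch-smoothed per-second labels;
  ## the raw sub-epoch labels that fed the dominance rule are kept
  sub <- tibble(second = features$second,
                state = lab[match(features$epoch, epochs_idx)],
                state_raw = sub_state)
  new_hypnogram(epochs, sub, epoch_len_s = epoch_len)
}

#' Stage a preprocessed record end to end
#'
#' Convenience wrapper: features, calibration, epoch scoring.
#' @param record preprocessed [signal_record()].
#' @param config a [swd_config()].
#' @return a `hypnogram`.
#' @export
stage_record <- function(record, config = swd_config()) {
  feats <- compute_epoch_features(record, config)
  th <- calibrate_thresholds(feats, config)
  score_epochs(feats, th, config)
}

#' State durations, bouts and transitions
#'
#' Durations are epoch counts times the epoch length; a bout is a maximal
#' run of consecutive epochs in one state (artifact epochs break runs);
#' transitions are counted between consecutive non-artifact epochs with
#' differing labels.
#'
#' @param hyp a `hypnogram`.
#' @return object of class `state_metrics`: `$durations` (state, seconds,
#'   bouts), `$transitions` (from, to, n), `$artifact_s`, `$total_s`.
#' @export
summarize_states <- function(hyp) {
  lab <- hyp$epochs$state
  el <- hyp$epoch_len_s
  dur <- vapply(states3, function(s) sum(lab == s) * el, numeric(1))
  runs <- rle(lab)
  bouts <- vapply(states3, function(s) sum(runs$values == s), numeric(1))
  keep <- which(lab[-length(lab)] != "artifact" & lab[-1] != "artifact" &
                  lab[-length(lab)] != lab[-1])
  trans <- tibble(from = lab[keep], to = lab[keep + 1]) |>
    dplyr::count(.data$from, .data$to, name = "n")
  structure(list(
    durations = tibble(state = states3, seconds = unname(dur),
                       bouts = unname(bouts)),
    transitions = trans,
    artifact_s = sum(lab == "artifact") * el,
    total_s = length(lab) * el), class = "state_metrics")
}

#' @export
print.state_metrics <- function(x, ...) {
  cat("<state_metrics>\n")
  print(x$durations)
  if (nrow(x$transitions)) print(x$transitions)
  cat(sprintf("artifact %g s / total %g s\n", x$artifact_s, x$total_s))
  invisible(x)
}

#' Count one ordered transition
#' @param metrics a `state_metrics` object.
#' @param from,to state names.
#' @return integer count.
#' @export
transition_count <- function(metrics, from, to) {
  r <- metrics$transitions[metrics$transitions$from == from &
                             metrics$transitions$to == to, ]
  if (nrow(r)) r$n[[1]] else 0L
}
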