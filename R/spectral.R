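.taper_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed from the classic symmetric tridiagonal formulation (the
#' eigenvectors of the tridiagonal matrix with diagonal
#' `((n-1-2t)/2)^2 cos(2*pi*W)` and off-diagonal `t(n-t)/2` are the DPSS in
#' order of concentration). Tapers are unit-energy, sign-fixed so each
#' taper's mean (first taper) or first lag (others) is positive, and cached
#' per `(n, nw, k)` since the pipeline reuses a handful of window lengths.
#'
#' @param n window length in samples.
#' @param nw time-bandwidth product (default 4).
#' @param k number of tapers, at most `2*nw - 1`.
#' @return `n x k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw = 4, k = 2 * nw - 1) {
  if (k > 2 * nw - 1)
    abort("n_tapers must be <= 2*nw - 1", class = "swd_parameter_error")
  key <- sprintf("%d_%g_%d", n, nw, k)
  hit <- get0(key, envir = .taper_cache)
  if (!is.null(hit)) return(hit)
  W <- nw / n
  t0 <- 0:(n - 1)
  dg <- (((n - 1) - 2 * t0) / 2)^2 * cos(2 * pi * W)
  i <- 1:(n - 1)
  od <- i * (n - i) / 2
  M <- diag(dg)
  M[cbind(i, i + 1)] <- od
  M[cbind(i + 1, i)] <- od
  ev <- eigen(M, symmetric = TRUE)
  V <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    V[, j] <- V[, j] / sqrt(sum(V[, j]^2))
    if (j %% 2 == 1) {
      if (sum(V[, j]) < 0) V[, j] <- -V[, j]
    } else {
      if (sum(V[-1, j] * t0[-1]) < 0) V[, j] <- -V[, j]
    }
  }
  assign(key, V, envir = .taper_cache)
  V
}

new_spectral_estimate <- function(freqs, psd, window_s, nw, n_tapers, rate) {
  structure(list(freqs = freqs, psd = psd, window_s = window_s, nw = nw,
                 n_tapers = n_tapers, rate = rate),
            class = "spectral_estimate")
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf("<spectral_estimate> %d bins, 0-%.4g Hz, nw=%g, %d tapers\n",
              length(x$freqs), max(x$freqs), x$nw, x$n_tapers))
  invisible(x)
}

#' @method as_tibble spectral_estimate
#' @export
as_tibble.spectral_estimate <- function(x, ...) {
  tibble(freq_hz = x$freqs, psd = x$psd)
}

## multitaper eigenspectra for a matrix of segments (one segment per
## column); returns one-sided psd matrix (n_freq x n_segments)
mt_psd_matrix <- function(segs, rate, nw, k) {
  n <- nrow(segs)
  V <- dpss_tapers(n, nw, k)
  acc <- NULL
  for (j in seq_len(k)) {
    Y <- Mod(stats::mvfft(segs * V[, j]))^2
    acc <- if (is.null(acc)) Y else acc + Y
  }
  two_sided <- acc / (k * rate)
  half <- floor(n / 2)
  idx <- 1:(half + 1)
  one <- two_sided[idx, , drop = FALSE]
  if (n %% 2 == 0) {
    if (half > 1) one[2:half, ] <- one[2:half, ] + two_sided[n:(half + 2), , drop = FALSE]
  } else {
    one[2:(half + 1), ] <- one[2:(half + 1), ] + two_sided[n:(half + 2), , drop = FALSE]
  }
  list(freqs = (idx - 1) * rate / n, psd = one)
}

#' Multitaper power spectral density
#'
#' Averages DPSS-tapered eigenspectra into a one-sided density in
#' signal-units squared per Hz, normalised so that `sum(psd) * df` equals
#' the biased variance estimate of the segment (Parseval).
#'
#' @param segment numeric vector, at least one second of samples.
#' @param rate sampling rate in Hz.
#' @param nw time-bandwidth product.
#' @param n_tapers taper count (`<= 2*nw - 1`).
#' @return a `spectral_estimate` (fields `freqs`, `psd`, taper parameters).
#' @export
multitaper_psd <- function(segment, rate, nw = 4, n_tapers = 2 * nw - 1) {
  if (length(segment) < rate)
    abort("segment must be at least 1 s long", class = "swd_input_error")
  m <- mt_psd_matrix(matrix(segment, ncol = 1), rate, nw, n_tapers)
  new_spectral_estimate(m$freqs, as.numeric(m$psd),
                        window_s = length(segment) / rate,
                        nw = nw, n_tapers = n_tapers, rate = rate)
}

#' Multitaper spectrogram of one channel
#'
#' Non-overlapping (or stepped) windows of `window_s` seconds; windows that
#' intersect the record's artifact mask are flagged and excluded from any
#' averaging done downstream.
#'
#' @param record a [signal_record()].
#' @param role channel role to analyse.
#' @param window_s,step_s window length and hop in seconds.
#' @param nw,n_tapers multitaper parameters.
#' @return object of class `spectrogram`: `times` (window starts), `freqs`,
#'   `power` (freq x window), `flagged` (logical per window).
#' @export
spectrogram <- function(record, role, window_s = 10, step_s = window_s,
                        nw = 4, n_tapers = 2 * nw - 1) {
  x <- channel_by_role(record, role)
  rate <- record$rate
  nwin_len <- as.integer(round(window_s * rate))
  if (length(x) < nwin_len)
    abort("record shorter than one window", class = "swd_input_error")
  starts <- seq(0, record_duration(record) - window_s, by = step_s)
  idx0 <- as.integer(round(starts * rate))
  segs <- vapply(idx0, function(i) x[(i + 1):(i + nwin_len)], numeric(nwin_len))
  m <- mt_psd_matrix(segs, rate, nw, n_tapers)
  flagged <- vapply(starts, function(s)
    intersects_any(record$artifacts, s, s + window_s), logical(1))
  structure(list(times = starts, freqs = m$freqs, power = m$psd,
                 flagged = flagged, window_s = window_s, nw = nw,
                 n_tapers = n_tapers),
            class = "spectrogram")
}

#' @method as_tibble spectrogram
#' @export
as_tibble.spectrogram <- function(x, ...) {
  tibble(time_s = rep(x$times, each = length(x$freqs)),
         freq_hz = rep(x$freqs, times = length(x$times)),
         psd = as.numeric(x$power),
         flagged = rep(x$flagged, each = length(x$freqs)))
}

#' NREM delta-band power
#'
#' The depth-of-sleep statistic: mean over the first `total_s` seconds of
#' NREM-scored 10-s windows (in record order; NREM is fragmented, so the
#' windows need not be contiguous in wall-clock time) of the band-average
#' PSD in `band`, averaged over the two EEG channels. REM/wake windows and
#' artifact-flagged windows are excluded.
#'
#' @param record preprocessed [signal_record()].
#' @param hyp its [hypnogram].
#' @param band analysis band in Hz (default the printed 0.1-4 Hz).
#' @param total_s amount of NREM to average (default 1800 s = 30 min).
#' @param nw,n_tapers multitaper parameters.
#' @return band-average NREM PSD in mV^2/Hz.
#' @export
nrem_delta_power <- function(record, hyp, band = c(0.1, 4), total_s = 1800,
                             nw = 4, n_tapers = 7) {
  ep <- hyp$epochs
  ok <- ep$state == "NREM" &
    !vapply(seq_len(nrow(ep)), function(i)
      intersects_any(record$artifacts, ep$start_s[i], ep$end_s[i]), logical(1))
  win_len_s <- hyp$epoch_len_s
  need <- as.integer(ceiling(total_s / win_len_s))
  avail <- sum(ok)
  if (avail < need)
    abort(sprintf("insufficient NREM: %g s available, %g s required",
                  avail * win_len_s, total_s), class = "swd_input_error")
  use <- which(ok)[seq_len(need)]
  rate <- record$rate
  nwin_len <- as.integer(round(win_len_s * rate))
  vals <- vapply(c("eeg_left", "eeg_right"), function(role) {
    x <- channel_by_role(record, role)
    segs <- vapply(ep$start_s[use], function(s) {
      i0 <- as.integer(round(s * rate))
      x[(i0 + 1):(i0 + nwin_len)]
    }, numeric(nwin_len))
    m <- mt_psd_matrix(segs, rate, nw, n_tapers)
    sel <- m$freqs >= band[1] & m$freqs <= band[2]
    mean(colMeans(m$psd[sel, , drop = FALSE]))
  }, numeric(1))
  mean(vals)
}
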