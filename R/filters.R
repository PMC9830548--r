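## Zero-phase IIR filtering.
##
## Filter design is delegated to signal::butter; the forward-backward pass
## runs through a compiled direct-form-II-transposed kernel with
## odd-reflection padding at both ends, so that multi-hour records filter in
## well under a second per pass.

apply_iir <- function(flt, x) {
  a <- flt$a / flt$a[1]
  b <- flt$b / flt$a[1]
  .iir_filter(b, a, x)
}

#' Zero-phase (forward-backward) IIR filtering
#'
#' Applies the filter forward and backward with odd-reflection end padding,
#' giving zero phase distortion and squared magnitude response.
#'
#' @param flt a filter object with `b`/`a` coefficients (e.g. from
#'   [signal::butter()]).
#' @param x numeric vector.
#' @return filtered vector, same length as `x`.
#' @export
filtfilt_zero_phase <- function(flt, x) {
  n <- length(x)
  nord <- max(length(flt$a), length(flt$b)) - 1L
  npad <- min(max(3L * nord, 12L), n - 1L)
  if (npad < 1L) return(apply_iir(flt, x))
  pre <- 2 * x[1] - x[(npad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - npad)]
  y <- apply_iir(flt, c(pre, x, post))
  y <- rev(apply_iir(flt, rev(y)))
  y[(npad + 1L):(npad + n)]
}

## Band-pass a vector, splitting into cascaded high-pass + low-pass when both
## edges are finite (a direct band-pass with edges spanning three decades is
## numerically fragile).
bandpass_vector <- function(x, rate, low_hz, high_hz, order = 4L) {
  nyq <- rate / 2
  if (low_hz < 0 || high_hz <= low_hz)
    abort("invalid band: need 0 <= low_hz < high_hz", class = "swd_parameter_error")
  if (high_hz >= nyq)
    abort(sprintf("band edge %.3g Hz is at or above Nyquist (%.3g Hz)", high_hz, nyq),
          class = "swd_parameter_error")
  y <- x
  if (high_hz < nyq)
    y <- filtfilt_zero_phase(signal::butter(order, high_hz / nyq, type = "low"), y)
  if (low_hz > 0)
    y <- filtfilt_zero_phase(signal::butter(order, low_hz / nyq, type = "high"), y)
  y
}

#' Band-limited analytic-signal envelope
#'
#' Computes the amplitude envelope of the band-limited component of a
#' signal in one pass: the FFT is masked to `[lo_hz, hi_hz]` (flat in-band,
#' raised-cosine transitions of `transition_hz` outside the band) and to
#' positive frequencies (analytic signal), and the magnitude of the inverse
#' transform is returned. Unlike an IIR band-pass, the in-band response is
#' exactly flat, so events at the band edges are not attenuated.
#'
#' @param x numeric vector.
#' @param rate sampling rate in Hz.
#' @param lo_hz,hi_hz band edges in Hz.
#' @param transition_hz width of the raised-cosine transition outside the
#'   band.
#' @return non-negative envelope vector, same length as `x`.
#' @export
band_envelope <- function(x, rate, lo_hz, hi_hz, transition_hz = 0.5) {
  n <- length(x)
  X <- fft(x)
  f <- (0:(n - 1)) * rate / n
  pos <- f <= rate / 2
  g <- numeric(n)
  fp <- f[pos]
  gp <- numeric(sum(pos))
  gp[fp >= lo_hz & fp <= hi_hz] <- 1
  lo_tr <- fp < lo_hz & fp > lo_hz - transition_hz
  gp[lo_tr] <- 0.5 * (1 + cos(pi * (lo_hz - fp[lo_tr]) / transition_hz))
  hi_tr <- fp > hi_hz & fp < hi_hz + transition_hz
  gp[hi_tr] <- 0.5 * (1 + cos(pi * (fp[hi_tr] - hi_hz) / transition_hz))
  g[pos] <- gp * 2
  g[1] <- 0
  if (n %% 2 == 0) g[n / 2 + 1] <- g[n / 2 + 1] / 2
  Mod(fft(X * g, inverse = TRUE) / n)
}

## Anti-aliased resampling of one vector from `rate` to `target`.
## Integer decimation: 8th-order low-pass at 0.8 * target Nyquist, then take
## every k-th sample. Non-integer ratios fall back to polyphase
## signal::resample.
resample_vector <- function(x, rate, target) {
  if (target == rate) return(x)
  k <- rate / target
  if (abs(k - round(k)) < 1e-9) {
    k <- as.integer(round(k))
    lp <- signal::butter(8, 0.8 / k, type = "low")
    y <- filtfilt_zero_phase(lp, x)
    y[seq(1L, length(y), by = k)]
  } else {
    fr <- MASS::fractions(target / rate, cycles = 8)
    pq <- as.integer(strsplit(attr(fr, "fracs"), "/")[[1]])
    if (length(pq) == 1L) pq <- c(pq, 1L)
    as.numeric(signal::resample(x, pq[1], pq[2]))
  }
}
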