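#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n rename across
#' @importFrom stats median mad sd var fft approx quantile rnorm runif rpois
#'   rlnorm t.test aov density setNames pt qnorm
#' @importFrom utils head tail
#' @useDynLib swdscore, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

rms <- function(x) sqrt(mean(x^2))

#' Amplitude envelope via the analytic signal
#'
#' Magnitude of the FFT-based analytic signal (Hilbert transform method).
#' This is the operational definition of "amplitude" used by every detector
#' in the package.
#'
#' @param x numeric vector.
#' @return non-negative numeric vector, same length as `x`.
#' @export
envelope <- function(x) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

## ---- half-open interval helpers -------------------------------------------
## Intervals are tibbles with columns start_s, end_s, [s, e), seconds from
## record start.

empty_intervals <- function() tibble(start_s = numeric(0), end_s = numeric(0))

#' Normalize a set of half-open intervals
#'
#' Sorts, drops empty intervals, and merges overlapping or touching ones
#' (gaps smaller than `gap` are closed).
#'
#' @param x tibble with columns `start_s`, `end_s`.
#' @param gap merge intervals separated by less than this many seconds.
#' @return normalized tibble, pairwise disjoint and sorted.
#' @export
normalize_intervals <- function(x, gap = 0) {
  if (is.null(x) || nrow(x) == 0) return(empty_intervals())
  stopifnot(all(c("start_s", "end_s") %in% names(x)))
  x <- x[x$end_s > x$start_s, c("start_s", "end_s")]
  if (nrow(x) == 0) return(empty_intervals())
  x <- x[order(x$start_s, x$end_s), ]
  st <- x$start_s[1]; en <- x$end_s[1]
  out_s <- numeric(0); out_e <- numeric(0)
  if (nrow(x) > 1) {
    for (i in 2:nrow(x)) {
      if (x$start_s[i] <= en + gap) {
        en <- max(en, x$end_s[i])
      } else {
        out_s <- c(out_s, st); out_e <- c(out_e, en)
        st <- x$start_s[i]; en <- x$end_s[i]
      }
    }
  }
  tibble(start_s = c(out_s, st), end_s = c(out_e, en))
}

interval_overlap_s <- function(a_start, a_end, b_start, b_end) {
  pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
}

## total seconds of [t0, t1) covered by intervals (assumed normalized)
covered_seconds <- function(intervals, t0, t1) {
  if (is.null(intervals) || nrow(intervals) == 0) return(0)
  sum(interval_overlap_s(intervals$start_s, intervals$end_s, t0, t1))
}

## logical: does [t0,t1) intersect any interval?
intersects_any <- function(intervals, t0, t1) {
  if (is.null(intervals) || nrow(intervals) == 0) return(FALSE)
  any(intervals$start_s < t1 & intervals$end_s > t0)
}

## per-sample logical mask (TRUE = inside an interval) for a signal of n
## samples at `rate`
interval_sample_mask <- function(intervals, n, rate) {
  m <- logical(n)
  if (is.null(intervals) || nrow(intervals) == 0) return(m)
  for (i in seq_len(nrow(intervals))) {
    i0 <- max(1L, floor(intervals$start_s[i] * rate) + 1L)
    i1 <- min(n, ceiling(intervals$end_s[i] * rate))
    if (i1 >= i0) m[i0:i1] <- TRUE
  }
  m
}
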