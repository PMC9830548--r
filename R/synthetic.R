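## Ground-truthed synthetic polysomnography.
##
## The generator realises the staging criteria the pipeline quantifies:
## NREM with high-amplitude delta-dominant EEG and low EMG tone, REM with
## low-amplitude theta-dominant EEG and atonia, wake with low-amplitude
## mixed-frequency EEG and strong EMG. Band-limited EEG content (< 30 Hz)
## is synthesised at a 100 Hz internal rate and interpolated to the native
## rate; EMG is broadband noise generated at the native rate.

#' Generator specification
#'
#' Defaults emulate a heterozygous epileptic mouse: fragmented sleep (mean
#' dwells wake 120 s / NREM 180 s / REM 60 s, log-normal), NREM-preferential
#' spike-wave discharges, NREM spindles, occasional movement artifacts.
#' Component amplitudes are in mV RMS.
#'
#' @param duration_s record length (default 6 h).
#' @param rate native sampling rate in Hz (default 1000; the pipeline
#'   resamples to 200 Hz).
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @param state_params per-state dwell and amplitude parameters.
#' @param event_params per-kind rates (events/hr by state), frequency
#'   ranges, amplitude multipliers vs local baseline, duration ranges.
#' @param artifact_rate movement artifacts per hour of wake.
#' @param sex_effect multiplier on NREM delta amplitude for group F animals
#'   (cohort designs).
#' @param phase_effect multipliers applied in the `post` phase of a
#'   pre/post design: `nrem_dwell` on the NREM mean dwell, `swd_rate` on
#'   SWD/SSWD rates.
#' @param bilateral_frac fraction of injected SWD/SSWD placed on both EEG
#'   channels.
#' @return list of class `generator_spec`.
#' @export
generator_spec <- function(duration_s = 21600, rate = 1000, seed = 1,
                           state_params = NULL, event_params = NULL,
                           artifact_rate = 2, sex_effect = 2,
                           phase_effect = list(nrem_dwell = 1.5,
                                               swd_rate = 1.7),
                           bilateral_frac = 0.9) {
  sp <- state_params %||% list(
    wake = list(dwell_mean_s = 120, dwell_sdlog = 0.6,
                bg_mv = 0.05, delta_mv = 0, theta_mv = 0.015, emg_mv = 0.06),
    NREM = list(dwell_mean_s = 180, dwell_sdlog = 0.6,
                bg_mv = 0.05, delta_mv = 0.18, theta_mv = 0.015,
                emg_mv = 0.008),
    REM = list(dwell_mean_s = 60, dwell_sdlog = 0.6,
               bg_mv = 0.035, delta_mv = 0, theta_mv = 0.055,
               emg_mv = 0.004))
  ep <- event_params %||% list(
    SWD = list(rate_per_hr = c(wake = 30, NREM = 120, REM = 20),
               freq_hz = c(6, 12), amp_mult = 3, dur_s = c(1.5, 6)),
    SSWD = list(rate_per_hr = c(wake = 5, NREM = 15, REM = 0),
                freq_hz = c(3, 6), amp_mult = 3, dur_s = c(1.5, 6)),
    spindle = list(rate_per_hr = c(wake = 0, NREM = 54, REM = 0),
                   freq_hz = c(10, 15), amp_mult = 3, dur_s = c(0.6, 2.5)))
  structure(list(duration_s = duration_s, rate = rate, seed = seed,
                 state_params = sp, event_params = ep,
                 artifact_rate = artifact_rate, sex_effect = sex_effect,
                 phase_effect = phase_effect, bilateral_frac = bilateral_frac,
                 bg_exponent = 0.7, channel_corr = 0.5),
            class = "generator_spec")
}

#' Sample a wake/NREM/REM bout sequence
#'
#' Semi-Markov alternation (wake -> NREM; NREM -> REM or wake; REM -> wake
#' or NREM) with log-normal dwell times truncated at 10 s.
#'
#' @param spec a [generator_spec()].
#' @return tibble of bouts (`start_s`, `end_s`, `state`), covering
#'   `[0, duration_s)`.
#' @export
sample_state_sequence <- function(spec) {
  set.seed(spec$seed)
  sp <- spec$state_params
  trans <- list(wake = c(NREM = 1),
                NREM = c(REM = 0.35, wake = 0.65),
                REM = c(wake = 0.8, NREM = 0.2))
  active <- names(sp)[vapply(sp, function(p) p$dwell_mean_s > 0, logical(1))]
  cur <- if ("wake" %in% active) "wake" else active[1]
  t <- 0
  rows <- list()
  while (t < spec$duration_s) {
    p <- sp[[cur]]
    dwell <- max(10, round(rlnorm(1, log(p$dwell_mean_s) - p$dwell_sdlog^2 / 2,
                                  p$dwell_sdlog)))
    en <- min(t + dwell, spec$duration_s)
    rows[[length(rows) + 1L]] <- tibble(start_s = t, end_s = en, state = cur)
    t <- en
    pr <- trans[[cur]]
    pr <- pr[names(pr) %in% active]
    if (!length(pr)) pr <- setNames(1, cur)
    cur <- sample(names(pr), 1, prob = pr)
  }
  bind_rows(rows)
}

## per-second state labels from a bout table
track_seconds <- function(track, duration_s) {
  sec <- 0:(duration_s - 1)
  track$state[findInterval(sec, track$start_s)]
}

## unit-RMS noise with power spectrum ~ f^-alpha above f0, band-limited to
## [f_lo, f_hi] when given, synthesised by FFT shaping
shaped_noise <- function(n, rate, alpha = 0, f_lo = NULL, f_hi = NULL,
                         f0 = 0.5) {
  X <- fft(rnorm(n))
  f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * rate / n
  g <- rep(1, n)
  if (alpha > 0) g <- 1 / pmax(f, f0)^(alpha / 2)
  if (!is.null(f_lo)) g[f < f_lo] <- 0
  if (!is.null(f_hi)) g[f > f_hi] <- 0
  g[1] <- 0
  x <- Re(fft(X * g, inverse = TRUE) / n)
  x / max(rms(x), .Machine$double.xmin)
}

## smooth per-sample gain for one state: indicator ramped by `ramp_s`
state_gain <- function(sec_state, state, rate_i, n_i, ramp_s = 0.5) {
  ind <- rep(as.numeric(sec_state == state), each = rate_i)[seq_len(n_i)]
  k <- as.integer(round(ramp_s * rate_i))
  if (k < 2) return(ind)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(k) / (k + 1)))
  w <- w / sum(w)
  pad <- c(rep(ind[1], k), ind, rep(ind[length(ind)], k))
  sm <- stats::filter(pad, w, sides = 2)
  as.numeric(sm[(k + 1):(k + n_i)])
}

## correlated channel pair from a shared + two independent unit series
mix_channels <- function(shared, left, right, w) {
  list(left = sqrt(w) * shared + sqrt(1 - w) * left,
       right = sqrt(w) * shared + sqrt(1 - w) * right)
}

#' Synthesise state-conditioned EEG/EMG signals
#'
#' EEG per channel = 1/f-like background plus state-gated band-limited
#' components (delta in NREM, theta in REM), with 0.5 s crossfades at
#' transitions and the two EEG channels sharing half their variance. EMG
#' is broadband noise with state-gated RMS. Movement artifacts (brief
#' high-power EMG+EEG bursts in wake) are added at `artifact_rate` per
#' wake hour and reported in the result's `artifacts`.
#'
#' @param state_track bout table from [sample_state_sequence()].
#' @param spec a [generator_spec()].
#' @return list with `record` (a [signal_record()], no artifact mask set)
#'   and `artifacts` (ground-truth intervals tibble).
#' @export
synth_signals <- function(state_track, spec) {
  set.seed(spec$seed + 1L)
  dur <- spec$duration_s
  rate <- spec$rate
  ri <- 100L
  n_i <- dur * ri
  n <- as.integer(round(dur * rate))
  sp <- spec$state_params
  sec_state <- track_seconds(state_track, dur)

  bg <- mix_channels(shaped_noise(n_i, ri, alpha = spec$bg_exponent, f_hi = 45),
                     shaped_noise(n_i, ri, alpha = spec$bg_exponent, f_hi = 45),
                     shaped_noise(n_i, ri, alpha = spec$bg_exponent, f_hi = 45),
                     spec$channel_corr)
  de <- mix_channels(shaped_noise(n_i, ri, f_lo = 0.8, f_hi = 3.5),
                     shaped_noise(n_i, ri, f_lo = 0.8, f_hi = 3.5),
                     shaped_noise(n_i, ri, f_lo = 0.8, f_hi = 3.5),
                     spec$channel_corr)
  th <- mix_channels(shaped_noise(n_i, ri, f_lo = 6, f_hi = 9.5),
                     shaped_noise(n_i, ri, f_lo = 6, f_hi = 9.5),
                     shaped_noise(n_i, ri, f_lo = 6, f_hi = 9.5),
                     spec$channel_corr)

  amp <- function(field) {
    a <- numeric(n_i)
    for (st in names(sp))
      a <- a + sp[[st]][[field]] * state_gain(sec_state, st, ri, n_i)
    a
  }
  a_bg <- amp("bg_mv"); a_de <- amp("delta_mv"); a_th <- amp("theta_mv")
  t_i <- (seq_len(n_i) - 1) / ri
  t_n <- (seq_len(n) - 1) / rate
  up <- function(x) approx(t_i, x, xout = t_n, rule = 2)$y
  eeg_l <- up(a_bg * bg$left + a_de * de$left + a_th * th$left)
  eeg_r <- up(a_bg * bg$right + a_de * de$right + a_th * th$right)

  a_emg <- numeric(n_i)
  for (st in names(sp))
    a_emg <- a_emg + sp[[st]]$emg_mv * state_gain(sec_state, st, ri, n_i)
  emg <- rnorm(n) * up(a_emg)

  ## movement artifacts in wake
  art <- empty_intervals()
  wake_sec <- which(sec_state == "wake") - 1L
  n_art <- rpois(1, spec$artifact_rate * length(wake_sec) / 3600)
  if (n_art > 0 && length(wake_sec) > 10) {
    onsets <- sort(sample(wake_sec, min(n_art, length(wake_sec))))
    lens <- runif(length(onsets), 2, 5)
    art <- normalize_intervals(
      tibble(start_s = as.numeric(onsets),
             end_s = pmin(dur, onsets + lens)), gap = 2)
    for (i in seq_len(nrow(art))) {
      i0 <- as.integer(art$start_s[i] * rate) + 1L
      i1 <- min(n, as.integer(art$end_s[i] * rate))
      seg <- i0:i1
      w <- spec$state_params$wake
      emg[seg] <- emg[seg] + rnorm(length(seg)) * 10 * w$emg_mv
      burst <- rnorm(length(seg)) * 5 * w$bg_mv
      eeg_l[seg] <- eeg_l[seg] + burst
      eeg_r[seg] <- eeg_r[seg] + burst
    }
  }

  rec <- signal_record(
    channels = list(eeg_left = eeg_l, eeg_right = eeg_r, emg = emg),
    rate = rate,
    roles = c(eeg_left = "eeg_left", eeg_right = "eeg_right", emg = "emg"))
  list(record = rec, artifacts = art)
}

## expected envelope median of the state-conditioned band signal, used to
## scale injected events (envelope of a narrowband Gaussian is Rayleigh;
## median = sigma * sqrt(2 log 2))
state_baseline_mv <- function(spec, state, kind) {
  p <- spec$state_params[[state]]
  bgfrac <- function(lo, hi) {
    a <- spec$bg_exponent
    (hi^(1 - a) - lo^(1 - a)) / (45^(1 - a) - 0.5^(1 - a))
  }
  sigma2 <- if (state == "NREM" && kind != "spindle") {
    p$delta_mv^2 + bgfrac(0.5, 4) * p$bg_mv^2
  } else if (kind == "spindle") {
    bgfrac(10, 15) * p$bg_mv^2 + (if (state == "REM") 0.25 * p$theta_mv^2 else 0)
  } else {
    p$bg_mv^2 + p$delta_mv^2 + p$theta_mv^2
  }
  sqrt(sigma2) * sqrt(2 * log(2))
}

## cosine-ramped event window: flat middle, `ramp_s` raised-cosine ends
event_window <- function(n_samp, rate, ramp_s) {
  k <- min(as.integer(ramp_s * rate), floor(n_samp / 2))
  w <- rep(1, n_samp)
  if (k > 0) {
    r <- 0.5 * (1 - cos(pi * seq_len(k) / k))
    w[seq_len(k)] <- r
    w[(n_samp - k + 1):n_samp] <- rev(r)
  }
  w
}

#' Inject ground-truth events into a synthetic record
#'
#' Event onsets are drawn per state as a Poisson process at the spec rates.
#' SWD/SSWD waveforms are stylised spike-wave cycles (fundamental plus a
#' 0.4-amplitude second harmonic with phase offset) at a frequency drawn in
#' the kind's band, scaled to `amp_mult` times the state-conditioned local
#' baseline envelope, bilateral or unilateral per `bilateral_frac`.
#' Spindles are Tukey-windowed (waxing-waning) sinusoids in 10-15 Hz.
#' Events are thinned so they never overlap on a channel (1 s minimum gap)
#' and only start where at least 10 s of same-state signal exists in the
#' preceding 60 s (so a pre-event baseline is defined).
#'
#' @param record record from [synth_signals()].
#' @param state_track bout table.
#' @param spec a [generator_spec()].
#' @return list: `record` (with events added) and `events` (ground-truth
#'   tibble: onset_s, offset_s, kind, freq_hz, amp_mult, laterality,
#'   state).
#' @export
inject_events <- function(record, state_track, spec) {
  set.seed(spec$seed + 2L)
  rate <- record$rate
  dur <- record_duration(record)
  sec_state <- track_seconds(state_track, floor(dur))
  n_sec <- length(sec_state)
  ## seconds with an established same-state lookback
  eligible <- vapply(seq_len(n_sec), function(s) {
    lo <- max(1L, s - 60L)
    s > 10L && sum(sec_state[lo:(s - 1L)] == sec_state[s]) >= 10L
  }, logical(1))

  placed <- empty_intervals()
  truth <- list()
  kinds <- names(spec$event_params)
  for (kind in kinds) {
    ep <- spec$event_params[[kind]]
    for (st in names(ep$rate_per_hr)) {
      lambda <- ep$rate_per_hr[[st]]
      if (lambda <= 0) next
      pool <- which(sec_state == st & eligible) - 1L
      if (!length(pool)) next
      n_ev <- rpois(1, lambda * sum(sec_state == st) / 3600)
      if (n_ev == 0) next
      onsets <- sort(sample(pool, min(n_ev, length(pool)))) + runif(min(n_ev, length(pool)))
      durs <- runif(length(onsets), ep$dur_s[1], ep$dur_s[2])
      freqs <- runif(length(onsets), ep$freq_hz[1], ep$freq_hz[2])
      for (i in seq_along(onsets)) {
        on <- onsets[i]; off <- min(on + durs[i], dur - 1)
        if (off - on < ep$dur_s[1]) next
        if (intersects_any(placed, on - 1, off + 1)) next  # thinning
        base <- state_baseline_mv(spec, st, kind)
        amp <- ep$amp_mult * base
        i0 <- as.integer(round(on * rate)) + 1L
        i1 <- as.integer(round(off * rate))
        tt <- (0:(i1 - i0)) / rate
        if (kind == "spindle") {
          wav <- amp * sin(2 * pi * freqs[i] * tt) *
            event_window(length(tt), rate, ramp_s = (off - on) / 4)
          lat <- "bilateral"
        } else {
          wav <- amp * (sin(2 * pi * freqs[i] * tt) +
                          0.4 * sin(4 * pi * freqs[i] * tt + 1.2)) *
            event_window(length(tt), rate, ramp_s = 0.15)
          lat <- if (runif(1) < spec$bilateral_frac) "bilateral" else
            sample(c("left", "right"), 1)
        }
        if (lat %in% c("bilateral", "left"))
          record$channels$eeg_left[i0:i1] <- record$channels$eeg_left[i0:i1] + wav
        if (lat %in% c("bilateral", "right"))
          record$channels$eeg_right[i0:i1] <- record$channels$eeg_right[i0:i1] + wav
        placed <- bind_rows(placed, tibble(start_s = on, end_s = off))
        truth[[length(truth) + 1L]] <- tibble(
          onset_s = on, offset_s = off, kind = kind, freq_hz = freqs[i],
          amp_mult = ep$amp_mult, laterality = lat, state = st)
      }
    }
  }
  ev <- if (length(truth)) {
    tv <- bind_rows(truth)
    tv[order(tv$onset_s), ]
  } else {
    tibble(onset_s = numeric(0), offset_s = numeric(0), kind = character(0),
           freq_hz = numeric(0), amp_mult = numeric(0),
           laterality = character(0), state = character(0))
  }
  list(record = record, events = ev)
}

#' Simulate one ground-truthed polysomnography record
#'
#' State sequence, state-conditioned signals, injected events and
#' artifacts, fully reproducible from `spec$seed`.
#'
#' @param spec a [generator_spec()].
#' @return list of class `synthetic_record`: `record` (raw
#'   [signal_record()], native rate, no artifact mask), `truth` (list:
#'   `bouts`, `sec_state`, `events`, `artifacts`, `spec`).
#' @export
simulate_record <- function(spec = generator_spec()) {
  track <- sample_state_sequence(spec)
  sig <- synth_signals(track, spec)
  inj <- inject_events(sig$record, track, spec)
  structure(list(
    record = inj$record,
    truth = list(bouts = track,
                 sec_state = track_seconds(track, floor(spec$duration_s)),
                 events = inj$events, artifacts = sig$artifacts,
                 spec = spec)), class = "synthetic_record")
}

#' Ground-truth hypnogram from a simulated record
#'
#' Applies the same 10-s epoch dominance rule to the true per-second state
#' sequence, so staging output and truth are compared on the same grid.
#'
#' @param truth the `truth` element of [simulate_record()].
#' @param epoch_len_s epoch length.
#' @return a [hypnogram].
#' @export
truth_hypnogram <- function(truth, epoch_len_s = 10) {
  sec <- truth$sec_state
  n_ep <- floor(length(sec) / epoch_len_s)
  lab <- character(n_ep)
  prev <- "wake"
  for (j in seq_len(n_ep)) {
    idx <- ((j - 1) * epoch_len_s + 1):(j * epoch_len_s)
    cnt <- table(factor(sec[idx], levels = states3))
    mx <- max(cnt)
    winners <- names(cnt)[cnt == mx]
    lab[j] <- if (mx > epoch_len_s / 2) winners[1] else
      if (prev %in% winners) prev else winners[1]
    prev <- lab[j]
  }
  epochs <- tibble(epoch = 0:(n_ep - 1), start_s = (0:(n_ep - 1)) * epoch_len_s,
                   end_s = (1:n_ep) * epoch_len_s, state = lab,
                   artifact_frac = 0)
  sub <- tibble(second = 0:(n_ep * epoch_len_s - 1),
                state = sec[seq_len(n_ep * epoch_len_s)])
  new_hypnogram(epochs, sub, epoch_len_s)
}

#' Epoch-level staging accuracy against ground truth
#'
#' Fraction of epochs scored identically, over epochs the scorer did not
#' flag as artifact.
#'
#' @param hyp scored [hypnogram].
#' @param truth_hyp ground-truth hypnogram ([truth_hypnogram()]).
#' @return accuracy in `[0, 1]`.
#' @export
staging_accuracy <- function(hyp, truth_hyp) {
  n <- min(nrow(hyp$epochs), nrow(truth_hyp$epochs))
  a <- hyp$epochs$state[seq_len(n)]
  b <- truth_hyp$epochs$state[seq_len(n)]
  ok <- a != "artifact"
  mean(a[ok] == b[ok])
}

#' Match detected events to ground truth
#'
#' One-to-one greedy matching by onset distance within `onset_tol_s`,
#' requiring the same kind class (SWD/SSWD are both epileptic trains and
#' may be matched across the two kinds when `strict_kind = FALSE`).
#'
#' @param detected detected event tibble.
#' @param truth ground-truth event tibble.
#' @param onset_tol_s onset tolerance (default 0.5 s).
#' @param kinds which truth kinds to evaluate.
#' @param strict_kind require exact kind equality.
#' @return list: `precision`, `recall`, `f1`, `n_detected`, `n_truth`.
#' @export
match_events <- function(detected, truth, onset_tol_s = 0.5,
                         kinds = c("SWD", "SSWD"), strict_kind = FALSE) {
  det <- detected[detected$kind %in% kinds, , drop = FALSE]
  tru <- truth[truth$kind %in% kinds, , drop = FALSE]
  used <- logical(nrow(det))
  matched <- 0L
  for (i in seq_len(nrow(tru))) {
    d_on <- abs(det$onset_s - tru$onset_s[i])
    ok <- which(!used & d_on <= onset_tol_s &
                  (!strict_kind | det$kind == tru$kind[i]))
    if (length(ok)) {
      j <- ok[which.min(d_on[ok])]
      used[j] <- TRUE
      matched <- matched + 1L
    }
  }
  precision <- if (nrow(det)) sum(used) / nrow(det) else 1
  recall <- if (nrow(tru)) matched / nrow(tru) else 1
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       n_detected = nrow(det), n_truth = nrow(tru))
}

#' Simulate a cohort with group and phase effects
#'
#' One record per animal per phase. Per-animal log-normal random effects
#' multiply event rates (sdlog 0.3) and EEG amplitudes (sdlog 0.15);
#' `sex_effect` multiplies the NREM delta amplitude for F animals;
#' `phase_effect` multiplies the NREM dwell mean and SWD/SSWD rates in the
#' `post` phase. All realised per-animal parameters are returned.
#'
#' @param design tibble with columns `genotype`, `sex`, `n` (animals per
#'   cell); optionally an `swd_rate_mult` column scaling that cell's
#'   SWD/SSWD rates (e.g. near-zero for wild types).
#' @param base_spec template [generator_spec()] (its `duration_s`/`rate`
#'   apply to every record).
#' @param seed cohort seed.
#' @param phases character vector, e.g. `"baseline"` or
#'   `c("pre", "post")`.
#' @return tibble: one row per animal x phase with `animal_id`, `genotype`,
#'   `sex`, `phase`, list-columns `record` and `truth`, and the realised
#'   multipliers.
#' @export
make_cohort <- function(design, base_spec = generator_spec(),
                        seed = 1, phases = "baseline") {
  set.seed(seed)
  n_animals <- sum(design$n)
  animal_seeds <- sample.int(2^30, n_animals * (length(phases) + 1L))
  rows <- list()
  aid <- 0L
  si <- 0L
  for (d in seq_len(nrow(design))) {
    cell <- design[d, ]
    for (k in seq_len(cell$n)) {
      aid <- aid + 1L
      si <- si + 1L
      set.seed(animal_seeds[si])
      rate_mult <- rlnorm(1, 0, 0.3)
      amp_mult <- rlnorm(1, 0, 0.15)
      for (ph in phases) {
        si <- si + 1L
        spec <- base_spec
        spec$seed <- animal_seeds[si]
        cell_rate_mult <- if ("swd_rate_mult" %in% names(cell))
          cell$swd_rate_mult else 1
        for (kind in c("SWD", "SSWD")) {
          r <- spec$event_params[[kind]]$rate_per_hr * rate_mult * cell_rate_mult
          if (ph == "post") r <- r * spec$phase_effect$swd_rate
          spec$event_params[[kind]]$rate_per_hr <- r
        }
        for (st in names(spec$state_params)) {
          for (f in c("bg_mv", "delta_mv", "theta_mv"))
            spec$state_params[[st]][[f]] <-
              spec$state_params[[st]][[f]] * amp_mult
        }
        if (cell$sex == "F")
          spec$state_params$NREM$delta_mv <-
            spec$state_params$NREM$delta_mv * spec$sex_effect
        if (ph == "post")
          spec$state_params$NREM$dwell_mean_s <-
            spec$state_params$NREM$dwell_mean_s * spec$phase_effect$nrem_dwell
        sim <- simulate_record(spec)
        rows[[length(rows) + 1L]] <- tibble(
          animal_id = sprintf("a%02d", aid),
          genotype = cell$genotype, sex = cell$sex, phase = ph,
          rate_mult = rate_mult * cell_rate_mult, amp_mult = amp_mult,
          record = list(sim$record), truth = list(sim$truth))
      }
    }
  }
  bind_rows(rows)
}

#' Slow-wave-oscillation induction timing track
#'
#' Optogenetic up/down-state protocol: each cycle is `down_s` of laser
#' (down-state) followed by `up_s` without laser (up-state), with an
#' intracortical pulse of `pulse_s` at the start of each up-state. The
#' standard protocol (0.5 Hz for 10 min: 1800 ms down, 200 ms up) gives
#' 300 cycles and 300 pulses.
#'
#' @param duration_s protocol length (default 600 s).
#' @param period_s cycle period; must equal `down_s + up_s`.
#' @param down_s,up_s down-/up-state durations in seconds.
#' @param pulse_s pulse width in seconds.
#' @return list: `cycles` tibble (laser_on, laser_off, pulse_on,
#'   pulse_off), `n_cycles`, `n_pulses`.
#' @export
swo_protocol_track <- function(duration_s = 600, period_s = 2.0,
                               down_s = 1.8, up_s = 0.2, pulse_s = 0.02) {
  if (abs(down_s + up_s - period_s) > 1e-9)
    abort("down_s + up_s must equal period_s", class = "swd_parameter_error")
  if (pulse_s > up_s)
    abort("pulse_s cannot exceed up_s", class = "swd_parameter_error")
  n_cycles <- as.integer(floor(duration_s / period_s + 1e-9))
  start <- (seq_len(n_cycles) - 1) * period_s
  cycles <- tibble(
    cycle = seq_len(n_cycles),
    laser_on = start,
    laser_off = start + down_s,
    pulse_on = start + down_s,
    pulse_off = start + down_s + pulse_s)
  list(cycles = cycles, n_cycles = n_cycles, n_pulses = n_cycles)
}
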