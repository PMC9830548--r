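# Independent oracles and small fixture builders shared across tests.

# Brute-force sample-by-sample threshold scan: explicit state machine over
# an envelope and per-sample threshold (gap closing, minimum duration),
# written independently of the run-length-encoding path it checks.
brute_force_scan <- function(env, thr, rate, min_dur_s, merge_gap_s) {
  n <- length(env)
  above <- is.finite(thr) & env >= thr
  # close interior sub-threshold gaps shorter than merge_gap_s
  i <- 1L
  while (i <= n) {
    if (!above[i]) {
      j <- i
      while (j <= n && !above[j]) j <- j + 1L
      if (i > 1L && j <= n && (j - i) < merge_gap_s * rate)
        above[i:(j - 1L)] <- TRUE
      i <- j
    } else i <- i + 1L
  }
  out <- list()
  i <- 1L
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j <= n && above[j]) j <- j + 1L
      if ((j - i) >= min_dur_s * rate)
        out[[length(out) + 1L]] <- c((i - 1L) / rate, (j - 1L) / rate)
      i <- j
    } else i <- i + 1L
  }
  if (!length(out))
    return(tibble::tibble(onset_s = numeric(0), offset_s = numeric(0)))
  m <- do.call(rbind, out)
  tibble::tibble(onset_s = m[, 1], offset_s = m[, 2])
}

# Textbook pooled two-sample t statistic.
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tval <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = tval, df = df, p = 2 * pt(-abs(tval), df))
}

paired_t_oracle <- function(a, b) {
  d <- a - b
  tval <- mean(d) / (sd(d) / sqrt(length(d)))
  df <- length(d) - 1
  list(t = tval, df = df, p = 2 * pt(-abs(tval), df))
}

# One-way ANOVA F from the explicit sum-of-squares decomposition.
anova_f_oracle <- function(groups) {
  all_v <- unlist(groups)
  gm <- mean(all_v)
  ss_between <- sum(vapply(groups, function(g)
    length(g) * (mean(g) - gm)^2, numeric(1)))
  ss_within <- sum(vapply(groups, function(g)
    sum((g - mean(g))^2), numeric(1)))
  df1 <- length(groups) - 1
  df2 <- length(all_v) - length(groups)
  f <- (ss_between / df1) / (ss_within / df2)
  list(f = f, df1 = df1, df2 = df2, p = pf(f, df1, df2, lower.tail = FALSE))
}

# A minimal hand-built record: named components, constant rate, roles set.
make_record <- function(eeg_left, eeg_right = eeg_left, emg = NULL, rate = 200) {
  if (is.null(emg)) emg <- numeric(length(eeg_left))
  signal_record(
    channels = list(eeg_left = eeg_left, eeg_right = eeg_right, emg = emg),
    rate = rate,
    roles = c(eeg_left = "eeg_left", eeg_right = "eeg_right", emg = "emg"))
}

# Hypnogram with uniform state labels over n_sec seconds.
uniform_hypnogram <- function(state, n_sec, epoch_len = 10) {
  n_ep <- n_sec %/% epoch_len
  epochs <- tibble::tibble(
    epoch = 0:(n_ep - 1), start_s = (0:(n_ep - 1)) * epoch_len,
    end_s = (1:n_ep) * epoch_len, state = state, artifact_frac = 0)
  sub <- tibble::tibble(second = 0:(n_sec - 1), state = state)
  swdscore:::new_hypnogram(epochs, sub, epoch_len)
}

# Fixed staging thresholds for constructed-feature tests.
manual_thresholds <- function(emg = 1, amp = 1, dfrac = 0.5, ratio = 1.5) {
  structure(list(emg_wake_cut = emg, eeg_amp_cut = amp,
                 delta_frac_cut = dfrac, theta_ratio_cut = ratio),
            class = "staging_thresholds")
}

# One feature row typical of a state, relative to manual_thresholds().
feature_row <- function(state, second, epoch) {
  v <- switch(state,
    wake = list(env = 0.5, delta = 0.3, theta = 0.3, total = 1.0, emg = 10),
    NREM = list(env = 2.0, delta = 0.8, theta = 0.2, total = 1.0, emg = 0.1),
    REM  = list(env = 0.5, delta = 0.15, theta = 0.75, total = 1.0, emg = 0.05))
  tibble::tibble(second = second, epoch = epoch, eeg_env = v$env,
                 delta_pow = v$delta, theta_pow = v$theta,
                 total_pow = v$total, delta_frac = v$delta / v$total,
                 theta_ratio = v$theta / v$delta, emg_rms = v$emg,
                 artifact_frac = 0)
}

features_from_states <- function(states) {
  dplyr::bind_rows(lapply(seq_along(states), function(i)
    feature_row(states[i], i - 1L, (i - 1L) %/% 10L)))
}
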