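test_that("state sequences follow the dwell-time design", {
  spec <- generator_spec(duration_s = 259200, seed = 51)
  track <- sample_state_sequence(spec)
  expect_equal(track$start_s[1], 0)
  expect_equal(max(track$end_s), 259200)
  expect_true(all(track$end_s > track$start_s))
  # renewal expectation: total state time / mean dwell, within 15%
  for (st in c("wake", "NREM", "REM")) {
    bouts <- sum(track$state == st)
    tot <- sum(track$end_s[track$state == st] - track$start_s[track$state == st])
    expected <- tot / spec$state_params[[st]]$dwell_mean_s
    expect_lt(abs(bouts - expected) / expected, 0.15)
  }
  # consecutive bouts always change state
  expect_true(all(track$state[-1] != track$state[-nrow(track)]))
})

test_that("degenerate and deterministic state sequences", {
  one <- generator_spec(duration_s = 3600, seed = 52)
  one$state_params$NREM$dwell_mean_s <- 0
  one$state_params$REM$dwell_mean_s <- 0
  track <- sample_state_sequence(one)
  expect_equal(unique(track$state), "wake")

  spec <- generator_spec(duration_s = 7200, seed = 53)
  expect_identical(sample_state_sequence(spec), sample_state_sequence(spec))
})

test_that("synthesised signals realise the staging criteria", {
  spec <- generator_spec(duration_s = 1800, rate = 200, seed = 54)
  track <- sample_state_sequence(spec)
  sig <- synth_signals(track, spec)
  feats <- compute_epoch_features(sig$record)
  states <- swdscore:::track_seconds(track, 1800)[seq_len(nrow(feats))]
  # NREM delta dominance in >= 90% of NREM sub-epochs
  expect_gte(mean(feats$delta_frac[states == "NREM"] > 0.5), 0.9)
  # wake EMG tone >> sleep EMG tone
  expect_gt(median(feats$emg_rms[states == "wake"]),
            3 * median(feats$emg_rms[states == "NREM"]))
  # REM is theta-dominant
  expect_gt(median(feats$theta_ratio[states == "REM"]), 1.5)
})

test_that("zero-amplitude spec produces a zero record", {
  spec <- generator_spec(duration_s = 600, rate = 200, seed = 55,
                         artifact_rate = 0)
  for (st in names(spec$state_params)) {
    spec$state_params[[st]]$bg_mv <- 0
    spec$state_params[[st]]$delta_mv <- 0
    spec$state_params[[st]]$theta_mv <- 0
    spec$state_params[[st]]$emg_mv <- 0
  }
  track <- sample_state_sequence(spec)
  sig <- synth_signals(track, spec)
  expect_equal(max(abs(sig$record$channels$eeg_left)), 0)
  expect_equal(max(abs(sig$record$channels$emg)), 0)
})

test_that("event injection follows Poisson counts and the bilateral fraction", {
  spec <- generator_spec(duration_s = 7200, rate = 200, seed = 56,
                         bilateral_frac = 1)
  spec$state_params$wake$dwell_mean_s <- 0
  spec$state_params$REM$dwell_mean_s <- 0
  spec$event_params$SWD$rate_per_hr <- c(wake = 0, NREM = 100, REM = 0)
  spec$event_params$SSWD$rate_per_hr <- c(wake = 0, NREM = 0, REM = 0)
  spec$event_params$spindle$rate_per_hr <- c(wake = 0, NREM = 0, REM = 0)
  sim <- simulate_record(spec)
  n <- nrow(sim$truth$events)
  lambda <- 200
  expect_lt(abs(n - lambda), 3 * sqrt(lambda))
  expect_true(all(sim$truth$events$laterality == "bilateral"))
  expect_true(all(sim$truth$events$state == "NREM"))
  # injected events respect their kind's band and duration rules
  expect_true(all(sim$truth$events$freq_hz >= 6 & sim$truth$events$freq_hz <= 12))
  expect_true(all(sim$truth$events$offset_s - sim$truth$events$onset_s > 1))
})

test_that("simulation is byte-identical under a fixed seed", {
  spec <- generator_spec(duration_s = 600, rate = 200, seed = 57)
  a <- simulate_record(spec)
  b <- simulate_record(spec)
  expect_identical(a$record$channels, b$record$channels)
  expect_identical(a$truth$events, b$truth$events)
  expect_identical(a$truth$bouts, b$truth$bouts)
})

test_that("cohort designs apply sex and phase effects by construction", {
  design <- tibble::tibble(genotype = "het", sex = c("M", "F"), n = c(2, 2))
  base <- generator_spec(duration_s = 60, rate = 200, seed = 1)
  coh <- make_cohort(design, base, seed = 58, phases = c("pre", "post"))
  expect_equal(nrow(coh), 8)
  # generator-truth NREM delta amplitude ratio F/M equals sex_effect
  # exactly, after removing the per-animal amplitude random effect
  delta <- vapply(coh$truth, function(tr)
    tr$spec$state_params$NREM$delta_mv, numeric(1))
  adj <- delta / coh$amp_mult
  expect_equal(mean(adj[coh$sex == "F"]) / mean(adj[coh$sex == "M"]),
               base$sex_effect, tolerance = 1e-12)
  # phase effect multiplies the injected NREM SWD rate per animal
  rate_of <- function(tr) tr$spec$event_params$SWD$rate_per_hr[["NREM"]]
  pre <- vapply(coh$truth[coh$phase == "pre"], rate_of, numeric(1))
  post <- vapply(coh$truth[coh$phase == "post"], rate_of, numeric(1))
  expect_equal(post / pre, rep(base$phase_effect$swd_rate, 4),
               tolerance = 1e-12)
})

test_that("the SWO induction protocol timing is exact", {
  tr <- swo_protocol_track()
  expect_identical(tr$n_cycles, 300L)
  expect_identical(tr$n_pulses, 300L)
  expect_equal(max(tr$cycles$laser_on) + 2.0, 600)
  expect_equal(tr$cycles$pulse_on, tr$cycles$laser_off)
  expect_equal(tr$cycles$pulse_off - tr$cycles$pulse_on,
               rep(0.02, 300))

  short <- swo_protocol_track(duration_s = 4)
  expect_identical(short$n_cycles, 2L)
  expect_error(swo_protocol_track(down_s = 1.9, up_s = 0.2, period_s = 2.0),
               class = "swd_parameter_error")
})
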