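test_that("epoch features separate synthetic NREM and wake segments", {
  spec <- generator_spec(duration_s = 1800, rate = 200, seed = 21)
  track <- sample_state_sequence(spec)
  sig <- synth_signals(track, spec)
  rec <- sig$record
  feats <- compute_epoch_features(rec)
  states <- swdscore:::track_seconds(track, 1800)[seq_len(nrow(feats))]
  nrem <- feats$delta_frac[states == "NREM"]
  expect_gt(mean(nrem > 0.5), 0.9)
  wake_emg <- feats$emg_rms[states == "wake"]
  q90 <- quantile(feats$emg_rms, 0.9)
  expect_gt(mean(wake_emg >= quantile(feats$emg_rms, 0.5)), 0.95)
  expect_gt(median(wake_emg), 3 * median(feats$emg_rms[states == "NREM"]))
})

test_that("features of a zero record are zero and short records error", {
  rec <- make_record(numeric(4000), rate = 200)
  feats <- compute_epoch_features(rec)
  expect_equal(max(feats$delta_pow), 0)
  expect_equal(max(feats$total_pow), 0)
  expect_equal(max(feats$eeg_env), 0)
  expect_equal(max(feats$delta_frac), 0)  # 0/0 defined as 0
  expect_error(compute_epoch_features(make_record(numeric(1000), rate = 200)),
               class = "swd_input_error")
})

test_that("threshold calibration splits bimodal EMG and honours overrides", {
  set.seed(22)
  n <- 3600
  lab <- rep(c("wake", "NREM"), each = 1) [sample.int(2, n, replace = TRUE)]
  emg <- ifelse(lab == "wake", rlnorm(n, log(0.06), 0.2),
                rlnorm(n, log(0.006), 0.2))
  feats <- tibble::tibble(second = 0:(n - 1), epoch = (0:(n - 1)) %/% 10,
                          eeg_env = rnorm(n, 1, 0.1), delta_pow = 1,
                          theta_pow = 1, total_pow = 2, delta_frac = 0.5,
                          theta_ratio = 1, emg_rms = emg, artifact_frac = 0)
  th <- calibrate_thresholds(feats)
  pred_wake <- emg > th$emg_wake_cut
  expect_gt(mean(pred_wake == (lab == "wake")), 0.95)

  cfg <- swd_config(staging = list(delta_frac_cut = 0.6))
  th2 <- calibrate_thresholds(feats, cfg)
  expect_equal(th2$delta_frac_cut, 0.6)
  expect_equal(th2$theta_ratio_cut, 1.5)

  const <- dplyr::mutate(feats, emg_rms = 1, eeg_env = 1)
  expect_error(calibrate_thresholds(const), class = "swd_calibration_error")
})

test_that("dominance rule: >5 s wins the epoch, 5/5 ties keep the previous state", {
  th <- manual_thresholds()
  # epoch 0 fully NREM, epoch 1: 7 s NREM + 3 s wake -> NREM
  feats <- features_from_states(c(rep("NREM", 10), rep("NREM", 7), rep("wake", 3)))
  hyp <- score_epochs(feats, th)
  expect_equal(hyp$epochs$state, c("NREM", "NREM"))

  # 5/5 split follows the previous epoch (NREM), then a wake context 5/5
  feats2 <- features_from_states(c(rep("NREM", 10), rep("NREM", 5), rep("wake", 5),
                                   rep("wake", 10), rep("wake", 5), rep("NREM", 5)))
  hyp2 <- score_epochs(feats2, th)
  expect_equal(hyp2$epochs$state, c("NREM", "NREM", "wake", "wake"))
})

test_that("dominance property: 6 of 10 sub-epochs force any epoch label", {
  th <- manual_thresholds()
  for (st in c("wake", "NREM", "REM")) {
    others <- setdiff(c("wake", "NREM", "REM"), st)
    states <- c(rep(st, 6), others[c(1, 2, 1, 2)])
    for (perm in 1:3) {
      set.seed(perm)
      hyp <- score_epochs(features_from_states(sample(states)), th)
      expect_equal(hyp$epochs$state, st)
    }
  }
})

test_that("epochs overlapping artifacts by >50% are labeled artifact", {
  th <- manual_thresholds()
  feats <- features_from_states(rep("NREM", 20))
  feats$artifact_frac[1:6] <- 1
  hyp <- score_epochs(feats, th)
  expect_equal(hyp$epochs$state, c("artifact", "NREM"))
})

test_that("state metrics: durations, bouts and transitions match enumeration", {
  lab <- c("NREM", "NREM", "wake", "NREM", "REM", "wake")
  hyp <- uniform_hypnogram("NREM", 60)
  hyp$epochs$state <- lab
  sm <- summarize_states(hyp)
  d <- sm$durations
  expect_equal(d$seconds[d$state == "NREM"], 30)
  expect_equal(d$bouts[d$state == "NREM"], 2)
  expect_equal(transition_count(sm, "NREM", "wake"), 1)
  expect_equal(transition_count(sm, "wake", "NREM"), 1)
  expect_equal(transition_count(sm, "NREM", "REM"), 1)
  expect_equal(transition_count(sm, "REM", "wake"), 1)
  expect_equal(sum(sm$transitions$n), 4)

  all_n <- uniform_hypnogram("NREM", 100)
  smn <- summarize_states(all_n)
  expect_equal(smn$durations$bouts[smn$durations$state == "NREM"], 1)
  expect_equal(nrow(smn$transitions), 0)
})

test_that("durations plus artifact time conserve the hypnogram span", {
  set.seed(23)
  lab <- sample(c("wake", "NREM", "REM", "artifact"), 200, replace = TRUE)
  hyp <- uniform_hypnogram("NREM", 2000)
  hyp$epochs$state <- lab
  sm <- summarize_states(hyp)
  expect_identical(sum(sm$durations$seconds) + sm$artifact_s, sm$total_s)
  expect_identical(sm$total_s, 2000)
})

test_that("staging recovers ground truth on a short synthetic record", {
  spec <- generator_spec(duration_s = 2400, rate = 200, seed = 24)
  sim <- simulate_record(spec)
  pre <- preprocess_record(sim$record)
  hyp <- stage_record(pre)
  acc <- staging_accuracy(hyp, truth_hypnogram(sim$truth))
  expect_gte(acc, 0.95)
})
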