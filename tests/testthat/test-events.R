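test_that("baseline estimation returns the envelope of the preceding signal", {
  rate <- 200
  t <- (0:(80 * rate - 1)) / rate
  A <- 0.4
  x <- A * sin(2 * pi * 2 * t)
  hyp <- uniform_hypnogram("NREM", 80)
  b <- estimate_baseline(x, rate, t = 60, hyp = hyp)
  expect_s3_class(b, "baseline_estimate")
  expect_equal(b$value, A, tolerance = 0.05)
  expect_equal(b$state, "NREM")
  expect_equal(b$band, c(0.5, 4))

  b0 <- estimate_baseline(numeric(80 * rate), rate, t = 60, hyp = hyp)
  expect_equal(b0$value, 0)

  # lookback fully occupied by prior events -> rejected (NULL)
  busy <- tibble::tibble(onset_s = 0, offset_s = 80)
  expect_null(estimate_baseline(x, rate, t = 60, hyp = hyp, events = busy))
})

test_that("band-limited threshold detection finds injected trains", {
  rate <- 200
  n <- 60 * rate
  t <- (0:(n - 1)) / rate
  base <- 0.1
  mk_train <- function(amp, from, dur) {
    y <- numeric(n)
    idx <- (from * rate):((from + dur) * rate - 1) + 1
    y[idx] <- amp * sin(2 * pi * 8 * t[idx])
    y
  }
  x <- mk_train(3 * base, 20, 2.5)
  ev <- detect_band_events(x, rate, c(6, 12), threshold_mult = 1.5,
                           baseline = base, min_dur_s = 1, merge_gap_s = 0.3)
  expect_equal(nrow(ev), 1)
  expect_gte(ev$offset_s - ev$onset_s, 2.0)
  expect_lte(ev$offset_s - ev$onset_s, 3.0)

  weak <- mk_train(1.2 * base, 20, 2.5)
  expect_equal(nrow(detect_band_events(weak, rate, c(6, 12), 1.5, base)), 0)

  two <- mk_train(3 * base, 20, 0.8) + mk_train(3 * base, 21, 0.8)
  ev2 <- detect_band_events(two, rate, c(6, 12), 1.5, base,
                            min_dur_s = 1, merge_gap_s = 0.3)
  expect_equal(nrow(ev2), 1)
})

test_that("detection equals a brute-force sample-by-sample scan", {
  rate <- 200
  set.seed(31)
  for (rep in 1:20) {
    x <- rnorm(60 * rate, sd = 0.05)
    # sprinkle a few strong bursts
    for (k in seq_len(sample(0:3, 1))) {
      at <- runif(1, 5, 50); dur <- runif(1, 0.5, 3)
      idx <- (at * rate):((at + dur) * rate)
      x[idx] <- x[idx] + 0.4 * sin(2 * pi * runif(1, 6, 12) * idx / rate)
    }
    base_sec <- runif(60, 0.03, 0.08)
    mult <- sample(c(1.5, 2), 1)
    got <- detect_band_events(x, rate, c(6, 12), mult, base_sec,
                              min_dur_s = 0.5, merge_gap_s = 0.3)
    env <- band_envelope(x, rate, 6, 12)
    thr <- rep(mult * base_sec, each = rate)[seq_along(env)]
    want <- brute_force_scan(env, thr, rate, min_dur_s = 0.5,
                             merge_gap_s = 0.3)
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("raising the threshold multiplier never increases event count", {
  rate <- 200
  set.seed(32)
  x <- rnorm(120 * rate, sd = 0.05)
  for (at in c(20, 50, 80)) {
    idx <- (at * rate):((at + 2) * rate)
    x[idx] <- x[idx] + 0.25 * sin(2 * pi * 9 * idx / rate)
  }
  counts <- vapply(c(1.5, 2, 3), function(m)
    nrow(detect_band_events(x, rate, c(6, 12), m, 0.05)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("onset/offset refinement extends to the baseline crossing", {
  rate <- 200
  n <- 20 * rate
  t <- (0:(n - 1)) / rate
  base <- 0.1
  x <- numeric(n)
  # 0.1 s sub-threshold ramp before the envelope crossing at t = 10
  ramp <- ((10 - 0.1) * rate):(10 * rate - 1) + 1
  x[ramp] <- seq(0.02, 0.28, length.out = length(ramp)) *
    sin(2 * pi * 8 * t[ramp])
  body <- (10 * rate):(12 * rate) + 1
  x[body] <- 0.3 * sin(2 * pi * 8 * t[body])
  ref <- refine_onset_offset(10, 12, x, rate, base)
  expect_lte(ref$onset_s, 10)
  expect_gte(ref$onset_s, 10 - 0.15)
  expect_gte(ref$offset_s, 12)

  # |signal| exactly at baseline throughout the margin: boundary case
  y <- rep(base, n)
  ref2 <- refine_onset_offset(10, 12, y, rate, base)
  expect_lte(abs(ref2$onset_s - 10), 1.5 / rate)
  expect_lte(abs(ref2$offset_s - 12), 1.5 / rate)

  # refinement never shrinks the candidate
  set.seed(33)
  z <- rnorm(n, sd = 0.2)
  for (k in 1:10) {
    on <- runif(1, 2, 15); off <- on + runif(1, 1, 3)
    r <- refine_onset_offset(on, off, z, rate, 0.1)
    expect_lte(r$onset_s, on)
    expect_gte(r$offset_s, off + 0)
  }
})

test_that("laterality classification merges concordant events", {
  mk <- function(on, off) tibble::tibble(onset_s = on, offset_s = off,
                                         kind = "SWD")
  same <- classify_laterality(mk(5, 7), mk(5, 7))
  expect_equal(nrow(same), 1)
  expect_equal(same$laterality, "bilateral")
  expect_equal(c(same$onset_s, same$offset_s), c(5, 7))

  disjoint <- classify_laterality(mk(5, 7), mk(9, 11))
  expect_equal(nrow(disjoint), 2)
  expect_setequal(disjoint$laterality, c("left", "right"))

  # 60% overlap of the shorter event -> bilateral spanning the union
  b60 <- classify_laterality(mk(0, 1), mk(0.4, 1.4))
  expect_equal(b60$laterality, "bilateral")
  expect_equal(c(b60$onset_s, b60$offset_s), c(0, 1.4))
  b40 <- classify_laterality(mk(0, 1), mk(0.6, 1.6))
  expect_equal(nrow(b40), 2)
})

test_that("detect_swd classifies band membership and needs a staged record", {
  rate <- 200
  set.seed(34)
  n <- 600 * rate
  t <- (0:(n - 1)) / rate
  bg_l <- rnorm(n, sd = 0.03)
  bg_r <- rnorm(n, sd = 0.03)
  idx <- (300 * rate):(303 * rate)
  train <- 0.5 * sin(2 * pi * 4.5 * t[idx])
  rec <- make_record(bg_l + replace(numeric(n), idx, train),
                     bg_r + replace(numeric(n), idx, train),
                     emg = rnorm(n, sd = 0.005), rate = rate)
  hyp <- uniform_hypnogram("NREM", 600)
  ev <- detect_swd(rec, hyp)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "SSWD")
  expect_equal(ev$laterality, "bilateral")
  expect_equal(ev$state, "NREM")
  expect_gte(ev$peak_freq_hz, 3)
  expect_lte(ev$peak_freq_hz, 6)

  # event-free record -> no events
  rec0 <- make_record(bg_l, bg_r, emg = rnorm(n, sd = 0.005), rate = rate)
  expect_equal(nrow(detect_swd(rec0, hyp)), 0)

  expect_error(detect_swd(rec, NULL), class = "swd_precondition_error")
})

test_that("spindle detection applies amplitude and duration gates", {
  rate <- 200
  set.seed(35)
  n <- 240 * rate
  t <- (0:(n - 1)) / rate
  bg <- function() rnorm(n, sd = 0.03)
  base_env <- band_envelope(bg(), rate, 10, 15)
  mu <- mean(base_env); sg <- sd(base_env)

  inject <- function(x, at, dur, peak, f = 12) {
    idx <- (at * rate):((at + dur) * rate - 1) + 1
    w <- swdscore:::event_window(length(idx), rate, ramp_s = dur / 4)
    x[idx] <- x[idx] + peak * w * sin(2 * pi * f * t[idx])
    x
  }
  hyp <- uniform_hypnogram("NREM", 240)

  # 1.5 s spindle with peak 4 SD above the baseline mean on both channels
  l <- inject(bg(), 60, 1.5, mu + 4 * sg)
  r <- inject(bg(), 60, 1.5, mu + 4 * sg)
  rec <- make_record(l, r, emg = rnorm(n, sd = 0.005), rate = rate)
  sp <- detect_spindles(rec, hyp)
  hit <- sp[abs(sp$onset_s - 60) < 1, ]
  expect_equal(nrow(hit), 1)
  expect_gte(hit$duration_s, 1.0)
  expect_lte(hit$duration_s, 2.0)
  expect_equal(hit$kind, "spindle")
  expect_equal(hit$state, "NREM")

  # 0.3 s burst: too short; 6 s continuous tone: too long (independent
  # background noise per channel, common injected waveform)
  l2 <- inject(bg(), 60, 0.3, mu + 6 * sg)
  r2 <- inject(bg(), 60, 0.3, mu + 6 * sg)
  rec2 <- make_record(l2, r2, emg = rnorm(n, sd = 0.005), rate = rate)
  expect_equal(nrow(detect_spindles(rec2, hyp)), 0)

  idx6 <- (60 * rate):(66 * rate)
  tone <- (mu + 10 * sg) * sin(2 * pi * 12 * t[idx6])
  x3 <- bg(); x3[idx6] <- x3[idx6] + tone
  y3 <- bg(); y3[idx6] <- y3[idx6] + tone
  rec3 <- make_record(x3, y3, emg = rnorm(n, sd = 0.005), rate = rate)
  expect_equal(nrow(detect_spindles(rec3, hyp)), 0)

  # spindles overlapping a detected SWD are discarded
  swd <- tibble::tibble(onset_s = 59.5, offset_s = 62, duration_s = 2.5,
                        kind = "SWD", band_lo_hz = 6, band_hi_hz = 12,
                        peak_freq_hz = 8, laterality = "bilateral",
                        state = "NREM")
  expect_equal(nrow(detect_spindles(rec, hyp, swd_events = swd)), 0)
})

test_that("events take the vigilance state at onset", {
  hyp <- uniform_hypnogram("NREM", 100)
  hyp$epochs$state[10] <- "wake"
  hyp$sub$state[91:100] <- "wake"
  ev <- tibble::tibble(onset_s = c(15, 85), offset_s = c(17, 95))
  got <- assign_state(ev, hyp)
  expect_equal(got$state, c("NREM", "NREM"))  # second event straddles into wake
  got2 <- assign_state(tibble::tibble(onset_s = 92, offset_s = 99), hyp)
  expect_equal(got2$state, "wake")
  expect_error(assign_state(tibble::tibble(onset_s = 150, offset_s = 151), hyp),
               class = "swd_input_error")
})

test_that("detection is deterministic for identical input and config", {
  spec <- generator_spec(duration_s = 900, rate = 200, seed = 36)
  run_once <- function() {
    sim <- simulate_record(spec)
    pre <- preprocess_record(sim$record)
    hyp <- stage_record(pre)
    detect_events(pre, hyp)
  }
  a <- run_once()
  b <- run_once()
  expect_identical(a, b)
})
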