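mk_sm <- function(nrem_s = 360, rem_s = 0, wake_s = 0) {
  structure(list(
    durations = tibble::tibble(state = c("wake", "NREM", "REM"),
                               seconds = c(wake_s, nrem_s, rem_s),
                               bouts = c(1, 1, 1)),
    transitions = tibble::tibble(from = character(0), to = character(0),
                                 n = integer(0)),
    artifact_s = 0, total_s = nrem_s + rem_s + wake_s),
    class = "state_metrics")
}

mk_events <- function(n, total_dur, state = "NREM", kind = "SWD") {
  tibble::tibble(onset_s = seq_len(n), offset_s = seq_len(n) + total_dur / n,
                 duration_s = rep(total_dur / n, n), kind = kind,
                 band_lo_hz = 6, band_hi_hz = 12, peak_freq_hz = 8,
                 laterality = "bilateral", state = state)
}

test_that("incidence metrics reproduce exact hand-computed normalisations", {
  # 12 SWDs totalling 30 s in 0.1 h of NREM
  inc <- incidence_metrics(mk_events(12, 30), mk_sm(nrem_s = 360))
  r <- inc[inc$state == "NREM", ]
  expect_identical(r$events_per_hr, 12 / 0.1)
  expect_identical(r$event_dur_s_per_hr, 30 / 0.1)
  expect_identical(r$event_pct_of_state, 30 / 360 * 100)
  expect_equal(r$event_pct_of_state, 8.33, tolerance = 1e-3)

  none <- incidence_metrics(empty_events(), mk_sm())
  expect_true(all(none$events_per_hr == 0))
  expect_true(all(none$event_pct_of_state == 0))

  bad <- mk_events(2, 4, state = "REM")
  expect_error(incidence_metrics(bad, mk_sm(rem_s = 0)),
               class = "swd_consistency_error")
})

test_that("spindle density is count over NREM seconds", {
  sp <- mk_events(10, 20, kind = "spindle")
  expect_identical(spindle_density(sp, mk_sm(nrem_s = 1000)), 0.01)
  expect_identical(spindle_density(empty_events(), mk_sm(nrem_s = 500)), 0)
  expect_error(spindle_density(sp, mk_sm(nrem_s = 0, wake_s = 100)),
               class = "swd_input_error")
})

test_that("t statistics match explicit-formula oracles to 1e-10", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  gc <- compare_groups(a, b)
  want <- pooled_t_oracle(a, b)
  expect_equal(gc$statistic, want$t, tolerance = 1e-10)
  expect_equal(gc$p_value, want$p, tolerance = 1e-10)
  expect_equal(abs(gc$statistic), 3.674, tolerance = 1e-3)
  expect_lt(abs(gc$p_value - 0.021), 5e-4)
  expect_equal(gc$groups$sem, c(sd(a) / sqrt(3), sd(b) / sqrt(3)))

  set.seed(41)
  for (k in 1:10) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1))
    expect_equal(compare_groups(x, y)$statistic, pooled_t_oracle(x, y)$t,
                 tolerance = 1e-10)
    z <- rnorm(length(x))
    got <- compare_groups(x, x + z, paired = TRUE)
    want <- paired_t_oracle(x, x + z)
    expect_equal(got$statistic, want$t, tolerance = 1e-10)
    expect_equal(got$p_value, want$p, tolerance = 1e-10)
  }
})

test_that("degenerate and directional t behaviour", {
  a <- c(1, 2, 3)
  gc <- compare_groups(a, a, paired = TRUE)
  expect_true(gc$degenerate)
  expect_identical(gc$p_value, 1)
  expect_identical(gc$statistic, 0)

  up <- compare_groups(a + 2, a, paired = TRUE)
  dn <- compare_groups(a - 2, a, paired = TRUE)
  expect_gt(up$statistic, 0)
  expect_lt(dn$statistic, 0)
  expect_error(compare_groups(1, c(1, 2)), class = "swd_input_error")
  expect_error(compare_groups(c(1, 2, 3), c(1, 2), paired = TRUE),
               class = "swd_input_error")
})

test_that("one-way ANOVA matches the sum-of-squares decomposition", {
  groups <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(10, 11, 12))
  gc <- anova_oneway(groups)
  want <- anova_f_oracle(groups)
  expect_equal(gc$statistic, want$f, tolerance = 1e-10)
  expect_equal(gc$p_value, want$p, tolerance = 1e-10)

  same <- anova_oneway(list(x = c(1, 1, 1), y = c(1, 1, 1), z = c(1, 1, 1)))
  expect_identical(same$statistic, 0)
  expect_identical(same$p_value, 1)

  set.seed(42)
  for (k in 1:5) {
    gs <- lapply(1:4, function(i) rnorm(sample(3:8, 1), mean = i / 2))
    names(gs) <- letters[1:4]
    expect_equal(anova_oneway(gs)$statistic, anova_f_oracle(gs)$f,
                 tolerance = 1e-10)
  }
  expect_error(anova_oneway(list(a = 1:3)), class = "swd_input_error")
})

test_that("Holm-Sidak adjustment dominates raw p and is rank-monotone", {
  set.seed(43)
  for (k in 1:10) {
    p <- runif(sample(2:8, 1))
    adj <- holm_sidak_adjust(p)
    expect_true(all(adj >= p - 1e-12))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))
    expect_true(all(adj <= 1))
  }
  gc <- anova_oneway(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(10, 11, 12)))
  expect_true(all(gc$pairwise$p_adj >= gc$pairwise$p_raw - 1e-12))
})

test_that("Holm-Sidak keeps family-wise error near the nominal level", {
  set.seed(44)
  n_rep <- 2000
  m <- 4
  fwer <- mean(vapply(seq_len(n_rep), function(r) {
    p <- vapply(seq_len(m), function(j)
      t.test(rnorm(6), rnorm(6), var.equal = TRUE)$p.value, numeric(1))
    any(holm_sidak_adjust(p) < 0.05)
  }, logical(1)))
  mc_err <- 3 * sqrt(0.05 * 0.95 / n_rep)
  expect_lte(fwer, 0.05 + mc_err)
})

test_that("cohort report flags designed effects and validates the design", {
  set.seed(45)
  animals <- tibble::tibble(
    animal_id = sprintf("a%02d", 1:12),
    genotype = rep(c("wt", "het"), each = 6),
    swd_per_hr_NREM = c(rnorm(6, 5, 2), rnorm(6, 120, 25)))
  cmp <- tibble::tibble(metric = "swd_per_hr_NREM", by = "genotype",
                        test = "unpaired_t")
  rep1 <- cohort_report(animals, cmp)
  expect_true(rep1$significant)

  same <- dplyr::mutate(animals, swd_per_hr_NREM = rep(c(1, 2, 3), 4))
  rep2 <- cohort_report(same, cmp)
  expect_false(rep2$significant)

  expect_error(cohort_report(animals,
    tibble::tibble(metric = "nope", by = "genotype", test = "unpaired_t")),
    class = "swd_config_error")
  expect_error(cohort_report(animals,
    tibble::tibble(metric = "swd_per_hr_NREM", by = "nope", test = "unpaired_t")),
    class = "swd_config_error")
})

test_that("tidy and glance summarise fitted comparisons", {
  gc <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  td <- generics::tidy(gc)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$test, "unpaired_t")
  gl <- generics::glance(gc)
  expect_equal(gl$n_total, 6)
})
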