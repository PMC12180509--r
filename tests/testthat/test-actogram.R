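test_that("onset detection finds exact threshold crossings on square waves", {
  rec <- square_wave_record(5, onset_h = 12)
  ons <- detect_onsets(rec)
  expect_false(any(ons$flagged))
  expect_equal(ons$onset_h, rep(12, 5))

  expect_error(detect_onsets(square_wave_record(2)), "3 days")
  all_zero <- activity_record(rep(0L, 4 * 288))
  oz <- detect_onsets(all_zero)
  expect_true(all(oz$flagged))
})

test_that("detected onsets track a drifting free-running period", {
  cfg <- sim_config(seed = 13, tau_h = 23.7, onset_jitter_sd_h = 0,
                    injected_shift_h = 0, poisson_noise = FALSE,
                    mean_counts_rest = 0)
  ons <- detect_onsets(simulate_actogram(cfg)$record)
  expect_false(any(ons$flagged))
  # successive onsets drop by tau - 24 = -0.3 h/day within bin quantisation
  expect_lt(abs(mean(diff(ons$onset_h)) + 0.3), 0.05)
})

test_that("onset regression recovers exact lines and extrapolates", {
  # onsets exactly on a line with slope -0.3
  ons <- data.frame(day_index = -3:-1, onset_h = c(12.0, 11.7, 11.4),
                    flagged = FALSE)
  class(ons) <- c("onset_series", class(ons))
  fit <- fit_onset_regression(ons, event_day = 0)
  expect_equal(fit$slope_h_per_day, -0.3, tolerance = 1e-12)
  expect_equal(fit$intercept_h, 11.1, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$period_h, 23.7, tolerance = 1e-12)

  # flagged days carry no weight
  ons2 <- rbind(ons, data.frame(day_index = 0, onset_h = 5, flagged = TRUE))
  class(ons2) <- c("onset_series", class(ons2))
  fit2 <- fit_onset_regression(ons2, event_day = 0)
  expect_equal(fit2$intercept_h, fit$intercept_h)

  expect_error(fit_onset_regression(ons[1:2, ], event_day = 0), "3 usable")
})

test_that("onset unwrapping crosses midnight correctly", {
  ons <- data.frame(day_index = 1:4, onset_h = c(23.5, 23.9, 0.3, 0.7),
                    flagged = FALSE)
  class(ons) <- c("onset_series", class(ons))
  fit <- fit_onset_regression(ons, event_day = 1)
  expect_equal(fit$slope_h_per_day, 0.4, tolerance = 1e-9)
})

test_that("phase_shift applies the delay-negative sign convention", {
  mkfit <- function(intercept, slope = -0.3, ev = 0)
    structure(list(slope_h_per_day = slope, intercept_h = intercept,
                   r2 = 1, n = 7, period_h = 24 + slope, event_day = ev),
              class = "onset_fit")
  expect_equal(phase_shift(mkfit(11.1), mkfit(11.1))$shift_h, 0)
  # post onsets uniformly 0.4 h later -> delay of 0.4 h
  d <- phase_shift(mkfit(11.1), mkfit(11.5))
  expect_equal(d$shift_h, -0.4, tolerance = 1e-12)
  expect_equal(d$direction, "delay")
  # post onsets 0.5 h earlier -> advance
  a <- phase_shift(mkfit(11.1), mkfit(10.6))
  expect_equal(a$shift_h, +0.5, tolerance = 1e-12)
  expect_equal(a$direction, "advance")
  # degenerate periods are flagged
  expect_true(phase_shift(mkfit(11.1, slope = -5), mkfit(11.1))$flagged)
})

test_that("shift estimate is equivariant in the injected displacement", {
  est <- function(delta) {
    cfg <- sim_config(seed = 31, injected_shift_h = delta,
                      onset_jitter_sd_h = 0, poisson_noise = FALSE,
                      mean_counts_rest = 0)
    sim <- simulate_actogram(cfg)
    estimate_phase_shift(sim$record, event_day = cfg$event_day)$shift_h
  }
  base <- est(0)
  for (delta in c(-1.6, -0.4, 0.5))
    expect_lt(abs(est(delta) - base - delta), 0.05)
})

test_that("whole-day translation leaves shift and period unchanged", {
  cfg <- sim_config(seed = 17, injected_shift_h = -0.4)
  sim <- simulate_actogram(cfg)
  s0 <- estimate_phase_shift(sim$record, event_day = cfg$event_day)
  pad <- 2L * 288L
  rec2 <- activity_record(c(rep(0L, pad), sim$record$counts))
  s2 <- estimate_phase_shift(rec2, event_day = cfg$event_day + 2L)
  expect_lt(abs(s2$shift_h - s0$shift_h), 1e-9)
  expect_lt(abs(s2$pre_period_h - s0$pre_period_h), 1e-9)
})

test_that("chi-square periodogram peaks at the construction period", {
  for (p in c(23.5, 24.0)) {
    rec <- square_wave_record(10, period_h = p)
    pg <- chisq_periodogram(rec)
    expect_lt(abs(attr(pg, "best_period_h") - p), 5 / 60 + 1e-9)
  }
  # constant (arrhythmic) record is flagged
  flat <- activity_record(rep(7L, 10 * 288))
  expect_true(is.na(attr(chisq_periodogram(flat), "best_period_h")))
  expect_true(is.na(estimate_period(flat, "chi_square_periodogram")))
})

test_that("both period estimators recover tau on 10-day records", {
  for (tau in c(23.5, 23.7, 24.0, 24.3)) {
    cfg <- sim_config(seed = 41, tau_h = tau, n_days_pre = 5,
                      n_days_post = 5, injected_shift_h = 0,
                      onset_jitter_sd_h = 0, poisson_noise = FALSE,
                      mean_counts_rest = 0)
    rec <- simulate_actogram(cfg)$record
    expect_lt(abs(as.numeric(estimate_period(rec, "onset_regression")) -
                    tau), 0.1)
    expect_lt(abs(as.numeric(estimate_period(
      rec, "chi_square_periodogram")) - tau), 0.1)
  }
})

test_that("group comparison matches the pooled-variance t statistic", {
  # hand-computed: means 0.2 vs 0.6, pooled var 1/150, t = -0.4/sqrt(1/300)
  a <- c(0.1, 0.2, 0.3, 0.2)
  b <- c(0.5, 0.6, 0.7, 0.6)
  res <- compare_shifts(a, b)
  expect_equal(res$t, -0.4 / sqrt((1 / 150) * (1 / 4 + 1 / 4)),
               tolerance = 1e-9)
  expect_equal(res$t, -6.93, tolerance = 0.005)

  ident <- compare_shifts(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  paired0 <- compare_shifts(c(1, 2, 3), c(1, 2, 3), paired = TRUE)
  expect_equal(paired0$t, 0)
  expect_equal(paired0$p, 1)
  # zero variance in both groups with equal means
  const <- compare_shifts(c(2, 2), c(2, 2))
  expect_equal(const$p, 1)
  expect_error(compare_shifts(1, c(1, 2)), "n >= 2")
})
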