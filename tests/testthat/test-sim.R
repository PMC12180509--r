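test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(tau_h = 0), "tau_h")
  expect_error(sim_config(duty_on_min = 13, duty_period_min = 12), "duty")
  expect_error(sim_config(roi_type_probs = c(typeI = 0.5, typeII = 0.5,
                                             nonresponder = 0.1)), "sum to 1")
  expect_error(sim_config(onset_jitter_sd_h = -1), "non-negative")
  expect_error(sim_config(mean_counts_active = 0), "mean_counts_active")
  expect_error(sim_config(n_days_pre = 2, n_days_post = 2, event_day = 9),
               "event_day")
  expect_error(preset_config("nonexistent"), "unknown preset")
})

test_that("identical configurations yield bit-identical outputs", {
  cfg <- sim_config(seed = 42)
  a <- simulate_actogram(cfg)
  b <- simulate_actogram(cfg)
  expect_identical(a, b)
  p1 <- simulate_trial_photometry(cfg)
  p2 <- simulate_trial_photometry(cfg)
  expect_identical(p1, p2)
  r1 <- simulate_roi_traces(cfg, n_rois = 20)
  r2 <- simulate_roi_traces(cfg, n_rois = 20)
  expect_identical(r1, r2)
  lcfg <- preset_config("longterm_sham", seed = 42, n_days_pre = 1,
                        n_days_post = 1)
  l1 <- simulate_longterm_photometry(lcfg)
  l2 <- simulate_longterm_photometry(lcfg)
  expect_identical(l1, l2)
})

test_that("actogram generator: counts valid, onsets drift at tau - 24", {
  cfg <- sim_config(seed = 3, tau_h = 23.7, onset_jitter_sd_h = 0)
  sim <- simulate_actogram(cfg)
  expect_true(all(sim$record$counts >= 0))
  expect_type(sim$record$counts, "integer")
  expect_length(sim$record$counts, 14 * 288)
  clock <- sim$truth$true_onsets_h - 24 * (seq_along(sim$truth$true_onsets_h)
                                           - 1)
  d <- diff(clock[1:7])                     # pre-event days only
  expect_equal(d, rep(23.7 - 24, 6), tolerance = 1e-12)

  # no drift, no jitter, tau = 24: identical clock time every day
  cfg0 <- sim_config(seed = 3, tau_h = 24, onset_jitter_sd_h = 0,
                     injected_shift_h = 0)
  s0 <- simulate_actogram(cfg0)
  c0 <- s0$truth$true_onsets_h - 24 * (seq_along(s0$truth$true_onsets_h) - 1)
  expect_equal(c0, rep(c0[1], length(c0)))
})

test_that("injected shift displaces post-event onsets by exactly delta", {
  base <- simulate_actogram(sim_config(seed = 9, injected_shift_h = -0.4))
  delta <- 0.7
  shifted <- simulate_actogram(sim_config(seed = 9,
                                          injected_shift_h = -0.4 + delta))
  diff_onsets <- shifted$truth$true_onsets_h - base$truth$true_onsets_h
  ev <- base$truth$event_day
  expect_equal(diff_onsets[seq_len(ev)], rep(0, ev))
  expect_equal(diff_onsets[(ev + 1):length(diff_onsets)],
               rep(-delta, length(diff_onsets) - ev), tolerance = 1e-12)
})

test_that("presets carry the reported condition effect sizes", {
  expect_equal(preset_config("ct14_footshock")$injected_shift_h, -0.4)
  expect_equal(preset_config("ct14_light")$injected_shift_h, -1.2)
  expect_equal(preset_config("ct22_light")$injected_shift_h, +0.5)
  expect_equal(preset_config("ct14_paired")$injected_shift_h, -1.6)
  expect_equal(preset_config("ct22_footshock")$injected_shift_h, -0.2)
  expect_equal(preset_config("ct22_paired")$injected_shift_h, +0.2)
  expect_equal(preset_config("ct6_footshock")$injected_shift_h, 0)
  lt <- preset_config("longterm_ct14_footshock")
  expect_equal(lt$injected_shift_h, -0.4)
  expect_equal(lt$n_days_pre, 2L)
  expect_equal(lt$n_days_post, 3L)
})

test_that("trial photometry: channels finite, events per protocol", {
  cfg <- sim_config(seed = 5)
  sim <- simulate_trial_photometry(cfg, n_trials = 5)
  expect_true(all(is.finite(sim$recording$sig)))
  expect_true(all(is.finite(sim$recording$ref)))
  expect_equal(nrow(sim$recording$events), 5)
  expect_equal(diff(sim$recording$events$time_s), rep(60, 4))
  expect_error(simulate_trial_photometry(cfg, n_trials = 0), "n_trials")
  expect_error(sim_config(transient_kind = "wiggly"), "one of")
})

test_that("duty-cycled generator emits one 4-min session per 12-min slot", {
  cfg <- preset_config("longterm_sham", n_days_pre = 1, n_days_post = 1,
                       tau_h = 24)
  sim <- simulate_longterm_photometry(cfg, n_days = 1)
  expect_length(sim$sessions, 24 * 60 / 12)   # 120 sessions in 24 h
  expect_equal(nrow(sim$sessions[[1]]), 4 * 60 * cfg$fs_hz)
  expect_equal(diff(sim$slot_start_h)[1], 0.2)
  expect_error(sim_config(duty_on_min = 20), "duty")
})

test_that("ROI generator: label frequencies match the type probabilities", {
  probs <- c(typeI = 0.5, typeII = 0.3, nonresponder = 0.2)
  cfg <- sim_config(seed = 21, roi_type_probs = probs)
  # short traces: only the labels matter here
  sim <- simulate_roi_traces(cfg, n_rois = 10000, n_stims = 1,
                             duration_s = 2)
  f <- label_proportions(sim$truth$roi_labels)
  se <- sqrt(probs * (1 - probs) / 10000)
  expect_true(all(abs(f - probs) < 3 * se))

  cfg1 <- sim_config(seed = 22, roi_type_probs = c(typeI = 1, typeII = 0,
                                                   nonresponder = 0))
  s1 <- simulate_roi_traces(cfg1, n_rois = 50, n_stims = 1, duration_s = 2)
  expect_true(all(s1$truth$roi_labels == "typeI"))

  s5 <- simulate_roi_traces(sim_config(seed = 23), n_rois = 3, n_stims = 5)
  expect_length(s5$traces$stim_frames, 5)
})
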