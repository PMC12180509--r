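test_that("isosbestic fit matches closed-form normal equations", {
  # exact line: sig = 2*ref + 3
  ref <- seq(1, 5, length.out = 100)
  fit <- fit_isosbestic(2 * ref + 3, ref)
  expect_equal(fit$a, 2, tolerance = 1e-10)
  expect_equal(fit$b, 3, tolerance = 1e-10)

  # identity: sig = ref
  fid <- fit_isosbestic(ref, ref)
  expect_equal(fid$fitted, ref, tolerance = 1e-10)

  # noisy case against the normal equations
  withr::with_seed(1, {
    r <- rnorm(500, 10, 2)
    s <- 1.7 * r + 0.4 + rnorm(500, 0, 0.3)
  })
  fit2 <- fit_isosbestic(s, r)
  oracle <- ols_normal_equations(r, s)
  expect_equal(fit2$a, unname(oracle["a"]), tolerance = 1e-10)
  expect_equal(fit2$b, unname(oracle["b"]), tolerance = 1e-10)

  # constant reference is flagged with the documented fallback
  expect_warning(fc <- fit_isosbestic(ref, rep(2, 100)), "constant")
  expect_true(fc$flagged)
  expect_equal(fc$fitted, rep(mean(ref), 100))
})

test_that("dff implements (sig - fitted)/fitted and masks bad samples", {
  f <- rep(2, 10)
  expect_equal(as.numeric(dff(f, f)), rep(0, 10))
  expect_equal(as.numeric(dff(1.1 * f, f)), rep(0.1, 10),
               tolerance = 1e-12)
  expect_warning(d <- dff(c(1, 1), c(1, 0)), "masked")
  expect_true(is.na(d[2]))
  expect_equal(attr(d, "n_masked"), 1L)
})

test_that("dff is invariant to a common positive gain on both channels", {
  withr::with_seed(2, {
    ref <- exp(-seq(0, 1, length.out = 400)) * (1 + 0.05 * sin(1:400 / 20))
    sig <- 2 * ref * (1 + 0.04 * dnorm(seq(-3, 3, length.out = 400)))
  })
  d1 <- dff(sig, fit_isosbestic(sig, ref)$fitted)
  for (g in c(0.5, 3, 17)) {
    d2 <- dff(g * sig, fit_isosbestic(g * sig, g * ref)$fitted)
    expect_lt(max(abs(as.numeric(d2) - as.numeric(d1))), 1e-9)
  }
})

test_that("shared multiplicative motion cancels after isosbestic correction", {
  cfg0 <- sim_config(seed = 7, transient_kind = "none", noise_sd = 0,
                     motion_amp = 0)
  cfgm <- sim_config(seed = 7, transient_kind = "none", noise_sd = 0,
                     motion_amp = 0.1)
  dmax <- function(cfg) {
    rec <- simulate_trial_photometry(cfg)$recording
    max(abs(dff(rec$sig, fit_isosbestic(rec)$fitted)))
  }
  expect_lt(dmax(cfgm), 1e-10)
  expect_lt(abs(dmax(cfgm) - dmax(cfg0)), 1e-10)
})

test_that("trial segmentation: grid, edge drops and baseline z-scoring", {
  cfg <- sim_config(seed = 8)
  rec <- simulate_trial_photometry(cfg, n_trials = 5)$recording
  d <- dff(rec$sig, fit_isosbestic(rec)$fitted)
  ts <- segment_trials(rec$time_s, d, rec$events, kind = "shock")
  expect_equal(nrow(ts$trials), 5)
  expect_equal(ts$stim_win_s, c(10, 20))
  expect_equal(max(ts$rel_time_s), 30)

  # event at t = 5 s lacks a 10-s baseline and is dropped
  expect_message(
    ts2 <- segment_trials(rec$time_s, d, c(5, rec$events$time_s)),
    "dropped")
  expect_equal(nrow(ts2$trials), 5)

  tz <- segment_trials(rec$time_s, d, rec$events, z_score = TRUE)
  base <- tz$rel_time_s <= 10
  for (i in 1:5) {
    expect_equal(mean(tz$trials[i, base]), 0, tolerance = 1e-9)
    expect_equal(sd(tz$trials[i, base]), 1, tolerance = 1e-9)
  }

  # light trials use the 10-40 s stimulus window
  tl <- segment_trials(rec$time_s, d, rec$events[1:2, ], kind = "light")
  expect_equal(tl$stim_win_s, c(10, 40))
})

test_that("trapezoidal AUC matches rectangles, triangles and the Riemann
          oracle", {
  t10 <- seq(0, 10, by = 0.05)
  expect_equal(trial_auc(rep(1, length(t10)), t10, c(0, 10)), 10)
  expect_equal(trial_auc(rep(0, length(t10)), t10, c(0, 10)), 0)
  tri <- ifelse(t10 <= 5, t10 / 5, 2 - t10 / 5)
  expect_equal(trial_auc(tri, t10, c(0, 10)), 5, tolerance = 1e-9)
  expect_lt(abs(trial_auc(tri, t10, c(0, 10)) -
                  riemann_auc(tri, t10, c(0, 10))), 1e-6)

  # additivity over adjacent windows and linearity in the trace
  withr::with_seed(3, v <- rnorm(length(t10)))
  expect_equal(trial_auc(v, t10, c(0, 10)),
               trial_auc(v, t10, c(0, 4.3)) + trial_auc(v, t10, c(4.3, 10)),
               tolerance = 1e-9)
  expect_equal(trial_auc(3 * v + tri, t10, c(1, 9)),
               3 * trial_auc(v, t10, c(1, 9)) + trial_auc(tri, t10, c(1, 9)),
               tolerance = 1e-9)
  expect_error(trial_auc(v, t10, c(9, 11)), "inside")
})

test_that("peak_response keeps the sign and breaks ties at the earliest
          sample", {
  tt <- 0:5
  pk <- peak_response(c(0, 0.1, -0.9, 0.5, 0, 0), tt, c(0, 5))
  expect_equal(pk$peak_value, -0.9)
  expect_equal(pk$latency_s, 2)
  tie <- peak_response(c(0, 0, 0.9, 0, 0, -0.9), tt, c(0, 5))
  expect_equal(tie$peak_value, 0.9)
  expect_equal(tie$latency_s, 2)
  expect_error(peak_response(c(NA, NA), 0:1, c(0, 1)), "empty")
})

test_that("2-SD rule labels peaks relative to baseline variability", {
  tt <- seq(0, 30, by = 0.1)
  mk <- function(peak) {
    withr::with_seed(4, v <- rnorm(length(tt), 0, 0.5))
    v[tt >= 12 & tt <= 14] <- peak
    v
  }
  sd0 <- sd(mk(0)[tt <= 10])
  # sustained plateaus survive smoothing, so thresholds apply to `peak`
  expect_equal(classify_response(mk(4 * sd0), tt)$label, "excitatory")
  expect_equal(classify_response(mk(-4 * sd0), tt)$label, "inhibitory")
  expect_equal(classify_response(mk(0), tt)$label, "no_change")
  expect_error(classify_response(mk(0), tt, baseline_win = c(0, 15),
                                 stim_win = c(10, 20)), "precede")
  expect_warning(classify_response(rep(0, length(tt)), tt), "zero")
})

test_that("classifier truth table meets its accuracy bounds", {
  lab <- simulate_labeled_traces(300, amp_sd_ratio = 4, seed = 100)
  pred <- apply(lab$trials, 1, function(v)
    classify_response(v, lab$rel_time_s)$label)
  expect_gte(mean(pred == lab$labels), 0.95)

  null <- simulate_labeled_traces(300, labels = "no_change",
                                  amp_sd_ratio = 0, seed = 101)
  pred0 <- apply(null$trials, 1, function(v)
    classify_response(v, null$rel_time_s)$label)
  expect_gte(mean(pred0 == "no_change"), 0.90)
})

test_that("recovered transient amplitude and latency ordering match truth", {
  cfg <- sim_config(seed = 51, transient_kind = "positive",
                    transient_amp = 0.05)
  exc <- analyze_trials(simulate_trial_photometry(cfg)$recording,
                        z_score = FALSE)
  expect_lt(abs(exc$call$peak_value - 0.05), 0.01)
  expect_equal(exc$call$label, "excitatory")

  cfg_i <- sim_config(seed = 52, transient_kind = "negative_delayed",
                      transient_amp = 0.05)
  inh <- analyze_trials(simulate_trial_photometry(cfg_i)$recording,
                        z_score = FALSE)
  expect_equal(inh$call$label, "inhibitory")
  expect_gt(inh$call$peak_latency_s, exc$call$peak_latency_s)
})
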