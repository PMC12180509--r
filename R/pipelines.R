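#' End-to-end locomotor phase-shift estimation for one record
#'
#' Runs onset detection, fits pre- and post-event onset regressions (pre:
#' days `1..event_day`; post: days `event_day+1` onward, up to `post_days`
#' days), and returns the [phase_shift()] result.
#'
#' @param record an `activity_record`.
#' @param event_day last pre-event day index.
#' @param post_days number of post-event days used in the post fit.
#' @param ... passed to [detect_onsets()].
#' @return a `phase_shift_result`.
#' @export
estimate_phase_shift <- function(record, event_day, post_days = 7, ...) {
  ons <- detect_onsets(record, ...)
  pre <- fit_onset_regression(ons, day_range = seq_len(event_day),
                              event_day = event_day)
  post <- fit_onset_regression(
    ons, day_range = (event_day + 1):(event_day + post_days),
    event_day = event_day)
  phase_shift(pre, post, event_day)
}

#' Simulate and analyse a locomotor cohort for one preset
#'
#' Generates `n_animals` actograms under the named preset (each animal gets
#' its own derived seed), runs the full onset-regression pipeline on each,
#' and tabulates per-animal estimates next to the injected truth.
#'
#' @param preset preset name (see [preset_config()]).
#' @param n_animals cohort size.
#' @param seed base seed for the cohort.
#' @param ... overrides forwarded to [preset_config()].
#' @return data.frame: `animal`, `shift_h`, `magnitude_h`, `direction`,
#'   `pre_period_h`, `post_period_h`, `true_shift_h`; attribute `summary`
#'   holds cohort means.
#' @export
cohort_phase_shifts <- function(preset, n_animals = 12, seed = 1L, ...) {
  rows <- lapply(seq_len(n_animals), function(i) {
    cfg <- preset_config(preset, seed = derive_seed(seed, i), ...)
    sim <- simulate_actogram(cfg, animal_id = sprintf("%s_%02d", preset, i))
    ps <- estimate_phase_shift(sim$record, event_day = cfg$event_day,
                               post_days = cfg$n_days_post)
    data.frame(animal = sim$record$animal_id, shift_h = ps$shift_h,
               magnitude_h = ps$magnitude_h, direction = ps$direction,
               pre_period_h = ps$pre_period_h,
               post_period_h = ps$post_period_h,
               true_shift_h = sim$truth$true_shift_h)
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- c(mean_shift_h = mean(out$shift_h),
                            mean_magnitude_h = mean(abs(out$shift_h)),
                            true_shift_h = out$true_shift_h[1])
  out
}

#' End-to-end calcium-rhythm phase shift for one long-term recording
#'
#' Global isosbestic correction, session-level 2nd-percentile series,
#' per-cycle cosinor acrophase, and acrophase-based phase shift.
#'
#' @param sessions list of session data.frames (`time_s`, `sig`, `ref`).
#' @param event_cycle last pre-event cycle index.
#' @param period_h cosinor period (hours).
#' @param ... passed to [rhythm_phase_shift()].
#' @return a `phase_shift_result`.
#' @export
estimate_rhythm_shift <- function(sessions, event_cycle, period_h, ...) {
  lt <- longterm_dff(sessions)
  series <- circadian_series(lt)
  acro <- fit_acrophase(series, period_h = period_h)
  rhythm_phase_shift(acro, event_cycle = event_cycle, period_h = period_h,
                     ...)
}

#' Simulate and analyse a long-term photometry cohort
#'
#' @param preset long-term preset name (e.g. `"longterm_ct14_footshock"`,
#'   `"longterm_sham"`).
#' @param n_animals cohort size.
#' @param seed base seed.
#' @param ... overrides forwarded to [preset_config()].
#' @return data.frame: `animal`, `shift_h`, `magnitude_h`, `direction`,
#'   `true_shift_h`; attribute `summary` holds cohort means.
#' @export
longterm_cohort <- function(preset = "longterm_ct14_footshock",
                            n_animals = 7, seed = 1L, ...) {
  rows <- lapply(seq_len(n_animals), function(i) {
    cfg <- preset_config(preset, seed = derive_seed(seed, i), ...)
    sim <- simulate_longterm_photometry(cfg)
    ps <- estimate_rhythm_shift(sim$sessions,
                                event_cycle = sim$truth$event_cycle,
                                period_h = cfg$tau_h)
    data.frame(animal = sprintf("%s_%02d", preset, i),
               shift_h = ps$shift_h, magnitude_h = ps$magnitude_h,
               direction = ps$direction,
               true_shift_h = sim$truth$true_shift_h)
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- c(mean_shift_h = mean(out$shift_h),
                            mean_magnitude_h = mean(abs(out$shift_h)),
                            true_shift_h = out$true_shift_h[1])
  out
}

#' Trial-photometry pipeline for one simulated recording
#'
#' Isosbestic fit, dF/F, trial segmentation and mean-trace classification.
#'
#' @param rec a `photometry_recording`.
#' @param kind `"shock"` or `"light"`.
#' @param z_score z-score trials by their baseline (default TRUE, the
#'   normalisation used for response statistics).
#' @param ... passed to [classify_trials()].
#' @return list: `trial_set`, `call` (`response_call`), `trial_labels`,
#'   `fit` (`isosbestic_fit`).
#' @export
analyze_trials <- function(rec, kind = "shock", z_score = TRUE, ...) {
  fit <- fit_isosbestic(rec)
  d <- dff(rec$sig, fit)
  ts <- segment_trials(rec$time_s, d, rec$events, kind = kind,
                       z_score = z_score)
  cl <- classify_trials(ts, ...)
  list(trial_set = ts, call = cl$call, trial_labels = cl$trial_labels,
       fit = fit)
}
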