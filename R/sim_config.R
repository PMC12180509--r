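#' Simulation configuration for the synthetic-data generator
#'
#' A single configuration object drives all four generators
#' ([simulate_actogram()], [simulate_trial_photometry()],
#' [simulate_longterm_photometry()], [simulate_roi_traces()]). Defaults
#' describe a C57BL/6J-like mouse free-running in constant darkness with a
#' 23.7-h endogenous period, nightly wheel activity covering half the cycle,
#' and photometry with mild shared bleaching and motion artifacts.
#'
#' @param seed integer seed; identical configurations yield bit-identical
#'   outputs.
#' @param tau_h free-running period in hours.
#' @param n_days_pre,n_days_post days simulated before/after the stimulus.
#' @param event_day day index (1-based) on which the stimulus is delivered;
#'   onsets of days strictly after `event_day` are displaced by
#'   `injected_shift_h`. Defaults to `n_days_pre`.
#' @param injected_shift_h signed injected phase shift in hours; advance
#'   positive, delay negative (standard phase-response-curve convention).
#' @param onset_jitter_sd_h SD (hours) of Gaussian day-to-day onset jitter.
#' @param active_fraction fraction of each cycle spent active.
#' @param mean_counts_active,mean_counts_rest expected wheel revolutions per
#'   5-min bin inside/outside the active phase.
#' @param fs_hz photometry sampling rate (Hz).
#' @param transient_kind evoked-transient shape: `"positive"`,
#'   `"negative_delayed"`, `"biphasic"` or `"none"`.
#' @param transient_amp peak transient amplitude in dF/F units.
#' @param transient_latency_s,transient_decay_s kernel latency and decay (s).
#' @param bleach_tau_h shared mono-exponential bleaching time constant (h).
#' @param motion_amp SD of the shared multiplicative low-frequency motion
#'   artifact (dimensionless, around 1).
#' @param noise_sd SD of per-channel white measurement noise (raw units).
#' @param rhythm_amp,rhythm_mesor amplitude and mean of the circadian calcium
#'   rhythm (dF/F units, long-term generator).
#' @param rhythm_acrophase_h clock hour of the calcium-rhythm peak at the
#'   start of the recording.
#' @param duty_on_min,duty_period_min duty cycle of long-term acquisition:
#'   minutes recorded per period (defaults 4 in 12).
#' @param roi_type_probs named probabilities over
#'   `c("typeI", "typeII", "nonresponder")`; must sum to 1.
#' @param onset_start_h activity-onset clock hour on the first simulated day.
#' @param poisson_noise logical; `FALSE` replaces Poisson counts by their
#'   rounded means (a noiseless square-wave actogram).
#'
#' @return an object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(seed = 1L,
                       tau_h = 23.7,
                       n_days_pre = 7L,
                       n_days_post = 7L,
                       event_day = NULL,
                       injected_shift_h = 0,
                       onset_jitter_sd_h = 0.2,
                       active_fraction = 0.5,
                       mean_counts_active = 60,
                       mean_counts_rest = 2,
                       fs_hz = 20,
                       transient_kind = c("positive", "negative_delayed",
                                          "biphasic", "none"),
                       transient_amp = 0.05,
                       transient_latency_s = 0,
                       transient_decay_s = 3,
                       bleach_tau_h = 120,
                       motion_amp = 0.02,
                       noise_sd = 0.005,
                       rhythm_amp = 0.2,
                       rhythm_mesor = 0.3,
                       rhythm_acrophase_h = 6,
                       duty_on_min = 4,
                       duty_period_min = 12,
                       roi_type_probs = c(typeI = 0.45, typeII = 0.25,
                                          nonresponder = 0.30),
                       onset_start_h = 12,
                       poisson_noise = TRUE) {
  transient_kind <- match.arg(transient_kind)
  if (is.null(event_day)) event_day <- n_days_pre
  cfg <- list(
    seed = as.integer(seed), tau_h = tau_h,
    n_days_pre = as.integer(n_days_pre), n_days_post = as.integer(n_days_post),
    event_day = as.integer(event_day), injected_shift_h = injected_shift_h,
    onset_jitter_sd_h = onset_jitter_sd_h, active_fraction = active_fraction,
    mean_counts_active = mean_counts_active, mean_counts_rest = mean_counts_rest,
    fs_hz = fs_hz, transient_kind = transient_kind,
    transient_amp = transient_amp, transient_latency_s = transient_latency_s,
    transient_decay_s = transient_decay_s, bleach_tau_h = bleach_tau_h,
    motion_amp = motion_amp, noise_sd = noise_sd,
    rhythm_amp = rhythm_amp, rhythm_mesor = rhythm_mesor,
    rhythm_acrophase_h = rhythm_acrophase_h,
    duty_on_min = duty_on_min, duty_period_min = duty_period_min,
    roi_type_probs = roi_type_probs,
    onset_start_h = onset_start_h, poisson_noise = isTRUE(poisson_noise)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.finite(cfg$tau_h) || cfg$tau_h <= 0)
    stop("tau_h must be a positive number of hours", call. = FALSE)
  if (cfg$duty_on_min > cfg$duty_period_min)
    stop("duty_on_min must not exceed duty_period_min", call. = FALSE)
  p <- cfg$roi_type_probs
  if (length(p) != 3L || is.null(names(p)) ||
      !setequal(names(p), c("typeI", "typeII", "nonresponder")))
    stop("roi_type_probs must be named over typeI/typeII/nonresponder",
         call. = FALSE)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("roi_type_probs must be non-negative and sum to 1 (tol 1e-9)",
         call. = FALSE)
  if (cfg$onset_jitter_sd_h < 0 || cfg$transient_amp < 0 ||
      cfg$motion_amp < 0 || cfg$noise_sd < 0 || cfg$rhythm_amp < 0)
    stop("SDs and amplitudes must be non-negative", call. = FALSE)
  if (cfg$mean_counts_active <= 0 || cfg$mean_counts_rest < 0)
    stop("mean_counts_active must be > 0 and mean_counts_rest >= 0",
         call. = FALSE)
  if (cfg$active_fraction <= 0 || cfg$active_fraction >= 1)
    stop("active_fraction must lie in (0, 1)", call. = FALSE)
  n_days <- cfg$n_days_pre + cfg$n_days_post
  if (cfg$event_day < 1L || cfg$event_day >= n_days)
    stop("event_day must lie inside the simulated span", call. = FALSE)
  cfg
}

#' Named experimental presets
#'
#' Each preset fixes the injected phase shift to the cohort-level effect size
#' of one experimental condition: footshock, a light pulse, their pairing, or
#' forced swim, delivered at early (CT14), late (CT22) or mid-rest (CT6)
#' circadian time, plus a long-term photometry variant (2 pre + 3 post days,
#' duty-cycled) and sham/control variants with no injected shift.
#'
#' @param name one of `"ct14_footshock"`, `"ct22_footshock"`,
#'   `"ct6_footshock"`, `"ct14_light"`, `"ct22_light"`, `"ct14_paired"`,
#'   `"ct22_paired"`, `"ct14_forcedswim"`, `"longterm_ct14_footshock"`,
#'   `"longterm_sham"`, `"control"`.
#' @param seed integer seed passed through to [sim_config()].
#' @param ... overrides forwarded to [sim_config()].
#'
#' @return a `sim_config`.
#' @export
preset_config <- function(name, seed = 1L, ...) {
  shifts <- c(
    ct14_footshock = -0.4, ct22_footshock = -0.2, ct6_footshock = 0,
    ct14_light = -1.2, ct22_light = +0.5,
    ct14_paired = -1.6, ct22_paired = +0.2,
    ct14_forcedswim = -0.4,
    longterm_ct14_footshock = -0.4, longterm_sham = 0,
    control = 0
  )
  if (!name %in% names(shifts))
    stop("unknown preset: ", name, call. = FALSE)
  args <- list(seed = seed, injected_shift_h = unname(shifts[[name]]))
  if (startsWith(name, "longterm")) {
    # duty-cycled calcium recording: 2 days free-run, stimulus, 3 more days
    args <- c(args, list(n_days_pre = 2L, n_days_post = 3L, fs_hz = 1))
  }
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> tau =", x$tau_h, "h, days =", x$n_days_pre, "+",
      x$n_days_post, ", injected shift =", x$injected_shift_h,
      "h, seed =", x$seed, "\n")
  invisible(x)
}
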