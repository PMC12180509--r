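#' Simulate a duty-cycled long-term photometry recording
#'
#' Emulates multi-day acquisition in which the two channels are sampled for
#' `duty_on_min` minutes in every `duty_period_min`-minute slot (defaults 4 in
#' 12, i.e. 120 sessions/day) to limit photobleaching. The underlying calcium
#' level follows a circadian cosine,
#' `mesor + amp * cos(2*pi*(t - acrophase)/tau)`, whose phase is displaced by
#' `injected_shift_h` (advance positive = earlier peak) for all times after
#' the stimulus, delivered at the boundary between pre and post cycles
#' (`n_days_pre * tau_h` hours into the recording). Sessions also carry brief
#' positive calcium transients, shared bleach/motion artifacts on both
#' channels, and white noise.
#'
#' @param cfg a [sim_config()]; `n_days_pre`/`n_days_post` set the span in
#'   cycles of length `tau_h`.
#' @param n_days optional override of the total number of 24-h days spanned;
#'   default derives the span from the configured pre/post cycles.
#' @return list with `sessions` (list of data.frames `time_s`, `sig`, `ref`,
#'   each with attribute `slot_start_h`), `slot_start_h` (numeric vector),
#'   and `truth` (`true_shift_h`, `true_period_h`, `true_acrophase_h` —
#'   absolute peak hours per cycle — and `event_time_h`).
#' @export
simulate_longterm_photometry <- function(cfg, n_days = NULL) {
  cfg <- validate_sim_config(cfg)
  n_cycles <- cfg$n_days_pre + cfg$n_days_post
  if (n_cycles < 2 && is.null(n_days))
    stop("need at least 2 simulated days", call. = FALSE)
  total_h <- if (is.null(n_days)) n_cycles * cfg$tau_h else n_days * 24
  fs <- cfg$fs_hz
  slot_h <- cfg$duty_period_min / 60
  on_s <- cfg$duty_on_min * 60
  slot_start_h <- seq(0, total_h - slot_h, by = slot_h)
  t_event_h <- cfg$n_days_pre * cfg$tau_h

  n_per <- as.integer(on_s * fs)
  omega <- 2 * pi / cfg$tau_h
  sessions <- vector("list", length(slot_start_h))

  withr::with_seed(cfg$seed, {
    for (i in seq_along(slot_start_h)) {
      ts <- slot_start_h[i] * 3600 + seq(0, on_s - 1 / fs, by = 1 / fs)
      th <- ts / 3600
      shift <- ifelse(th > t_event_h, cfg$injected_shift_h, 0)
      calcium <- cfg$rhythm_mesor + cfg$rhythm_amp *
        cos(omega * (th - cfg$rhythm_acrophase_h + shift))
      # sparse positive transients within the session (spiking activity)
      n_ev <- rpois(1, 2)
      bump <- rep(0, n_per)
      if (n_ev > 0) {
        ev <- runif(n_ev, 0, on_s)
        for (e in ev)
          bump <- bump + 0.1 * transient_kernel(seq(0, on_s - 1 / fs,
                                                    by = 1 / fs) - e,
                                                "positive", decay_s = 2)
      }
      bleach <- exp(-th / cfg$bleach_tau_h)
      motion <- motion_series(n_per, fs, cfg$motion_amp)
      ref <- 1.0 * bleach * motion + rnorm(n_per, 0, cfg$noise_sd)
      sig <- 2.0 * bleach * motion * (1 + calcium + bump) +
        rnorm(n_per, 0, cfg$noise_sd)
      s <- data.frame(time_s = ts, sig = sig, ref = ref)
      attr(s, "slot_start_h") <- slot_start_h[i]
      sessions[[i]] <- s
    }
  })

  cyc <- seq_len(max(1L, floor(total_h / cfg$tau_h)))
  peak0 <- cfg$rhythm_acrophase_h %% cfg$tau_h
  acro <- peak0 + (cyc - 1) * cfg$tau_h
  acro <- acro - cfg$injected_shift_h * (acro > t_event_h)
  truth <- structure(
    list(true_shift_h = cfg$injected_shift_h, true_period_h = cfg$tau_h,
         true_acrophase_h = acro, event_time_h = t_event_h,
         event_cycle = cfg$n_days_pre),
    class = "ground_truth")
  list(sessions = sessions, slot_start_h = slot_start_h, truth = truth)
}
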