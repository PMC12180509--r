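# Evoked-transient kernels. `t` is time since event onset in seconds; all
# kernels are zero for t < latency and are normalised to unit peak magnitude.
transient_kernel <- function(t, kind, latency_s = 0, decay_s = 3,
                             rise_s = 0.5) {
  shape <- function(tt, dec) {
    k <- ifelse(tt > 0, exp(-tt / dec) - exp(-tt / rise_s), 0)
    m <- max(k)
    if (m > 0) k / m else k
  }
  switch(kind,
    none = rep(0, length(t)),
    positive = shape(t - latency_s, decay_s),
    # inhibition develops later and recovers more slowly than excitation
    negative_delayed = -shape(t - latency_s - 2, 2 * decay_s),
    biphasic = shape(t - latency_s, decay_s) -
      0.6 * shape(t - latency_s - 3, 2 * decay_s),
    stop("unknown transient_kind: ", kind, call. = FALSE)
  )
}

# Shared multiplicative low-frequency motion artifact: moving-average-smoothed
# white noise rescaled to SD `amp`, centred on 1 and floored away from zero.
motion_series <- function(n, fs_hz, amp, smooth_s = 2) {
  if (amp <= 0) return(rep(1, n))
  w <- max(1L, as.integer(round(smooth_s * fs_hz)))
  z <- as.numeric(stats::filter(rnorm(n + 2 * w), rep(1 / w, w),
                                sides = 2))
  z <- z[(w + 1):(w + n)]
  z[is.na(z)] <- 0
  s <- sd(z)
  if (s > 0) z <- z / s
  pmax(1 + amp * z, 0.1)
}

#' Simulate an event-locked two-channel photometry recording
#'
#' Emulates a trial session: a 2-min habituation baseline followed by
#' `n_trials` stimuli at a 60-s inter-trial interval. Both channels share a
#' mono-exponential bleach and a multiplicative low-frequency motion artifact;
#' the signal channel additionally carries an evoked transient (per
#' `cfg$transient_kind`) at each event, plus white measurement noise on each
#' channel. Because the artifacts are shared and multiplicative, a
#' least-squares isosbestic fit removes them exactly up to noise.
#'
#' @param cfg a [sim_config()].
#' @param n_trials number of stimuli (>= 1).
#' @param kind event label stored with the event times (`"shock"` or
#'   `"light_on"`).
#' @return list with `recording` (a `photometry_recording`: `time_s`, `sig`,
#'   `ref`, `events`, `fs_hz`) and `truth` (`trial_labels`,
#'   `true_peak_dff`, `transient_kind`).
#' @export
simulate_trial_photometry <- function(cfg, n_trials = 5, kind = "shock") {
  cfg <- validate_sim_config(cfg)
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  fs <- cfg$fs_hz
  events <- 120 + (seq_len(n_trials) - 1) * 60
  dur <- max(events) + 60
  t <- seq(0, dur, by = 1 / fs)
  n <- length(t)

  withr::with_seed(cfg$seed, {
    bleach <- exp(-(t / 3600) / cfg$bleach_tau_h)
    motion <- motion_series(n, fs, cfg$motion_amp)
    resp <- rep(0, n)
    for (ev in events)
      resp <- resp + cfg$transient_amp *
        transient_kernel(t - ev, cfg$transient_kind,
                         cfg$transient_latency_s, cfg$transient_decay_s)
    ref <- 1.0 * bleach * motion + rnorm(n, 0, cfg$noise_sd)
    sig <- 2.0 * bleach * motion * (1 + resp) + rnorm(n, 0, cfg$noise_sd)
  })

  label <- switch(cfg$transient_kind,
                  positive = "excitatory", biphasic = "excitatory",
                  negative_delayed = "inhibitory", none = "no_change")
  rec <- photometry_recording(t, sig, ref,
                              events = data.frame(time_s = events,
                                                  kind = kind),
                              fs_hz = fs)
  truth <- structure(
    list(trial_labels = rep(label, n_trials),
         true_peak_dff = cfg$transient_amp *
           (if (cfg$transient_kind == "negative_delayed") -1 else
              if (cfg$transient_kind == "none") 0 else 1),
         transient_kind = cfg$transient_kind),
    class = "ground_truth")
  list(recording = rec, truth = truth)
}

#' Simulate labelled trial-averaged dF/F traces
#'
#' Produces single mean traces on the standard trial grid (stimulus at 10 s)
#' with known class labels, for validating the SD-threshold response
#' classifier: excitatory/inhibitory traces carry a transient whose peak
#' magnitude is `amp_sd_ratio` times the white-noise SD; `no_change` traces
#' are pure noise.
#'
#' @param n number of traces.
#' @param labels classes to draw uniformly from.
#' @param amp_sd_ratio peak amplitude over noise SD.
#' @param noise_sd white-noise SD (dF/F units).
#' @param fs_hz sampling rate; the grid is 0–30 s.
#' @param seed integer seed.
#' @return list with `trials` (n x time matrix), `rel_time_s`, `labels`.
#' @export
simulate_labeled_traces <- function(n, labels = c("excitatory", "inhibitory",
                                                  "no_change"),
                                    amp_sd_ratio = 4, noise_sd = 0.02,
                                    fs_hz = 20, seed = 1L) {
  rel_t <- seq(0, 30, by = 1 / fs_hz)
  amp <- amp_sd_ratio * noise_sd
  withr::with_seed(seed, {
    lab <- sample(labels, n, replace = TRUE)
    tr <- matrix(rnorm(n * length(rel_t), 0, noise_sd), nrow = n)
    for (i in seq_len(n)) {
      kind <- switch(lab[i], excitatory = "positive",
                     inhibitory = "negative_delayed", no_change = "none")
      tr[i, ] <- tr[i, ] + amp * transient_kernel(rel_t - 10, kind)
    }
  })
  list(trials = tr, rel_time_s = rel_t, labels = lab)
}
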