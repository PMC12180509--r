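#' Construct an event-locked photometry recording
#'
#' @param time_s strictly increasing sample times, seconds.
#' @param sig raw signal-channel fluorescence (calcium-dependent excitation).
#' @param ref raw reference-channel fluorescence (isosbestic excitation).
#' @param events data.frame with columns `time_s` and `kind`
#'   (`"shock"`/`"light_on"`), or a numeric vector of event times.
#' @param fs_hz nominal sampling rate; inferred from `time_s` when missing.
#' @return a `photometry_recording`.
#' @export
photometry_recording <- function(time_s, sig, ref, events = NULL,
                                 fs_hz = NULL) {
  if (length(time_s) != length(sig) || length(sig) != length(ref))
    stop("time_s, sig and ref must have equal length", call. = FALSE)
  if (any(diff(time_s) <= 0))
    stop("time_s must be strictly increasing", call. = FALSE)
  if (is.numeric(events)) events <- data.frame(time_s = events,
                                               kind = "shock")
  if (!is.null(events) && nrow(events) &&
      (min(events$time_s) < min(time_s) || max(events$time_s) > max(time_s)))
    stop("events must lie within the record span", call. = FALSE)
  if (is.null(fs_hz)) fs_hz <- 1 / stats::median(diff(time_s))
  structure(list(time_s = time_s, sig = sig, ref = ref,
                 events = events, fs_hz = fs_hz),
            class = "photometry_recording")
}

#' Least-squares isosbestic fit of the reference channel to the signal
#'
#' Fits `sig ~ a * ref + b` by ordinary least squares over the whole
#' recording and returns the fitted reference series, which carries the
#' shared motion/bleaching artifacts scaled to the signal channel. A
#' zero-variance reference cannot be fitted; the result then falls back to
#' `a = 0`, `b = mean(sig)` with a warning and a flag.
#'
#' @param rec a `photometry_recording`, or a numeric signal vector (then
#'   `ref` must be supplied).
#' @param ref reference vector when `rec` is numeric.
#' @return list (`isosbestic_fit`): `fitted` (series), `a`, `b`, `flagged`.
#' @export
fit_isosbestic <- function(rec, ref = NULL) {
  if (inherits(rec, "photometry_recording")) {
    sig <- rec$sig; ref <- rec$ref
  } else sig <- as.numeric(rec)
  if (length(sig) < 2) stop("need at least 2 samples", call. = FALSE)
  if (!all(is.finite(sig)) || !all(is.finite(ref)))
    stop("channels must be finite everywhere", call. = FALSE)
  if (var(ref) == 0) {
    warning("reference channel is constant; using a = 0, b = mean(sig)")
    b <- mean(sig)
    return(structure(list(fitted = rep(b, length(sig)), a = 0, b = b,
                          flagged = TRUE), class = "isosbestic_fit"))
  }
  cf <- stats::.lm.fit(cbind(1, ref), sig)$coefficients
  structure(list(fitted = cf[1] + cf[2] * ref, a = unname(cf[2]),
                 b = unname(cf[1]), flagged = FALSE),
            class = "isosbestic_fit")
}

#' Fractional fluorescence change relative to the fitted reference
#'
#' `dFF = (sig - fitted_ref) / fitted_ref`, elementwise. Samples at which the
#' fitted reference is zero or negative are masked to `NA` and reported.
#'
#' @param sig raw signal-channel samples.
#' @param fitted_ref fitted reference series (from [fit_isosbestic()]) or an
#'   `isosbestic_fit`.
#' @return numeric dF/F series; attribute `n_masked` counts masked samples.
#' @export
dff <- function(sig, fitted_ref) {
  if (inherits(fitted_ref, "isosbestic_fit")) fitted_ref <- fitted_ref$fitted
  if (length(sig) != length(fitted_ref))
    stop("sig and fitted_ref must have equal length", call. = FALSE)
  bad <- !(fitted_ref > 0)
  out <- (sig - fitted_ref) / fitted_ref
  if (any(bad)) {
    out[bad] <- NA_real_
    warning(sum(bad), " samples masked (non-positive fitted reference)")
  }
  attr(out, "n_masked") <- sum(bad)
  out
}

#' Segment a dF/F series into event-locked trials
#'
#' Each trial window opens 10 s before the stimulus (so the stimulus begins
#' at relative time 10 s, matching the baseline 0-10 s / stimulus 10-20 s
#' (shock) or 10-40 s (light) windows) and closes 10 s after the stimulus
#' window. Trials are linearly interpolated onto a common relative-time grid
#' at the native sampling rate. Events too close to the record edges are
#' dropped with a message. Optional per-trial z-scoring uses the baseline
#' mean and SD.
#'
#' @param time_s sample times of `dff_series`.
#' @param dff_series dF/F samples.
#' @param events numeric event onset times (s) or a data.frame with `time_s`.
#' @param kind `"shock"` (stimulus window 10-20 s) or `"light"`
#'   (10-40 s).
#' @param baseline_s baseline duration before the stimulus, seconds.
#' @param stim_dur_s stimulus-window duration; default by `kind`.
#' @param tail_s extra time kept after the stimulus window.
#' @param z_score logical: z-score each trial by its baseline mean/SD.
#' @return a `trial_set`: `trials` (trial x time matrix), `rel_time_s`,
#'   `baseline_win_s`, `stim_win_s`, `kind`, `zscored`, `n_dropped`.
#' @export
segment_trials <- function(time_s, dff_series, events,
                           kind = c("shock", "light"),
                           baseline_s = 10, stim_dur_s = NULL, tail_s = 10,
                           z_score = FALSE) {
  kind <- match.arg(kind)
  if (is.data.frame(events)) events <- events$time_s
  if (is.null(stim_dur_s)) stim_dur_s <- if (kind == "shock") 10 else 30
  span <- baseline_s + stim_dur_s + tail_s
  fs <- 1 / stats::median(diff(time_s))
  rel_t <- seq(0, span, length.out = round(span * fs) + 1)

  keep <- events - baseline_s >= min(time_s) &
    events + stim_dur_s + tail_s <= max(time_s)
  if (any(!keep))
    message(sum(!keep), " event(s) dropped: too close to the record edges")
  events <- events[keep]
  if (length(events) == 0) stop("no usable events", call. = FALSE)

  trials <- t(vapply(events, function(ev) {
    approx(time_s, dff_series, xout = ev - baseline_s + rel_t)$y
  }, numeric(length(rel_t))))
  base_idx <- rel_t >= 0 & rel_t <= baseline_s
  if (z_score) {
    for (i in seq_len(nrow(trials))) {
      m <- mean(trials[i, base_idx], na.rm = TRUE)
      s <- sd(trials[i, base_idx], na.rm = TRUE)
      if (!is.finite(s) || s == 0) s <- 1e-9
      trials[i, ] <- (trials[i, ] - m) / s
    }
  }
  structure(list(trials = trials, rel_time_s = rel_t,
                 baseline_win_s = c(0, baseline_s),
                 stim_win_s = c(baseline_s, baseline_s + stim_dur_s),
                 kind = kind, zscored = z_score, n_dropped = sum(!keep)),
            class = "trial_set")
}

#' Trapezoidal area under the curve over a time window
#'
#' Integrates the trace over `[window[1], window[2]]` by the trapezoid rule,
#' with linear interpolation at the window endpoints when they fall between
#' samples. Units: trace units x seconds.
#'
#' @param values trace samples.
#' @param time_s sample times.
#' @param window numeric length-2 window (seconds).
#' @return the integral.
#' @export
trial_auc <- function(values, time_s, window) {
  if (length(window) != 2 || window[2] <= window[1])
    stop("window must be an increasing length-2 vector", call. = FALSE)
  if (window[1] < min(time_s) || window[2] > max(time_s))
    stop("window must lie inside the trace span", call. = FALSE)
  inside <- time_s > window[1] & time_s < window[2]
  xs <- c(window[1], time_s[inside], window[2])
  ys <- c(approx(time_s, values, xout = window[1])$y,
          values[inside],
          approx(time_s, values, xout = window[2])$y)
  pracma::trapz(xs, ys)
}

#' Signed peak response and latency within a stimulus window
#'
#' Returns the sample with the largest absolute value in the window, sign
#' preserved (so inhibitory responses report negative peaks), and its latency
#' from the stimulus onset (the window start). Ties are broken by the
#' earliest sample.
#'
#' @param values trace samples.
#' @param time_s sample times.
#' @param stim_window length-2 window; its start is the stimulus onset.
#' @return list: `peak_value`, `latency_s`.
#' @export
peak_response <- function(values, time_s, stim_window) {
  idx <- which(time_s >= stim_window[1] & time_s <= stim_window[2] &
                 !is.na(values))
  if (length(idx) == 0) stop("empty stimulus window", call. = FALSE)
  k <- idx[which.max(abs(values[idx]))]       # which.max takes the first tie
  list(peak_value = values[k], latency_s = time_s[k] - stim_window[1])
}

# Centred moving-average smoother used before peak extraction in the
# SD-threshold classifiers; width in samples, edges keep raw values.
smooth_trace <- function(x, width) {
  if (width <= 1) return(x)
  width <- as.integer(width)
  if (width %% 2 == 0) width <- width + 1L
  s <- as.numeric(stats::filter(x, rep(1 / width, width), sides = 2))
  s[is.na(s)] <- x[is.na(s)]
  s
}

#' Classify an event-locked response by the 2-SD rule
#'
#' Applied to a (typically trial-averaged) trace: the baseline SD is computed
#' from the raw samples of the baseline window — the per-sample noise scale —
#' and the signed peak (largest absolute excursion) is taken from a smoothed
#' copy of the trace within the stimulus window, so that a response must
#' exceed the noise floor in a sustained way. Labels: `excitatory` if
#' `peak > +2 * SD`, `inhibitory` if `peak < -2 * SD`, otherwise `no_change`.
#'
#' @param values trace samples (dF/F or z-scored dF/F).
#' @param time_s sample times (trial-relative).
#' @param baseline_win,stim_win length-2 windows, seconds.
#' @param sd_mult threshold multiplier (default 2).
#' @param smooth_s smoothing width in seconds applied before peak extraction
#'   (0 disables smoothing).
#' @return list (`response_call`): `label`, `peak_value`, `peak_latency_s`,
#'   `auc_baseline`, `auc_stim`, `baseline_sd`.
#' @export
classify_response <- function(values, time_s, baseline_win = c(0, 10),
                              stim_win = c(10, 20), sd_mult = 2,
                              smooth_s = 1) {
  if (baseline_win[2] > stim_win[1])
    stop("baseline window must precede the stimulus window", call. = FALSE)
  base_idx <- time_s >= baseline_win[1] & time_s <= baseline_win[2]
  base_sd <- sd(values[base_idx], na.rm = TRUE)
  if (!is.finite(base_sd) || base_sd == 0) {
    warning("baseline SD is zero; using absolute floor 1e-9")
    base_sd <- 1e-9
  }
  fs <- 1 / stats::median(diff(time_s))
  sm <- smooth_trace(values, round(smooth_s * fs))
  pk <- peak_response(sm, time_s, stim_win)
  label <- if (pk$peak_value > sd_mult * base_sd) "excitatory"
  else if (pk$peak_value < -sd_mult * base_sd) "inhibitory"
  else "no_change"
  structure(list(label = label, peak_value = pk$peak_value,
                 peak_latency_s = pk$latency_s,
                 auc_baseline = trial_auc(values, time_s, baseline_win),
                 auc_stim = trial_auc(values, time_s, stim_win),
                 baseline_sd = base_sd),
            class = "response_call")
}

#' Across-trial mean trace of a trial set
#'
#' @param ts a `trial_set`.
#' @return numeric vector, one value per point of `ts$rel_time_s`.
#' @export
trial_mean <- function(ts) {
  stopifnot(inherits(ts, "trial_set"))
  colMeans(ts$trials, na.rm = TRUE)
}

#' Per-animal response call from a trial set
#'
#' Classifies the across-trial mean trace by the 2-SD rule and also emits
#' per-trial labels.
#'
#' @param ts a `trial_set`.
#' @param ... passed to [classify_response()].
#' @return list: `call` (the mean-trace `response_call`), `trial_labels`.
#' @export
classify_trials <- function(ts, ...) {
  stopifnot(inherits(ts, "trial_set"))
  mt <- trial_mean(ts)
  call <- classify_response(mt, ts$rel_time_s, ts$baseline_win_s,
                            ts$stim_win_s, ...)
  per_trial <- apply(ts$trials, 1, function(v)
    classify_response(v, ts$rel_time_s, ts$baseline_win_s,
                      ts$stim_win_s, ...)$label)
  list(call = call, trial_labels = per_trial)
}
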