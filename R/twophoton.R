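#' ROI dF/F0 relative to a baseline-window mean
#'
#' `F0` is the mean raw fluorescence over the baseline frames; the series is
#' `(F - F0) / F0`. ROIs with non-positive `F0` cannot be normalised and are
#' excluded (all-NA, with a warning).
#'
#' @param f_row raw fluorescence of one ROI (vector over frames).
#' @param baseline_frames integer frame indices of the baseline window.
#' @return dF/F0 vector; attribute `excluded` is TRUE when F0 <= 0.
#' @export
roi_dff <- function(f_row, baseline_frames) {
  if (min(baseline_frames) < 1 || max(baseline_frames) > length(f_row))
    stop("baseline frames outside the trace", call. = FALSE)
  f0 <- mean(f_row[baseline_frames])
  if (!is.finite(f0) || f0 <= 0) {
    warning("non-positive baseline F0; ROI excluded")
    return(structure(rep(NA_real_, length(f_row)), excluded = TRUE))
  }
  structure((f_row - f0) / f0, excluded = FALSE)
}

#' Stimulation-aligned average response
#'
#' Extracts a window around each stimulation frame and averages across
#' stimulations; windows that run past the trace edges are dropped.
#'
#' @param dff_series dF/F0 samples of one ROI.
#' @param stim_frames stimulation onset frames (1-based).
#' @param fps frames per second.
#' @param window_s length-2 window relative to stimulation onset, seconds.
#' @return list: `mean_trace`, `rel_time_s`, `n_used`.
#' @export
average_stim_response <- function(dff_series, stim_frames, fps = 30,
                                  window_s = c(-2, 18)) {
  w <- as.integer(round(window_s * fps))
  offs <- seq(w[1], w[2])
  rows <- lapply(stim_frames, function(sf) {
    idx <- sf + offs
    if (min(idx) < 1 || max(idx) > length(dff_series)) return(NULL)
    v <- dff_series[idx]
    if (anyNA(v)) return(NULL)
    v
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) stop("no stimulation with a full window",
                              call. = FALSE)
  list(mean_trace = colMeans(do.call(rbind, rows)),
       rel_time_s = offs / fps, n_used = length(rows))
}

#' Classify an ROI response: type I, type II, or nonresponder
#'
#' The 1-SD rule: the baseline SD is computed from the raw samples of the
#' baseline window; peak and dip are measured on a smoothed copy of the trace
#' within the post-stimulation window (see [classify_response()] for the
#' rationale). Labels: `typeI` if the smoothed post-window maximum exceeds
#' `+1 SD` with no subsequent sample below `-1 SD`; `typeII` if the maximum
#' exceeds `+1 SD` and a sample *after the peak frame* falls below `-1 SD`;
#' `nonresponder` if the trace stays within `(-1, +1) SD`.
#'
#' @param mean_trace dF/F0 samples (typically the full-recording ROI trace or
#'   a stimulation-averaged trace).
#' @param time_s sample times of `mean_trace`.
#' @param baseline_window,post_window length-2 windows, seconds.
#' @param sd_mult threshold multiplier (default 1).
#' @param smooth_s smoothing width in seconds before peak/dip extraction.
#' @return list (`roi_call`): `label`, `post_excursion_sd`, `post_dip_sd`
#'   (peak excursions in baseline-SD units), `baseline_sd`.
#' @export
classify_roi <- function(mean_trace, time_s, baseline_window, post_window,
                         sd_mult = 1, smooth_s = 1) {
  base_idx <- time_s >= baseline_window[1] & time_s <= baseline_window[2]
  base_mean <- mean(mean_trace[base_idx], na.rm = TRUE)
  base_sd <- sd(mean_trace[base_idx], na.rm = TRUE)
  if (!is.finite(base_sd) || base_sd == 0) {
    warning("baseline SD is zero; using absolute floor 1e-9")
    base_sd <- 1e-9
  }
  fs <- 1 / stats::median(diff(time_s))
  sm <- smooth_trace(mean_trace, round(smooth_s * fs)) - base_mean
  post_idx <- which(time_s >= post_window[1] & time_s <= post_window[2] &
                      !is.na(sm))
  if (length(post_idx) == 0) stop("empty post window", call. = FALSE)
  pk_i <- post_idx[which.max(sm[post_idx])]
  peak_sd <- sm[pk_i] / base_sd
  after <- post_idx[post_idx > pk_i]
  dip_sd <- if (length(after)) min(sm[after]) / base_sd else
    min(sm[post_idx]) / base_sd
  label <- if (peak_sd > sd_mult) {
    if (length(after) && min(sm[after]) < -sd_mult * base_sd) "typeII"
    else "typeI"
  } else "nonresponder"
  structure(list(label = label, post_excursion_sd = peak_sd,
                 post_dip_sd = dip_sd, baseline_sd = base_sd),
            class = "roi_call")
}

#' Trapezoidal AUC of a mean trace over a fixed window
#'
#' Default window 30-90 s, the sustained-response window used to compare
#' pharmacological conditions.
#'
#' @param mean_trace dF/F0 samples.
#' @param time_s sample times.
#' @param window_s length-2 window, seconds.
#' @return the integral (value x seconds).
#' @export
condition_auc <- function(mean_trace, time_s, window_s = c(30, 90)) {
  trial_auc(mean_trace, time_s, window_s)
}

#' Fractions of ROI labels
#'
#' @param calls character vector of labels, or list of `roi_call`s.
#' @return named numeric vector over typeI/typeII/nonresponder, summing to 1.
#' @export
label_proportions <- function(calls) {
  if (is.list(calls) && length(calls) && inherits(calls[[1]], "roi_call"))
    calls <- vapply(calls, `[[`, character(1), "label")
  if (length(calls) == 0) stop("no calls", call. = FALSE)
  lv <- c("typeI", "typeII", "nonresponder")
  tab <- table(factor(calls, levels = lv))
  stats::setNames(as.numeric(tab) / length(calls), lv)
}

#' Classify every ROI of a trace matrix
#'
#' Computes dF/F0 per ROI (baseline = `baseline_s` seconds before the first
#' stimulation), classifies each with [classify_roi()], and reports the AUC
#' over `auc_window_s`.
#'
#' @param traces a `roi_trace_matrix`.
#' @param baseline_s baseline duration before the first stimulation, seconds.
#' @param post_window_s post-stimulation classification window: seconds after
#'   the first stimulation onset.
#' @param auc_window_s AUC window, seconds.
#' @param ... passed to [classify_roi()].
#' @return data.frame: `roi`, `label`, `post_excursion_sd`, `post_dip_sd`,
#'   `auc`.
#' @export
classify_roi_matrix <- function(traces, baseline_s = 10, post_window_s = 30,
                                auc_window_s = c(30, 90), ...) {
  stopifnot(inherits(traces, "roi_trace_matrix"))
  fps <- traces$fps
  t <- (seq_len(ncol(traces$F)) - 1) / fps
  first_stim <- (min(traces$stim_frames) - 1) / fps
  base_frames <- which(t >= first_stim - baseline_s & t < first_stim)
  base_win <- c(first_stim - baseline_s, first_stim)
  post_win <- c(first_stim, first_stim + post_window_s)
  rows <- lapply(seq_len(nrow(traces$F)), function(i) {
    d <- roi_dff(traces$F[i, ], base_frames)
    if (isTRUE(attr(d, "excluded")))
      return(data.frame(roi = i, label = NA_character_,
                        post_excursion_sd = NA_real_, post_dip_sd = NA_real_,
                        auc = NA_real_))
    cl <- classify_roi(d, t, base_win, post_win, ...)
    data.frame(roi = i, label = cl$label,
               post_excursion_sd = cl$post_excursion_sd,
               post_dip_sd = cl$post_dip_sd,
               auc = condition_auc(d, t, auc_window_s))
  })
  do.call(rbind, rows)
}
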