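#' Global isosbestic correction across duty-cycled sessions
#'
#' Concatenates all sessions, fits one global least-squares line of the
#' reference channel to the signal channel (a per-session fit would absorb
#' the circadian signal itself, because bleaching and rhythm both span
#' sessions), and returns per-session dF/F with session boundaries preserved.
#'
#' @param sessions list of data.frames with columns `time_s`, `sig`, `ref`
#'   (as produced by [simulate_longterm_photometry()] or
#'   [read_photometry_csv()]).
#' @return list (`longterm_dff`): `dff` (list of per-session dF/F vectors),
#'   `fit` (the global `isosbestic_fit`), `slot_start_h`.
#' @export
longterm_dff <- function(sessions) {
  if (length(sessions) < 2) stop("need at least 2 sessions", call. = FALSE)
  sig <- unlist(lapply(sessions, `[[`, "sig"), use.names = FALSE)
  ref <- unlist(lapply(sessions, `[[`, "ref"), use.names = FALSE)
  fit <- fit_isosbestic(sig, ref)
  d <- dff(sig, fit$fitted)
  lens <- vapply(sessions, nrow, integer(1))
  idx <- rep(seq_along(sessions), lens)
  slot <- vapply(sessions, function(s) {
    a <- attr(s, "slot_start_h")
    if (is.null(a)) s$time_s[1] / 3600 else a
  }, numeric(1))
  structure(list(dff = split(as.numeric(d), idx), fit = fit,
                 slot_start_h = slot),
            class = "longterm_dff")
}

#' Session-level calcium statistic: the 2nd percentile
#'
#' The lower envelope of the session's dF/F — its 2nd percentile, computed
#' with the linear-interpolation definition (R quantile type 7) — tracks the
#' slowly varying intracellular calcium level while being robust to
#' upper-tail transients from spiking activity. Sessions with fewer than
#' `min_samples` values are flagged as gaps (NA).
#'
#' @param session_dff numeric dF/F samples of one session.
#' @param probs percentile (default 0.02).
#' @param min_samples minimum usable samples.
#' @return the level, or `NA` with attribute `gap_flag = TRUE`.
#' @export
session_level <- function(session_dff, probs = 0.02, min_samples = 50) {
  x <- session_dff[is.finite(session_dff)]
  if (length(x) < min_samples)
    return(structure(NA_real_, gap_flag = TRUE))
  structure(unname(quantile(x, probs = probs, type = 7)), gap_flag = FALSE)
}

#' Build a circadian calcium series from corrected sessions
#'
#' @param lt a `longterm_dff` (or list of per-session dF/F vectors plus
#'   `slot_start_h`).
#' @param slot_start_h session start times in hours (taken from `lt` when it
#'   is a `longterm_dff`).
#' @param ... passed to [session_level()].
#' @return data.frame (`circadian_series`): `session_id`, `bin_start_h`,
#'   `level`, `gap_flag`.
#' @export
circadian_series <- function(lt, slot_start_h = NULL, ...) {
  if (inherits(lt, "longterm_dff")) {
    slot_start_h <- lt$slot_start_h
    lt <- lt$dff
  }
  lev <- lapply(lt, session_level, ...)
  out <- data.frame(session_id = seq_along(lt),
                    bin_start_h = slot_start_h,
                    level = vapply(lev, as.numeric, numeric(1)),
                    gap_flag = vapply(lev, function(z)
                      isTRUE(attr(z, "gap_flag")), logical(1)))
  class(out) <- c("circadian_series", class(out))
  out
}

#' Per-cycle cosinor acrophase of a circadian calcium series
#'
#' For each cycle of length `period_h` (cycles partition the series timeline
#' from its start) a least-squares cosinor
#' `level ~ M + A cos(2 pi (t - phi) / period)` is fit to the unflagged bins;
#' the acrophase is the absolute hour of the fitted maximum within the cycle.
#' Amplitude is non-negative by the phase convention. Cycles whose fitted
#' amplitude is below the noise floor (`A < flag_k * SE(A)`) or with too few
#' bins are flagged arrhythmic.
#'
#' @param series a `circadian_series`.
#' @param period_h cosinor period, hours (fixed; typically the behavioral
#'   free-running period, or 24 when none is available).
#' @param min_bins minimum unflagged bins per cycle.
#' @param flag_k amplitude significance multiple.
#' @return data.frame (`acrophase_series`): `cycle_index`, `acrophase_h`,
#'   `amplitude`, `mesor`, `fit_r2`, `flagged`.
#' @export
fit_acrophase <- function(series, period_h = 24, min_bins = 8, flag_k = 2) {
  stopifnot(inherits(series, "circadian_series"))
  s <- series[!series$gap_flag & is.finite(series$level), ]
  if (nrow(s) == 0) stop("no usable bins", call. = FALSE)
  cyc <- floor(s$bin_start_h / period_h) + 1L
  omega <- 2 * pi / period_h
  rows <- lapply(sort(unique(cyc)), function(k) {
    sk <- s[cyc == k, ]
    out <- data.frame(cycle_index = k, acrophase_h = NA_real_,
                      amplitude = NA_real_, mesor = NA_real_,
                      fit_r2 = NA_real_, flagged = TRUE)
    if (nrow(sk) < min_bins) return(out)
    cc <- cos(omega * sk$bin_start_h); ss <- sin(omega * sk$bin_start_h)
    fit <- lm(level ~ cc + ss, data = cbind(sk, cc = cc, ss = ss))
    bc <- coef(fit)[["cc"]]; bs <- coef(fit)[["ss"]]
    A <- sqrt(bc^2 + bs^2)
    resid_sd <- sqrt(sum(residuals(fit)^2) / max(1, nrow(sk) - 3))
    se_A <- resid_sd * sqrt(2 / nrow(sk))
    phi <- atan2(bs, bc) / omega               # peak location mod period
    start <- (k - 1) * period_h
    acro <- phi + period_h * ceiling((start - phi) / period_h)
    out$acrophase_h <- acro
    out$amplitude <- A
    out$mesor <- coef(fit)[["(Intercept)"]]
    out$fit_r2 <- suppressWarnings(summary(fit)$r.squared)
    out$flagged <- !is.finite(A) || A < flag_k * se_A
    out
  })
  out <- do.call(rbind, rows)
  class(out) <- c("acrophase_series", class(out))
  out
}

#' Phase shift of the calcium rhythm from per-cycle acrophases
#'
#' Projects the pre-event acrophase sequence onto the post-event cycles and
#' reports `shift_h = -(mean(observed post) - mean(projected post))`, the
#' same sign convention as the locomotor module (later acrophase = delay =
#' negative). By default the projection advances by exactly `period_h` per
#' cycle (the slope implied by the cosinor model); with `slope = "fit"` and
#' at least 3 pre-event cycles the slope is estimated by OLS instead.
#'
#' @param acro an `acrophase_series`.
#' @param event_cycle last pre-event cycle index.
#' @param period_h cycle length used for the fixed-slope projection.
#' @param slope `"fixed"` (default) or `"fit"`.
#' @return list (`phase_shift_result`): `shift_h`, `direction`,
#'   `magnitude_h`, `n_pre`, `n_post`, `flagged`.
#' @export
rhythm_phase_shift <- function(acro, event_cycle, period_h,
                               slope = c("fixed", "fit")) {
  stopifnot(inherits(acro, "acrophase_series"))
  slope <- match.arg(slope)
  ok <- !acro$flagged & is.finite(acro$acrophase_h)
  pre <- acro[ok & acro$cycle_index <= event_cycle, ]
  post <- acro[ok & acro$cycle_index > event_cycle, ]
  if (nrow(pre) < 2 || nrow(post) < 2)
    return(structure(list(shift_h = NA_real_, direction = NA_character_,
                          magnitude_h = NA_real_, n_pre = nrow(pre),
                          n_post = nrow(post), flagged = TRUE),
                     class = "phase_shift_result"))
  if (slope == "fit" && nrow(pre) >= 3) {
    f <- lm(acrophase_h ~ cycle_index, data = pre)
    proj <- predict(f, newdata = post)
  } else {
    proj <- mean(pre$acrophase_h - period_h * pre$cycle_index) +
      period_h * post$cycle_index
  }
  shift <- -mean(post$acrophase_h - proj)
  structure(list(shift_h = shift,
                 direction = if (shift > 0) "advance" else if (shift < 0)
                   "delay" else "none",
                 magnitude_h = abs(shift),
                 n_pre = nrow(pre), n_post = nrow(post), flagged = FALSE),
            class = "phase_shift_result")
}
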