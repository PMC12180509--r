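#' Detect daily activity onsets in a wheel-running record
#'
#' For each cycle (default 24-h calendar day on the record's own timeline)
#' the onset is the start of the first run of at least `min_run_bins`
#' consecutive bins whose (optionally smoothed) counts reach
#' `threshold_frac` times that cycle's maximum, preceded by at least
#' `quiet_h` hours in which counts stay below the threshold (so activity
#' spilling over from the previous cycle is not mistaken for an onset). Days
#' on which no bin run satisfies the rule are flagged, never fabricated.
#'
#' @param record an `activity_record` spanning >= 3 days.
#' @param cycle_h cycle length used to partition the record into days.
#' @param min_run_bins minimum run length in bins (default 6 = 30 min at
#'   5-min bins).
#' @param threshold_frac onset threshold as a fraction of the cycle maximum.
#' @param quiet_h required quiet period before the onset, hours.
#' @param smooth_bins width (bins) of a centred moving average applied before
#'   thresholding; 1 = no smoothing (the run-length rule already rejects
#'   isolated noisy bins).
#' @return data.frame (`onset_series`): `day_index`, `onset_h` (clock hour of
#'   onset within the day, NA when flagged), `flagged`.
#' @export
detect_onsets <- function(record, cycle_h = 24, min_run_bins = 6,
                          threshold_frac = 0.2, quiet_h = 4,
                          smooth_bins = 1) {
  stopifnot(inherits(record, "activity_record"))
  bin_h <- record$bin_width_min / 60
  x <- as.numeric(record$counts)
  n <- length(x)
  if (n * bin_h < 3 * cycle_h)
    stop("record must span at least 3 days", call. = FALSE)
  if (smooth_bins > 1) {
    s <- as.numeric(stats::filter(x, rep(1 / smooth_bins, smooth_bins),
                                  sides = 2))
    s[is.na(s)] <- x[is.na(s)]
  } else s <- x

  bins_per_day <- as.integer(round(cycle_h / bin_h))
  n_days <- floor(n / bins_per_day)
  q_bins <- as.integer(round(quiet_h / bin_h))
  t_start <- (seq_len(n) - 1) * bin_h

  out <- data.frame(day_index = seq_len(n_days), onset_h = NA_real_,
                    flagged = TRUE)
  for (d in seq_len(n_days)) {
    idx <- ((d - 1) * bins_per_day + 1):(d * bins_per_day)
    cyc_max <- max(s[idx])
    if (cyc_max <= 0) next
    thr <- threshold_frac * cyc_max
    above <- s >= thr
    r <- rle(above[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    cand <- which(r$values & r$lengths >= min_run_bins)
    for (k in cand) {
      g <- idx[starts[k]]                      # global bin index of run start
      pre <- max(1L, g - q_bins):(g - 1L)
      if (g == 1L || all(!above[pre])) {
        out$onset_h[d] <- t_start[g] - (d - 1) * cycle_h
        out$flagged[d] <- FALSE
        break
      }
    }
  }
  class(out) <- c("onset_series", class(out))
  out
}

# Unwrap clock-hour onsets across midnight so successive values differ by
# less than 12 h; required before regressing onset on day.
unwrap_onsets <- function(onset_h) {
  out <- onset_h
  for (i in seq_along(out)[-1])
    out[i] <- out[i] + 24 * round((out[i - 1] - out[i]) / 24)
  out
}

#' Fit an ordinary least-squares regression to daily activity onsets
#'
#' Onsets are unwrapped across midnight, then regressed on day index; the
#' intercept is evaluated at `event_day` so pre- and post-stimulus lines can
#' be compared at a common abscissa. The free-running period implied by the
#' fit is `24 + slope`.
#'
#' @param onsets an `onset_series` from [detect_onsets()].
#' @param day_range integer vector of day indices to use (default: all).
#' @param event_day day at which the intercept is evaluated.
#' @return list (`onset_fit`): `slope_h_per_day`, `intercept_h` (at
#'   `event_day`), `r2`, `n`, `period_h`, `event_day`.
#' @export
fit_onset_regression <- function(onsets, day_range = NULL, event_day = 0) {
  ok <- !onsets$flagged & !is.na(onsets$onset_h)
  if (!is.null(day_range)) ok <- ok & onsets$day_index %in% day_range
  d <- onsets$day_index[ok]
  y <- unwrap_onsets(onsets$onset_h[ok])
  if (length(d) < 3)
    stop("need at least 3 usable onsets to fit a regression", call. = FALSE)
  fit <- lm(y ~ I(d - event_day))
  r2 <- suppressWarnings(summary(fit)$r.squared)
  slope <- unname(coef(fit)[2])
  structure(list(slope_h_per_day = slope,
                 intercept_h = unname(coef(fit)[1]),
                 r2 = r2, n = length(d), period_h = 24 + slope,
                 event_day = event_day),
            class = "onset_fit")
}

#' Phase shift from pre- and post-stimulus onset regressions
#'
#' The shift is the signed difference of the two regression lines at the
#' event day, with the phase-response-curve sign convention: a later
#' post-stimulus onset is a phase delay and yields a negative `shift_h`;
#' an earlier onset is an advance (positive).
#'
#' @param pre,post `onset_fit` objects evaluated at the same `event_day`.
#' @param event_day event day (consistency check against the fits).
#' @return list (`phase_shift_result`): `shift_h`, `direction`
#'   (`"advance"`/`"delay"`/`"none"`), `magnitude_h`, `pre_period_h`,
#'   `post_period_h`, `pre_intercept_h`, `post_intercept_h`, `n_pre`,
#'   `n_post`, `r2_pre`, `r2_post`, `flagged`.
#' @export
phase_shift <- function(pre, post, event_day = pre$event_day) {
  stopifnot(inherits(pre, "onset_fit"), inherits(post, "onset_fit"))
  if (!isTRUE(all.equal(pre$event_day, event_day)) ||
      !isTRUE(all.equal(post$event_day, event_day)))
    stop("pre and post fits must be evaluated at the same event day",
         call. = FALSE)
  delta <- post$intercept_h - pre$intercept_h
  delta <- delta - 24 * round(delta / 24)     # principal value
  shift <- -delta
  flagged <- pre$period_h <= 20 || pre$period_h >= 28 ||
    post$period_h <= 20 || post$period_h >= 28
  structure(list(
    shift_h = shift,
    direction = if (shift > 0) "advance" else if (shift < 0) "delay" else
      "none",
    magnitude_h = abs(shift),
    pre_period_h = pre$period_h, post_period_h = post$period_h,
    pre_intercept_h = pre$intercept_h, post_intercept_h = post$intercept_h,
    n_pre = pre$n, n_post = post$n, r2_pre = pre$r2, r2_post = post$r2,
    flagged = flagged), class = "phase_shift_result")
}

#' Estimate the free-running period of an activity record
#'
#' Either from the slope of the onset regression (`24 + slope`) or from the
#' peak of the Sokolove-Bushell chi-square periodogram over 20-28 h at the
#' record's bin resolution. Arrhythmic records (periodogram peak below the
#' alpha = 0.05 significance line, or too few detectable onsets) return `NA`
#' with a flag attribute.
#'
#' @param record an `activity_record` spanning >= 6 days.
#' @param method `"onset_regression"` or `"chi_square_periodogram"`.
#' @param period_range search range in hours (periodogram method).
#' @param ... passed to [detect_onsets()].
#' @return period in hours (`NA` if flagged; attribute `flagged`).
#' @export
estimate_period <- function(record,
                            method = c("onset_regression",
                                       "chi_square_periodogram"),
                            period_range = c(20, 28), ...) {
  method <- match.arg(method)
  bin_h <- record$bin_width_min / 60
  if (length(record$counts) * bin_h < 6 * 24)
    stop("need at least 6 days of data to estimate a period", call. = FALSE)
  if (method == "onset_regression") {
    ons <- detect_onsets(record, ...)
    if (sum(!ons$flagged) < 3)
      return(structure(NA_real_, flagged = TRUE))
    fit <- fit_onset_regression(ons)
    structure(fit$period_h, flagged = FALSE)
  } else {
    pg <- chisq_periodogram(record, period_range = period_range)
    best <- attr(pg, "best_period_h")
    structure(best, flagged = is.na(best))
  }
}

#' Sokolove-Bushell chi-square periodogram
#'
#' For each candidate period of P bins the record is folded into P phase
#' columns over K complete cycles and the statistic
#' `Qp = K * sum((col means - grand mean)^2) / overall variance` is computed;
#' under noise `Qp ~ chi-square(P - 1)`. The best period is the candidate
#' whose Qp exceeds its `1 - alpha` significance line by the largest margin
#' (NA when no candidate is significant, e.g. an arrhythmic record).
#'
#' @param record an `activity_record`.
#' @param period_range candidate period range, hours.
#' @param alpha significance level for the chi-square line.
#' @return data.frame `period_h`, `Qp`, `Q_crit`; attributes
#'   `best_period_h`, `alpha`.
#' @export
chisq_periodogram <- function(record, period_range = c(20, 28),
                              alpha = 0.05) {
  stopifnot(inherits(record, "activity_record"))
  bin_h <- record$bin_width_min / 60
  x <- as.numeric(record$counts)
  n <- length(x)
  p_bins <- seq(as.integer(ceiling(period_range[1] / bin_h)),
                as.integer(floor(period_range[2] / bin_h)))
  p_bins <- p_bins[p_bins * 2 <= n]          # need >= 2 full cycles
  if (length(p_bins) == 0)
    stop("record too short for the requested period range", call. = FALSE)
  gm <- mean(x)
  s2 <- mean((x - gm)^2)
  Qp <- vapply(p_bins, function(P) {
    K <- n %/% P
    xm <- matrix(x[seq_len(K * P)], nrow = P)
    colm <- rowMeans(xm)                      # mean per phase bin
    if (s2 == 0) return(NA_real_)
    K * sum((colm - mean(x[seq_len(K * P)]))^2) / s2
  }, numeric(1))
  Q_crit <- qchisq(1 - alpha, df = p_bins - 1)
  out <- data.frame(period_h = p_bins * bin_h, Qp = Qp, Q_crit = Q_crit)
  excess <- Qp - Q_crit
  best <- if (all(is.na(excess)) || max(excess, na.rm = TRUE) <= 0)
    NA_real_ else out$period_h[which.max(excess)]
  attr(out, "best_period_h") <- best
  attr(out, "alpha") <- alpha
  out
}

#' Compare phase shifts between two groups
#'
#' Two-tailed Student's t test (pooled variance) or paired t test on the
#' per-animal `shift_h` values, matching standard practice for two-sample
#' comparisons of phase shifts. When both groups are constant with equal
#' means the convention `t = 0, p = 1` is used; constant groups with unequal
#' means return `t = +/-Inf, p = 0`.
#'
#' @param group_a,group_b numeric vectors of shifts, or lists of
#'   `phase_shift_result`.
#' @param paired logical; paired test requires equal lengths.
#' @return list: `mean_a`, `mean_b`, `t`, `p`, `df`, `paired`.
#' @export
compare_shifts <- function(group_a, group_b, paired = FALSE) {
  pull <- function(g) {
    if (is.list(g) && !is.data.frame(g) && length(g) &&
        inherits(g[[1]], "phase_shift_result"))
      vapply(g, `[[`, numeric(1), "shift_h") else as.numeric(g)
  }
  a <- pull(group_a); b <- pull(group_b)
  if (length(a) < 2 || length(b) < 2)
    stop("need n >= 2 per group", call. = FALSE)
  if (paired && length(a) != length(b))
    stop("paired comparison requires equal group sizes", call. = FALSE)
  res <- tryCatch(
    t.test(a, b, paired = paired, var.equal = !paired),
    error = function(e) NULL)
  if (!is.null(res) && !is.finite(res$statistic)) res <- NULL
  if (is.null(res)) {                          # zero-variance convention
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      tv <- 0; pv <- 1
    } else {
      tv <- sign(mean(a) - mean(b)) * Inf; pv <- 0
    }
    df <- if (paired) length(a) - 1 else length(a) + length(b) - 2
    return(list(mean_a = mean(a), mean_b = mean(b), t = tv, p = pv,
                df = df, paired = paired))
  }
  list(mean_a = mean(a), mean_b = mean(b),
       t = unname(res$statistic), p = res$p.value,
       df = unname(res$parameter), paired = paired)
}
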