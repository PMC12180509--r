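# Independent oracles used across test files.

# Fine-grid midpoint Riemann-sum integral of a linearly interpolated trace.
riemann_auc <- function(values, time_s, window, dt = 1e-4) {
  n <- ceiling((window[2] - window[1]) / dt)
  dt <- (window[2] - window[1]) / n
  xs <- window[1] + (seq_len(n) - 0.5) * dt
  ys <- approx(time_s, values, xout = xs)$y
  sum(ys) * dt
}

# Sort-based 2nd percentile with the linear-interpolation (type 7) rule,
# written out from first principles.
sort_percentile <- function(x, p = 0.02) {
  x <- sort(x)
  h <- (length(x) - 1) * p
  lo <- floor(h)
  x[lo + 1] + (h - lo) * (x[min(lo + 2, length(x))] - x[lo + 1])
}

# Closed-form OLS slope/intercept via the normal equations.
ols_normal_equations <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  a <- sum((x - mean(x)) * (y - mean(y))) / sxx
  c(b = mean(y) - a * mean(x), a = a)
}

# A square-wave activity record: active (count `hi`) for `active_h` hours
# starting at `onset_h` each `period_h`-hour cycle.
square_wave_record <- function(n_days, onset_h = 12, period_h = 24,
                               active_h = 10, hi = 50, bin_min = 5) {
  bin_h <- bin_min / 60
  n <- as.integer(n_days * 24 / bin_h)
  mid <- (seq_len(n) - 0.5) * bin_h
  phase <- (mid - onset_h) %% period_h
  counts <- ifelse(phase < active_h, hi, 0)
  activity_record(counts, bin_width_min = bin_min)
}
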