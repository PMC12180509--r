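#' Double-plotted actogram
#'
#' Standard chronobiology raster: each row shows 48 h (day d followed by day
#' d + 1) so rhythms crossing midnight stay readable.
#'
#' @param record an `activity_record`.
#' @param double logical; FALSE gives a single-plotted 24-h raster.
#' @return a ggplot object.
#' @export
plot_actogram <- function(record, double = TRUE) {
  stopifnot(inherits(record, "activity_record"))
  bin_h <- record$bin_width_min / 60
  bins_per_day <- as.integer(round(24 / bin_h))
  n_days <- floor(length(record$counts) / bins_per_day)
  x <- record$counts[seq_len(n_days * bins_per_day)]
  df <- data.frame(day = rep(seq_len(n_days), each = bins_per_day),
                   hour = rep((seq_len(bins_per_day) - 0.5) * bin_h, n_days),
                   count = x)
  if (double && n_days > 1) {
    nxt <- df[df$day > 1, ]
    nxt$day <- nxt$day - 1
    nxt$hour <- nxt$hour + 24
    df <- rbind(df, nxt)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = hour, y = day, alpha = count)) +
    ggplot2::geom_tile(fill = "black", height = 0.9) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_alpha_continuous(range = c(0, 1), guide = "none") +
    ggplot2::labs(x = "Time (h)", y = "Day",
                  title = record$animal_id) +
    ggplot2::theme_minimal()
}

#' Peri-event trial heatmap
#'
#' @param ts a `trial_set`.
#' @return a ggplot object.
#' @export
plot_trial_heatmap <- function(ts) {
  stopifnot(inherits(ts, "trial_set"))
  df <- data.frame(trial = rep(seq_len(nrow(ts$trials)),
                               times = ncol(ts$trials)),
                   time = rep(ts$rel_time_s, each = nrow(ts$trials)),
                   value = as.vector(ts$trials))
  ggplot2::ggplot(df, ggplot2::aes(x = time, y = trial, fill = value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_vline(xintercept = ts$stim_win_s, linetype = 2) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red") +
    ggplot2::labs(x = "Time from window start (s)", y = "Trial",
                  fill = if (ts$zscored) "z(dF/F)" else "dF/F") +
    ggplot2::theme_minimal()
}
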