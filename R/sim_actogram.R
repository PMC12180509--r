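#' Simulate a wheel-running actogram with a known injected phase shift
#'
#' Generates 5-min-binned wheel-revolution counts for one animal free-running
#' at period `tau_h` in constant darkness. The activity onset of day `d`
#' drifts by `tau_h - 24` hours per day, carries Gaussian day-to-day jitter,
#' and for days after `event_day` is additionally displaced by
#' `injected_shift_h` (advance positive = earlier onset). Counts are Poisson:
#' `mean_counts_active` per bin inside the active phase
#' (`active_fraction * tau_h` hours from onset), `mean_counts_rest` outside.
#'
#' @param cfg a [sim_config()].
#' @param animal_id identifier stored on the record.
#' @return a list with elements `record` (an `activity_record`: `start_time`,
#'   `bin_width_min`, `counts`, `animal_id`) and `truth` (a `ground_truth`
#'   list carrying `true_shift_h`, `true_period_h`, `true_onsets_h` — absolute
#'   hours from record start, before count discretisation — and `event_day`).
#' @export
simulate_actogram <- function(cfg, animal_id = "sim") {
  cfg <- validate_sim_config(cfg)
  n_days <- cfg$n_days_pre + cfg$n_days_post
  bin_h <- 5 / 60
  bins_per_day <- as.integer(24 / bin_h)
  n_bins <- n_days * bins_per_day

  withr::with_seed(cfg$seed, {
    jitter <- rnorm(n_days, 0, cfg$onset_jitter_sd_h)
    day <- seq_len(n_days)
    onset_abs <- cfg$onset_start_h + (day - 1) * cfg$tau_h + jitter -
      cfg$injected_shift_h * (day > cfg$event_day)
    active_len <- cfg$active_fraction * cfg$tau_h

    mid <- (seq_len(n_bins) - 0.5) * bin_h
    lambda <- rep(cfg$mean_counts_rest, n_bins)
    for (d in day) {
      on <- onset_abs[d]
      lambda[mid >= on & mid < on + active_len] <- cfg$mean_counts_active
    }
    counts <- if (cfg$poisson_noise) rpois(n_bins, lambda) else
      as.integer(round(lambda))
  })

  record <- structure(
    list(start_time = as.POSIXct("2024-01-01 00:00:00", tz = "UTC"),
         bin_width_min = 5, counts = as.integer(counts),
         animal_id = animal_id),
    class = "activity_record")
  truth <- structure(
    list(true_shift_h = cfg$injected_shift_h, true_period_h = cfg$tau_h,
         true_onsets_h = onset_abs, event_day = cfg$event_day),
    class = "ground_truth")
  list(record = record, truth = truth)
}

#' Construct an activity record
#'
#' @param counts non-negative integer counts, one per bin.
#' @param bin_width_min bin width in minutes (must divide 60).
#' @param start_time absolute timestamp of the first bin.
#' @param animal_id identifier.
#' @return an `activity_record`.
#' @export
activity_record <- function(counts, bin_width_min = 5,
                            start_time = as.POSIXct("2024-01-01 00:00:00",
                                                    tz = "UTC"),
                            animal_id = "animal") {
  counts <- as.integer(counts)
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative integers", call. = FALSE)
  if (60 %% bin_width_min != 0)
    stop("bin_width_min must divide 60", call. = FALSE)
  structure(list(start_time = start_time, bin_width_min = bin_width_min,
                 counts = counts, animal_id = animal_id),
            class = "activity_record")
}

#' @export
print.activity_record <- function(x, ...) {
  cat("<activity_record>", x$animal_id, "-", length(x$counts), "bins of",
      x$bin_width_min, "min (", round(length(x$counts) * x$bin_width_min
                                      / 60 / 24, 2), "days )\n")
  invisible(x)
}
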