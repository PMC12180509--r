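#' Read a binned activity record from CSV
#'
#' Expects a header with `timestamp` (ISO-8601) and `count` columns.
#' Malformed rows are reported with their line numbers; non-monotone
#' timestamps and negative counts are errors.
#'
#' @param path CSV file path.
#' @param animal_id identifier stored on the record (default: file name).
#' @return an `activity_record`.
#' @export
read_activity_csv <- function(path, animal_id = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty input: ", path, call. = FALSE)
  if (!all(c("timestamp", "count") %in% names(df)))
    stop("header must name 'timestamp' and 'count' columns", call. = FALSE)
  ts <- as.POSIXct(df$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  bad <- which(is.na(ts) | is.na(suppressWarnings(as.numeric(df$count))))
  if (length(bad))
    stop("malformed rows at lines: ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  cnt <- as.numeric(df$count)
  neg <- which(cnt < 0)
  if (length(neg))
    stop("negative count at line ", neg[1] + 1L, call. = FALSE)
  dt <- as.numeric(diff(ts), units = "mins")
  if (any(dt <= 0))
    stop("non-monotone timestamps at line ",
         which(dt <= 0)[1] + 2L, call. = FALSE)
  bin <- stats::median(dt)
  if (is.null(animal_id)) animal_id <- basename(path)
  activity_record(cnt, bin_width_min = bin, start_time = ts[1],
                  animal_id = animal_id)
}

#' Write an activity record to CSV
#'
#' @param record an `activity_record`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_activity_csv <- function(record, path) {
  stopifnot(inherits(record, "activity_record"))
  ts <- record$start_time +
    (seq_along(record$counts) - 1) * record$bin_width_min * 60
  df <- data.frame(timestamp = format(ts, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                   count = record$counts)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a two-channel photometry recording as CSV
#'
#' The trace file has columns `time_s`, `sig`, `ref`; events go to a sidecar
#' `<path>.events.csv` with columns `time_s`, `kind`.
#'
#' @param rec a `photometry_recording`.
#' @param path trace CSV path.
#' @return `path`, invisibly.
#' @export
write_photometry_csv <- function(rec, path) {
  stopifnot(inherits(rec, "photometry_recording"))
  write.csv(data.frame(time_s = rec$time_s, sig = rec$sig, ref = rec$ref),
            path, row.names = FALSE, quote = FALSE)
  if (!is.null(rec$events))
    write.csv(rec$events, paste0(path, ".events.csv"), row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_photometry_csv
#' @export
read_photometry_csv <- function(path) {
  df <- read.csv(path)
  if (nrow(df) == 0) stop("empty input: ", path, call. = FALSE)
  ev_path <- paste0(path, ".events.csv")
  events <- if (file.exists(ev_path)) read.csv(ev_path) else NULL
  photometry_recording(df$time_s, df$sig, df$ref, events = events)
}

#' Write / read an ROI trace matrix as long-format CSV
#'
#' Columns `roi_id`, `frame`, `F`; stimulation frames, fps and condition go
#' to a JSON sidecar `<path>.meta.json`.
#'
#' @param traces a `roi_trace_matrix`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_roi_csv <- function(traces, path) {
  stopifnot(inherits(traces, "roi_trace_matrix"))
  n_roi <- nrow(traces$F); n_fr <- ncol(traces$F)
  df <- data.frame(roi_id = rep(seq_len(n_roi), each = n_fr),
                   frame = rep(seq_len(n_fr), n_roi),
                   F = as.vector(t(traces$F)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(fps = traces$fps,
                            stim_frames = traces$stim_frames,
                            condition = traces$condition),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_roi_csv
#' @export
read_roi_csv <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  rois <- sort(unique(df$roi_id))
  n_fr <- max(df$frame)
  Fm <- matrix(NA_real_, length(rois), n_fr)
  for (i in seq_along(rois)) {
    sub <- df[df$roi_id == rois[i], ]
    Fm[i, sub$frame] <- sub$F
  }
  structure(list(F = Fm, fps = meta$fps,
                 stim_frames = as.integer(meta$stim_frames),
                 condition = meta$condition),
            class = "roi_trace_matrix")
}

#' Write / read a ground-truth sidecar as JSON
#'
#' @param truth a `ground_truth` list.
#' @param path JSON path.
#' @return `path` invisibly / a `ground_truth`.
#' @export
write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth_json
#' @export
read_ground_truth_json <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "ground_truth")
}
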