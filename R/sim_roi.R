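#' Simulate a two-photon ROI x frame fluorescence matrix
#'
#' Emulates slice calcium imaging at 30 frames/s with `n_stims` optogenetic
#' stimulation trains (default 5, 20-s inter-stimulus interval, first at
#' 10 s). ROI types, drawn from `cfg$roi_type_probs`:
#' * `typeI` — sustained positive transient at each stimulation;
#' * `typeII` — brief positive transient followed by a slow dip below
#'   baseline (an excitation/inhibition sequence);
#' * `nonresponder` — noise only.
#'
#' @param cfg a [sim_config()].
#' @param n_rois number of ROIs (>= 1).
#' @param n_stims number of stimulations (>= 1; default 5).
#' @param condition recording condition label: `"ACSF"`, `"TTX_4AP"`, or
#'   `"APV_CNQX"`. Under `"TTX_4AP"` the inhibitory lobe of typeII ROIs is
#'   removed and excitation is enhanced (network inhibition blocked); under
#'   `"APV_CNQX"` evoked responses are abolished (glutamatergic transmission
#'   blocked).
#' @param fps frames per second.
#' @param duration_s total trace duration in seconds.
#' @return list with `traces` (a `roi_trace_matrix`: `F` matrix ROI x frame,
#'   `fps`, `stim_frames`, `condition`) and `truth` (`roi_labels`).
#' @export
simulate_roi_traces <- function(cfg, n_rois, n_stims = 5,
                                condition = c("ACSF", "TTX_4AP", "APV_CNQX"),
                                fps = 30, duration_s = 120) {
  cfg <- validate_sim_config(cfg)
  condition <- match.arg(condition)
  if (n_rois < 1 || n_stims < 1)
    stop("n_rois and n_stims must be >= 1", call. = FALSE)
  stim_s <- 10 + (seq_len(n_stims) - 1) * 20
  if (max(stim_s) + 20 > duration_s)
    duration_s <- max(stim_s) + 30
  n_frames <- as.integer(duration_s * fps)
  t <- (seq_len(n_frames) - 1) / fps

  amp_pos <- 0.30
  amp_neg <- 0.20
  gain <- switch(condition, ACSF = 1, TTX_4AP = 1.5, APV_CNQX = 0)
  keep_dip <- condition == "ACSF"
  noise_sd <- 0.05

  kern_pos_I <- function(tt) transient_kernel(tt, "positive", decay_s = 8,
                                              rise_s = 0.5)
  kern_pos_II <- function(tt) transient_kernel(tt, "positive", decay_s = 1.5,
                                               rise_s = 0.3)
  kern_dip <- function(tt) -transient_kernel(tt - 3, "positive",
                                             decay_s = 15, rise_s = 2)

  withr::with_seed(cfg$seed, {
    labels <- sample(names(cfg$roi_type_probs), n_rois, replace = TRUE,
                     prob = cfg$roi_type_probs)
    F0 <- rnorm(n_rois, 100, 10)
    F0 <- pmax(F0, 20)
    Fm <- matrix(0, n_rois, n_frames)
    for (i in seq_len(n_rois)) {
      resp <- rep(0, n_frames)
      if (labels[i] != "nonresponder" && gain > 0) {
        for (s in stim_s) {
          if (labels[i] == "typeI") {
            resp <- resp + gain * amp_pos * kern_pos_I(t - s)
          } else {
            resp <- resp + gain * amp_pos * kern_pos_II(t - s)
            if (keep_dip) resp <- resp + amp_neg * kern_dip(t - s)
          }
        }
      }
      Fm[i, ] <- F0[i] * (1 + resp + rnorm(n_frames, 0, noise_sd))
    }
  })

  traces <- structure(
    list(F = Fm, fps = fps,
         stim_frames = as.integer(round(stim_s * fps)) + 1L,
         condition = condition),
    class = "roi_trace_matrix")
  truth <- structure(list(roi_labels = labels), class = "ground_truth")
  list(traces = traces, truth = truth)
}
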