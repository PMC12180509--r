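#!/usr/bin/env Rscript
# Generates one example dataset per recording modality with its ground-truth
# sidecar, written as plain CSV/JSON under results/simulated/. These files
# illustrate the on-disk formats; all downstream analyses regenerate their
# own cohorts in memory.

suppressPackageStartupMessages(library(zeitshift))
out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# wheel-running actogram, footshock at early subjective night
cfg <- preset_config("ct14_footshock", seed = 1)
act <- simulate_actogram(cfg, animal_id = "example_mouse")
write_activity_csv(act$record, file.path(out, "actogram_ct14_footshock.csv"))
write_ground_truth_json(act$truth,
                        file.path(out, "actogram_ct14_footshock.truth.json"))
message("actogram: ", length(act$record$counts), " five-min bins, ",
        "injected shift ", act$truth$true_shift_h, " h")

# event-locked photometry, five footshocks
ph <- simulate_trial_photometry(sim_config(seed = 2), n_trials = 5)
write_photometry_csv(ph$recording, file.path(out, "photometry_shock.csv"))
write_ground_truth_json(ph$truth,
                        file.path(out, "photometry_shock.truth.json"))
message("photometry: ", length(ph$recording$time_s), " samples, ",
        nrow(ph$recording$events), " events")

# ROI trace matrix (kept small on disk)
ro <- simulate_roi_traces(sim_config(seed = 3), n_rois = 12)
write_roi_csv(ro$traces, file.path(out, "roi_traces.csv"))
write_ground_truth_json(ro$truth, file.path(out, "roi_traces.truth.json"))
message("ROI matrix: ", nrow(ro$traces$F), " x ", ncol(ro$traces$F))

message("wrote example data under ", out)
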