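#!/usr/bin/env Rscript
# Event-locked photometry analysis: simulates animals with excitatory,
# delayed-inhibitory, or absent evoked transients, runs the isosbestic ->
# dF/F -> trial segmentation -> 2-SD classification pipeline per animal, and
# tabulates response calls, AUC (baseline vs stimulus window) and peak
# latencies. Reproduces the qualitative latency ordering: inhibition peaks
# later than excitation.

suppressPackageStartupMessages(library(zeitshift))
dir.create("results", showWarnings = FALSE)

kinds <- rep(c("positive", "negative_delayed", "none"), each = 6)
rows <- lapply(seq_along(kinds), function(i) {
  cfg <- sim_config(seed = 200 + i, transient_kind = kinds[i])
  sim <- simulate_trial_photometry(cfg, n_trials = 5)
  res <- analyze_trials(sim$recording, z_score = TRUE)
  data.frame(animal = i, transient_kind = kinds[i],
             true_label = sim$truth$trial_labels[1],
             label = res$call$label,
             peak_z = res$call$peak_value,
             latency_s = res$call$peak_latency_s,
             auc_baseline = res$call$auc_baseline,
             auc_stim = res$call$auc_stim)
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/photometry_response_calls.csv", row.names = FALSE)

acc <- mean(tab$label == tab$true_label)
lat_exc <- mean(tab$latency_s[tab$label == "excitatory"])
lat_inh <- mean(tab$latency_s[tab$label == "inhibitory"])
message(sprintf("classification accuracy: %.2f", acc))
message(sprintf("mean latency to peak: excitation %.2f s, inhibition %.2f s",
                lat_exc, lat_inh))

ex <- analyze_trials(simulate_trial_photometry(
  sim_config(seed = 201, transient_kind = "positive"))$recording)
g <- plot_trial_heatmap(ex$trial_set)
ggplot2::ggsave("results/trial_heatmap_excitatory.png", g, width = 6,
                height = 3, dpi = 150)

jsonlite::write_json(list(accuracy = acc, mean_latency_excitatory_s = lat_exc,
                          mean_latency_inhibitory_s = lat_inh),
                     "results/photometry_summary.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
message("wrote results/photometry_response_calls.csv and summary")
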