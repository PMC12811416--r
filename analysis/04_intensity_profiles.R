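#!/usr/bin/env Rscript
# Extract the distal 50-um axial intensity profiles, subtract
# background, compute per-axon integrated fold change versus the
# control group, the growth-cone (first 10 um) fraction, and the two
# visualization baseline corrections.

library(axoquant)

cal <- calibration(0.2)
axons <- read_table("results/sim_profiles.csv")
bg <- 10  # cell-free background of the simulated images
profs <- list(); rows <- list()
for (i in seq_len(nrow(axons))) {
  g <- axons$group[i]; id <- axons$axon[i]
  img <- read_image(sprintf("scratch/sim/profile_%s_%02d.tif", g, id),
                    cal)
  roi <- load_roi(sprintf("scratch/sim/profile_%s_%02d_roi.csv", g, id))
  p <- subtract_background(extract_profile(img, roi, 50), bg)
  profs[[i]] <- p
  rows[[i]] <- data.frame(group = g, axon = id,
                          integral = integrated_intensity(p),
                          terminal_fraction_pct = terminal_fraction(p))
}
tab <- do.call(rbind, rows)

ctrl <- which(tab$group == "scrambled")
fc <- integrated_fold_change(profs[-ctrl], profs[ctrl])
tab$fold <- NA
tab$fold[-ctrl] <- fc$fold_treated
tab$fold[ctrl] <- fc$fold_control
write_table(tab, "results/profile_metrics.csv")

# corrected mean traces (visualization only, never used for the folds)
mean_trace <- function(idx, mode) {
  mats <- vapply(profs[idx], function(p)
    correct_baseline(p, mode)$values, numeric(length(profs[[1]]$values)))
  rowMeans(mats)
}
trace <- data.frame(
  distance_um = profs[[1]]$distances_um,
  scrambled_distal = mean_trace(ctrl, "distal_window"),
  axonal_kd_distal = mean_trace(setdiff(seq_along(profs), ctrl),
                                "distal_window"))
write_table(trace, "results/profile_corrected_traces.csv")

kd_fold <- mean(tab$fold[tab$group == "axonal_kd"])
cat(sprintf("Mean integrated fold change, axonal KD vs scrambled: %.3f\n",
            kd_fold))
cat(sprintf("  (the simulation reduced the distal signal to 0.54; the\n"))
cat(sprintf("   measured decrease is %.0f%%)\n", 100 * (1 - kd_fold)))
cat(sprintf("Mean terminal (first 10 um) fraction: %.1f%% of the 0-50 um\n",
            mean(tab$terminal_fraction_pct)))
cat("signal, as expected for a tip-enriched exponential distribution.\n")
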