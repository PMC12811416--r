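#!/usr/bin/env Rscript
# Simulate the full synthetic study: axon fields, growth cones, axial
# profiles, comet movies and two-channel/puncta images for two
# experimental conditions (control vs axonal knockdown emulation).
# Images (binary TIFFs) go to scratch/sim/; the truth tables the later
# stages compare against go to results/.

library(axoquant)

dir.create("scratch/sim", showWarnings = FALSE, recursive = TRUE)
dir.create("results", showWarnings = FALSE)
set.seed(1234)

cal_axon <- calibration(1)                       # um/px, outgrowth fields
cal_live <- calibration(0.2, frame_interval_s = 0.5)  # 2 fps live imaging

## Axon fields: the knockdown condition grows longer axons, the effect
## the outgrowth assay is designed to detect.
conds <- list(scrambled = c(100, 1100), axonal_kd = c(400, 1400))
truth_rows <- list()
for (g in names(conds)) {
  for (i in 1:8) {
    rays <- random_ray_spec(sample(5:9, 1), conds[[g]],
                            seed = 10000 + 100 * match(g, names(conds)) + i)
    af <- make_axon_field(rays, c(1420, 2840), cal_axon,
                          radii_um = seq(2, 1500, 2))
    write_image(af$mask, sprintf("scratch/sim/axons_%s_%02d.tif", g, i))
    write_table(data.frame(radius_um = af$truth$radii_um,
                           expected = af$truth$expected_counts),
                sprintf("scratch/sim/axons_%s_%02d_truth.csv", g, i))
    truth_rows[[length(truth_rows) + 1]] <-
      data.frame(group = g, field = i,
                 center_x = af$truth$center[1],
                 center_y = af$truth$center[2],
                 n_rays = length(rays))
  }
}
write_table(do.call(rbind, truth_rows), "results/sim_axon_fields.csv")

## Growth cones: knockdown GCs are more elongated with fewer filopodia.
gc_spec <- list(
  scrambled = list(ab = c(1.3, 1.9), filo = 4:7),
  axonal_kd = list(ab = c(2.1, 2.9), filo = 1:3))
gc_rows <- list()
for (g in names(gc_spec)) {
  for (i in 1:10) {
    set.seed(20000 + 100 * match(g, names(gc_spec)) + i)
    ab <- runif(1, gc_spec[[g]]$ab[1], gc_spec[[g]]$ab[2])
    b <- runif(1, 3, 4.5); a <- ab * b
    nf <- sample(gc_spec[[g]]$filo, 1)
    filo <- data.frame(t_rad = runif(nf, 0.3, pi - 0.3) *
                         sample(c(-1, 1), nf, replace = TRUE),
                       length_um = runif(nf, 1.3, 3.5), width_px = 3)
    gcn <- make_growth_cone(a, b, runif(1, 0, pi), filo,
                            c(420, 420), calibration(0.1))
    write_image(gcn$mask, sprintf("scratch/sim/gc_%s_%02d.tif", g, i))
    gc_rows[[length(gc_rows) + 1]] <-
      data.frame(group = g, cell = i, a_um = a, b_um = b,
                 true_ab = ab, n_filopodia_true = nf)
  }
}
write_table(do.call(rbind, gc_rows), "results/sim_growth_cones.csv")

## Distal axon profiles: knockdown reduces the protein's distal signal
## by ~46% while the baseline stays.
prof_rows <- list()
for (g in c("scrambled", "axonal_kd")) {
  gain <- if (g == "scrambled") 1 else 0.54
  for (i in 1:12) {
    set.seed(30000 + 100 * (g == "axonal_kd") + i)
    amp <- gain * runif(1, 90, 110)
    pf <- make_profile_image(function(d) amp * exp(-d / 18),
                             50, 5, baseline = 10, calibration(0.2))
    write_image(pf$image, sprintf("scratch/sim/profile_%s_%02d.tif", g, i))
    write_roi(pf$roi, sprintf("scratch/sim/profile_%s_%02d_roi.csv", g, i))
    prof_rows[[length(prof_rows) + 1]] <-
      data.frame(group = g, axon = i, amplitude = amp)
  }
}
write_table(do.call(rbind, prof_rows), "results/sim_profiles.csv")

## EB3 comet movies, 3 min at 2 fps: injury slows the growth rate
## (0.09 -> 0.06 um/s emulation).
for (g in c("noninjured", "injured")) {
  v0 <- if (g == "noninjured") 0.09 else 0.06
  comets <- random_comet_spec(25, (260 - 11) * 0.2, 180,
                              v_range_um_s = v0 + c(-0.02, 0.02),
                              lifetime_range_s = c(10, 30),
                              seed = 40000 + (g == "injured"))
  cm <- make_comet_movie(comets, image_size_px = c(260, 21),
                         calibration = cal_live, n_frames = 360,
                         noise_sd = 20, seed = 40010 + (g == "injured"))
  write_movie(cm$movie, sprintf("scratch/sim/comets_%s.tif", g))
  write_roi(cm$axis, sprintf("scratch/sim/comets_%s_axis.csv", g))
  write_table(comets, sprintf("scratch/sim/comets_%s_truth.csv", g))
}

## Two-channel pairs at controlled overlap, and puncta fields.
for (f in c(0.1, 0.6)) {
  cp <- make_coloc_pair(40, 40, f, c(256, 256), calibration(1),
                        seed = 50000 + round(100 * f))
  write_image(cp$ch1, sprintf("scratch/sim/coloc_f%02d_ch1.tif", 100 * f))
  write_image(cp$ch2, sprintf("scratch/sim/coloc_f%02d_ch2.tif", 100 * f))
}
mk <- matrix(FALSE, 256, 256); mk[, 1:128] <- TRUE
mask <- binary_mask(mk, calibration(1))
write_image(mask, "scratch/sim/puncta_mask.tif")
pr <- list()
for (i in 1:10) {
  n_in <- sample(4:10, 1); n_out <- sample(2:6, 1)
  pf <- make_puncta_field(mask, n_in, n_out, noise_sd = 20,
                          min_sep_px = 6, seed = 60000 + i)
  write_image(pf$image, sprintf("scratch/sim/puncta_%02d.tif", i))
  pr[[i]] <- data.frame(field = i, n_inside = n_in, n_outside = n_out,
                        background = pf$truth$background)
}
write_table(do.call(rbind, pr), "results/sim_puncta_truth.csv")

cat("Simulated: 16 axon fields, 20 growth cones, 24 profile images,\n",
    "2 comet movies, 2 coloc pairs, 10 puncta fields.\n",
    "Images under scratch/sim/, truth tables under results/.\n")
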