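# axoquant

Quantitative fluorescence image analysis of axonal regeneration, for
neurobiologists measuring how cortical axons regrow after injury in
microfluidic chambers. The package provides tested, scriptable
implementations of the measurements such studies usually assemble from
interactive FIJI sessions:

- **Sholl analysis of outgrowth** — intersections of a binarized axon
  field with concentric *semicircles* of radius *r = 2, 4, … µm*
  (up to 1,200–1,500 µm) centered at the microgroove exit, plus the
  summed intersections per distance bin (0–500, 500–1,000,
  1,000–1,500 µm).
- **Growth-cone morphometry** — from an actin-outline mask: area (µm²),
  perimeter (µm), elongation ratio (major/minor axis of the
  second-moment ellipse), longest shortest path
  (LSP = max<sub>u,v</sub> d<sub>geo</sub>(u, v) over skeleton nodes),
  and the number of filopodia (terminal skeleton branches longer than
  1.0 µm).
- **Axial intensity profiles** — mean intensity along a 1-µm-wide
  segmented line from the axon tip 50 µm proximally; background
  subtraction, tip-anchored and distal-window (45–50 µm) baseline
  corrections, integrated fold change vs a control group, and the
  growth-cone fraction (% of signal in the first 10 µm).
- **Microtubule plus-end dynamics** — EB3 comet movies (3 min at
  2 fps) are separated into mobile and static components by a temporal
  difference of Gaussians (σ = 4 vs 50 frames), turned into kymographs
  along the axon, and each dash converted to
  track length = |Δx| · µm/px, lifetime = Δy/Y · T, and growth
  rate = track/lifetime (≡ L·cos θ and L·sin θ·T/Y for isotropic
  kymograph pixels).
- **Colocalization and local translation** — thresholded Manders
  coefficients M1/M2 for two-channel images, and counting of
  PLA-style puncta whose centroids fall inside a cell or axon mask.

Because raw microscopy for such experiments is rarely public, the
package ships a **synthetic-microscopy generator** (`make_axon_field`,
`make_growth_cone`, `make_comet_movie`, `make_coloc_pair`,
`make_puncta_field`, `make_profile_image`) that renders each input
modality with known ground truth — every stage of the pipeline is
validated against analytic geometry or generator bookkeeping, not
against eyeballed output.

## Worked example: comet dynamics end to end

```r
library(axoquant)

cal <- calibration(0.2, frame_interval_s = 0.5)   # 0.2 um/px, 2 fps
comets <- random_comet_spec(5, axis_length_um = 45, total_time_s = 180,
                            seed = 42)
sim <- make_comet_movie(comets, image_size_px = c(260, 21),
                        calibration = cal, n_frames = 360,
                        noise_sd = 20, seed = 43)          # SNR 5
kymo   <- build_kymograph(separate_mobile_static(sim$movie), sim$axis)
params <- do.call(rbind, lapply(detect_dashes(kymo), dash_params,
                                kymo = kymo))
summarize_dynamics(params)
```

```
                metric       mean          se n
1      track_length_um  2.4750777 0.414070502 5
2           lifetime_s 19.5817356 2.856472424 5
3 growth_rate_um_per_s  0.1259424 0.005210158 5
```

All five simulated comets are recovered as one dash each; the mean
growth rate of 0.126 µm/s sits within 5% of the generator's true mean
of 0.133 µm/s (`mean(comets$v_um_s)`), and each comet's
rate × lifetime equals its track length by construction.

## The analysis workflow

`analysis/` contains numbered drivers that run the whole synthetic
study — two conditions per assay (control vs axonal-knockdown-like,
noninjured vs injured) — and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R              # all synthetic inputs
Rscript analysis/02_outgrowth_sholl.R       # Sholl profiles + bin sums
Rscript analysis/03_growth_cone_morphometry.R
Rscript analysis/04_intensity_profiles.R    # folds, terminal fractions
Rscript analysis/05_comet_dynamics.R        # kymograph pipeline
Rscript analysis/06_colocalization_puncta.R
```

Intermediate TIFFs land in `scratch/` (disposable); CSV tables in
`results/`.

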