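# End-to-end orchestration: a declarative JSON/list config drives
# simulate -> analyze -> summarize stages, with a manifest for exact
# reproducibility. Identical config + seed give byte-identical CSVs.

stage_param_spec <- list(
  simulate_axons = c("name", "n_rays", "length_range_um", "image_size_px",
                     "radii_um"),
  simulate_gc = c("name", "a_um", "b_um", "theta_rad", "image_size_px"),
  simulate_comets = c("name", "n_comets", "image_size_px", "n_frames",
                      "noise_sd", "amplitude", "sigma_px", "v_range_um_s",
                      "lifetime_range_s", "n_static"),
  simulate_coloc = c("name", "n_ch1", "n_ch2", "overlap_fraction",
                     "image_size_px", "amplitude", "sigma_px"),
  simulate_puncta = c("name", "n_inside", "n_outside", "amplitude",
                      "sigma_px", "noise_sd", "image_size_px"),
  simulate_profile = c("name", "peak", "decay_um", "baseline",
                       "length_um", "width_px"),
  sholl = c("name", "mask", "center", "direction", "radius_step_um",
            "r_max_um", "bin_edges_um", "threshold"),
  gc = c("name", "mask", "min_filopodium_len_um", "prune_len_um"),
  profile = c("name", "image", "roi", "bg", "correct", "length_um"),
  kymo = c("name", "movie", "roi", "sigma_mobile", "sigma_static",
           "threshold", "min_dash_len_px", "dashes"),
  coloc = c("name", "ch1", "ch2", "thr1", "thr2"),
  puncta = c("name", "image", "mask", "threshold", "min_area_px",
             "max_area_px", "smooth_sigma_px"),
  summarize = c("name", "table", "group_col", "control", "value_cols")
)

#' Validate an analysis configuration
#'
#' A config is a list (or JSON file) with fields `seed` (integer),
#' `calibration` (pixel sizes and optional frame interval) and `stages`
#' (ordered list of stage specs, each with a `type` and per-type
#' parameters). Unknown top-level or stage keys are rejected so typos
#' cannot silently fall back to defaults.
#'
#' @param config A list, or path to a JSON config.
#' @return The validated config list, invisibly classed
#'   `analysis_config`.
#' @export
load_config <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  }
  stopifnot(is.list(config))
  allowed_top <- c("seed", "calibration", "stages", "log_level",
                   "out_dir")
  unknown <- setdiff(names(config), allowed_top)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (is.null(config$seed)) config$seed <- 1L
  cal <- config$calibration %||% list(pixel_size_x_um = 1)
  config$calibration <- calibration(
    cal$pixel_size_x_um,
    cal$pixel_size_y_um %||% cal$pixel_size_x_um,
    cal$frame_interval_s)
  config$stages <- config$stages %||% list()
  for (i in seq_along(config$stages)) {
    st <- config$stages[[i]]
    if (is.null(st$type) || !st$type %in% names(stage_param_spec))
      stop("stage ", i, ": unknown or missing type")
    extra <- setdiff(names(st), c("type", stage_param_spec[[st$type]]))
    if (length(extra) > 0)
      stop("stage ", i, " (", st$type, "): unknown keys: ",
           paste(extra, collapse = ", "))
    if (is.null(st$name)) config$stages[[i]]$name <- paste0("s", i)
  }
  structure(config, class = "analysis_config")
}

run_stage <- function(st, dir, cal) {
  p <- function(f) file.path(dir, f)
  need <- function(f) {
    if (!file.exists(p(f))) stop("missing input file: ", f)
    p(f)
  }
  outputs <- character(0)
  emit <- function(obj, f, writer) { writer(obj, p(f)); outputs <<- c(outputs, f) }
  switch(st$type,
    simulate_axons = {
      spec <- random_ray_spec(st$n_rays,
                              st$length_range_um %||% c(100, 1400))
      sz <- st$image_size_px %||%
        c(ceiling(max(vapply(spec, `[[`, 1, "length_um")) /
                    cal$pixel_size_x_um) + 20, NA)
      if (is.na(sz[2])) sz[2] <- 2 * sz[1]
      af <- make_axon_field(spec, sz, cal,
                            radii_um = st$radii_um %||% seq(2, 1500, 2))
      emit(af$mask, paste0(st$name, "_mask.tif"), write_image)
      emit(data.frame(radius_um = af$truth$radii_um,
                      expected = af$truth$expected_counts,
                      uncertain = af$truth$uncertain),
           paste0(st$name, "_truth.csv"), write_table)
      jsonlite::write_json(list(center = af$truth$center),
                           p(paste0(st$name, "_center.json")),
                           auto_unbox = TRUE)
      outputs <- c(outputs, paste0(st$name, "_center.json"))
    },
    simulate_gc = {
      gcn <- make_growth_cone(st$a_um, st$b_um, st$theta_rad %||% 0,
                              image_size_px = st$image_size_px,
                              calibration = cal)
      emit(gcn$mask, paste0(st$name, "_mask.tif"), write_image)
    },
    simulate_comets = {
      sz <- st$image_size_px %||% c(260, 21)
      axis_len <- (sz[1] - 11) * cal$pixel_size_x_um
      nf <- st$n_frames %||% 360
      dt <- require_frame_interval(cal)
      comets <- random_comet_spec(
        st$n_comets, axis_len, nf * dt,
        st$v_range_um_s %||% c(0.05, 0.15),
        st$lifetime_range_s %||% c(10, 30),
        st$amplitude %||% 100, st$sigma_px %||% 1.5)
      statics <- NULL
      if ((st$n_static %||% 0) > 0)
        statics <- data.frame(
          x = stats::runif(st$n_static, 10, sz[1] - 10),
          y = stats::runif(st$n_static, 2, sz[2] - 1),
          amplitude = st$amplitude %||% 100, sigma_px = st$sigma_px %||% 1.5)
      cm <- make_comet_movie(comets, static_spots = statics,
                             image_size_px = sz, calibration = cal,
                             n_frames = nf,
                             noise_sd = st$noise_sd %||% 0)
      emit(cm$movie, paste0(st$name, "_movie.tif"), write_movie)
      emit(cm$axis, paste0(st$name, "_axis.csv"),
           function(o, f) write_roi(o, f))
      emit(comets, paste0(st$name, "_truth.csv"), write_table)
    },
    simulate_coloc = {
      cp <- make_coloc_pair(st$n_ch1, st$n_ch2, st$overlap_fraction,
                            st$image_size_px %||% c(256, 256), cal,
                            st$amplitude %||% 100, st$sigma_px %||% 1.5)
      emit(cp$ch1, paste0(st$name, "_ch1.tif"), write_image)
      emit(cp$ch2, paste0(st$name, "_ch2.tif"), write_image)
    },
    simulate_puncta = {
      sz <- st$image_size_px %||% c(256, 256)
      mk <- matrix(FALSE, sz[2], sz[1])
      mk[, seq_len(floor(sz[1] / 2))] <- TRUE
      mask <- binary_mask(mk, cal)
      pf <- make_puncta_field(mask, st$n_inside, st$n_outside,
                              st$amplitude %||% 100,
                              st$sigma_px %||% 1.5,
                              st$noise_sd %||% 0)
      emit(pf$image, paste0(st$name, "_image.tif"), write_image)
      emit(mask, paste0(st$name, "_mask.tif"), write_image)
      emit(data.frame(n_inside = pf$truth$n_inside,
                      n_outside = pf$truth$n_outside),
           paste0(st$name, "_truth.csv"), write_table)
    },
    simulate_profile = {
      peak <- st$peak %||% 100; dec <- st$decay_um %||% 15
      pf <- make_profile_image(function(d) peak * exp(-d / dec),
                               st$length_um %||% 50,
                               st$width_px %||% 5,
                               st$baseline %||% 10, cal)
      emit(pf$image, paste0(st$name, "_image.tif"), write_image)
      emit(pf$roi, paste0(st$name, "_roi.csv"),
           function(o, f) write_roi(o, f))
    },
    sholl = {
      mask_img <- read_image(need(st$mask), cal)
      mask <- binarize(mask_img, st$threshold %||% 0.5)
      prm <- sholl_params(unlist(st$center),
                          unlist(st$direction %||% c(1, 0)),
                          st$radius_step_um %||% 2,
                          st$r_max_um %||% 1500,
                          unlist(st$bin_edges_um %||%
                                   c(0, 500, 1000, 1500)))
      prof <- sholl_intersections(mask, prm)
      emit(data.frame(radius_um = prof$radii_um, count = prof$counts),
           paste0(st$name, "_profile.csv"), write_table)
      emit(bin_sums(prof), paste0(st$name, "_bins.csv"), write_table)
    },
    gc = {
      mask <- binarize(read_image(need(st$mask), cal), 0.5)
      prm <- gc_params(st$min_filopodium_len_um %||% 1,
                       st$prune_len_um %||% 0.5)
      emit(gc_metrics(mask, prm), paste0(st$name, "_metrics.csv"),
           write_table)
    },
    profile = {
      img <- read_image(need(st$image), cal)
      roi <- load_roi(need(st$roi))
      prof <- extract_profile(img, roi, st$length_um %||% 50)
      prof <- subtract_background(prof, st$bg %||% 0)
      corr_mode <- st$correct %||% "none"
      corr <- if (corr_mode == "none") prof else
        correct_baseline(prof, corr_mode)
      emit(data.frame(distance_um = prof$distances_um,
                      raw = prof$values, corrected = corr$values),
           paste0(st$name, "_profile.csv"), write_table)
      emit(data.frame(integral = integrated_intensity(prof),
                      terminal_fraction_pct = terminal_fraction(prof)),
           paste0(st$name, "_summary.csv"), write_table)
    },
    kymo = {
      mv <- read_movie(need(st$movie), cal)
      roi <- load_roi(need(st$roi))
      sep <- separate_mobile_static(mv, separation_params(
        st$sigma_mobile %||% 4, st$sigma_static %||% 50))
      ky <- build_kymograph(sep, roi)
      if (!is.null(st$dashes)) {
        tab <- utils::read.csv(need(st$dashes))
        ds <- lapply(seq_len(nrow(tab)), function(i)
          dash(tab$x0[i], tab$y0[i], tab$x1[i], tab$y1[i]))
      } else {
        ds <- detect_dashes(ky, st$threshold %||% "otsu",
                            st$min_dash_len_px %||% 5)
      }
      if (length(ds) == 0) stop("no dashes found in kymograph")
      dp <- do.call(rbind, lapply(ds, dash_params, kymo = ky))
      emit(do.call(rbind, lapply(ds, function(d)
        data.frame(x0 = d$x0, y0 = d$y0, x1 = d$x1, y1 = d$y1,
                   L_px = d$L_px, theta_rad = d$theta_rad))),
           paste0(st$name, "_dashes.csv"), write_table)
      emit(dp, paste0(st$name, "_comets.csv"), write_table)
      emit(summarize_dynamics(dp), paste0(st$name, "_summary.csv"),
           write_table)
    },
    coloc = {
      r <- manders(read_image(need(st$ch1), cal),
                   read_image(need(st$ch2), cal), st$thr1, st$thr2)
      emit(data.frame(M1 = r$M1, M2 = r$M2, thr1 = r$thr1,
                      thr2 = r$thr2),
           paste0(st$name, "_coloc.csv"), write_table)
    },
    puncta = {
      img <- read_image(need(st$image), cal)
      mask <- binarize(read_image(need(st$mask), cal), 0.5)
      r <- count_puncta(img, mask, st$threshold,
                        st$min_area_px %||% 2, st$max_area_px %||% 200,
                        st$smooth_sigma_px %||% 1)
      emit(data.frame(count = r$count, mask_area_um2 = r$mask_area_um2,
                      density_per_um2 = r$density_per_um2),
           paste0(st$name, "_puncta.csv"), write_table)
    },
    summarize = {
      tab <- utils::read.csv(need(st$table))
      sg <- summarize_groups(tab, st$value_cols,
                             st$group_col %||% "group", st$control)
      emit(sg$summary, paste0(st$name, "_groups.csv"), write_table)
      emit(sg$fold, paste0(st$name, "_folds.csv"), write_table)
    },
    stop("unhandled stage type: ", st$type))
  outputs
}

#' Run a configured simulate/analyze/summarize pipeline
#'
#' Stages execute in order inside `out_dir`; file-valued stage parameters
#' resolve relative to it, so simulation outputs feed later analysis
#' stages. One seed set at the start drives every stochastic stage, and
#' rerunning an identical config and seed reproduces every CSV byte for
#' byte. A `manifest.json` (config, seed, package version, input hashes,
#' outputs) is written on success; on failure the manifest carries the
#' failing stage's name and error, and earlier outputs are retained.
#'
#' @param config A config list or JSON path; see [load_config()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  outputs <- list()
  failed <- NULL
  for (st in config$stages) {
    res <- tryCatch(run_stage(st, out_dir, config$calibration),
                    error = function(e)
                      simpleError(paste0("stage '", st$name, "' (",
                                         st$type, "): ",
                                         conditionMessage(e))))
    if (inherits(res, "error")) { failed <- res; break }
    outputs[[st$name]] <- res
  }
  all_out <- unlist(outputs, use.names = FALSE)
  manifest <- list(
    config = config[setdiff(names(config), "calibration")],
    calibration = unclass(config$calibration),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("axoquant")),
    outputs = all_out,
    output_md5 = as.list(tools::md5sum(file.path(out_dir, all_out))),
    status = if (is.null(failed)) "ok" else "failed",
    error = if (is.null(failed)) NULL else conditionMessage(failed))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(failed)) stop(failed)
  invisible(out_dir)
}

#' Per-group mean, SE and per-sample fold change versus a control group
#'
#' Summarizes a per-sample metric table the way the figures report them:
#' group mean +/- SE with n, plus each sample's fold change relative to
#' the control group's mean (so the control group's mean fold is 1).
#' Row order does not affect the result.
#'
#' @param df Data.frame of per-sample metrics.
#' @param value_cols Character vector of metric column names.
#' @param group_col Name of the grouping column; default `"group"`.
#' @param control Label of the control group (must be present).
#' @return `list(summary, fold)`: `summary` has one row per group x
#'   metric (`group`, `metric`, `n`, `mean`, `se`, `fold_of_mean`);
#'   `fold` repeats `df`'s group column with per-sample fold columns.
#' @export
summarize_groups <- function(df, value_cols, group_col = "group",
                             control) {
  stopifnot(is.data.frame(df), group_col %in% names(df),
            all(value_cols %in% names(df)))
  groups <- unique(as.character(df[[group_col]]))
  if (!control %in% groups)
    stop("control group '", control, "' not present")
  groups <- c(control, sort(setdiff(groups, control)))
  rows <- list()
  fold <- data.frame(group = as.character(df[[group_col]]))
  for (vc in value_cols) {
    ctrl_mean <- mean(df[[vc]][df[[group_col]] == control])
    fold[[paste0(vc, "_fold")]] <- df[[vc]] / ctrl_mean
    for (g in groups) {
      x <- df[[vc]][df[[group_col]] == g]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, metric = vc, n = length(x), mean = mean(x),
        se = if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0,
        fold_of_mean = mean(x) / ctrl_mean)
    }
  }
  list(summary = do.call(rbind, rows), fold = fold)
}
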