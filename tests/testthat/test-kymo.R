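test_that("separation removes time-constant movies to numerical zero", {
  cal <- calibration(0.2, frame_interval_s = 0.5)
  statics <- data.frame(x = c(40, 90, 200), y = c(10, 12, 11),
                        amplitude = 100, sigma_px = 1.5)
  cm <- make_comet_movie(data.frame()[0, ], static_spots = statics,
                         image_size_px = c(260, 21), calibration = cal,
                         n_frames = 360)
  sep <- separate_mobile_static(cm$movie)
  expect_lt(max(abs(sep$frames)),
            1e-6 * diff(range(cm$movie$frames)))
})

test_that("the impulse response equals the difference of the two kernels", {
  cal <- calibration(1, frame_interval_s = 1)
  fr <- array(0, c(4, 4, 600))
  fr[2, 2, 300] <- 1000
  sep <- separate_mobile_static(movie(fr, cal),
                                separation_params(4, 50))
  got <- sep$frames[2, 2, ]
  R <- 200
  km <- dnorm(seq(-R, R), sd = 4); ks <- dnorm(seq(-R, R), sd = 50)
  dk <- km / sum(km) - ks / sum(ks)
  want <- numeric(600)
  want[(300 - R):(300 + R)] <- 1000 * dk
  expect_equal(got, want, tolerance = 1e-9)
  # untouched pixels stay zero
  expect_true(all(abs(sep$frames[4, 4, ]) < 1e-12))
  expect_error(separation_params(50, 4), "smaller")
})

test_that("separation suppresses static spots while retaining comet signal", {
  cal <- calibration(0.2, frame_interval_s = 0.5)
  comets <- data.frame(t0_s = 40, x0_um = 5, v_um_s = 0.1,
                       lifetime_s = 20, amplitude = 100, sigma_px = 1.5)
  statics <- data.frame(x = 200, y = 11, amplitude = 100, sigma_px = 1.5)
  cm <- make_comet_movie(comets, static_spots = statics,
                         image_size_px = c(260, 21), calibration = cal,
                         n_frames = 360)
  sep <- separate_mobile_static(cm$movie)
  expect_lt(max(abs(sep$frames[11, 200, ])) / 100, 0.05)  # >= 95% gone
  # mid-lifetime (t = 50 s) the comet keeps at least half its amplitude
  expect_gt(max(sep$frames[, , 101]), 50)
})

test_that("kymographs are time-invariant for static movies and mirror with the roi", {
  cal <- calibration(0.2, frame_interval_s = 0.5)
  statics <- data.frame(x = c(60, 150), y = c(11, 10), amplitude = 100,
                        sigma_px = 1.5)
  cm <- make_comet_movie(data.frame()[0, ], static_spots = statics,
                         image_size_px = c(260, 21), calibration = cal,
                         n_frames = 10)
  ky <- build_kymograph(cm$movie, cm$axis)
  expect_true(all(apply(ky$values, 1, identical, ky$values[1, ])))
  expect_equal(ky$n_rows, 10)
  expect_equal(ky$total_time_s, 5)
  rev_roi <- polyline_roi(cm$axis$vertices[2:1, ], cm$axis$width_um)
  ky_rev <- build_kymograph(cm$movie, rev_roi)
  expect_equal(ky_rev$values, ky$values[, ncol(ky$values):1],
               tolerance = 1e-9)
})

test_that("a constant-velocity comet draws a dash of slope v", {
  cal <- calibration(0.2, frame_interval_s = 0.5)
  comets <- data.frame(t0_s = 40, x0_um = 5, v_um_s = 0.1,
                       lifetime_s = 20, amplitude = 100, sigma_px = 1.5)
  cm <- make_comet_movie(comets, image_size_px = c(260, 21),
                         calibration = cal, n_frames = 360)
  ky <- build_kymograph(separate_mobile_static(cm$movie), cm$axis)
  ds <- detect_dashes(ky)
  expect_length(ds, 1L)
  dp <- dash_params(ds[[1]], ky)
  expect_equal(dp$growth_rate_um_per_s, 0.1, tolerance = 0.1)
  expect_equal(dp$lifetime_s, 20, tolerance = 0.15 * 20)
})

test_that("dash parameters follow the projection formulas exactly", {
  ky <- structure(list(values = matrix(0, 360, 300), space_step_um = 0.1,
                       time_step_s = 0.5, n_rows = 360,
                       total_time_s = 180), class = "kymograph")
  dp <- dash_params(dash(0, 0, 30, 40), ky)
  expect_equal(dp$track_length_um, 3)
  expect_equal(dp$lifetime_s, 20)
  expect_equal(dp$growth_rate_um_per_s, 0.15)
  # a dash spanning the full time axis lives the whole 180 s
  full <- dash_params(dash(10, 0, 50, 360), ky)
  expect_equal(full$lifetime_s, 180)
  # a vertical dash is a stationary comet
  vert <- dash_params(dash(20, 10, 20, 60), ky)
  expect_equal(vert$track_length_um, 0)
  expect_equal(vert$growth_rate_um_per_s, 0)
  expect_error(dash(5, 7, 5, 7), "coincide")
  expect_error(dash_params(dash(0, 0, 10, 0), ky), "dy > 0")
})

test_that("endpoint deltas equal the trigonometric formulation for random dashes", {
  ky <- structure(list(values = matrix(0, 360, 300), space_step_um = 0.1,
                       time_step_s = 0.5, n_rows = 360,
                       total_time_s = 180), class = "kymograph")
  set.seed(4)
  for (i in 1:200) {
    x0 <- runif(1, 0, 300); x1 <- runif(1, 0, 300)
    y0 <- runif(1, 0, 359); y1 <- runif(1, y0 + 0.5, 360)
    d <- dash(x0, y0, x1, y1)
    dp <- dash_params(d, ky)
    track_trig <- d$L_px * cos(d$theta_rad) * ky$space_step_um
    life_trig <- d$L_px * sin(d$theta_rad) / ky$n_rows * ky$total_time_s
    expect_equal(dp$track_length_um, track_trig, tolerance = 1e-9)
    expect_equal(dp$lifetime_s, life_trig, tolerance = 1e-9)
    expect_equal(dp$growth_rate_um_per_s * dp$lifetime_s,
                 dp$track_length_um, tolerance = 1e-12)
  }
})

test_that("dash detection finds the events that are there and nothing else", {
  cal <- calibration(0.2, frame_interval_s = 0.5)
  blank <- structure(list(values = matrix(0, 100, 50),
                          space_step_um = 0.2, time_step_s = 0.5,
                          n_rows = 100, total_time_s = 50),
                     class = "kymograph")
  expect_length(detect_dashes(blank), 0L)
  comets <- data.frame(t0_s = c(20, 120), x0_um = c(5, 25),
                       v_um_s = 0.1, lifetime_s = 20, amplitude = 100,
                       sigma_px = 1.5)
  cm <- make_comet_movie(comets, image_size_px = c(260, 21),
                         calibration = cal, n_frames = 360)
  ky <- build_kymograph(separate_mobile_static(cm$movie), cm$axis)
  expect_length(detect_dashes(ky), 2L)
})

test_that("dynamics summaries pool comets with the usual SE scaling", {
  one <- dash_params(dash(0, 0, 30, 40),
                     structure(list(values = matrix(0, 360, 300),
                                    space_step_um = 0.1, time_step_s = 0.5,
                                    n_rows = 360, total_time_s = 180),
                               class = "kymograph"))
  s1 <- summarize_dynamics(one)
  expect_equal(s1$se, rep(0, 3))
  expect_equal(s1$n, rep(1L, 3))
  expect_equal(s1$mean[s1$metric == "growth_rate_um_per_s"], 0.15)
  mixed <- one; mixed$track_length_um <- 5; mixed$lifetime_s <- 10
  mixed$growth_rate_um_per_s <- 0.5
  df <- rbind(one, mixed)
  s2 <- summarize_dynamics(df)
  expect_equal(s2$mean[s2$metric == "track_length_um"], mean(c(3, 5)))
  expect_equal(s2$se[s2$metric == "track_length_um"],
               sd(c(3, 5)) / sqrt(2))
  # pooling more comets shrinks the SE as sd/sqrt(n)
  df2 <- rbind(df, df)
  s4 <- summarize_dynamics(df2)
  expect_equal(s4$se[s4$metric == "track_length_um"],
               sd(c(3, 5, 3, 5)) / 2)
  expect_lt(s4$se[1], s2$se[1])
  expect_error(summarize_dynamics(df[0, ]), "nrow")
})
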