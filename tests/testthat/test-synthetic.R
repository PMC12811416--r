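test_that("axon-field truth matches forced geometry and empty case", {
  cal <- cal1()
  rays <- lapply(c(-0.8, 0, 0.8),
                 function(a) list(angle_rad = a, length_um = 700))
  af <- make_axon_field(rays, c(760, 1520), cal,
                        radii_um = seq(2, 1000, 2))
  tr <- af$truth
  # 3 rays of 700 um: naive counts are 3 up to 700 um and 0 beyond, and
  # the continuous-geometry counts agree wherever rays are resolvable
  expect_true(all(tr$naive_counts[tr$radii_um <= 700] == 3))
  expect_true(all(tr$naive_counts[tr$radii_um > 701] == 0))
  sep <- tr$radii_um >= 20 & tr$radii_um <= 698
  expect_true(all(tr$expected_counts[sep] == 3))
  # empty field
  af0 <- make_axon_field(list(), c(100, 200), cal,
                         radii_um = seq(2, 50, 2))
  expect_false(any(af0$mask$values))
  expect_true(all(af0$truth$expected_counts == 0))
  # out-of-bounds ray rejected
  expect_error(make_axon_field(list(list(angle_rad = 0, length_um = 900)),
                               c(760, 1520), cal), "bounds")
})

test_that("branched rays count once below and twice above the fork", {
  cal <- cal1()
  rays <- list(list(angle_rad = 0.1, length_um = 300,
                    branches = list(list(at_um = 100, angle_rad = 0.55,
                                         length_um = 210))))
  af <- make_axon_field(rays, c(400, 800), cal, radii_um = seq(2, 400, 2))
  tr <- af$truth
  r <- tr$radii_um
  branch_tip_r <- max(sqrt(tr$segments$x1^2 + tr$segments$y1^2))
  sep <- !tr$uncertain
  expect_true(all(tr$expected_counts[sep & r > 20 & r < 98] == 1))
  expect_true(all(tr$expected_counts[sep & r > 110 &
                                     r < min(300, branch_tip_r) - 2] == 2))
  expect_true(all(tr$expected_counts[r > branch_tip_r + 2] == 0))
})

test_that("growth-cone generator keeps geometry verbatim and renders it", {
  cal <- calibration(0.1)
  gc <- make_growth_cone(5, 5, 0, NULL, c(140, 140), cal)
  area_px <- sum(gc$mask$values) * 0.01
  expect_equal(area_px, pi * 25, tolerance = 0.02)
  filo <- data.frame(t_rad = c(0.3, 1.2, 2.0),
                     length_um = c(2.5, 1.5, 0.5), width_px = 3)
  gc2 <- make_growth_cone(10, 4, 0.2, filo, c(400, 400), cal)
  expect_equal(gc2$truth$filopodia$length_um, c(2.5, 1.5, 0.5))
  # rendered filopodium tips are foreground at base + length * direction
  ft <- gc2$truth$filopodia
  for (i in seq_len(nrow(ft))) {
    tip <- c(ft$base_x[i] + ft$length_um[i] / 0.1 * ft$dir_x[i],
             ft$base_y[i] + ft$length_um[i] / 0.1 * ft$dir_y[i])
    expect_true(gc2$mask$values[round(tip[2]), round(tip[1])])
  }
  expect_error(make_growth_cone(4, 10, 0, NULL, c(100, 100), cal),
               "a_um >= b_um")
})

test_that("comet movies obey kinematics, seeds and duration checks", {
  cal <- calibration(0.2, frame_interval_s = 0.5)
  comets <- data.frame(t0_s = 40, x0_um = 5, v_um_s = 0.1,
                       lifetime_s = 20, amplitude = 100, sigma_px = 1.5)
  cm <- make_comet_movie(comets, image_size_px = c(260, 21),
                         calibration = cal, n_frames = 360)
  # centroid-tracking oracle: displacement between first and last active
  # frame equals v * lifetime = 2 um
  f_first <- cm$movie$frames[, , 81]   # t = 40 s
  f_last <- cm$movie$frames[, , 121]   # t = 60 s
  d_px <- frame_centroid(f_last)["x"] - frame_centroid(f_first)["x"]
  expect_equal(unname(d_px) * 0.2, 2.0, tolerance = 0.05)
  # static-only movie: all frames identical
  statics <- data.frame(x = c(40, 90), y = c(10, 12), amplitude = 50,
                        sigma_px = 1.5)
  cm0 <- make_comet_movie(comets[0, ], static_spots = statics,
                          image_size_px = c(260, 21), calibration = cal,
                          n_frames = 10)
  expect_true(all(apply(cm0$movie$frames, 3, identical,
                        cm0$movie$frames[, , 1])))
  # seed determinism with noise
  short <- data.frame(t0_s = 2, x0_um = 5, v_um_s = 0.1,
                      lifetime_s = 5, amplitude = 100, sigma_px = 1.5)
  a <- make_comet_movie(short, image_size_px = c(260, 21),
                        calibration = cal, n_frames = 20,
                        noise_sd = 5, seed = 9)
  b <- make_comet_movie(short, image_size_px = c(260, 21),
                        calibration = cal, n_frames = 20,
                        noise_sd = 5, seed = 9)
  expect_identical(a$movie$frames, b$movie$frames)
  # active outside the movie or off the axis
  bad <- comets; bad$t0_s <- 175
  expect_error(make_comet_movie(bad, image_size_px = c(260, 21),
                                calibration = cal, n_frames = 360),
               "duration")
  bad2 <- comets; bad2$x0_um <- 49
  expect_error(make_comet_movie(bad2, image_size_px = c(260, 21),
                                calibration = cal, n_frames = 360),
               "axis")
})

test_that("coloc pairs share exactly the requested centers", {
  cal <- cal1()
  cp <- make_coloc_pair(40, 40, 0.5, c(256, 256), cal, seed = 3)
  shared <- sum(apply(cp$truth$centers_ch1, 1, function(p)
    any(abs(cp$truth$centers_ch2[, 1] - p[1]) < 1e-9 &
        abs(cp$truth$centers_ch2[, 2] - p[2]) < 1e-9)))
  expect_equal(shared, 20)
  cp1 <- make_coloc_pair(10, 10, 1, c(128, 128), cal, seed = 4)
  expect_identical(cp1$truth$centers_ch1[order(cp1$truth$centers_ch1[, 1]), ],
                   cp1$truth$centers_ch2[order(cp1$truth$centers_ch2[, 1]), ])
  cp0 <- make_coloc_pair(10, 10, 0, c(128, 128), cal, seed = 5)
  d2 <- outer(cp0$truth$centers_ch1[, 1], cp0$truth$centers_ch2[, 1], "-")^2 +
    outer(cp0$truth$centers_ch1[, 2], cp0$truth$centers_ch2[, 2], "-")^2
  expect_gt(sqrt(min(d2)), 4 * 1.5)
})

test_that("puncta fields classify centers by mask and reproduce under a seed", {
  cal <- cal1()
  mk <- matrix(FALSE, 128, 128); mk[, 1:64] <- TRUE
  mask <- binary_mask(mk, cal)
  pf <- make_puncta_field(mask, 5, 3, noise_sd = 10, seed = 11)
  ci <- round(pf$truth$centers_inside)
  expect_true(all(mk[cbind(ci[, 2], ci[, 1])]))
  co <- round(pf$truth$centers_outside)
  expect_false(any(mk[cbind(co[, 2], co[, 1])]))
  pf2 <- make_puncta_field(mask, 5, 3, noise_sd = 10, seed = 11)
  expect_identical(pf$image$values, pf2$image$values)
  # empty inside: the masked half carries only background
  pf0 <- make_puncta_field(mask, 0, 3, noise_sd = 0, seed = 1)
  expect_true(all(pf0$image$values[, 1:55] == pf0$truth$background))
})

test_that("profile images carry the axial function plus baseline", {
  cal <- calibration(0.2)
  pf <- make_profile_image(function(d) rep(100, length(d)), 50, 5, 10,
                           cal)
  stripe_rows <- which(apply(pf$image$values > 10, 1, any))
  expect_equal(length(stripe_rows), 5L)
  expect_true(all(pf$image$values[stripe_rows[3],
                                  pf$roi$vertices[1, 1] + 0:10] == 110))
  expect_true(all(pf$truth$f_values == 100))
  expect_error(make_profile_image(function(d) -d, 50, 5, 0, cal),
               "nonnegative")
})
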