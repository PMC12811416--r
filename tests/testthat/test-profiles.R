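test_that("a constant stripe extracts as a constant profile", {
  cal <- calibration(0.2)
  pf <- make_profile_image(function(d) rep(100, length(d)), 50, 7, 10,
                           cal)
  prof <- extract_profile(pf$image, pf$roi, 50)
  expect_equal(range(prof$distances_um), c(0, 50))
  expect_true(all(abs(prof$values - 110) < 1e-9))
})

test_that("extraction reproduces the generator's axial function within 2% RMS", {
  cal <- calibration(0.2)
  f <- function(d) pmax(0, 100 * (1 - d / 20))
  pf <- make_profile_image(f, 50, 7, 10, cal)
  prof <- extract_profile(pf$image, pf$roi, 50)
  want <- stats::approx(pf$truth$distances_um, pf$truth$f_values + 10,
                        prof$distances_um)$y
  rms <- sqrt(mean((prof$values - want)^2))
  expect_lt(rms, 0.02 * diff(range(want)))
  expect_equal(which.max(prof$values), 1L)  # peak at the tip
})

test_that("widening the sampling width over a narrow stripe dilutes the mean", {
  cal <- calibration(0.2)
  pf <- make_profile_image(function(d) rep(100, length(d)), 50, 3, 0,
                           cal)
  means <- vapply(c(0.5, 2, 4), function(w) {
    roi <- polyline_roi(pf$roi$vertices, width_um = w)
    mean(extract_profile(pf$image, roi, 50)$values)
  }, numeric(1))
  expect_true(all(diff(means) < 0))
  expect_lt(means[2], 100)
})

test_that("profiles that leave the image or fall short are rejected", {
  cal <- calibration(0.2)
  img <- image2d(matrix(1, 30, 30), cal)
  short <- polyline_roi(rbind(c(2, 15), c(20, 15)))
  expect_error(extract_profile(img, short, 50), "shorter")
  out <- polyline_roi(rbind(c(2, 15), c(400, 15)))
  expect_error(extract_profile(img, out, 50), "bounds")
})

test_that("background subtraction shifts without clipping", {
  prof <- intensity_profile(0:50, rep(110, 51))
  p <- subtract_background(prof, 10)
  expect_true(all(p$values == 100))
  expect_identical(subtract_background(prof, 0)$values, prof$values)
  deep <- subtract_background(prof, 200)
  expect_true(all(deep$values == -90))  # negatives preserved
  r <- subtract_background(region_intensity(50, 100), 10)
  expect_equal(r$total_intensity, 4000)
})

test_that("baseline corrections anchor the tip or zero the distal window", {
  prof <- intensity_profile(0:50, rep(7, 51))
  tipc <- correct_baseline(prof, "tip_anchor")
  expect_true(all(tipc$values == 0))
  ramp <- intensity_profile(0:50, 0:50)
  dw <- correct_baseline(ramp, "distal_window")
  # closed form: mean of a ramp over samples 45..50 is 47.5
  expect_equal(dw$values, 0:50 - 47.5)
  sel <- dw$distances_um >= 45 & dw$distances_um <= 50
  expect_lt(abs(mean(dw$values[sel])), 1e-9 * diff(range(ramp$values)))
  tip2 <- correct_baseline(ramp, "tip_anchor")
  expect_identical(tip2$values[1], 0)
  expect_error(correct_baseline(dw, "tip_anchor"), "already corrected")
  expect_error(correct_baseline(ramp, "distal_window",
                                window_um = c(60, 70)), "window")
})

test_that("fold change normalizes to the control mean and is scale invariant", {
  mk <- function(v) intensity_profile(0:50, rep(v, 51))
  fc <- integrated_fold_change(list(mk(1)), list(mk(2), mk(2)))
  expect_equal(fc$fold_treated, 0.5)
  self <- integrated_fold_change(list(mk(3), mk(5)), list(mk(3), mk(5)))
  expect_equal(mean(self$fold_treated), 1)
  # x10 on every profile leaves folds unchanged
  f1 <- integrated_fold_change(list(mk(3)), list(mk(4), mk(6)))
  f2 <- integrated_fold_change(list(mk(30)), list(mk(40), mk(60)))
  expect_equal(f1$fold_treated, f2$fold_treated, tolerance = 1e-12)
  expect_error(integrated_fold_change(list(mk(1)), list(mk(0))),
               "positive")
  corr <- correct_baseline(mk(2), "tip_anchor")
  expect_error(integrated_fold_change(list(corr), list(mk(1))),
               "uncorrected")
})

test_that("terminal fraction is exact on uniform profiles and monotone in the window", {
  unif <- intensity_profile(0:50, rep(4, 51))
  expect_equal(terminal_fraction(unif, 10), 20)
  tipheavy <- intensity_profile(0:50, c(rep(10, 11), rep(0, 40)))
  expect_equal(terminal_fraction(tipheavy, 11), 100)
  fr <- vapply(c(5, 10, 20, 50), function(w)
    terminal_fraction(unif, w), numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_true(all(fr >= 0 & fr <= 100))
  # generator truth: fraction of mass inside the window
  cal <- calibration(0.2)
  f <- function(d) 100 * exp(-d / 15)
  pf <- make_profile_image(f, 50, 5, 0, cal)
  prof <- extract_profile(pf$image, pf$roi, 50)
  want <- 100 * (1 - exp(-10 / 15)) / (1 - exp(-50 / 15))
  expect_equal(terminal_fraction(prof, 10), want, tolerance = 0.01)
})
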