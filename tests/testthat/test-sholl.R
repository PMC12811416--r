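test_that("binarize applies fixed and automatic thresholds deterministically", {
  cal <- cal1()
  v <- matrix(0, 40, 40); v[18:22, ] <- 200
  img <- image2d(v, cal)
  m <- binarize(img, 100)
  expect_identical(m$values, v > 100)
  expect_equal(attr(m, "threshold_value"), 100)
  expect_false(any(binarize(img, 500)$values))
  mo1 <- binarize(img, "otsu"); mo2 <- binarize(img, "otsu")
  expect_identical(mo1$values, mo2$values)
  expect_identical(mo1$values, v > 100)  # two clean classes
  expect_error(binarize(image2d(matrix(5, 4, 4), cal), "otsu"),
               "constant")
})

test_that("sholl params validate their geometry", {
  expect_error(sholl_params(c(1, 1), radius_step_um = 0), "positive")
  expect_error(sholl_params(c(1, 1), bin_edges_um = c(0, 500, 400)),
               "increasing")
  expect_error(sholl_params(c(1, 1), r_max_um = 100,
                            bin_edges_um = c(0, 500)), "exceed")
  expect_error(sholl_params(c(1, 1), direction = c(0, 0)), "nonzero")
})

test_that("empty masks give zero counts and centers must lie inside", {
  cal <- cal1()
  mask <- binary_mask(matrix(FALSE, 100, 100), cal)
  p <- sholl_params(c(1, 50), r_max_um = 80, bin_edges_um = c(0, 80))
  prof <- sholl_intersections(mask, p)
  expect_true(all(prof$counts == 0))
  expect_error(sholl_intersections(mask, sholl_params(c(500, 50),
                                                      r_max_um = 80,
                                                      bin_edges_um = c(0, 80))),
               "outside")
  aniso <- binary_mask(matrix(FALSE, 10, 10), calibration(1, 2))
  expect_error(sholl_intersections(aniso, p), "isotropic")
})

test_that("a single ray along the direction counts one at every radius", {
  cal <- cal1()
  af <- make_axon_field(list(list(angle_rad = 0, length_um = 120)),
                        c(140, 100), cal, radii_um = seq(2, 100, 2))
  p <- sholl_params(af$truth$center, c(1, 0), radius_step_um = 2,
                    r_max_um = 100, bin_edges_um = c(0, 100))
  prof <- sholl_intersections(af$mask, p)
  expect_length(prof$counts, 50L)
  expect_true(all(prof$counts == 1))
})

test_that("counts are equivariant under a 90-degree rotation of mask and direction", {
  cal <- cal1()
  rays <- random_ray_spec(5, c(40, 90), seed = 21)
  af <- make_axon_field(rays, c(100, 200), cal, radii_um = seq(2, 90, 2))
  p <- sholl_params(af$truth$center, c(1, 0), 2, 90, c(0, 90))
  prof <- sholl_intersections(af$mask, p)
  # rotate the raster 90 degrees clockwise: (x, y) -> (ny + 1 - y, x)
  mv <- af$mask$values
  rot <- t(mv)[, nrow(mv):1]
  ctr <- c(nrow(mv) + 1 - af$truth$center[2], af$truth$center[1])
  p_rot <- sholl_params(ctr, c(0, 1), 2, 90, c(0, 90))
  prof_rot <- sholl_intersections(binary_mask(rot, cal), p_rot)
  expect_identical(prof$counts, prof_rot$counts)
})

test_that("adding a resolvable ray never decreases any resolvable count", {
  # an extra foreground process can only add crossings, provided it does
  # not merge with an existing arc run; compare where both fields are
  # raster-stable
  cal <- cal1()
  rays <- lapply(c(-1.0, -0.4, 0.3, 0.9),
                 function(a) list(angle_rad = a, length_um = 80))
  af1 <- make_axon_field(rays, c(100, 200), cal, radii_um = seq(2, 90, 2))
  extra <- c(rays, list(list(angle_rad = 1.3, length_um = 70)))
  af2 <- make_axon_field(extra, c(100, 200), cal,
                         radii_um = seq(2, 90, 2))
  p <- sholl_params(af1$truth$center, c(1, 0), 2, 90, c(0, 90))
  c1 <- sholl_intersections(af1$mask, p)$counts
  c2 <- sholl_intersections(af2$mask, p)$counts
  ok <- !af1$truth$uncertain & !af2$truth$uncertain
  expect_gt(sum(ok), 20)
  expect_true(all(c2[ok] >= c1[ok]))
})

test_that("bin sums use half-open bins and conserve totals", {
  prof <- structure(list(radii_um = seq(2, 1500, 2),
                         counts = rep(3L, 750),
                         params = sholl_params(c(1, 1))),
                    class = "sholl_profile")
  bs <- bin_sums(prof, c(0, 500, 1000, 1500))
  expect_equal(bs$sum, c(750, 750, 750))  # 250 radii x 3 per bin
  expect_equal(sum(bs$sum), sum(prof$counts))
  one <- bin_sums(prof, c(0, 1500))
  expect_equal(one$sum, sum(prof$counts))
  prof$counts <- rep(0L, 750)
  expect_true(all(bin_sums(prof, c(0, 500, 1000, 1500))$sum == 0))
  expect_error(bin_sums(prof, c(0, 1000, 500)), "increasing")
})
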