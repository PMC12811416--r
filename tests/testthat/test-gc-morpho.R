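test_that("region metrics recover circle and ellipse geometry", {
  cal <- calibration(0.1)
  circ <- make_growth_cone(5, 5, 0, NULL, c(140, 140), cal)
  rm <- region_metrics(circ$mask)
  expect_equal(rm$area_um2, pi * 25, tolerance = 0.02)
  expect_equal(rm$elongation_ratio, 1, tolerance = 0.02)
  ell <- make_growth_cone(10, 4, 0.4, NULL, c(260, 260), cal)
  expect_equal(region_metrics(ell$mask)$elongation_ratio, 2.5,
               tolerance = 0.02)
  expect_error(region_metrics(binary_mask(matrix(FALSE, 4, 4), cal)),
               "empty")
  two <- matrix(FALSE, 20, 20); two[2:4, 2:4] <- TRUE; two[15:17, 15:17] <- TRUE
  expect_error(region_metrics(binary_mask(two, cal)), "components")
})

test_that("region metrics are invariant under translation and 90-degree rotation", {
  cal <- calibration(0.1)
  ell <- make_growth_cone(8, 4, 0.7, NULL, c(220, 220), cal,
                          center = c(100, 100))
  m1 <- region_metrics(ell$mask)
  shifted <- make_growth_cone(8, 4, 0.7, NULL, c(220, 220), cal,
                              center = c(130, 115))
  m2 <- region_metrics(shifted$mask)
  mv <- ell$mask$values
  rot <- binary_mask(t(mv)[, nrow(mv):1], cal)
  m3 <- region_metrics(rot)
  for (f in c("area_um2", "perimeter_um", "elongation_ratio")) {
    expect_equal(m2[[f]], m1[[f]], tolerance = 0.01)
    expect_equal(m3[[f]], m1[[f]], tolerance = 0.01)
  }
})

test_that("skeleton of a bar is a single chain; circle collapses centrally", {
  cal <- calibration(0.1)
  m <- matrix(FALSE, 40, 230); m[19:21, 11:210] <- TRUE
  sk <- skeletonize_mask(binary_mask(m, cal))
  expect_equal(sum(sk$degree == 1), 2L)
  expect_equal(sum(sk$degree >= 3), 0L)
  sm <- skeleton_metrics(sk)
  # thinning erodes roughly half the bar width at each end
  expect_equal(sm$lsp_um, 20, tolerance = 0.025)
  expect_equal(sm$n_filopodia, 0L)  # a bare path has no junctions
  circ <- make_growth_cone(5, 5, 0, NULL, c(140, 140), cal)
  smc <- skeleton_metrics(skeletonize_mask(circ$mask))
  expect_lt(smc$lsp_um, 5)  # far below the 10 um diameter
})

test_that("a Y-shaped mask yields three endpoints and one junction", {
  cal <- calibration(0.1)
  m <- matrix(FALSE, 60, 60)
  m[30, 10:30] <- TRUE
  for (k in 1:15) { m[30 - k, 30 + k] <- TRUE; m[30 + k, 30 + k] <- TRUE }
  sk <- skeletonize_mask(binary_mask(m, cal))
  expect_equal(sum(sk$degree == 1), 3L)
  expect_equal(sum(sk$degree >= 3), 1L)
})

test_that("filopodia counting applies the 1-um threshold to terminal branches", {
  cal <- calibration(0.1)
  # main chain whose free ends stay below threshold, with terminal
  # branches of 2.5, 1.5 and 0.5 um
  m <- matrix(FALSE, 80, 200)
  m[40, 52:148] <- TRUE
  m[41:65, 60] <- TRUE    # 2.5 um
  m[41:55, 100] <- TRUE   # 1.5 um
  m[41:45, 140] <- TRUE   # 0.5 um
  sk <- skeletonize_mask(binary_mask(m, cal))
  sm <- skeleton_metrics(sk, gc_params(1.0, 0.3))
  expect_equal(sm$n_filopodia, 2L)
  # monotone non-increasing in the length threshold
  thresholds <- c(0.4, 1.0, 1.6, 2.6)
  counts <- vapply(thresholds, function(th)
    skeleton_metrics(sk, gc_params(th, 0.3))$n_filopodia, integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[length(counts)], 0L)
})

test_that("pruning removes short spurs and is idempotent", {
  cal <- calibration(0.1)
  m <- matrix(FALSE, 60, 120)
  m[30, 10:110] <- TRUE
  m[31:33, 50] <- TRUE  # 0.3 um spur
  sk <- skeletonize_mask(binary_mask(m, cal))
  p1 <- prune_skeleton(sk, 0.5)
  expect_equal(sum(p1$degree >= 3), 0L)  # spur gone, pure path left
  p2 <- prune_skeleton(p1, 0.5)
  expect_identical(sort(p1$coords[, 1] * 1000 + p1$coords[, 2]),
                   sort(p2$coords[, 1] * 1000 + p2$coords[, 2]))
})

test_that("lsp matches brute-force all-pairs geodesics and scales with pixel size", {
  for (seed in 1:8) {
    mk <- random_tree_mask(seed, size = 70, n_seg = 5)
    cal <- calibration(0.1)
    sk <- skeletonize_mask(binary_mask(mk, cal))
    got <- skeleton_metrics(sk, gc_params(1, 1e-9))$lsp_um
    want <- oracle_lsp(sk$coords, 0.1)
    expect_equal(got, want, tolerance = 1e-9)
  }
  mk <- random_tree_mask(99, size = 70, n_seg = 5)
  l1 <- skeleton_metrics(skeletonize_mask(binary_mask(mk, calibration(0.1))),
                         gc_params(1, 1e-9))$lsp_um
  l2 <- skeleton_metrics(skeletonize_mask(binary_mask(mk, calibration(0.2))),
                         gc_params(1, 1e-9))$lsp_um
  expect_equal(l2, 2 * l1, tolerance = 1e-12)
})

test_that("gc_metrics bundles the five morphometrics", {
  cal <- calibration(0.1)
  gc <- make_growth_cone(6, 3, 0.3, NULL, c(180, 180), cal)
  met <- gc_metrics(gc$mask)
  expect_named(met, c("area_um2", "perimeter_um", "elongation_ratio",
                      "lsp_um", "n_filopodia"))
  expect_gt(met$area_um2, 0)
  expect_gte(met$elongation_ratio, 1)
})
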