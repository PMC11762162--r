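test_that("mean axial projection matches its closed forms and a loop oracle", {
  v <- voxel_volume(array(3.5, c(4, 5, 6)))
  expect_true(all(mean_axial_projection(v) == 3.5))

  ramp <- voxel_volume(array(rep(0:3, each = 12), c(3, 4, 4)))
  expect_true(all(mean_axial_projection(ramp) == 1.5))

  withr::local_seed(10)
  r <- voxel_volume(array(rnorm(3 * 4 * 5), c(3, 4, 5)))
  oracle <- matrix(0, 3, 4)
  for (i in 1:3) for (j in 1:4) oracle[i, j] <- mean(r$data[i, j, ])
  expect_equal(mean_axial_projection(r), oracle)
})

test_that("fit_arch_curve recovers a painted parabola within 1 voxel RMS", {
  nx <- 120; ny <- 80
  img <- matrix(0, nx, ny)
  for (i in 15:105) {
    yc <- 0.02 * (i - 60)^2 + 10
    jj <- round(yc) + (-2:2)
    jj <- jj[jj >= 1 & jj <= ny]
    img[i, jj] <- 100
  }
  curve <- fit_arch_curve(img, n_points = 150, extend_px = 0)
  resid <- curve$points[, 2] - (0.02 * (curve$points[, 1] - 60)^2 + 10)
  expect_lt(sqrt(mean(resid^2)), 1)
  # normals are unit and perpendicular (constructor invariant re-checked)
  expect_equal(sqrt(rowSums(curve$normals^2)), rep(1, 150), tolerance = 1e-9)

  expect_error(fit_arch_curve(matrix(0, 20, 20)), "arch not found")
})

test_that("arch curve passes close to every true tooth center", {
  ph <- coarse_cbct()
  curve <- coarse_sep()$curve
  for (jw in c("upper", "lower")) {
    cen <- truth_centers_px(ph$truth, ph$volume, jw)
    for (i in seq_len(nrow(cen))) {
      d <- min(sqrt((curve$points[, 1] - cen[i, 1])^2 +
                      (curve$points[, 2] - cen[i, 2])^2))
      expect_lt(d * ph$volume$spacing[1], 1.0)   # within 1 mm of the curve
    }
  }
})

test_that("panoramic extraction averages correctly and is intensity-bounded", {
  v <- voxel_volume(array(2.25, c(20, 20, 6)))
  curve <- arch_curve(cbind(5:15, rep(10, 11)),
                      cbind(rep(0, 11), rep(1, 11)))
  pano <- extract_panoramic(v, curve, w = 3)
  expect_true(all(abs(pano$data - 2.25) < 1e-12))

  # volume nonzero only on a straight "curve": P = value / (2K + 1)
  v2 <- voxel_volume(array(0, c(21, 21, 4)))
  v2$data[11, 5:17, ] <- 30
  line <- arch_curve(cbind(rep(11, 13), 5:17),
                     cbind(rep(1, 13), rep(0, 13)))
  pano2 <- extract_panoramic(v2, line, w = 3, K = 3)
  expect_equal(unique(as.numeric(pano2$data)), 30 / 7)

  # bounded by the input intensity range on the phantom
  sep <- coarse_sep()
  ph <- coarse_cbct()
  expect_gte(min(sep$pano$data, na.rm = TRUE), min(ph$volume$data))
  expect_lte(max(sep$pano$data, na.rm = TRUE), max(ph$volume$data))
})

test_that("panoramic point projection matches exhaustive search", {
  curve <- coarse_sep()$curve
  # projecting a curve point returns its own column (inverse-consistency)
  for (c0 in c(1, 57, 200, nrow(curve$points))) {
    p <- c(curve$points[c0, ], 40)
    got <- project_point_to_panoramic(p, curve, w = 9)
    expect_equal(unname(got[1, "c"]), c0)
    expect_equal(unname(got[1, "z"]), 40)
  }
  # far point returns none
  far <- c(max(curve$points[, 1]) + 50, max(curve$points[, 2]) + 50, 10)
  expect_true(is.na(project_point_to_panoramic(far, curve, w = 9)[1, 1]))
  # 100 seeded random points vs brute force
  withr::local_seed(11)
  pts <- cbind(runif(100, 1, 130), runif(100, 1, 170), runif(100, 1, 80))
  got <- project_point_to_panoramic(pts, curve, w = 9)
  for (i in 1:100) {
    d <- sqrt((curve$points[, 1] - pts[i, 1])^2 +
                (curve$points[, 2] - pts[i, 2])^2)
    j <- which.min(d)
    if (d[j] <= 9) {
      expect_equal(unname(got[i, 1]), j)
      expect_equal(unname(got[i, 2]), pts[i, 3])
    } else {
      expect_true(is.na(got[i, 1]))
    }
  }
})

test_that("arch_curve rejects malformed geometry", {
  pts <- cbind(c(1, 1, 2), c(1, 1, 2))
  nrm <- cbind(rep(0, 3), rep(1, 3))
  expect_error(arch_curve(pts, nrm), "distinct")
  expect_error(arch_curve(cbind(1:3, rep(1, 3)), cbind(rep(2, 3), rep(0, 3))),
               "unit length")
  expect_error(arch_curve(cbind(1:3, rep(1, 3)), cbind(rep(1, 3), rep(0, 3))),
               "perpendicular")
})
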