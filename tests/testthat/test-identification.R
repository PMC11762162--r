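test_that("MIP matches the per-pixel max/argmax oracle and its tie rule", {
  v <- voxel_volume(array(0, c(6, 6, 10)))
  v$data[3, 4, 7] <- 5
  mip <- compute_mip(v)
  expect_equal(sum(mip$data != 0), 1)
  expect_equal(mip$data[3, 4], 5)
  expect_equal(mip$depth$z[3, 4], 6)            # zero-based z index
  cst <- compute_mip(voxel_volume(array(2, c(4, 4, 4))))
  expect_true(all(cst$data == 2))
  expect_true(all(cst$depth$z == 0))            # smallest index attains the max
  withr::local_seed(16)
  r <- voxel_volume(array(rnorm(4 * 5 * 6), c(4, 5, 6)))
  mr <- compute_mip(r)
  for (i in 1:4) for (j in 1:5) {
    expect_equal(mr$data[i, j], max(r$data[i, j, ]))
    expect_equal(mr$depth$z[i, j], which.max(r$data[i, j, ]) - 1)
  }
})

test_that("align_jaw is the identity at zero and guards implausible angles", {
  v <- coarse_cbct()$volume
  expect_identical(align_jaw(v, 0)$data, v$data)
  expect_error(align_jaw(v, 75), "60")
})

test_that("aligning an inclined phantom levels the occlusal plane", {
  ph <- generate_cbct_phantom(coarse_spec(alpha_deg = 10, noise_sd = 0))
  ph0 <- generate_cbct_phantom(coarse_spec(alpha_deg = 0, noise_sd = 0))
  thr <- 1200
  spread <- function(vol) {
    # spread of per-tooth occlusal z across the arch
    idx <- which(vol$data > thr, arr.ind = TRUE)
    diff(range(tapply(idx[, 3], cut(idx[, 2], 8), min)))
  }
  before <- spread(ph$volume)
  al <- align_jaw(ph$volume, 10)
  expect_lte(spread(al), spread(ph0$volume) + 1)    # within one voxel
  expect_lt(spread(al), before)
  # fallback estimator recovers the angle within 2 degrees
  sep <- separate_jaws(ph$volume, coarse_config())
  est <- align_jaw(voxel_volume(ph$volume$data * sep$assignment$lower,
                                spacing = ph$volume$spacing,
                                origin = ph$volume$origin),
                   alpha = NULL, threshold = sep$threshold, jaw = "lower")
  expect_lt(abs(attr(est, "alpha_deg") - 10), 2)
})

test_that("teeth detection finds all 12 teeth near their true centers", {
  fx <- coarse_upper_ident()
  expect_equal(nrow(fx$det$detections), 12)
  cen <- truth_centers_px(fx$ph$truth, fx$ph$volume, "upper")
  dd <- fx$det$detections
  used <- integer(0)
  for (i in seq_len(nrow(cen))) {
    d <- sqrt((dd$cx - cen[i, 1])^2 + (dd$cy - cen[i, 2])^2) *
      fx$ph$volume$spacing[1]
    j <- which.min(d)
    expect_lt(d[j], 1.5)
    expect_false(j %in% used)   # each detection matches a distinct tooth
    used <- c(used, j)
  }
  expect_error(detect_teeth_on_mip(matrix(0, 30, 30), threshold = 10),
               "no teeth")
})

test_that("detection still finds 12 teeth with a crowded, rotated incisor", {
  cr <- data.frame(jaw = "upper", side = "R", pos = 2,
                   du_mm = 0.6, dv_mm = 1.3, rot_deg = 25)
  ph <- generate_cbct_phantom(coarse_spec(crowding = cr))
  sep <- separate_jaws(ph$volume, coarse_config())
  mvol <- voxel_volume(ph$volume$data * sep$assignment$upper,
                       spacing = ph$volume$spacing, origin = ph$volume$origin)
  det <- detect_teeth_on_mip(compute_mip(mvol, jaw = "upper"),
                             threshold = sep$threshold)
  expect_equal(nrow(det$detections), 12)
})

test_that("the jaw profile traces the outer boundary of a disk correctly", {
  img <- matrix(0, 41, 41)
  for (i in 1:41) for (j in 1:41)
    if ((i - 21)^2 + (j - 21)^2 <= 13^2) img[i, j] <- 100
  prof <- extract_jaw_profile(img, threshold = 50)
  r <- sqrt(rowSums(sweep(prof$boundary, 2, c(21, 21))^2))
  expect_true(all(abs(r - 13) < 2))
  expect_equal(unname(prof$centroid), c(21, 21), tolerance = 0.8)
  expect_error(extract_jaw_profile(matrix(0, 20, 20), threshold = 1),
               "not found")
})

test_that("the midline operator follows its defining equation", {
  # hand-listed anterior boundary, centroid (0, 5), delta_d = 0.2:
  # the three distance-5 points average to (0, 10)
  b <- rbind(c(-2, 9), c(-1, 10), c(0, 10), c(1, 10), c(2, 9))
  prof <- structure(list(
    boundary = b, centroid = c(0, 5),
    arc = c(0, cumsum(sqrt(rowSums(diff(b)^2)))),
    tangents = matrix(rep(c(1, 0), each = 5), 5, 2),
    smooth = NULL, spacing = c(1, 1), mask = matrix(TRUE, 1, 1)),
    class = "jaw_profile")
  # restrict-to-anterior plays no role here: distances peak mid-arc
  est <- estimate_midline(prof, delta_d = 0.2)
  expect_equal(unname(est$p_mid), c(0, 10))
  # delta_d = 0 with a unique farthest point returns that point exactly
  b2 <- rbind(c(-2, 9), c(-1, 9.5), c(0, 10), c(1, 9.5), c(2, 9))
  prof2 <- prof; prof2$boundary <- b2
  prof2$arc <- c(0, cumsum(sqrt(rowSums(diff(b2)^2))))
  est2 <- estimate_midline(prof2, delta_d = 0)
  expect_equal(unname(est2$p_mid), c(0, 10))
  # the axis points from the midline through the centroid, unit length
  expect_equal(unname(est$axis), c(0, -1))
})

test_that("the adaptive midline lands near the true midline under rotation", {
  for (th in c(-12, 0, 12)) {
    ph <- generate_cbct_phantom(coarse_spec(theta_deg = th))
    sep <- separate_jaws(ph$volume, coarse_config())
    mvol <- voxel_volume(ph$volume$data * sep$assignment$upper,
                         spacing = ph$volume$spacing,
                         origin = ph$volume$origin)
    mip <- compute_mip(mvol, jaw = "upper")
    prof <- estimate_midline(extract_jaw_profile(mip, threshold = sep$threshold),
                             delta_d = 0.6 / 0.5)
    tp <- ph$truth$midline$upper$point
    tpx <- (tp[1:2] - ph$volume$origin[1:2]) / ph$volume$spacing[1:2] + 0.5
    d_mm <- sqrt(sum((prof$p_mid - tpx)^2)) * ph$volume$spacing[1]
    expect_lt(d_mm, 2.0)
  }
})

test_that("FDI numbering is complete, disjoint, and flags shortfalls", {
  fx <- coarse_upper_ident()
  det <- fx$det$detections
  expect_setequal(det$pos[det$side == "L"], 1:6)
  expect_setequal(det$pos[det$side == "R"], 1:6)
  # compare against truth by nearest center
  cen <- truth_centers_px(fx$ph$truth, fx$ph$volume, "upper")
  tt <- fx$ph$truth$teeth[fx$ph$truth$teeth$jaw == "upper", ]
  for (i in seq_len(nrow(tt))) {
    j <- which.min((det$cx - cen[i, 1])^2 + (det$cy - cen[i, 2])^2)
    expect_identical(det$side[j], tt$side[i])
    expect_equal(det$pos[j], tt$pos[i])
  }
  # shortfall: drop one side's teeth from the detections
  det5 <- fx$det
  keep <- det5$detections$side == "L" | det5$detections$pos <= 5
  det5$detections <- det5$detections[keep, ]
  renum <- assign_fdi(det5, fx$prof)
  rside <- renum$detections[renum$detections$side == "R", ]
  expect_setequal(rside$pos, 1:5)
  expect_true(all(grepl("side_shortfall", rside$flag)))
})

test_that("scan identification on the depth map numbers all teeth", {
  det <- identify_from_depthmap(scan_seg()$depth)
  expect_equal(nrow(det$detections), 12)
  expect_setequal(det$detections$pos[det$detections$side == "L"], 1:6)
  expect_setequal(det$detections$pos[det$detections$side == "R"], 1:6)
  empty <- depth_map(matrix(NA_real_, 8, 8),
                     valid = matrix(FALSE, 8, 8), units = "mm")
  expect_error(identify_from_depthmap(empty), "empty depth map")
})
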