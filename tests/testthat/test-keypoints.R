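test_that("tooth ROI cropping honors margins and clips at borders", {
  fx <- coarse_upper_ident()
  id <- fx$det$detections$id[1]
  row <- fx$det$detections[1, ]
  roi0 <- crop_tooth_roi(fx$mip$data, fx$det, id, fx$prof, margin_mm = 0,
                         spacing = fx$ph$volume$spacing[1:2])
  expect_equal(dim(roi0$img), c(row$w, row$h))
  expect_equal(roi0$offset, c(row$x0, row$y0))
  # a huge margin clips to the image without error
  roi_big <- crop_tooth_roi(fx$mip$data, fx$det, id, fx$prof,
                            margin_mm = 500,
                            spacing = fx$ph$volume$spacing[1:2])
  expect_equal(dim(roi_big$img), dim(fx$mip$data))
  expect_error(crop_tooth_roi(fx$mip$data, fx$det, 999, fx$prof), "unknown")
})

test_that("the ROI mesio-distal axis is close to the true direction", {
  fx <- coarse_upper_ident()
  tt <- fx$ph$truth$teeth[fx$ph$truth$teeth$jaw == "upper", ]
  cen <- truth_centers_px(fx$ph$truth, fx$ph$volume, "upper")
  dd <- fx$det$detections
  for (i in which(tt$pos %in% c(1, 4))) {
    j <- dd$id[which.min((dd$cx - cen[i, 1])^2 + (dd$cy - cen[i, 2])^2)]
    roi <- crop_tooth_roi(fx$mip$data, fx$det, j, fx$prof,
                          spacing = fx$ph$volume$spacing[1:2])
    u <- c(tt$dis_x[i] - tt$mes_x[i], tt$dis_y[i] - tt$mes_y[i])
    u <- u / sqrt(sum(u^2))
    ang <- acos(min(1, abs(sum(roi$axis * u)))) * 180 / pi
    expect_lt(ang, 10)
  }
})

test_that("the reference backend finds box-edge midpoints on a clean mask", {
  img <- matrix(0, 40, 30)
  img[10:25, 12:20] <- 1
  roi <- structure(list(
    img = img, mask = img > 0, fg = img > 0, offset = c(0L, 0L),
    axis = c(1, 0), det = NULL, profile = NULL, spacing = c(1, 1)),
    class = "tooth_roi")
  pair <- reference_landmark_backend(roi)
  expect_equal(unname(pair$lo[2]), 16, tolerance = 0.8)  # edge midpoint in y
  expect_equal(unname(pair$hi[2]), 16, tolerance = 0.8)
  expect_equal(unname(pair$hi[1] - pair$lo[1]), 15, tolerance = 1.2)
  expect_error(reference_landmark_backend(
    structure(list(img = img, mask = img > 2, fg = img > 2,
                   offset = c(0L, 0L), axis = c(1, 0), profile = NULL,
                   spacing = c(1, 1)), class = "tooth_roi")),
    "degenerate")
})

test_that("landmarks are equivariant to a joint mask/axis rotation", {
  mk <- function(theta) {
    img <- matrix(0, 60, 60)
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    for (i in 1:60) for (j in 1:60) {
      q <- t(R) %*% (c(i, j) - 30)
      if (abs(q[1]) <= 10 && abs(q[2]) <= 5) img[i, j] <- 1
    }
    ax <- as.vector(R %*% c(1, 0))
    structure(list(img = img, mask = img > 0, fg = img > 0,
                   offset = c(0L, 0L), axis = ax, profile = NULL,
                   spacing = c(1, 1)), class = "tooth_roi")
  }
  p0 <- reference_landmark_backend(mk(0))
  p30 <- reference_landmark_backend(mk(30 * pi / 180))
  R30 <- matrix(c(cos(pi / 6), sin(pi / 6), -sin(pi / 6), cos(pi / 6)), 2)
  for (endp in c("lo", "hi")) {
    rot_expected <- as.vector(R30 %*% (p0[[endp]] - 30)) + 30
    expect_equal(unname(p30[[endp]]), unname(rot_expected), tolerance = 1.5)
  }
})

test_that("mesiodistal width reproduces exact Euclidean distances", {
  expect_equal(mesiodistal_width(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(mesiodistal_width(c(0, 0, 0), c(2, 3, 6)), 7)
  # symmetric and rigid-motion invariant
  withr::local_seed(17)
  a <- rnorm(3); b <- rnorm(3)
  expect_equal(mesiodistal_width(a, b), mesiodistal_width(b, a))
  th <- 33 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  t0 <- c(5, -2, 1)
  expect_equal(mesiodistal_width(as.vector(R %*% a) + t0,
                                 as.vector(R %*% b) + t0),
               mesiodistal_width(a, b))
})

test_that("lifted phantom cusp tips carry the true surface height", {
  sc <- scan_fix()
  seg <- scan_seg()
  tt <- sc$truth$teeth
  # at a cusp tip the surface is locally flat, so the max-z rasterization
  # of the depth cell reproduces the true height; at steep crown edges the
  # cell maximum is the property being rasterized, not the edge height
  for (i in which(tt$pos %in% c(3, 4))) {
    gi <- (tt$tipb_x[i] - seg$depth$origin[1]) / seg$depth$spacing[1] + 0.5
    gj <- (tt$tipb_y[i] - seg$depth$origin[2]) / seg$depth$spacing[2] + 0.5
    p <- lift_to_3d(c(gi, gj), seg$depth)
    expect_lt(abs(p[3] - tt$tipb_z[i]), 0.3)
  }
})

test_that("cusp peaks follow discrete peak-finding with prominence", {
  pk <- odontometry:::find_peaks(c(1, 3, 6, 3, 2, 5, 2), min_prominence = 0.5)
  expect_equal(pk$index, c(3, 6))          # zero-based indices 2 and 5
  expect_equal(pk$value, c(6, 5))
  flat <- odontometry:::find_peaks(rep(2, 9), min_prominence = 0.5)
  expect_equal(nrow(flat), 0)
})

test_that("scan-phantom cusp tips land within 0.5 mm of the truth", {
  sc <- scan_fix()
  seg <- scan_seg()
  tt <- sc$truth$teeth
  cen_mm <- c(mean(tt$cx), mean(tt$cy))
  for (i in which(tt$pos %in% c(3, 4))) {
    pair <- list(mesial = c(tt$mes_x[i], tt$mes_y[i], tt$mes_z[i]),
                 distal = c(tt$dis_x[i], tt$dis_y[i], tt$dis_z[i]))
    md <- (pair$distal - pair$mesial)[1:2]; md <- md / sqrt(sum(md^2))
    tip <- cusp_tips(pair, seg$depth, md, cen_mm, tt$pos[i])
    err <- sqrt(sum((tip$buccal - c(tt$tipb_x[i], tt$tipb_y[i],
                                    tt$tipb_z[i]))^2))
    expect_lt(err, 0.5)
  }
  # a flat surface has no cusp
  flatz <- matrix(1, 40, 40)
  flat <- depth_map(flatz, spacing = c(0.25, 0.25), units = "mm")
  expect_error(cusp_tips(list(mesial = c(3, 5, 1), distal = c(7, 5, 1)),
                         flat, c(1, 0), c(5, -20), 4), "cusp not found")
})

test_that("arch widths pair cusp tips across the midline", {
  tips <- tibble::tibble(side = c("L", "R"), pos = c(3, 3),
                         x = c(-15, 15), y = c(0, 0), z = c(0, 0))
  aw <- arch_widths(tips)
  expect_equal(aw$width_mm, 30)
  # a missing side drops that parameter, others are reported
  tips2 <- tibble::tibble(side = c("R", "L", "R"), pos = c(3, 4, 4),
                          x = c(15, -19, 19), y = 0, z = 0)
  aw2 <- arch_widths(tips2)
  expect_equal(aw2$parameter, "premolar")
  expect_equal(aw2$width_mm, 38)
})
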