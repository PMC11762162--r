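test_that("representative point is the sagittal box center", {
  expect_equal(representative_point(c(10, 20, 6, 4), 50), c(12, 50, 23))
  expect_error(representative_point(c(0, 0, 0, 2), 1), "positive")
  # 50 random boxes vs an independent recomputation of the formula
  withr::local_seed(12)
  for (i in 1:50) {
    b <- c(runif(2, 0, 100), runif(2, 1, 30))
    s <- sample.int(200, 1)
    expect_equal(representative_point(b, s),
                 c(b[1] + b[4] / 2, s, b[2] + b[3] / 2))
  }
})

test_that("the reference slice segmenter finds separate bright blobs", {
  img <- matrix(0, 60, 60)
  img[10:20, 10:20] <- 1500
  img[35:45, 30:40] <- 1500
  seg <- slice_segmenter(threshold = 1000)
  masks <- seg(img)
  expect_length(masks, 2)
  # masks are disjoint
  expect_equal(max(Reduce(`+`, lapply(masks, `*`, 1))), 1)
  expect_length(seg(matrix(0, 40, 40)), 0)
})

test_that("a mid-sagittal phantom slice yields one mask per jaw", {
  ph <- coarse_cbct()
  thr <- coarse_sep()$threshold
  tt <- ph$truth$teeth
  y_inc <- tt$cy[tt$jaw == "upper" & tt$pos == 1][1]
  s <- round((y_inc - ph$volume$origin[2]) / ph$volume$spacing[2])
  masks <- slice_segmenter(threshold = thr)(ph$volume$data[, s, ])
  expect_length(masks, 2)   # upper incisor pair, lower incisor pair
})

test_that("panoramic masks split into 12 upper and 12 lower", {
  pm <- coarse_sep()$pano_masks
  expect_length(pm$upper, 12)
  expect_length(pm$lower, 12)
  up <- Reduce(`|`, pm$upper); lo <- Reduce(`|`, pm$lower)
  expect_false(any(up & lo))    # no pixel belongs to both sets
  # every upper centroid above the line, every lower below
  line <- pm$line
  for (m in pm$upper) {
    cen <- colMeans(which(m, arr.ind = TRUE))
    expect_gt(cen[2], line["a"] * cen[1] + line["b"])
  }
  for (m in pm$lower) {
    cen <- colMeans(which(m, arr.ind = TRUE))
    expect_lt(cen[2], line["a"] * cen[1] + line["b"])
  }
})

test_that("two stacked masks are assigned by z-order", {
  img <- matrix(0, 30, 40)
  m1 <- img > 1; m1[10:20, 5:12] <- TRUE    # low z
  m2 <- img > 1; m2[10:20, 25:32] <- TRUE   # high z
  pano <- structure(list(data = img + 1600 * (m1 | m2), w = 3, K = 3),
                    class = "panoramic_image")
  out <- split_panoramic_masks(pano, segmenter = function(image) list(m1, m2))
  expect_length(out$upper, 1); expect_length(out$lower, 1)
  expect_true(identical(out$upper[[1]], m2))   # z axis points up
  expect_true(identical(out$lower[[1]], m1))
  expect_error(split_panoramic_masks(pano, segmenter = function(image) list(m1)),
               "fewer than 2")
})

test_that("jaw assignment agrees with the voxel-level truth labels", {
  ph <- coarse_cbct()
  ja <- coarse_sep()$assignment
  tl <- ph$truth$jaw_label
  expect_false(any(ja$upper & ja$lower))            # hard invariant
  expect_gte(sum(ja$upper & tl == 1L) / sum(tl == 1L), 0.97)
  expect_gte(sum(ja$lower & tl == 2L) / sum(tl == 2L), 0.97)
  expect_equal(sum(ja$upper & tl == 2L), 0)          # zero cross-assignment
  expect_equal(sum(ja$lower & tl == 1L), 0)
})

test_that("a slice mask projecting beyond w is counted unassigned", {
  # one bright blob far from a short arch curve
  v <- voxel_volume(array(0, c(60, 5, 40)))
  v$data[5:10, 2:4, 10:20] <- 1600
  curve <- arch_curve(cbind(40:50, rep(3, 11)), cbind(rep(0, 11), rep(1, 11)))
  pm <- structure(list(
    upper = list(matrix(TRUE, 11, 40)), lower = list(matrix(FALSE, 11, 40)),
    line = c(a = 0, b = 1e6)), class = "panoramic_tooth_masks")
  ja <- assign_jaws(v, pm, curve, w = 5,
                    segmenter = slice_segmenter(threshold = 1000))
  expect_gt(ja$n_unassigned, 0)
  expect_equal(ja$n_unassigned, ja$n_masks)
})

test_that("separation quality is monotone in the inter-jaw gap", {
  ph0 <- generate_cbct_phantom(coarse_spec(gap_mm = 0))
  sep0 <- separate_jaws(ph0$volume, coarse_config())
  cr0 <- cross_assignment_rate(sep0$assignment, ph0$truth$jaw_label)
  ph4 <- coarse_cbct()
  cr4 <- cross_assignment_rate(coarse_sep()$assignment, ph4$truth$jaw_label)
  expect_lte(cr4, cr0 + 1e-12)
  expect_lte(cr0, 0.02)
})
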