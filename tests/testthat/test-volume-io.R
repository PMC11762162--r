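test_that("voxel_volume enforces its invariants and crop geometry", {
  v <- voxel_volume(array(0, c(4, 4, 4)), spacing = c(0.3, 0.3, 0.3))
  expect_equal(dim(v), c(4L, 4L, 4L))
  expect_error(voxel_volume(array(0, c(4, 4, 4)), spacing = c(0.3, 0, 0.3)),
               "positive")
  bad <- array(0, c(2, 2, 2)); bad[1] <- NA
  expect_error(voxel_volume(bad), "non-finite")

  grid <- voxel_volume(array(seq_len(4 * 3 * 2), c(4, 3, 2)),
                       spacing = c(1, 2, 3), origin = c(10, 20, 30))
  # full-grid roi is the identity
  full <- crop_volume(grid, region_of_interest(c(0, 4), c(0, 3), c(0, 2)))
  expect_identical(full$data, grid$data)
  expect_equal(full$origin, grid$origin)
  # sub-block [1,3) x [0,2) x [0,1)
  sub <- crop_volume(grid, region_of_interest(c(1, 3), c(0, 2), c(0, 1)))
  expect_identical(sub$data, grid$data[2:3, 1:2, 1, drop = FALSE])
  expect_equal(sub$origin, c(10 + 1 * 1, 20, 30))
  # roi exceeding the grid errors
  expect_error(crop_volume(grid, region_of_interest(c(0, 5), c(0, 3), c(0, 2))),
               "exceeds")
  expect_error(region_of_interest(c(2, 2), c(0, 1), c(0, 1)), "low < high")
})

test_that("NRRD and NIfTI volume round-trips are lossless", {
  withr::local_seed(7)
  v <- voxel_volume(array(rnorm(4 * 5 * 6), c(4, 5, 6)),
                    spacing = c(0.3, 0.3, 0.3), origin = c(1, -2, 3))
  p1 <- withr::local_tempfile(fileext = ".nrrd")
  write_volume(v, p1)
  v1 <- load_volume(p1)
  expect_identical(v1$data, v$data)   # bitwise round trip
  expect_equal(v1$spacing, v$spacing)
  expect_equal(v1$origin, v$origin)

  p2 <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, p2)
  v2 <- load_volume(p2)
  expect_equal(v2$data, v$data, tolerance = 1e-12)
  expect_equal(as.numeric(v2$spacing), v$spacing, tolerance = 1e-6)

  # zero 4x4x4 volume loads back as written
  z <- voxel_volume(array(0, c(4, 4, 4)), spacing = c(0.3, 0.3, 0.3))
  p3 <- withr::local_tempfile(fileext = ".nrrd")
  write_volume(z, p3)
  expect_true(all(load_volume(p3)$data == 0))
})

test_that("non-positive spacing in a volume file is a hard error", {
  p <- withr::local_tempfile(fileext = ".nrrd")
  writeLines(c("NRRD0004", "type: double", "dimension: 3", "sizes: 1 1 1",
               "spacings: 0 1 1", "encoding: raw", "endian: little", ""),
             con = p, sep = "\n")
  con <- file(p, "ab"); writeBin(1.0, con, endian = "little"); close(con)
  expect_error(load_volume(p), "spacings")
})

test_that("colored PLY clouds round-trip with HSV unit-range colors", {
  withr::local_seed(8)
  n <- 1000
  # saturation/value away from zero: at v = 0 the 8-bit RGB quantization
  # collapses hue and saturation (achromatic black), as in any color space
  cl <- colored_cloud(matrix(rnorm(3 * n), n),
                      cbind(runif(n), runif(n, 0.2, 1), runif(n, 0.3, 1)))
  expect_equal(nrow(cl), n)
  for (fmt in c("binary_little_endian", "ascii")) {
    p <- withr::local_tempfile(fileext = ".ply")
    write_colored_mesh(cl, p, format = fmt)
    back <- load_colored_mesh(p)
    expect_equal(nrow(back), n)
    expect_equal(back$x, cl$x, tolerance = 1e-5)
    # colors quantized to 8 bits on write: 1/255 per RGB channel, which
    # bounds the value error directly and the saturation error after
    # scaling by the value (s is a ratio of channel differences)
    expect_lt(max(abs(back$v - cl$v)), 1.5 / 255)
    expect_lt(max(abs(back$s - cl$s) * cl$v), 2 / 255)
  }
})

test_that("RGB->HSV conversion matches the color-space identities", {
  hsv <- rgb255_to_hsv(rbind(c(255, 0, 0), c(255, 255, 255)))
  expect_equal(unname(hsv[1, ]), c(0, 1, 1))       # pure red
  expect_equal(unname(hsv[2, 2:3]), c(0, 1))       # white: s = 0, v = 1
  # conversion composed with its inverse is identity within 1/255
  withr::local_seed(9)
  rgb <- matrix(sample(0:255, 300, replace = TRUE), ncol = 3)
  back <- hsv_to_rgb255(rgb255_to_hsv(rgb))
  expect_lte(max(abs(back - rgb)), 1)
})

test_that("a PLY without vertex color is rejected with guidance", {
  p <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 1",
               "property float x", "property float y", "property float z",
               "end_header", "0 0 0"), p)
  expect_error(load_colored_mesh(p), "red/green/blue")
})

test_that("depth maps validate and look up nearest valid cells", {
  z <- matrix(NA_real_, 5, 5); z[2:4, 2:4] <- 7
  dm <- depth_map(z, spacing = c(0.3, 0.3), units = "voxel")
  expect_equal(sum(dm$valid), 9)
  p <- lift_to_3d(c(3, 3), dm, spacing = c(0.3, 0.3, 0.3))
  expect_equal(p[3], 2.1)                          # depth 7 at 0.3 mm
  # one cell off the valid region: nearest valid cell's depth
  expect_equal(lift_to_3d(c(1, 3), dm, spacing = c(0.3, 0.3, 0.3))[3], 2.1)
  big <- matrix(NA_real_, 20, 20); big[1, 1] <- 1
  dmb <- depth_map(big, units = "voxel")
  expect_error(lift_to_3d(c(15, 15), dmb), "off tooth surface")
})
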