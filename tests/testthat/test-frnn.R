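test_that("FRNN candidate selection matches an exhaustive distance scan", {
  withr::local_seed(13)
  n <- 500
  samples <- tibble::tibble(h = runif(n), s = runif(n), v = runif(n),
                            label = sample(1:2, n, replace = TRUE))
  model <- frnn_model(samples, R = 0.15)
  queries <- cbind(runif(100), runif(100), runif(100))
  for (i in 1:100) {
    cand <- frnn_candidates(model, queries[i, ])
    dh <- abs(samples$h - queries[i, 1]); dh <- pmin(dh, 1 - dh)
    d <- sqrt(dh^2 + (samples$s - queries[i, 2])^2 +
                (samples$v - queries[i, 3])^2)
    expect_identical(nrow(cand), sum(d < 0.15))
    expect_equal(sort(cand$d), sort(d[d < 0.15]))
  }
  # R covering the whole cube returns everything; R -> 0 returns nothing
  all_model <- frnn_model(samples, R = 2)
  expect_equal(nrow(frnn_candidates(all_model, c(0.5, 0.5, 0.5))), n)
  tiny <- frnn_model(samples, R = 1e-12)
  expect_equal(nrow(frnn_candidates(tiny, c(0.123, 0.456, 0.789))), 0)
})

test_that("the gravity score follows the signed inverse-square law", {
  samples <- tibble::tibble(h = c(0.1, 0.1), s = c(0.5, 0.5), v = c(0.2, 0.7),
                            label = c(1L, 2L))
  model <- frnn_model(samples, R = 2)
  # one teeth candidate at d = 0.5 -> F = -1 / 0.25 = -4
  cand <- frnn_candidates(model, c(0.1, 0.5, 0.7))
  one <- cand[cand$label == 1L, ]
  expect_equal(one$d, 0.5)
  expect_equal(gravity_score(model, one), -4)
  # one teeth and one gum at equal distance cancel
  both <- frnn_candidates(model, c(0.1, 0.5, 0.45))
  expect_equal(gravity_score(model, both), 0)
  # empty candidate set scores 0
  expect_equal(gravity_score(model, both[0, ]), 0)
  # 50 seeded queries vs an independent recomputation
  withr::local_seed(14)
  big <- tibble::tibble(h = runif(80), s = runif(80), v = runif(80),
                        label = sample(1:2, 80, replace = TRUE))
  bm <- frnn_model(big, R = 0.4)
  for (i in 1:50) {
    q <- runif(3)
    cand <- frnn_candidates(bm, q)
    expected <- sum(ifelse(cand$label == 1L, -1, 1) / pmax(cand$d, 1e-6)^2)
    expect_equal(gravity_score(bm, cand), expected)
  }
})

test_that("classification follows the F < 0 rule with ties to gum", {
  samples <- tibble::tibble(h = c(0.1, 0.9), s = c(0.1, 0.6), v = c(0.9, 0.5),
                            label = c(1L, 2L))
  model <- frnn_model(samples, R = 0.15)
  expect_equal(classify_point(model, c(0.1, 0.1, 0.9)), 1L)  # at a teeth sample
  expect_equal(classify_point(model, c(0.5, 0.95, 0.05)), 2L) # empty set -> gum
})

test_that("classification is invariant to a global hue shift", {
  withr::local_seed(15)
  n <- 120
  samples <- tibble::tibble(h = runif(n), s = runif(n), v = runif(n),
                            label = sample(1:2, n, replace = TRUE))
  queries <- cbind(runif(40), runif(40), runif(40))
  m1 <- frnn_model(samples, R = 0.2)
  shifted <- samples; shifted$h <- (shifted$h + 0.5) %% 1
  m2 <- frnn_model(shifted, R = 0.2)
  q2 <- queries; q2[, 1] <- (q2[, 1] + 0.5) %% 1
  expect_identical(classify_point(m1, queries), classify_point(m2, q2))
})

test_that("enlarging R cannot flip a teeth label until gum enters the ball", {
  # teeth samples close to the query, one gum sample far away
  samples <- tibble::tibble(h = c(0.10, 0.12, 0.11, 0.60),
                            s = c(0.05, 0.06, 0.07, 0.70),
                            v = c(0.90, 0.92, 0.91, 0.40),
                            label = c(1L, 1L, 1L, 2L))
  q <- c(0.11, 0.06, 0.91)
  gum_d <- sqrt(min(abs(0.60 - 0.11), 1 - abs(0.60 - 0.11))^2 +
                  (0.70 - 0.06)^2 + (0.40 - 0.91)^2)
  for (R in seq(0.05, gum_d - 0.01, length.out = 6)) {
    expect_equal(classify_point(frnn_model(samples, R = R), q), 1L)
  }
})

test_that("scan phantom classification is exact at zero color jitter", {
  sc <- generate_scan_phantom(phantom_spec(seed = 4, color_jitter = 0),
                              jaw = "upper")
  model <- frnn_model(phantom_color_samples(jitter = 0, seed = 2))
  pred <- classify_point(model, sc$cloud)
  truth <- ifelse(sc$cloud$label > 0, 1L, 2L)
  expect_equal(mean(pred == truth), 1)
})

test_that("teeth cloud extraction produces a depth map over the teeth only", {
  seg <- scan_seg()
  sc <- scan_fix()
  expect_true(all(seg$teeth$label > 0))          # no gum points survive
  expect_gt(mean(seg$depth$valid), 0)
  # all-gum cloud fails loudly
  gum <- sc$cloud[sc$cloud$label == 0, ]
  class(gum) <- class(sc$cloud)
  expect_error(teeth_cloud_and_depthmap(gum, scan_model()), "no teeth")
})

test_that("frnn model validation rejects degenerate training sets", {
  expect_error(frnn_model(tibble::tibble(h = 0.1, s = 0.1, v = 0.1,
                                         label = 1L)), "both labels")
  expect_error(frnn_model(tibble::tibble(h = c(0.1, 0.2), s = c(0.1, 0.2),
                                         v = c(0.1, 0.2), label = c(1L, 2L)),
                          R = 0), "positive")
})
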