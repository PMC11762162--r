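test_that("mae matches hand sums and a loop oracle", {
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae(c(7.0, 8.0), c(7.5, 7.0)), 0.75)
  withr::local_seed(19)
  a <- rnorm(40); b <- rnorm(40)
  acc <- 0
  for (i in seq_along(a)) acc <- acc + abs(a[i] - b[i])
  expect_equal(mae(a, b), acc / 40)
  expect_error(mae(1:3, 1:4), "length")
})

test_that("measurement tables enforce the long-format schema", {
  expect_error(measurement_table("c1", "upper", "R1", "auto", -1), "positive")
  expect_error(
    measurement_table(c("c1", "c1"), "upper", "R1", "auto", c(7, 7)),
    "duplicate")
})

test_that("ICC(A,1) reproduces a hand mean-squares computation", {
  # two identical sources: perfect agreement
  tb <- measurement_table(case = rep(1:10, 2), jaw = "u",
                          tooth = "R1", source = rep(c("a", "b"), each = 10),
                          value = rep(seq(5, 9, length.out = 10), 2))
  fit <- icc(tb)
  expect_equal(fit$estimate, 1)

  # 4 cases x 2 sources, hand-computed from the two-way decomposition
  vals <- rbind(c(5, 5.2), c(7, 6.9), c(9, 9.3), c(11, 10.8))
  n <- 4; k <- 2
  grand <- mean(vals)
  MSR <- k * sum((rowMeans(vals) - grand)^2) / (n - 1)
  MSC <- n * sum((colMeans(vals) - grand)^2) / (k - 1)
  MSE <- (sum((vals - grand)^2) - (n - 1) * MSR - (k - 1) * MSC) /
    ((n - 1) * (k - 1))
  expected <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  tb2 <- measurement_table(case = rep(1:4, 2), jaw = "u", tooth = "R1",
                           source = rep(c("a", "b"), each = 4),
                           value = as.vector(vals))
  fit2 <- icc(tb2)
  expect_equal(fit2$estimate, expected, tolerance = 1e-12)
  expect_lt(fit2$conf_low, fit2$estimate)
  expect_gt(fit2$conf_high, fit2$estimate)

  # invariant to adding a constant to every value
  tb3 <- tb2; tb3$value <- tb3$value + 100
  expect_equal(icc(tb3)$estimate, fit2$estimate, tolerance = 1e-9)

  # incomplete designs are rejected, naming missing cells
  tb4 <- tb2[-1, ]
  expect_error(icc(tb4), "missing cells")

  td <- tidy(fit2)
  expect_equal(td$estimate, fit2$estimate)
  expect_equal(glance(fit2)$n.subjects, 4)
})

test_that("one-way ANOVA reproduces the textbook mean squares", {
  g <- anova_consistency(list(c(1, 2), c(3, 4)))
  expect_equal(g$F, 8)                        # SSB = 4, SSW = 1, df (1, 2)
  expect_equal(g$df1, 1); expect_equal(g$df2, 2)
  same <- anova_consistency(list(c(2, 3, 4), c(2, 3, 4)))
  expect_equal(same$F, 0)
  # critical value for 4 groups of 30 at alpha = 0.05
  withr::local_seed(20)
  four <- anova_consistency(replicate(4, rnorm(30), simplify = FALSE))
  expect_equal(round(four$F_critical, 2), 2.68)
  expect_error(anova_consistency(list(1, c(2, 3))), "at least 2")
})

test_that("Bland-Altman limits follow mean(d) +/- 1.96 sd(d)", {
  ba <- bland_altman(c(1, 0), c(0, 1))         # d = (1, -1)
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$upper, 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(ba$lower, -ba$upper)            # symmetric about the mean
  same <- bland_altman(c(5, 6, 7), c(5, 6, 7))
  expect_equal(c(same$mean_diff, same$lower, same$upper), c(0, 0, 0))
  withr::local_seed(21)
  a <- rnorm(30); b <- rnorm(30)
  ba2 <- bland_altman(a, b)
  expect_equal(ba2$mean_diff, mean(a - b))
  expect_equal(ba2$upper, mean(a - b) + 1.96 * sd(a - b))
})

test_that("success-rate curves are strict, monotone and bounded", {
  sc <- success_rate_curve(c(0.2, 0.5, 1.2), thresholds = c(0, 0.8, 2))
  expect_equal(sc$fraction, c(0, 2 / 3, 1))    # strict inequality at 0
  withr::local_seed(22)
  sc2 <- success_rate_curve(abs(rnorm(100, 0, 0.5)))
  expect_true(all(diff(sc2$fraction) >= 0))
  expect_true(all(sc2$fraction >= 0 & sc2$fraction <= 1))
})

test_that("the agreement report assembles all statistics coherently", {
  withr::local_seed(23)
  truth <- runif(24, 6, 11)
  auto <- truth + rnorm(24, 0, 0.2)
  tb <- measurement_table(
    case = rep(rep(1:4, each = 6), 2), jaw = "upper",
    tooth = rep(rep(paste0("R", 1:6), 4), 2),
    source = rep(c("auto", "manual"), each = 24),
    value = c(auto, truth))
  rep <- agreement_report(tb, "auto", "manual")
  expect_equal(rep$mae, mean(abs(auto - truth)))
  expect_gt(rep$icc$estimate, 0.9)
  expect_true(all(diff(rep$success$fraction) >= 0))
  expect_lt(rep$anova$F, rep$anova$F_critical)
})
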