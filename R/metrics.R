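#' Mean absolute error between paired measurements
#'
#' @param a,b numeric vectors of equal length (>= 1).
#' @return mean of `|a - b|`, in the units of the inputs (mm here).
#' @export
mae <- function(a, b) {
  if (length(a) != length(b)) stop("a and b differ in length")
  if (!length(a)) stop("empty input")
  mean(abs(a - b))
}

#' Build a long-format measurement table
#'
#' The shared schema for agreement analyses: one row per
#' (case, jaw, tooth, source) with a positive mm value. Duplicate keys are
#' an error.
#'
#' @param case,jaw,tooth,source,value vectors of equal length.
#' @return a tibble of class `measurement_table`.
#' @export
measurement_table <- function(case, jaw, tooth, source, value) {
  tb <- tibble::tibble(case = as.character(case), jaw = as.character(jaw),
                       tooth = as.character(tooth),
                       source = as.character(source),
                       value = as.numeric(value))
  if (any(!is.finite(tb$value) | tb$value <= 0))
    stop("values must be positive and finite")
  key <- paste(tb$case, tb$jaw, tb$tooth, tb$source)
  if (anyDuplicated(key)) stop("duplicate (case, jaw, tooth, source) keys")
  class(tb) <- c("measurement_table", class(tb))
  tb
}

#' Intraclass correlation coefficient for inter-method agreement
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC --
#' ICC(A,1) in the McGraw--Wong taxonomy, the standard choice for agreement
#' between measurement methods -- computed from the two-way mean-squares
#' decomposition over a complete subjects x sources design, with the
#' F-based 95\% confidence interval.
#'
#' @param table a [measurement_table] (subjects are the distinct
#'   (case, jaw, tooth) triples).
#' @param sources which source labels to compare (>= 2; default: all).
#' @param conf_level confidence level of the interval.
#' @return object of class `icc_fit`: estimate, CI bounds, mean squares,
#'   dimensions.
#' @export
icc <- function(table, sources = NULL, conf_level = 0.95) {
  sources <- sources %||% unique(table$source)
  if (length(sources) < 2) stop("at least two sources are required")
  tb <- table[table$source %in% sources, ]
  tb$subject <- paste(tb$case, tb$jaw, tb$tooth, sep = "\r")
  wide <- tapply(tb$value, list(tb$subject, tb$source), function(v) {
    if (length(v) != 1L) stop("duplicate cell in the crossed design")
    v
  })
  if (anyNA(wide)) {
    miss <- which(is.na(wide), arr.ind = TRUE)
    stop("incomplete crossed design; missing cells: ",
         paste(sprintf("(%s, %s)", gsub("\r", "/", rownames(wide)[miss[, 1]]),
                       colnames(wide)[miss[, 2]]), collapse = ", "))
  }
  n <- nrow(wide); k <- ncol(wide)
  grand <- mean(wide)
  row_m <- rowMeans(wide); col_m <- colMeans(wide)
  SSR <- k * sum((row_m - grand)^2)
  SSC <- n * sum((col_m - grand)^2)
  SST <- sum((wide - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1); MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  est <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  if (!is.finite(est)) est <- 1  # zero variance everywhere: exact agreement
  alpha <- 1 - conf_level
  if (MSE <= .Machine$double.eps * max(1, MSR)) {
    lo <- hi <- est
  } else {
    a <- k * est / (n * (1 - est)); b <- 1 + k * est * (n - 1) / (n * (1 - est))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    FL <- stats::qf(1 - alpha / 2, n - 1, v)
    FU <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (MSR - FL * MSE) /
      (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    hi <- n * (FU * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  }
  structure(list(estimate = est, conf_low = lo, conf_high = hi,
                 conf_level = conf_level, n_subjects = n, n_sources = k,
                 MSR = MSR, MSC = MSC, MSE = MSE,
                 model = "two-way random, absolute agreement, single measure (ICC(A,1))"),
            class = "icc_fit")
}

#' @export
print.icc_fit <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.4f, %d%% CI (%.4f, %.4f)  [%d subjects x %d sources]\n",
              x$estimate, round(100 * x$conf_level), x$conf_low, x$conf_high,
              x$n_subjects, x$n_sources))
  cat("  model:", x$model, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.icc_fit <- function(x, ...) {
  tibble::tibble(term = "ICC(A,1)", estimate = x$estimate,
                 conf.low = x$conf_low, conf.high = x$conf_high)
}

#' @export
glance.icc_fit <- function(x, ...) {
  tibble::tibble(icc = x$estimate, conf.low = x$conf_low,
                 conf.high = x$conf_high, n.subjects = x$n_subjects,
                 n.sources = x$n_sources)
}

#' One-way ANOVA consistency test across measurement sources
#'
#' Fixed-effects one-way ANOVA of k groups: tests the null that all group
#' means are equal (the consistency hypothesis between automated and manual
#' measurements). Reports F, the degrees of freedom, the upper-alpha
#' critical value `F_crit` at (k - 1, N - k), and the p-value.
#'
#' @param groups list of >= 2 numeric vectors (each of length >= 2).
#' @param alpha significance level for the critical value.
#' @return object of class `anova_consistency`.
#' @export
anova_consistency <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) stop("at least two groups are required")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("every group needs at least 2 values")
  vals <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  fit <- stats::aov(vals ~ g)
  an <- stats::anova(fit)
  Fv <- an$`F value`[1]
  df1 <- an$Df[1]; df2 <- an$Df[2]
  structure(list(F = Fv, df1 = df1, df2 = df2,
                 F_critical = stats::qf(1 - alpha, df1, df2),
                 p_value = an$`Pr(>F)`[1], alpha = alpha),
            class = "anova_consistency")
}

#' @export
print.anova_consistency <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, F_crit(alpha=%g) = %.4g, p = %.4g\n",
              x$df1, x$df2, x$F, x$alpha, x$F_critical, x$p_value))
  cat(if (x$F < x$F_critical)
    "  no evidence against equal means (consistent sources)\n"
    else "  group means differ at the chosen level\n")
  invisible(x)
}

#' @export
glance.anova_consistency <- function(x, ...) {
  tibble::tibble(statistic = x$F, df1 = x$df1, df2 = x$df2,
                 f.critical = x$F_critical, p.value = x$p_value)
}

#' Bland--Altman agreement limits
#'
#' For paired measurements, the mean difference and the limits of agreement
#' `mean(d) +/- 1.96 sd(d)` (sample standard deviation, n - 1).
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @return object of class `bland_altman`: `mean_diff`, `lower`, `upper`,
#'   `sd_diff`, and the per-pair tibble `data`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("a and b differ in length")
  if (length(a) < 2) stop("at least two pairs are required")
  d <- a - b
  m <- mean(d); s <- stats::sd(d)
  structure(list(mean_diff = m, sd_diff = s,
                 lower = m - 1.96 * s, upper = m + 1.96 * s,
                 data = tibble::tibble(mean_mm = (a + b) / 2, diff_mm = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean diff %.4g, limits (%.4g, %.4g)\n",
              x$mean_diff, x$lower, x$upper))
  invisible(x)
}

#' Success-rate curve over error thresholds
#'
#' The fraction of cases whose absolute error is strictly smaller than each
#' threshold ("deviations smaller than a considered threshold"), evaluated
#' over a grid; nondecreasing in the threshold and bounded in \[0, 1\].
#'
#' @param errors nonempty vector of absolute errors (mm).
#' @param thresholds sorted threshold grid (default 0..1.5 mm).
#' @return tibble of class `success_curve` with `threshold`, `fraction`.
#' @export
success_rate_curve <- function(errors, thresholds = seq(0, 1.5, by = 0.05)) {
  if (!length(errors)) stop("empty error vector")
  if (is.unsorted(thresholds)) stop("thresholds must be sorted")
  out <- tibble::tibble(
    threshold = thresholds,
    fraction = vapply(thresholds, function(t) mean(abs(errors) < t),
                      numeric(1)))
  class(out) <- c("success_curve", class(out))
  out
}

#' Full agreement report between two measurement sources
#'
#' Convenience wrapper producing the per-tooth-type MAE, the ICC with 95\%
#' CI, the one-way ANOVA consistency test, Bland--Altman limits and the
#' success-rate curve for two sources of a [measurement_table].
#'
#' @param table a [measurement_table].
#' @param source_a,source_b the two source labels to compare.
#' @param alpha ANOVA significance level.
#' @return list of class `agreement_report`.
#' @export
agreement_report <- function(table, source_a, source_b, alpha = 0.05) {
  ta <- table[table$source == source_a, ]
  tb <- table[table$source == source_b, ]
  key <- function(t) paste(t$case, t$jaw, t$tooth)
  common <- intersect(key(ta), key(tb))
  ta <- ta[match(common, key(ta)), ]; tb <- tb[match(common, key(tb)), ]
  err <- abs(ta$value - tb$value)
  tooth_type <- sub("^[0-9]*", "", ta$tooth)
  per_type <- tibble::tibble(tooth = ta$tooth, err = err) %>%
    dplyr::group_by(tooth) %>%
    dplyr::summarise(mae_mm = mean(err), n = dplyr::n(), .groups = "drop")
  structure(list(
    mae = mae(ta$value, tb$value),
    mae_by_tooth = per_type,
    icc = icc(table[table$source %in% c(source_a, source_b), ],
              sources = c(source_a, source_b)),
    anova = anova_consistency(list(ta$value, tb$value), alpha = alpha),
    bland_altman = bland_altman(ta$value, tb$value),
    success = success_rate_curve(err),
    sources = c(source_a, source_b), n = length(common)),
    class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %s vs %s over %d measurements\n",
              x$sources[1], x$sources[2], x$n))
  cat(sprintf("  MAE %.3f mm\n", x$mae))
  print(x$icc); print(x$anova); print(x$bland_altman)
  invisible(x)
}
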