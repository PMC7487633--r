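# Test-retest statistics between two measurements per eye: paired t-test,
# Pearson correlation, and Bland-Altman 95% limits of agreement
# (bias +/- 1.96 x sample SD of the differences).

#' Paired repeated measurements
#'
#' @param m1,m2 equal-length numeric vectors (one entry per eye): the first
#'   and second measurement of a metric.
#' @param metric_name `"av_ratio"` or `"density_percent"` (or any label).
#' @return a `repeat_pair`.
#' @export
repeat_pair <- function(m1, m2, metric_name = "metric") {
  if (length(m1) != length(m2) || length(m1) < 2) {
    stop("m1 and m2 must have equal length >= 2", call. = FALSE)
  }
  if (!all(is.finite(m1)) || !all(is.finite(m2))) {
    stop("measurements must be finite", call. = FALSE)
  }
  structure(list(metric_name = metric_name, m1 = as.numeric(m1),
                 m2 = as.numeric(m2), n = length(m1)),
            class = "repeat_pair")
}

as_repeat_pair <- function(pair) {
  if (inherits(pair, "repeat_pair")) pair else repeat_pair(pair[[1]], pair[[2]])
}

#' Bland-Altman limits of agreement
#'
#' Bias is the mean of `m1 - m2`; the 95% limits of agreement are
#' `bias +/- 1.96 x SD` with the sample (n-1 denominator) standard
#' deviation of the differences.
#'
#' @param pair a [repeat_pair()].
#' @return a `bland_altman` result: `bias`, `sd_diff`, `loa_lower`,
#'   `loa_upper`, `n`, plus the per-eye `means` and `diffs` for plotting.
#' @export
bland_altman <- function(pair) {
  pair <- as_repeat_pair(pair)
  d <- pair$m1 - pair$m2
  bias <- mean(d)
  s <- sd(d)
  structure(list(bias = bias, sd_diff = s,
                 loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
                 n = pair$n, means = (pair$m1 + pair$m2) / 2, diffs = d,
                 metric_name = pair$metric_name),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (%s, n = %d): bias %.4g, LoA [%.4g, %.4g]\n",
              x$metric_name, x$n, x$bias, x$loa_lower, x$loa_upper))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Mean of the two measurements against their difference, with the bias and
#' the 95% limits of agreement drawn as horizontal lines.
#'
#' @param x a [bland_altman()] result.
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$diffs,
                 xlab = paste("Mean of measurements,", x$metric_name),
                 ylab = "Difference (1st - 2nd)", pch = 19, ...)
  graphics::abline(h = x$bias, lty = 1)
  graphics::abline(h = c(x$loa_lower, x$loa_upper), lty = 2)
  invisible(x)
}

#' Paired Student's t-test on repeated measurements
#'
#' Classical two-sided paired t on the differences (df = n - 1). A pair
#' with zero difference variance is degenerate: the test is flagged and
#' p = 1 is returned when the bias is also zero.
#'
#' @param pair a [repeat_pair()].
#' @return list with `statistic`, `df`, `p_value`, `degenerate`.
#' @export
paired_t <- function(pair) {
  pair <- as_repeat_pair(pair)
  d <- pair$m1 - pair$m2
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(statistic = NaN, df = pair$n - 1, p_value = 1,
                  degenerate = TRUE))
    }
    return(list(statistic = sign(mean(d)) * Inf, df = pair$n - 1,
                p_value = 0, degenerate = TRUE))
  }
  tt <- t.test(pair$m1, pair$m2, paired = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, degenerate = FALSE)
}

#' Pearson correlation between repeated measurements
#'
#' @param pair a [repeat_pair()] with n >= 3 and non-constant vectors.
#' @return list with `r`, `p_value`, `n`.
#' @export
pearson_r <- function(pair) {
  pair <- as_repeat_pair(pair)
  if (pair$n < 3) stop("Pearson correlation needs n >= 3", call. = FALSE)
  if (sd(pair$m1) == 0 || sd(pair$m2) == 0) {
    stop("correlation undefined for a constant measurement vector",
         call. = FALSE)
  }
  ct <- cor.test(pair$m1, pair$m2, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = pair$n)
}

#' Full test-retest report
#'
#' Assembles the summary (mean +/- SD per measurement), the paired t-test,
#' the Pearson correlation and the Bland-Altman limits of agreement. The
#' 0.05 significance threshold is recorded as metadata only; no data are
#' dropped. Degenerate inputs (identical vectors) yield flagged components
#' rather than forced values.
#'
#' @param pair a [repeat_pair()].
#' @return a `repeat_report`.
#' @export
repeat_report <- function(pair) {
  pair <- as_repeat_pair(pair)
  pr <- if (all(pair$m1 == pair$m2)) {
    # identical measurement vectors: the correlation of a variable with
    # itself is vacuous, flag rather than report r = 1
    list(r = NA_real_, p_value = NA_real_, n = pair$n,
         undefined = "identical measurements (zero difference variance)")
  } else {
    tryCatch(pearson_r(pair), error = function(e) {
      list(r = NA_real_, p_value = NA_real_, n = pair$n,
           undefined = conditionMessage(e))
    })
  }
  structure(list(metric_name = pair$metric_name, n = pair$n,
                 mean1 = mean(pair$m1), sd1 = sd(pair$m1),
                 mean2 = mean(pair$m2), sd2 = sd(pair$m2),
                 paired_t = paired_t(pair), pearson = pr,
                 bland_altman = bland_altman(pair),
                 alpha = 0.05),
            class = "repeat_report")
}

#' @export
print.repeat_report <- function(x, ...) {
  cat("Test-retest repeatability:", x$metric_name, "(n =", x$n, "eyes)\n")
  cat(sprintf("  measurement 1: %.4g +/- %.4g\n", x$mean1, x$sd1))
  cat(sprintf("  measurement 2: %.4g +/- %.4g\n", x$mean2, x$sd2))
  if (x$paired_t$degenerate) {
    cat("  paired t: degenerate (zero difference variance)\n")
  } else {
    cat(sprintf("  paired t: t = %.3f, df = %d, p = %.3g\n",
                x$paired_t$statistic, as.integer(x$paired_t$df),
                x$paired_t$p_value))
  }
  if (is.na(x$pearson$r)) {
    cat("  Pearson r: undefined (constant vector)\n")
  } else {
    cat(sprintf("  Pearson r = %.3f, p = %.3g\n", x$pearson$r,
                x$pearson$p_value))
  }
  ba <- x$bland_altman
  cat(sprintf("  Bland-Altman: bias %.4g, LoA [%.4g, %.4g]\n",
              ba$bias, ba$loa_lower, ba$loa_upper))
  invisible(x)
}
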