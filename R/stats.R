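#' Bland-Altman agreement against ground truth
#'
#' Computes the systematic bias (mean of measured minus truth) and the 95%
#' limits of agreement `bias +/- 1.96 * SD(differences)` (sample SD).
#' Variability of a measurement method is summarised by the distance between
#' the limits of agreement, `2 * 1.96 * SD(differences)`. The truth may be
#' repeated across measurements (e.g. 27 jittered measurements of a scan all
#' share the scan's one ground-truth noise level); all points are pooled.
#'
#' @param measured Numeric vector of measured values.
#' @param truth Numeric vector of reference values, same length.
#' @return A `bland_altman` object with `bias`, `loa_low`, `loa_high`,
#'   `loa_distance`, `sd_diff`, `n` and the per-point `data` tibble.
#' @seealso [glance.bland_altman()], [autoplot.bland_altman()]
#' @export
bland_altman <- function(measured, truth) {
  if (length(measured) != length(truth)) {
    abort("`measured` and `truth` must have equal length.",
          class = "voinoise_invalid_parameter")
  }
  keep <- is.finite(measured) & is.finite(truth)
  measured <- measured[keep]; truth <- truth[keep]
  n <- length(measured)
  if (n < 2L) {
    abort("Bland-Altman analysis needs at least 2 valid pairs.",
          class = "voinoise_undefined_error")
  }
  d <- measured - truth
  bias <- mean(d)
  s <- sd(d)
  structure(list(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, loa_distance = 2 * 1.96 * s,
                 sd_diff = s, n = n,
                 data = tibble(measured = measured, truth = truth, diff = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d: bias %.3f HU, LoA [%.3f, %.3f], distance %.3f HU\n",
              x$n, x$bias, x$loa_low, x$loa_high, x$loa_distance))
  invisible(x)
}

#' @rdname bland_altman
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @method glance bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble(bias = x$bias, loa_low = x$loa_low, loa_high = x$loa_high,
         loa_distance = x$loa_distance, sd_diff = x$sd_diff, n = x$n)
}

#' @rdname bland_altman
#' @method tidy bland_altman
#' @export
tidy.bland_altman <- function(x, ...) glance.bland_altman(x)

#' Levene's test for equal variability of two methods
#'
#' Classic (mean-centered) Levene's test on two groups: each observation is
#' replaced by its absolute deviation from its group mean and a one-way
#' ANOVA F-test is applied. Because the distance between Bland-Altman limits
#' of agreement is proportional to the SD of the differences, this is the
#' appropriate test for comparing the variability of two measurement
#' methods.
#'
#' @param diffs_a,diffs_b Numeric vectors (e.g. measured-minus-truth
#'   differences per method), each of length >= 2.
#' @return An object of class `htest` with the F statistic, degrees of
#'   freedom and two-sided p-value. When both groups are constant the
#'   statistic is 0 and p = 1 by convention.
#' @export
levene_variability_test <- function(diffs_a, diffs_b) {
  a <- diffs_a[is.finite(diffs_a)]
  b <- diffs_b[is.finite(diffs_b)]
  if (length(a) < 2L || length(b) < 2L) {
    abort("Each group needs at least 2 values.",
          class = "voinoise_undefined_error")
  }
  za <- abs(a - mean(a))
  zb <- abs(b - mean(b))
  na <- length(za); nb <- length(zb); N <- na + nb
  zbar <- (sum(za) + sum(zb)) / N
  ssb <- na * (mean(za) - zbar)^2 + nb * (mean(zb) - zbar)^2
  ssw <- sum((za - mean(za))^2) + sum((zb - mean(zb))^2)
  df1 <- 1L; df2 <- N - 2L
  if (ssw == 0 && ssb == 0) {
    stat <- 0; p <- 1
  } else if (ssw == 0) {
    stat <- Inf; p <- 0
  } else {
    stat <- (ssb / df1) / (ssw / df2)
    p <- pf(stat, df1, df2, lower.tail = FALSE)
  }
  structure(list(statistic = c(F = stat), parameter = c(df1 = df1, df2 = df2),
                 p.value = p,
                 method = "Levene's test for homogeneity of variance (mean-centered)",
                 data.name = paste(deparse(substitute(diffs_a)), "and",
                                   deparse(substitute(diffs_b)))),
            class = "htest")
}

#' Wilcoxon signed-rank test for a difference in bias
#'
#' Paired signed-rank test on per-position differences between two methods
#' (pairs with zero difference are dropped by the usual Wilcoxon
#' convention). The p-value is exact for n <= 25 without ties in the
#' absolute differences, otherwise a normal approximation with tie
#' correction is used (no continuity correction).
#'
#' @param diffs_a,diffs_b Numeric vectors paired per measurement position.
#' @param alternative One of "two.sided", "greater", "less" (of `a - b`).
#' @return An object of class `htest` with the signed-rank statistic `V`
#'   (sum of ranks of positive differences) and p-value.
#' @export
wilcoxon_bias_test <- function(diffs_a, diffs_b,
                               alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(diffs_a) != length(diffs_b)) {
    abort("Paired vectors must have equal length.",
          class = "voinoise_invalid_parameter")
  }
  d <- diffs_a - diffs_b
  d <- d[is.finite(d) & d != 0]
  n <- length(d)
  if (n < 1L) {
    abort("No nonzero paired differences; signed-rank test undefined.",
          class = "voinoise_undefined_error")
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- length(unique(abs(d))) != n
  exact <- n <= 25L && !ties
  mu <- n * (n + 1) / 4
  if (exact) {
    p <- switch(alternative,
      two.sided = {
        pv <- if (V > mu) 2 * psignrank(V - 1, n, lower.tail = FALSE)
              else 2 * psignrank(V, n)
        min(1, pv)
      },
      greater = psignrank(V - 1, n, lower.tail = FALSE),
      less = psignrank(V, n))
  } else {
    tt <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tt^3 - tt) / 48
    z <- (V - mu) / sqrt(sigma2)
    p <- switch(alternative,
                two.sided = 2 * pnorm(-abs(z)),
                greater = pnorm(z, lower.tail = FALSE),
                less = pnorm(z))
    p <- min(1, p)
  }
  structure(list(statistic = c(V = V), p.value = p,
                 parameter = c(n = n),
                 alternative = alternative,
                 method = if (exact) "Wilcoxon signed-rank test (exact)"
                          else "Wilcoxon signed-rank test (normal approximation, tie-corrected)",
                 data.name = paste(deparse(substitute(diffs_a)), "and",
                                   deparse(substitute(diffs_b)))),
            class = "htest")
}

#' Compare ROI- and VOI-based noise measurement
#'
#' Given position-paired measured-minus-truth differences for the circular
#' ROI and the spherical VOI, runs Levene's test on the variability and the
#' Wilcoxon signed-rank test on the bias.
#'
#' @param diffs_circle,diffs_sphere Numeric vectors of differences to truth,
#'   paired by measurement position (kept positions only; the containment
#'   rule guarantees the pairing).
#' @return A `method_comparison` object: list with `levene` and `wilcoxon`
#'   `htest` objects.
#' @export
compare_methods <- function(diffs_circle, diffs_sphere) {
  structure(list(
    levene = levene_variability_test(diffs_circle, diffs_sphere),
    wilcoxon = wilcoxon_bias_test(diffs_circle, diffs_sphere)),
    class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("<method_comparison> Levene F = %.3f (p = %.3g); Wilcoxon V = %g (p = %.3g)\n",
              x$levene$statistic, x$levene$p.value,
              x$wilcoxon$statistic, x$wilcoxon$p.value))
  invisible(x)
}
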