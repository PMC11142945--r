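#' Bland–Altman agreement analysis
#'
#' Differences are oriented `d = a - b` (in the validation use, a = native,
#' b = corrected arterial). Reports the mean difference with a t-based
#' confidence interval, the limits of agreement `mean(d) +/- 1.96 sd(d)` with
#' their confidence intervals (standard error `sd * sqrt(1/n + z^2 / (2(n-1)))`),
#' and the one-sample t-test p-value for H0: mean difference = 0. With zero
#' difference variance the test is degenerate; the p-value is reported as NA
#' with a note.
#'
#' @param a,b paired numeric vectors, n >= 3.
#' @param conf_level confidence level (default 0.95).
#' @return Object of class `paft_bland_altman`.
#' @export
bland_altman <- function(a, b, conf_level = 0.95) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 3L) stop("at least 3 pairs required", call. = FALSE)
  d <- a - b
  md <- mean(d)
  s <- stats::sd(d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
  se_mean <- s / sqrt(n)
  se_loa <- s * sqrt(1 / n + z^2 / (2 * (n - 1)))
  loa_low <- md - z * s
  loa_high <- md + z * s
  if (s == 0) {
    p <- NA_real_
    note <- "zero difference variance; H0 test degenerate (perfect agreement)"
  } else {
    p <- stats::t.test(d, mu = 0)$p.value
    note <- NA_character_
  }
  structure(
    list(
      mean_diff = md,
      mean_diff_ci = c(md - tcrit * se_mean, md + tcrit * se_mean),
      sd_diff = s,
      loa_low = loa_low,
      loa_low_ci = c(loa_low - tcrit * se_loa, loa_low + tcrit * se_loa),
      loa_high = loa_high,
      loa_high_ci = c(loa_high - tcrit * se_loa, loa_high + tcrit * se_loa),
      h0_p = p, note = note, n = n, conf_level = conf_level,
      data = tibble::tibble(mean = (a + b) / 2, diff = d)
    ),
    class = "paft_bland_altman"
  )
}

#' @export
print.paft_bland_altman <- function(x, ...) {
  cat(sprintf(
    "<paft_bland_altman> n = %d\n  mean difference %.4g [%.4g, %.4g], H0 p = %.4g\n  limits of agreement [%.4g, %.4g]\n",
    x$n, x$mean_diff, x$mean_diff_ci[1], x$mean_diff_ci[2], x$h0_p,
    x$loa_low, x$loa_high
  ))
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Passing–Bablok regression
#'
#' Non-parametric method-comparison regression. All pairwise slopes
#' `S_ij = (b_j - b_i) / (a_j - a_i)` for i < j are formed; slopes of exactly
#' −1 are discarded and identical points contribute none. With
#' `K = #\{S_ij < -1\}`, the slope estimate is the K-shifted median of the
#' sorted slopes, which makes the estimate invariant to swapping the two
#' methods (the swapped slope is the exact reciprocal for tie-free data).
#' The confidence interval is rank-based with the normal quantile
#' `w = z * sqrt(n (n-1) (2n+5) / 18)`, and the intercept is
#' `median(b - slope * a)` with its CI evaluated at the slope CI endpoints.
#'
#' @param a,b paired numeric vectors (method 1 and method 2).
#' @param conf_level confidence level (default 0.95).
#' @return Object of class `paft_passing_bablok` with slope and intercept
#'   estimates and CIs.
#' @export
passing_bablok <- function(a, b, conf_level = 0.95) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 3L) stop("at least 3 pairs required", call. = FALSE)
  ij <- utils::combn(n, 2)
  da <- a[ij[2, ]] - a[ij[1, ]]
  db <- b[ij[2, ]] - b[ij[1, ]]
  degenerate <- da == 0 & db == 0
  if (any(degenerate)) {
    if (sum(degenerate) > length(da) / 2) {
      bad <- paste(ij[1, degenerate], ij[2, degenerate], sep = "-", collapse = ", ")
      stop("too many identical point pairs for Passing-Bablok regression: ", bad,
           call. = FALSE)
    }
  }
  slopes <- ifelse(da == 0, sign(db) * Inf, db / da)
  slopes <- slopes[!degenerate & slopes != -1]
  if (length(slopes) == 0L) stop("no valid pairwise slopes", call. = FALSE)
  s <- sort(slopes)
  N <- length(s)
  K <- sum(s < -1)
  # shifted median
  if (N %% 2 == 1) {
    slope <- s[(N + 1) / 2 + K]
  } else {
    slope <- mean(s[N / 2 + K + c(0L, 1L)])
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  w <- z * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  M1 <- round((N - w) / 2)
  M2 <- N - M1 + 1
  slope_ci <- c(
    if (M1 + K >= 1 && M1 + K <= N) s[M1 + K] else -Inf,
    if (M2 + K >= 1 && M2 + K <= N) s[M2 + K] else Inf
  )
  intercept <- stats::median(b - slope * a)
  intercept_ci <- sort(c(
    stats::median(b - slope_ci[2] * a),
    stats::median(b - slope_ci[1] * a)
  ))
  structure(
    list(slope = slope, slope_ci = slope_ci,
         intercept = intercept, intercept_ci = intercept_ci,
         n = n, conf_level = conf_level,
         data = tibble::tibble(a = a, b = b)),
    class = "paft_passing_bablok"
  )
}

#' @export
print.paft_passing_bablok <- function(x, ...) {
  cat(sprintf(
    "<paft_passing_bablok> n = %d\n  slope %.4g [%.4g, %.4g]\n  intercept %.4g [%.4g, %.4g]\n",
    x$n, x$slope, x$slope_ci[1], x$slope_ci[2],
    x$intercept, x$intercept_ci[1], x$intercept_ci[2]
  ))
  invisible(x)
}

#' Cusum test for deviation from linearity
#'
#' Companion test to Passing–Bablok regression: points are scored by the side
#' of the fitted line they fall on (`+sqrt(L/l)` above, `-sqrt(l/L)` below,
#' with l/L the counts above/below), ordered along the fitted line by
#' `a + b/slope`, and cumulatively summed. The maximum absolute cusum,
#' normalised by `sqrt(L + l + 1)`, is referred to the Kolmogorov–Smirnov
#' distribution to obtain the p-value. Data lying exactly on the line give no
#' deviations and p = 1.
#'
#' @param fit a `paft_passing_bablok` object.
#' @return One-row tibble: `statistic` (normalised max cusum), `p_value`.
#' @export
cusum_linearity <- function(fit) {
  stopifnot(inherits(fit, "paft_passing_bablok"))
  a <- fit$data$a; b <- fit$data$b
  resid <- b - (fit$intercept + fit$slope * a)
  above <- resid > 0
  below <- resid < 0
  l <- sum(above); L <- sum(below)
  if (l == 0 || L == 0) {
    return(tibble::tibble(statistic = 0, p_value = 1))
  }
  score <- numeric(length(a))
  score[above] <- sqrt(L / l)
  score[below] <- -sqrt(l / L)
  # rank points along the fitted line
  dist <- a + b / fit$slope
  cs <- cumsum(score[order(dist)])
  lambda <- max(abs(cs)) / sqrt(L + l + 1)
  # two-sided Kolmogorov tail probability
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  p <- min(max(p, 0), 1)
  tibble::tibble(statistic = lambda, p_value = p)
}

#' Mann–Whitney (Wilcoxon rank-sum) group comparison
#'
#' Two-sided test: exact for 20 or fewer pooled observations without ties,
#' normal approximation with tie correction otherwise. Group medians are
#' reported alongside.
#'
#' @param g1,g2 numeric vectors for the two independent groups.
#' @return One-row tibble: `U`, `p_value`, `median_g1`, `median_g2`, `exact`.
#' @export
mann_whitney <- function(g1, g2) {
  if (length(g1) == 0L || length(g2) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  pooled_n <- length(g1) + length(g2)
  has_ties <- anyDuplicated(c(g1, g2)) > 0
  exact <- pooled_n <= 20 && !has_ties
  wt <- suppressWarnings(
    stats::wilcox.test(g1, g2, exact = exact, correct = !exact,
                       alternative = "two.sided")
  )
  tibble::tibble(
    U = unname(wt$statistic),
    p_value = wt$p.value,
    median_g1 = stats::median(g1),
    median_g2 = stats::median(g2),
    exact = exact
  )
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measures ICC computed
#' from the two-way ANOVA mean squares
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`, with the F-based
#' confidence interval of McGraw & Wong (Satterthwaite degrees of freedom for
#' the column term).
#'
#' @param ratings numeric matrix, subjects in rows, raters (or sessions) in
#'   columns; at least 5 subjects and 2 raters.
#' @param conf_level confidence level (default 0.95).
#' @return One-row tibble: `icc`, `conf_low`, `conf_high`, `n_subjects`,
#'   `n_raters`.
#' @export
icc <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (k < 2L) stop("at least 2 raters required", call. = FALSE)
  if (n < 5L) stop("at least 5 subjects required", call. = FALSE)
  if (stats::sd(as.numeric(ratings)) == 0) {
    stop("constant ratings; ICC undefined", call. = FALSE)
  }
  grand <- mean(ratings)
  row_means <- rowMeans(ratings)
  col_means <- colMeans(ratings)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((ratings - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc_val <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  if (mse <= 1e-12 * msr && msc <= 1e-12 * msr) {
    # raters agree exactly: ICC is 1 with a degenerate interval
    return(tibble::tibble(icc = 1, conf_low = 1, conf_high = 1,
                          n_subjects = n, n_raters = k))
  }
  alpha <- 1 - conf_level
  # McGraw & Wong F-based interval for ICC(A,1)
  a <- k * icc_val / (n * (1 - icc_val))
  bb <- 1 + k * icc_val * (n - 1) / (n * (1 - icc_val))
  v <- (a * msc + bb * mse)^2 /
    ((a * msc)^2 / (k - 1) + (bb * mse)^2 / ((n - 1) * (k - 1)))
  f_up <- stats::qf(1 - alpha / 2, n - 1, v)
  f_lo <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_up * mse) /
    (f_up * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_lo * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_lo * msr)
  tibble::tibble(
    icc = icc_val, conf_low = lower, conf_high = upper,
    n_subjects = n, n_raters = k
  )
}
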