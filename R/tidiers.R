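#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a derivation result
#'
#' One row per endpoint/statistic combination (Pearson correlation and
#' through-origin regression slope for volume and mean HU).
#'
#' @param x a `paft_derivation`.
#' @param ... unused.
#' @return Tibble: `endpoint`, `statistic`, `estimate`, `conf_low`,
#'   `conf_high`, `p_value`.
#' @export
tidy.paft_derivation <- function(x, ...) {
  row <- function(endpoint, statistic, est, lo, hi, p) {
    tibble::tibble(endpoint = endpoint, statistic = statistic, estimate = est,
                   conf_low = lo, conf_high = hi, p_value = p)
  }
  dplyr::bind_rows(
    row("volume", "pearson_r", x$volume$pearson$r, x$volume$pearson$conf_low,
        x$volume$pearson$conf_high, x$volume$pearson$p_value),
    row("volume", "slope_through_origin", x$volume$regression$slope,
        x$volume$regression$conf_low, x$volume$regression$conf_high,
        x$volume$regression$p_value),
    row("meanHU", "pearson_r", x$meanHU$pearson$r, x$meanHU$pearson$conf_low,
        x$meanHU$pearson$conf_high, x$meanHU$pearson$p_value),
    row("meanHU", "slope_through_origin", x$meanHU$regression$slope,
        x$meanHU$regression$conf_low, x$meanHU$regression$conf_high,
        x$meanHU$regression$p_value)
  )
}

#' @rdname tidy.paft_derivation
#' @export
glance.paft_derivation <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    volume_factor = x$volume_factor,
    hu_factor = x$hu_factor,
    volume_r = x$volume$pearson$r,
    meanHU_r = x$meanHU$pearson$r,
    volume_screen_r2 = if (!is.null(x$screens)) x$screens$volume$r_squared else NA_real_,
    meanHU_screen_r2 = if (!is.null(x$screens)) x$screens$meanHU$r_squared else NA_real_
  )
}

#' Tidy a validation result
#'
#' @param x a `paft_validation`.
#' @param ... unused.
#' @return Tibble with one row per endpoint/statistic: Bland–Altman mean
#'   difference and limits of agreement, Passing–Bablok slope and intercept,
#'   Cusum and Spearman.
#' @export
tidy.paft_validation <- function(x, ...) {
  one <- function(endpoint, e) {
    ba <- e$bland_altman; pb <- e$passing_bablok
    tibble::tibble(
      endpoint = endpoint,
      statistic = c("ba_mean_diff", "ba_loa_low", "ba_loa_high",
                    "pb_slope", "pb_intercept", "cusum_p", "spearman_rho"),
      estimate = c(ba$mean_diff, ba$loa_low, ba$loa_high,
                   pb$slope, pb$intercept, e$cusum$p_value, e$spearman$rho),
      conf_low = c(ba$mean_diff_ci[1], ba$loa_low_ci[1], ba$loa_high_ci[1],
                   pb$slope_ci[1], pb$intercept_ci[1], NA, NA),
      conf_high = c(ba$mean_diff_ci[2], ba$loa_low_ci[2], ba$loa_high_ci[2],
                    pb$slope_ci[2], pb$intercept_ci[2], NA, NA),
      p_value = c(ba$h0_p, NA, NA, NA, NA, e$cusum$p_value, e$spearman$p_value)
    )
  }
  dplyr::bind_rows(one("volume", x$volume), one("meanHU", x$meanHU))
}

#' @rdname tidy.paft_validation
#' @export
glance.paft_validation <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_excluded = x$n_excluded,
    volume_mean_diff = x$volume$bland_altman$mean_diff,
    volume_h0_p = x$volume$bland_altman$h0_p,
    volume_pb_slope = x$volume$passing_bablok$slope,
    meanHU_mean_diff = x$meanHU$bland_altman$mean_diff,
    meanHU_h0_p = x$meanHU$bland_altman$h0_p,
    meanHU_pb_slope = x$meanHU$passing_bablok$slope
  )
}

#' Tidy a Bland–Altman analysis
#' @param x a `paft_bland_altman`.
#' @param ... unused.
#' @return Tibble with mean difference and limits of agreement rows.
#' @export
tidy.paft_bland_altman <- function(x, ...) {
  tibble::tibble(
    statistic = c("mean_diff", "loa_low", "loa_high"),
    estimate = c(x$mean_diff, x$loa_low, x$loa_high),
    conf_low = c(x$mean_diff_ci[1], x$loa_low_ci[1], x$loa_high_ci[1]),
    conf_high = c(x$mean_diff_ci[2], x$loa_low_ci[2], x$loa_high_ci[2])
  )
}

#' Tidy a Passing–Bablok fit
#' @param x a `paft_passing_bablok`.
#' @param ... unused.
#' @return Tibble with slope and intercept rows.
#' @export
tidy.paft_passing_bablok <- function(x, ...) {
  tibble::tibble(
    term = c("slope", "intercept"),
    estimate = c(x$slope, x$intercept),
    conf_low = c(x$slope_ci[1], x$intercept_ci[1]),
    conf_high = c(x$slope_ci[2], x$intercept_ci[2])
  )
}
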