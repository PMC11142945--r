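#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @param conf_level confidence level (default 0.95).
#' @return One-row tibble: `r`, `conf_low`, `conf_high`, `p_value`, `n`.
#' @export
pearson_ci <- function(x, y, conf_level = 0.95) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("at least 3 pairs required", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y; correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = conf_level)
  tibble::tibble(
    r = unname(ct$estimate),
    conf_low = ct$conf.int[1],
    conf_high = ct$conf.int[2],
    p_value = ct$p.value,
    n = length(x)
  )
}

#' Linear regression through the origin
#'
#' Fits `y = slope * x` with no intercept: `slope = sum(x*y) / sum(x^2)`,
#' standard no-intercept standard error on `n - 1` residual degrees of
#' freedom, t statistic and t-based confidence interval. The no-intercept R²
#' is reported but is not comparable to R² from models with an intercept.
#'
#' @param x,y paired numeric vectors (x = arterial value, y = native value in
#'   the derivation use).
#' @param conf_level confidence level (default 0.95).
#' @return One-row tibble: `slope`, `conf_low`, `conf_high`, `se`,
#'   `t_statistic`, `p_value`, `r_squared`, `n`.
#' @export
regress_through_origin <- function(x, y, conf_level = 0.95) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2L) stop("at least 2 pairs required", call. = FALSE)
  if (all(x == 0)) stop("all x are zero; slope undefined", call. = FALSE)
  fit <- stats::lm(y ~ 0 + x)
  sm <- summary(fit)
  ci <- stats::confint(fit, level = conf_level)
  tibble::tibble(
    slope = unname(stats::coef(fit)[1]),
    conf_low = ci[1, 1],
    conf_high = ci[1, 2],
    se = sm$coefficients[1, 2],
    t_statistic = sm$coefficients[1, 3],
    p_value = sm$coefficients[1, 4],
    r_squared = sm$r.squared,
    n = length(x)
  )
}

#' Multivariate confounder screen
#'
#' Ordinary least squares with the native value as dependent variable and the
#' arterial value plus all candidate confounders as independents, fitted as a
#' single full model. Each covariate is flagged when its p-value is below
#' `alpha`. Perfectly collinear covariates (rank deficiency) are dropped with
#' a warning and reported with `dropped = TRUE`.
#'
#' @param data data frame with one row per study.
#' @param response name of the native-value column.
#' @param predictor name of the arterial-value column.
#' @param covariates character vector of candidate confounder columns.
#' @param alpha significance threshold for flagging (default 0.05).
#' @return Object of class `paft_confounder_screen`: list with `terms` (tibble
#'   of term, estimate, se, p_value, flagged, dropped), `r_squared`,
#'   `adj_r_squared`, `n`, and the fitted `model`.
#' @export
screen_confounders <- function(data, response, predictor, covariates,
                               alpha = 0.05) {
  stopifnot(is.data.frame(data))
  vars <- c(response, predictor, covariates)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(data) < length(vars) + 2L) {
    stop("too few studies for a stable multivariate screen", call. = FALSE)
  }
  form <- stats::reformulate(c(predictor, covariates), response = response)
  fit <- stats::lm(form, data = data)
  aliased <- names(which(summary(fit)$aliased))
  dropped <- character(0)
  if (length(aliased) > 0) {
    dropped <- aliased
    warning("dropping perfectly collinear covariate(s): ",
            paste(aliased, collapse = ", "), call. = FALSE)
    keep <- setdiff(c(predictor, covariates), aliased)
    fit <- stats::lm(stats::reformulate(keep, response = response), data = data)
  }
  sm <- summary(fit)
  coefs <- sm$coefficients
  terms_tbl <- tibble::tibble(
    term = rownames(coefs),
    estimate = coefs[, 1],
    se = coefs[, 2],
    p_value = coefs[, 4],
    flagged = coefs[, 4] < alpha,
    dropped = FALSE
  )
  if (length(dropped) > 0) {
    terms_tbl <- dplyr::bind_rows(
      terms_tbl,
      tibble::tibble(term = dropped, estimate = NA_real_, se = NA_real_,
                     p_value = NA_real_, flagged = FALSE, dropped = TRUE)
    )
  }
  structure(
    list(terms = terms_tbl, r_squared = sm$r.squared,
         adj_r_squared = sm$adj.r.squared, n = nrow(data), model = fit,
         response = response, predictor = predictor, alpha = alpha),
    class = "paft_confounder_screen"
  )
}

#' @export
print.paft_confounder_screen <- function(x, ...) {
  cat(sprintf("<paft_confounder_screen> n = %d, R^2 = %.4f\n", x$n, x$r_squared))
  print(x$terms)
  invisible(x)
}

#' Apply an arterial-to-native conversion factor
#'
#' Corrected value = `factor * arterial_value`. The derivation-study defaults
#' are 1.1057 for PaFT volume and 1.0011 for PaFT mean HU.
#'
#' @param arterial_value numeric vector of arterial-phase measurements.
#' @param factor positive multiplicative conversion factor.
#' @return Corrected values.
#' @export
apply_correction <- function(arterial_value, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) || factor <= 0) {
    stop("conversion factor must be a single positive number", call. = FALSE)
  }
  factor * arterial_value
}
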