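#' Pipeline configuration
#'
#' Collects every tunable of the measurement workflow with its standard
#' default: the adipose HU window (−195 to −45 HU), the 5 mm periaortic ring
#' width, the 8 mm intraluminal sample ROI, the SD > 35 HU arterial noise
#' exclusion, the 130 HU calcium detection threshold, and the
#' arterial-to-native conversion factors (1.1057 for volume, 1.0011 for mean
#' HU).
#'
#' @param hu_window fat window `c(low, high)` in HU, strictly increasing.
#' @param ring_margin_mm periaortic ring width, mm.
#' @param sample_roi_mm intraluminal sample ROI diameter, mm (8, 10 or 12).
#' @param noise_sd_cutoff arterial intraluminal SD exclusion cutoff, HU.
#' @param agatston_threshold calcium detection threshold, HU.
#' @param volume_factor,hu_factor conversion factors applied to arterial
#'   values in validation.
#' @return A `paft_config` list.
#' @export
paft_config <- function(hu_window = c(-195, -45),
                        ring_margin_mm = 5,
                        sample_roi_mm = 8,
                        noise_sd_cutoff = 35,
                        agatston_threshold = 130,
                        volume_factor = 1.1057,
                        hu_factor = 1.0011) {
  if (length(hu_window) != 2L || hu_window[1] >= hu_window[2]) {
    stop("hu_window must be c(low, high) with low < high", call. = FALSE)
  }
  stopifnot(ring_margin_mm > 0, sample_roi_mm > 0, noise_sd_cutoff > 0,
            volume_factor > 0, hu_factor > 0)
  structure(as.list(environment()), class = "paft_config")
}

#' Quantify one paired study end-to-end
#'
#' Builds the ROI masks once from the native-series aortic contours, applies
#' them to both phases, and assembles the full per-study record: volumes and
#' fat metrics for both phases, the native intraluminal fat-voxel audit, the
#' arterial contrast profile (sample-ROI means, longitudinal variability,
#' noise exclusion flag) and the native calcification score.
#'
#' @param pair a [pair_phases()] result.
#' @param aortic_rois aortic ROI tibble (operator- or phantom-supplied).
#' @param config a [paft_config()].
#' @return One-row wide tibble (see column names in the vignette).
#' @export
run_quantify <- function(pair, aortic_rois, config = paft_config()) {
  stopifnot(inherits(pair, "ct_study_pair"), inherits(config, "paft_config"))
  rois <- build_roi_masks(pair$native, aortic_rois, config$ring_margin_mm)
  met_n <- paft_metrics(pair$native, rois, config$hu_window)
  met_a <- paft_metrics(pair$arterial, rois, config$hu_window)
  qc <- contrast_profile(pair$arterial, aortic_rois, config$sample_roi_mm)
  calc <- agatston_score(pair$native, rois$periaortic_mask,
                         config$agatston_threshold)
  tibble::tibble(
    AVol = met_n$AVol,
    PaVol = met_n$PaVol,
    PaRVol = met_n$PaRVol,
    native_PaFTVol = met_n$PaFTVol,
    arterial_PaFTVol = met_a$PaFTVol,
    native_ratio = met_n$PaFT_ratio,
    arterial_ratio = met_a$PaFT_ratio,
    native_meanHU = met_n$PaFT_meanHU,
    arterial_meanHU = met_a$PaFT_meanHU,
    native_sdHU = met_n$PaFT_sdHU,
    arterial_sdHU = met_a$PaFT_sdHU,
    intraluminal_fat_voxels = audit_intraluminal_fat_voxels(
      pair$native, rois$aortic_mask, config$hu_window),
    max_diameter = measure_max_diameter(aortic_rois),
    mean_contrast = qc$mean_contrast,
    arterial_sd = qc$intraluminal_sd,
    longitudinal_variability = qc$longitudinal_variability,
    agatston = calc$agatston,
    excluded = noise_exclude(qc$intraluminal_sd, config$noise_sd_cutoff)
  )
}

#' Generate and quantify a synthetic cohort
#'
#' Runs the full measurement pipeline over every study drawn by
#' [generate_cohort_specs()]: phantom generation, ROI construction, fat
#' segmentation, volume reconstruction, contrast QC and calcium scoring.
#'
#' @param specs tibble from [generate_cohort_specs()] (or `n`/`seed` to draw
#'   one internally).
#' @param config a [paft_config()].
#' @param ... passed to [generate_cohort_specs()] when `specs` is a count.
#' @return Cohort tibble: one row per study, cohort-spec columns (`kv`,
#'   `slice_thickness`, `true_ratio`, ...) joined with the measured record.
#' @export
quantify_cohort <- function(specs, config = paft_config(), ...) {
  if (is.numeric(specs) && length(specs) == 1L) {
    specs <- generate_cohort_specs(specs, ...)
  }
  rows <- purrr::map(seq_len(nrow(specs)), function(i) {
    row <- specs[i, ]
    study <- generate_phantom_pair(cohort_row_spec(row))
    pair <- pair_phases(study$native, study$arterial)
    meas <- run_quantify(pair, study$aortic_rois, config)
    dplyr::bind_cols(
      row[, c("study_id", "is_aaa", "kv", "slice_thickness", "fat_fraction",
              "true_ratio")],
      meas
    )
  })
  dplyr::bind_rows(rows)
}

# the candidate confounders screened in the derivation analysis
DERIVATION_COVARIATES <- c(
  "agatston", "mean_contrast", "max_diameter", "slice_thickness", "kv",
  "arterial_sd", "longitudinal_variability"
)

#' Derivation-study analysis: conversion factors
#'
#' On a quantified paired cohort, computes for both PaFT volume and PaFT mean
#' HU: the Pearson correlation between phases (Fisher-z CI), the regression
#' through the origin of the native on the arterial value (whose slope is the
#' conversion factor), and the multivariate confounder screen over
#' calcification, contrast intensity, maximum diameter, slice thickness,
#' tube voltage, image noise and longitudinal variability.
#'
#' @param cohort cohort tibble from [quantify_cohort()] (or any tibble with
#'   the same measurement columns).
#' @param exclude_large_aaa_mm if non-`NULL`, drop studies with maximum
#'   diameter above this value (sensitivity analysis excluding large
#'   aneurysms, e.g. 55).
#' @param screen run the confounder screen (needs the covariate columns).
#' @return Object of class `paft_derivation`.
#' @export
run_derivation <- function(cohort, exclude_large_aaa_mm = NULL, screen = TRUE) {
  stopifnot(is.data.frame(cohort))
  if (!is.null(exclude_large_aaa_mm)) {
    cohort <- dplyr::filter(cohort, .data$max_diameter <= exclude_large_aaa_mm)
  }
  vol <- list(
    pearson = pearson_ci(cohort$arterial_PaFTVol, cohort$native_PaFTVol),
    regression = regress_through_origin(cohort$arterial_PaFTVol,
                                        cohort$native_PaFTVol)
  )
  hu <- list(
    pearson = pearson_ci(cohort$arterial_meanHU, cohort$native_meanHU),
    regression = regress_through_origin(cohort$arterial_meanHU,
                                        cohort$native_meanHU)
  )
  screens <- NULL
  if (screen && all(DERIVATION_COVARIATES %in% names(cohort))) {
    screens <- list(
      volume = screen_confounders(cohort, "native_PaFTVol", "arterial_PaFTVol",
                                  DERIVATION_COVARIATES),
      meanHU = screen_confounders(cohort, "native_meanHU", "arterial_meanHU",
                                  DERIVATION_COVARIATES)
    )
  }
  structure(
    list(
      volume = vol, meanHU = hu, screens = screens,
      volume_factor = vol$regression$slope,
      hu_factor = hu$regression$slope,
      n = nrow(cohort)
    ),
    class = "paft_derivation"
  )
}

#' @export
print.paft_derivation <- function(x, ...) {
  cat(sprintf("<paft_derivation> n = %d\n", x$n))
  cat(sprintf("  volume:  r = %.4f [%.4f, %.4f], factor = %.4f [%.4f, %.4f]\n",
              x$volume$pearson$r, x$volume$pearson$conf_low, x$volume$pearson$conf_high,
              x$volume$regression$slope, x$volume$regression$conf_low,
              x$volume$regression$conf_high))
  cat(sprintf("  mean HU: r = %.4f [%.4f, %.4f], factor = %.4f [%.4f, %.4f]\n",
              x$meanHU$pearson$r, x$meanHU$pearson$conf_low, x$meanHU$pearson$conf_high,
              x$meanHU$regression$slope, x$meanHU$regression$conf_low,
              x$meanHU$regression$conf_high))
  invisible(x)
}

#' Validation-study analysis: agreement after correction
#'
#' Applies the conversion factors to the arterial arm, removes studies failing
#' the arterial-noise exclusion rule, and assesses agreement between native
#' and corrected arterial values with Bland–Altman analysis, Passing–Bablok
#' regression with the Cusum linearity test and the Spearman correlation, for
#' both PaFT volume and PaFT mean HU. Differences are oriented native minus
#' corrected arterial.
#'
#' @param cohort cohort tibble from [quantify_cohort()].
#' @param config a [paft_config()] carrying the factors and the noise cutoff.
#' @return Object of class `paft_validation`: per-endpoint list with
#'   `bland_altman`, `passing_bablok`, `cusum`, `spearman`; plus counts of
#'   excluded studies.
#' @export
run_validation <- function(cohort, config = paft_config()) {
  stopifnot(is.data.frame(cohort), inherits(config, "paft_config"))
  if ("excluded" %in% names(cohort)) {
    n_excl <- sum(cohort$excluded)
    cohort <- dplyr::filter(cohort, !.data$excluded)
  } else {
    n_excl <- 0L
  }
  one <- function(native, corrected) {
    ba <- bland_altman(native, corrected)
    pb <- passing_bablok(corrected, native)
    sp <- suppressWarnings(
      stats::cor.test(native, corrected, method = "spearman"))
    list(bland_altman = ba, passing_bablok = pb,
         cusum = cusum_linearity(pb),
         spearman = tibble::tibble(rho = unname(sp$estimate), p_value = sp$p.value))
  }
  structure(
    list(
      volume = one(cohort$native_PaFTVol,
                   apply_correction(cohort$arterial_PaFTVol, config$volume_factor)),
      meanHU = one(cohort$native_meanHU,
                   apply_correction(cohort$arterial_meanHU, config$hu_factor)),
      n = nrow(cohort), n_excluded = n_excl,
      volume_factor = config$volume_factor, hu_factor = config$hu_factor
    ),
    class = "paft_validation"
  )
}

#' @export
print.paft_validation <- function(x, ...) {
  cat(sprintf("<paft_validation> n = %d (%d excluded by noise rule)\n",
              x$n, x$n_excluded))
  for (ep in c("volume", "meanHU")) {
    e <- x[[ep]]
    cat(sprintf(
      "  %s: mean diff %.4g [%.4g, %.4g] (H0 p = %.3g); PB slope %.4g [%.4g, %.4g]; Cusum p = %.3g\n",
      ep, e$bland_altman$mean_diff, e$bland_altman$mean_diff_ci[1],
      e$bland_altman$mean_diff_ci[2], e$bland_altman$h0_p,
      e$passing_bablok$slope, e$passing_bablok$slope_ci[1],
      e$passing_bablok$slope_ci[2], e$cusum$p_value
    ))
  }
  invisible(x)
}

#' Compare aneurysmal and non-aneurysmal groups
#'
#' Mann–Whitney comparison of a per-study measurement between the AAA and
#' non-AAA groups.
#'
#' @param cohort cohort tibble with an `is_aaa` column.
#' @param column name of the column to compare.
#' @return One-row tibble from [mann_whitney()] plus group sizes.
#' @export
compare_aaa_groups <- function(cohort, column = "native_ratio") {
  stopifnot(is.data.frame(cohort), "is_aaa" %in% names(cohort),
            column %in% names(cohort))
  g1 <- cohort[[column]][!cohort$is_aaa]
  g2 <- cohort[[column]][cohort$is_aaa]
  dplyr::bind_cols(
    mann_whitney(g1, g2),
    tibble::tibble(n_non_aaa = length(g1), n_aaa = length(g2))
  )
}
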