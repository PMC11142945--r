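#' Sample intraluminal attenuation at one aortic level
#'
#' Places a circular sample ROI of the requested diameter at the centre of
#' the aortic ellipse of the slice representing the named level (infrarenal =
#' first ROI slice, mid-aortic = middle, bifurcation = last) and returns the
#' mean and SD of the HU values inside the disc. If the disc does not fit
#' inside the aortic ellipse (small aorta), it is shrunk to fit with a
#' warning.
#'
#' @param vol a [ct_volume] (typically arterial phase).
#' @param aortic_rois aortic ROI tibble.
#' @param level `"infrarenal"`, `"mid"` or `"bifurcation"`.
#' @param diameter_mm sample ROI diameter in mm (the workflow uses 8, 10 or
#'   12).
#' @return One-row tibble: `level`, `diameter_mm` (after any shrink),
#'   `mean_hu`, `sd_hu`, `n_voxels`.
#' @export
sample_lumen <- function(vol, aortic_rois, level = c("infrarenal", "mid", "bifurcation"),
                         diameter_mm = 8) {
  level <- match.arg(level)
  check_roi_tbl(aortic_rois)
  rois <- aortic_rois[order(aortic_rois$slice), ]
  k <- switch(level,
    infrarenal = 1L,
    mid = as.integer(ceiling(nrow(rois) / 2)),
    bifurcation = nrow(rois)
  )
  r <- diameter_mm / 2
  rmax <- min(rois$a[k], rois$b[k])
  if (r > rmax) {
    warning(sprintf(
      "sample ROI (%g mm) does not fit inside the aortic lumen at the %s level; shrunk to %g mm",
      diameter_mm, level, 2 * rmax), call. = FALSE)
    r <- rmax
  }
  disc <- rasterize_ellipse(rois$cx[k], rois$cy[k], r, r, 0,
                            dim(vol$voxels)[1:2], vol$spacing_xy)
  hu <- vol$voxels[, , rois$slice[k]][disc]
  tibble::tibble(
    level = level, diameter_mm = 2 * r,
    mean_hu = mean(hu), sd_hu = stats::sd(hu), n_voxels = length(hu)
  )
}

#' Longitudinal intraluminal contrast variability
#'
#' `(max(level means) - min(level means)) / mean(level means)`, computed from
#' the intraluminal means sampled at the infrarenal, mid-aortic and
#' bifurcation levels. Dimensionless; 0 for perfectly even enhancement.
#'
#' @param level_means numeric vector of exactly three level means (HU).
#' @return Variability as a fraction.
#' @export
longitudinal_variability <- function(level_means) {
  if (length(level_means) != 3L || any(!is.finite(level_means))) {
    stop("exactly three finite level means are required", call. = FALSE)
  }
  m <- mean(level_means)
  if (m <= 0) stop("average contrast attenuation must be positive", call. = FALSE)
  (max(level_means) - min(level_means)) / m
}

#' Intraluminal contrast profile of one study
#'
#' Samples the lumen at the three longitudinal levels with one sample-ROI
#' diameter and assembles the per-study contrast QC record.
#'
#' @inheritParams sample_lumen
#' @return One-row tibble: `diameter_mm`, the three level means,
#'   `mean_contrast` (average of the three), `intraluminal_sd` (mean of the
#'   three level SDs), `longitudinal_variability`.
#' @export
contrast_profile <- function(vol, aortic_rois, diameter_mm = 8) {
  levels <- c("infrarenal", "mid", "bifurcation")
  samples <- purrr::map_dfr(levels, function(lv) {
    sample_lumen(vol, aortic_rois, level = lv, diameter_mm = diameter_mm)
  })
  tibble::tibble(
    diameter_mm = diameter_mm,
    infrarenal_hu = samples$mean_hu[1],
    mid_hu = samples$mean_hu[2],
    bifurcation_hu = samples$mean_hu[3],
    mean_contrast = mean(samples$mean_hu),
    intraluminal_sd = mean(samples$sd_hu),
    longitudinal_variability = longitudinal_variability(samples$mean_hu)
  )
}

#' Noise-based exclusion rule
#'
#' Studies whose arterial-phase intraluminal SD exceeds `cutoff` HU (strict
#' inequality) are flagged for exclusion as having very high image noise.
#'
#' @param arterial_sd intraluminal SD in the arterial phase (HU); vectorised.
#' @param cutoff exclusion threshold in HU (default 35).
#' @return Logical: `TRUE` = exclude.
#' @export
noise_exclude <- function(arterial_sd, cutoff = 35) {
  arterial_sd > cutoff
}

# 8-connected labeling of one logical slice via union-find.
label_components_8 <- function(fg) {
  idx <- which(fg)
  if (length(idx) == 0L) return(array(0L, dim = dim(fg)))
  nr <- nrow(fg)
  parent <- seq_along(idx)
  pos <- integer(length(fg)); pos[idx] <- seq_along(idx)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  for (k in seq_along(idx)) {
    # union with one neighbour of each symmetric pair (W, NW, N, NE)
    for (d in list(c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L))) {
      ri <- rows[k] + d[1]; ci <- cols[k] + d[2]
      if (ri >= 1L && ri <= nr && ci >= 1L && ci <= ncol(fg) && fg[ri, ci]) {
        j <- pos[(ci - 1L) * nr + ri]
        if (j > 0L) {
          rk <- find(k); rj <- find(j)
          if (rk != rj) parent[rk] <- rj
        }
      }
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  labels <- array(0L, dim = dim(fg))
  labels[idx] <- match(roots, unique(roots))
  labels
}

#' Modified Agatston calcification score
#'
#' Scores aortic wall calcification on the unenhanced series: per axial
#' slice, 8-connected components of voxels at or above `threshold_hu` inside
#' the supplied mask form lesions; a lesion with in-plane area of at least
#' `min_area_mm2` contributes `area (mm²) x weight`, where the weight is 1,
#' 2, 3 or 4 for a lesion peak HU of 130–199, 200–299, 300–399 or ≥ 400.
#' Lesions are not merged across slices; the score is the sum over all slices
#' and lesions. No slice-thickness renormalisation is applied, so the score
#' is computed on the reconstruction as given.
#'
#' @param native a native-phase [ct_volume].
#' @param mask logical array restricting the search (periaortic ROI).
#' @param threshold_hu detection threshold in HU (default 130).
#' @param min_area_mm2 minimum lesion area in mm² (default 1).
#' @return One-row tibble: `agatston`, `lesion_count`.
#' @export
agatston_score <- function(native, mask, threshold_hu = 130, min_area_mm2 = 1) {
  stopifnot(inherits(native, "ct_volume"))
  if (native$phase != "native") {
    stop("calcium scoring is defined on the unenhanced series only", call. = FALSE)
  }
  if (!identical(dim(mask), dim(native$voxels))) {
    stop("mask shape does not match the volume grid", call. = FALSE)
  }
  px_area <- pixel_area_mm2(native)
  total <- 0
  n_lesions <- 0L
  for (s in seq_len(dim(native$voxels)[3])) {
    sl <- native$voxels[, , s]
    fg <- mask[, , s] & sl >= threshold_hu
    if (!any(fg)) next
    labels <- label_components_8(fg)
    for (lb in seq_len(max(labels))) {
      in_lesion <- labels == lb
      area <- sum(in_lesion) * px_area
      if (area < min_area_mm2) next
      peak <- max(sl[in_lesion])
      weight <- if (peak >= 400) 4 else if (peak >= 300) 3 else if (peak >= 200) 2 else 1
      total <- total + area * weight
      n_lesions <- n_lesions + 1L
    }
  }
  tibble::tibble(agatston = total, lesion_count = n_lesions)
}
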