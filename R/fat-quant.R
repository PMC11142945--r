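#' Segment fat-containing voxels inside the periaortic ROI
#'
#' Fat is detected with the conventional adipose HU window: a voxel is
#' fat-containing iff `hu_low <= HU <= hu_high` (both bounds inclusive) and it
#' lies inside the periaortic mask. This is equivalent to zeroing everything
#' outside the ROI and thresholding, but keeps HU values intact.
#'
#' @param vol a [ct_volume].
#' @param periaortic_mask logical array matching the volume grid.
#' @param hu_low,hu_high fat window bounds in HU (defaults −195 and −45).
#' @return Logical array of selected voxels.
#' @export
segment_fat <- function(vol, periaortic_mask, hu_low = -195, hu_high = -45) {
  stopifnot(inherits(vol, "ct_volume"))
  if (!identical(dim(periaortic_mask), dim(vol$voxels))) {
    stop("mask shape does not match the volume grid", call. = FALSE)
  }
  if (hu_low > hu_high) {
    stop("invalid HU window: lower bound exceeds upper bound", call. = FALSE)
  }
  periaortic_mask & vol$voxels >= hu_low & vol$voxels <= hu_high
}

#' Volume of a voxel mask
#'
#' `volume = n_voxels * pixel_area * slice_increment / 1000` in cm³. The
#' reconstruction increment, not the slice thickness, is the inter-slice step,
#' so it is the correct height of each slice's contribution (overlapping
#' 3 mm/2 mm reconstructions would otherwise be double-counted).
#'
#' @param mask logical array.
#' @param vol the [ct_volume] providing pixel area and increment (any object
#'   with `spacing_xy` and `slice_increment` works).
#' @return Volume in cm³.
#' @export
volume_of <- function(mask, vol) {
  sum(mask) * pixel_area_mm2(vol) * vol$slice_increment / 1000
}

#' Quantify periaortic fat for one phase
#'
#' Computes the per-study measurement record: aortic volume (AVol), periaortic
#' volume (PaVol), ring volume (PaRVol = PaVol − AVol), fat volume (PaFTVol,
#' fat-range voxels within the whole periaortic ROI — aortic disc included),
#' the ring-adjusted fat ratio `PaFTVol / PaRVol`, and the pooled mean and
#' sample SD of the selected voxels' HU values.
#'
#' @param vol a [ct_volume] (either phase).
#' @param rois an `aorto_periaortic_roi` from [build_roi_masks()].
#' @param hu_window fat window, default `c(-195, -45)`.
#' @return One-row tibble: `phase`, `AVol`, `PaVol`, `PaRVol`, `PaFTVol`,
#'   `PaFT_ratio`, `PaFT_meanHU`, `PaFT_sdHU`, `n_fat_voxels` (volumes in cm³,
#'   attenuations in HU).
#' @export
paft_metrics <- function(vol, rois, hu_window = c(-195, -45)) {
  stopifnot(inherits(rois, "aorto_periaortic_roi"))
  avol <- volume_of(rois$aortic_mask, vol)
  pavol <- volume_of(rois$periaortic_mask, vol)
  parvol <- pavol - avol   # identical to volume_of(ring_mask, vol) up to fp rounding
  if (parvol <= 0) {
    stop("periaortic ring volume is zero; fat ratio undefined", call. = FALSE)
  }
  fat <- segment_fat(vol, rois$periaortic_mask, hu_window[1], hu_window[2])
  n_fat <- sum(fat)
  fat_hu <- vol$voxels[fat]
  tibble::tibble(
    phase = vol$phase,
    AVol = avol,
    PaVol = pavol,
    PaRVol = parvol,
    PaFTVol = volume_of(fat, vol),
    PaFT_ratio = volume_of(fat, vol) / parvol,
    PaFT_meanHU = if (n_fat > 0) mean(fat_hu) else NA_real_,
    PaFT_sdHU = if (n_fat > 1) stats::sd(fat_hu) else NA_real_,
    n_fat_voxels = n_fat
  )
}

#' Count fat-range voxels inside the unenhanced aortic lumen
#'
#' Isolated voxels with fat-range HU can appear inside the native aortic disc
#' (noise, metal artifacts). Counting them per study quantifies whether the
#' aortic disc must be excluded from the fat search; on clean data the count
#' is zero or near-zero. The audit is only meaningful on the native phase —
#' the contrast-filled arterial lumen sits hundreds of HU above the fat
#' window — so calling it on an arterial volume is an error.
#'
#' @param native a native-phase [ct_volume].
#' @param aortic_mask logical array for the aortic ROI.
#' @param hu_window fat window, default `c(-195, -45)`.
#' @return Integer count of fat-range voxels inside the aortic mask.
#' @export
audit_intraluminal_fat_voxels <- function(native, aortic_mask,
                                          hu_window = c(-195, -45)) {
  stopifnot(inherits(native, "ct_volume"))
  if (native$phase != "native") {
    stop("intraluminal fat-voxel audit is defined on the native phase only",
         call. = FALSE)
  }
  if (!identical(dim(aortic_mask), dim(native$voxels))) {
    stop("mask shape does not match the volume grid", call. = FALSE)
  }
  sum(aortic_mask & native$voxels >= hu_window[1] & native$voxels <= hu_window[2])
}
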