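#' Read a CT volume from disk
#'
#' Reads either a NIfTI-1 file (`.nii` / `.nii.gz`) or a directory containing
#' one DICOM series (one file per axial slice). NIfTI is the canonical
#' interchange format of this package; DICOM is supported read-only. DICOM
#' stored values are converted to HU with the rescale slope/intercept from the
#' headers, and slices are ordered cranio-caudally by their position along the
#' patient axis.
#'
#' NIfTI carries only one inter-slice step in its header (`pixdim[3]`, used
#' here as the reconstruction increment), so [write_ct()] places the slice
#' thickness and the phase label in a JSON sidecar next to the image; when the
#' sidecar is absent the thickness is assumed equal to the increment.
#'
#' @param path a NIfTI file path or a DICOM series directory.
#' @param phase phase label to attach when the file itself does not record
#'   one; ignored when a sidecar or DICOM metadata provides it.
#' @return A [ct_volume].
#' @seealso [write_ct()], [pair_phases()]
#' @export
read_ct <- function(path, phase = c("native", "arterial")) {
  phase <- match.arg(phase)
  if (dir.exists(path)) {
    return(read_dicom_series(path, phase = phase))
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  pd <- attr(img, "pixdim")
  if (is.null(pd)) pd <- RNifti::pixdim(img)
  if (length(pd) < 3L) {
    stop("missing geometry metadata: pixdim has fewer than 3 entries", call. = FALSE)
  }
  if (any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0)) {
    bad <- c("pixdim[1] (row spacing)", "pixdim[2] (column spacing)",
             "pixdim[3] (slice increment)")[which(!is.finite(pd[1:3]) | pd[1:3] <= 0)][1]
    stop("missing geometry metadata: ", bad, " is not a positive number", call. = FALSE)
  }
  voxels <- array(as.numeric(img), dim = dim(img))
  increment <- pd[3]
  thickness <- increment
  sidecar <- sidecar_path(path)
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$SliceThickness)) thickness <- as.numeric(meta$SliceThickness)
    if (!is.null(meta$Phase)) phase <- match.arg(meta$Phase, c("native", "arterial"))
  }
  ct_volume(voxels, spacing_xy = pd[1:2], slice_thickness = thickness,
            slice_increment = increment, phase = phase)
}

#' Write a CT volume (or mask) as NIfTI with a JSON sidecar
#'
#' @param vol a [ct_volume].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_ct <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- c(vol$spacing_xy, vol$slice_increment)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(
    list(
      SliceThickness = vol$slice_thickness,
      SpacingBetweenSlices = vol$slice_increment,
      PixelSpacing = vol$spacing_xy,
      Phase = vol$phase
    ),
    sidecar_path(path),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Convert stored values to HU with a DICOM rescale transform
#'
#' HU = `slope * stored + intercept`. The transform is affine and must be
#' applied exactly once; arrays already carrying the `hu_rescaled` attribute
#' are refused so that a double application cannot silently corrupt HU values.
#'
#' @param stored numeric array of stored pixel values.
#' @param slope,intercept rescale slope and intercept from the DICOM header.
#' @return numeric array of HU with attribute `hu_rescaled = TRUE`.
#' @export
apply_hu_rescale <- function(stored, slope, intercept) {
  if (isTRUE(attr(stored, "hu_rescaled"))) {
    stop("values have already been rescaled to HU; refusing to rescale twice",
         call. = FALSE)
  }
  out <- slope * stored + intercept
  attr(out, "hu_rescaled") <- TRUE
  out
}
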