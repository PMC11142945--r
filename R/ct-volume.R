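#' CT volume container
#'
#' A `ct_volume` wraps a 3-D array of Hounsfield units (HU) together with the
#' geometry metadata every downstream stage needs: in-plane pixel spacing,
#' slice thickness and the reconstruction increment (the cranio-caudal step
#' between consecutive slice centres, which may be smaller than the thickness
#' for overlapping reconstructions). Slices are indexed cranio-caudally along
#' the third array dimension.
#'
#' @param voxels 3-D numeric array of HU values, dimensions
#'   `(rows, columns, slices)`. HU may be non-integer (DICOM rescale slopes
#'   can produce fractional values) but must lie in the plausible CT range
#'   \[-1024, 4000\].
#' @param spacing_xy numeric length-2, mm per pixel in-plane (row, column).
#' @param slice_thickness slice thickness in mm.
#' @param slice_increment reconstruction increment in mm (distance between
#'   consecutive slice positions). May be smaller than `slice_thickness`
#'   (overlapping slices) or larger (gapped).
#' @param phase one of `"native"` or `"arterial"`.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing_xy, slice_thickness, slice_increment,
                      phase = c("native", "arterial")) {
  phase <- match.arg(phase)
  if (length(dim(voxels)) != 3L) {
    stop("`voxels` must be a 3-D array (rows x columns x slices)", call. = FALSE)
  }
  spacing_xy <- as.numeric(spacing_xy)
  if (length(spacing_xy) == 1L) spacing_xy <- rep(spacing_xy, 2L)
  if (length(spacing_xy) != 2L || any(!is.finite(spacing_xy)) || any(spacing_xy <= 0)) {
    stop("`spacing_xy` must be two positive values (mm per pixel)", call. = FALSE)
  }
  for (nm in c("slice_thickness", "slice_increment")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("`%s` must be a single positive number (mm)", nm), call. = FALSE)
    }
  }
  rng <- range(voxels)
  if (rng[1] < -1024 || rng[2] > 4000) {
    stop(sprintf(
      "HU values outside the plausible CT range [-1024, 4000]: observed [%.1f, %.1f]",
      rng[1], rng[2]
    ), call. = FALSE)
  }
  structure(
    list(
      voxels = voxels,
      spacing_xy = spacing_xy,
      slice_thickness = as.numeric(slice_thickness),
      slice_increment = as.numeric(slice_increment),
      phase = phase
    ),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<ct_volume> %s phase, %d x %d x %d voxels, %.3g x %.3g mm pixels, %g mm slices at %g mm increment\n",
    x$phase, d[1], d[2], d[3], x$spacing_xy[1], x$spacing_xy[2],
    x$slice_thickness, x$slice_increment
  ))
  hu <- range(x$voxels)
  cat(sprintf("  HU range [%.1f, %.1f]\n", hu[1], hu[2]))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

n_slices <- function(vol) dim(vol$voxels)[3]

pixel_area_mm2 <- function(vol) prod(vol$spacing_xy)

#' Pair a native and an arterial volume
#'
#' Both phases of a study must be reconstructed with identical pixel spacing,
#' slice thickness and increment, and must cover the same slice range;
#' otherwise per-voxel comparison of the two phases is meaningless. A pair
#' whose slice counts differ is rejected with a "slice mismatch" error, and
#' differing thickness/increment/spacing is likewise rejected.
#'
#' @param native,arterial `ct_volume` objects with `phase` `"native"` and
#'   `"arterial"` respectively.
#' @return An object of class `ct_study_pair` with elements `native` and
#'   `arterial`.
#' @export
pair_phases <- function(native, arterial) {
  stopifnot(inherits(native, "ct_volume"), inherits(arterial, "ct_volume"))
  if (native$phase != "native" || arterial$phase != "arterial") {
    stop("pair_phases() expects a native and an arterial ct_volume, in that order",
         call. = FALSE)
  }
  dn <- dim(native$voxels); da <- dim(arterial$voxels)
  if (dn[3] != da[3]) {
    stop(sprintf("slice mismatch between native and arterial phase (%d vs %d slices)",
                 dn[3], da[3]), call. = FALSE)
  }
  if (!all(dn == da)) {
    stop("in-plane grid mismatch between native and arterial phase", call. = FALSE)
  }
  geom_equal <- isTRUE(all.equal(native$spacing_xy, arterial$spacing_xy)) &&
    isTRUE(all.equal(native$slice_thickness, arterial$slice_thickness)) &&
    isTRUE(all.equal(native$slice_increment, arterial$slice_increment))
  if (!geom_equal) {
    stop("native and arterial phases must share identical pixel spacing, slice thickness and increment",
         call. = FALSE)
  }
  structure(list(native = native, arterial = arterial), class = "ct_study_pair")
}

#' @export
print.ct_study_pair <- function(x, ...) {
  cat("<ct_study_pair>\n  native:  "); print(x$native)
  cat("  arterial: "); print(x$arterial)
  invisible(x)
}
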