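#' Per-slice elliptical aortic ROIs
#'
#' Aortic regions of interest are ovals traced on axial slices following the
#' outer aortic wall, one per slice between the most distal renal artery and
#' the aortic bifurcation. They are represented as a tibble with one row per
#' slice. In-plane coordinates are in mm: `x` runs along image columns, `y`
#' along rows, and the centre of pixel `(i, j)` sits at
#' `((j - 0.5) * spacing_x, (i - 0.5) * spacing_y)`.
#'
#' @param slice integer slice indices (cranio-caudal).
#' @param cx,cy ellipse centre in mm.
#' @param a,b semi-axes in mm (must be positive).
#' @param theta rotation of the `a` axis in radians, counter-clockwise.
#' @return A tibble with columns `slice`, `cx`, `cy`, `a`, `b`, `theta`.
#' @export
ellipse_roi <- function(slice, cx, cy, a, b, theta = 0) {
  out <- tibble::tibble(slice = as.integer(slice), cx = cx, cy = cy,
                        a = a, b = b, theta = theta)
  if (any(out$a <= 0) || any(out$b <= 0)) {
    stop("ellipse semi-axes must be positive", call. = FALSE)
  }
  out
}

check_roi_tbl <- function(rois) {
  need <- c("slice", "cx", "cy", "a", "b", "theta")
  if (!is.data.frame(rois) || !all(need %in% names(rois))) {
    stop("ROI table must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(rois$a <= 0) || any(rois$b <= 0)) {
    stop("ellipse semi-axes must be positive", call. = FALSE)
  }
  invisible(rois)
}

#' Expand aortic ROIs to periaortic ROIs
#'
#' The periaortic ROI extends the aortic ellipse by 10 mm in both full axes —
#' i.e. each semi-axis grows by exactly `margin_mm` (default 5 mm) — keeping
#' the centre and rotation, which yields the 5 mm-wide periaortic ring once
#' the aortic region is subtracted.
#'
#' @param rois ROI tibble as returned by [ellipse_roi()].
#' @param margin_mm ring width in mm added to each semi-axis (default 5).
#' @return ROI tibble of the same shape with enlarged semi-axes.
#' @export
expand_to_periaortic <- function(rois, margin_mm = 5) {
  check_roi_tbl(rois)
  stopifnot(is.numeric(margin_mm), length(margin_mm) == 1L, margin_mm > 0)
  dplyr::mutate(rois, a = .data$a + margin_mm, b = .data$b + margin_mm)
}

# Half-extent of a rotated ellipse's axis-aligned bounding box.
ellipse_extent <- function(a, b, theta) {
  c(
    x = sqrt((a * cos(theta))^2 + (b * sin(theta))^2),
    y = sqrt((a * sin(theta))^2 + (b * cos(theta))^2)
  )
}

#' Rasterize one elliptical ROI onto a slice grid
#'
#' A voxel belongs to the ROI iff its centre lies inside or on the ellipse
#' boundary (boundary-inclusive point-in-ellipse membership).
#'
#' @param cx,cy,a,b,theta ellipse parameters in mm (see [ellipse_roi()]).
#' @param dim_xy integer `(rows, columns)` of the slice grid.
#' @param spacing_xy mm per pixel `(row, column)`.
#' @return Logical matrix `(rows x columns)` of voxel membership.
#' @export
rasterize_ellipse <- function(cx, cy, a, b, theta, dim_xy, spacing_xy) {
  if (length(spacing_xy) == 1L) spacing_xy <- rep(spacing_xy, 2L)
  ys <- (seq_len(dim_xy[1]) - 0.5) * spacing_xy[1]
  xs <- (seq_len(dim_xy[2]) - 0.5) * spacing_xy[2]
  dx <- outer(rep(1, dim_xy[1]), xs - cx)
  dy <- outer(ys - cy, rep(1, dim_xy[2]))
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  u * u + v * v <= 1
}

#' Build aortic, periaortic and ring masks for a study
#'
#' Constructs the geometric backbone of the measurement: per-slice aortic
#' masks, periaortic masks (aortic ellipses expanded by `margin_mm` per
#' semi-axis) and the ring mask (periaortic minus aortic). The periaortic
#' ROIs are constructed once — on the native series — and the same masks are
#' applied verbatim to the arterial series, so the periaortic volume is
#' identical in both phases by construction.
#'
#' @param vol a [ct_volume] providing the grid geometry.
#' @param aortic_rois aortic ROI tibble ([ellipse_roi()]), one row per slice
#'   covered by the infrarenal segment.
#' @param margin_mm ring width in mm (default 5).
#' @return An object of class `aorto_periaortic_roi`: list with the two ROI
#'   tibbles, 3-D logical `aortic_mask`, `periaortic_mask`, `ring_mask`, and
#'   a `clipped` logical vector flagging slices whose periaortic ellipse
#'   exceeded the image bounds (mask truncated at the edge).
#' @export
build_roi_masks <- function(vol, aortic_rois, margin_mm = 5) {
  stopifnot(inherits(vol, "ct_volume"))
  check_roi_tbl(aortic_rois)
  d <- dim(vol$voxels)
  if (any(aortic_rois$slice < 1L) || any(aortic_rois$slice > d[3])) {
    stop("ROI slice indices outside the volume", call. = FALSE)
  }
  peri <- expand_to_periaortic(aortic_rois, margin_mm)
  aortic_mask <- array(FALSE, dim = d)
  peri_mask <- array(FALSE, dim = d)
  clipped <- logical(nrow(peri))
  img_extent <- c(x = d[2] * vol$spacing_xy[2], y = d[1] * vol$spacing_xy[1])
  for (k in seq_len(nrow(aortic_rois))) {
    s <- aortic_rois$slice[k]
    aortic_mask[, , s] <- rasterize_ellipse(
      aortic_rois$cx[k], aortic_rois$cy[k], aortic_rois$a[k], aortic_rois$b[k],
      aortic_rois$theta[k], d[1:2], vol$spacing_xy
    )
    peri_mask[, , s] <- rasterize_ellipse(
      peri$cx[k], peri$cy[k], peri$a[k], peri$b[k], peri$theta[k],
      d[1:2], vol$spacing_xy
    )
    ext <- ellipse_extent(peri$a[k], peri$b[k], peri$theta[k])
    if (peri$cx[k] - ext["x"] < 0 || peri$cx[k] + ext["x"] > img_extent["x"] ||
        peri$cy[k] - ext["y"] < 0 || peri$cy[k] + ext["y"] > img_extent["y"]) {
      clipped[k] <- TRUE
    }
  }
  if (any(clipped)) {
    warning(sprintf("periaortic ellipse exceeds image bounds on %d slice(s); mask clipped",
                    sum(clipped)), call. = FALSE)
  }
  structure(
    list(
      aortic = aortic_rois, periaortic = peri,
      aortic_mask = aortic_mask, periaortic_mask = peri_mask,
      ring_mask = build_ring(aortic_mask, peri_mask),
      clipped = clipped, margin_mm = margin_mm
    ),
    class = "aorto_periaortic_roi"
  )
}

#' Ring mask: periaortic minus aortic
#'
#' @param aortic_mask,periaortic_mask logical arrays of identical shape; the
#'   aortic mask must be a subset of the periaortic mask.
#' @return Logical array: voxels in the periaortic but not the aortic mask.
#' @export
build_ring <- function(aortic_mask, periaortic_mask) {
  stopifnot(identical(dim(aortic_mask), dim(periaortic_mask)))
  if (any(aortic_mask & !periaortic_mask)) {
    stop("aortic mask contains voxels outside the periaortic mask; ring undefined",
         call. = FALSE)
  }
  periaortic_mask & !aortic_mask
}

#' Maximum aortic diameter
#'
#' Defined as twice the shorter semi-axis of the largest aortic disc (the
#' slice whose ellipse has the greatest area, i.e. greatest `a * b`). Ties go
#' to the first slice in cranio-caudal order.
#'
#' @param rois aortic ROI tibble.
#' @return Maximum aortic diameter in mm.
#' @export
measure_max_diameter <- function(rois) {
  check_roi_tbl(rois)
  if (nrow(rois) == 0L) stop("at least one slice ROI required", call. = FALSE)
  areas <- rois$a * rois$b
  k <- which.max(areas)   # which.max returns the first maximum
  2 * min(rois$a[k], rois$b[k])
}

#' @export
print.aorto_periaortic_roi <- function(x, ...) {
  cat(sprintf("<aorto_periaortic_roi> %d slices, ring width %g mm, %d clipped\n",
              nrow(x$aortic), x$margin_mm, sum(x$clipped)))
  invisible(x)
}

#' Write ROI tables as JSON
#'
#' @param rois ROI tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_roi_json <- function(rois, path) {
  check_roi_tbl(rois)
  jsonlite::write_json(rois, path, dataframe = "rows", digits = NA)
  invisible(path)
}

#' Read ROI tables from JSON
#' @param path JSON file written by [write_roi_json()].
#' @return ROI tibble.
#' @export
read_roi_json <- function(path) {
  out <- tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  out$slice <- as.integer(out$slice)
  check_roi_tbl(out)
  out
}
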