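# Minimal DICOM series reader: uncompressed little-endian CT slices only
# (implicit or explicit VR), one file per slice. Reads just the tags needed
# for geometry and HU semantics; anything exotic (sequences of undefined
# length, compressed transfer syntaxes, big endian) is a hard error rather
# than a silent misread.

DICOM_TAGS <- list(
  transfer_syntax   = c(0x0002, 0x0010),
  slice_thickness   = c(0x0018, 0x0050),
  spacing_between   = c(0x0018, 0x0088),
  image_position    = c(0x0020, 0x0032),
  instance_number   = c(0x0020, 0x0013),
  rows              = c(0x0028, 0x0010),
  cols              = c(0x0028, 0x0011),
  pixel_spacing     = c(0x0028, 0x0030),
  bits_allocated    = c(0x0028, 0x0100),
  pixel_representation = c(0x0028, 0x0103),
  rescale_intercept = c(0x0028, 0x1052),
  rescale_slope     = c(0x0028, 0x1053),
  pixel_data        = c(0x7FE0, 0x0010)
)

read_uint16 <- function(raw2) sum(as.integer(raw2) * c(1L, 256L))
read_uint32 <- function(raw4) sum(as.numeric(raw4) * c(1, 256, 65536, 16777216))

# Parse one DICOM file, returning the tag values needed for a CT slice.
parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM") {
    stop("not a DICOM part-10 file: ", path, call. = FALSE)
  }
  pos <- 133L
  found <- list()
  explicit <- TRUE   # the file meta group is always explicit VR little endian
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

  while (pos + 8L <= length(raw) + 1L) {
    group <- read_uint16(raw[pos:(pos + 1L)])
    element <- read_uint16(raw[(pos + 2L):(pos + 3L)])
    pos <- pos + 4L
    if (explicit || group == 0x0002) {
      vr <- rawToChar(raw[pos:(pos + 1L)])
      if (vr %in% long_vrs) {
        len <- read_uint32(raw[(pos + 4L):(pos + 7L)])
        pos <- pos + 8L
      } else {
        len <- read_uint16(raw[(pos + 2L):(pos + 3L)])
        pos <- pos + 4L
      }
    } else {
      vr <- NA_character_
      len <- read_uint32(raw[pos:(pos + 3L)])
      pos <- pos + 4L
    }
    if (len == 4294967295) {
      stop("undefined-length element (", sprintf("%04X,%04X", group, element),
           ") not supported: ", path, call. = FALSE)
    }
    value_raw <- if (len > 0) raw[pos:(pos + len - 1L)] else raw(0)
    pos <- pos + len

    tag_name <- NULL
    for (nm in names(DICOM_TAGS)) {
      tg <- DICOM_TAGS[[nm]]
      if (group == tg[1] && element == tg[2]) { tag_name <- nm; break }
    }
    if (!is.null(tag_name)) {
      found[[tag_name]] <- list(vr = vr, raw = value_raw)
      if (tag_name == "transfer_syntax") {
        uid <- sub("\\x00+$", "", rawToChar(value_raw))
        uid <- trimws(uid)
        if (uid == "1.2.840.10008.1.2") {
          explicit <- FALSE
        } else if (uid %in% c("1.2.840.10008.1.2.1", "1.2.840.10008.1.2.1.99")) {
          explicit <- TRUE
        } else {
          stop("unsupported transfer syntax ", uid, " in ", path, call. = FALSE)
        }
      }
      if (tag_name == "pixel_data") break
    }
  }
  found
}

dicom_numeric <- function(found, name, path, required = TRUE, default = NULL) {
  el <- found[[name]]
  if (is.null(el)) {
    if (!required) return(default)
    stop("missing geometry metadata: DICOM tag '", name, "' absent in ", path,
         call. = FALSE)
  }
  vr <- el$vr
  if (!is.na(vr) && vr %in% c("US", "SS")) {
    n <- length(el$raw) / 2L
    v <- numeric(n)
    for (i in seq_len(n)) v[i] <- read_uint16(el$raw[(2L * i - 1L):(2L * i)])
    return(v)
  }
  # string VRs (DS, IS, ...) and implicit VR: decimal strings, backslash-separated
  s <- rawToChar(el$raw[el$raw != as.raw(0)])
  as.numeric(strsplit(trimws(s), "\\\\")[[1]])
}

dicom_pixels <- function(found, rows, cols, signed, path) {
  el <- found$pixel_data
  if (is.null(el)) stop("missing PixelData in ", path, call. = FALSE)
  n <- rows * cols
  if (length(el$raw) < 2L * n) {
    stop("PixelData shorter than Rows x Columns in ", path, call. = FALSE)
  }
  v <- readBin(el$raw, "integer", n = n, size = 2L, signed = signed,
               endian = "little")
  if (!signed) v[v < 0] <- v[v < 0] + 65536L  # readBin size-2 unsigned workaround
  t(matrix(v, nrow = cols, ncol = rows))      # DICOM stores row-major
}

# Read a directory holding one DICOM series (one file per axial slice).
read_dicom_series <- function(dir, phase = "native") {
  files <- sort(list.files(dir, full.names = TRUE))
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no files in DICOM directory: ", dir, call. = FALSE)

  slices <- lapply(files, function(f) {
    found <- parse_dicom_file(f)
    rows <- dicom_numeric(found, "rows", f)
    cols <- dicom_numeric(found, "cols", f)
    bits <- dicom_numeric(found, "bits_allocated", f, required = FALSE, default = 16)
    if (bits != 16) stop("only 16-bit DICOM pixel data supported: ", f, call. = FALSE)
    pixrep <- dicom_numeric(found, "pixel_representation", f, required = FALSE, default = 0)
    spacing <- dicom_numeric(found, "pixel_spacing", f)
    thickness <- dicom_numeric(found, "slice_thickness", f)
    slope <- dicom_numeric(found, "rescale_slope", f, required = FALSE, default = 1)
    intercept <- dicom_numeric(found, "rescale_intercept", f, required = FALSE, default = 0)
    pos <- dicom_numeric(found, "image_position", f, required = FALSE,
                         default = c(0, 0, dicom_numeric(found, "instance_number", f)))
    stored <- dicom_pixels(found, rows, cols, signed = pixrep == 1, path = f)
    hu <- apply_hu_rescale(stored, slope, intercept)
    list(hu = hu, spacing = spacing, thickness = thickness, z = pos[3])
  })

  sp0 <- slices[[1]]$spacing
  th0 <- slices[[1]]$thickness
  for (s in slices) {
    if (max(abs(s$spacing - sp0)) > 1e-6 || abs(s$thickness - th0) > 1e-6) {
      stop("mixed pixel spacing or slice thickness within the DICOM series", call. = FALSE)
    }
  }
  ord <- order(vapply(slices, function(s) s$z, numeric(1)))
  slices <- slices[ord]
  zs <- vapply(slices, function(s) s$z, numeric(1))
  if (length(zs) > 1L) {
    steps <- diff(zs)
    if (any(steps <= 0)) stop("duplicate or unordered slice positions in series", call. = FALSE)
    if (max(steps) - min(steps) > 1e-3) {
      stop("mixed slice spacing within the DICOM series (increments ",
           paste(signif(unique(round(steps, 4)), 4), collapse = ", "), " mm)",
           call. = FALSE)
    }
    increment <- mean(steps)
  } else {
    increment <- th0
  }

  voxels <- array(0, dim = c(nrow(slices[[1]]$hu), ncol(slices[[1]]$hu), length(slices)))
  for (i in seq_along(slices)) voxels[, , i] <- slices[[i]]$hu
  ct_volume(voxels, spacing_xy = sp0, slice_thickness = th0,
            slice_increment = increment, phase = phase)
}
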