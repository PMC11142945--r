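#' Synthetic paired-CT phantom specification
#'
#' Defines one synthetic study: a stack of axial slices holding a circular or
#' elliptical aorta (contrast-filled lumen inside a soft-tissue wall)
#' surrounded by a fat-bearing periaortic ring on a soft-tissue background.
#' The native and arterial volumes share identical geometry, fat placement
#' and tissue noise draws; only contrast-dependent effects differ: the lumen
#' attenuation (about 40 HU native vs about 316 HU arterial, with an optional
#' cranio-caudal gradient) and a partial-volume surrogate at the aortic
#' boundary, where a calibrated fraction of wall-adjacent fat voxels rises
#' above the −45 HU fat limit in the arterial phase. That boundary-shell loss
#' reproduces the contrast-induced underestimation of arterial fat volume
#' while leaving interior fat HU untouched.
#'
#' `volume_loss_ratio` is the study's true native/arterial fat-volume ratio;
#' the number of boundary-shell voxels lost is derived from it analytically
#' (`round(n_fat * (1 - 1/ratio))`), plus the additive perturbation
#' `extra_loss_voxels` (positive = extra loss, negative = less loss than the
#' systematic expectation; the net count is clamped to `[0, n_shell_fat]`).
#'
#' @param n_slices number of axial slices.
#' @param pixel_mm in-plane pixel size (isotropic), mm.
#' @param slice_thickness_mm,slice_increment_mm slice thickness and
#'   reconstruction increment, mm.
#' @param aortic_diameter_mm outer aortic diameter, scalar or one value per
#'   slice (aneurysmal shapes).
#' @param axis_ratio ratio of the short to the long ellipse axis (1 =
#'   circular aorta).
#' @param lumen_native_hu,lumen_arterial_hu,wall_hu,fat_hu,background_hu
#'   length-2 `(mean, sd)` HU distributions.
#' @param arterial_gradient_hu end-to-end cranio-caudal difference added to
#'   the arterial lumen mean (longitudinal contrast dispersion).
#' @param wall_thickness_mm aortic wall thickness, mm.
#' @param fat_fraction fraction of ring voxels that contain fat.
#' @param volume_loss_ratio true native/arterial fat-volume ratio (>= 1).
#' @param shell_mm width of the wall-adjacent shell over which arterial fat
#'   loss occurs.
#' @param extra_loss_voxels additive perturbation of the arterial lost-voxel
#'   count (study-level measurement variability; 0 for a clean phantom).
#' @param ring_margin_mm periaortic ring width, mm.
#' @param n_calc_lesions number of calcified wall lesions.
#' @param n_artifact_voxels fat-range artifact voxels injected into the
#'   native lumen.
#' @param seed RNG seed for this study.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(n_slices = 10,
                         pixel_mm = 0.7,
                         slice_thickness_mm = 3,
                         slice_increment_mm = 2,
                         aortic_diameter_mm = 22,
                         axis_ratio = 1,
                         lumen_native_hu = c(40, 5),
                         lumen_arterial_hu = c(316, 22),
                         arterial_gradient_hu = 0,
                         wall_hu = c(45, 10),
                         wall_thickness_mm = 2,
                         fat_fraction = 0.467,
                         fat_hu = c(-77, 9.7),
                         background_hu = c(20, 15),
                         volume_loss_ratio = 1.1057,
                         shell_mm = 2.5,
                         extra_loss_voxels = 0,
                         ring_margin_mm = 5,
                         n_calc_lesions = 0,
                         n_artifact_voxels = 0,
                         seed = 1L) {
  spec <- as.list(environment())
  stopifnot(spec$n_slices >= 1, spec$pixel_mm > 0, spec$volume_loss_ratio >= 1,
            spec$fat_fraction >= 0, spec$fat_fraction <= 1,
            spec$axis_ratio > 0, spec$axis_ratio <= 1)
  if (length(spec$aortic_diameter_mm) == 1L) {
    spec$aortic_diameter_mm <- rep(spec$aortic_diameter_mm, spec$n_slices)
  }
  if (length(spec$aortic_diameter_mm) != spec$n_slices) {
    stop("aortic_diameter_mm must be scalar or one value per slice", call. = FALSE)
  }
  if (any(spec$aortic_diameter_mm / 2 - spec$wall_thickness_mm <= 1)) {
    stop("geometry too small: aortic lumen vanishes at the given wall thickness",
         call. = FALSE)
  }
  class(spec) <- "phantom_spec"
  spec
}

#' Generate one paired native/arterial phantom study
#'
#' Deterministic for a fixed `spec$seed`. Returns both phases and the ground
#' truth needed to verify every pipeline stage: the aortic ROI table, the
#' true fat placement, the per-phase in-range fat voxel counts, the true
#' loss ratio realised on this grid, and the true arterial lumen level means.
#'
#' @param spec a [phantom_spec()].
#' @return List with `native`, `arterial` ([ct_volume]s), `aortic_rois`
#'   (tibble) and `truth` (list).
#' @export
generate_phantom_pair <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  px <- spec$pixel_mm
  dmax <- max(spec$aortic_diameter_mm)
  fov <- dmax + 2 * spec$ring_margin_mm + 16   # 8 mm clearance each side
  n_xy <- as.integer(ceiling(fov / px))
  nz <- spec$n_slices
  cx <- n_xy * px / 2
  cy <- cx

  native <- array(stats::rnorm(n_xy * n_xy * nz, spec$background_hu[1],
                               spec$background_hu[2]), dim = c(n_xy, n_xy, nz))
  arterial <- native
  fat_mask <- array(FALSE, dim = dim(native))
  shell_mask <- array(FALSE, dim = dim(native))
  aortic_mask <- array(FALSE, dim = dim(native))
  lumen_mask <- array(FALSE, dim = dim(native))

  a_axis <- spec$aortic_diameter_mm / 2
  b_axis <- a_axis * spec$axis_ratio
  rois <- ellipse_roi(seq_len(nz), cx, cy, a_axis, b_axis, 0)

  grad <- if (nz > 1) {
    spec$arterial_gradient_hu * (seq_len(nz) - (nz + 1) / 2) / (nz - 1)
  } else rep(0, nz)

  for (s in seq_len(nz)) {
    ao <- rasterize_ellipse(cx, cy, a_axis[s], b_axis[s], 0, c(n_xy, n_xy), px)
    lu <- rasterize_ellipse(cx, cy,
                            max(a_axis[s] - spec$wall_thickness_mm, 0.5),
                            max(b_axis[s] - spec$wall_thickness_mm, 0.5),
                            0, c(n_xy, n_xy), px)
    peri <- rasterize_ellipse(cx, cy, a_axis[s] + spec$ring_margin_mm,
                              b_axis[s] + spec$ring_margin_mm, 0, c(n_xy, n_xy), px)
    shell_outer <- rasterize_ellipse(cx, cy, a_axis[s] + spec$shell_mm,
                                     b_axis[s] + spec$shell_mm, 0, c(n_xy, n_xy), px)
    ring <- peri & !ao
    wall <- ao & !lu

    n_ring <- sum(ring)
    is_fat <- ring
    is_fat[ring] <- stats::runif(n_ring) < spec$fat_fraction

    sl_nat <- native[, , s]
    sl_nat[wall] <- stats::rnorm(sum(wall), spec$wall_hu[1], spec$wall_hu[2])
    fat_draw <- stats::rnorm(sum(is_fat), spec$fat_hu[1], spec$fat_hu[2])
    sl_nat[is_fat] <- fat_draw
    sl_art <- sl_nat
    sl_nat[lu] <- stats::rnorm(sum(lu), spec$lumen_native_hu[1], spec$lumen_native_hu[2])
    sl_art[lu] <- stats::rnorm(sum(lu), spec$lumen_arterial_hu[1] + grad[s],
                               spec$lumen_arterial_hu[2])

    native[, , s] <- sl_nat
    arterial[, , s] <- sl_art
    fat_mask[, , s] <- is_fat
    shell_mask[, , s] <- is_fat & shell_outer & !ao
    aortic_mask[, , s] <- ao
    lumen_mask[, , s] <- lu
  }

  # calcified wall lesions: small discs straddling the wall, present in both
  # phases, excluded from fat placement by HU (>= 130)
  if (spec$n_calc_lesions > 0) {
    for (i in seq_len(spec$n_calc_lesions)) {
      s <- sample.int(nz, 1)
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- stats::runif(1, 1, 2)   # lesion radius mm
      lx <- cx + a_axis[s] * cos(ang)
      ly <- cy + b_axis[s] * sin(ang)
      lesion <- rasterize_ellipse(lx, ly, rad, rad, 0, c(n_xy, n_xy), px)
      hu <- stats::runif(1, 160, 600)
      sl_nat <- native[, , s]; sl_art <- arterial[, , s]
      sl_nat[lesion] <- hu; sl_art[lesion] <- hu
      native[, , s] <- sl_nat; arterial[, , s] <- sl_art
      fm <- fat_mask[, , s]; fm[lesion] <- FALSE; fat_mask[, , s] <- fm
      sm <- shell_mask[, , s]; sm[lesion] <- FALSE; shell_mask[, , s] <- sm
    }
  }

  # native intraluminal fat-range artifact voxels
  if (spec$n_artifact_voxels > 0) {
    lum_idx <- which(lumen_mask)
    pick <- sample(lum_idx, min(spec$n_artifact_voxels, length(lum_idx)))
    native[pick] <- -90
  }

  # arterial boundary-shell fat loss calibrated to the true volume ratio;
  # the additive perturbation (study-level measurement variability) is
  # clipped symmetrically so it stays mean-zero and the net count feasible
  n_fat <- sum(fat_mask)
  n_shell <- sum(shell_mask)
  systematic <- round(n_fat * (1 - 1 / spec$volume_loss_ratio))
  lost_idx <- integer(0)
  if (systematic > 0 && n_fat > 0) {
    if (n_shell == 0) {
      stop("geometry too small: no wall-adjacent fat shell to carry the enhancement loss",
           call. = FALSE)
    }
    if (systematic > n_shell) {
      stop("geometry too small: boundary shell holds fewer fat voxels than the systematic loss",
           call. = FALSE)
    }
    headroom <- min(systematic, n_shell - systematic)
    extra <- sign(spec$extra_loss_voxels) *
      min(abs(spec$extra_loss_voxels), headroom)
    target <- systematic + round(extra)
    shell_idx <- which(shell_mask)
    lost_idx <- if (length(shell_idx) == 1L) shell_idx else sample(shell_idx, target)
    # partial-volume voxels: fat mixed with enhancing wall rises above -45 HU
    arterial[lost_idx] <- pmax(stats::rnorm(length(lost_idx), -20, 10), -44)
  }

  native_vol <- ct_volume(native, px, spec$slice_thickness_mm,
                          spec$slice_increment_mm, phase = "native")
  arterial_vol <- ct_volume(arterial, px, spec$slice_thickness_mm,
                            spec$slice_increment_mm, phase = "arterial")

  in_range <- function(x) x >= -195 & x <= -45
  truth <- list(
    fat_mask = fat_mask,
    shell_mask = shell_mask,
    lumen_mask = lumen_mask,
    lost_voxels = lost_idx,
    n_fat_native = sum(in_range(native[fat_mask])),
    n_fat_arterial = sum(in_range(arterial[fat_mask])),
    volume_loss_ratio = spec$volume_loss_ratio,
    fat_fraction = spec$fat_fraction,
    arterial_level_means = spec$lumen_arterial_hu[1] +
      grad[c(1L, as.integer(ceiling(nz / 2)), nz)],
    spec = spec
  )
  list(native = native_vol, arterial = arterial_vol,
       aortic_rois = rois, truth = truth)
}

#' Write a phantom study to disk
#'
#' Emits the NIfTI pair with sidecars, the aortic contour JSON and the
#' ground-truth summary JSON under `dir`.
#'
#' @param study output of [generate_phantom_pair()].
#' @param dir output directory (created if needed).
#' @param id study identifier used in file names.
#' @return `dir`, invisibly.
#' @export
write_phantom_study <- function(study, dir, id = "study") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ct(study$native, file.path(dir, paste0(id, "_native.nii.gz")))
  write_ct(study$arterial, file.path(dir, paste0(id, "_arterial.nii.gz")))
  write_roi_json(study$aortic_rois, file.path(dir, paste0(id, "_aortic_rois.json")))
  tr <- study$truth
  jsonlite::write_json(
    list(n_fat_native = tr$n_fat_native, n_fat_arterial = tr$n_fat_arterial,
         volume_loss_ratio = tr$volume_loss_ratio, fat_fraction = tr$fat_fraction,
         seed = tr$spec$seed),
    file.path(dir, paste0(id, "_truth.json")), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Draw per-study parameters for a synthetic cohort
#'
#' Emulates the derivation cohort's structure: about 14% aneurysmal aortas
#' (diameter > 30 mm, up to ~110 mm, fusiform bulge along the stack), non-AAA
#' diameters near 22 mm, tube voltage 100/120/130 kV in roughly 14:86:1
#' proportions, slice thickness/increment 3/2 mm with a small 5/4 mm
#' minority, Beta-distributed ring fat fractions (mean ~0.47), occasional
#' calcified lesions and rare native intraluminal artifact voxels. Every
#' study's systematic enhancement loss follows the common `ratio_mean`;
#' study-level measurement variability enters as an additive perturbation of
#' the arterial fat volume with constant SD in cm³ across studies
#' (`volume_noise_sd` times the fat volume of a nominal 22 mm study),
#' matching the roughly constant limits of agreement such paired measurements
#' show across aorta sizes. Covariates are generated independently of the
#' enhancement effect (null confounding) unless `confounded_kv_effect` is
#' nonzero, which adds a kV-dependent shift to the true ratio for power
#' studies of the confounder screen.
#'
#' @param n number of studies.
#' @param seed cohort seed; per-study seeds are derived from it.
#' @param ratio_mean mean true native/arterial fat-volume ratio.
#' @param volume_noise_sd SD of the additive arterial fat-volume
#'   perturbation, as a fraction of a nominal (22 mm, mean fat fraction)
#'   study's fat volume.
#' @param n_slices slices per study.
#' @param pixel_mm in-plane pixel size.
#' @param prop_aaa proportion of aneurysmal studies.
#' @param confounded_kv_effect additive shift of the true ratio per 20 kV
#'   above 100 kV (0 = null confounding).
#' @return Tibble of per-study parameters, one row per study.
#' @export
generate_cohort_specs <- function(n, seed = 1L,
                                  ratio_mean = 1.1057,
                                  volume_noise_sd = 0.015,
                                  n_slices = 10,
                                  pixel_mm = 0.7,
                                  prop_aaa = 14 / 101,
                                  confounded_kv_effect = 0) {
  stopifnot(n >= 2)
  set.seed(seed)
  # fat volume of a nominal 22 mm, mean-fat-fraction study (3/2 mm slices)
  nominal_fat_cm3 <- pi * ((11 + 5)^2 - 11^2) * 0.467 * n_slices * 2 / 1000
  loss_noise_sd_cm3 <- volume_noise_sd * nominal_fat_cm3
  is_aaa <- stats::runif(n) < prop_aaa
  diameter <- ifelse(
    is_aaa,
    pmin(pmax(stats::rlnorm(n, log(48), 0.35), 31), 110),
    pmin(pmax(stats::rnorm(n, 22.3, 2.7), 15.6), 29.4)
  )
  kv <- sample(c(100, 120, 130), n, replace = TRUE, prob = c(14, 86, 1))
  thick5 <- stats::runif(n) < 5 / 101
  fat_fraction <- pmin(pmax(stats::rbeta(n, 1.91, 2.19), 0.05), 0.9)
  true_ratio <- rep(ratio_mean, n)
  if (confounded_kv_effect != 0) {
    true_ratio <- true_ratio + confounded_kv_effect * (kv - 100) / 20
  }
  tibble::tibble(
    study_id = sprintf("S%03d", seq_len(n)),
    is_aaa = is_aaa,
    max_diameter = diameter,
    kv = kv,
    slice_thickness = ifelse(thick5, 5, 3),
    slice_increment = ifelse(thick5, 4, 2),
    n_slices = n_slices,
    pixel_mm = pixel_mm,
    fat_fraction = fat_fraction,
    true_ratio = pmax(true_ratio, 1),
    extra_loss_voxels = stats::rnorm(n, 0, loss_noise_sd_cm3) /
      (pixel_mm^2 * ifelse(thick5, 4, 2) / 1000),
    arterial_gradient_hu = abs(stats::rnorm(n, 0, 20)),
    lumen_arterial_mean = pmin(pmax(stats::rnorm(n, 315.9, 82.3), 195), 612),
    n_calc_lesions = stats::rpois(n, 1.5),
    n_artifact_voxels = ifelse(stats::runif(n) < 0.545, 0L,
                               stats::rgeom(n, 0.35) + 1L),
    study_seed = sample.int(.Machine$integer.max, n)
  )
}

# Per-slice diameter profile: constant for non-AAA, fusiform bulge for AAA.
diameter_profile <- function(max_diameter, is_aaa, n_slices) {
  if (!is_aaa) return(rep(max_diameter, n_slices))
  neck <- min(22, max_diameter)
  z <- seq_len(n_slices)
  z0 <- (n_slices + 1) / 2
  neck + (max_diameter - neck) * exp(-((z - z0) / (n_slices / 3.5))^2)
}

#' Build the phantom spec for one cohort row
#'
#' @param row one row of [generate_cohort_specs()] output.
#' @return A [phantom_spec()].
#' @export
cohort_row_spec <- function(row) {
  phantom_spec(
    n_slices = row$n_slices,
    pixel_mm = row$pixel_mm,
    slice_thickness_mm = row$slice_thickness,
    slice_increment_mm = row$slice_increment,
    aortic_diameter_mm = diameter_profile(row$max_diameter, row$is_aaa, row$n_slices),
    lumen_arterial_hu = c(row$lumen_arterial_mean, 22),
    arterial_gradient_hu = row$arterial_gradient_hu,
    fat_fraction = row$fat_fraction,
    volume_loss_ratio = row$true_ratio,
    extra_loss_voxels = row$extra_loss_voxels,
    n_calc_lesions = row$n_calc_lesions,
    n_artifact_voxels = row$n_artifact_voxels,
    seed = row$study_seed
  )
}
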