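test_that("lumen sampling recovers homogeneous and Gaussian attenuation", {
  # homogeneous lumen: identical means for all sample diameters, SD 0
  vol <- flat_volume(c(60, 60, 3), hu = 316, spacing = 1, phase = "arterial")
  rois <- ellipse_roi(1:3, 30, 30, 20, 20)
  means <- sapply(c(8, 10, 12), function(d) {
    sample_lumen(vol, rois, "mid", d)$mean_hu
  })
  expect_equal(means, rep(316, 3))
  expect_equal(sample_lumen(vol, rois, "mid", 8)$sd_hu, 0)

  # Gaussian lumen 316 +/- 22: recovered within sampling error
  set.seed(77)
  st <- generate_phantom_pair(phantom_spec(aortic_diameter_mm = 40, seed = 88))
  s <- sample_lumen(st$arterial, st$aortic_rois, "mid", 12)
  expect_gt(s$n_voxels, 200)
  expect_lt(abs(s$mean_hu - 316), 3)
  expect_lt(abs(s$sd_hu - 22), 3)
})

test_that("a sample ROI larger than the lumen is shrunk with a warning", {
  vol <- flat_volume(c(30, 30, 1), hu = 316, phase = "arterial")
  rois <- ellipse_roi(1, 15, 15, 3, 3)
  expect_warning(s <- sample_lumen(vol, rois, "infrarenal", 12), "shrunk")
  expect_equal(s$diameter_mm, 6)
})

test_that("longitudinal variability follows (max - min)/mean and its symmetries", {
  expect_equal(longitudinal_variability(c(300, 330, 360)), 60 / 330)
  expect_equal(longitudinal_variability(c(330, 330, 330)), 0)
  v <- c(280, 350, 310)
  expect_equal(longitudinal_variability(v), longitudinal_variability(rev(v)))
  expect_equal(longitudinal_variability(v), longitudinal_variability(v[c(2, 1, 3)]))
  expect_equal(longitudinal_variability(3 * v), longitudinal_variability(v))
  expect_error(longitudinal_variability(c(300, 330)), "three")
  expect_error(longitudinal_variability(c(-400, 100, 100)), "positive")
})

test_that("noise exclusion uses a strict 35 HU cutoff", {
  expect_true(noise_exclude(36))
  expect_false(noise_exclude(35))
  expect_false(noise_exclude(21.7))
  expect_identical(noise_exclude(c(10, 40)), c(FALSE, TRUE))
})

test_that("calcium scoring reproduces the per-lesion area-times-weight rule", {
  # one 5-voxel lesion at 0.8 mm^2 pixels, peak 320 HU -> 4 mm^2 * 3 = 12
  vol <- ct_volume(array(0, c(10, 10, 1)), spacing_xy = c(0.8, 1),
                   slice_thickness = 3, slice_increment = 2, phase = "native")
  vol$voxels[3, 3:6, 1] <- 150
  vol$voxels[3, 7, 1] <- 320
  mask <- array(TRUE, c(10, 10, 1))
  sc <- agatston_score(vol, mask)
  expect_equal(sc$agatston, 12)
  expect_equal(sc$lesion_count, 1L)

  # no voxel over threshold
  expect_equal(agatston_score(flat_volume(c(5, 5, 1), hu = 50), array(TRUE, c(5, 5, 1)))$agatston, 0)

  # doubling the area at fixed peak doubles the contribution
  vol2 <- vol
  vol2$voxels[4, 3:6, 1] <- 150
  vol2$voxels[4, 7, 1] <- 150
  expect_equal(agatston_score(vol2, mask)$agatston, 24)

  # lesions below 1 mm^2 are ignored
  tiny <- flat_volume(c(10, 10, 1), hu = 0, spacing = 0.7)
  tiny$voxels[5, 5, 1] <- 500          # 0.49 mm^2 single voxel
  expect_equal(agatston_score(tiny, array(TRUE, c(10, 10, 1)))$agatston, 0)

  expect_error(agatston_score(flat_volume(phase = "arterial"), array(TRUE, c(6, 6, 1))),
               "unenhanced")
})

test_that("lesion labelling matches an independent graph-components oracle", {
  skip_if_not_installed("igraph")
  oracle_score <- function(vol, mask, threshold = 130) {
    px <- prod(vol$spacing_xy)
    total <- 0
    for (s in seq_len(dim(vol$voxels)[3])) {
      sl <- vol$voxels[, , s]
      fg <- which(mask[, , s] & sl >= threshold)
      if (length(fg) == 0) next
      nr <- nrow(sl)
      coords <- cbind((fg - 1) %% nr + 1, (fg - 1) %/% nr + 1)
      edges <- c()
      if (length(fg) > 1) {
        for (i in 1:(length(fg) - 1)) for (j in (i + 1):length(fg)) {
          if (max(abs(coords[i, ] - coords[j, ])) <= 1) edges <- c(edges, i, j)
        }
      }
      g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
      if (length(edges)) g <- igraph::add_edges(g, edges)
      comp <- igraph::components(g)$membership
      for (lb in unique(comp)) {
        idx <- fg[comp == lb]
        area <- length(idx) * px
        if (area < 1) next
        peak <- max(sl[idx])
        w <- if (peak >= 400) 4 else if (peak >= 300) 3 else if (peak >= 200) 2 else 1
        total <- total + area * w
      }
    }
    total
  }
  set.seed(5)
  for (k in 1:5) {
    vol <- flat_volume(c(20, 20, 2), hu = 0, spacing = 1.1)
    n_hot <- 30
    idx <- sample(length(vol$voxels), n_hot)
    vol$voxels[idx] <- runif(n_hot, 130, 600)
    mask <- array(TRUE, dim(vol$voxels))
    expect_equal(agatston_score(vol, mask)$agatston, oracle_score(vol, mask))
  }
})

test_that("contrast profile reflects the arterial longitudinal gradient", {
  st <- generate_phantom_pair(phantom_spec(arterial_gradient_hu = 60, seed = 12,
                                           aortic_diameter_mm = 30))
  qc <- contrast_profile(st$arterial, st$aortic_rois, diameter_mm = 8)
  expect_gt(qc$bifurcation_hu, qc$infrarenal_hu)
  expect_equal(qc$longitudinal_variability,
               (max(c(qc$infrarenal_hu, qc$mid_hu, qc$bifurcation_hu)) -
                min(c(qc$infrarenal_hu, qc$mid_hu, qc$bifurcation_hu))) /
                 qc$mean_contrast)
  expect_lt(abs(qc$mean_contrast - 316), 10)
})
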