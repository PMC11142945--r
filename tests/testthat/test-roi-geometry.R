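# brute-force boundary-inclusive point-in-ellipse scan, independent of the
# vectorised rasteriser
raster_oracle <- function(cx, cy, a, b, theta, dim_xy, spacing) {
  out <- matrix(FALSE, dim_xy[1], dim_xy[2])
  for (i in seq_len(dim_xy[1])) {
    for (j in seq_len(dim_xy[2])) {
      x <- (j - 0.5) * spacing; y <- (i - 0.5) * spacing
      dx <- x - cx; dy <- y - cy
      u <- (dx * cos(theta) + dy * sin(theta)) / a
      v <- (-dx * sin(theta) + dy * cos(theta)) / b
      out[i, j] <- u^2 + v^2 <= 1
    }
  }
  out
}

test_that("periaortic expansion adds exactly 5 mm per semi-axis, keeping centre and rotation", {
  circ <- ellipse_roi(1, 30, 30, 12, 12)
  out <- expand_to_periaortic(circ)
  expect_equal(out$a, 17); expect_equal(out$b, 17)
  ell <- ellipse_roi(2, 25, 28, 15, 10, 0.3)
  out2 <- expand_to_periaortic(ell)
  expect_equal(c(out2$a, out2$b, out2$theta, out2$cx, out2$cy),
               c(20, 15, 0.3, 25, 28))
  expect_error(expand_to_periaortic(ell, margin_mm = -1))
})

test_that("rasterisation agrees with the exhaustive point-in-ellipse oracle", {
  set.seed(42)
  for (k in 1:6) {
    a <- runif(1, 3, 14); b <- runif(1, 3, 14); th <- runif(1, 0, pi)
    cx <- runif(1, 15, 25); cy <- runif(1, 15, 25)
    got <- rasterize_ellipse(cx, cy, a, b, th, c(40, 40), 1)
    expect_identical(got, raster_oracle(cx, cy, a, b, th, c(40, 40), 1))
  }
  # boundary-inclusive circle on integer grid
  got <- rasterize_ellipse(10.5, 10.5, 5, 5, 0, c(21, 21), 1)
  expect_identical(got, raster_oracle(10.5, 10.5, 5, 5, 0, c(21, 21), 1))
})

test_that("degenerate and symmetric rasterisation cases behave", {
  # half-pixel ellipse captures exactly the voxel whose centre it sits on
  m <- rasterize_ellipse(5.5, 5.5, 0.5, 0.5, 0, c(11, 11), 1)
  expect_equal(sum(m), 1L)
  expect_true(m[6, 6])
  # rotation by pi leaves membership unchanged
  m0 <- rasterize_ellipse(20, 20, 9, 4, 0.7, c(40, 40), 1)
  m1 <- rasterize_ellipse(20, 20, 9, 4, 0.7 + pi, c(40, 40), 1)
  expect_identical(m0, m1)
})

test_that("ring mask is the exact set difference and its volume matches the analytic annulus", {
  n <- 50
  inner <- rasterize_ellipse(17.5, 17.5, 10, 10, 0, c(n, n), 0.7)
  outer <- rasterize_ellipse(17.5, 17.5, 15, 15, 0, c(n, n), 0.7)
  ring <- build_ring(array(inner, c(n, n, 1)), array(outer, c(n, n, 1)))
  expect_equal(sum(ring), sum(outer) - sum(inner))
  expect_false(any(ring & array(inner, c(n, n, 1))))
  expect_identical(ring | array(inner, c(n, n, 1)), array(outer, c(n, n, 1)))

  # identical masks give an empty ring; inverted containment errors
  expect_equal(sum(build_ring(array(inner, c(n, n, 1)), array(inner, c(n, n, 1)))), 0L)
  expect_error(build_ring(array(outer, c(n, n, 1)), array(inner, c(n, n, 1))),
               "outside the periaortic")

  # 10-slice annulus volume vs pi (R^2 - r^2) * length at 0.7 mm pixels
  vol <- flat_volume(c(n, n, 10), hu = 0, spacing = 0.7, thickness = 3, increment = 2)
  ring10 <- array(outer & !inner, c(n, n, 10))
  analytic <- pi * (15^2 - 10^2) * 10 * 2 / 1000
  expect_lt(abs(volume_of(ring10, vol) - analytic) / analytic, 0.02)
})

test_that("maximum aortic diameter is the shorter axis of the largest disc", {
  expect_equal(measure_max_diameter(ellipse_roi(1:4, 30, 30, 11, 11)), 22)
  rois <- ellipse_roi(1:2, 30, 30, c(20, 18), c(15, 17))
  expect_equal(measure_max_diameter(rois), 34)  # 18*17 > 20*15
  expect_equal(measure_max_diameter(ellipse_roi(1, 40, 40, 30, 25)), 50)
  expect_error(measure_max_diameter(ellipse_roi(integer(0), numeric(0),
                                                numeric(0), numeric(0), numeric(0))))
})

test_that("mask construction flags clipped slices and truncates at image bounds", {
  vol <- flat_volume(c(30, 30, 1), spacing = 1)
  near_edge <- ellipse_roi(1, 6, 15, 4, 4)   # periaortic radius 9 > cx 6
  expect_warning(rois <- build_roi_masks(vol, near_edge), "clipped")
  expect_true(rois$clipped[1])
  expect_equal(sum(rois$periaortic_mask),
               sum(raster_oracle(6, 15, 9, 9, 0, c(30, 30), 1)))
})

test_that("periaortic masks are constructed once and identical for both phases", {
  st <- generate_phantom_pair(tiny_spec(seed = 9))
  rois_n <- build_roi_masks(st$native, st$aortic_rois)
  rois_a <- build_roi_masks(st$arterial, st$aortic_rois)
  expect_identical(rois_n$periaortic_mask, rois_a$periaortic_mask)
  expect_identical(rois_n$ring_mask, rois_a$ring_mask)
})

test_that("ROI tables survive a JSON round trip", {
  rois <- ellipse_roi(1:3, c(30, 31, 32), 30, c(11, 12, 13), c(10, 11, 12), 0.1)
  path <- file.path(withr::local_tempdir(), "rois.json")
  write_roi_json(rois, path)
  expect_equal(as.data.frame(read_roi_json(path)), as.data.frame(rois))
})
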