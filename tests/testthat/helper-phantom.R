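# Small phantom configurations used across the suite; kept tiny so the
# brute-force oracles stay cheap.

tiny_spec <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(n_slices = 3, aortic_diameter_mm = 18, seed = seed)
  do.call(phantom_spec, utils::modifyList(defaults, args))
}

# Minimal hand-built ROI-mask object (class contract of build_roi_masks)
# whose ring consists of exactly the given voxel indices of a flat volume.
manual_roi_masks <- function(dim3, aortic_idx, ring_idx) {
  aortic <- array(FALSE, dim = dim3); aortic[aortic_idx] <- TRUE
  peri <- aortic; peri[ring_idx] <- TRUE
  structure(
    list(aortic = NULL, periaortic = NULL,
         aortic_mask = aortic, periaortic_mask = peri,
         ring_mask = peri & !aortic, clipped = FALSE, margin_mm = 5),
    class = "aorto_periaortic_roi"
  )
}

flat_volume <- function(dim3 = c(6, 6, 1), hu = 0, spacing = 1,
                        thickness = 2, increment = 2, phase = "native") {
  ct_volume(array(hu, dim = dim3), spacing, thickness, increment, phase)
}
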