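#' Render a short-axis segmentation stack from the phantom
#'
#' Emulates the SSFP volumetric input: per-phase, per-slice LV cavity masks
#' with known ground-truth volume. At each of `n_phases_ssfp` reconstructed
#' phases (times `(j-1) * RR / n`), the phase volume is the LV volume curve
#' boxcar-blurred by the SSFP true temporal resolution. The cavity is a
#' prolate spheroid whose long axis spans the slice slab; its short semi-axis
#' is chosen per phase so that the sum of sliced-disc volumes equals the
#' phase volume exactly. Exact-area mode stores the analytic disc areas;
#' raster mode additionally fills pixelated circular masks (subject to the
#' usual rasterisation error).
#'
#' @param spec a [phantom_spec()].
#' @param raster if `TRUE`, fill per-slice pixel masks as well as storing
#'   analytic areas.
#' @param blur_ms boxcar blur width, ms; defaults to
#'   `spec$true_temporal_resolution_ssfp`.
#' @return An object of class `segmentation_stack`: `analytic_slice_areas`
#'   (mm2, slices x phases), `masks` (logical x-y-slice-phase array, raster
#'   mode only), slice geometry, `phase_times` (ms), `rr_ms`, and
#'   `phase_volumes`, the ground-truth (blurred) volume per phase in mL.
#' @export
render_ssfp_stack <- function(spec, raster = FALSE, blur_ms = NULL) {
  validate_phantom_spec(spec)
  blur_ms <- blur_ms %||% spec$true_temporal_resolution_ssfp
  wf <- make_volume_waveform(spec)
  n <- spec$n_phases_ssfp
  times <- (seq_len(n) - 1) * wf$rr_ms / n
  v_b <- if (blur_ms > 0) temporal_blur(wf$V, blur_ms)(times) else wf$V(times)

  dz <- spec$slice_thickness + spec$slice_gap           # mm per slice
  c_ax <- spec$n_slices * dz / 2                        # long semi-axis, mm
  z <- -c_ax + (seq_len(spec$n_slices) - 0.5) * dz      # slice centres
  shape <- 1 - z^2 / c_ax^2                             # relative disc areas
  # short semi-axis^2 per phase so that sum(pi a^2 shape) * dz = V * 1000 mm3
  a2 <- v_b * 1000 / (pi * dz * sum(shape))
  areas <- outer(shape, a2) * pi                        # mm2, slices x phases

  max_r <- sqrt(max(areas) / pi)
  if (max_r > spec$matrix * spec$pixel_size / 2)
    stop("render_ssfp_stack: cavity radius ", round(max_r, 1),
         " mm exceeds the image half-extent; enlarge matrix or pixel_size",
         call. = FALSE)

  masks <- NULL
  if (raster) {
    m <- spec$matrix
    ctr <- (m + 1) / 2
    ix <- seq_len(m)
    d2 <- outer((ix - ctr)^2, (ix - ctr)^2, "+") * spec$pixel_size^2
    masks <- array(FALSE, dim = c(m, m, spec$n_slices, n))
    for (j in seq_len(n))
      for (s in seq_len(spec$n_slices))
        masks[, , s, j] <- d2 <= areas[s, j] / pi
  }

  structure(list(
    analytic_slice_areas = areas,
    masks = masks,
    pixel_size = spec$pixel_size,
    slice_thickness = spec$slice_thickness,
    slice_gap = spec$slice_gap,
    phase_times = times,
    rr_ms = wf$rr_ms,
    phase_volumes = v_b,
    blur_ms = blur_ms
  ), class = "segmentation_stack")
}
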