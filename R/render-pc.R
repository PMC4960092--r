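#' Render a velocity-encoded PC cine series from the phantom
#'
#' Emulates through-plane velocity mapping at the mitral valve orifice.
#' For each of `n_phases_pc` reconstructed phases at times `(j-1) * RR / n`,
#' the mitral inflow rate (boxcar-blurred by the true temporal resolution)
#' is converted to a velocity `v = flow / orifice_area` (cm/s) and painted
#' uniformly over a disc ROI whose pixel count matches the orifice area;
#' background velocity is zero. Per-pixel Gaussian noise is added, and
#' velocities are stored as signed integers,
#' `round(v / venc * phase_scale)`, clipped to full scale (a wrap mode that
#' aliases instead of clipping is available). The magnitude images are a
#' bright disc on a dark background, as a tracing aid only.
#'
#' @param spec a [phantom_spec()].
#' @param blur_ms boxcar blur width, ms; defaults to
#'   `spec$true_temporal_resolution_pc`. Pass the spatial-PC width
#'   (e.g. 100.8) to emulate the low-temporal-resolution acquisition.
#' @param method label stored on the series (`"temporal_pc"`,
#'   `"spatial_pc"`, ...), carried into downstream PFR results.
#' @param wrap if `TRUE`, velocities beyond VENC alias (wrap around) instead
#'   of clipping.
#' @return An object of class `velocity_series`: lists of per-phase integer
#'   phase images and magnitude images, `venc`, `phase_scale`, `pixel_size`,
#'   `phase_times` (ms), `rr_ms`, the `ground_truth_roi` mask, the method
#'   label, and (for oracle use) `blurred_inflow`, the noise-free blurred
#'   inflow rate (mL/s) at each phase time.
#' @export
render_pc_series <- function(spec, blur_ms = NULL, method = "temporal_pc",
                             wrap = FALSE) {
  validate_phantom_spec(spec)
  blur_ms <- blur_ms %||% spec$true_temporal_resolution_pc
  wf <- make_volume_waveform(spec)
  n <- spec$n_phases_pc
  times <- (seq_len(n) - 1) * wf$rr_ms / n
  inflow_b <- temporal_blur(wf$inflow, blur_ms)
  flows <- inflow_b(times)                       # mL/s
  v_roi <- flows / spec$orifice_area             # cm/s

  roi <- disc_roi(spec$matrix, spec$pixel_size, spec$orifice_area)
  if (max(abs(v_roi)) > spec$venc)
    warning("render_pc_series: peak velocity ", round(max(abs(v_roi)), 1),
            " cm/s exceeds VENC ", spec$venc,
            if (wrap) " cm/s; velocities wrap (alias)"
            else " cm/s; stored values clip at full scale",
            call. = FALSE)

  m <- spec$matrix
  mag <- matrix(0.05, m, m)
  mag[roi] <- 1
  phase_images <- vector("list", n)
  with_seed(spec$seed, {
    for (j in seq_len(n)) {
      v <- matrix(0, m, m)
      v[roi] <- v_roi[j]
      if (spec$noise_sd_velocity > 0)
        v <- v + matrix(rnorm(m * m, sd = spec$noise_sd_velocity), m, m)
      phase_images[[j]] <- encode_phase(v, spec$venc, spec$phase_scale, wrap)
    }
  })

  structure(list(
    phase_images = phase_images,
    magnitude_images = rep(list(mag), n),
    venc = spec$venc,
    phase_scale = spec$phase_scale,
    pixel_size = spec$pixel_size,
    phase_times = times,
    rr_ms = wf$rr_ms,
    ground_truth_roi = roi,
    method = method,
    blur_ms = blur_ms,
    blurred_inflow = flows,
    seed = spec$seed
  ), class = "velocity_series")
}

# Disc ROI as the N grid pixels nearest the image centre, with
# N = round(area_cm2 * 100 / pixel_area_mm2), so that pixel-count area
# matches the nominal orifice area as closely as the grid allows.
disc_roi <- function(matrix_size, pixel_size, area_cm2) {
  n_px <- round(area_cm2 * 100 / pixel_size^2)
  if (n_px < 1 || n_px > matrix_size^2)
    stop("disc_roi: orifice does not fit the image matrix", call. = FALSE)
  ctr <- (matrix_size + 1) / 2
  ix <- seq_len(matrix_size)
  d2 <- outer((ix - ctr)^2, (ix - ctr)^2, "+")
  thr <- sort(d2)[n_px]
  roi <- d2 < thr
  # deterministic tie-break at the boundary radius: fill in array order
  short <- n_px - sum(roi)
  if (short > 0) roi[which(d2 == thr)[seq_len(short)]] <- TRUE
  roi
}

encode_phase <- function(v, venc, phase_scale, wrap = FALSE) {
  s <- v / venc * phase_scale
  if (wrap) {
    # alias into (-phase_scale, phase_scale]
    s <- ((s + phase_scale) %% (2 * phase_scale)) - phase_scale
  }
  s <- round(s)
  s[s > phase_scale] <- phase_scale
  s[s < -phase_scale] <- -phase_scale
  mode(s) <- "integer"
  s
}
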