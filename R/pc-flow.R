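#' Decode stored phase values to velocities
#'
#' In PC cine imaging the stored pixel phase is proportional to the
#' through-plane velocity, with full scale mapping to the velocity
#' sensitivity threshold (VENC): `v = stored / phase_scale * venc`.
#'
#' @param phase_image integer matrix of stored phase values.
#' @param venc velocity sensitivity threshold, cm/s.
#' @param phase_scale integer full-scale stored value.
#' @return Velocity map, cm/s (same dimensions as the input).
#' @export
#' @examples
#' decode_velocity(matrix(4096L), venc = 150, phase_scale = 4096L)  # 150 cm/s
decode_velocity <- function(phase_image, venc, phase_scale) {
  if (phase_scale <= 0)
    stop("decode_velocity: phase_scale must be positive", call. = FALSE)
  if (any(abs(phase_image) > phase_scale))
    stop("decode_velocity: stored phase values exceed full scale ",
         phase_scale, call. = FALSE)
  phase_image / phase_scale * venc
}

#' Flow through a region of interest
#'
#' The mitral flow volume (mL/s) is the ROI area multiplied by the absolute
#' value of the mean velocity over the ROI:
#' `area_cm2 = n_pixels * pixel_size^2 / 100`, `flow = area_cm2 * |mean(v)|`
#' (cm2 x cm/s = cm3/s = mL/s).
#'
#' @param velocity_map velocity matrix, cm/s.
#' @param roi logical mask, same dimensions; must be non-empty.
#' @param pixel_size in-plane pixel size, mm.
#' @return Flow in mL/s (non-negative).
#' @export
roi_flow <- function(velocity_map, roi, pixel_size) {
  if (!any(roi)) stop("roi_flow: ROI is empty", call. = FALSE)
  if (pixel_size <= 0)
    stop("roi_flow: pixel_size must be positive", call. = FALSE)
  area_cm2 <- sum(roi) * pixel_size^2 / 100
  area_cm2 * abs(mean(velocity_map[roi]))
}

#' ROI flow at every reconstructed phase
#'
#' @param series a [render_pc_series()] result (or any `velocity_series`).
#' @param roi logical mask; defaults to the series' ground-truth ROI.
#' @param phases 1-based phase indices to evaluate.
#' @return A data.frame with columns `phase`, `time_ms`, `flow_ml_s`.
#' @export
flow_curve <- function(series, roi = NULL, phases = NULL) {
  roi <- roi %||% series$ground_truth_roi
  phases <- phases %||% seq_along(series$phase_images)
  flows <- vapply(phases, function(j) {
    v <- decode_velocity(series$phase_images[[j]], series$venc,
                         series$phase_scale)
    roi_flow(v, roi, series$pixel_size)
  }, numeric(1))
  data.frame(phase = phases, time_ms = series$phase_times[phases],
             flow_ml_s = flows)
}

#' Locate the peak filling phase within an early-filling window
#'
#' Automates the operator's visual choice of the peak filling phase: returns
#' the phase index with maximal ROI flow over the given index window. Ties
#' are broken toward the earliest phase of the window.
#'
#' @inheritParams flow_curve
#' @param window 1-based phase-index vector (e.g. `20:40`) to search.
#' @return The 1-based phase index of the flow maximum.
#' @export
find_visual_peak <- function(series, roi = NULL, window = NULL) {
  window <- window %||% seq_along(series$phase_images)
  if (length(window) == 0L)
    stop("find_visual_peak: window is empty", call. = FALSE)
  if (any(window < 1L) || any(window > length(series$phase_images)))
    stop("find_visual_peak: window outside the series", call. = FALSE)
  fc <- flow_curve(series, roi, phases = window)
  fc$phase[which.max(fc$flow_ml_s)]   # which.max: earliest on ties
}

#' PFR by the three-phase rule on a PC series
#'
#' Evaluates the ROI flow at the visual peak filling phase and at the phases
#' immediately before and after it; PFR is the maximum of the three and the
#' peak filling time is the phase time of the argmax. Ties are broken toward
#' the centre phase. Boundary indices (first or last phase) are an error —
#' early filling never abuts the cycle boundary physiologically, so
#' wraparound is refused rather than silently applied.
#'
#' @inheritParams flow_curve
#' @param visual_peak_index 1-based index of the visually determined peak
#'   filling phase; must satisfy `2 <= k <= n_phases - 1`.
#' @return An object of class `pfr_result`: `pfr` (mL/s),
#'   `peak_filling_time` (ms from cycle start), `method`, and `diagnostics`
#'   (the three evaluated flows and indices).
#' @export
pfr_from_three_phases <- function(series, roi = NULL, visual_peak_index) {
  n <- length(series$phase_images)
  k <- visual_peak_index
  if (k < 2L || k > n - 1L)
    stop("pfr_from_three_phases: visual_peak_index ", k,
         " is at the sequence boundary (need 2 <= k <= ", n - 1L,
         "); no wraparound is applied", call. = FALSE)
  fc <- flow_curve(series, roi, phases = (k - 1L):(k + 1L))
  # preference order: centre, then earlier, then later
  pref <- c(2L, 1L, 3L)
  best <- pref[which.max(fc$flow_ml_s[pref] >= max(fc$flow_ml_s))]
  pfr_result(
    pfr = fc$flow_ml_s[best],
    peak_filling_time = fc$time_ms[best],
    method = series$method %||% "pc",
    diagnostics = list(phases = fc$phase, flows = fc$flow_ml_s,
                       selected = fc$phase[best])
  )
}

pfr_result <- function(pfr, peak_filling_time, method, diagnostics = list()) {
  stopifnot(pfr >= 0)
  structure(list(pfr = pfr, peak_filling_time = peak_filling_time,
                 method = method, diagnostics = diagnostics),
            class = "pfr_result")
}

#' @export
print.pfr_result <- function(x, ...) {
  cat(sprintf("<pfr_result> %s: PFR %.1f mL/s at %.1f ms\n",
              x$method, x$pfr, x$peak_filling_time))
  invisible(x)
}
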