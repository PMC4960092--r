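#' LV volume of one phase from a segmentation stack
#'
#' Simpson-style slice summation: the cavity volume is the sum over slices of
#' slice area times the inter-slice distance (thickness + gap). Areas come
#' from the analytic per-slice areas when the stack carries them (exact-area
#' mode) or from mask pixel counts times the pixel area (raster mode).
#'
#' @param stack a `segmentation_stack` (see [render_ssfp_stack()]).
#' @param phase_index 1-based phase index.
#' @param source `"auto"` (analytic areas if present), `"exact"` or
#'   `"raster"`.
#' @param basal_fraction fraction (0, 1] of the basal slice (slice 1) volume
#'   attributed to the LV, emulating the long-axis division of ventricle
#'   from atrium/outflow within the basal slice; default 1.
#' @return Volume in mL.
#' @export
stack_volume <- function(stack, phase_index,
                         source = c("auto", "exact", "raster"),
                         basal_fraction = 1) {
  source <- match.arg(source)
  n_phases <- length(stack$phase_times)
  if (phase_index < 1L || phase_index > n_phases)
    stop("stack_volume: phase ", phase_index, " not in stack (1..",
         n_phases, ")", call. = FALSE)
  if (basal_fraction <= 0 || basal_fraction > 1)
    stop("stack_volume: basal_fraction must be in (0, 1]", call. = FALSE)
  use_exact <- switch(source,
    auto = !is.null(stack$analytic_slice_areas),
    exact = TRUE, raster = FALSE)
  if (use_exact) {
    if (is.null(stack$analytic_slice_areas))
      stop("stack_volume: stack has no analytic slice areas", call. = FALSE)
    areas <- stack$analytic_slice_areas[, phase_index]     # mm2
  } else {
    if (is.null(stack$masks))
      stop("stack_volume: stack has no raster masks", call. = FALSE)
    areas <- apply(stack$masks[, , , phase_index, drop = FALSE], 3, sum) *
      stack$pixel_size^2
  }
  areas[1] <- areas[1] * basal_fraction
  dz <- stack$slice_thickness + stack$slice_gap            # mm
  sum(areas) * dz / 1000                                   # mm3 -> mL
}

#' SSFP analysis window from the PC peak filling phase
#'
#' With 64 PC phases and 32 SSFP phases reconstructed over the same cycle,
#' SSFP phase n coincides with PC phase 2n - 1. When the peak filling
#' appears at an odd PC phase 2n - 1, the five SSFP phases
#' {n-2, ..., n+2} centred on it are analysed; at an even PC phase 2n the
#' peak falls midway between SSFP phases n and n + 1, and the six phases
#' {n-2, ..., n+3} are used. Windows that would extend past the first or
#' last SSFP phase are an error (clamping would bias the fit window
#' asymmetrically).
#'
#' @param pc_peak_index 1-based PC phase index of peak filling.
#' @param n_pc,n_ssfp reconstructed phase counts; `n_pc == 2 * n_ssfp`.
#' @return Integer vector of 1-based SSFP phase indices (length 5 or 6).
#' @export
#' @examples
#' phase_window_from_pc_peak(7, 64, 32)   # odd:  2 3 4 5 6
#' phase_window_from_pc_peak(8, 64, 32)   # even: 2 3 4 5 6 7
phase_window_from_pc_peak <- function(pc_peak_index, n_pc, n_ssfp) {
  if (n_pc != 2L * n_ssfp)
    stop("phase_window_from_pc_peak: need n_pc == 2 * n_ssfp", call. = FALSE)
  if (pc_peak_index < 1L || pc_peak_index > n_pc)
    stop("phase_window_from_pc_peak: pc_peak_index out of range", call. = FALSE)
  if (pc_peak_index %% 2L == 1L) {
    n <- (pc_peak_index + 1L) %/% 2L
    win <- (n - 2L):(n + 2L)
  } else {
    n <- pc_peak_index %/% 2L
    win <- (n - 2L):(n + 3L)
  }
  if (win[1] < 1L || win[length(win)] > n_ssfp)
    stop("phase_window_from_pc_peak: window ", win[1], "..", win[length(win)],
         " extends outside SSFP phases 1..", n_ssfp,
         "; peak too close to the cycle boundary", call. = FALSE)
  win
}

#' First-derivative curve of a time-volume curve
#'
#' Change rates of the LV volume between consecutive phases, plotted against
#' the interval midpoints: `rate_i = (V[i+1] - V[i]) / (t[i+1] - t[i]) * 1000`
#' (volumes mL, times ms, rates mL/s).
#'
#' @param tvc list or data.frame with `phase_times` (ms) and `volumes` (mL).
#' @return A list of class `derivative_curve` with `midpoint_times` (ms) and
#'   `rates` (mL/s).
#' @export
derivative_curve <- function(tvc) {
  t <- tvc$phase_times
  v <- tvc$volumes
  if (length(t) < 2L)
    stop("derivative_curve: need at least two points", call. = FALSE)
  if (any(diff(t) <= 0))
    stop("derivative_curve: times must be strictly increasing", call. = FALSE)
  structure(list(
    midpoint_times = (t[-length(t)] + t[-1]) / 2,
    rates = diff(v) / diff(t) * 1000
  ), class = "derivative_curve")
}

#' Least-squares parabola through a derivative curve
#'
#' Fits `rate = a t^2 + b t + c` by ordinary least squares (times are
#' centred at their mean before solving, for conditioning; coefficients are
#' mapped back to the raw time axis). The fit is the peak-preserving smoother
#' for the filling-rate curve: the vertex gives PFR and the peak filling
#' time. A fit without a concave peak (curvature `a >= 0`, or curvature too
#' small to produce a meaningful vertex over the fitted window) is an error.
#'
#' @param dc a [derivative_curve()] (or list with `midpoint_times`, `rates`).
#' @return A list of class `parabola_fit`: coefficients `a`, `b`, `c`,
#'   `vertex_time` (ms), `vertex_rate` (mL/s), and `rss`.
#' @export
fit_parabola <- function(dc) {
  t <- dc$midpoint_times
  y <- dc$rates
  if (length(t) < 3L)
    stop("fit_parabola: need at least three points", call. = FALSE)
  tbar <- mean(t)
  tc <- t - tbar
  beta <- unname(qr.solve(cbind(1, tc, tc^2), y))
  a <- beta[3]
  b <- beta[2] - 2 * beta[3] * tbar
  cc <- beta[1] - beta[2] * tbar + beta[3] * tbar^2
  # degenerate: convex, flat, or curvature negligible over the fitted span
  span2 <- (max(t) - min(t))^2 / 4
  if (a >= 0 || abs(a) * span2 < 1e-9 * max(abs(y), 1))
    stop("fit_parabola: no concave peak (quadratic coefficient ",
         signif(a, 3), ")", call. = FALSE)
  vt <- -b / (2 * a)
  vr <- cc - b^2 / (4 * a)
  fitted <- a * t^2 + b * t + cc
  structure(list(a = a, b = b, c = cc,
                 vertex_time = vt, vertex_rate = vr,
                 rss = sum((y - fitted)^2)),
            class = "parabola_fit")
}

#' PFR by the SSFP volumetric pathway
#'
#' Composes the full SSFP chain: pick the 5- or 6-phase analysis window from
#' the temporal-PC peak index, compute the slice-stack volume at each phase,
#' form the first-derivative curve, fit the parabola, and read PFR and peak
#' filling time off its vertex.
#'
#' @inheritParams stack_volume
#' @param pc_peak_index 1-based PC phase index of peak filling (from
#'   [find_visual_peak()] on the temporal-PC series).
#' @return A `pfr_result` with `method = "ssfp"`; diagnostics carry the
#'   time-volume curve and the parabola fit.
#' @export
pfr_ssfp <- function(stack, pc_peak_index, source = c("auto", "exact", "raster"),
                     basal_fraction = 1) {
  source <- match.arg(source)
  n_ssfp <- length(stack$phase_times)
  win <- phase_window_from_pc_peak(pc_peak_index, 2L * n_ssfp, n_ssfp)
  vols <- vapply(win, function(j)
    stack_volume(stack, j, source = source, basal_fraction = basal_fraction),
    numeric(1))
  tvc <- list(phase_times = stack$phase_times[win], volumes = vols,
              phase_indices = win)
  fit <- fit_parabola(derivative_curve(tvc))
  pfr_result(
    pfr = fit$vertex_rate,
    peak_filling_time = fit$vertex_time,
    method = "ssfp",
    diagnostics = list(time_volume_curve = tvc, fit = fit)
  )
}

#' Global LV indices from a full-cycle stack
#'
#' EDV is the maximum and ESV the minimum volume over all phases;
#' `EF = 100 (EDV - ESV) / EDV` %. Volumes are indexed to body surface area
#' computed by the Du Bois formula (see [bsa_dubois()]).
#'
#' @inheritParams stack_volume
#' @param height cm.
#' @param weight kg.
#' @return A list: `edv`, `esv` (mL), `ef` (%), `bsa` (m2), `edv_per_bsa`,
#'   `esv_per_bsa` (mL/m2).
#' @export
global_indices <- function(stack, height, weight,
                           source = c("auto", "exact", "raster")) {
  source <- match.arg(source)
  vols <- vapply(seq_along(stack$phase_times), function(j)
    stack_volume(stack, j, source = source), numeric(1))
  if (any(vols <= 0))
    stop("global_indices: non-positive phase volumes", call. = FALSE)
  edv <- max(vols); esv <- min(vols)
  bsa <- bsa_dubois(height, weight)
  list(edv = edv, esv = esv, ef = 100 * (edv - esv) / edv,
       bsa = bsa, edv_per_bsa = edv / bsa, esv_per_bsa = esv / bsa)
}

#' Body surface area by the Du Bois formula
#'
#' `BSA = 0.007184 * height^0.725 * weight^0.425` (height cm, weight kg,
#' BSA m2).
#'
#' @param height cm.
#' @param weight kg.
#' @return BSA in m2.
#' @export
#' @examples
#' bsa_dubois(169.5, 60.2)  # ~1.69 m2
bsa_dubois <- function(height, weight) {
  if (any(height <= 0) || any(weight <= 0))
    stop("bsa_dubois: height and weight must be positive", call. = FALSE)
  0.007184 * height^0.725 * weight^0.425
}
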