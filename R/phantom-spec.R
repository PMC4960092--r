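#' Synthetic cine phantom specification
#'
#' Bundles every parameter of the synthetic left ventricle and of the two
#' emulated acquisitions (velocity-encoded PC cine and short-axis SSFP cine)
#' into a validated list. The defaults describe a healthy adult volunteer:
#' EDV 150 mL, ESV 65 mL, heart rate 62 beats/min, a biphasic filling pattern
#' (early E wave peaking at 49 % of the RR interval, atrial A wave late in
#' diastole) with an E:A filling-volume ratio of 1.5, and a 4 cm2 mitral
#' orifice. Under these defaults the instantaneous peak filling rate is
#' 468.5 mL/s in closed form (see [make_volume_waveform()]).
#'
#' The acquisition side mirrors a clinical protocol: velocity encoding with
#' VENC 150 cm/s stored as signed integers with full scale `phase_scale`,
#' 64 reconstructed PC phases and 32 SSFP phases (the 2:1 ratio is required
#' by the odd/even phase-correspondence rule used to centre the SSFP
#' analysis window), and true temporal resolutions modelled as boxcar blurs
#' of the underlying signal (43.2 ms PC, 40 ms SSFP by default).
#'
#' @param heart_rate beats/min.
#' @param edv,esv end-diastolic and end-systolic volume, mL (`edv >= esv > 0`).
#' @param systole_end_frac fraction of the RR interval at which ejection ends.
#' @param e_onset_frac,e_peak_frac,e_end_frac onset, peak and end of the early
#'   (E) filling wave, as fractions of RR.
#' @param a_onset_frac,a_end_frac onset and end of the atrial (A) filling
#'   wave, as fractions of RR. Fractions must satisfy
#'   `0 < systole_end < e_onset < e_peak < e_end <= a_onset < a_end <= 1`.
#' @param e_to_a_volume_ratio ratio of E-wave to A-wave filling volume.
#' @param orifice_area mitral orifice area, cm2.
#' @param venc velocity sensitivity threshold, cm/s.
#' @param phase_scale integer full-scale stored phase value mapping to VENC.
#' @param pixel_size in-plane pixel size, mm.
#' @param matrix image matrix size (pixels per side).
#' @param n_slices,slice_thickness,slice_gap short-axis stack geometry
#'   (counts, mm, mm).
#' @param n_phases_pc,n_phases_ssfp reconstructed phase counts; must satisfy
#'   `n_phases_pc == 2 * n_phases_ssfp`.
#' @param true_temporal_resolution_pc,true_temporal_resolution_ssfp boxcar
#'   blur widths, ms, emulating the finite data-acquisition window per phase.
#' @param noise_sd_velocity per-pixel Gaussian velocity noise SD, cm/s.
#' @param seed integer RNG seed for reproducible rendering.
#'
#' @return An object of class `phantom_spec` (a named list).
#' @export
#' @examples
#' spec <- phantom_spec()
#' spec$edv
phantom_spec <- function(heart_rate = 62,
                         edv = 150,
                         esv = 65,
                         systole_end_frac = 0.38,
                         e_onset_frac = 0.40,
                         e_peak_frac = 0.49,
                         e_end_frac = 0.625,
                         a_onset_frac = 0.78,
                         a_end_frac = 0.98,
                         e_to_a_volume_ratio = 1.5,
                         orifice_area = 4,
                         venc = 150,
                         phase_scale = 4096L,
                         pixel_size = 1.2,
                         matrix = 96L,
                         n_slices = 10L,
                         slice_thickness = 8,
                         slice_gap = 0,
                         n_phases_pc = 64L,
                         n_phases_ssfp = 32L,
                         true_temporal_resolution_pc = 43.2,
                         true_temporal_resolution_ssfp = 40,
                         noise_sd_velocity = 2,
                         seed = 1L) {
  spec <- list(
    heart_rate = heart_rate, edv = edv, esv = esv,
    systole_end_frac = systole_end_frac,
    e_onset_frac = e_onset_frac, e_peak_frac = e_peak_frac,
    e_end_frac = e_end_frac,
    a_onset_frac = a_onset_frac, a_end_frac = a_end_frac,
    e_to_a_volume_ratio = e_to_a_volume_ratio,
    orifice_area = orifice_area, venc = venc,
    phase_scale = as.integer(phase_scale),
    pixel_size = pixel_size, matrix = as.integer(matrix),
    n_slices = as.integer(n_slices),
    slice_thickness = slice_thickness, slice_gap = slice_gap,
    n_phases_pc = as.integer(n_phases_pc),
    n_phases_ssfp = as.integer(n_phases_ssfp),
    true_temporal_resolution_pc = true_temporal_resolution_pc,
    true_temporal_resolution_ssfp = true_temporal_resolution_ssfp,
    noise_sd_velocity = noise_sd_velocity,
    seed = as.integer(seed)
  )
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (!(edv >= esv && esv > 0))
      stop("phantom_spec: need edv >= esv > 0 (got edv = ", edv,
           ", esv = ", esv, ")", call. = FALSE)
    fr <- c(systole_end_frac, e_onset_frac, e_peak_frac, e_end_frac)
    if (!(all(fr > 0) && all(diff(fr) > 0)))
      stop("phantom_spec: cycle fractions must satisfy 0 < systole_end < ",
           "e_onset < e_peak < e_end", call. = FALSE)
    if (!(e_end_frac <= a_onset_frac && a_onset_frac < a_end_frac &&
          a_end_frac <= 1))
      stop("phantom_spec: need e_end <= a_onset < a_end <= 1", call. = FALSE)
    if (venc <= 0) stop("phantom_spec: venc must be positive", call. = FALSE)
    if (orifice_area <= 0)
      stop("phantom_spec: orifice_area must be positive", call. = FALSE)
    if (heart_rate <= 0)
      stop("phantom_spec: heart_rate must be positive", call. = FALSE)
    if (n_phases_pc != 2L * n_phases_ssfp)
      stop("phantom_spec: n_phases_pc must equal 2 * n_phases_ssfp ",
           "(phase-correspondence rule)", call. = FALSE)
    if (true_temporal_resolution_pc < 0 || true_temporal_resolution_ssfp < 0)
      stop("phantom_spec: blur widths must be non-negative", call. = FALSE)
    if (e_to_a_volume_ratio <= 0)
      stop("phantom_spec: e_to_a_volume_ratio must be positive", call. = FALSE)
  })
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec>\n")
  cat(sprintf("  LV: EDV %.1f mL, ESV %.1f mL, HR %.1f bpm (RR %.1f ms)\n",
              x$edv, x$esv, x$heart_rate, 60000 / x$heart_rate))
  cat(sprintf("  filling: E %.2f-%.2f (peak %.2f), A %.2f-%.2f of RR, E:A vol %.2f\n",
              x$e_onset_frac, x$e_end_frac, x$e_peak_frac,
              x$a_onset_frac, x$a_end_frac, x$e_to_a_volume_ratio))
  cat(sprintf("  PC: %d phases, VENC %g cm/s, blur %.1f ms; SSFP: %d phases, blur %.1f ms\n",
              x$n_phases_pc, x$venc, x$true_temporal_resolution_pc,
              x$n_phases_ssfp, x$true_temporal_resolution_ssfp))
  invisible(x)
}
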