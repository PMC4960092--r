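#' True temporal resolution of a retrospectively gated cine acquisition
#'
#' The true temporal resolution is the actual data-acquisition window per
#' reconstructed phase: `TR x VPS x 2` for PC cine imaging (two velocity
#' encodings per view) and `TR x VPS` for SSFP cine imaging.
#'
#' @param tr repetition time, ms.
#' @param vps views per segment (k-space lines per cycle per phase).
#' @param sequence_kind `"pc"` or `"ssfp"`.
#' @return True temporal resolution, ms.
#' @export
#' @examples
#' true_temporal_resolution(5.4, 4, "pc")    # 43.2 ms (temporal PC)
#' true_temporal_resolution(6.4, 8, "pc")    # 102.4 ms (spatial PC)
#' true_temporal_resolution(4.0, 10, "ssfp") # 40 ms
true_temporal_resolution <- function(tr, vps, sequence_kind = c("pc", "ssfp")) {
  if (tr <= 0) stop("true_temporal_resolution: tr must be positive", call. = FALSE)
  if (vps < 1) stop("true_temporal_resolution: vps must be >= 1", call. = FALSE)
  sequence_kind <- match.arg(sequence_kind)
  switch(sequence_kind, pc = tr * vps * 2, ssfp = tr * vps)
}

#' Apparent temporal resolution of a reconstructed cine series
#'
#' The interval between adjacent reconstructed phases:
#' `(60000 / heart_rate) / n_recon_phases` ms. Retrospective gating can make
#' this much finer than the true temporal resolution, but interpolated
#' phases do not restore information lost to the acquisition window.
#'
#' @param heart_rate beats/min.
#' @param n_recon_phases number of reconstructed cardiac phases.
#' @return Apparent temporal resolution, ms.
#' @export
#' @examples
#' apparent_temporal_resolution(60, 64)  # 15.625 ms
apparent_temporal_resolution <- function(heart_rate, n_recon_phases) {
  if (heart_rate <= 0)
    stop("apparent_temporal_resolution: heart_rate must be positive",
         call. = FALSE)
  if (n_recon_phases < 1)
    stop("apparent_temporal_resolution: n_recon_phases must be >= 1",
         call. = FALSE)
  (60000 / heart_rate) / n_recon_phases
}
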