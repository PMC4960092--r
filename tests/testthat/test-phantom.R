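test_that("volume waveform honours its boundary conditions and conserves volume", {
  spec <- default_spec()
  wf <- make_volume_waveform(spec)
  expect_equal(wf$V(0), spec$edv)
  grid <- seq(0, wf$rr_ms, length.out = 20001)
  expect_equal(min(wf$V(grid)), spec$esv, tolerance = 1e-6)
  # periodicity: net volume change over one cycle is zero
  h <- wf$rr_ms / 2e5
  g <- seq(0, wf$rr_ms, by = h)
  r <- wf$dVdt(g)
  integral <- sum((r[-1] + r[-length(r)]) / 2) * h / 1000   # mL
  expect_lt(abs(integral) / (spec$edv - spec$esv), 1e-9)
  # continuity at segment joins
  joins <- wf$rr_ms * c(spec$systole_end_frac, spec$e_onset_frac,
                        spec$e_peak_frac, spec$e_end_frac,
                        spec$a_onset_frac, spec$a_end_frac)
  expect_equal(wf$V(joins - 1e-9), wf$V(joins + 1e-9), tolerance = 1e-6)
})

test_that("degenerate and scaled waveforms behave as the family predicts", {
  flat <- make_volume_waveform(default_spec(edv = 100, esv = 100))
  g <- seq(0, flat$rr_ms, length.out = 1001)
  expect_true(all(flat$dVdt(g) == 0))
  expect_equal(true_pfr(flat), 0)
  # doubling the stroke volume at fixed shape fractions doubles true PFR
  w1 <- make_volume_waveform(default_spec(edv = 150, esv = 65))
  w2 <- make_volume_waveform(default_spec(edv = 235, esv = 65))
  expect_equal(true_pfr(w2), 2 * true_pfr(w1), tolerance = 1e-8)
})

test_that("grid-search PFR matches the closed-form E-lobe maximum", {
  for (hr in c(55, 62, 70)) {
    wf <- make_volume_waveform(default_spec(heart_rate = hr))
    expect_equal(true_pfr(wf), wf$peak_rate, tolerance = 1e-3)
  }
})

test_that("invalid phantom parameters are rejected before any computation", {
  expect_error(phantom_spec(edv = 60, esv = 65), "edv >= esv")
  expect_error(phantom_spec(e_onset_frac = 0.3, systole_end_frac = 0.35),
               "fractions")
  expect_error(phantom_spec(n_phases_pc = 60), "2 \\* n_phases_ssfp")
  expect_error(phantom_spec(venc = -1), "venc")
})

test_that("boxcar blur is the identity at width 0 and shrinks strict peaks", {
  wf <- make_volume_waveform(default_spec())
  expect_identical(temporal_blur(wf$inflow, 0), wf$inflow)
  expect_error(temporal_blur(wf$inflow, -1), "non-negative")
  for (b in c(20, 43.2, 100.8)) {
    blurred <- temporal_blur(wf$inflow, b)
    expect_lt(blurred(wf$peak_time_ms), wf$peak_rate)
  }
})

test_that("boxcar blur of a triangular pulse matches the closed form", {
  # triangle of half-width w and peak P: blurred peak = P (1 - b / (4 w))
  w <- 50; P <- 300
  tri <- function(t) P * pmax(0, 1 - abs(t) / w)
  for (b in c(10, 40, 80, 100)) {
    expect_equal(temporal_blur(tri, b)(0), P * (1 - b / (4 * w)),
                 tolerance = 1e-4)
  }
})

test_that("blurred peak is monotone non-increasing in blur width", {
  wf <- make_volume_waveform(default_spec())
  widths <- c(0, 20, 43.2, 60, 100.8, 150)
  peaks <- vapply(widths, function(b)
    optimize(temporal_blur(wf$inflow, b), wf$e_window_ms,
             maximum = TRUE)$objective, numeric(1))
  expect_true(all(diff(peaks) < 0))
})

test_that("PC rendering is seed-reproducible and clips with a warning beyond VENC", {
  s1 <- render_pc_series(default_spec(seed = 7))
  s2 <- render_pc_series(default_spec(seed = 7))
  expect_identical(s1$phase_images, s2$phase_images)
  s3 <- render_pc_series(default_spec(seed = 8))
  expect_false(identical(s1$phase_images, s3$phase_images))
  # shrinking the orifice pushes peak velocity beyond 150 cm/s
  expect_warning(render_pc_series(noise_free_spec(orifice_area = 2)),
                 "exceeds VENC")
})

test_that("systolic phases carry no net ROI velocity", {
  series <- render_pc_series(default_spec())
  roi <- series$ground_truth_roi
  # phase 5 is mid-ejection: inflow is zero, only noise remains
  v <- decode_velocity(series$phase_images[[5]], series$venc,
                       series$phase_scale)
  noise_se <- 2 / sqrt(sum(roi))
  expect_lt(abs(mean(v[roi])), 5 * noise_se)
})

test_that("encode-decode round trip is exact to one quantisation step", {
  spec <- noise_free_spec()
  series <- render_pc_series(spec)
  wf <- make_volume_waveform(spec)
  blurred <- temporal_blur(wf$inflow, spec$true_temporal_resolution_pc)
  q <- spec$venc / spec$phase_scale
  roi <- series$ground_truth_roi
  for (j in c(1, 20, 33, 50)) {
    v <- decode_velocity(series$phase_images[[j]], series$venc,
                         series$phase_scale)
    v_true <- blurred(series$phase_times[j]) / spec$orifice_area
    expect_lt(abs(mean(v[roi]) - v_true), q)
  }
})

test_that("exact-area SSFP stack reproduces the phantom phase volumes", {
  spec <- default_spec()
  stack <- render_ssfp_stack(spec)
  vols <- vapply(seq_along(stack$phase_times), function(j)
    stack_volume(stack, j), numeric(1))
  expect_equal(vols, stack$phase_volumes, tolerance = 1e-6)
})

test_that("rasterised SSFP masks agree with analytic areas to 2 %", {
  spec <- default_spec(pixel_size = 1.0)
  stack <- render_ssfp_stack(spec, raster = TRUE)
  for (j in c(1, 8, 16, 24)) {
    expect_equal(stack_volume(stack, j, source = "raster"),
                 stack_volume(stack, j, source = "exact"),
                 tolerance = 0.02)
  }
})

test_that("a flat phantom yields identical geometry at every phase", {
  stack <- render_ssfp_stack(default_spec(edv = 120, esv = 120))
  expect_true(all(apply(stack$analytic_slice_areas, 1,
                        function(a) max(a) - min(a)) < 1e-9))
})

test_that("an oversized cavity is a geometry error", {
  expect_error(render_ssfp_stack(default_spec(matrix = 24L)),
               "exceeds the image half-extent")
})
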