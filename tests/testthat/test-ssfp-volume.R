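test_that("stack volume is slice-area summation with unit conversion", {
  # 10 slices x 600 pixels x 2.25 mm2 pixels x 8 mm spacing = 108 mL
  masks <- array(FALSE, dim = c(40, 40, 10, 1))
  masks[1:30, 1:20, , 1] <- TRUE             # 600 pixels per slice
  stack <- structure(list(masks = masks, analytic_slice_areas = NULL,
                          pixel_size = 1.5, slice_thickness = 8,
                          slice_gap = 0, phase_times = 0),
                     class = "segmentation_stack")
  expect_equal(stack_volume(stack, 1), 108)
  masks[] <- FALSE
  stack$masks <- masks
  expect_equal(stack_volume(stack, 1), 0)
  expect_error(stack_volume(stack, 2), "not in stack")
})

test_that("volume is additive over disjoint slice masks", {
  m1 <- array(FALSE, dim = c(20, 20, 4, 1)); m1[1:5, , , 1] <- TRUE
  m2 <- array(FALSE, dim = c(20, 20, 4, 1)); m2[11:20, , , 1] <- TRUE
  mk <- function(m) structure(
    list(masks = m, analytic_slice_areas = NULL, pixel_size = 1,
         slice_thickness = 10, slice_gap = 0, phase_times = 0),
    class = "segmentation_stack")
  expect_equal(stack_volume(mk(m1), 1) + stack_volume(mk(m2), 1),
               stack_volume(mk(m1 | m2), 1))
})

test_that("basal coverage fraction scales only the basal slice", {
  stack <- render_ssfp_stack(default_spec())
  v_full <- stack_volume(stack, 1)
  v_half <- stack_volume(stack, 1, basal_fraction = 0.5)
  basal <- stack$analytic_slice_areas[1, 1] *
    (stack$slice_thickness + stack$slice_gap) / 1000
  expect_equal(v_full - v_half, basal / 2)
  expect_error(stack_volume(stack, 1, basal_fraction = 0), "basal_fraction")
})

test_that("odd/even PC peak phases map to 5- and 6-phase SSFP windows", {
  expect_equal(phase_window_from_pc_peak(7, 64, 32), 2:6)    # odd, n = 4
  expect_equal(phase_window_from_pc_peak(8, 64, 32), 2:7)    # even, n = 4
  expect_equal(phase_window_from_pc_peak(33, 64, 32), 15:19) # odd, n = 17
  expect_error(phase_window_from_pc_peak(3, 64, 32), "outside")
  expect_error(phase_window_from_pc_peak(62, 64, 32), "outside")
  expect_error(phase_window_from_pc_peak(7, 64, 30), "2 \\* n_ssfp")
})

test_that("derivative curve is the midpoint finite difference in mL/s", {
  dc <- derivative_curve(list(phase_times = c(0, 30), volumes = c(100, 110)))
  expect_equal(dc$midpoint_times, 15)
  expect_equal(dc$rates, 10 / 30 * 1000)
  flat <- derivative_curve(list(phase_times = c(0, 30, 60),
                                volumes = c(90, 90, 90)))
  expect_true(all(flat$rates == 0))
  expect_error(derivative_curve(list(phase_times = c(0, 0),
                                     volumes = c(1, 2))), "increasing")
  # central differences of a cubic are exact at midpoints up to O(dt^2):
  # halving dt shrinks the error ~4x
  cubic <- function(t) 1e-6 * t^3 - 2e-4 * t^2 + 0.05 * t + 100
  dcub <- function(t) 3e-6 * t^2 - 4e-4 * t + 0.05
  err <- function(dt) {
    t <- seq(0, 240, by = dt)
    d <- derivative_curve(list(phase_times = t, volumes = cubic(t)))
    max(abs(d$rates / 1000 - dcub(d$midpoint_times)))
  }
  expect_equal(err(30) / err(15), 4, tolerance = 0.05)
})

test_that("parabola fit interpolates exact quadratics and reports the vertex", {
  t <- 1:5
  y <- -(t - 5)^2 + 25
  fit <- fit_parabola(list(midpoint_times = t, rates = y))
  expect_equal(fit$vertex_time, 5)
  expect_equal(fit$vertex_rate, 25)
  expect_equal(fit$rss, 0, tolerance = 1e-20)
  expect_error(fit_parabola(list(midpoint_times = 1:2, rates = 1:2)),
               "three points")
  expect_error(fit_parabola(list(midpoint_times = 1:5, rates = 1:5 * 2)),
               "no concave peak")
  expect_error(fit_parabola(list(midpoint_times = 1:5, rates = (1:5)^2)),
               "no concave peak")
})

test_that("parabola fit equals brute-force normal equations on random instances", {
  set.seed(42)
  worst <- 0
  for (i in 1:1000) {
    n <- sample(4:6, 1)
    t <- cumsum(runif(n, 10, 40))
    t <- t - mean(t)
    y <- -runif(1, 0.05, 0.3) * (t - runif(1, -10, 10))^2 +
      runif(1, 300, 500) + rnorm(n, sd = 5)
    fit <- fit_parabola(list(midpoint_times = t, rates = y))
    oracle <- normal_equations_parabola(t, y)
    got <- c(fit$c, fit$b, fit$a)
    rel <- max(abs(got - unname(oracle))) / max(abs(oracle))
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-8)
})

test_that("SSFP pathway recovers phantom PFR and respects invariances", {
  spec <- noise_free_spec()
  wf <- make_volume_waveform(spec)
  stack <- render_ssfp_stack(spec)
  series <- render_pc_series(spec)
  k <- find_visual_peak(series)
  res <- pfr_ssfp(stack, pc_peak_index = k)
  truth <- true_pfr(wf)
  expect_lte(res$pfr, truth)
  expect_gt(res$pfr, 0.9 * truth)           # within 10 % below truth
  # constant volume offset leaves PFR unchanged; scaling scales it
  stack_off <- stack
  stack_off$analytic_slice_areas <- stack$analytic_slice_areas +
    5000 / (stack$slice_thickness * nrow(stack$analytic_slice_areas))  # +5 mL
  res_off <- pfr_ssfp(stack_off, pc_peak_index = k)
  expect_equal(res_off$pfr, res$pfr, tolerance = 1e-9)
  stack_x2 <- stack
  stack_x2$analytic_slice_areas <- stack$analytic_slice_areas * 2
  expect_equal(pfr_ssfp(stack_x2, pc_peak_index = k)$pfr, 2 * res$pfr,
               tolerance = 1e-9)
})

test_that("a flat time-volume curve has no concave filling peak", {
  stack <- render_ssfp_stack(default_spec(edv = 120, esv = 120))
  expect_error(pfr_ssfp(stack, pc_peak_index = 33), "no concave peak")
})

test_that("global indices compute EF and Du Bois BSA indexing", {
  areas <- matrix(0, nrow = 2, ncol = 2)
  areas[, 1] <- 100 / (2 * 10) * 1000  # 100 mL across 2 slices, dz 10 mm
  areas[, 2] <- 50 / (2 * 10) * 1000
  stack <- structure(list(analytic_slice_areas = areas, masks = NULL,
                          pixel_size = 1, slice_thickness = 10, slice_gap = 0,
                          phase_times = c(0, 400)),
                     class = "segmentation_stack")
  gi <- global_indices(stack, height = 169.5, weight = 60.2)
  expect_equal(gi$edv, 100)
  expect_equal(gi$esv, 50)
  expect_equal(gi$ef, 50)
  expect_equal(gi$bsa, 0.007184 * 169.5^0.725 * 60.2^0.425)
  expect_equal(gi$bsa, 1.69, tolerance = 0.005)
  expect_equal(gi$edv_per_bsa, 100 / gi$bsa)
  # EF from the cohort mean volumes (a ratio of means, not a mean of ratios)
  expect_equal(100 * (149.5 - 65.1) / 149.5, 56.5, tolerance = 0.05)
})
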