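test_that("beam angles follow the plane-angle convention", {
  ## pure lateral approach: in transverse and coronal planes, normal to sagittal
  b <- beamAngles(c(0, 0, 0), c(10, 0, 0))
  expect_equal(b$angle_transverse, 0)
  expect_equal(b$angle_sagittal, 90)
  expect_equal(b$angle_coronal, 0)
  expect_equal(b$stimulus_distance, 10)
  ## symmetric diagonal: all angles asin(1/sqrt(3))
  b3 <- beamAngles(c(0, 0, 0), c(1, 1, 1))
  expect_equal(b3$angle_transverse, 35.26439, tolerance = 1e-5)
  expect_equal(b3$angle_sagittal, b3$angle_transverse)
  expect_equal(b3$angle_coronal, b3$angle_transverse)
  expect_error(beamAngles(c(1, 2, 3), c(1, 2, 3)), "zero-length")
})

test_that("sin^2 identity holds for random beam vectors", {
  set.seed(42)
  for (i in 1:1000) {
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    b <- beamAngles(c(0, 0, 0), v)
    s <- sin(b$angle_transverse * pi / 180)^2 +
      sin(b$angle_sagittal * pi / 180)^2 +
      sin(b$angle_coronal * pi / 180)^2
    expect_lt(abs(s - 1), 1e-9)
  }
})

test_that("FWHM of a gaussian field matches 2*sqrt(2 ln 2)*sigma", {
  g <- gaussianField2d(96, sigmaAxial = 6, sigmaLateral = 2)
  m <- extractFWHM(g, beamAxis = c(1, 0), spacing = c(1, 1))
  expect_lt(abs(m$fwhm_length - 2 * sqrt(2 * log(2)) * 6), 1)
  expect_lt(abs(m$fwhm_width - 2 * sqrt(2 * log(2)) * 2), 1)
  expect_false(m$degenerate)
  ## scaling invariance: normalization makes the metrics exact-equal
  m2 <- extractFWHM(5.7e6 * g, beamAxis = c(1, 0), spacing = c(1, 1))
  expect_equal(m2$fwhm_length, m$fwhm_length)
  expect_equal(m2$fwhm_width, m$fwhm_width)
  expect_equal(m2$offset_angle, m$offset_angle)
  ## rotated gaussian: principal-axis offset recovered within a degree
  gr <- gaussianField2d(96, 6, 2, thetaDeg = 10)
  mr <- extractFWHM(gr, beamAxis = c(1, 0), spacing = c(1, 1))
  expect_lt(abs(mr$offset_angle - 10), 1)
})

test_that("only the peak-containing half-max blob is measured", {
  g <- gaussianField2d(96, 3, 3, centre = 30)
  g2 <- 0.8 * gaussianField2d(96, 3, 3, centre = 70)
  m <- extractFWHM(g + g2, beamAxis = c(1, 0), spacing = c(1, 1))
  ## a single 3-sigma blob, not the 40-voxel-separated pair
  expect_lt(m$fwhm_length, 12)
  expect_equal(as.numeric(m$peak_index), c(31, 31))
  ## focus argument picks the secondary blob's local maximum
  msec <- extractFWHM(g + g2, beamAxis = c(1, 0), spacing = c(1, 1),
                      focus = c(70, 70), focusRadius = 10)
  expect_equal(as.numeric(msec$peak_index), c(71, 71))
  ## plateau touching the boundary is flagged degenerate
  flat <- array(1, c(32, 32))
  mf <- extractFWHM(flat, beamAxis = c(1, 0), spacing = c(1, 1))
  expect_true(mf$degenerate)
})

test_that("water-vs-skull deviation follows the sign conventions", {
  g <- gaussianField2d(64, 5, 2)
  mw <- extractFWHM(g, c(1, 0), spacing = c(1, 1))
  ## identical fields: all deltas zero
  d0 <- deviationVsWater(mw, mw)
  expect_equal(d0$delta_length_mm, 0)
  expect_equal(d0$delta_width_mm, 0)
  expect_equal(d0$amplitude_drop_pct, 0)
  ## pure scaling: 50% drop, zero geometric deltas
  ms <- extractFWHM(0.5 * g, c(1, 0), spacing = c(1, 1))
  dh <- deviationVsWater(ms, mw)
  expect_equal(dh$amplitude_drop_pct, 50)
  expect_equal(dh$delta_length_mm, 0)
  expect_equal(dh$delta_width_mm, 0)
  ## narrower, weaker skull focus: positive deltas and drop
  gn <- 0.6 * gaussianField2d(64, 3.5, 1.2)
  dn <- deviationVsWater(extractFWHM(gn, c(1, 0), spacing = c(1, 1)), mw)
  expect_gt(dn$delta_length_mm, 0)
  expect_gt(dn$delta_width_mm, 0)
  expect_gt(dn$amplitude_drop_pct, 0)
  expect_equal(dn$delta_length_pct,
               100 * dn$delta_length_mm / mw$fwhm_length)
  expect_error(deviationVsWater(mw, list(peak_amplitude = 0, fwhm_length = 0)),
               "water reference")
})

test_that("safety indices follow the MI and intensity formulas", {
  ## unit case: 1 MPa at 1 MHz
  s <- safetyIndices(1e6, 1e6, dutyCycle = 0.06)
  expect_equal(s$MI, 1)
  ## 1 MPa at 500 kHz (frozen: 1/sqrt(0.5))
  s5 <- safetyIndices(1e6, 500e3, rho = 1000, c = 1482, dutyCycle = 0.06)
  expect_equal(s5$MI, 1.414214, tolerance = 1e-6)
  ## plane-wave intensities in water (frozen arithmetic)
  expect_equal(s5$I_SPPA_W_cm2, 33.73819, tolerance = 1e-5)
  expect_equal(s5$I_SPTA_mW_cm2, 2024.291, tolerance = 1e-4)
  expect_true(s5$fda_mi_ok)
  expect_true(s5$fda_isppa_ok)
  ## homogeneity: doubling pressure doubles MI, quadruples I_SPPA
  s2 <- safetyIndices(2e6, 500e3, dutyCycle = 0.06)
  expect_equal(s2$MI, 2 * s5$MI)
  expect_equal(s2$I_SPPA_W_cm2, 4 * s5$I_SPPA_W_cm2)
  ## flags flip at the FDA bounds
  expect_false(safetyIndices(4e6, 1e6)$fda_mi_ok)
  expect_false(safetyIndices(8e6, 1e6)$fda_isppa_ok)
  expect_error(safetyIndices(1e6, 0), "positive")
})
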