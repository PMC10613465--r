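test_that("grid time step follows the CFL rule", {
  ## heterogeneous medium: max speed rules the step
  hu <- HUVolume(array(1000, c(48, 48, 48)), spacing = 1)
  mk <- binarizeSkull(hu)           # all bone, c = 3100
  med <- propertyMaps(hu, mk)
  g <- makeGrid(med, cfl = 0.3, pmlWidth = 8L)
  expect_equal(g@dt, 0.3 * 1e-3 / 3100, tolerance = 1e-12)
  ## water medium: dt larger by the speed ratio
  gw <- makeGrid(waterMedium(c(48, 48, 48)), cfl = 0.3, pmlWidth = 8L)
  expect_equal(gw@dt / g@dt, 3100 / 1482, tolerance = 1e-12)
  expect_error(makeGrid(med, cfl = 1.5), "stability")
  expect_error(makeGrid(waterMedium(c(20, 20)), pmlWidth = 8L), "too small")
  expect_warning(makeGrid(waterMedium(c(64, 64)), pmlWidth = 8L,
                          frequency = 1.1e6), "points per wavelength")
})

test_that("bowl discretization matches spherical-cap geometry", {
  spec <- transducerSpec(30, 25)
  ## cap half-angle (frozen: asin(12.5/30) in degrees)
  expect_equal(asin(spec@apertureDiameter / (2 * spec@radiusOfCurvature)) *
                 180 / pi, 24.62431, tolerance = 1e-5)
  expect_equal(fNumber(spec), 1.2)
  med <- waterMedium(c(48L, 48L, 48L))
  g <- makeGrid(med, pmlWidth = 8L)
  src <- discretizeBowl(spec, c(8, 23.5, 23.5), c(38, 23.5, 23.5), g)
  ai <- src@activeIndices
  expect_gt(nrow(ai), 0)
  ## every active voxel within half a voxel of the ROC sphere
  ctr <- src@centreOfCurvature
  r <- sqrt(rowSums(sweep(ai, 2, ctr, `-`)^2))
  expect_true(all(abs(r - 30) <= 0.5 + 1e-9))
  ## mirror symmetry about the on-axis configuration (y and z)
  expect_identical(sort(ai[, 2]), sort(47L - ai[, 2]))
  expect_identical(sort(ai[, 3]), sort(47L - ai[, 3]))
  ## hemisphere: active count matches analytic cap area within 10%
  hemi <- discretizeBowl(transducerSpec(15, 30), c(8, 23.5, 23.5),
                         c(23, 23.5, 23.5), g)
  expect_lt(abs(nrow(hemi@activeIndices) - 2 * pi * 15^2) / (2 * pi * 15^2),
            0.1)
  expect_error(discretizeBowl(spec, c(8, 23.5, 23.5), c(8, 23.5, 23.5), g),
               "degenerate")
  expect_error(discretizeBowl(spec, c(-3, 23.5, 23.5), c(27, 23.5, 23.5), g),
               "clipped")
})

test_that("plane waves travel at the medium sound speed", {
  med <- waterMedium(256L, spacing = 1)
  g <- makeGrid(med, cfl = 0.3, pmlWidth = 12L)
  drive <- pulseSequence(fundamentalFrequency = 250e3)
  fld <- propagate(g, med, pointSource1d(19), drive,
                   probes = matrix(c(100, 104), 2, 1),
                   settlePeriods = 60, measurePeriods = 10)
  ## probes under one wavelength apart: no phase unwrapping needed
  ph <- vapply(1:2, function(j)
    tracePhase(fld@probeTraces[, j], g@dt, 250e3), numeric(1))
  dphi <- (ph[1] - ph[2]) %% (2 * pi)
  speed <- 2 * pi * 250e3 * 0.004 / dphi
  expect_equal(speed, 1482, tolerance = 0.01)
})

test_that("amplitude decays as exp(-alpha d) in a lossy medium", {
  med <- waterMedium(256L, spacing = 1, alpha0 = 100)
  g <- makeGrid(med, cfl = 0.3, pmlWidth = 12L)
  drive <- pulseSequence(fundamentalFrequency = 250e3)
  fld <- propagate(g, med, pointSource1d(19), drive,
                   probes = matrix(c(100, 160), 2, 1),
                   settlePeriods = 60, measurePeriods = 10)
  a <- vapply(1:2, function(j)
    amplitudeFromTrace(fld@probeTraces[, j], g@dt, 250e3)$amplitude,
    numeric(1))
  alpha <- attenuationAtFrequency(100, 250e3, 1.51)
  expect_equal(a[2] / a[1], exp(-alpha * 0.060), tolerance = 0.02)
})

test_that("the scheme is linear and conserves the discrete energy", {
  med <- waterMedium(c(64L, 64L))
  g <- makeGrid(med, pmlWidth = 8L)
  spec <- transducerSpec(30, 25)
  src <- discretizeBowl(spec, c(10, 31.5), c(40, 31.5), g)
  d1 <- pulseSequence(fundamentalFrequency = 250e3, sourcePressure = 1e6)
  d2 <- pulseSequence(fundamentalFrequency = 250e3, sourcePressure = 2e6)
  f1 <- propagate(g, med, src, d1, settlePeriods = 6, measurePeriods = 2)
  f2 <- propagate(g, med, src, d2, settlePeriods = 6, measurePeriods = 2)
  expect_equal(amplitude(f2), 2 * amplitude(f1), tolerance = 1e-12)
  ## closed lossless homogeneous domain: energy conserved over 100 steps
  gp <- makeGrid(med, pmlWidth = 0L)
  x <- outer((0:63) - 32, rep(1, 64)); y <- t(x)
  p0 <- 1e5 * exp(-(x^2 + y^2) / (2 * 4^2))
  fld <- propagate(gp, med, NULL, NULL, p0 = p0, nSteps = 100L,
                   pmlAxes = FALSE, absorption = "off", trackEnergy = TRUE)
  e <- attr(fld, "energy")
  expect_lt((max(e) - min(e)) / e[1], 0.005)
})

test_that("a z-invariant 3D run reproduces the 2D solution", {
  med2 <- waterMedium(c(64L, 64L))
  g2 <- makeGrid(med2, pmlWidth = 8L)
  spec <- transducerSpec(30, 25)
  src2 <- discretizeBowl(spec, c(10, 31.5), c(40, 31.5), g2)
  drive <- pulseSequence(fundamentalFrequency = 250e3)
  f2 <- propagate(g2, med2, src2, drive, settlePeriods = 6, measurePeriods = 2)
  med3 <- waterMedium(c(64L, 64L, 16L))
  g3 <- suppressWarnings(makeGrid(med3, pmlWidth = c(8L, 8L, 0L)))  # thin z axis is periodic
  act3 <- do.call(rbind, lapply(0:15, function(z)
    cbind(src2@activeIndices, z)))
  src3 <- new("SourceGeometry", activeIndices = act3,
              weights = rep(1, nrow(act3)), apex = c(10, 31.5, 7.5),
              axis = c(1, 0, 0), centreOfCurvature = c(40, 31.5, 7.5))
  f3 <- propagate(g3, med3, src3, drive, settlePeriods = 6,
                  measurePeriods = 2, pmlAxes = c(TRUE, TRUE, FALSE))
  i <- 12:52
  sl <- amplitude(f3)[, , 8]
  expect_lt(max(abs(sl[i, i] - amplitude(f2)[i, i])) / max(amplitude(f2)[i, i]),
            0.01)
})

test_that("amplitude estimator reads steady state, not transients", {
  dt <- 1e-7; ff <- 250e3; t <- (0:4999) * dt
  ## settles well before the trailing window
  tr <- 2e5 * (1 - exp(-t / 5e-5)) * sin(2 * pi * ff * t)
  est <- amplitudeFromTrace(tr, dt, ff, measurePeriods = 4)
  expect_equal(est$amplitude, 2e5, tolerance = 0.01)
  expect_equal(est$peak_negative, 2e5, tolerance = 0.01)
  ## pure sinusoid and zero signal
  expect_equal(amplitudeFromTrace(3e5 * sin(2 * pi * ff * t), dt, ff)$amplitude,
               3e5, tolerance = 0.01)
  expect_equal(amplitudeFromTrace(numeric(5000) , dt, ff)$amplitude, 0)
  ## rms variant agrees for a sinusoid
  expect_equal(amplitudeFromTrace(tr, dt, ff, method = "rms")$amplitude,
               2e5, tolerance = 0.01)
  expect_error(amplitudeFromTrace(tr[1:10], dt, ff), "window")
})
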