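test_that("heat deposition follows the plane-wave absorption law", {
  med <- waterMedium(c(32L, 32L), alpha0 = 50)
  amp <- array(1e6, c(32, 32))
  Q1 <- heatDeposition(amp, med, 500e3, duty = 1)
  ## Q = alpha(f) p^2 / (rho c), uniform here
  alpha <- attenuationAtFrequency(50, 500e3, 1.51)
  expect_equal(Q1[1, 1], alpha * 1e12 / (1000 * 1482))
  ## zero amplitude -> zero source; quadratic scaling exact
  expect_true(all(heatDeposition(amp * 0, med, 500e3) == 0))
  expect_equal(heatDeposition(2 * amp, med, 500e3), 4 * Q1)
  ## duty scales linearly
  expect_equal(heatDeposition(amp, med, 500e3, duty = 0.06), 0.06 * Q1)
  expect_error(heatDeposition(array(0, c(4, 4)), med, 500e3), "dimensions")
})

test_that("deposited power balances the intensity loss across a slab", {
  ## 1D exponentially decaying plane wave in a uniform lossy medium
  n <- 400L; dx <- 0.5e-3
  med <- waterMedium(n, spacing = 0.5, alpha0 = 50)
  alpha <- attenuationAtFrequency(50, 500e3, 1.51)
  x <- (0:(n - 1)) * dx
  p <- 1e6 * exp(-alpha * x)
  Q <- heatDeposition(array(p, n), med, 500e3)
  ## sum Q dx vs I(0) - I(L) = p0^2/(2 rho c) (1 - exp(-2 alpha L))
  lhs <- sum(Q) * dx
  rhs <- 1e12 / (2 * 1000 * 1482) * (1 - exp(-2 * alpha * max(x)))
  expect_equal(lhs, rhs, tolerance = 0.02)
})

test_that("Pennes solver preserves uniform states and the maximum principle", {
  med <- waterMedium(c(48L, 48L))
  th <- thermalProperties(med)
  r0 <- solvePennes(th, array(0, c(48, 48)), spacing = 1, duration = 0.5,
                    T0 = 38.5)
  expect_true(all(r0$temperature == 38.5))
  expect_equal(r0$peak_temperature, 38.5)
  ## with Q >= 0 and insulated boundaries, T never falls below the start
  Q <- array(0, c(48, 48)); Q[20:28, 20:28] <- 5e5
  r1 <- solvePennes(th, Q, spacing = 1, duration = 1, T0 = 38.5,
                    dtThermal = 0.1)
  expect_gte(min(r1$temperature), 38.5)
  expect_gt(r1$peak_temperature, 38.5)
  ## peak is inside the heated block
  expect_true(all(r1$peak_index >= 20 & r1$peak_index <= 28))
  expect_error(solvePennes(th, Q, spacing = 1, duration = 1, dtThermal = 10),
               "stability")
})

test_that("a gaussian perturbation spreads like the heat kernel", {
  dims <- c(96L, 96L)
  med <- waterMedium(dims)
  th <- thermalProperties(med)
  alpha <- 0.54 / (1000 * 4178)           # water diffusivity, m^2/s
  s0 <- 4e-3
  x <- outer(((0:95) - 48) * 1e-3, rep(1, 96)); y <- t(x)
  Tinit <- 38.5 + 5 * exp(-(x^2 + y^2) / (2 * s0^2))
  res <- solvePennes(th, array(0, dims), spacing = 1, duration = 1,
                     T0 = 38.5, Tinit = Tinit, dtThermal = 0.05)
  s2 <- s0^2 + 2 * alpha * 1
  Texp <- 38.5 + 5 * (s0^2 / s2) * exp(-(x^2 + y^2) / (2 * s2))
  expect_lt(max(abs(res$temperature - Texp)) / 5, 0.02)
})

test_that("insulated-domain thermal energy balances the injected power", {
  dims <- c(48L, 48L)
  med <- waterMedium(dims)
  th <- thermalProperties(med)
  Q <- array(0, dims); Q[20:28, 20:28] <- 1e6
  res <- solvePennes(th, Q, spacing = 1, duration = 2, T0 = 38.5,
                     dtThermal = 0.2)
  rhoC <- th$density * th$specific_heat
  dV <- (1e-3)^2
  dE <- sum(rhoC * (res$temperature - 38.5)) * dV
  expect_equal(dE, sum(Q) * dV * 2, tolerance = 0.01)
})

test_that("temperature rise is linear in the heat source", {
  dims <- c(32L, 32L)
  th <- thermalProperties(waterMedium(dims))
  Q <- array(0, dims); Q[12:20, 12:20] <- 1e6
  rA <- solvePennes(th, Q, spacing = 1, duration = 1, dtThermal = 0.1)
  rB <- solvePennes(th, 2 * Q, spacing = 1, duration = 1, dtThermal = 0.1)
  expect_equal(rB$temperature - 38.5, 2 * (rA$temperature - 38.5),
               tolerance = 1e-6)
})

test_that("the pulsed schedule gates the source on and off", {
  dims <- c(32L, 32L)
  th <- thermalProperties(waterMedium(dims))
  Q <- array(0, dims); Q[12:20, 12:20] <- 1e6
  full <- solvePennes(th, Q, spacing = 1, duration = 1, dtThermal = 0.05)
  half <- solvePennes(th, Q, spacing = 1, duration = 1, dtThermal = 0.05,
                      schedule = data.frame(start = 0, stop = 0.5))
  expect_equal(sum(half$temperature - 38.5) / sum(full$temperature - 38.5),
               0.5, tolerance = 0.01)
})

test_that("thermal safety flags trip at the literature thresholds", {
  ok <- thermalSafetyReport(38.5)
  expect_false(ok$exceeds_42 || ok$exceeds_47 || ok$exceeds_50)
  mid <- thermalSafetyReport(43.73)   # denaturation but no bone necrosis
  expect_true(mid$exceeds_42)
  expect_false(mid$exceeds_47)
  hot <- thermalSafetyReport(51)
  expect_true(hot$exceeds_42 && hot$exceeds_47 && hot$exceeds_50)
  expect_error(thermalSafetyReport(numeric(0)), "empty")
})
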