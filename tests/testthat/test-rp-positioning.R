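test_that("model centre sits at the shell centre and translates with it", {
  fx <- shellFixture(target = c(0, 0, 0))
  ctr <- modelCentre(fx$mask)
  expect_lt(max(abs(ctr)), 0.5 + 1e-9)   # within half a voxel of the centre
  ## translation equivariance
  ph2 <- generatePhantom(outerRadius = 18, thickness = 5, shellHU = 600,
                         center = c(10, 0, 0), domainExtent = rep(60, 3),
                         spacing = 1, targetPoint = c(10, 0, 0))
  ctr2 <- modelCentre(binarizeSkull(ph2))
  expect_lt(max(abs(ctr2 - c(10, 0, 0))), 0.5 + 1e-9)
  ## two disjoint shells: midpoint of the combined bounding extent
  a <- array(0, c(40, 20, 20))
  a[5, 10, 10] <- 1; a[35, 10, 10] <- 1
  mk <- new("SkullMask", data = a, spacing = rep(1, 3), origin = rep(0, 3))
  expect_equal(modelCentre(mk), c(19, 9, 9))
  expect_error(modelCentre(new("SkullMask", data = array(0, c(4, 4, 4)),
                               spacing = rep(1, 3), origin = rep(0, 3))),
               "empty")
})

test_that("candidate matrix equals the literal brute-force screen", {
  fx <- shellFixture(outer = 16, thickness = 4, domain = 44,
                     target = c(0, -4, 0))
  clear <- bowlCapDepth(transducerSpec())
  cm <- candidateMatrix(fx$mask, fx$target, roc = 30, clearance = clear)
  bf <- bruteForceCandidates(fx$mask, fx$target, roc = 30, clearance = clear)
  expect_equal(cm@meanCentreShellDistance, bf$meanD)
  key <- function(m) sort(apply(m, 1, paste, collapse = ","))
  expect_identical(key(as.matrix(candidates(cm)[, 1:3])), key(bf$points))
  ## no candidate is on the skull or intracranial, by construction
  filled <- fillSkullVolume(fx$mask)
  for (i in seq_len(min(200, nrow(candidates(cm))))) {
    vi <- round(as.numeric(candidates(cm)[i, 1:3]) - origin(fx$mask)) + 1
    expect_false(filled[vi[1], vi[2], vi[3]])
  }
  ## exclusion bookkeeping covers the whole ball
  expect_true(all(cm@excluded >= 0))
  expect_gt(cm@excluded[["inside_skull"]], 0)
  expect_gt(cm@excluded[["intracranial"]], 0)
})

test_that("screening is monotone in clearance and ball radius", {
  fx <- shellFixture(outer = 16, thickness = 4, domain = 44,
                     target = c(0, -4, 0))
  key <- function(cm) apply(as.matrix(candidates(cm)[, 1:3]), 1,
                            paste, collapse = ",")
  k0 <- key(candidateMatrix(fx$mask, fx$target, roc = 30, clearance = 0))
  k3 <- key(candidateMatrix(fx$mask, fx$target, roc = 30, clearance = 3))
  k6 <- key(candidateMatrix(fx$mask, fx$target, roc = 30, clearance = 6))
  expect_true(all(k3 %in% k0))
  expect_true(all(k6 %in% k3))
  ## smaller ROC: candidates confined to the smaller ball
  k25 <- candidateMatrix(fx$mask, fx$target, roc = 25, clearance = 0)
  expect_true(all(k25@candidates$dist_to_target_mm <= 25))
  expect_true(all(key(k25) %in% k0))
})

test_that("an unreachable target raises an explicit error", {
  ## inner cavity radius beyond the ROC ball: skull nowhere within reach
  ph <- generatePhantom(outerRadius = 42, thickness = 4, shellHU = 600,
                        domainExtent = rep(96, 3), spacing = 1,
                        targetPoint = c(0, 0, 0))
  mask <- binarizeSkull(ph)
  expect_error(candidateMatrix(mask, c(0, 0, 0), roc = 30),
               "no reachable placement")
  ## target outside the cavity is rejected up front
  fx <- shellFixture()
  expect_error(candidateMatrix(fx$mask, c(0, 30, 0), roc = 30),
               "inside the skull cavity")
})

test_that("control poses rotate from the coronal axis in both planes", {
  tg <- c(3, -2, 5)
  ctrl <- controlGroupPlacement(tg, roc = 30)
  ## 0 degrees: the coronal-axis baseline, reported once
  expect_equal(sum(ctrl$angle_deg == 0), 1)
  expect_equal(as.numeric(ctrl[ctrl$angle_deg == 0, c("x_mm", "y_mm", "z_mm")]),
               tg + c(0, 30, 0))
  ## transverse 30 degrees (frozen rotation arithmetic)
  t30 <- ctrl[ctrl$plane == "transverse" & ctrl$angle_deg == 30, ]
  expect_equal(as.numeric(t30[c("x_mm", "y_mm", "z_mm")]),
               tg + c(15, 25.98076, 0), tolerance = 1e-6)
  ## counts: |angles| * |planes| - duplicate baseline
  expect_equal(nrow(ctrl), 4 * 2 - 1)
  ## every pose at stimulation distance ROC; shear caveat beyond 45 degrees
  d <- sqrt(rowSums(sweep(as.matrix(ctrl[, c("x_mm", "y_mm", "z_mm")]),
                          2, tg)^2))
  expect_equal(d, rep(30, 7), tolerance = 1e-9)
  expect_identical(ctrl$shear_caveat, ctrl$angle_deg > 45)
})

test_that("positioning picks the single candidate and is deterministic", {
  fx <- shellFixture(outer = 16, thickness = 4, domain = 44,
                     target = c(0, -4, 0))
  drive <- pulseSequence(fundamentalFrequency = 250e3)
  spec <- transducerSpec(30, 25)
  cm <- candidateMatrix(fx$mask, fx$target, roc = 30)
  ## single candidate: trivially chosen
  one <- new("CandidateMatrix", candidates = candidates(cm)[7, , drop = FALSE],
             modelCentre = cm@modelCentre,
             meanCentreShellDistance = cm@meanCentreShellDistance,
             excluded = cm@excluded, target = cm@target)
  p1 <- positionTransducer(one, spec, fx$medium, drive, mode = "2d",
                           settlePeriods = 6, measurePeriods = 2)
  expect_equal(chosenCentre(p1), as.numeric(candidates(cm)[7, 1:3]))
  ## same seed, same subsample, identical result tables
  pa <- positionTransducer(cm, spec, fx$medium, drive, mode = "2d",
                           maxCandidates = 2, seed = 11,
                           settlePeriods = 6, measurePeriods = 2)
  pb <- positionTransducer(cm, spec, fx$medium, drive, mode = "2d",
                           maxCandidates = 2, seed = 11,
                           settlePeriods = 6, measurePeriods = 2)
  expect_identical(pa@table, pb@table)
  expect_true(sum(pa@table$chosen_flag) == 1)
  expect_equal(max(pa@table$target_amplitude_Pa),
               pa@table$target_amplitude_Pa[pa@table$chosen_flag])
})
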