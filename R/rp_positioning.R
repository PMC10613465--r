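## Radius positioning (RP): candidate-matrix screening and peak-pressure
## transducer placement.
##
## A ball of the bowl's radius of curvature is drawn around the
## intracranial target. Ball voxels on the skull shell set the mean
## centre-to-shell distance; ball voxels outside the filled skull volume,
## farther from the model centre than that mean and clear of skull contact
## form the candidate matrix. Each candidate is then simulated with the
## bowl aimed at the target and the candidate with peak target amplitude
## wins.

#' Geometric centre of a skull model
#'
#' Per axis, the midpoint between the minimum and maximum mask extent,
#' converted to world coordinates. For disjoint components this is the
#' midpoint of the combined bounding extent.
#'
#' @param mask a [SkullMask-class]
#' @return world mm
#' @export
modelCentre <- function(mask) {
  stopifnot(is(mask, "SkullMask"))
  idx <- which(mask@data > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  mid0 <- (apply(idx, 2, min) + apply(idx, 2, max)) / 2 - 1
  as.numeric(voxelToWorld(mid0, mask@spacing, mask@origin))
}

#' Default skull-contact clearance: depth of the bowl cap
#'
#' `ROC - sqrt(ROC^2 - (diameter/2)^2)`, about 2.73 mm for a 30 mm ROC,
#' 25 mm aperture bowl.
#'
#' @param spec a [TransducerSpec-class]
#' @return mm
#' @export
bowlCapDepth <- function(spec) {
  r <- spec@radiusOfCurvature
  r - sqrt(r^2 - (spec@apertureDiameter / 2)^2)
}

#' RP candidate matrix for a target inside a skull
#'
#' Screening rules, applied to voxel centres:
#' 1. the search ball: all voxels within `ROC + ballMargin` of the target;
#' 2. shell hits = ball voxels on the skull mask; their mean distance to
#'    the model centre defines the mean-radius rule (an error is raised if
#'    the skull is nowhere within reach);
#' 3. candidates = ball voxels outside the *filled* skull volume (shell
#'    plus intracranial cavity) whose distance to the model centre exceeds
#'    that mean;
#' 4. candidates closer than `clearance` to any skull voxel are removed
#'    (transducer-skull contact).
#' By construction no candidate is intracranial or on the skull.
#'
#' @param mask a [SkullMask-class]
#' @param target world mm, strictly intracranial
#' @param roc search-ball radius = bowl radius of curvature, mm
#' @param clearance minimum candidate-to-skull distance, mm; default the
#'   bowl cap depth for the default transducer
#' @param ballMargin additive enlargement of the search ball, mm (default 0)
#' @param filled optional precomputed [fillSkullVolume()] result
#' @return a [CandidateMatrix-class]
#' @export
candidateMatrix <- function(mask, target, roc = 30,
                            clearance = bowlCapDepth(transducerSpec()),
                            ballMargin = 0, filled = NULL) {
  stopifnot(is(mask, "SkullMask"), roc > 0)
  d <- dim(mask@data)
  target <- as.numeric(target)[1:3]
  if (is.null(filled)) filled <- fillSkullVolume(mask)
  if (!isIntracranial(mask, target, filled))
    stop("target must lie strictly inside the skull cavity")
  ctr <- modelCentre(mask)
  cx <- axisCoords(d[1], mask@spacing[1], mask@origin[1])
  cy <- axisCoords(d[2], mask@spacing[2], mask@origin[2])
  cz <- axisCoords(d[3], mask@spacing[3], mask@origin[3])
  dt2 <- outer(outer((cx - target[1])^2, (cy - target[2])^2, "+"),
               (cz - target[3])^2, "+")
  ball <- dt2 <= (roc + ballMargin)^2
  inSkull <- mask@data > 0
  shellHits <- ball & inSkull
  if (!any(shellHits))
    stop("no reachable placement: skull nowhere within ROC of the target")
  dc2 <- outer(outer((cx - ctr[1])^2, (cy - ctr[2])^2, "+"),
               (cz - ctr[3])^2, "+")
  meanD <- mean(sqrt(dc2[shellHits]))
  insideFilled <- ball & filled
  beyondMean <- sqrt(dc2) > meanD
  cand <- ball & !filled & beyondMean
  nInSkull <- sum(ball & inSkull)
  nIntracranial <- sum(insideFilled & !inSkull)
  nBelowMean <- sum(ball & !filled & !beyondMean)
  ## contact clearance: distance from each candidate to the nearest skull
  ## voxel, restricted to skull voxels near the ball for speed
  candIdx <- which(cand, arr.ind = TRUE)
  nContact <- 0L
  if (nrow(candIdx) > 0 && clearance > 0) {
    near <- which(inSkull & dt2 <= (roc + ballMargin + clearance + max(mask@spacing))^2,
                  arr.ind = TRUE)
    if (nrow(near) > 0) {
      candW <- sweep(candIdx - 1, 2, mask@spacing, `*`) +
        matrix(mask@origin, nrow(candIdx), 3, byrow = TRUE)
      nearW <- sweep(near - 1, 2, mask@spacing, `*`) +
        matrix(mask@origin, nrow(near), 3, byrow = TRUE)
      minD <- minCrossDist(candW, nearW)
      keep <- minD >= clearance
      nContact <- sum(!keep)
      candIdx <- candIdx[keep, , drop = FALSE]
    }
  }
  candW <- sweep(candIdx - 1, 2, mask@spacing, `*`) +
    matrix(mask@origin, nrow(candIdx), 3, byrow = TRUE)
  dtg <- sqrt(rowSums(sweep(candW, 2, target, `-`)^2))
  df <- data.frame(x_mm = candW[, 1], y_mm = candW[, 2], z_mm = candW[, 3],
                   dist_to_target_mm = dtg)
  new("CandidateMatrix", candidates = df, modelCentre = ctr,
      meanCentreShellDistance = meanD,
      excluded = c(inside_skull = nInSkull, intracranial = nIntracranial,
                   below_average_radius = nBelowMean,
                   contact_clearance = nContact),
      target = target)
}

#' Chunked minimum cross-distance between two point sets
#' @noRd
minCrossDist <- function(a, b, chunk = 512L) {
  out <- numeric(nrow(a))
  b2 <- rowSums(b^2)
  for (s in seq(1, nrow(a), by = chunk)) {
    e <- min(s + chunk - 1, nrow(a))
    blk <- a[s:e, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), b2, "+") - 2 * blk %*% t(b)
    out[s:e] <- sqrt(pmax(0, apply(d2, 1, min)))
  }
  out
}

#' Control-group transducer poses at fixed directional angles
#'
#' Places the bowl centre at distance ROC from the target along directions
#' rotated from the coronal (y) axis by the given angles, within the
#' transverse (xy) and coronal (yz) planes, aimed at the target. The 0
#' degree poses of the two planes coincide (the coronal-axis baseline) and
#' are reported once. Angles above 45 degrees are flagged: at such oblique
#' incidence the neglect of shear-wave conversion in the skull becomes
#' questionable.
#'
#' @param target world mm
#' @param roc mm, stimulation distance of each control pose
#' @param angles degrees, default `c(0, 30, 45, 60)`
#' @param planes subset of `c("transverse", "coronal")`
#' @return data.frame with plane, angle_deg, centre coordinates and a
#'   `shear_caveat` flag
#' @export
controlGroupPlacement <- function(target, roc = 30,
                                  angles = c(0, 30, 45, 60),
                                  planes = c("transverse", "coronal")) {
  stopifnot(roc > 0)
  target <- as.numeric(target)[1:3]
  rows <- list()
  seen0 <- FALSE
  for (pl in planes) for (a in angles) {
    if (a == 0) { if (seen0) next; seen0 <- TRUE }
    th <- a * pi / 180
    dir <- if (pl == "transverse") c(sin(th), cos(th), 0)
           else c(0, cos(th), sin(th))
    ctr <- target + roc * dir
    rows[[length(rows) + 1]] <- data.frame(
      plane = if (a == 0) "baseline" else pl, angle_deg = a,
      x_mm = ctr[1], y_mm = ctr[2], z_mm = ctr[3],
      shear_caveat = a > 45)
  }
  do.call(rbind, rows)
}

#' Extract a 2D plane slice of a 3D medium through two points
#'
#' Builds a 2D medium on the plane spanned by the beam direction (from
#' `from` toward `to`) and a perpendicular, sampling the 3D property maps
#' by nearest neighbour. Used by the desk-scale 2D positioning mode.
#'
#' @param medium a 3D [MediumMaps-class]
#' @param from,to world mm; the plane contains both
#' @param extent c(length, width) of the 2D domain, mm
#' @param spacing 2D voxel size, mm
#' @param centre world mm mapped to the 2D domain centre (default midpoint)
#' @return list with `medium2d` ([MediumMaps-class]), `toPlane(points)` and
#'   `fromPlane(points2d)` coordinate mappers
#' @export
sliceMedium <- function(medium, from, to, extent, spacing = min(medium@spacing),
                        centre = (from + to) / 2) {
  stopifnot(is(medium, "MediumMaps"), length(dim(medium)) == 3)
  e1 <- to - from; e1 <- e1 / sqrt(sum(e1^2))
  ref <- if (abs(e1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e2 <- ref - sum(ref * e1) * e1; e2 <- e2 / sqrt(sum(e2^2))
  dims2 <- as.integer(round(extent / spacing))
  org2 <- -(dims2 - 1) * spacing / 2
  a <- axisCoords(dims2[1], spacing, org2[1])
  b <- axisCoords(dims2[2], spacing, org2[2])
  ## world coordinates of every plane voxel
  pts <- cbind(rep(a, times = dims2[2]), rep(b, each = dims2[1]))
  w <- matrix(centre, nrow(pts), 3, byrow = TRUE) +
    pts[, 1] %o% e1 + pts[, 2] %o% e2
  pos <- sweep(sweep(w, 2, medium@origin, `-`), 2, medium@spacing, `/`)
  d3 <- dim(medium)
  pos <- pmin(pmax(pos, 0), matrix(d3 - 1, nrow(pos), 3, byrow = TRUE))
  lo <- pmin(floor(pos), matrix(d3 - 2, nrow(pos), 3, byrow = TRUE))
  fr <- pos - lo
  strides <- cumprod(c(1, d3[-3]))
  corner <- function(ox, oy, oz)
    1 + (lo + matrix(c(ox, oy, oz), nrow(lo), 3, byrow = TRUE)) %*% strides
  cidx <- list(corner(0,0,0), corner(1,0,0), corner(0,1,0), corner(1,1,0),
               corner(0,0,1), corner(1,0,1), corner(0,1,1), corner(1,1,1))
  cwt <- list((1-fr[,1])*(1-fr[,2])*(1-fr[,3]), fr[,1]*(1-fr[,2])*(1-fr[,3]),
              (1-fr[,1])*fr[,2]*(1-fr[,3]),     fr[,1]*fr[,2]*(1-fr[,3]),
              (1-fr[,1])*(1-fr[,2])*fr[,3],     fr[,1]*(1-fr[,2])*fr[,3],
              (1-fr[,1])*fr[,2]*fr[,3],         fr[,1]*fr[,2]*fr[,3])
  ## trilinear sampling of the 3D property fields onto the plane
  mk <- function(arr, logical = FALSE) {
    v <- 0
    for (q in 1:8) v <- v + cwt[[q]] * arr[cidx[[q]]]
    if (logical) array(v >= 0.5, dims2) else array(v, dims2)
  }
  m2 <- new("MediumMaps", soundSpeed = mk(medium@soundSpeed),
            density = mk(medium@density), alpha0 = mk(medium@alpha0),
            BonA = mk(medium@BonA), mask = mk(medium@mask + 0, logical = TRUE),
            spacing = rep(spacing, 2), origin = org2,
            powerLawExponent = medium@powerLawExponent,
            constants = medium@constants)
  toPlane <- function(p) {
    p <- rbind(p); rel <- sweep(p, 2, centre, `-`)
    cbind(rel %*% e1, rel %*% e2)
  }
  fromPlane <- function(p2) {
    p2 <- rbind(p2)
    matrix(centre, nrow(p2), 3, byrow = TRUE) + p2[, 1] %o% e1 + p2[, 2] %o% e2
  }
  list(medium2d = m2, toPlane = toPlane, fromPlane = fromPlane,
       e1 = e1, e2 = e2, centre = centre)
}

#' Target amplitude of one bowl pose
#'
#' Simulates a bowl with apex at `centre` aimed at `target` and returns the
#' steady-state amplitude at the target voxel. In `mode = "2d"` the medium
#' is sliced on the plane through centre and target (desk-scale default);
#' `mode = "3d"` runs the full volume.
#'
#' @param centre,target world mm
#' @param spec a [TransducerSpec-class]
#' @param medium a 3D [MediumMaps-class]
#' @param drive a [PulseSequence-class]
#' @param mode `"2d"` or `"3d"`
#' @param settlePeriods,measurePeriods solver windows (carrier periods)
#' @param cfl,pmlWidth solver settings
#' @param extent2d 2D domain size, mm (default fits bowl and skull)
#' @param spacing2d 2D voxel size, mm
#' @return list with `amplitude` (Pa at target) and the `field`
#' @export
simulatePose <- function(centre, target, spec, medium, drive,
                         mode = c("2d", "3d"), settlePeriods = 15,
                         measurePeriods = 5, cfl = 0.3, pmlWidth = 10L,
                         extent2d = NULL, spacing2d = min(medium@spacing)) {
  mode <- match.arg(mode)
  if (mode == "2d") {
    L <- sqrt(sum((target - centre)^2))
    if (is.null(extent2d)) {
      ## beam corridor: apex-to-target plus post-focal room along the beam,
      ## aperture plus clearance across it (PML included on all sides)
      pmlmm <- pmlWidth * spacing2d
      extent2d <- c(L + 18 + 2 * (pmlmm + 3),
                    spec@apertureDiameter + 2 * (pmlmm + 5))
    }
    sl <- sliceMedium(medium, from = centre, to = target, extent = extent2d,
                      spacing = spacing2d)
    m2 <- sl$medium2d
    grid <- makeGrid(m2, cfl = cfl, pmlWidth = pmlWidth)
    c2 <- as.numeric(sl$toPlane(centre)); t2 <- as.numeric(sl$toPlane(target))
    src <- discretizeBowl(spec, c2, t2, grid)
    fld <- propagate(grid, m2, src, drive, probes = matrix(t2, 1),
                     settlePeriods = settlePeriods,
                     measurePeriods = measurePeriods)
    tv <- worldToVoxel(t2, m2@spacing, m2@origin)
    amp <- fld@amplitude[matrix(tv + 1L, 1)]
    return(list(amplitude = amp, field = fld, medium = m2,
                targetVoxel = tv + 1L, slice = sl, targetLocal = t2,
                beamAxis2d = (t2 - c2) / sqrt(sum((t2 - c2)^2))))
  } else {
    grid <- makeGrid(medium, cfl = cfl, pmlWidth = pmlWidth)
    src <- discretizeBowl(spec, centre, target, grid)
    fld <- propagate(grid, medium, src, drive,
                     probes = matrix(target, 1),
                     settlePeriods = settlePeriods,
                     measurePeriods = measurePeriods)
    tv <- worldToVoxel(target, medium@spacing, medium@origin)
    amp <- fld@amplitude[matrix(tv + 1L, 1)]
  }
  list(amplitude = amp, field = fld, medium = medium, targetVoxel = tv + 1L,
       slice = NULL, targetLocal = target, beamAxis2d = NULL)
}

#' Position the transducer by peak target pressure
#'
#' Simulates every (optionally subsampled) candidate with the bowl aimed at
#' the target, records the steady-state amplitude at the target voxel and
#' selects the candidate with maximal amplitude. Ties are broken by
#' smallest distance to target, then by lexicographic candidate order.
#' Control-group poses, when requested, are simulated identically and
#' reported with their amplitude ratio to the chosen candidate.
#'
#' @param cm a [CandidateMatrix-class]
#' @param spec a [TransducerSpec-class]
#' @param medium a 3D [MediumMaps-class]
#' @param drive a [PulseSequence-class]
#' @param mode `"2d"` (plane-slice, desk-scale default) or `"3d"`
#' @param subsample evaluate every k-th candidate (stride; default 1 = all)
#' @param maxCandidates random subsample cap (applied after stride; uses
#'   `seed`)
#' @param seed RNG seed for the random subsample
#' @param controls optional data.frame from [controlGroupPlacement()]
#' @param ... passed to [simulatePose()]
#' @return a [PositioningResult-class]
#' @export
positionTransducer <- function(cm, spec, medium, drive, mode = "2d",
                               subsample = 1L, maxCandidates = Inf,
                               seed = 1L, controls = NULL, ...) {
  stopifnot(is(cm, "CandidateMatrix"))
  cand <- cm@candidates
  if (nrow(cand) == 0) stop("candidate list is empty")
  sel <- seq(1, nrow(cand), by = subsample)
  if (length(sel) > maxCandidates) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    sel <- sort(sample(sel, maxCandidates))
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  tab <- cand[sel, , drop = FALSE]
  tab$target_amplitude_Pa <- NA_real_
  for (i in seq_len(nrow(tab))) {
    ctr <- as.numeric(tab[i, c("x_mm", "y_mm", "z_mm")])
    amp <- tryCatch(
      simulatePose(ctr, cm@target, spec, medium, drive, mode = mode,
                   ...)$amplitude,
      error = function(e) {
        warning(sprintf("candidate %d skipped: %s", i, conditionMessage(e)))
        NA_real_
      })
    tab$target_amplitude_Pa[i] <- amp
  }
  ok <- which(!is.na(tab$target_amplitude_Pa))
  if (length(ok) == 0) stop("all candidate simulations failed")
  ord <- ok[order(-tab$target_amplitude_Pa[ok], tab$dist_to_target_mm[ok], ok)]
  best <- ord[1]
  tab$chosen_flag <- seq_len(nrow(tab)) == best
  chosen <- as.numeric(tab[best, c("x_mm", "y_mm", "z_mm")])
  ctrlTab <- data.frame()
  if (!is.null(controls) && nrow(controls) > 0) {
    controls$target_amplitude_Pa <- NA_real_
    for (i in seq_len(nrow(controls))) {
      ctr <- as.numeric(controls[i, c("x_mm", "y_mm", "z_mm")])
      controls$target_amplitude_Pa[i] <- tryCatch(
        simulatePose(ctr, cm@target, spec, medium, drive, mode = mode,
                     ...)$amplitude,
        error = function(e) NA_real_)
    }
    controls$ratio <- controls$target_amplitude_Pa /
      tab$target_amplitude_Pa[best]
    ctrlTab <- controls
  }
  new("PositioningResult", chosenCentre = chosen, table = tab,
      controls = ctrlTab, target = cm@target)
}
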