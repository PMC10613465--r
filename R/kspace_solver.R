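## k-space pseudospectral solver for the first-order linear acoustic system
##
##   du/dt   = -(1/rho0) grad(p)          (momentum, staggered grids)
##   drho/dt = -rho0 div(u) + source      (continuity, split per axis for PML)
##   p       = c0^2 (rho + absorption)    (pressure closure)
##
## Spatial derivatives are spectral with the k-space temporal correction
## kappa = sinc(c_ref |k| dt / 2); heterogeneous density is handled with
## staggered-grid spectral gradients; power-law absorption follows the
## fractional-Laplacian closure with heterogeneous prefactors applied in
## real space; boundaries are absorbed by a quartic-profile PML applied to
## the split velocity/density components.

#' Build a simulation grid for a medium
#'
#' Sets the time step from the CFL rule `dt = cfl * min(dx) / max(c)` using
#' the medium's maximum sound speed. Grid dimensions are taken from the
#' medium as-is (R's mixed-radix FFT handles arbitrary sizes; sizes with
#' small prime factors run fastest). At least 8 voxels per axis must remain
#' inside the PML; fewer than 32 draws a warning.
#'
#' @param medium a [MediumMaps-class]
#' @param cfl Courant-Friedrichs-Lewy number, default 0.3
#' @param pmlWidth absorbing layer width in voxels per axis (default 10;
#'   use 0 with `pmlAxes = FALSE` in [propagate()] for periodic runs)
#' @param refSpeed reference speed for the k-space correction, m/s; default
#'   the medium's maximum sound speed
#' @param frequency optional drive frequency, Hz; when given, spatial
#'   sampling below 3 points per wavelength draws a warning (or an error
#'   with `ppwError = TRUE`)
#' @param ppwError escalate the points-per-wavelength warning to an error
#' @return a [SimulationGrid-class]
#' @export
makeGrid <- function(medium, cfl = 0.3, pmlWidth = 10L, refSpeed = NULL,
                     frequency = NULL, ppwError = FALSE) {
  stopifnot(is(medium, "MediumMaps"))
  if (cfl <= 0 || cfl > 1) stop("cfl must lie in (0, 1] (stability bound)")
  d <- dim(medium)
  pmlWidth <- rep(as.integer(pmlWidth), length.out = length(d))
  interior <- d - 2L * pmlWidth
  if (any(interior < 8)) stop("domain too small inside the PML")
  if (any(interior < 32))
    warning("fewer than 32 voxels per axis inside the PML")
  cmax <- max(medium@soundSpeed)
  dxm <- min(medium@spacing) * 1e-3
  dt <- cfl * dxm / cmax
  if (!is.null(frequency)) {
    ppw <- min(medium@soundSpeed) / frequency / dxm
    if (ppw < 3) {
      msg <- sprintf("spatial sampling is %.2f points per wavelength (< 3)", ppw)
      if (ppwError) stop(msg) else warning(msg)
    }
  }
  new("SimulationGrid", dims = as.integer(d), spacing = medium@spacing,
      origin = medium@origin, dt = dt, cfl = cfl,
      pmlWidth = pmlWidth,
      refSpeed = refSpeed %||% cmax)
}

#' Discretize a focused bowl source onto a simulation grid
#'
#' The cap apex sits at `centerPosition`; the beam axis points from the
#' apex toward `focusPoint`; the centre of curvature (geometric focus) lies
#' at `apex + ROC * axis`. Active voxels are those within half a voxel of
#' the sphere of radius ROC about the centre of curvature and within the
#' cap half-angle `asin(diameter / (2 ROC))` of the apex direction. In 2D
#' grids the cap degenerates to a focused arc.
#'
#' @param spec a [TransducerSpec-class]
#' @param centerPosition world mm of the cap apex
#' @param focusPoint world mm the bowl is aimed at
#' @param grid a [SimulationGrid-class]
#' @return a [SourceGeometry-class]
#' @export
discretizeBowl <- function(spec, centerPosition, focusPoint, grid) {
  stopifnot(is(spec, "TransducerSpec"), is(grid, "SimulationGrid"))
  nd <- length(grid@dims)
  centerPosition <- as.numeric(centerPosition)[seq_len(nd)]
  focusPoint <- as.numeric(focusPoint)[seq_len(nd)]
  axis <- focusPoint - centerPosition
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-9) stop("degenerate (zero-length) bowl axis")
  axis <- axis / nrm
  roc <- spec@radiusOfCurvature
  halfAngle <- asin(spec@apertureDiameter / (2 * roc))
  ctr <- centerPosition + roc * axis   # centre of curvature
  ## bounding check: apex and rim must lie inside the grid
  gmin <- grid@origin; gmax <- grid@origin + (grid@dims - 1) * grid@spacing
  rim <- capRimSamples(ctr, -axis, roc, halfAngle, nd)
  pts <- rbind(centerPosition, rim)
  if (any(sweep(pts, 2, gmin - 1e-9, `<`)) ||
      any(sweep(pts, 2, gmax + 1e-9, `>`)))
    stop("bowl clipped by the simulation domain")
  coords <- lapply(seq_len(nd), function(j)
    axisCoords(grid@dims[j], grid@spacing[j], grid@origin[j]) - ctr[j])
  ## squared distance to centre of curvature and cosine with apex direction
  r2 <- 0; dotA <- 0
  for (j in seq_len(nd)) {
    cj <- coords[[j]]
    shape <- rep(1L, nd); shape[j] <- grid@dims[j]
    cArr <- array(rep(cj, each = prod(grid@dims[seq_len(j - 1)])),
                  dim = grid@dims)
    r2 <- r2 + cArr^2
    dotA <- dotA + cArr * (-axis[j])
  }
  r <- sqrt(r2)
  tol <- max(grid@spacing) / 2
  onSphere <- abs(r - roc) <= tol
  inCap <- dotA >= r * cos(halfAngle) - 1e-9
  act <- which(onSphere & inCap, arr.ind = TRUE)
  if (nrow(act) == 0) stop("active voxel set is empty (bowl not resolvable)")
  new("SourceGeometry", activeIndices = act - 1L,
      weights = rep(1, nrow(act)), apex = centerPosition, axis = axis,
      centreOfCurvature = ctr)
}

#' @noRd
capRimSamples <- function(ctr, apexDir, roc, halfAngle, nd, n = 16) {
  if (nd == 2) {
    e2 <- c(-apexDir[2], apexDir[1])
    ang <- c(-halfAngle, halfAngle)
    t(sapply(ang, function(a)
      ctr + roc * (cos(a) * apexDir + sin(a) * e2)))
  } else {
    ref <- if (abs(apexDir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e2 <- ref - sum(ref * apexDir) * apexDir; e2 <- e2 / sqrt(sum(e2^2))
    e3 <- c(apexDir[2] * e2[3] - apexDir[3] * e2[2],
            apexDir[3] * e2[1] - apexDir[1] * e2[3],
            apexDir[1] * e2[2] - apexDir[2] * e2[1])
    phi <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    t(sapply(phi, function(p)
      ctr + roc * (cos(halfAngle) * apexDir +
                     sin(halfAngle) * (cos(p) * e2 + sin(p) * e3))))
  }
}

#' @noRd
axisArray <- function(vec, ax, dims) {
  array(rep(vec, each = prod(dims[seq_len(ax - 1)])), dim = dims)
}

#' @noRd
wavenumbers <- function(n, dxm) {
  idx <- 0:(n - 1)
  ifelse(idx <= n / 2, idx, idx - n) * 2 * pi / (n * dxm)
}

#' @noRd
pmlProfile <- function(n, w, sigmaMax, dt, staggered = FALSE) {
  pos <- seq_len(n) - 1 + if (staggered) 0.5 else 0
  s <- numeric(n)
  if (w > 0) {
    left <- pmax(0, (w - pos) / w)
    right <- pmax(0, (pos - (n - 1 - w)) / w)
    s <- sigmaMax * (pmax(left, right))^4
  }
  exp(-s * dt / 2)
}

#' Staggered-grid density: average along +half step with edge replication
#' @noRd
staggeredAvg <- function(a, ax) {
  d <- dim(a); n <- d[ax]
  idx <- lapply(d, seq_len)
  idx[[ax]] <- c(2:n, n)
  (a + do.call(`[`, c(list(a), idx, list(drop = FALSE)))) / 2
}

#' Propagate acoustic waves through a heterogeneous medium
#'
#' Runs the k-space pseudospectral scheme with a continuous sinusoidal
#' drive at the fundamental frequency of `drive` (one tone burst at cyclic
#' steady state; the full pulsed schedule matters only for thermal dosing).
#' The steady-state amplitude map is the per-voxel maximum of |p| over the
#' trailing `measurePeriods` carrier periods, after `settlePeriods` periods
#' of settling.
#'
#' @param grid a [SimulationGrid-class]
#' @param medium a [MediumMaps-class] on the same grid
#' @param source a [SourceGeometry-class], or NULL for source-free runs
#' @param drive a [PulseSequence-class] (carrier frequency and source
#'   pressure are used), or NULL
#' @param probes optional matrix of world points (one row per probe) or
#'   named list of points at which full time traces are recorded
#' @param settlePeriods carrier periods before the measurement window (40)
#' @param measurePeriods carrier periods in the measurement window (10)
#' @param sourceMode `"additive"` (mass source, default) or `"dirichlet"`
#'   (pressure imposed at the active voxels)
#' @param p0 optional initial pressure array (Pa)
#' @param pmlAxes logical per axis; FALSE leaves that axis periodic
#' @param absorption `"auto"` (on when the medium attenuation is
#'   non-negligible), `"on"` or `"off"`
#' @param nSteps override the number of time steps
#' @param trackEnergy record total acoustic energy per step (attribute
#'   `"energy"` of the result)
#' @return a [PressureField-class]
#' @export
propagate <- function(grid, medium, source, drive, probes = NULL,
                      settlePeriods = 40, measurePeriods = 10,
                      sourceMode = c("additive", "dirichlet"), p0 = NULL,
                      pmlAxes = TRUE, absorption = c("auto", "on", "off"),
                      nSteps = NULL, trackEnergy = FALSE) {
  stopifnot(is(grid, "SimulationGrid"), is(medium, "MediumMaps"))
  sourceMode <- match.arg(sourceMode)
  absorption <- match.arg(absorption)
  dims <- grid@dims; nd <- length(dims); Ntot <- prod(dims)
  if (!identical(as.integer(dim(medium)), dims))
    stop("medium and grid dimensions differ")
  dt <- grid@dt
  dxm <- medium@spacing * 1e-3
  pmlAxes <- rep(pmlAxes, length.out = nd)

  ff <- if (!is.null(drive)) drive@fundamentalFrequency else NULL
  amp0 <- if (!is.null(drive)) drive@sourcePressure else 0
  if (is.null(nSteps)) {
    if (is.null(ff)) stop("nSteps must be given for source-free runs")
    nSteps <- ceiling((settlePeriods + measurePeriods) / ff / dt)
  }
  measureStart <- if (!is.null(ff))
    max(1L, nSteps - ceiling(measurePeriods / ff / dt) + 1L) else 1L

  ## spectral operators
  kv <- lapply(seq_len(nd), function(j) wavenumbers(dims[j], dxm[j]))
  k2 <- 0
  for (j in seq_len(nd)) k2 <- k2 + axisArray(kv[[j]]^2, j, dims)
  kabs <- sqrt(k2)
  kappa <- ifelse(kabs == 0, 1, sin(grid@refSpeed * kabs * dt / 2) /
                    (grid@refSpeed * kabs * dt / 2))
  Dp <- Dm <- vector("list", nd)
  for (j in seq_len(nd)) {
    kj <- axisArray(kv[[j]], j, dims)
    Dp[[j]] <- 1i * kj * kappa * exp( 1i * kj * dxm[j] / 2)
    Dm[[j]] <- 1i * kj * kappa * exp(-1i * kj * dxm[j] / 2)
  }

  rho0 <- medium@density; c0 <- medium@soundSpeed; c0sq <- c0^2
  rho0sg <- lapply(seq_len(nd), function(j) staggeredAvg(rho0, j))

  ## PML factors
  pmlR <- pmlS <- vector("list", nd)
  for (j in seq_len(nd)) {
    w <- if (pmlAxes[j]) grid@pmlWidth[j] else 0L
    sigMax <- 2 * grid@refSpeed / dxm[j]
    pmlR[[j]] <- axisArray(pmlProfile(dims[j], w, sigMax, dt, FALSE), j, dims)
    pmlS[[j]] <- axisArray(pmlProfile(dims[j], w, sigMax, dt, TRUE), j, dims)
  }

  ## power-law absorption closure
  y <- medium@powerLawExponent
  useAbs <- switch(absorption, on = TRUE, off = FALSE,
                   auto = max(medium@alpha0) > 1e-2)
  if (useAbs) {
    a0w <- medium@alpha0 / (2 * pi * 1e6)^y     # Np/(rad/s)^y/m
    absTau <- -2 * a0w * c0^(y - 1)
    absEta <- 2 * a0w * c0^y * tan(pi * y / 2)
    nab1 <- ifelse(kabs == 0, 0, kabs^(y - 2)) * kappa
    nab2 <- ifelse(kabs == 0, 0, kabs^(y - 1)) * kappa
  }

  ## source bookkeeping
  hasSrc <- !is.null(source) && !is.null(drive)
  if (hasSrc) {
    stopifnot(is(source, "SourceGeometry"))
    srcIdx <- 1L + as.integer(
      source@activeIndices %*% cumprod(c(1L, dims[-nd])))
    srcW <- source@weights
    srcC <- c0[srcIdx]; srcC2 <- c0sq[srcIdx]
    addScale <- 2 * dt / (min(dxm) * srcC) / nd    # additive: delta-rho per unit Pa
  }

  ## probes
  probeIdx <- integer(0); probeNames <- character(0)
  if (!is.null(probes)) {
    if (is.list(probes)) { probeNames <- names(probes); probes <- do.call(rbind, probes) }
    else probeNames <- paste0("probe", seq_len(nrow(probes)))
    probeIdx <- apply(probes, 1, function(pt) {
      vi <- worldToVoxel(pt[seq_len(nd)], medium@spacing, medium@origin)
      if (any(vi < 0) || any(vi >= dims)) stop("probe outside the grid")
      1L + sum(vi * cumprod(c(1L, dims[-nd])))
    })
  }

  ## state
  u <- lapply(seq_len(nd), function(j) array(0, dims))
  rhoC <- lapply(seq_len(nd), function(j) array(0, dims))
  p <- array(0, dims)
  if (!is.null(p0)) {
    p <- array(as.numeric(p0), dims)
    for (j in seq_len(nd)) rhoC[[j]] <- p / (nd * c0sq)
  }
  ampMap <- array(0, dims)
  traces <- matrix(0, nSteps, length(probeIdx))
  energy <- if (trackEnergy) numeric(nSteps) else NULL
  dV <- prod(dxm)
  duxdx <- vector("list", nd)

  uPrev <- if (trackEnergy) lapply(u, identity) else NULL
  for (n in seq_len(nSteps)) {
    if (trackEnergy) { for (j in seq_len(nd)) uPrev[[j]] <- u[[j]]; pOld <- p }
    Phat <- fft(p)
    for (j in seq_len(nd)) {
      dpdx <- Re(fft(Dp[[j]] * Phat, inverse = TRUE)) / Ntot
      u[[j]] <- pmlS[[j]] * (pmlS[[j]] * u[[j]] -
                               (dt / rho0sg[[j]]) * dpdx)
    }
    for (j in seq_len(nd)) {
      duxdx[[j]] <- Re(fft(Dm[[j]] * fft(u[[j]]), inverse = TRUE)) / Ntot
      rhoC[[j]] <- pmlR[[j]] * (pmlR[[j]] * rhoC[[j]] -
                                  dt * rho0 * duxdx[[j]])
    }
    if (hasSrc) {
      st <- amp0 * sin(2 * pi * ff * (n - 1) * dt)
      if (sourceMode == "additive") {
        for (j in seq_len(nd))
          rhoC[[j]][srcIdx] <- rhoC[[j]][srcIdx] + srcW * st * addScale
      } else {
        for (j in seq_len(nd))
          rhoC[[j]][srcIdx] <- srcW * st / (nd * srcC2)
      }
    }
    rhoSum <- rhoC[[1]]
    for (j in seq_len(nd)[-1]) rhoSum <- rhoSum + rhoC[[j]]
    if (useAbs) {
      dsum <- duxdx[[1]]
      for (j in seq_len(nd)[-1]) dsum <- dsum + duxdx[[j]]
      p <- c0sq * (rhoSum +
        absTau * (Re(fft(nab1 * fft(rho0 * dsum), inverse = TRUE)) / Ntot) +
        absEta * (Re(fft(nab2 * fft(rhoSum), inverse = TRUE)) / Ntot))
    } else {
      p <- c0sq * rhoSum
    }
    if (length(probeIdx)) traces[n, ] <- p[probeIdx]
    if (n >= measureStart) ampMap <- pmax(ampMap, abs(p))
    if (trackEnergy) {
      ## discrete leapfrog invariant: kinetic term is the product of the
      ## half-step velocities bracketing the pressure level they straddle
      e <- sum(pOld^2 / (2 * rho0 * c0sq))
      for (j in seq_len(nd))
        e <- e + sum(rho0sg[[j]] * u[[j]] * uPrev[[j]]) / 2
      energy[n] <- e * dV
    }
    if (hasSrc && n %% 50 == 0 && max(abs(p)) > 10 * amp0)
      stop(sprintf("instability detected at step %d: |p| exceeds 10x source", n))
  }

  pnp <- if (length(probeIdx)) {
    apply(traces[measureStart:nSteps, , drop = FALSE], 2, function(tr) -min(tr))
  } else numeric(0)
  out <- new("PressureField", amplitude = ampMap, spacing = medium@spacing,
             origin = medium@origin, probeTraces = traces,
             probeNames = probeNames, peakNegativePressure = pnp,
             dt = dt, nSteps = as.integer(nSteps))
  if (trackEnergy) attr(out, "energy") <- energy
  out
}

#' Steady-state amplitude and peak negative pressure from a time trace
#'
#' Estimates the cyclic steady-state amplitude of a pressure trace as the
#' maximum |p| over the final `measurePeriods` carrier periods (default),
#' or as sqrt(2) times the windowed RMS. Also returns the peak negative
#' pressure (magnitude of the deepest rarefaction) over the same window.
#'
#' @param trace pressure samples, Pa
#' @param dt sample interval, s
#' @param ff carrier frequency, Hz
#' @param measurePeriods carrier periods in the trailing window (10)
#' @param method `"max"` (default) or `"rms"`
#' @return list with `amplitude` (Pa) and `peak_negative` (Pa)
#' @export
amplitudeFromTrace <- function(trace, dt, ff, measurePeriods = 10,
                               method = c("max", "rms")) {
  method <- match.arg(method)
  nWin <- ceiling(measurePeriods / ff / dt)
  if (nWin > length(trace))
    stop("measurement window exceeds the simulated duration")
  w <- trace[(length(trace) - nWin + 1):length(trace)]
  amp <- if (method == "max") max(abs(w)) else sqrt(2) * sqrt(mean(w^2))
  list(amplitude = amp, peak_negative = -min(w))
}
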