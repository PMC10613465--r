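## Shared fixtures, built in code at test time.

## small absorbing-shell phantom with its mask and property maps
shellFixture <- function(outer = 18, thickness = 5, shellHU = 600,
                         domain = 48, spacing = 1, target = c(0, -4, 0)) {
  ph <- generatePhantom(outerRadius = outer, thickness = thickness,
                        shellHU = shellHU, domainExtent = rep(domain, 3),
                        spacing = spacing, targetPoint = target)
  mask <- binarizeSkull(ph)
  list(hu = ph, mask = mask, medium = propertyMaps(ph, mask),
       target = target)
}

## anisotropic gaussian amplitude field (2D), optionally rotated
gaussianField2d <- function(n = 96, sigmaAxial = 6, sigmaLateral = 2,
                            thetaDeg = 0, centre = (n - 1) / 2) {
  th <- thetaDeg * pi / 180
  x <- outer(seq_len(n) - 1 - centre, rep(1, n))
  y <- t(x)
  xr <- cos(th) * x + sin(th) * y
  yr <- -sin(th) * x + cos(th) * y
  exp(-xr^2 / (2 * sigmaAxial^2) - yr^2 / (2 * sigmaLateral^2))
}

## single-voxel (1D) or plane source at a grid index
pointSource1d <- function(i0) {
  new("SourceGeometry", activeIndices = matrix(as.integer(i0), 1, 1),
      weights = 1, apex = i0, axis = 1, centreOfCurvature = i0)
}

## phase of a trace at frequency ff over its trailing window
tracePhase <- function(trace, dt, ff, periods = 10) {
  nw <- ceiling(periods / ff / dt)
  idx <- (length(trace) - nw + 1):length(trace)
  t <- (idx - 1) * dt
  Arg(sum(trace[idx] * exp(-2i * pi * ff * t)))
}

## literal brute-force RP candidate oracle (independent of the package
## implementation: plain per-voxel loops over the written rules)
bruteForceCandidates <- function(mask, target, roc, clearance) {
  filled <- fillSkullVolume(mask)
  d <- dim(mask@data); sp <- spacing(mask); org <- origin(mask)
  co <- as.matrix(expand.grid(x = org[1] + (0:(d[1] - 1)) * sp[1],
                              y = org[2] + (0:(d[2] - 1)) * sp[2],
                              z = org[3] + (0:(d[3] - 1)) * sp[3]))
  distT <- sqrt(rowSums(sweep(co, 2, target)^2))
  ball <- distT <= roc
  msk <- as.vector(mask@data) > 0
  idxB <- which(msk)
  mid0 <- (apply(which(mask@data > 0, arr.ind = TRUE), 2, min) +
             apply(which(mask@data > 0, arr.ind = TRUE), 2, max)) / 2 - 1
  ctr <- org + mid0 * sp
  distC <- sqrt(rowSums(sweep(co, 2, ctr)^2))
  meanD <- mean(distC[ball & msk])
  cand <- which(ball & !as.vector(filled) & distC > meanD)
  skpts <- co[msk, , drop = FALSE]
  keep <- vapply(cand, function(i)
    sqrt(min(rowSums(sweep(skpts, 2, co[i, ])^2))) >= clearance, logical(1))
  list(points = co[cand[keep], , drop = FALSE], meanD = meanD)
}

## numerical Rayleigh integral over a focused spherical cap (uniform
## normal velocity): on-axis |p| up to a constant factor
oneilAxial <- function(xFromApex, roc, aperture, f, c0 = 1482, nTheta = 1500) {
  k <- 2 * pi * f / c0
  thMax <- asin(aperture / (2 * roc))
  th <- (seq_len(nTheta) - 0.5) * thMax / nTheta
  zs <- roc * (1 - cos(th)); rs <- roc * sin(th)
  dA <- roc^2 * sin(th) * (thMax / nTheta) * 2 * pi
  vapply(xFromApex, function(x) {
    R <- sqrt((x - zs)^2 + rs^2)
    abs(sum(dA * exp(1i * k * R) / R))
  }, numeric(1))
}
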