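## Focal-spot geometry (FWHM), beam-path angles and safety indices.

#' Beam-path angles and stimulus distance
#'
#' The sonication path vector runs from the transducer centre to the
#' target. The angle to each anatomical plane is `asin(|v . n|)` with `n`
#' the plane normal (transverse: z, sagittal: x, coronal: y), so that a
#' vector lying in a plane makes 0 degrees with it. The three angles
#' satisfy `sin^2 + sin^2 + sin^2 = 1`.
#'
#' @param centre world mm of the transducer centre
#' @param target world mm of the target
#' @return list with `path_vector`, `angle_transverse`, `angle_sagittal`,
#'   `angle_coronal` (degrees) and `stimulus_distance` (mm)
#' @export
beamAngles <- function(centre, target) {
  v <- as.numeric(target) - as.numeric(centre)
  L <- sqrt(sum(v^2))
  if (L < 1e-12) stop("zero-length beam vector")
  v <- v / L
  ang <- function(comp) asin(min(1, abs(comp))) * 180 / pi
  list(path_vector = v,
       angle_transverse = ang(v[3]),
       angle_sagittal = ang(v[1]),
       angle_coronal = ang(v[2]),
       stimulus_distance = L)
}

#' Full-width-at-half-maximum focal geometry
#'
#' The amplitude field is normalized by its peak; the 6-connected region
#' at or above 0.5 (the -6 dB pressure contour) containing the peak voxel
#' is isolated and measured: length = extent of the region projected on
#' the beam axis, width = maximum extent perpendicular to the beam axis,
#' and the offset angle = angle between the region's amplitude-weighted
#' principal axis (second-moment eigenvector) and the beam axis. Extents
#' include the voxel footprint (span of voxel centres plus one voxel).
#' With `level = "intensity"` the half-maximum is taken on the squared
#' field (-3 dB pressure contour).
#'
#' @param field a [PressureField-class] or a plain amplitude array
#' @param beamAxis unit vector (grid axes) of the geometric beam
#' @param spacing voxel size mm (taken from `field` when available)
#' @param plane optional restriction: `"transverse"` measures width within
#'   the transverse (xy) projection for 3D fields; default `"free"`
#' @param level `"pressure"` (default, threshold 0.5 on amplitude) or
#'   `"intensity"` (threshold sqrt(0.5))
#' @param focus optional world point (mm): the analyzed peak is the field
#'   maximum within `focusRadius` of this point rather than the global
#'   maximum (separates the focal blob from reverberant hot spots, e.g.
#'   standing waves outside the skull)
#' @param focusRadius search radius around `focus`, mm (default 15)
#' @param volOrigin world origin of voxel (0,0,..) when `field` is a plain
#'   array and `focus` is used
#' @return list with `fwhm_length`, `fwhm_width` (mm), `offset_angle`
#'   (degrees), `peak_amplitude` (Pa), `peak_index` (1-based voxel),
#'   `degenerate` flag (TRUE when the half-max region touches the domain
#'   boundary)
#' @export
extractFWHM <- function(field, beamAxis, spacing = NULL,
                        plane = c("free", "transverse"),
                        level = c("pressure", "intensity"),
                        focus = NULL, focusRadius = 15, volOrigin = NULL) {
  plane <- match.arg(plane); level <- match.arg(level)
  if (is(field, "PressureField")) {
    arr <- field@amplitude; spacing <- field@spacing
    volOrigin <- field@origin
  } else {
    arr <- field
    if (is.null(spacing)) spacing <- rep(1, length(dim(arr)))
    if (is.null(volOrigin)) volOrigin <- rep(0, length(dim(arr)))
  }
  d <- dim(arr); nd <- length(d)
  if (is.null(focus)) {
    pk <- max(arr)
    pkIdx <- arrayInd(which.max(arr), d)
  } else {
    r2 <- 0
    for (j in seq_len(nd)) {
      cj <- (axisCoords(d[j], spacing[j], volOrigin[j]) - focus[j])^2
      r2 <- r2 + axisArray(cj, j, d)
    }
    near <- r2 <= focusRadius^2
    if (!any(near)) stop("no voxels within focusRadius of the focus")
    masked <- arr; masked[!near] <- -Inf
    pk <- max(masked)
    pkIdx <- arrayInd(which.max(masked), d)
  }
  if (!(pk > 0)) stop("amplitude field must have a strict positive maximum")
  thr <- if (level == "pressure") 0.5 else sqrt(0.5)
  above <- arr >= thr * pk
  region <- connectedRegion(above, pkIdx)
  idx <- which(region, arr.ind = TRUE)
  degenerate <- any(idx == 1) || any(sweep(idx, 2, d, `==`))
  w <- sweep(idx - 1, 2, spacing, `*`)   # mm, relative to voxel (0,0,..)
  ax <- as.numeric(beamAxis)[seq_len(nd)]
  ax <- ax / sqrt(sum(ax^2))
  proj <- w %*% ax
  fwhmLength <- diff(range(proj)) + mean(spacing)
  ## perpendicular extent
  perp <- w - proj %*% t(ax)
  if (nd == 3 && plane == "transverse") perp[, 3] <- 0
  pd <- sqrt(rowSums(perp^2))
  ## width as max extent across the axis: 2 * max perpendicular distance
  ## from the beam line through the amplitude-weighted centroid
  wt <- arr[region]
  cen <- colSums(w * wt) / sum(wt)
  rel <- sweep(w, 2, cen, `-`)
  relPerp <- rel - (rel %*% ax) %*% t(ax)
  if (nd == 3 && plane == "transverse") relPerp[, 3] <- 0
  fwhmWidth <- diff(range(relPerp %*% principalDir(relPerp, wt))) +
    mean(spacing)
  ## principal axis of the full region
  pdir <- principalDir(rel, wt)
  cosang <- min(1, abs(sum(pdir * ax)))
  offset <- acos(cosang) * 180 / pi
  list(fwhm_length = as.numeric(fwhmLength),
       fwhm_width = as.numeric(fwhmWidth),
       offset_angle = offset, peak_amplitude = pk,
       peak_index = as.integer(pkIdx), degenerate = degenerate)
}

#' Leading eigenvector of the weighted second-moment matrix
#' @noRd
principalDir <- function(rel, wt) {
  M <- crossprod(rel * sqrt(wt / sum(wt)))
  ev <- eigen(M, symmetric = TRUE)
  ev$vectors[, 1]
}

#' 6-connected region of a logical array containing a seed voxel
#' @noRd
connectedRegion <- function(mask, seed) {
  d <- dim(mask)
  region <- array(FALSE, d)
  region[matrix(as.integer(seed), 1)] <- TRUE
  repeat {
    grown <- region
    for (ax in seq_along(d))
      grown <- grown | shiftArray(region, ax, 1L) | shiftArray(region, ax, -1L)
    grown <- grown & mask
    if (!any(grown & !region)) break
    region <- grown
  }
  region
}

#' Skull-vs-water focal deviation report
#'
#' Compares focal metrics of the same transducer pose simulated through the
#' skull and in free water: `delta_length`/`delta_width` = water minus
#' skull (positive when the skull shrinks the focus), `delta_offset` =
#' skull minus water offset angle, `amplitude_drop` = percentage loss of
#' peak amplitude relative to water.
#'
#' @param skullMetrics,waterMetrics outputs of [extractFWHM()] from the
#'   same pose and grid
#' @return list with `delta_length_mm`, `delta_length_pct`,
#'   `delta_width_mm`, `delta_width_pct`, `delta_offset_deg`,
#'   `amplitude_drop_pct`
#' @export
deviationVsWater <- function(skullMetrics, waterMetrics) {
  if (!(waterMetrics$peak_amplitude > 0) || !(waterMetrics$fwhm_length > 0))
    stop("water reference must have positive peak and FWHM length")
  dl <- waterMetrics$fwhm_length - skullMetrics$fwhm_length
  dw <- waterMetrics$fwhm_width - skullMetrics$fwhm_width
  list(delta_length_mm = dl,
       delta_length_pct = 100 * dl / waterMetrics$fwhm_length,
       delta_width_mm = dw,
       delta_width_pct = 100 * dw / waterMetrics$fwhm_width,
       delta_offset_deg = skullMetrics$offset_angle - waterMetrics$offset_angle,
       amplitude_drop_pct = 100 * (1 - skullMetrics$peak_amplitude /
                                     waterMetrics$peak_amplitude))
}

#' Mechanical index and intensity safety indices
#'
#' `MI = p_neg[MPa] / sqrt(f[MHz])`; `I_SPPA = p_amp^2 / (2 rho c)`
#' (plane-wave pulse-average intensity, W/cm^2); `I_SPTA = I_SPPA * duty`
#' (mW/cm^2). Flags compare against the FDA diagnostic bounds MI <= 1.9
#' and I_SPPA <= 190 W/cm^2. The in-situ (simulated, post-skull) peak
#' negative pressure is used without additional derating.
#'
#' @param peakNegativePressure Pa (magnitude of the rarefactional peak)
#' @param f frequency, Hz
#' @param rho density at the focal voxel, kg/m^3 (default water)
#' @param c sound speed at the focal voxel, m/s (default water)
#' @param dutyCycle fraction (default 0.06)
#' @param peakAmplitude Pa used for the intensities; defaults to
#'   `peakNegativePressure`
#' @return list with `MI`, `I_SPPA_W_cm2`, `I_SPTA_mW_cm2`, `fda_mi_ok`,
#'   `fda_isppa_ok`
#' @export
safetyIndices <- function(peakNegativePressure, f, rho = 1000, c = 1482,
                          dutyCycle = 0.06,
                          peakAmplitude = peakNegativePressure) {
  if (f <= 0) stop("frequency must be positive")
  stopifnot(rho > 0, c > 0)
  mi <- (peakNegativePressure / 1e6) / sqrt(f / 1e6)
  isppa <- peakAmplitude^2 / (2 * rho * c) / 1e4      # W/m^2 -> W/cm^2
  ispta <- isppa * dutyCycle * 1e3                     # -> mW/cm^2
  list(MI = mi, I_SPPA_W_cm2 = isppa, I_SPTA_mW_cm2 = ispta,
       fda_mi_ok = mi <= 1.9, fda_isppa_ok = isppa <= 190)
}
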