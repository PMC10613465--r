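## Pennes bioheat: acoustic heat deposition and explicit finite-difference
## thermal stepping.
##
##   rho C dT/dt = div(k grad T) + Q(t) - w rho C (T - Ta)
##
## Q is the plane-wave absorbed power 2 alpha I = alpha(f) p^2 / (rho c),
## duty-scaled over each sonication window; boundaries are insulated
## (zero-flux Neumann); conductivity at cell faces is the arithmetic mean
## of the adjacent voxels.

#' Thermal property maps for a medium
#'
#' Skull voxels receive bone values (specific heat 1300 J/kg/K, thermal
#' conductivity 1.16 W/m/K); everything else water (4178 J/kg/K,
#' 0.54 W/m/K). Densities are shared with the acoustic medium. Perfusion
#' defaults to zero.
#'
#' @param medium a [MediumMaps-class]
#' @param specificHeatSkull,specificHeatWater J/kg/K
#' @param conductivitySkull,conductivityWater W/m/K
#' @param perfusion 1/s, scalar or array (default 0)
#' @return list with arrays `specific_heat`, `conductivity`, `perfusion`,
#'   `density`
#' @export
thermalProperties <- function(medium, specificHeatSkull = 1300,
                              specificHeatWater = 4178,
                              conductivitySkull = 1.16,
                              conductivityWater = 0.54,
                              perfusion = 0) {
  stopifnot(is(medium, "MediumMaps"))
  d <- dim(medium)
  C <- array(specificHeatWater, d); C[medium@mask] <- specificHeatSkull
  k <- array(conductivityWater, d); k[medium@mask] <- conductivitySkull
  stopifnot(all(C > 0), all(k > 0), all(perfusion >= 0))
  list(specific_heat = C, conductivity = k,
       perfusion = array(perfusion, d), density = medium@density)
}

#' Volumetric heat deposition from an acoustic amplitude field
#'
#' `Q = alpha(f) * p_amp^2 / (rho * c)` per voxel (plane-wave absorption,
#' alpha in Np/m from [attenuationAtFrequency()]), scaled by the
#' within-burst duty cycle when averaging over a sonication window.
#'
#' @param field a [PressureField-class] or amplitude array (Pa)
#' @param medium a congruent [MediumMaps-class]
#' @param f drive frequency, Hz
#' @param duty within-burst duty cycle applied as a time-average factor
#'   (default 1 = continuous within the window)
#' @return array Q, W/m^3
#' @export
heatDeposition <- function(field, medium, f, duty = 1) {
  amp <- if (is(field, "PressureField")) field@amplitude else field
  if (!identical(dim(amp), dim(medium)))
    stop("amplitude and medium dimensions differ")
  alphaF <- attenuationAtFrequency(medium@alpha0, f, medium@powerLawExponent)
  alphaF * amp^2 / (medium@density * medium@soundSpeed) * duty
}

#' Solve the Pennes bioheat equation under a pulsed schedule
#'
#' Explicit finite differences with insulated (zero-flux) boundaries. The
#' source is active during the given sonication windows and zero
#' otherwise; individual microsecond-scale tone bursts are not resolved
#' thermally (the within-burst duty belongs in Q via [heatDeposition()]).
#' The peak temperature is tracked at every step.
#'
#' @param thermal property list from [thermalProperties()]
#' @param Q heat source array, W/m^3
#' @param spacing voxel size mm
#' @param duration total simulated time, s
#' @param dtThermal time step, s; default 90% of the explicit diffusion
#'   stability bound
#' @param T0 initial (and arterial) temperature, degrees C, default 38.5
#' @param schedule data.frame of sonication windows with columns
#'   `start`, `stop` (s); default one window covering the full duration
#' @param snapshots number of evenly spaced temperature snapshots kept (5)
#' @param Tinit optional initial temperature array (degC) overriding the
#'   uniform `T0` start
#' @return list with `temperature` (final array, degC), `snapshots` (list
#'   of arrays), `snapshot_times` (s), `peak_temperature`, `peak_index`
#'   (1-based voxel), `time_of_peak` (s), `dt` (s), `T0`
#' @export
solvePennes <- function(thermal, Q, spacing, duration, dtThermal = NULL,
                        T0 = 38.5, schedule = NULL, snapshots = 5,
                        Tinit = NULL) {
  d <- dim(Q)
  nd <- length(d)
  if (length(spacing) == 1) spacing <- rep(spacing, nd)
  dxm <- spacing * 1e-3
  rhoC <- thermal$density * thermal$specific_heat
  k <- thermal$conductivity
  if (any(k < 0)) stop("negative conductivity")
  diffus <- max(k / rhoC)
  dtMax <- 1 / (2 * diffus * sum(1 / dxm^2))
  if (is.null(dtThermal)) dtThermal <- 0.9 * dtMax
  if (dtThermal > dtMax + 1e-15)
    stop(sprintf("dtThermal %.3g s violates the explicit stability bound %.3g s",
                 dtThermal, dtMax))
  if (is.null(schedule)) schedule <- data.frame(start = 0, stop = duration)
  stopifnot(all(schedule$stop > schedule$start))
  nSteps <- max(1L, ceiling(duration / dtThermal))
  dtThermal <- duration / nSteps   # steps tile the duration exactly
  snapAt <- unique(pmax(1L, round(seq_len(snapshots) * nSteps / snapshots)))
  Tn <- if (is.null(Tinit)) array(T0, d) else array(as.numeric(Tinit), d)
  peakT <- max(Tn); peakIdx <- arrayInd(which.max(Tn), d); peakTime <- 0
  snaps <- list(); snapTimes <- numeric(0)
  ## face conductivities (arithmetic mean), per axis
  kFace <- lapply(seq_len(nd), function(ax) faceMean(k, ax))
  w <- thermal$perfusion
  hasPerf <- any(w > 0)
  for (n in seq_len(nSteps)) {
    t0 <- (n - 1) * dtThermal
    lap <- 0
    for (ax in seq_len(nd)) {
      lap <- lap + fluxDivAxis(Tn, kFace[[ax]], ax) / dxm[ax]^2
    }
    qOn <- any(t0 >= schedule$start & t0 < schedule$stop)
    rhs <- lap + if (qOn) Q else 0
    if (hasPerf) rhs <- rhs - w * rhoC * (Tn - T0)
    Tn <- Tn + dtThermal * rhs / rhoC
    mx <- max(Tn)
    if (mx > peakT) {
      peakT <- mx
      peakIdx <- arrayInd(which.max(Tn), d)
      peakTime <- n * dtThermal
    }
    if (n %in% snapAt) {
      snaps[[length(snaps) + 1]] <- Tn
      snapTimes <- c(snapTimes, n * dtThermal)
    }
  }
  list(temperature = Tn, snapshots = snaps, snapshot_times = snapTimes,
       peak_temperature = peakT, peak_index = as.integer(peakIdx),
       time_of_peak = peakTime, dt = dtThermal, T0 = T0)
}

#' Arithmetic-mean conductivity at the +half faces along an axis
#' @noRd
faceMean <- function(k, ax) {
  d <- dim(k); n <- d[ax]
  idx <- lapply(d, seq_len); idx[[ax]] <- c(2:n, n)
  (k + do.call(`[`, c(list(k), idx, list(drop = FALSE)))) / 2
}

#' Conservative flux divergence along one axis with zero-flux boundaries
#' @noRd
fluxDivAxis <- function(Tn, kf, ax) {
  d <- dim(Tn); n <- d[ax]
  idxP <- lapply(d, seq_len); idxP[[ax]] <- c(2:n, n)
  idxM <- lapply(d, seq_len); idxM[[ax]] <- c(1L, 1:(n - 1))
  Tp <- do.call(`[`, c(list(Tn), idxP, list(drop = FALSE)))
  Tm <- do.call(`[`, c(list(Tn), idxM, list(drop = FALSE)))
  kfM <- do.call(`[`, c(list(kf), idxM, list(drop = FALSE)))
  ## replicated edge indices make the boundary fluxes vanish (T_p = T at
  ## the top face, T_m = T at the bottom face)
  kf * (Tp - Tn) - kfM * (Tn - Tm)
}

#' Thermal safety flags against literature damage thresholds
#'
#' Flags the peak temperature against 42 degC (onset of tissue
#' denaturation), 47 degC (cancellous bone necrosis) and 50 degC
#' (irreversible necrosis).
#'
#' @param result output of [solvePennes()], or a numeric peak temperature
#' @return list with `peak_temperature_C`, `exceeds_42`, `exceeds_47`,
#'   `exceeds_50`
#' @export
thermalSafetyReport <- function(result) {
  pk <- if (is.list(result)) result$peak_temperature else result
  if (length(pk) == 0 || !is.finite(pk)) stop("empty thermal result")
  list(peak_temperature_C = pk, exceeds_42 = pk > 42,
       exceeds_47 = pk > 47, exceeds_50 = pk > 50)
}
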