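#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Axis-aligned scalar volume with world-coordinate metadata
#'
#' Base container for rectilinear 3D (or 2D) scalar grids. World coordinates
#' are in millimetres; `origin` is the world position of the centre of voxel
#' (0,0,0) (0-based indices), and the centre of voxel `i` lies at
#' `origin + i * spacing`. Axes are fixed as x = left-right (sagittal-plane
#' normal), y = anterior-posterior (coronal-plane normal), z =
#' inferior-superior (transverse-plane normal).
#'
#' @slot data numeric array of voxel values
#' @slot spacing numeric per-axis voxel size (mm), all positive
#' @slot origin numeric world coordinate of voxel (0,0,...) centre (mm)
#' @exportClass ScalarVolume
setClass("ScalarVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(object@spacing) != length(d))
      return("spacing length must match array dimensionality")
    if (length(object@origin) != length(d))
      return("origin length must match array dimensionality")
    if (any(!is.finite(object@spacing)) || any(object@spacing <= 0))
      return("all spacing components must be positive and finite")
    TRUE
  })

#' Hounsfield-unit CT volume
#'
#' A [ScalarVolume-class] whose voxel values are CT attenuation in
#' Hounsfield units (water 0, air -1000, dense bone above ~1000).
#' All values must be finite.
#'
#' @exportClass HUVolume
setClass("HUVolume", contains = "ScalarVolume",
  validity = function(object) {
    if (any(!is.finite(object@data))) return("HU values must be finite")
    TRUE
  })

#' Binary skull mask
#'
#' A [ScalarVolume-class] whose voxels are 1 (inside skull bone) or 0
#' (outside). Produced by [binarizeSkull()].
#'
#' @exportClass SkullMask
setClass("SkullMask", contains = "ScalarVolume",
  validity = function(object) {
    if (!all(object@data %in% c(0, 1)))
      return("mask values must be 0 or 1")
    TRUE
  })

#' Heterogeneous acoustic medium property maps
#'
#' Per-voxel acoustic properties of the propagation medium: compressional
#' sound speed (m/s), density (kg/m^3), power-law attenuation prefactor
#' alpha0 (Np/MHz^y/m, i.e. the attenuation at 1 MHz) and the nonlinearity
#' parameter B/A. Water voxels carry the water constants; skull voxels carry
#' the porosity-mapped values. Built by [propertyMaps()].
#'
#' @slot soundSpeed numeric array, m/s, strictly positive
#' @slot density numeric array, kg/m^3, strictly positive
#' @slot alpha0 numeric array, Np/MHz^y/m, non-negative
#' @slot BonA numeric array, dimensionless
#' @slot mask logical array marking skull voxels
#' @slot spacing,origin world metadata as in [ScalarVolume-class]
#' @slot powerLawExponent numeric scalar y of the absorption law alpha0 * f^y
#' @slot constants list of the mapping constants used (see [propertyConstants()])
#' @exportClass MediumMaps
setClass("MediumMaps",
  representation(soundSpeed = "array", density = "array", alpha0 = "array",
                 BonA = "array", mask = "array", spacing = "numeric",
                 origin = "numeric", powerLawExponent = "numeric",
                 constants = "list"),
  validity = function(object) {
    d <- dim(object@soundSpeed)
    for (nm in c("density", "alpha0", "BonA", "mask"))
      if (!identical(dim(slot(object, nm)), d))
        return(sprintf("dim mismatch between soundSpeed and %s", nm))
    if (any(object@soundSpeed <= 0)) return("sound speed must be positive")
    if (any(object@density <= 0)) return("density must be positive")
    if (any(object@alpha0 < 0)) return("alpha0 must be non-negative")
    if (length(object@powerLawExponent) != 1 || object@powerLawExponent <= 0)
      return("powerLawExponent must be a positive scalar")
    TRUE
  })

#' Pulsed sonication drive schedule
#'
#' Tone-burst drive: a carrier at the fundamental frequency gated into
#' bursts of length `toneBurstDuration` repeating at `pulseRepFrequency`
#' over a total `sonicationDuration`, with peak pressure `sourcePressure`.
#'
#' @slot fundamentalFrequency Hz
#' @slot toneBurstDuration s
#' @slot pulseRepFrequency Hz
#' @slot sonicationDuration s
#' @slot sourcePressure Pa
#' @exportClass PulseSequence
setClass("PulseSequence",
  representation(fundamentalFrequency = "numeric", toneBurstDuration = "numeric",
                 pulseRepFrequency = "numeric", sonicationDuration = "numeric",
                 sourcePressure = "numeric"),
  validity = function(object) {
    ff <- object@fundamentalFrequency; tbd <- object@toneBurstDuration
    prf <- object@pulseRepFrequency; sd <- object@sonicationDuration
    if (tbd <= 0) return("tone burst duration must be positive")
    if (tbd > 1 / prf + 1e-12) return("tone burst duration must not exceed 1/PRF")
    if (sd < 1 / prf) return("sonication duration must cover at least one pulse period")
    if (ff * tbd < 1) return("burst must contain at least one carrier cycle (FF*TBD >= 1)")
    if (object@sourcePressure <= 0) return("source pressure must be positive")
    TRUE
  })

#' Focused bowl (spherical-cap) transducer geometry
#'
#' Single-element focused source defined by its radius of curvature (ROC)
#' and aperture diameter. The F-number ROC/diameter is derived, never
#' stored.
#'
#' @slot radiusOfCurvature mm
#' @slot apertureDiameter mm
#' @exportClass TransducerSpec
setClass("TransducerSpec",
  representation(radiusOfCurvature = "numeric", apertureDiameter = "numeric"),
  validity = function(object) {
    if (object@radiusOfCurvature <= 0) return("ROC must be positive")
    if (object@apertureDiameter <= 0) return("aperture diameter must be positive")
    if (object@apertureDiameter > 2 * object@radiusOfCurvature)
      return("aperture diameter cannot exceed 2*ROC")
    TRUE
  })

#' Simulation grid for the k-space pseudospectral solver
#'
#' @slot dims voxels per axis
#' @slot spacing mm (isotropic across axes is not required)
#' @slot dt time step, s, set from the CFL rule dt = cfl*min(dx)/max(c)
#' @slot cfl Courant-Friedrichs-Lewy number in (0,1]
#' @slot pmlWidth perfectly-matched-layer width, voxels, per axis
#' @slot refSpeed reference sound speed for the k-space correction, m/s
#' @exportClass SimulationGrid
setClass("SimulationGrid",
  representation(dims = "integer", spacing = "numeric", origin = "numeric",
                 dt = "numeric", cfl = "numeric", pmlWidth = "integer",
                 refSpeed = "numeric"),
  validity = function(object) {
    if (object@cfl <= 0 || object@cfl > 1) return("cfl must lie in (0, 1]")
    if (object@dt <= 0) return("dt must be positive")
    if (any(object@dims < 1)) return("dims must be positive")
    TRUE
  })

#' Discretised bowl source geometry on a simulation grid
#'
#' @slot activeIndices integer matrix (one row per active voxel, 0-based grid indices)
#' @slot weights per-voxel drive weights
#' @slot apex world position of the cap apex (mm)
#' @slot axis unit vector from apex toward the focus
#' @slot centreOfCurvature world position of the geometric focus (mm)
#' @exportClass SourceGeometry
setClass("SourceGeometry",
  representation(activeIndices = "matrix", weights = "numeric",
                 apex = "numeric", axis = "numeric",
                 centreOfCurvature = "numeric"),
  validity = function(object) {
    if (nrow(object@activeIndices) == 0) return("active voxel set is empty")
    if (nrow(object@activeIndices) != length(object@weights))
      return("one weight per active voxel required")
    TRUE
  })

#' Steady-state acoustic pressure field
#'
#' Result of [propagate()]: the per-voxel steady-state pressure amplitude
#' (max |p| over the trailing measurement window) plus full time traces and
#' peak negative pressure at named probe points.
#'
#' @slot amplitude array, Pa, non-negative
#' @slot spacing,origin world metadata
#' @slot probeTraces matrix, one column per probe, Pa per time sample
#' @slot probeNames character
#' @slot peakNegativePressure Pa per probe (positive number, magnitude of rarefaction)
#' @slot dt solver time step s
#' @slot nSteps number of simulated steps
#' @exportClass PressureField
setClass("PressureField",
  representation(amplitude = "array", spacing = "numeric", origin = "numeric",
                 probeTraces = "matrix", probeNames = "character",
                 peakNegativePressure = "numeric", dt = "numeric",
                 nSteps = "integer"),
  validity = function(object) {
    if (any(object@amplitude < 0)) return("amplitude must be non-negative")
    TRUE
  })

#' RP candidate matrix
#'
#' Extracranial transducer-centre candidates produced by the radius
#' positioning screen: voxels inside the search ball around the target,
#' outside the filled skull volume, farther from the model centre than the
#' mean centre-to-shell distance, and clear of skull contact.
#'
#' @slot candidates data.frame with columns x_mm, y_mm, z_mm, dist_to_target_mm
#' @slot modelCentre world mm
#' @slot meanCentreShellDistance mm
#' @slot excluded named integer vector of exclusion counts by reason
#' @slot target world mm
#' @exportClass CandidateMatrix
setClass("CandidateMatrix",
  representation(candidates = "data.frame", modelCentre = "numeric",
                 meanCentreShellDistance = "numeric", excluded = "numeric",
                 target = "numeric"))

#' Transducer positioning result
#'
#' @slot chosenCentre world mm of the winning candidate
#' @slot table data.frame of evaluated candidates with target amplitudes
#' @slot controls data.frame of control-group placements (plane, angle, amplitude, ratio)
#' @slot target world mm
#' @exportClass PositioningResult
setClass("PositioningResult",
  representation(chosenCentre = "numeric", table = "data.frame",
                 controls = "data.frame", target = "numeric"))

## ---- constructors ----

#' Construct a Hounsfield-unit volume
#'
#' @param data numeric array (HU)
#' @param spacing per-axis voxel size, mm
#' @param origin world coordinate of voxel (0,0,0) centre, mm (default zeros)
#' @return an [HUVolume-class]
#' @export
HUVolume <- function(data, spacing, origin = rep(0, length(dim(data)))) {
  if (length(spacing) == 1) spacing <- rep(spacing, length(dim(data)))
  new("HUVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a pulsed sonication schedule
#'
#' Defaults are the low-intensity neuromodulation drive used throughout the
#' package: 500 kHz carrier, 200 us tone bursts at 300 Hz PRF (6% duty
#' cycle) over 500 ms, 1 MPa source pressure.
#'
#' @param fundamentalFrequency Hz
#' @param toneBurstDuration s
#' @param pulseRepFrequency Hz
#' @param sonicationDuration s
#' @param sourcePressure Pa
#' @return a [PulseSequence-class]
#' @export
pulseSequence <- function(fundamentalFrequency = 500e3,
                          toneBurstDuration = 200e-6,
                          pulseRepFrequency = 300,
                          sonicationDuration = 0.5,
                          sourcePressure = 1e6) {
  new("PulseSequence", fundamentalFrequency = fundamentalFrequency,
      toneBurstDuration = toneBurstDuration,
      pulseRepFrequency = pulseRepFrequency,
      sonicationDuration = sonicationDuration,
      sourcePressure = sourcePressure)
}

#' Construct a focused bowl transducer specification
#'
#' Defaults follow a 30 mm radius-of-curvature, 25 mm aperture single
#' element probe; a 31 mm aperture is a common alternate.
#'
#' @param radiusOfCurvature mm
#' @param apertureDiameter mm
#' @return a [TransducerSpec-class]
#' @export
transducerSpec <- function(radiusOfCurvature = 30, apertureDiameter = 25) {
  new("TransducerSpec", radiusOfCurvature = radiusOfCurvature,
      apertureDiameter = apertureDiameter)
}

## ---- generics & accessors ----

#' Voxel data array of a volume-like object
#' @param x object
#' @return the underlying array
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))
#' @rdname volData
#' @export
setMethod("volData", "ScalarVolume", function(x) x@data)

#' Voxel spacing (mm)
#' @param x object
#' @return numeric per-axis spacing
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname spacing
#' @export
setMethod("spacing", "ScalarVolume", function(x) x@spacing)
#' @rdname spacing
#' @export
setMethod("spacing", "MediumMaps", function(x) x@spacing)
#' @rdname spacing
#' @export
setMethod("spacing", "PressureField", function(x) x@spacing)

#' World origin (mm) of voxel (0,0,0) centre
#' @param x object
#' @return numeric world coordinate
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))
#' @rdname origin
#' @export
setMethod("origin", "ScalarVolume", function(x) x@origin)
#' @rdname origin
#' @export
setMethod("origin", "MediumMaps", function(x) x@origin)
#' @rdname origin
#' @export
setMethod("origin", "PressureField", function(x) x@origin)

#' @export
setMethod("dim", "ScalarVolume", function(x) dim(x@data))
#' @export
setMethod("dim", "MediumMaps", function(x) dim(x@soundSpeed))
#' @export
setMethod("dim", "PressureField", function(x) dim(x@amplitude))

#' F-number of a bowl transducer (ROC / aperture diameter)
#' @param x a [TransducerSpec-class]
#' @return numeric
#' @export
setGeneric("fNumber", function(x) standardGeneric("fNumber"))
#' @rdname fNumber
#' @export
setMethod("fNumber", "TransducerSpec",
          function(x) x@radiusOfCurvature / x@apertureDiameter)

#' Candidate table of an RP candidate matrix
#' @param x a [CandidateMatrix-class]
#' @return data.frame
#' @export
setGeneric("candidates", function(x) standardGeneric("candidates"))
#' @rdname candidates
#' @export
setMethod("candidates", "CandidateMatrix", function(x) x@candidates)

#' Chosen transducer centre of a positioning run
#' @param x a [PositioningResult-class]
#' @return world mm
#' @export
setGeneric("chosenCentre", function(x) standardGeneric("chosenCentre"))
#' @rdname chosenCentre
#' @export
setMethod("chosenCentre", "PositioningResult", function(x) x@chosenCentre)

#' Steady-state amplitude array of a pressure field
#' @param x a [PressureField-class]
#' @return array, Pa
#' @export
setGeneric("amplitude", function(x) standardGeneric("amplitude"))
#' @rdname amplitude
#' @export
setMethod("amplitude", "PressureField", function(x) x@amplitude)

## ---- show methods ----

setMethod("show", "ScalarVolume", function(object) {
  cat(sprintf("%s: %s voxels, spacing %s mm, origin %s mm\n",
              class(object), paste(dim(object@data), collapse = "x"),
              paste(signif(object@spacing, 4), collapse = "x"),
              paste(signif(object@origin, 4), collapse = ", ")))
  rng <- range(object@data)
  cat(sprintf("  value range [%g, %g]\n", rng[1], rng[2]))
})

setMethod("show", "MediumMaps", function(object) {
  cat(sprintf("MediumMaps: %s voxels, %d skull voxels\n",
              paste(dim(object), collapse = "x"), sum(object@mask)))
  cat(sprintf("  c [%g, %g] m/s; rho [%g, %g] kg/m^3; alpha0 [%g, %g] Np/MHz^y/m (y = %g)\n",
              min(object@soundSpeed), max(object@soundSpeed),
              min(object@density), max(object@density),
              min(object@alpha0), max(object@alpha0),
              object@powerLawExponent))
})

setMethod("show", "PulseSequence", function(object) {
  tm <- deriveTiming(object)
  cat(sprintf(paste0("PulseSequence: FF %g kHz, TBD %g us, PRF %g Hz, SD %g ms, ",
                     "%g Pa\n  duty cycle %.3g%%, %d bursts, %d cycles/burst\n"),
              object@fundamentalFrequency / 1e3, object@toneBurstDuration * 1e6,
              object@pulseRepFrequency, object@sonicationDuration * 1e3,
              object@sourcePressure, 100 * tm$duty_cycle, tm$n_bursts,
              tm$cycles_per_burst))
})

setMethod("show", "TransducerSpec", function(object) {
  cat(sprintf("TransducerSpec: ROC %g mm, aperture %g mm (F-number %.3g)\n",
              object@radiusOfCurvature, object@apertureDiameter,
              fNumber(object)))
})

setMethod("show", "SimulationGrid", function(object) {
  cat(sprintf("SimulationGrid: %s voxels @ %s mm, dt %.4g s (CFL %g, c_ref %g m/s), PML %d\n",
              paste(object@dims, collapse = "x"),
              paste(signif(object@spacing, 4), collapse = "x"),
              object@dt, object@cfl, object@refSpeed, object@pmlWidth[1]))
})

setMethod("show", "CandidateMatrix", function(object) {
  cat(sprintf("CandidateMatrix: %d candidates around target (%s) mm\n",
              nrow(object@candidates),
              paste(signif(object@target, 4), collapse = ", ")))
  cat(sprintf("  mean centre-to-shell distance %.3g mm; excluded: %s\n",
              object@meanCentreShellDistance,
              paste(sprintf("%s=%d", names(object@excluded),
                            as.integer(object@excluded)), collapse = ", ")))
})

setMethod("show", "PositioningResult", function(object) {
  cat(sprintf("PositioningResult: chosen centre (%s) mm, %d candidates evaluated\n",
              paste(signif(object@chosenCentre, 4), collapse = ", "),
              nrow(object@table)))
  if (nrow(object@controls))
    cat(sprintf("  %d control poses, amplitude ratios %.3g-%.3g\n",
                nrow(object@controls), min(object@controls$ratio),
                max(object@controls$ratio)))
})
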