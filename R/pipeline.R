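## End-to-end planning pipeline: phantom -> properties -> RP positioning ->
## focal metrics -> thermal verification, with YAML configuration.

#' Default planning configuration
#'
#' All defaults follow the study drive conditions: 500 kHz carrier at
#' 1 MPa, 200 us tone bursts at 300 Hz PRF (6% duty) over 500 ms; 30 mm
#' ROC / 25 mm aperture bowl; CFL 0.3; power-law exponent 1.51; 100 HU
#' binarization threshold; 38.5 degC initial temperature. The frequency
#' sweep covers 250, 500, 690 and 1100 kHz.
#'
#' @return nested configuration list
#' @export
defaultConfig <- function() {
  list(
    input = list(
      phantom = list(outer_radius_mm = 22, thickness_mm = 7,
                     shell_hu = 600, background_hu = -1000,
                     domain_extent_mm = 60,
                     target_offset_mm = c(0, -6, 0)),
      nifti_path = NULL,
      target_mm = NULL),
    threshold_hu = 100,
    spacing_mm = 1,
    frequencies_hz = c(250e3, 500e3, 690e3, 1100e3),
    transducer = list(roc_mm = 30, diameter_mm = 25),
    pulse = list(source_pressure_pa = 1e6, tone_burst_duration_s = 200e-6,
                 prf_hz = 300, sonication_duration_s = 0.5),
    solver = list(cfl = 0.3, power_law_exponent = 1.51, pml_width = 10,
                  mode = "2d", settle_periods = 15, measure_periods = 5,
                  spacing2d_mm = NULL),
    rp = list(ball_margin_mm = 0, clearance_mm = NULL, subsample = 1,
              max_candidates = 6, seed = 1),
    thermal = list(t0_c = 38.5, duration_s = 0.5, snapshots = 3),
    output_dir = NULL)
}

#' Parse a frequency given as number (Hz) or string with units
#' @noRd
parseFrequency <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  m <- regmatches(x, regexec("^\\s*([0-9.eE+-]+)\\s*(k?M?Hz)?\\s*$", x))[[1]]
  if (length(m) < 2 || m[2] == "") stop("cannot parse frequency: ", x)
  val <- as.numeric(m[2])
  unit <- if (length(m) >= 3 && nzchar(m[3])) m[3] else "Hz"
  val * switch(unit, Hz = 1, kHz = 1e3, MHz = 1e6,
               stop("unknown frequency unit: ", unit))
}

#' Validate and normalize a planning configuration
#'
#' Merges user settings over [defaultConfig()], normalizes frequency units
#' (strings like `"500 kHz"` are accepted), injects transducer and pulse
#' defaults when blocks are missing, and range-checks the physics
#' settings. Errors are aggregated into a single message.
#'
#' @param config nested list (possibly partial), or path to a YAML file
#' @return normalized configuration list
#' @export
validateConfig <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(defaultConfig(), config)
  errs <- character(0)
  cfg$frequencies_hz <- tryCatch(
    vapply(as.list(cfg$frequencies_hz), parseFrequency, numeric(1)),
    error = function(e) { errs <<- c(errs, conditionMessage(e)); numeric(0) })
  if (length(cfg$frequencies_hz) == 0)
    errs <- c(errs, "frequency list must be non-empty")
  if (any(cfg$frequencies_hz <= 0))
    errs <- c(errs, "frequencies must be positive")
  if (cfg$solver$cfl <= 0 || cfg$solver$cfl > 1)
    errs <- c(errs, sprintf("cfl = %g violates the stability bound (0, 1]",
                            cfg$solver$cfl))
  if (cfg$spacing_mm <= 0) errs <- c(errs, "spacing must be positive")
  if (cfg$transducer$roc_mm <= 0) errs <- c(errs, "ROC must be positive")
  if (cfg$transducer$diameter_mm > 2 * cfg$transducer$roc_mm)
    errs <- c(errs, "aperture diameter cannot exceed 2*ROC")
  if (cfg$thermal$t0_c < 0) errs <- c(errs, "initial temperature below 0 degC")
  if (length(errs)) stop("invalid configuration:\n  - ",
                         paste(errs, collapse = "\n  - "))
  if (is.null(cfg$rp$clearance_mm))
    cfg$rp$clearance_mm <- bowlCapDepth(
      transducerSpec(cfg$transducer$roc_mm, cfg$transducer$diameter_mm))
  if (is.null(cfg$solver$spacing2d_mm)) cfg$solver$spacing2d_mm <- cfg$spacing_mm
  ## sub-Nyquist spatial sampling warning (3 points per wavelength in water)
  ppw <- 1482 / max(cfg$frequencies_hz) / (cfg$solver$spacing2d_mm * 1e-3)
  if (ppw < 3)
    warning(sprintf("coarsest sampling is %.2f points per wavelength (< 3)", ppw))
  cfg
}

#' FNV-1a hash of the serialized configuration (traceability id)
#' @noRd
configHash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the end-to-end tFUS planning pipeline
#'
#' Stages: skull model (phantom generation or NIfTI input, resampling,
#' binarization) -> acoustic property mapping -> RP candidate matrix ->
#' per-candidate simulation and peak-pressure positioning (with control
#' group) -> water/skull focal metrics and safety indices -> Pennes
#' bioheat verification. One report row per drive frequency.
#'
#' @param config configuration list or YAML path; see [validateConfig()]
#' @param verbose print per-stage progress
#' @return list with `report` (data.frame, one row per frequency),
#'   `candidates` ([CandidateMatrix-class]), `positioning` (list of
#'   [PositioningResult-class] per frequency), `config` (normalized),
#'   `runtime_s`
#' @export
runPipeline <- function(config = list(), verbose = TRUE) {
  t0 <- Sys.time()
  cfg <- validateConfig(config)
  say <- function(...) if (verbose) message(sprintf(...))
  ## stage 1: skull model
  if (!is.null(cfg$input$nifti_path)) {
    hu <- readHUVolume(cfg$input$nifti_path)
    target <- cfg$input$target_mm
    if (is.null(target)) stop("target_mm required with NIfTI input")
  } else {
    ph <- cfg$input$phantom
    hu <- generatePhantom(outerRadius = ph$outer_radius_mm,
                          thickness = ph$thickness_mm,
                          shellHU = ph$shell_hu,
                          backgroundHU = ph$background_hu,
                          domainExtent = rep(ph$domain_extent_mm, 3),
                          spacing = cfg$spacing_mm,
                          targetPoint = ph$target_offset_mm)
    target <- cfg$input$target_mm %||% attr(hu, "targetPoint")
  }
  hu <- resampleIsotropic(hu, cfg$spacing_mm)
  mask <- binarizeSkull(hu, cfg$threshold_hu)
  say("skull model: %s voxels, %d bone voxels",
      paste(dim(mask), collapse = "x"), sum(mask@data))
  ## stage 2: acoustic properties
  const <- propertyConstants(power_law_exponent = cfg$solver$power_law_exponent)
  medium <- propertyMaps(hu, mask, const)
  ## stage 3: RP candidate matrix
  spec <- transducerSpec(cfg$transducer$roc_mm, cfg$transducer$diameter_mm)
  cm <- candidateMatrix(mask, target, roc = spec@radiusOfCurvature,
                        clearance = cfg$rp$clearance_mm,
                        ballMargin = cfg$rp$ball_margin_mm)
  say("RP matrix: %d candidates (excluded: %s)", nrow(candidates(cm)),
      paste(sprintf("%s %d", names(cm@excluded), as.integer(cm@excluded)),
            collapse = ", "))
  ctrl <- controlGroupPlacement(target, roc = spec@radiusOfCurvature)
  rows <- list(); posList <- list()
  dutyCycle <- cfg$pulse$tone_burst_duration_s * cfg$pulse$prf_hz
  for (f in cfg$frequencies_hz) {
    say("frequency %g kHz: positioning over candidate matrix", f / 1e3)
    drive <- pulseSequence(fundamentalFrequency = f,
                           toneBurstDuration = cfg$pulse$tone_burst_duration_s,
                           pulseRepFrequency = cfg$pulse$prf_hz,
                           sonicationDuration = cfg$pulse$sonication_duration_s,
                           sourcePressure = cfg$pulse$source_pressure_pa)
    pos <- positionTransducer(cm, spec, medium, drive,
                              mode = cfg$solver$mode,
                              subsample = cfg$rp$subsample,
                              maxCandidates = cfg$rp$max_candidates,
                              seed = cfg$rp$seed, controls = ctrl,
                              settlePeriods = cfg$solver$settle_periods,
                              measurePeriods = cfg$solver$measure_periods,
                              cfl = cfg$solver$cfl,
                              pmlWidth = cfg$solver$pml_width,
                              spacing2d = cfg$solver$spacing2d_mm)
    posList[[as.character(f)]] <- pos
    chosen <- chosenCentre(pos)
    geom <- beamAngles(chosen, target)
    ## chosen pose: skull and water reference fields
    runPose <- function(med) simulatePose(
      chosen, target, spec, med, drive, mode = cfg$solver$mode,
      settlePeriods = cfg$solver$settle_periods,
      measurePeriods = cfg$solver$measure_periods,
      cfl = cfg$solver$cfl, pmlWidth = cfg$solver$pml_width,
      spacing2d = cfg$solver$spacing2d_mm)
    sk <- runPose(medium)
    water3d <- waterMedium(dim(medium), spacing = medium@spacing,
                           origin = medium@origin, const = const)
    wt <- runPose(water3d)
    axis2 <- sk$beamAxis2d %||% geom$path_vector
    mSk <- extractFWHM(sk$field, axis2, focus = sk$targetLocal)
    mWt <- extractFWHM(wt$field, axis2, focus = wt$targetLocal)
    dev <- deviationVsWater(mSk, mWt)
    ## safety indices at the target voxel
    pnp <- if (length(sk$field@peakNegativePressure))
      sk$field@peakNegativePressure[1] else sk$amplitude
    focalRho <- sk$medium@density[matrix(sk$targetVoxel, 1)]
    focalC <- sk$medium@soundSpeed[matrix(sk$targetVoxel, 1)]
    saf <- safetyIndices(pnp, f, rho = focalRho, c = focalC,
                         dutyCycle = dutyCycle, peakAmplitude = sk$amplitude)
    ## thermal verification on the simulated (2D-slice or 3D) medium
    say("frequency %g kHz: thermal verification", f / 1e3)
    th <- thermalProperties(sk$medium)
    Q <- heatDeposition(sk$field, sk$medium, f, duty = dutyCycle)
    pen <- solvePennes(th, Q, spacing = sk$medium@spacing,
                       duration = cfg$thermal$duration_s,
                       T0 = cfg$thermal$t0_c,
                       snapshots = cfg$thermal$snapshots)
    tsr <- thermalSafetyReport(pen)
    rows[[length(rows) + 1]] <- data.frame(
      frequency_hz = f,
      chosen_x_mm = chosen[1], chosen_y_mm = chosen[2], chosen_z_mm = chosen[3],
      angle_transverse_deg = geom$angle_transverse,
      angle_sagittal_deg = geom$angle_sagittal,
      angle_coronal_deg = geom$angle_coronal,
      stimulus_distance_mm = geom$stimulus_distance,
      n_candidates = nrow(candidates(cm)),
      n_evaluated = nrow(pos@table),
      excl_inside_skull = cm@excluded[["inside_skull"]],
      excl_intracranial = cm@excluded[["intracranial"]],
      excl_below_average_radius = cm@excluded[["below_average_radius"]],
      excl_contact_clearance = cm@excluded[["contact_clearance"]],
      fwhm_length_water_mm = mWt$fwhm_length,
      fwhm_width_water_mm = mWt$fwhm_width,
      offset_water_deg = mWt$offset_angle,
      fwhm_length_skull_mm = mSk$fwhm_length,
      fwhm_width_skull_mm = mSk$fwhm_width,
      offset_skull_deg = mSk$offset_angle,
      delta_length_mm = dev$delta_length_mm,
      delta_length_pct = dev$delta_length_pct,
      delta_width_mm = dev$delta_width_mm,
      delta_width_pct = dev$delta_width_pct,
      delta_offset_deg = dev$delta_offset_deg,
      amplitude_drop_pct = dev$amplitude_drop_pct,
      peak_amplitude_pa = sk$amplitude,
      MI = saf$MI, I_SPPA_W_cm2 = saf$I_SPPA_W_cm2,
      I_SPTA_mW_cm2 = saf$I_SPTA_mW_cm2,
      fda_mi_ok = saf$fda_mi_ok, fda_isppa_ok = saf$fda_isppa_ok,
      peak_temperature_C = tsr$peak_temperature_C,
      exceeds_42 = tsr$exceeds_42,
      duty_cycle = dutyCycle,
      seed = cfg$rp$seed,
      config_hash = configHash(cfg))
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report, file.path(cfg$output_dir, "report.csv"),
                     row.names = FALSE)
    ctab <- candidates(cm)
    utils::write.csv(ctab, file.path(cfg$output_dir, "candidates.csv"),
                     row.names = FALSE)
    writeVolume(hu, file.path(cfg$output_dir, "phantom_hu.nii.gz"))
    writeVolume(mask, file.path(cfg$output_dir, "skull_mask.nii.gz"))
  }
  list(report = report, candidates = cm, positioning = posList,
       config = cfg,
       runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
}

#' Stable column schema of the planning report
#'
#' @return character vector of report column names, in order
#' @export
reportSchema <- function() {
  c("frequency_hz", "chosen_x_mm", "chosen_y_mm", "chosen_z_mm",
    "angle_transverse_deg", "angle_sagittal_deg", "angle_coronal_deg",
    "stimulus_distance_mm", "n_candidates", "n_evaluated",
    "excl_inside_skull", "excl_intracranial", "excl_below_average_radius",
    "excl_contact_clearance", "fwhm_length_water_mm", "fwhm_width_water_mm",
    "offset_water_deg", "fwhm_length_skull_mm", "fwhm_width_skull_mm",
    "offset_skull_deg", "delta_length_mm", "delta_length_pct",
    "delta_width_mm", "delta_width_pct", "delta_offset_deg",
    "amplitude_drop_pct", "peak_amplitude_pa", "MI", "I_SPPA_W_cm2",
    "I_SPTA_mW_cm2", "fda_mi_ok", "fda_isppa_ok", "peak_temperature_C",
    "exceeds_42", "duty_cycle", "seed", "config_hash")
}
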