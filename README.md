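# tfusplan

Planning toolkit for low-intensity **transcranial focused ultrasound
(tFUS)**: where should a single-element focused bowl sit on the head so
that its beam, after crossing the skull, delivers peak pressure to a
deep brain target — and is that sonication acoustically and thermally
safe?

The package is aimed at computational medical physicists and
neuromodulation researchers who want a self-contained, scriptable
simulation chain for treatment-planning studies on synthetic skull
phantoms or their own CT volumes (NIfTI).

## What it computes

**Skull model.** HU volumes are resampled to isotropic spacing and
binarized at 100 HU (`resampleIsotropic`, `binarizeSkull`); a
deterministic spherical-shell phantom generator (`generatePhantom`)
stands in for patient CTs.

**Acoustic properties.** Per voxel, from the CT porosity
`psi = 1 - HU/1000` (clamped to [0, 1]), inside the skull mask:

    c     = c_water psi + c_bone (1 - psi)              [1482 / 3100 m/s]
    rho   = rho_water psi + rho_bone (1 - psi)          [1000 / 2200 kg/m^3]
    alpha0 = a_min + (a_max - a_min) sqrt(psi)          [21.5 / 208.9 Np/MHz^y/m]
    alpha(f) = alpha0 (f / 1 MHz)^y,  y = 1.51

Outside the mask everything is water (`propertyMaps`).

**Wave propagation.** A k-space pseudospectral solver (`propagate`)
advances the first-order linear acoustic system on the heterogeneous
maps: spectral derivatives with the k-space temporal correction,
staggered grids for heterogeneous density, fractional-Laplacian
power-law absorption, and a perfectly matched layer; CFL 0.3. Bowl
sources are discretized spherical caps (`discretizeBowl`); 1D/2D/3D
grids share one stepping core.

**Radius positioning (RP).** `candidateMatrix` screens transducer-centre
candidates inside a ball of the bowl's radius of curvature around the
target: outside the flood-filled skull, farther from the model centre
than the mean centre-to-shell distance, and clear of skull contact.
`positionTransducer` simulates each (optionally subsampled) candidate
with the bowl aimed at the target and selects the peak-pressure
placement; fixed-angle control poses (`controlGroupPlacement`) quantify
what naive placement would lose.

**Metrics & safety.** `extractFWHM` measures the -6 dB focal region
(length, width, principal-axis offset); `deviationVsWater` compares
skull and free-water runs; `beamAngles` reports the sonication path's
angles to the anatomical planes; `safetyIndices` computes MI,
I_SPPA and I_SPTA against the FDA diagnostic bounds.

**Thermal verification.** `heatDeposition` converts amplitude to
absorbed power `Q = alpha(f) p^2 / (rho c)`; `solvePennes` integrates
the Pennes bioheat equation over the pulsed schedule (insulated
boundaries, explicit conservative scheme) and `thermalSafetyReport`
flags the 42/47/50 degC thresholds.

`runPipeline` chains all stages from a YAML/list configuration;
`inst/cli/tfusplan.R` is a thin command-line front end.

## Worked example

```r
library(tfusplan)

## pulsed drive: 500 kHz carrier, 200 us bursts at 300 Hz, 500 ms, 1 MPa
drive <- pulseSequence(fundamentalFrequency = 500e3)
drive
#> PulseSequence: FF 500 kHz, TBD 200 us, PRF 300 Hz, SD 500 ms, 1e+06 Pa
#>   duty cycle 6%, 150 bursts, 100 cycles/burst

## porosity-based property mapping at the endpoints
hu  <- HUVolume(array(c(1000, 0, 750), c(3, 1, 1)), spacing = 1)
msk <- binarizeSkull(hu, threshold = 0)   # treat all three voxels as bone
mm  <- propertyMaps(hu, msk)
data.frame(HU = c(1000, 0, 750), psi = porosityFromHU(c(1000, 0, 750)),
           c_m_s = as.vector(mm@soundSpeed),
           rho_kg_m3 = as.vector(mm@density),
           alpha0_Np_MHzy_m = as.vector(mm@alpha0))
#>     HU  psi  c_m_s rho_kg_m3 alpha0_Np_MHzy_m
#> 1 1000 0.00 3100.0      2200             21.5
#> 2    0 1.00 1482.0      1000            208.9
#> 3  750 0.25 2695.5      1900            115.2

## RP candidate screen on the default skull phantom
ph   <- generatePhantom()        # 22 mm shell, 600 HU, target 6 mm off-centre
mask <- binarizeSkull(ph)
cm   <- candidateMatrix(mask, attr(ph, "targetPoint"), roc = 30)
cm
#> CandidateMatrix: 49528 candidates around target (0, -6, 0) mm
#>   mean centre-to-shell distance 19 mm; excluded: inside_skull=30392,
#>   intracranial=14328, below_average_radius=0, contact_clearance=15704

## safety indices for a 1 MPa focal rarefaction at 500 kHz, 6% duty
str(safetyIndices(1e6, 500e3, dutyCycle = 0.06))
#> List of 5
#>  $ MI           : num 1.41
#>  $ I_SPPA_W_cm2 : num 33.7
#>  $ I_SPTA_mW_cm2: num 2024
#>  $ fda_mi_ok    : logi TRUE
#>  $ fda_isppa_ok : logi TRUE
```

Reading the numbers: the drive's 6% duty cycle and 150
pulse-repetition periods per 500 ms sonication define the thermal
loading; the mapping table shows the water/bone endpoints (porosity 0
is compact bone at 3100 m/s and minimum attenuation 21.5, porosity 1
the water-like limit at maximum attenuation 208.9); the candidate
matrix keeps ~50k extracranial placements after excluding in-skull,
intracranial, sub-mean-radius and contact-zone voxels; and a 1 MPa
rarefaction at 500 kHz sits below the MI 1.9 and I_SPPA 190 W/cm^2
diagnostic bounds. A full planning run (positioning, focal metrics and
thermal check per frequency) is one call:
`runPipeline(list(frequencies_hz = 250e3))`.

## Layout

- `R/` — S4 classes (`HUVolume`, `SkullMask`, `MediumMaps`,
  `PulseSequence`, `TransducerSpec`, `SimulationGrid`,
  `SourceGeometry`, `PressureField`, `CandidateMatrix`,
  `PositioningResult`) and the module implementations.
- `tests/testthat/` — unit, property and acceptance suites with
  brute-force and analytic oracles built in code.
- `vignettes/tfus-planning.Rmd` — models, assumptions, numerical
  choices and limitations.
- `inst/cli/tfusplan.R` — command-line front end
  (`phantom | props | pulse | position | run`).
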