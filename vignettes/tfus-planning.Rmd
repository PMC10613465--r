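---
title: "Skull-aware planning of transcranial focused ultrasound: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skull-aware planning of transcranial focused ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The planning problem

Low-intensity transcranial focused ultrasound (tFUS) steers acoustic
energy through the intact skull onto a millimetre-scale brain target.
The skull refracts, attenuates and partially reflects the beam, so both
the focal position and the delivered pressure depend strongly on where
the transducer sits on the head. `tfusplan` implements a complete
planning chain for a single-element focused bowl:

1. **Skull model** — a Hounsfield-unit (HU) CT volume is resampled to
   1 mm isotropic voxels and binarized at 100 HU; a synthetic
   spherical-shell phantom generator stands in for patient CTs.
2. **Acoustic properties** — porosity `psi = 1 - HU/1000` (clamped to
   [0, 1]) maps each skull voxel to sound speed, density and power-law
   attenuation between water and compact-bone endpoints.
3. **Wave propagation** — a k-space pseudospectral solver advances the
   first-order linear acoustic equations through the heterogeneous
   medium and reports steady-state pressure-amplitude maps.
4. **Radius positioning (RP)** — extracranial transducer-centre
   candidates inside a ball of the bowl's radius of curvature around the
   target are screened geometrically, then simulated one by one; the
   candidate with peak target pressure wins.
5. **Focal metrics and safety** — FWHM focal geometry, water-vs-skull
   deviation, beam-path angles, mechanical index (MI) and
   I_SPPA/I_SPTA intensities against the FDA diagnostic bounds.
6. **Thermal verification** — the acoustic field drives a Pennes
   bioheat simulation of the pulsed sonication schedule.

# Models and assumptions

## Acoustic property mapping

Within the binarized skull mask,

- `c = c_water * psi + c_bone * (1 - psi)` (1482 / 3100 m/s),
- `rho = rho_water * psi + rho_bone * (1 - psi)` (1000 / 2200 kg/m^3),
- `alpha0 = alpha_min + (alpha_max - alpha_min) * sqrt(psi)`
  (21.5 / 208.9 Np/MHz^y/m),

with attenuation at frequency `f` given by `alpha(f) = alpha0 *
(f/1 MHz)^y` and `y = 1.51`. Three choices deserve comment:

- **Clamping.** CT bone routinely exceeds 1000 HU (negative porosity
  otherwise) and air sits at -1000 HU, so `psi` is clamped to [0, 1].
- **Mask-only mapping.** The attenuation law evaluated at `psi = 1`
  returns the *maximum* skull attenuation, which cannot describe water
  (3.48e-4 Np/MHz^y/m). The square-root law is therefore applied only
  inside the skull mask; everything else — including brain tissue,
  which is approximated as water — receives the water constants. This
  guards the physical inconsistency of the bare formula at high
  porosity.
- **Units of the attenuation table.** The tabulated skull attenuation
  values are read as power-law prefactors at 1 MHz with the exponent
  applied multiplicatively; the solver converts them internally to the
  angular-frequency prefactor its absorption operators use.

Shear waves are not modelled: soft tissue barely supports them and at
near-normal incidence on the skull their contribution is small. The
control-placement helper flags poses beyond 45 degrees where this
neglect becomes questionable.

## The wave solver

The solver advances pressure `p`, per-axis particle velocity `u_i`
(staggered half a voxel) and per-axis density perturbations (split for
the absorbing boundary):

- spectral spatial derivatives with the k-space temporal correction
  `kappa = sinc(c_ref |k| dt / 2)`, `c_ref` = maximum medium speed —
  exact in time for homogeneous regions at that speed;
- heterogeneous density via staggered-grid spectral gradients
  (arithmetic face averages of `rho0`);
- power-law absorption through the fractional-Laplacian closure with
  the loss and dispersion prefactors applied voxelwise in real space,
  so heterogeneous `alpha0` maps are honoured;
- a quartic-profile perfectly matched layer applied to the split
  velocity/density components (default 10 voxels per face; any axis can
  be left periodic instead).

The time step follows the CFL rule `dt = cfl * min(dx) / max(c)` with
`cfl = 0.3`. Sources are injected as additive mass sources on the
discretized spherical cap (apex at the requested centre, geometric
focus at apex + ROC along the aim direction, half-angle
`asin(d / 2 ROC)`); a Dirichlet mode is available. Propagation is
linear: B/A is stored per voxel (uniform 5.2) but nonlinear steepening
is out of scope, consistent with treating the drive as low intensity.

**Amplitude estimator.** Reported amplitude maps are the per-voxel
maximum of |p| over the trailing measurement window (default 10 carrier
periods after 40 periods of settling; both configurable, and scaled
down in the bundled tests to each benchmark's actual transit time). A
windowed RMS times sqrt(2) alternative exists for traces. Peak negative
pressure is taken from probe traces over the same window.

**Verification.** The test suite checks the solver against independent
oracles: plane-wave phase speed (1D, two probes under a wavelength
apart), Beer-Lambert amplitude decay in a uniform lossy medium, a
numerically evaluated Rayleigh/O'Neil integral for the focused bowl in
water, an exactly conserved discrete energy invariant in a closed
lossless domain, grid-translation symmetry of the discretized cap, and
agreement of a z-invariant 3D run with the 2D solution. Note a physical
subtlety: for the default bowl (30 mm ROC, 25 mm aperture) the true
on-axis maximum sits one to several wavelengths *proximal* of the
geometric focus — the focal gain is modest (Fresnel number near one at
250-500 kHz) — and both the solver and the oracle reproduce exactly
this shift, so focal-position checks are made against the oracle's
maximum, not against the geometric focus.

## Radius positioning

Within the ball of radius ROC around the target: ball voxels on the
skull shell define the mean centre-to-shell distance; candidates are
ball voxels *outside the flood-filled skull volume* whose distance to
the model centre exceeds that mean, minus those closer to the skull
than the contact clearance (default: the bowl cap depth,
`ROC - sqrt(ROC^2 - (d/2)^2)`, about 2.73 mm for the default bowl).
Flood-filling the cavity guarantees zero intracranial candidates by
construction. The screen is validated against a literal brute-force
voxel scan (exact set equality) and is monotone in both the clearance
and the ball radius. Tie-breaks in the peak-pressure selection are
deterministic: largest amplitude, then smallest distance to target,
then candidate order.

The search-ball radius defaults to exactly ROC; a `ballMargin` argument
widens it when placements slightly beyond the radius of curvature
should be admitted.

## 2D desk-scale mode

Full 3D simulation of every candidate is the reference mode but is
expensive; the default planning mode simulates each pose on the 2D
plane through the candidate and the target. The 3D property maps are
sampled onto the plane by trilinear interpolation — nearest-neighbour
sampling was found to alias the sub-wavelength shell thickness of a
voxelized sphere into spurious pose-to-pose transmission differences —
and the bowl becomes a focused arc. The 2D domain is a beam corridor:
the apex-target segment plus post-focal room along the beam, the
aperture plus clearance across it, PML included. 2D amplitudes are not
identical to 3D ones (cylindrical versus spherical spreading), but the
mode is used for *comparisons across poses*, which share the geometry.
The solver core is dimension-agnostic, and 3D runs up to 128^3 are
supported directly.

## Pennes bioheat

Heat deposition uses the plane-wave absorbed-power closure
`Q = alpha(f) p^2 / (rho c)`, duty-scaled over each sonication window;
individual 200 us tone bursts are not resolved thermally because the
thermal diffusion time across a voxel (seconds) dwarfs the pulse
period (milliseconds). The explicit conservative finite-difference
scheme uses arithmetic face conductivities, insulated (zero-flux)
boundaries, a stability-bounded default step, and tracks the running
peak temperature at every step. Perfusion defaults to zero and can be
switched on per voxel.

Thermal constants: skull specific heat 1300 J/kg/K and conductivity
1.16 W/m/K; water 4178 J/kg/K and 0.54 W/m/K. The water conductivity
is stated here in W/m/K — sources occasionally print such values in
W/cm/degC, which for water would be physically impossible (54 W/m/K),
so this package standardises on SI units and makes both values
configurable.

The solver is verified against the analytic spreading-Gaussian heat
kernel, exact insulated-domain energy balance, linearity in the
source, the maximum principle, and zero-source invariance.

## Focal metrics

The FWHM region is the 6-connected component of the
amplitude-normalized field at or above 0.5 (the -6 dB *pressure*
contour, the common tFUS convention; an intensity-based -3 dB variant
is available) containing the analysed peak. Length is the region's
extent along the beam axis, width the maximal perpendicular extent,
and the offset angle the angle between the region's amplitude-weighted
principal axis (second-moment eigenvector) and the geometric beam axis
— our reading of a "focal offset" in degrees. Extents include the
voxel footprint; fields whose half-max region touches the domain
boundary are flagged degenerate rather than silently measured. For
skull runs the analysed peak is the local maximum near the target
(`focus`/`focusRadius` arguments): a closed bony shell can sustain
reverberant hot spots outside the cavity that are not the therapeutic
focus.

Beam-path angles follow the anatomical-plane convention: the angle
between the sonication vector and the transverse, sagittal and coronal
planes is `asin(|v . n|)` with n the respective plane normal (z, x, y),
so the three angles satisfy `sin^2 + sin^2 + sin^2 = 1` — a property the
test suite checks both on random vectors and on a published mean-angle
triple of this convention.

Safety indices: `MI = p_neg[MPa] / sqrt(f[MHz])` with the in-situ
(post-skull, simulated) peak negative pressure and no additional
derating; `I_SPPA = p^2 / (2 rho c)` with the focal-voxel impedance;
`I_SPTA = I_SPPA * duty cycle`. Flags compare with MI <= 1.9 and
I_SPPA <= 190 W/cm^2.

## Pulsed drive

The drive schedule is a sinusoid at the fundamental frequency gated
into rectangular tone bursts: duty cycle = TBD x PRF, bursts in a
sonication = floor(SD x PRF), carrier cycles per burst = round(FF x
TBD). With the default 500 kHz / 200 us / 300 Hz / 500 ms drive this
gives a 6% duty cycle and 150 bursts per sonication — the "cycles" of
a pulsed protocol are pulse-repetition periods, not carrier cycles.
For steady-state amplitude mapping a single continuous burst suffices;
the full schedule matters only for thermal dosing, where it enters as
the duty-scaled source and the on/off windows.

# The synthetic phantom: what it emulates, and what it does not

The generator produces a closed spherical bony shell in water with an
intracranial target: defaults are 22 mm outer radius, 7 mm thickness,
600 HU shell on a -1000 HU background, 60 mm domain at 1 mm spacing,
target 6 mm off-centre. The 600 HU default (porosity 0.4, c ~2453 m/s,
rho ~1720 kg/m^3, alpha0 ~140 Np/MHz^y/m) represents an *effective*
mixed cortical/diploic bone: a pure cortical shell (1500 HU and above)
clamps to zero porosity and nearly zero absorption, and a closed
lossless spherical cavity then accumulates reverberant energy under
continuous drive until the "post-skull" amplitude can exceed the
free-water focus — behaviour no real, absorbing, irregular skull
shows. An absorbing shell suppresses this artefact and produces the
expected focal shrinkage and amplitude drop.

What passing tests on the phantom do show: correct screening geometry,
correct relative ranking of transducer poses through an attenuating
shell, heat concentrating in bone, and all the solver physics above.
What they cannot show: patient-specific angles, distances, FWHM
deviations or temperatures — real skulls have spatially varying
thickness, layered cortical/diploic structure, non-spherical shape and
orientation-dependent incidence, so numbers from the phantom are not
comparable to any individual anatomy.

# Problem sizes and numerical settings used by the bundled checks

The test and acceptance suites run at desk scale, chosen so the full
suite completes on a single CPU: 1D plane-wave benchmarks at n = 256;
2D solver checks at 64^2-96^2; the 3D bowl benchmark at 64^3 and
250 kHz (5.9 points per wavelength at 1 mm); RP oracle equality on a
44^3 phantom; positioning dominance with six sampled candidates plus
seven control poses in 2D mode; bioheat on 48^2-96^2 grids and a
160 x 110 half-millimetre slice for the end-to-end heating check.
Settling windows are set from each domain's transit time rather than
the 40-period production default. A grid-size guard (>= 8 voxels
inside the PML, warning under 32) and a 3-points-per-wavelength
sampling warning protect against under-resolved runs; 1 mm spacing is
marginal at 500 kHz and above, so finer `spacing2d_mm` (0.5 mm or
less) is recommended there.

# Known limitations

- Linear propagation only; B/A is carried but unused by default.
- No shear-wave conversion; oblique poses beyond 45 degrees are
  flagged, not modelled.
- 2D positioning mode compares poses on beam planes; absolute 2D
  amplitudes differ from 3D by spreading geometry.
- No thermal dose (CEM43) accumulation; safety reporting is
  threshold-based (42/47/50 degC).
- Single-element bowls only; no phased-array steering.
- The phantom is a single-porosity shell; patient CTs should be
  supplied as NIfTI volumes for anything anatomy-specific.
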