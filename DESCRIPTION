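Package: tfusplan
Title: Transcranial Focused Ultrasound Treatment Planning with Skull-Aware
    Acoustic and Thermal Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for planning low-intensity transcranial focused
    ultrasound (tFUS) sonication through the skull. Provides synthetic
    skull phantom generation and Hounsfield-unit volume handling,
    porosity-based mapping of CT intensity to heterogeneous acoustic
    property volumes (sound speed, density, power-law attenuation), a
    k-space pseudospectral solver for linear acoustic propagation with
    perfectly matched layers, a radius-positioning (RP) algorithm that
    screens extracranial transducer-center candidates and selects the
    placement maximising target pressure, focal-spot metrics (FWHM
    geometry, beam-path angles, mechanical index and intensity safety
    indices), and a Pennes bioheat solver for sonication-induced
    heating under pulsed drive schedules.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
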