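## Porosity-based mapping of CT Hounsfield units to acoustic properties.
##
## Inside the binarized skull the medium interpolates between water and
## compact-bone endpoints through the porosity psi = 1 - HU/1000:
##   c    = c_water * psi + c_bone * (1 - psi)
##   rho  = rho_water * psi + rho_bone * (1 - psi)
##   a0   = a_min + (a_max - a_min) * psi^0.5
## Everything outside the mask is water (brain/CSF approximated as water).

#' Acoustic property-mapping constants
#'
#' Returns the default constant set for the porosity mapping (overridable
#' per call): water/bone sound speeds and densities, the minimum and
#' maximum skull compressional attenuation, water attenuation, the
#' nonlinearity parameter B/A and the power-law absorption exponent.
#' Attenuation prefactors are expressed in Np/MHz^y/m, i.e. the attenuation
#' at 1 MHz with `alpha(f) = alpha0 * (f/1 MHz)^y`.
#'
#' @param ... named overrides of any constant
#' @return named list of constants
#' @export
propertyConstants <- function(...) {
  const <- list(
    c_water = 1482,          # m/s
    c_bone = 3100,           # m/s
    rho_water = 1000,        # kg/m^3
    rho_bone = 2200,         # kg/m^3
    alpha_water = 3.48e-4,   # Np/MHz^y/m
    alpha_min_skull = 21.5,  # Np/MHz^y/m
    alpha_max_skull = 208.9, # Np/MHz^y/m
    BonA = 5.2,
    power_law_exponent = 1.51)
  ov <- list(...)
  bad <- setdiff(names(ov), names(const))
  if (length(bad)) stop("unknown constants: ", paste(bad, collapse = ", "))
  const[names(ov)] <- ov
  stopifnot(const$c_water > 0, const$c_bone > 0, const$rho_water > 0,
            const$rho_bone > 0, const$alpha_min_skull <= const$alpha_max_skull)
  const
}

#' Porosity from Hounsfield units
#'
#' `psi = clamp(1 - H/1000, 0, 1)`. Dense bone above 1000 HU clamps to 0,
#' air below -1000 HU (and anything water-like or below) clamps to 1.
#'
#' @param H Hounsfield units (scalar or array)
#' @return porosity in `[0, 1]`, same shape as `H`
#' @export
porosityFromHU <- function(H) {
  if (any(!is.finite(H))) stop("HU values must be finite")
  pmin(pmax(1 - H / 1000, 0), 1)
}

#' Map a Hounsfield volume to heterogeneous acoustic property maps
#'
#' Applies the porosity mapping inside the skull mask and assigns water
#' constants everywhere else (the skull is modelled as immersed in water,
#' with brain tissue approximated as water). B/A is uniform.
#'
#' @param hu an [HUVolume-class]
#' @param mask a [SkullMask-class] congruent with `hu`
#' @param const constants from [propertyConstants()]
#' @return a [MediumMaps-class]
#' @export
propertyMaps <- function(hu, mask, const = propertyConstants()) {
  stopifnot(is(hu, "HUVolume"), is(mask, "SkullMask"))
  if (!identical(dim(hu@data), dim(mask@data)))
    stop("hu and mask dimensions differ")
  d <- dim(hu@data)
  inb <- mask@data > 0
  psi <- porosityFromHU(hu@data)
  c0 <- array(const$c_water, d)
  rho <- array(const$rho_water, d)
  a0 <- array(const$alpha_water, d)
  c0[inb] <- const$c_water * psi[inb] + const$c_bone * (1 - psi[inb])
  rho[inb] <- const$rho_water * psi[inb] + const$rho_bone * (1 - psi[inb])
  a0[inb] <- const$alpha_min_skull +
    (const$alpha_max_skull - const$alpha_min_skull) * sqrt(psi[inb])
  new("MediumMaps", soundSpeed = c0, density = rho, alpha0 = a0,
      BonA = array(const$BonA, d), mask = array(inb, d),
      spacing = hu@spacing, origin = hu@origin,
      powerLawExponent = const$power_law_exponent, constants = const)
}

#' Homogeneous water medium of given dimensions
#'
#' Convenience constructor used for free-field benchmarks and water
#' reference runs.
#'
#' @param dims voxels per axis
#' @param spacing mm
#' @param origin world mm of voxel (0,0,...) centre
#' @param const constants from [propertyConstants()]
#' @param alpha0 optional uniform attenuation prefactor (Np/MHz^y/m)
#'   overriding the water value, e.g. for lossy-medium benchmarks
#' @return a [MediumMaps-class]
#' @export
waterMedium <- function(dims, spacing = 1, origin = rep(0, length(dims)),
                        const = propertyConstants(), alpha0 = NULL) {
  d <- as.integer(dims)
  if (length(spacing) == 1) spacing <- rep(spacing, length(d))
  new("MediumMaps",
      soundSpeed = array(const$c_water, d),
      density = array(const$rho_water, d),
      alpha0 = array(alpha0 %||% const$alpha_water, d),
      BonA = array(const$BonA, d), mask = array(FALSE, d),
      spacing = spacing, origin = as.numeric(origin),
      powerLawExponent = const$power_law_exponent, constants = const)
}

#' Attenuation at a given frequency from the power-law prefactor
#'
#' `alpha(f) = alpha0 * (f / 1 MHz)^y` in Np/m.
#'
#' @param alpha0 Np/MHz^y/m (scalar or array)
#' @param f frequency, Hz, positive
#' @param y power-law exponent (default 1.51)
#' @return attenuation in Np/m, same shape as `alpha0`
#' @export
attenuationAtFrequency <- function(alpha0, f, y = 1.51) {
  if (!is.numeric(f) || length(f) != 1 || f <= 0)
    stop("frequency must be a single positive number")
  alpha0 * (f / 1e6)^y
}
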