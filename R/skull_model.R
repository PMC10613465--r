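## Skull model: HU volume handling, resampling, binarization, phantoms.

#' World coordinates of every voxel centre along one axis
#' @noRd
axisCoords <- function(n, sp, or) or + (seq_len(n) - 1) * sp

#' Trilinear (or bilinear/linear) resampling to isotropic spacing
#'
#' Resamples a Hounsfield volume onto an isotropic grid. The physical box
#' covered by the voxel cells (dims * spacing, cell-edge convention) is
#' preserved; output dimensions are `round(extent / spacing)` per axis.
#' Sampling uses separable linear interpolation by default
#' (`order = 1`); `order = 0` selects nearest-neighbour.
#'
#' @param vol an [HUVolume-class]
#' @param spacing requested isotropic voxel size, mm
#' @param order interpolation order: 0 (nearest) or 1 (trilinear, default)
#' @return an [HUVolume-class] at the requested spacing
#' @export
resampleIsotropic <- function(vol, spacing = 1, order = 1) {
  stopifnot(is(vol, "HUVolume"))
  if (!is.numeric(spacing) || length(spacing) != 1 || spacing <= 0)
    stop("spacing must be a single positive number")
  d <- dim(vol@data)
  if (any(d == 0) || length(vol@data) == 0) stop("empty volume")
  extent <- d * vol@spacing
  nd <- pmax(1L, as.integer(round(extent / spacing)))
  ## identity short-circuit keeps the result bitwise identical
  if (all(abs(vol@spacing - spacing) < 1e-12) && all(nd == d)) return(vol)
  ## align cell boxes: first output voxel centre sits half an output voxel
  ## into the box, whose corner is origin - spacing_in/2
  newOrigin <- vol@origin - vol@spacing / 2 + spacing / 2
  out <- vol@data
  for (ax in seq_along(d)) {
    xin <- axisCoords(dim(out)[ax], vol@spacing[ax], vol@origin[ax])
    xout <- axisCoords(nd[ax], spacing, newOrigin[ax])
    out <- interpAlongAxis(out, ax, xin, xout, order)
  }
  new("HUVolume", data = out, spacing = rep(spacing, length(d)),
      origin = newOrigin)
}

#' Linear/nearest interpolation of an array along one axis (clamped ends)
#' @noRd
interpAlongAxis <- function(arr, ax, xin, xout, order) {
  d <- dim(arr)
  nin <- d[ax]; nout <- length(xout)
  if (nin == 1) {
    idx <- rep(1L, nout); w <- rep(0, nout); idx2 <- idx
  } else {
    pos <- (xout - xin[1]) / (xin[2] - xin[1])  # fractional 0-based index
    pos <- pmin(pmax(pos, 0), nin - 1)
    if (order == 0) {
      idx <- as.integer(round(pos)) + 1L; idx2 <- idx; w <- rep(0, nout)
    } else {
      idx <- pmin(as.integer(floor(pos)) + 1L, nin - 1L)
      idx2 <- idx + 1L
      w <- pos - (idx - 1L)
    }
  }
  perm <- c(ax, seq_along(d)[-ax])
  a <- aperm(arr, perm)
  dim(a) <- c(nin, prod(d[-ax]))
  res <- a[idx, , drop = FALSE] * (1 - w) + a[idx2, , drop = FALSE] * w
  dim(res) <- c(nout, d[-ax])
  aperm(res, order(perm))
}

#' Binarize a Hounsfield volume into a skull mask
#'
#' A voxel is inside-skull iff its HU value is greater than or equal to the
#' threshold (default 100 HU, the single-threshold bone segmentation used
#' throughout the package). The comparison is inclusive; pass a slightly
#' larger threshold for strict behaviour.
#'
#' @param vol an [HUVolume-class]
#' @param threshold HU, default 100
#' @return a [SkullMask-class] with the same grid
#' @export
binarizeSkull <- function(vol, threshold = 100) {
  stopifnot(is(vol, "HUVolume"))
  if (length(vol@data) == 0) stop("empty volume")
  m <- (vol@data >= threshold) * 1
  new("SkullMask", data = m, spacing = vol@spacing, origin = vol@origin)
}

#' Synthetic spherical-shell skull phantom
#'
#' Generates a closed bony shell standing in for a patient CT: voxels whose
#' distance r to `center` satisfies `outerRadius - thickness <= r <=
#' outerRadius` receive `shellHU` (a constant, or a function of r for a
#' radial HU profile); all others receive `backgroundHU`. The result is
#' deterministic for a fixed specification.
#'
#' @param outerRadius mm
#' @param thickness mm, 0 < thickness < outerRadius
#' @param center world mm (length 3)
#' @param shellHU HU value of the shell (scalar), or `function(r)` of the
#'   radius giving a radial HU profile; must stay at or above the
#'   binarization threshold
#' @param backgroundHU HU outside the shell (default -1000, air-like water
#'   stand-in below threshold)
#' @param domainExtent mm per axis (length 3); must enclose the shell
#' @param spacing mm, isotropic
#' @param targetPoint world mm, strictly inside the inner cavity
#' @return an [HUVolume-class]; the target point is stored in
#'   `attr(, "targetPoint")`
#' @export
generatePhantom <- function(outerRadius = 22, thickness = 7,
                            center = c(0, 0, 0), shellHU = 600,
                            backgroundHU = -1000,
                            domainExtent = rep(2 * outerRadius + 16, 3),
                            spacing = 1,
                            targetPoint = center + c(0, -6, 0)) {
  if (thickness <= 0 || thickness >= outerRadius)
    stop("need 0 < thickness < outerRadius")
  rt <- sqrt(sum((targetPoint - center)^2))
  if (rt >= outerRadius - thickness)
    stop("target point must lie strictly inside the inner cavity")
  if (any(domainExtent < 2 * outerRadius))
    stop("domain extent must enclose the shell")
  dims <- pmax(1L, as.integer(round(domainExtent / spacing)))
  origin <- center - (dims - 1) * spacing / 2
  cx <- axisCoords(dims[1], spacing, origin[1]) - center[1]
  cy <- axisCoords(dims[2], spacing, origin[2]) - center[2]
  cz <- axisCoords(dims[3], spacing, origin[3]) - center[3]
  r2 <- outer(outer(cx^2, cy^2, "+"), cz^2, "+")
  r <- sqrt(r2)
  inShell <- r >= (outerRadius - thickness) & r <= outerRadius
  hu <- array(backgroundHU, dim = dims)
  if (is.function(shellHU)) hu[inShell] <- shellHU(r[inShell])
  else hu[inShell] <- shellHU
  vol <- new("HUVolume", data = hu, spacing = rep(spacing, 3), origin = origin)
  attr(vol@data, "targetPoint") <- NULL
  attr(vol, "targetPoint") <- targetPoint
  vol
}

#' Fill the skull volume (shell plus intracranial cavity)
#'
#' Flood-fills the exterior from the domain boundary through non-skull
#' voxels (6-connectivity) and returns a logical array that is TRUE on the
#' skull and on every enclosed cavity voxel. Used to exclude intracranial
#' points from RP candidate screening and to test that a target is
#' intracranial.
#'
#' @param mask a [SkullMask-class]
#' @return logical array, TRUE = skull bone or enclosed cavity
#' @export
fillSkullVolume <- function(mask) {
  stopifnot(is(mask, "SkullMask"))
  solid <- mask@data > 0
  d <- dim(solid)
  outside <- array(FALSE, d)
  ## seed every boundary voxel that is not bone
  idx <- lapply(d, seq_len)
  bnd <- array(FALSE, d)
  for (ax in seq_along(d)) {
    sl <- idx; sl[[ax]] <- c(1L, d[ax])
    bnd <- do.call(`[<-`, c(list(bnd), sl, list(TRUE)))
  }
  outside <- bnd & !solid
  repeat {
    grown <- outside
    for (ax in seq_along(d)) {
      grown <- grown | shiftArray(outside, ax, 1L) | shiftArray(outside, ax, -1L)
    }
    grown <- grown & !solid
    if (!any(grown & !outside)) break
    outside <- grown
  }
  !outside
}

#' Shift an array by k voxels along an axis, padding with FALSE/0
#' @noRd
shiftArray <- function(a, ax, k) {
  d <- dim(a)
  out <- array(if (is.logical(a)) FALSE else 0, d)
  n <- d[ax]
  if (abs(k) >= n) return(out)
  src <- lapply(d, seq_len); dst <- lapply(d, seq_len)
  if (k > 0) { dst[[ax]] <- (1L + k):n; src[[ax]] <- 1L:(n - k) }
  else if (k < 0) { dst[[ax]] <- 1L:(n + k); src[[ax]] <- (1L - k):n }
  do.call(`[<-`, c(list(out), dst, list(do.call(`[`, c(list(a), src)))))
}

#' Is a world point inside the intracranial cavity of a skull mask?
#'
#' @param mask a [SkullMask-class]
#' @param point world mm
#' @param filled optional precomputed [fillSkullVolume()] result
#' @return logical
#' @export
isIntracranial <- function(mask, point, filled = fillSkullVolume(mask)) {
  vi <- worldToVoxel(point, mask@spacing, mask@origin)
  d <- dim(mask@data)
  if (any(vi < 0) || any(vi > d - 1)) return(FALSE)
  filled[matrix(vi + 1L, 1)] && !(mask@data[matrix(vi + 1L, 1)] > 0)
}

#' @noRd
worldToVoxel <- function(point, spacing, origin)
  as.integer(round((point - origin) / spacing))

#' @noRd
voxelToWorld <- function(idx0, spacing, origin)
  origin + idx0 * spacing

## ---- NIfTI input/output ----

#' Read a Hounsfield volume from a NIfTI-1 file
#'
#' Voxel spacing is taken from the header pixdim and the origin from the
#' affine translation; the axis order of the stored array is used as-is
#' (x, y, z).
#'
#' @param path NIfTI file
#' @return an [HUVolume-class]
#' @export
readHUVolume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  arr <- array(as.numeric(img), dim(img))
  org <- tryCatch(-RNifti::xform(img)[seq_along(dim(arr)), 4],
                  error = function(e) rep(0, length(dim(arr))))
  HUVolume(arr, spacing = sp[seq_along(dim(arr))], origin = as.numeric(org))
}

#' Write a volume-like object to NIfTI-1
#'
#' @param vol a [ScalarVolume-class] (or subclass), or a plain array with
#'   `spacing`/`origin` supplied
#' @param path output file (`.nii` or `.nii.gz`)
#' @param spacing,origin used when `vol` is a plain array
#' @return `path`, invisibly
#' @export
writeVolume <- function(vol, path, spacing = NULL, origin = NULL) {
  if (is(vol, "ScalarVolume")) { arr <- vol@data; sp <- vol@spacing }
  else { arr <- vol; sp <- spacing %||% rep(1, length(dim(vol))) }
  img <- RNifti::asNifti(arr, reference = NULL)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
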