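#' Volume and projection containers
#'
#' `volume_hu()` wraps a rank-3 numeric array of Hounsfield units (a raw CT
#' scan). `volume8()` wraps a rank-4 array (depth x height x width x channel)
#' of dimensionless intensities on either the 8-bit `[0, 255]` scale or the
#' model-space `[0, 1]` scale, together with its effective gradation in bits.
#' `projection()` wraps a 2D view of a volume with its axis label and the
#' standard deviation of any additive noise.
#'
#' Axis convention: depth = anterior-posterior, height = cranio-caudal,
#' width = left-right.
#'
#' @param voxels numeric array; rank 3 for `volume_hu`, rank 3 or 4 for
#'   `volume8` (a trailing channel axis is added when missing).
#' @param spacing optional numeric length-3 voxel spacing in mm.
#' @param scale `"eightbit"` (values in `[0, 255]`) or `"unit"` (`[0, 1]`).
#' @param bits integer 1-8, the effective gradation of the stored values.
#' @return An object of class `volume_hu`, `volume8` or `projection`.
#' @examples
#' v <- volume8(array(runif(64, 0, 255), c(4, 4, 4)))
#' dim(v$voxels)
#' @export
volume_hu <- function(voxels, spacing = NULL) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop_input("volume_hu expects a rank-3 array, got rank %d", length(dim(voxels)))
  if (!all(is.finite(voxels))) stop_input("volume contains non-finite values")
  structure(list(voxels = voxels, spacing = spacing), class = "volume_hu")
}

#' @rdname volume_hu
#' @export
volume8 <- function(voxels, scale = c("eightbit", "unit"), bits = 8L) {
  scale <- match.arg(scale)
  voxels <- as.array(voxels)
  if (length(dim(voxels)) == 3L) dim(voxels) <- c(dim(voxels), 1L)
  if (length(dim(voxels)) != 4L)
    stop_input("volume8 expects a rank-3 or rank-4 array")
  bits <- as.integer(bits)
  if (bits < 1L || bits > 8L) stop_input("bits must be in 1..8")
  lim <- if (scale == "eightbit") c(0, 255) else c(0, 1)
  rng <- range(voxels)
  if (rng[1] < lim[1] - 1e-9 || rng[2] > lim[2] + 1e-9)
    stop_input("values [%g, %g] outside the declared %s scale", rng[1], rng[2], scale)
  structure(list(voxels = voxels, scale = scale, bits = bits), class = "volume8")
}

#' @rdname volume_hu
#' @param pixels numeric matrix or rank-3 array (height x width x channel).
#' @param view `"coronal"` (depth average) or `"sagittal"` (width average).
#' @param noise_sigma noise standard deviation on the 8-bit scale.
#' @export
projection <- function(pixels, view = c("coronal", "sagittal"),
                       noise_sigma = 0, scale = c("eightbit", "unit")) {
  view <- match.arg(view)
  scale <- match.arg(scale)
  pixels <- as.array(pixels)
  if (length(dim(pixels)) == 2L) dim(pixels) <- c(dim(pixels), 1L)
  if (length(dim(pixels)) != 3L) stop_input("projection expects a matrix or rank-3 array")
  structure(list(pixels = pixels, view = view, noise_sigma = noise_sigma,
                 scale = scale), class = "projection")
}

#' @export
print.volume_hu <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volume_hu %dx%dx%d, HU range [%.0f, %.0f]>\n",
              d[1], d[2], d[3], min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.volume8 <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volume8 %dx%dx%dx%d, %s scale, %d bits>\n",
              d[1], d[2], d[3], d[4], x$scale, x$bits))
  invisible(x)
}

#' @export
print.projection <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<projection %s %dx%d, sigma=%g (%s scale)>\n",
              x$view, d[1], d[2], x$noise_sigma, x$scale))
  invisible(x)
}

#' Convert a volume between the 8-bit and unit intensity scales
#'
#' The conversion is the exact multiplication by 1/255 (or 255); the bit
#' depth tag is preserved.
#'
#' @param vol a [volume8()].
#' @param scale target scale.
#' @return a [volume8()] on the requested scale.
#' @export
rescale_volume <- function(vol, scale = c("unit", "eightbit")) {
  scale <- match.arg(scale)
  stopifnot(inherits(vol, "volume8"))
  if (vol$scale == scale) return(vol)
  f <- if (scale == "unit") 1 / 255 else 255
  volume8(vol$voxels * f, scale = scale, bits = vol$bits)
}

# internal: coerce to a plain unit-scale array
as_unit_array <- function(vol) {
  if (inherits(vol, "volume8")) {
    if (vol$scale == "eightbit") vol$voxels / 255 else vol$voxels
  } else if (is.array(vol) || is.numeric(vol)) {
    as.array(vol)
  } else stop_input("expected a volume8 or an array")
}
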