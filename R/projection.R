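#' Forward-project a volume to a 2D view
#'
#' The observation model is linear depth averaging: for the coronal view,
#' `y(h, w) = mean over d of x(d, h, w)`; for the sagittal view the average
#' runs over the width axis and the output columns index depth
#' (`y(h, d) = mean over w of x(d, h, w)`). This emulates a digitally
#' reconstructed radiograph with a mean-intensity operator rather than
#' physical attenuation.
#'
#' @param x a [volume8()] (either scale) or rank-3/4 array.
#' @param view `"coronal"` or `"sagittal"`.
#' @return a [projection()] on the same intensity scale as the input.
#' @examples
#' v <- generate_phantom(phantom_spec(size = 16), 1)
#' p <- project(v, "coronal")
#' dim(p$pixels)
#' @export
project <- function(x, view = c("coronal", "sagittal")) {
  view <- match.arg(view)
  scale <- if (inherits(x, "volume8")) x$scale else "eightbit"
  a <- if (inherits(x, "volume8")) x$voxels else as.array(x)
  if (length(dim(a)) == 3L) dim(a) <- c(dim(a), 1L)
  d <- dim(a)
  D <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  px <- if (view == "coronal") {
    array(colMeans(matrix(a, D, H * W * C)), c(H, W, C))
  } else {
    # mean over width: reorder to (W, D, H, C) and average the first axis
    b <- aperm(a, c(3, 1, 2, 4))
    y0 <- array(colMeans(matrix(b, W, D * H * C)), c(D, H, C))
    aperm(y0, c(2, 1, 3))
  }
  projection(px, view = view, noise_sigma = 0, scale = scale)
}

#' Project a volume onto several distinct views
#'
#' @inheritParams project
#' @param views character vector of distinct view labels.
#' @return a list of [projection()]s, one per view.
#' @export
project_multi <- function(x, views = c("coronal", "sagittal")) {
  if (length(views) == 0) stop_input("need at least one view")
  if (anyDuplicated(views)) stop_input("duplicate views requested")
  lapply(views, function(v) project(x, v))
}

#' Add Gaussian observation noise to a projection
#'
#' Adds i.i.d. `N(0, sigma^2)` noise per pixel, with `sigma` specified on the
#' 8-bit gray-level scale regardless of the projection's stored scale (the
#' ultra-low-dose protocol uses `sigma^2 = 100`). The applied sigma is
#' recorded in the result's `noise_sigma` field.
#'
#' @param y a [projection()].
#' @param sigma noise standard deviation in 8-bit gray levels (>= 0).
#' @param seed optional RNG seed.
#' @return a [projection()] with noisy pixels.
#' @export
add_noise <- function(y, sigma, seed = NULL) {
  stopifnot(inherits(y, "projection"))
  if (sigma < 0) stop_input("sigma must be >= 0")
  if (sigma == 0) return(y)
  s <- if (y$scale == "unit") sigma / 255 else sigma
  body <- function() array(rnorm(length(y$pixels), sd = s), dim(y$pixels))
  n <- if (!is.null(seed)) with_seed(seed, body()) else body()
  projection(y$pixels + n, view = y$view,
             noise_sigma = sqrt(y$noise_sigma^2 + sigma^2), scale = y$scale)
}
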