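#' Gradation reduction from Hounsfield units to the 8-bit scale
#'
#' Maps a raw CT volume `I` (in HU) to `255 * (clip(I, -1000, max(I)) + 1000)
#' / (max(I) + 1000)`, so that -1000 HU (air) lands on 0 and the volume
#' maximum on 255. Values are kept in floating point; use [quantize_bits()]
#' to bin them.
#'
#' @param src a [volume_hu()] or rank-3 numeric array of HU values.
#' @return a [volume8()] on the 8-bit scale with `bits = 8`.
#' @examples
#' v <- volume_hu(array(c(-1000, 0, 500, 1000), c(4, 1, 1)))
#' reduce_gradation(v)$voxels[, 1, 1, 1]  # 0, 127.5, 191.25, 255
#' @export
reduce_gradation <- function(src) {
  if (!inherits(src, "volume_hu")) src <- volume_hu(src)
  x <- src$voxels
  mx <- max(x)
  if (mx <= -1000)
    stop_input("degenerate volume: maximum HU (%g) does not exceed -1000", mx)
  out <- 255 * (pmin(pmax(x, -1000), mx) + 1000) / (mx + 1000)
  dim(out) <- c(dim(x), 1L)
  volume8(out, scale = "eightbit", bits = 8L)
}

#' Reduce the bit depth of an 8-bit volume
#'
#' Floor-division binning: each voxel `v` becomes `floor(v / 2^(8 - k))`,
#' giving integer values in `[0, 2^k - 1]`. This is the per-stage gradation
#' used by progressive training.
#'
#' @param vol a [volume8()] on the 8-bit scale.
#' @param k target bit depth, integer in 1..8.
#' @return a [volume8()] with `bits = k` (values still live on the eightbit
#'   container scale; [to_model_space()] normalizes by `2^k`).
#' @export
quantize_bits <- function(vol, k) {
  stopifnot(inherits(vol, "volume8"))
  if (vol$scale != "eightbit") stop_input("quantize_bits expects the eightbit scale")
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > 8L)
    stop_input("bit depth k must be a single integer in 1..8")
  q <- floor(vol$voxels / 2^(8L - k))
  v <- structure(list(voxels = q, scale = "eightbit", bits = k),
                 class = "volume8")
  v
}

#' Map a quantized volume into flow model space
#'
#' A `k`-bit volume with integer values `v` is mapped to `[0, 1)` as
#' `(v + u) / 2^k`, where `u` is uniform dequantization noise during
#' training (`dequantize = TRUE`) and the bin midpoint 0.5 otherwise.
#'
#' @param vol a [volume8()] produced by [quantize_bits()] (or any 8-bit volume).
#' @param dequantize add uniform noise instead of the bin midpoint.
#' @param seed optional seed making the noise reproducible.
#' @return a [volume8()] on the unit scale.
#' @export
to_model_space <- function(vol, dequantize = FALSE, seed = NULL) {
  stopifnot(inherits(vol, "volume8"))
  if (vol$scale != "eightbit")
    stop_input("to_model_space expects a quantized eightbit-scale volume")
  k <- vol$bits
  v <- vol$voxels
  body <- function() {
    u <- if (dequantize) array(runif(length(v)), dim(v)) else 0.5
    (v + u) / 2^k
  }
  out <- if (!is.null(seed)) with_seed(seed, body()) else body()
  out <- pmin(pmax(out, 0), 1 - 1e-12)
  dim(out) <- dim(v)
  volume8(out, scale = "unit", bits = k)
}

#' Downsample a volume by integer mean-pooling
#'
#' @param vol a [volume8()] or [volume_hu()].
#' @param factor integer pooling factor per axis (scalar or length 3).
#' @return the pooled object of the same class.
#' @export
downsample_volume <- function(vol, factor = 2L) {
  f <- as.integer(rep(factor, length.out = 3))
  pool <- function(x) {
    d <- dim(x)[1:3]
    if (any(d %% f != 0)) stop_input("dims (%s) not divisible by pooling factors",
                                     paste(d, collapse = "x"))
    d2 <- d %/% f
    ch <- if (length(dim(x)) == 4L) dim(x)[4] else 1L
    dim(x) <- c(d[1], d[2], d[3], ch)
    out <- array(0, c(d2, ch))
    for (c in seq_len(ch)) {
      a <- array(x[, , , c], c(f[1], d2[1], f[2], d2[2], f[3], d2[3]))
      out[, , , c] <- apply(a, c(2, 4, 6), mean)
    }
    out
  }
  if (inherits(vol, "volume8")) {
    volume8(pool(vol$voxels), scale = vol$scale, bits = vol$bits)
  } else if (inherits(vol, "volume_hu")) {
    p <- pool(vol$voxels)
    volume_hu(array(p, dim(p)[1:3]), spacing = if (!is.null(vol$spacing)) vol$spacing * f)
  } else stop_input("expected a volume8 or volume_hu")
}

#' Read and write volumes as NIfTI
#'
#' Volumes are stored as `.nii`/`.nii.gz`. `read_volume()` returns a
#' [volume_hu()] when the file contains negative values (or `scale = "hu"`),
#' otherwise a [volume8()] on the 8-bit scale.
#'
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @param scale `"auto"`, `"hu"`, `"eightbit"`, or `"unit"`.
#' @return `read_volume()`: a volume object; `write_volume()`: `path`, invisibly.
#' @export
read_volume <- function(path, scale = c("auto", "hu", "eightbit", "unit")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop_input("volume file not found: %s", path)
  if (!grepl("\\.nii(\\.gz)?$", path))
    stop_input("unsupported volume format (expect .nii/.nii.gz): %s", path)
  x <- tryCatch(as.array(RNifti::readNifti(path)),
                error = function(e) stop_input("cannot read %s: %s", path, conditionMessage(e)))
  if (scale == "auto") scale <- if (min(x) < 0) "hu" else "eightbit"
  if (scale == "hu") volume_hu(x) else volume8(x, scale = scale)
}

#' @rdname read_volume
#' @param vol the volume to write.
#' @export
write_volume <- function(vol, path) {
  if (!grepl("\\.nii(\\.gz)?$", path))
    stop_input("unsupported volume format (expect .nii/.nii.gz): %s", path)
  x <- if (inherits(vol, "volume_hu")) vol$voxels
       else if (inherits(vol, "volume8")) {
         d <- dim(vol$voxels)
         if (d[4] != 1L) vol$voxels else array(vol$voxels, d[1:3])
       } else stop_input("expected a volume8 or volume_hu")
  RNifti::writeNifti(RNifti::asNifti(x, datatype = "double"), file = path)
  invisible(path)
}

#' Read and write projection images
#'
#' Projections are stored as 8-bit PNG or 16-bit TIFF, with a plain-text
#' sidecar (`<path>.meta`) recording the view label, the noise sigma and the
#' intensity scale. 8-bit-integer pixel values round-trip exactly through the
#' 16-bit TIFF encoding.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return `read_projection()`: a [projection()]; `write_projection()`:
#'   `path`, invisibly.
#' @export
read_projection <- function(path) {
  if (!file.exists(path)) stop_input("projection file not found: %s", path)
  px <- if (grepl("\\.png$", path)) {
    tryCatch(png::readPNG(path), error = function(e)
      stop_input("cannot read %s: %s", path, conditionMessage(e)))
  } else if (grepl("\\.tiff?$", path)) {
    tryCatch(tiff::readTIFF(path), error = function(e)
      stop_input("cannot read %s: %s", path, conditionMessage(e)))
  } else stop_input("unsupported projection format: %s", path)
  meta <- list(view = "coronal", sigma = 0)
  mp <- paste0(path, ".meta")
  if (file.exists(mp)) {
    kv <- read.dcf(mp)
    meta$view <- if ("view" %in% colnames(kv)) kv[1, "view"] else meta$view
    meta$sigma <- if ("sigma" %in% colnames(kv)) as.numeric(kv[1, "sigma"]) else 0
  }
  projection(px * 255, view = meta$view, noise_sigma = meta$sigma,
             scale = "eightbit")
}

#' @rdname read_projection
#' @param p a [projection()].
#' @export
write_projection <- function(p, path) {
  stopifnot(inherits(p, "projection"))
  px <- if (p$scale == "eightbit") p$pixels / 255 else p$pixels
  px <- pmin(pmax(px, 0), 1)
  img <- if (dim(px)[3] == 1L) matrix(px[, , 1], dim(px)[1], dim(px)[2]) else px
  if (grepl("\\.png$", path)) {
    png::writePNG(img, target = path)
  } else if (grepl("\\.tiff?$", path)) {
    tiff::writeTIFF(img, where = path, bits.per.sample = 16L)
  } else stop_input("unsupported projection format: %s", path)
  write.dcf(data.frame(view = p$view, sigma = p$noise_sigma), paste0(path, ".meta"))
  invisible(path)
}

#' @importFrom utils write.csv
NULL
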