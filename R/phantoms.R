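#' Specification of a synthetic chest phantom population
#'
#' Each phantom is a geometric composite on a cubic grid: a soft-tissue body
#' ellipsoid, two low-intensity lung ellipsoids, a heart sphere, a spine
#' cylinder and a flat bed slab near the posterior face, all smoothed with a
#' Gaussian kernel. Per-subject jitter of centres, semi-axes and intensities
#' makes the population variable yet structurally consistent, standing in for
#' a cohort of normal-subject chest CT scans.
#'
#' Geometry is expressed in normalized coordinates in `[-1, 1]` per axis
#' (depth = anterior-posterior, height = cranio-caudal, width = left-right);
#' intensities are on the 8-bit scale.
#'
#' @param size grid edge length (the volume is `size^3`).
#' @param body,lung,heart,spine,bed lists overriding the default structure
#'   parameters (`center`, `semi`, `intensity`, ...).
#' @param background background (air) intensity.
#' @param blur_sigma Gaussian smoothing in voxels.
#' @param jitter_center,jitter_semi,jitter_intensity per-subject uniform
#'   jitter half-widths: centre shift (normalized units), relative semi-axis
#'   scaling, and intensity shift (gray levels).
#' @param seed base seed; phantom `i` is a pure function of `(seed, i)`.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = 32L,
                         body = list(center = c(0.00, 0.00, 0.00),
                                     semi = c(0.62, 0.95, 0.78), intensity = 135),
                         lung = list(center_d = 0.02, center_h = 0.05,
                                     center_w = 0.38, semi = c(0.36, 0.55, 0.24),
                                     intensity = 30),
                         heart = list(center = c(0.14, -0.05, -0.08),
                                      radius = 0.22, intensity = 150),
                         spine = list(center_d = 0.42, radius = 0.10,
                                      height_frac = 0.9, intensity = 210),
                         bed = list(d_range = c(0.84, 0.96), half_width = 0.85,
                                    intensity = 80),
                         background = 2,
                         blur_sigma = 0.8,
                         jitter_center = 0.04,
                         jitter_semi = 0.08,
                         jitter_intensity = 8,
                         seed = 1L) {
  spec <- list(size = as.integer(size), body = body, lung = lung, heart = heart,
               spine = spine, bed = bed, background = background,
               blur_sigma = blur_sigma, jitter_center = jitter_center,
               jitter_semi = jitter_semi, jitter_intensity = jitter_intensity,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  reach <- max(abs(spec$body$center)) + max(spec$body$semi) * (1 + spec$jitter_semi) +
    spec$jitter_center
  if (reach > 1.45)
    stop_input("body ellipsoid (reach %.2f) does not fit the grid", reach)
  ints <- c(spec$body$intensity, spec$lung$intensity, spec$heart$intensity,
            spec$spine$intensity, spec$bed$intensity, spec$background)
  if (any(ints < 0 | ints > 255)) stop_input("intensities must lie in [0, 255]")
  invisible(spec)
}

#' Generate one phantom volume
#'
#' Deterministic in `(spec$seed, subject_index)`: the same pair always yields
#' the identical volume.
#'
#' @param spec a [phantom_spec()].
#' @param subject_index positive integer identifying the subject.
#' @return a [volume8()] on the 8-bit scale.
#' @examples
#' v <- generate_phantom(phantom_spec(size = 16), 1)
#' @export
generate_phantom <- function(spec, subject_index = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  S <- spec$size
  with_seed(derive_seed(spec$seed, subject_index), {
    jc <- function(x) x + runif(length(x), -spec$jitter_center, spec$jitter_center)
    js <- function(x) x * (1 + runif(length(x), -spec$jitter_semi, spec$jitter_semi))
    ji <- function(x) x + runif(1, -spec$jitter_intensity, spec$jitter_intensity)

    g <- (seq_len(S) - 0.5) / S * 2 - 1  # voxel centres in [-1, 1]
    dd <- array(g, c(S, S, S))
    hh <- array(rep(g, each = S), c(S, S, S))
    ww <- array(rep(g, each = S * S), c(S, S, S))

    vol <- array(spec$background, c(S, S, S))

    paint_ellipsoid <- function(vol, center, semi, val) {
      m <- ((dd - center[1]) / semi[1])^2 + ((hh - center[2]) / semi[2])^2 +
        ((ww - center[3]) / semi[3])^2 <= 1
      vol[m] <- val
      vol
    }

    # bed slab (posterior, outside the body)
    bed_d <- spec$bed$d_range
    mbed <- dd >= bed_d[1] & dd <= bed_d[2] & abs(ww) <= spec$bed$half_width
    vol[mbed] <- ji(spec$bed$intensity)

    body_c <- jc(spec$body$center); body_s <- js(spec$body$semi)
    vol <- paint_ellipsoid(vol, body_c, body_s, ji(spec$body$intensity))

    lung_s <- js(spec$lung$semi)
    lung_i <- ji(spec$lung$intensity)
    for (side in c(-1, 1)) {
      lc <- jc(c(spec$lung$center_d, spec$lung$center_h,
                 side * spec$lung$center_w))
      vol <- paint_ellipsoid(vol, body_c + lc * body_s / spec$body$semi,
                             lung_s, lung_i)
    }

    hc <- jc(spec$heart$center); hr <- js(spec$heart$radius)
    vol <- paint_ellipsoid(vol, body_c + hc, rep(hr, 3), ji(spec$heart$intensity))

    sc_d <- jc(spec$spine$center_d); sr <- js(spec$spine$radius)
    msp <- ((dd - sc_d)^2 + ww^2) <= sr^2 &
      abs(hh) <= spec$spine$height_frac * body_s[2]
    vol[msp] <- ji(spec$spine$intensity)

    if (spec$blur_sigma > 0)
      vol <- array(cpp_blur3(vol, dim(vol), spec$blur_sigma), dim(vol))
    vol <- pmin(pmax(vol, 0), 255)
    volume8(vol, scale = "eightbit", bits = 8L)
  })
}

#' Split subjects into train / validation / test sets
#'
#' Subjects are shuffled (seeded) and assigned by largest-remainder rounding
#' of the requested ratios, so the split is disjoint and exhaustive. The
#' default ratios 384:32:34 mirror a 450-subject cohort split.
#'
#' @param n_subjects number of subjects (>= 3).
#' @param split_ratios length-3 positive weights for train/val/test; they are
#'   normalized to sum to one.
#' @param seed shuffle seed.
#' @return a list with integer vectors `train`, `val`, `test`.
#' @examples
#' lengths(make_dataset(450, seed = 1))  # 384, 32, 34
#' @export
make_dataset <- function(n_subjects, split_ratios = c(384, 32, 34), seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 3L) stop_input("need at least 3 subjects")
  if (length(split_ratios) != 3L || any(split_ratios < 0) || sum(split_ratios) <= 0)
    stop_input("split_ratios must be 3 non-negative weights")
  r <- split_ratios / sum(split_ratios)
  sizes <- floor(n_subjects * r)
  rem <- n_subjects * r - sizes
  short <- n_subjects - sum(sizes)
  if (short > 0) {
    give <- order(rem, decreasing = TRUE)[seq_len(short)]
    sizes[give] <- sizes[give] + 1
  }
  if (any(sizes == 0)) stop_input("a split would be empty (sizes %s)",
                                  paste(sizes, collapse = "/"))
  idx <- with_seed(seed, sample.int(n_subjects))
  list(train = sort(idx[seq_len(sizes[1])]),
       val = sort(idx[sizes[1] + seq_len(sizes[2])]),
       test = sort(idx[sizes[1] + sizes[2] + seq_len(sizes[3])]))
}

#' Generate a phantom dataset on disk
#'
#' Writes one NIfTI volume per subject plus plain-text split lists
#' (`train.txt`, `val.txt`, `test.txt`) with one file name per line.
#'
#' @param n number of subjects.
#' @param spec a [phantom_spec()].
#' @param dir output directory (created if needed).
#' @param split_ratios passed to [make_dataset()].
#' @return invisibly, the list of split file vectors.
#' @export
simulate_phantom_dataset <- function(n, spec = phantom_spec(), dir,
                                     split_ratios = c(384, 32, 34)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(n)
  for (i in seq_len(n)) {
    files[i] <- file.path(dir, sprintf("phantom_%04d.nii.gz", i))
    write_volume(generate_phantom(spec, i), files[i])
  }
  sp <- make_dataset(n, split_ratios, seed = spec$seed)
  out <- lapply(sp, function(ix) files[ix])
  for (nm in names(out))
    writeLines(out[[nm]], file.path(dir, paste0(nm, ".txt")))
  invisible(out)
}
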