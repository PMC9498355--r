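test_that("phantom generation is deterministic per (seed, subject)", {
  spec <- phantom_spec(size = 16, seed = 5)
  a <- generate_phantom(spec, 3)
  b <- generate_phantom(spec, 3)
  expect_identical(a$voxels, b$voxels)
  c <- generate_phantom(spec, 4)
  expect_gt(mean(abs(a$voxels - c$voxels)), 0)
})

test_that("phantom population varies but shares structure", {
  spec <- phantom_spec(size = 16, seed = 5)
  vols <- lapply(1:6, function(i) generate_phantom(spec, i)$voxels)
  maes <- combn(6, 2, function(ix) mean(abs(vols[[ix[1]]] - vols[[ix[2]]])))
  expect_true(all(maes > 0))
  avg <- Reduce(`+`, vols) / length(vols)
  # the mean image shows the shared anatomy: interior darker than shell
  S <- 16
  centre <- avg[S / 2, S / 2, c(3, S - 2), 1]   # lung territory both sides
  shell <- avg[S / 2, S / 2, S / 2, 1]          # mid-body (heart/tissue)
  expect_lt(mean(centre), shell)
})

test_that("lung interior is darker than the body shell", {
  spec <- phantom_spec(size = 32, seed = 1, blur_sigma = 0,
                       jitter_center = 0, jitter_semi = 0, jitter_intensity = 0)
  v <- generate_phantom(spec, 1)$voxels[, , , 1]
  S <- 32
  g <- (seq_len(S) - 0.5) / S * 2 - 1
  dd <- array(g, c(S, S, S))
  hh <- array(rep(g, each = S), c(S, S, S))
  ww <- array(rep(g, each = S * S), c(S, S, S))
  bs <- spec$body$semi
  lung_mask <- ((dd - spec$lung$center_d) / (0.6 * spec$lung$semi[1]))^2 +
    ((hh - spec$lung$center_h) / (0.6 * spec$lung$semi[2]))^2 +
    ((abs(ww) - spec$lung$center_w) / (0.6 * spec$lung$semi[3]))^2 <= 1
  body_mask <- (dd / bs[1])^2 + (hh / bs[2])^2 + (ww / bs[3])^2
  shell_mask <- body_mask <= 1 & body_mask >= 0.9
  expect_lt(mean(v[lung_mask]), mean(v[shell_mask]))
})

test_that("voxels above background match the analytic composed volume", {
  spec <- phantom_spec(size = 32, seed = 1, blur_sigma = 0,
                       jitter_center = 0, jitter_semi = 0, jitter_intensity = 0)
  v <- generate_phantom(spec, 1)$voxels
  n_above <- sum(v > spec$background + 1)
  S <- 32
  vox_per_unit <- (S / 2)^3
  body_frac <- 4 / 3 * pi * prod(spec$body$semi) / 8          # of [-1,1]^3
  bed_frac <- diff(spec$bed$d_range) / 2 * spec$bed$half_width
  expected <- (body_frac + bed_frac) * S^3
  expect_lt(abs(n_above - expected) / expected, 0.06)
})

test_that("dataset splits are disjoint, exhaustive and rounded by largest remainder", {
  sp <- make_dataset(450, seed = 1)
  expect_equal(lengths(sp), c(train = 384L, val = 32L, test = 34L))
  sp50 <- make_dataset(50, seed = 1)
  expect_equal(lengths(sp50), c(train = 43L, val = 3L, test = 4L))
  for (n in c(10, 37, 101)) {
    sp <- make_dataset(n, seed = n)
    all_ix <- sort(unname(unlist(sp)))
    expect_equal(all_ix, seq_len(n))
    expect_equal(anyDuplicated(unlist(sp)), 0L)
  }
  expect_error(make_dataset(2), "at least 3")
  expect_error(make_dataset(4, c(1, 0, 0)), "empty")
})

test_that("structures that cannot fit the grid are rejected", {
  expect_error(phantom_spec(body = list(center = c(0.5, 0, 0),
                                        semi = c(1.2, 0.9, 0.8),
                                        intensity = 135)),
               "fit")
  expect_error(phantom_spec(background = 400), "intensities")
})

test_that("phantom dataset writer produces volumes and split lists", {
  dir <- withr::local_tempdir()
  out <- simulate_phantom_dataset(6, phantom_spec(size = 8, seed = 2), dir,
                                  split_ratios = c(4, 1, 1))
  expect_equal(lengths(out), c(train = 4L, val = 1L, test = 1L))
  expect_true(all(file.exists(unlist(out))))
  expect_true(file.exists(file.path(dir, "train.txt")))
  v <- read_volume(out$train[1])
  expect_equal(dim(v$voxels)[1:3], c(8L, 8L, 8L))
})
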