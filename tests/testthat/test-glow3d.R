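# configurations exercised by the invertibility / Jacobian property tests
config_matrix <- list(
  list(shape = c(4, 4, 4), levels = 1, depth = 2, width = 8),
  list(shape = c(4, 4, 4), levels = 2, depth = 1, width = 6),
  list(shape = c(8, 8, 8), levels = 2, depth = 2, width = 8),
  list(shape = c(1, 1, 2), levels = 1, depth = 1, width = 4),
  list(shape = c(16, 16, 16), levels = 2, depth = 2, width = 8))

test_that("decode inverts encode (and vice versa) across the config matrix", {
  for (cm in config_matrix) {
    st <- tiny_flow(cm$shape, cm$levels, cm$depth, cm$width, seed = 7)
    x <- rand_volume(c(cm$shape, 1), seed = 13)
    enc <- flow_encode(st, x)
    xb <- flow_decode(st, enc$z)
    expect_lt(max(abs(xb$voxels - x)), 1e-4)
    expect_equal(xb$logdet, enc$logdet, tolerance = 1e-9)
    # encode(decode(z)) = z on a random latent
    z <- sample_latent(st, 1, seed = 17)
    x2 <- flow_decode(st, z)
    z2 <- flow_encode(st, x2$voxels)$z
    expect_lt(max(abs(flat_z(z2) - flat_z(z))), 1e-4)
    # decode is deterministic
    expect_identical(flow_decode(st, z)$voxels, x2$voxels)
  }
})

test_that("total latent size always equals the input size", {
  for (cm in config_matrix) {
    cfg <- flow_config(cm$shape, cm$levels, cm$depth, cm$width)
    zdims <- vapply(cfg$plan, function(L) prod(L$z_dim), numeric(1))
    expect_equal(sum(zdims), prod(cm$shape))
  }
})

test_that("analytic log-determinant matches the finite-difference Jacobian", {
  # composed flow on small inputs
  for (cm in config_matrix[c(1, 2, 4)]) {
    st <- tiny_flow(cm$shape, cm$levels, cm$depth, cm$width, seed = 3)
    x0 <- as.numeric(rand_volume(c(cm$shape, 1), seed = 5))
    f <- function(v) flat_z(flow_encode(st, array(v, c(cm$shape, 1)))$z)
    ld_fd <- fd_logdet(f, x0)
    ld_an <- flow_encode(st, array(x0, c(cm$shape, 1)))$logdet
    expect_lt(abs(ld_an - ld_fd) / max(abs(ld_fd), 1), 1e-3)
  }
})

test_that("each layer type has the correct log-determinant in isolation", {
  dims <- c(2L, 2L, 2L, 4L)
  x0 <- as.numeric(rand_volume(dims, seed = 8))
  with_test_seed(31, {
    logs <- rnorm(4, sd = 0.3); b <- rnorm(4)
    Wm <- qr.Q(qr(matrix(rnorm(16), 4, 4))) %*% diag(exp(rnorm(4, sd = 0.2)))
    weights <- list(c1_W = matrix(rnorm(27 * 2 * 6, sd = 0.1), 27 * 2, 6),
                    c1_b = rnorm(6),
                    c2_W = matrix(rnorm(36, sd = 0.1), 6, 6), c2_b = rnorm(6),
                    c3_W = matrix(rnorm(27 * 6 * 4, sd = 0.1), 27 * 6, 4),
                    c3_b = rnorm(4))
  })
  layers <- list(
    actnorm = function(v) flowct:::cpp_layer_actnorm(array(v, dims), dims, logs, b, FALSE),
    invconv = function(v) flowct:::cpp_layer_invconv(array(v, dims), dims, Wm, FALSE),
    coupling = function(v) flowct:::cpp_layer_coupling(array(v, dims), dims, weights,
                                                       1e-3, FALSE))
  for (nm in names(layers)) {
    fy <- function(v) as.numeric(layers[[nm]](v)$y)
    ld_fd <- fd_logdet(fy, x0)
    ld_an <- layers[[nm]](x0)$logdet
    expect_lt(abs(ld_an - ld_fd) / max(abs(ld_fd), 1), 1e-3)
    # every layer inverts exactly
    inv <- switch(nm,
      actnorm = flowct:::cpp_layer_actnorm(layers[[nm]](x0)$y, dims, logs, b, TRUE),
      invconv = flowct:::cpp_layer_invconv(layers[[nm]](x0)$y, dims, Wm, TRUE),
      coupling = flowct:::cpp_layer_coupling(layers[[nm]](x0)$y, dims, weights,
                                             1e-3, TRUE))
    expect_lt(max(abs(as.numeric(inv$y) - x0)), 1e-10)
  }
  # squeeze is a pure permutation (logdet 0, exact inverse, volume-preserving)
  sq <- flowct:::cpp_squeeze3(array(x0, dims), dims, FALSE)
  expect_equal(sort(as.numeric(sq)), sort(x0))
  expect_equal(as.numeric(flowct:::cpp_squeeze3(sq, dims, TRUE)), x0)
})

test_that("identity-initialized flow has the closed-form scale log-determinant", {
  cfg <- flow_config(c(4, 4, 4), levels = 2, depth = 2, width = 8)
  st <- flow_init(cfg, seed = 1, identity_init = TRUE)
  x <- rand_volume(c(4, 4, 4, 1), seed = 2)
  enc <- flow_encode(st, x)
  s0 <- coupling_scale(0)                      # sigmoid(2) + 1e-3
  # scaled elements: per level, per step, the transformed channel half
  n_scaled <- sum(vapply(cfg$plan, function(L)
    prod(L$dim[1:3]) * L$cb, numeric(1))) * cfg$depth
  expect_equal(enc$logdet, n_scaled * log(s0), tolerance = 1e-10)
  # closed-form likelihood of the zero volume under the standard-normal prior
  x0 <- array(0, c(4, 4, 4, 1))
  enc0 <- flow_encode(st, x0)
  n <- 64
  expect_equal(flow_log_likelihood(st, x0),
               -n / 2 * log(2 * pi) - sum(flat_z(enc0$z)^2) / 2 + enc0$logdet,
               tolerance = 1e-8)
})

test_that("coupling scale is bounded in (eps, 1 + eps] for any input", {
  expect_equal(coupling_scale(-2), 0.5 + 1e-3)
  expect_equal(coupling_scale(-1e6), 1e-3)
  expect_equal(coupling_scale(1e6), 1 + 1e-3)
  raw <- c(-Inf, -1e6, -50, 0, 50, 1e6, Inf)
  s <- coupling_scale(raw)
  expect_true(all(s > 0 & s <= 1 + 1e-3))
  expect_true(all(is.finite(log(s))))
})

test_that("batch NLL equals the mean of per-element likelihoods", {
  st <- tiny_flow(c(4, 4, 4), 1, 2, 8, seed = 9)
  xs <- lapply(1:3, function(i) rand_volume(c(4, 4, 4, 1), seed = i))
  nll <- flow_nll(st, xs)
  per <- vapply(xs, function(x) -flow_log_likelihood(st, x), numeric(1))
  expect_equal(as.numeric(nll), mean(per), tolerance = 1e-10)
  expect_equal(attr(nll, "per_sample"), per, tolerance = 1e-10)
  expect_equal(as.numeric(flow_nll(st, xs[1])), per[1], tolerance = 1e-10)
  expect_equal(as.numeric(flow_nll(st, xs[c(1, 1)])), per[1], tolerance = 1e-10)
  expect_equal(attr(nll, "bits_per_dim"), mean(per) * bpd_factor(4, 4, 4))
  expect_error(flow_nll(st, list()), "empty")
})

test_that("the flow density integrates to one on a two-pixel toy configuration", {
  st <- tiny_flow(c(1, 1, 2), 1, 1, 4, seed = 21, perturb = 0.1)
  grid <- seq(-9, 9, length.out = 241)
  h <- diff(grid[1:2])
  pts <- expand.grid(a = grid, b = grid)
  xs <- lapply(seq_len(nrow(pts)), function(i)
    array(c(pts$a[i], pts$b[i]), c(1, 1, 2, 1)))
  nll <- flow_nll(st, xs)
  integral <- sum(exp(-attr(nll, "per_sample"))) * h^2
  expect_lt(abs(integral - 1), 0.01)
})

test_that("temperature controls the latent spread and T = 0 is deterministic", {
  st <- tiny_flow(c(4, 4, 4), 1, 1, 6, seed = 30, perturb = 0.1)
  mu <- st$params$prior_L1_mu
  sdv <- exp(st$params$prior_L1_logs)
  z0a <- sample_latent(st, 0, seed = 1)
  z0b <- sample_latent(st, 0, seed = 999)     # no randomness left at T = 0
  expect_equal(flat_z(z0a), mu)
  expect_identical(flat_z(z0a), flat_z(z0b))
  s0 <- flow_sample(st, 0, seed = 5)
  expect_identical(s0$x$voxels, flow_decode(st, z0a)$voxels)

  draws <- sample_latent(st, 0.5, n = 2000, seed = 77)
  zm <- vapply(draws, function(z) flat_z(z), numeric(64))
  emp_sd <- apply(zm, 1, sd)
  se <- 0.5 * sdv / sqrt(2 * (2000 - 1))
  expect_true(all(abs(emp_sd - 0.5 * sdv) < 4 * se))
  # seeded sampling is reproducible
  again <- sample_latent(st, 0.5, n = 2000, seed = 77)
  expect_identical(flat_z(draws[[5]]), flat_z(again[[5]]))
})

test_that("checkpoints save and restore bit-exactly", {
  dir <- withr::local_tempdir()
  st <- tiny_flow(c(4, 4, 4), 2, 1, 6, seed = 2)
  p <- file.path(dir, "ckpt.rds")
  save_flow(st, p)
  st2 <- load_flow(p)
  expect_identical(st2$params, st$params)
  x <- rand_volume(c(4, 4, 4, 1), seed = 3)
  expect_identical(flow_log_likelihood(st, x), flow_log_likelihood(st2, x))
  expect_error(load_flow(file.path(dir, "nope.rds")), "not found")
})

test_that("shape mismatches are rejected with informative errors", {
  st <- tiny_flow(c(4, 4, 4), 1, 1, 6)
  expect_error(flow_encode(st, array(0, c(3, 4, 4, 1))), "match")
  z <- sample_latent(st, 1, seed = 1)
  z[[1]] <- z[[1]][, , , 1, drop = FALSE]
  expect_error(flow_decode(st, z), "expects")
  expect_error(flow_config(c(5, 5, 5), levels = 2), "squeeze|channel")
  expect_error(sample_latent(st, -0.1), ">= 0")
})
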