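# a small trained-ish flow shared within this file (perturbed, not trained:
# the objective/step algebra does not depend on training quality)
recon_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      st <- tiny_flow(c(8, 8, 8), 2, 2, 8, seed = 51, perturb = 0.03)
      truth <- generate_phantom(phantom_spec(size = 8, seed = 52), 1)
      cache <<- list(st = st, truth = truth,
                     ys = project_multi(truth, c("coronal", "sagittal")))
    }
    cache
  }
})

test_that("the bits-per-dimension factor matches its closed form", {
  expect_equal(bpd_factor(128, 128, 128), 1 / (log(2) * 128^3))
  expect_equal(bpd_factor(128, 128, 128), 6.879e-7, tolerance = 1e-3)
  expect_equal(bpd_factor(1, 1, 1), 1 / log(2))
  expect_equal(bpd_factor(32, 32, 32), 4.403e-5, tolerance = 1e-3)
  expect_error(bpd_factor(0, 1, 1), "positive")
})

test_that("the relaxation schedule reproduces its printed values", {
  std <- recon_settings("standard")
  ul <- recon_settings("ultralow", sigma2 = 100)
  expect_equal(recon_alpha(0, std), 0)
  expect_equal(recon_alpha(0, ul), 0)
  expect_equal(recon_alpha(1e9, ul), 0.9)
  expect_equal(recon_alpha(100, std), 0.2 * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(recon_alpha(100, std), 0.12642, tolerance = 1e-4)
  expect_true(all(diff(vapply(0:50, recon_alpha, numeric(1),
                              settings = ul)) > 0))
})

test_that("the stopping rule applies the residual threshold and budgets", {
  set <- recon_settings("standard", n_max = 1000, tau = 3)
  thr <- 3^2 * 2 * 128 * 128
  expect_equal(thr, 294912)
  expect_false(recon_stop(5, thr + 1, 2 * 128^2, set))
  expect_equal(recon_stop(5, thr, 2 * 128^2, set), "residual-met")   # boundary
  expect_equal(recon_stop(5, thr - 1, 2 * 128^2, set), "residual-met")
  expect_equal(recon_stop(1001, thr + 1, 2 * 128^2, set), "n_max")
  expect_equal(recon_stop(500, thr + 1, 2 * 128^2, set, latent_step = 1e-5),
               "latent-converged")
  expect_false(recon_stop(50, thr + 1, 2 * 128^2, set, latent_step = 1e-5))
})

test_that("settings validate their protocol constraints", {
  expect_error(recon_settings("ultralow", sigma2 = 0), "sigma2 > 0")
  s <- recon_settings("standard")
  expect_equal(s$alpha_amplitude, 0.2)
  expect_equal(recon_settings("ultralow")$alpha_amplitude, 0.9)
  expect_equal(s$tau, 3)
  expect_equal(s$n_max, 1000L)
  expect_equal(s$temperature, 0.5)
})

test_that("the objective is zero-cycle at the ground-truth code and quadratic in the residual", {
  fx <- recon_fixture()
  z_true <- flow_encode(fx$st, fx$truth)$z
  obj <- recon_objective(z_true, fx$ys, fx$st,
                         recon_settings("ultralow", sigma2 = 100))
  expect_lt(obj$cycle, 1e-18)

  # doubling every projection residual quadruples the cycle component
  z <- sample_latent(fx$st, 0.4, seed = 3)
  xdec <- flow_decode(fx$st, z)
  base <- project_multi(xdec, c("coronal", "sagittal"))
  delta <- lapply(fx$ys, function(p) p$pixels / 255)   # any fixed perturbation
  mk <- function(f) lapply(1:2, function(j)
    projection(base[[j]]$pixels + f * delta[[j]], view = base[[j]]$view,
               scale = "unit"))
  o1 <- recon_objective(z, mk(1), fx$st, recon_settings("standard"))
  o2 <- recon_objective(z, mk(2), fx$st, recon_settings("standard"))
  expect_equal(o2$cycle / o1$cycle, 4, tolerance = 1e-9)
})

test_that("the objective matches a naive recomposition from its pieces", {
  fx <- recon_fixture()
  set <- recon_settings("ultralow", sigma2 = 100)
  z <- sample_latent(fx$st, 0.6, seed = 9)
  obj <- recon_objective(z, fx$ys, fx$st, set)
  xdec <- flow_decode(fx$st, z)
  cyc <- 0
  for (p in fx$ys) {
    mine <- project(xdec, p$view)$pixels
    cyc <- cyc + sum((mine - p$pixels / 255)^2)
  }
  # likelihood via the independent encode route
  ll2 <- flow_log_likelihood(fx$st, xdec$voxels)
  tb2 <- bpd_factor(8, 8, 8)
  expect_equal(obj$cycle, cyc, tolerance = 1e-9)
  expect_equal(obj$loglik, ll2, tolerance = 1e-6)
  expect_equal(obj$E, cyc / (2 * 100) - tb2 * ll2, tolerance = 1e-6)
  expect_equal(obj$residual8, cyc * 255^2, tolerance = 1e-6)
})

test_that("one descent step follows the finite-difference gradient", {
  fx <- recon_fixture()
  set <- recon_settings("ultralow", sigma2 = 100)
  z <- sample_latent(fx$st, 0.5, seed = 4)
  stepped <- recon_step(z, n = 50, fx$ys, fx$st, set)
  a <- recon_alpha(50, set)
  for (k in 1:2) {
    for (idx in c(1, 7)) {
      h <- 1e-5
      zp <- z; zp[[k]][idx] <- zp[[k]][idx] + h
      zm <- z; zm[[k]][idx] <- zm[[k]][idx] - h
      g_fd <- (recon_objective(zp, fx$ys, fx$st, set)$E -
               recon_objective(zm, fx$ys, fx$st, set)$E) / (2 * h)
      expect_equal(stepped$z[[k]][idx], z[[k]][idx] - a * g_fd,
                   tolerance = 1e-5)
    }
  }
  # n = 0 gives alpha = 0, hence no movement
  still <- recon_step(z, n = 0, fx$ys, fx$st, set)
  expect_equal(flat_z(still$z), flat_z(z))
})

test_that("a zero-gradient point does not move under the standard protocol", {
  fx <- recon_fixture()
  z <- sample_latent(fx$st, 0.5, seed = 6)
  ys <- project_multi(flow_decode(fx$st, z), c("coronal", "sagittal"))
  stepped <- recon_step(z, n = 100, ys, fx$st, recon_settings("standard"))
  expect_lt(max(abs(flat_z(stepped$z) - flat_z(z))), 1e-10)
})

test_that("the ultra-low-dose path reduces to the standard path as sigma^2 -> 0", {
  fx <- recon_fixture()
  z <- sample_latent(fx$st, 0.5, seed = 8)
  std <- recon_settings("standard")
  tiny <- 1e-9
  lim <- recon_settings("ultralow", sigma2 = tiny,
                        alpha_amplitude = 0.2 * tiny)
  za <- recon_step(z, 40, fx$ys, fx$st, std)$z
  zb <- recon_step(z, 40, fx$ys, fx$st, lim)$z
  expect_lt(max(abs(flat_z(za) - flat_z(zb))) / max(abs(flat_z(za))), 1e-5)
})

test_that("reconstruction from a model sample's own projections is an immediate fixed point", {
  fx <- recon_fixture()
  s <- flow_sample(fx$st, 0.5, seed = 12)
  ys <- project_multi(s$x, c("coronal", "sagittal"))
  rec <- reconstruct(ys, fx$st, recon_settings("standard", seed = 1),
                     init_z = s$z)
  expect_equal(rec$stop_reason, "residual-met")
  expect_equal(rec$iterations, 0L)
  expect_equal(rec$volume$voxels, s$x$voxels, tolerance = 1e-12)
})

test_that("reconstruction is deterministic and returns a well-formed trace", {
  fx <- recon_fixture()
  set <- recon_settings("standard", seed = 31, n_max = 8)
  a <- reconstruct(fx$ys, fx$st, set)
  b <- reconstruct(fx$ys, fx$st, set)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$trace$residual, b$trace$residual)
  expect_s3_class(a$trace, "recon_trace")
  expect_true(all(c("n", "alpha", "residual", "loglik", "E") %in%
                    names(a$trace)))
  expect_lte(nrow(a$trace), set$n_max + 1)
  expect_equal(a$trace$alpha,
               vapply(a$trace$n, recon_alpha, numeric(1), settings = set))
  g <- glance(a)
  expect_equal(g$stop_reason, a$stop_reason)
  expect_error(reconstruct(list(), fx$st), "at least one")
  expect_error(reconstruct(rep(fx$ys[1], 2), fx$st), "duplicate")
})
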