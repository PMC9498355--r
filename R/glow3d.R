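#' Configure the 3D multi-scale normalizing flow
#'
#' The flow is a GLOW-style invertible network extended to three spatial
#' dimensions: per level a squeeze (halving each even spatial axis and
#' multiplying channels accordingly), then `depth` steps of
#' actnorm -> invertible 1x1x1 convolution -> affine coupling, then a channel
#' split that factors out half the channels as that level's latent variables
#' under a learned diagonal Gaussian. The top level keeps its whole tensor as
#' the final latent block (the "learn-top" prior).
#'
#' The affine coupling uses the stabilized scale
#' `sigmoid(raw + 2) + eps`, bounded in `(eps, 1 + eps]`, so no division by
#' zero can occur when inverting.
#'
#' @param shape integer length 3 or 4, the input volume shape
#'   (depth, height, width\[, channels\]).
#' @param levels number of multi-scale levels `K` (paper-scale model: 5).
#' @param depth flow steps per level (paper-scale: 8).
#' @param width hidden filter width of the coupling network (paper-scale: 512).
#' @param eps coupling-scale floor (default `1e-3`).
#' @param learn_top learn the mean/log-sd of the top-level prior.
#' @return an object of class `flow_config`.
#' @examples
#' cfg <- flow_config(c(16, 16, 16), levels = 2, depth = 2, width = 16)
#' @export
flow_config <- function(shape, levels = 3L, depth = 4L, width = 64L,
                        eps = 1e-3, learn_top = TRUE) {
  shape <- as.integer(shape)
  if (length(shape) == 3L) shape <- c(shape, 1L)
  stopifnot(length(shape) == 4L, all(shape >= 1L), depth >= 1L, eps > 0)
  cfg <- list(D = shape[1], H = shape[2], W = shape[3], C = shape[4],
              K = as.integer(levels), depth = as.integer(depth),
              width = as.integer(width), eps = eps,
              learn_top = isTRUE(learn_top))
  # validates squeezability / channel parity
  plan <- cpp_flow_plan(cfg$D, cfg$H, cfg$W, cfg$C, cfg$K)
  cfg$plan <- plan
  class(cfg) <- "flow_config"
  cfg
}

#' Paper-scale flow configuration
#'
#' Convenience constructor for the full-scale model: 128^3 input, 5 levels,
#' depth 8, filter width 512.
#' @return a [flow_config()].
#' @export
flow_config_full <- function() {
  flow_config(c(128L, 128L, 128L), levels = 5L, depth = 8L, width = 512L)
}

#' Initialize flow parameters
#'
#' Coupling networks start at the identity (final convolution zero-filled), so
#' an untrained flow is an exactly invertible near-identity map; 1x1x1
#' convolutions start as random rotations; actnorm starts neutral and is
#' normally re-initialized from data by [flow_actnorm_init()].
#'
#' @param config a [flow_config()].
#' @param seed RNG seed for the permutation/coupling initialization.
#' @param identity_init if `TRUE`, 1x1x1 convolutions also start as the
#'   identity, making the whole flow the identity map up to the coupling
#'   scale constant (useful for closed-form checks).
#' @return an object of class `flow3d` holding `config`, `params` and
#'   training metadata.
#' @export
flow_init <- function(config, seed = 1L, identity_init = FALSE) {
  stopifnot(inherits(config, "flow_config"))
  params <- with_seed(seed, {
    p <- list()
    for (k in seq_len(config$K)) {
      L <- config$plan[[k]]
      C <- L$dim[4]; Ca <- L$ca; Cb <- L$cb; wd <- config$width
      for (s in seq_len(config$depth)) {
        nm <- function(x) sprintf("L%dS%d_%s", k, s, x)
        p[[nm("an_logs")]] <- numeric(C)
        p[[nm("an_b")]] <- numeric(C)
        p[[nm("perm_W")]] <- if (identity_init) diag(C) else
          qr.Q(qr(matrix(rnorm(C * C), C, C)))
        p[[nm("c1_W")]] <- matrix(rnorm(27 * Ca * wd, sd = 0.05), 27 * Ca, wd)
        p[[nm("c1_b")]] <- numeric(wd)
        p[[nm("c2_W")]] <- matrix(rnorm(wd * wd, sd = 0.05), wd, wd)
        p[[nm("c2_b")]] <- numeric(wd)
        p[[nm("c3_W")]] <- matrix(0, 27 * wd, 2 * Cb)
        p[[nm("c3_b")]] <- numeric(2 * Cb)
      }
      m <- prod(L$z_dim)
      p[[sprintf("prior_L%d_mu", k)]] <- numeric(m)
      p[[sprintf("prior_L%d_logs", k)]] <- numeric(m)
    }
    p
  })
  structure(list(config = config, params = params,
                 meta = list(bits_stage = NA_integer_, epochs = 0L,
                             actnorm_initialized = FALSE)),
            class = "flow3d")
}

#' @export
print.flow3d <- function(x, ...) {
  cfg <- x$config
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf(
    "<flow3d %dx%dx%dx%d | K=%d depth=%d width=%d | %s parameters%s>\n",
    cfg$D, cfg$H, cfg$W, cfg$C, cfg$K, cfg$depth, cfg$width,
    format(np, big.mark = ","),
    if (is.na(x$meta$bits_stage)) "" else
      sprintf(" | trained through %d-bit stage", x$meta$bits_stage)))
  invisible(x)
}

cfg_list <- function(state) {
  cfg <- state$config
  list(D = cfg$D, H = cfg$H, W = cfg$W, C = cfg$C, K = cfg$K,
       depth = cfg$depth, eps = cfg$eps)
}

as_model_array <- function(state, x) {
  cfg <- state$config
  a <- as_unit_array(x)
  if (length(dim(a)) == 3L) dim(a) <- c(dim(a), 1L)
  expect <- c(cfg$D, cfg$H, cfg$W, cfg$C)
  if (!identical(dim(a), as.integer(expect)))
    stop_input("volume shape (%s) does not match the flow input (%s)",
               paste(dim(a), collapse = "x"), paste(expect, collapse = "x"))
  a
}

#' Encode a volume into its latent code
#'
#' Runs the invertible encoder `G^-1`, returning the per-level latent arrays
#' and the accumulated log-determinant `log|det df/dx|`, so that
#' `log p(x) = log p(z) + logdet`.
#'
#' @param state a [flow_init()] (possibly trained) model.
#' @param x a unit-scale [volume8()] or array matching the configured shape.
#' @return a list with `z` (class `latent_code`: one array per level) and
#'   `logdet` (scalar, nats).
#' @export
flow_encode <- function(state, x) {
  stopifnot(inherits(state, "flow3d"))
  out <- cpp_encode(as_model_array(state, x), state$params, cfg_list(state))
  class(out$z) <- "latent_code"
  out
}

#' Decode a latent code into a volume
#'
#' The exact inverse of [flow_encode()].
#'
#' @param state a `flow3d` model.
#' @param z a `latent_code` (list of per-level arrays).
#' @return a [volume8()] on the unit scale (values may slightly exceed
#'   `[0, 1]` for off-manifold codes; they are not clipped).
#' @export
flow_decode <- function(state, z) {
  stopifnot(inherits(state, "flow3d"))
  out <- cpp_decode(unclass(z), state$params, cfg_list(state))
  structure(list(voxels = out$x, scale = "unit", bits = 8L,
                 logdet = out$logdet), class = "volume8")
}

#' The stabilized affine-coupling scale
#'
#' `sigmoid(raw + 2) + eps`, bounded in `(eps, 1 + eps]`; the `+2` shift
#' biases an untrained coupling towards scale ~0.88, and the floor `eps`
#' prevents division by zero when inverting.
#'
#' @param raw numeric, the raw scale activation from the coupling network.
#' @param eps positive floor (default `1e-3`).
#' @return numeric of the same shape as `raw`.
#' @examples
#' coupling_scale(c(-Inf, -2, 0, Inf))
#' @export
coupling_scale <- function(raw, eps = 1e-3) {
  stopifnot(eps > 0)
  stats::plogis(raw + 2) + eps
}

#' Exact log-likelihood of a volume under the flow
#'
#' `log p(x) = log p(z) + log|det df/dx|` with `p(z)` the learned diagonal
#' Gaussian over all latent levels. Returned in nats for the whole volume;
#' divide by `log(2) * n_voxels` (see [bpd_factor()]) for bits per dimension.
#'
#' @inheritParams flow_encode
#' @return scalar log-likelihood in nats.
#' @export
flow_log_likelihood <- function(state, x) {
  enc <- flow_encode(state, x)
  prior_logp(state, enc$z) + enc$logdet
}

prior_logp <- function(state, z) {
  lp <- 0
  for (k in seq_len(state$config$K)) {
    mu <- state$params[[sprintf("prior_L%d_mu", k)]]
    logs <- state$params[[sprintf("prior_L%d_logs", k)]]
    e <- (as.numeric(z[[k]]) - mu) * exp(-logs)
    lp <- lp - sum(0.5 * log(2 * pi) + logs + 0.5 * e^2)
  }
  lp
}

#' Mean negative log-likelihood of a batch
#'
#' @param state a `flow3d` model.
#' @param xs a list of unit-scale volumes/arrays (or a single one).
#' @return scalar mean NLL in nats, with attribute `"bits_per_dim"`.
#' @export
flow_nll <- function(state, xs) {
  if (!is.list(xs) || inherits(xs, "volume8")) xs <- list(xs)
  if (length(xs) == 0) stop_input("empty batch")
  xb <- lapply(xs, function(x) as_model_array(state, x))
  out <- cpp_nll_grad(xb, state$params, cfg_list(state), FALSE)
  cfg <- state$config
  structure(out$nll,
            bits_per_dim = out$nll * bpd_factor(cfg$D, cfg$H, cfg$W),
            per_sample = out$per_sample)
}

#' Sample a volume from the flow at a given temperature
#'
#' Latents are drawn per level from `N(mu, T^2 * Sigma^2)` (the learned
#' prior with its standard deviation scaled by `T`) and decoded. `T = 0`
#' deterministically returns the decoded prior mean.
#'
#' @param state a `flow3d` model.
#' @param temperature sampling temperature `T >= 0`.
#' @param seed optional RNG seed.
#' @return a list with `x` (unit-scale [volume8()]) and `z` (`latent_code`).
#' @export
flow_sample <- function(state, temperature = 0.5, seed = NULL) {
  z <- sample_latent(state, temperature, seed = seed)
  list(x = flow_decode(state, z), z = z)
}

#' @rdname flow_sample
#' @param n number of latent draws (only for `sample_latent`).
#' @return `sample_latent()`: one `latent_code`, or a list of `n` of them.
#' @export
sample_latent <- function(state, temperature = 0.5, n = 1L, seed = NULL) {
  stopifnot(inherits(state, "flow3d"))
  if (temperature < 0) stop_input("temperature must be >= 0")
  body <- function() {
    draws <- lapply(seq_len(n), function(i) {
      z <- lapply(seq_len(state$config$K), function(k) {
        L <- state$config$plan[[k]]
        mu <- state$params[[sprintf("prior_L%d_mu", k)]]
        sdv <- exp(state$params[[sprintf("prior_L%d_logs", k)]])
        array(mu + temperature * sdv * rnorm(length(mu)), L$z_dim)
      })
      class(z) <- "latent_code"
      z
    })
    if (n == 1L) draws[[1]] else draws
  }
  if (!is.null(seed)) with_seed(seed, body()) else body()
}

#' Data-dependent actnorm initialization
#'
#' Sets every actnorm scale/bias so that its outputs have zero mean and unit
#' variance per channel on the given batch (the standard GLOW warm start).
#'
#' @param state a `flow3d` model.
#' @param xs list of unit-scale volumes/arrays.
#' @return the updated `flow3d` model.
#' @export
flow_actnorm_init <- function(state, xs) {
  if (!is.list(xs) || inherits(xs, "volume8")) xs <- list(xs)
  xb <- lapply(xs, function(x) as_model_array(state, x))
  state$params <- cpp_actnorm_init(xb, state$params, cfg_list(state))
  state$meta$actnorm_initialized <- TRUE
  state
}

#' Save / load a flow checkpoint
#'
#' The whole model state (configuration, every parameter array, training
#' metadata) is serialized to a single file and restored bit-exactly.
#'
#' @param state a `flow3d` model.
#' @param path checkpoint file path.
#' @return `load_flow()` returns the restored `flow3d`.
#' @export
save_flow <- function(state, path) {
  stopifnot(inherits(state, "flow3d"))
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_flow
#' @export
load_flow <- function(path) {
  if (!file.exists(path)) stop_input("checkpoint not found: %s", path)
  state <- readRDS(path)
  if (!inherits(state, "flow3d")) stop_input("%s is not a flow checkpoint", path)
  state
}

#' @export
glance.flow3d <- function(x, ...) {
  tibble::tibble(
    levels = x$config$K, depth = x$config$depth, width = x$config$width,
    n_params = sum(vapply(x$params, length, integer(1))),
    input_dim = prod(c(x$config$D, x$config$H, x$config$W, x$config$C)),
    bits_stage = x$meta$bits_stage, epochs_trained = x$meta$epochs,
    actnorm_initialized = x$meta$actnorm_initialized)
}

#' @export
tidy.flow3d <- function(x, ...) {
  tibble::tibble(
    parameter = names(x$params),
    length = vapply(x$params, length, integer(1)),
    l2_norm = vapply(x$params, function(p) sqrt(sum(p^2)), numeric(1)))
}
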