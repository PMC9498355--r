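#' Bits-per-dimension weighting factor
#'
#' `1 / (log(2) * D * H * W)`: the constant that converts a whole-volume
#' log-likelihood in nats to bits per voxel. The reconstruction objective
#' weights its log-likelihood term by this factor.
#'
#' @param d,h,w positive volume dimensions.
#' @return scalar weight.
#' @examples
#' bpd_factor(128, 128, 128)  # ~6.879e-7
#' @export
bpd_factor <- function(d, h, w) {
  if (any(c(d, h, w) <= 0)) stop_input("dimensions must be positive")
  1 / (log(2) * d * h * w)
}

#' Reconstruction settings
#'
#' Two dose protocols are supported. In the *standard* protocol the noise
#' variance tends to zero: the likelihood-prior objective degenerates to pure
#' projection matching, with the relaxation coefficient
#' `alpha(n) = 0.2 * (1 - exp(-rate * n))` applied to the gradient of
#' `0.5 * sum_j ||y_j - P_j G(z)||^2`. In the *ultra-low-dose* protocol the
#' objective keeps both terms,
#' `E = sum_j ||y_j - P_j G(z)||^2 / (2 sigma2) - Tb2 * log p(G(z))`,
#' with `alpha(n) = 0.9 * (1 - exp(-rate * n))`.
#'
#' Intensity-scale convention: the optimizer works on the model's unit
#' `[0, 1]` scale, with `sigma2` entering the cycle term as the printed
#' dimensionless weight; the stopping residual is evaluated in 8-bit gray
#' levels, where the threshold `tau^2 * N * H2D * W2D` (RMS of `tau` gray
#' levels per pixel) is meaningful. See the methods vignette for why this is
#' the only self-consistent reading of the printed relaxation amplitudes.
#'
#' @param protocol `"standard"` or `"ultralow"`.
#' @param sigma2 noise variance on the 8-bit scale (ultra-low-dose: 100).
#' @param alpha_amplitude relaxation amplitude; defaults to 0.2 (standard,
#'   after the variance cancels) or 0.9 (ultralow).
#' @param alpha_rate relaxation ramp rate (default 0.01).
#' @param n_max maximum iterations (default 1000).
#' @param tau residual stopping tolerance in gray levels per pixel (default 3).
#' @param temperature initial-guess sampling temperature (default 0.5).
#' @param latent_tol latent-step convergence tolerance: the descent is
#'   declared converged when one step moves the latent code by less than
#'   `latent_tol` times its total displacement from the initial guess (a step
#'   that small no longer changes where the trajectory has gone).
#' @param latent_min_iter iterations before the latent-step criterion may
#'   fire (the alpha ramp makes early steps vanishingly small).
#' @param seed seed for the initial latent sample.
#' @return an object of class `recon_settings`.
#' @export
recon_settings <- function(protocol = c("standard", "ultralow"),
                           sigma2 = 100, alpha_amplitude = NULL,
                           alpha_rate = 0.01, n_max = 1000L, tau = 3,
                           temperature = 0.5, latent_tol = 1e-4,
                           latent_min_iter = 100L, seed = 1L) {
  protocol <- match.arg(protocol)
  if (protocol == "ultralow" && sigma2 <= 0)
    stop_input("the ultra-low-dose protocol needs sigma2 > 0 (standard uses the limit form)")
  stopifnot(n_max >= 1, tau >= 0, temperature >= 0, alpha_rate > 0)
  structure(list(
    protocol = protocol, sigma2 = sigma2,
    alpha_amplitude = alpha_amplitude %||% if (protocol == "standard") 0.2 else 0.9,
    alpha_rate = alpha_rate, n_max = as.integer(n_max), tau = tau,
    temperature = temperature, latent_tol = latent_tol,
    latent_min_iter = as.integer(latent_min_iter), seed = as.integer(seed)),
    class = "recon_settings")
}

#' Relaxation coefficient schedule
#'
#' `alpha(n) = A * (1 - exp(-rate * n))` with `A = 0.2 * sigma2` for the
#' standard protocol (the variance later cancels against the cycle term's
#' `1/sigma2`, leaving an effective amplitude of 0.2) and `A = 0.9` for the
#' ultra-low-dose protocol.
#'
#' @param n iteration number (>= 0).
#' @param settings a [recon_settings()]; for the standard protocol the
#'   returned value is the effective (post-cancellation) coefficient.
#' @return scalar step size.
#' @export
recon_alpha <- function(n, settings) {
  stopifnot(n >= 0)
  settings$alpha_amplitude * (1 - exp(-settings$alpha_rate * n))
}

#' Stopping rule for the latent descent
#'
#' Stops when the iteration budget is exhausted, when the summed squared
#' projection residual (8-bit scale) falls to
#' `tau^2 * sum_j n_pixels_j` (an RMS of `tau` gray levels per pixel across
#' all views; boundary counts as met), or when the relative latent step
#' drops below `latent_tol`.
#'
#' @param n current iteration.
#' @param residual summed squared residual over all views, 8-bit scale.
#' @param n_pixels total pixel count across views.
#' @param settings a [recon_settings()].
#' @param latent_step optional relative latent step size (step norm divided
#'   by the trajectory's total displacement from its initial guess).
#' @return `FALSE` to continue, or a character stop reason.
#' @export
recon_stop <- function(n, residual, n_pixels, settings, latent_step = Inf) {
  if (residual <= settings$tau^2 * n_pixels) return("residual-met")
  if (n > settings$n_max) return("n_max")
  if (n >= settings$latent_min_iter && latent_step < settings$latent_tol)
    return("latent-converged")
  FALSE
}

# normalize input projections: list of projection objects -> unit matrices +
# view codes + pixel counts
prep_projections <- function(projections, state) {
  if (inherits(projections, "projection")) projections <- list(projections)
  if (length(projections) == 0) stop_input("need at least one projection")
  views <- vapply(projections, function(p) p$view, character(1))
  if (anyDuplicated(views)) stop_input("duplicate views among the projections")
  cfg <- state$config
  ys <- lapply(projections, function(p) {
    px <- if (p$scale == "eightbit") p$pixels / 255 else p$pixels
    matrix(px[, , 1], dim(px)[1], dim(px)[2])
  })
  codes <- ifelse(views == "coronal", 1L, 2L)
  npix <- sum(vapply(ys, length, numeric(1)))
  list(ys = ys, codes = as.integer(codes), npix = npix, views = views)
}

#' Evaluate the reconstruction objective at a latent code
#'
#' Returns the objective `E`, its cycle-consistency component (both on the
#' unit scale, as optimized) and the volume log-likelihood, plus the 8-bit
#' summed squared residual used by the stopping rule.
#'
#' @param z a `latent_code`.
#' @param projections a [projection()] or list of them (distinct views).
#' @param state a trained `flow3d`.
#' @param settings a [recon_settings()].
#' @return list with `E`, `cycle`, `loglik`, `residual8`.
#' @export
recon_objective <- function(z, projections, state, settings) {
  pp <- prep_projections(projections, state)
  w <- recon_weights(state, settings)
  out <- cpp_recon_eg(unclass(z), pp$ys, pp$codes, state$params,
                      cfg_list(state), w$cycle_w, w$prior_w, FALSE)
  list(E = out$E, cycle = out$cycle, loglik = out$loglik,
       residual8 = out$cycle * 255^2)
}

recon_weights <- function(state, settings) {
  cfg <- state$config
  if (settings$protocol == "standard") {
    # sigma^2 -> 0 limit: prior term vanishes, alpha's sigma^2 cancels the
    # cycle term's 1/sigma^2; optimize 0.5*||r||^2 directly.
    list(cycle_w = 1, prior_w = 0)
  } else {
    list(cycle_w = 1 / settings$sigma2,
         prior_w = bpd_factor(cfg$D, cfg$H, cfg$W))
  }
}

#' One gradient-descent step in latent space
#'
#' `z' = z - alpha(n) * grad_z E(z)`; gradients flow through the frozen
#' decoder and the projection operator only.
#'
#' @inheritParams recon_objective
#' @param n iteration number (alpha ramps up from 0).
#' @return list with `z` (updated `latent_code`), `E`, `cycle`, `loglik`,
#'   `residual8`, `step_rel` (relative latent step).
#' @export
recon_step <- function(z, n, projections, state, settings) {
  pp <- prep_projections(projections, state)
  w <- recon_weights(state, settings)
  out <- cpp_recon_eg(unclass(z), pp$ys, pp$codes, state$params,
                      cfg_list(state), w$cycle_w, w$prior_w, TRUE)
  a <- recon_alpha(n, settings)
  znew <- z
  num <- 0; den <- 0
  for (k in seq_along(z)) {
    stepk <- a * out$grad[[k]]
    znew[[k]] <- z[[k]] - stepk
    num <- num + sum(stepk^2); den <- den + sum(z[[k]]^2)
  }
  class(znew) <- "latent_code"
  list(z = znew, E = out$E, cycle = out$cycle, loglik = out$loglik,
       residual8 = out$cycle * 255^2,
       step_rel = sqrt(num) / max(sqrt(den), 1e-12))
}

#' MAP reconstruction of a volume from projections
#'
#' Runs the full latent-space descent: a temperature-`T` prior sample as the
#' initial guess, then iterative gradient steps on the protocol's objective
#' until the stopping rule fires.
#'
#' @param projections a [projection()] or list of them (distinct views),
#'   8-bit or unit scale.
#' @param state a trained `flow3d`.
#' @param settings a [recon_settings()].
#' @param init_z optional explicit initial `latent_code` (overrides the
#'   temperature sample).
#' @param trace_every record every `k`-th iteration in the trace (stop and
#'   start are always recorded).
#' @return an object of class `flow_recon`: list with `volume` (unit-scale
#'   [volume8()]), `z`, `trace` (tibble: n, alpha, residual, loglik, E),
#'   `stop_reason`, `iterations`.
#' @export
reconstruct <- function(projections, state, settings = recon_settings(),
                        init_z = NULL, trace_every = 1L) {
  stopifnot(inherits(state, "flow3d"))
  pp <- prep_projections(projections, state)
  w <- recon_weights(state, settings)
  cl <- cfg_list(state)
  z <- init_z %||% sample_latent(state, settings$temperature,
                                 seed = settings$seed)
  z0 <- z
  rows <- list()
  stop_reason <- "n_max"
  step_rel <- Inf
  n <- 0L
  repeat {
    out <- cpp_recon_eg(unclass(z), pp$ys, pp$codes, state$params, cl,
                        w$cycle_w, w$prior_w, TRUE)
    residual8 <- out$cycle * 255^2
    a <- recon_alpha(n, settings)
    sr <- recon_stop(n, residual8, pp$npix, settings, step_rel)
    if (n <= settings$n_max && (n %% trace_every == 0L || !isFALSE(sr)))
      rows[[length(rows) + 1]] <- tibble::tibble(
        n = n, alpha = a, residual = residual8,
        cycle = out$cycle, loglik = out$loglik, E = out$E)
    if (!isFALSE(sr)) { stop_reason <- sr; break }
    num <- 0; den <- 0
    for (k in seq_along(z)) {
      stepk <- a * out$grad[[k]]
      z[[k]] <- z[[k]] - stepk
      num <- num + sum(stepk^2)
      den <- den + sum((z[[k]] - z0[[k]])^2)
    }
    step_rel <- sqrt(num) / max(sqrt(den), 1e-12)
    n <- n + 1L
  }
  class(z) <- "latent_code"
  vol <- flow_decode(state, z)
  if (!all(is.finite(vol$voxels))) stop_input("reconstruction produced non-finite voxels")
  trace <- do.call(rbind, rows)
  class(trace) <- c("recon_trace", class(trace))
  structure(list(volume = vol, z = z, trace = trace,
                 stop_reason = stop_reason, iterations = n,
                 settings = settings, views = pp$views),
            class = "flow_recon")
}

#' @export
print.flow_recon <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  cat(sprintf(
    "<flow_recon %s | views %s | %d iterations, stopped: %s | residual %.1f (8-bit SSE), RMS %.2f gray>\n",
    x$settings$protocol, paste(x$views, collapse = "+"), x$iterations,
    x$stop_reason, last$residual,
    sqrt(last$residual / (length(x$views) * prod(dim(x$volume$voxels)[2:3])))))
  invisible(x)
}

#' @export
glance.flow_recon <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  tibble::tibble(protocol = x$settings$protocol,
                 n_views = length(x$views),
                 iterations = x$iterations, stop_reason = x$stop_reason,
                 residual = last$residual, loglik = last$loglik, E = last$E)
}

#' @export
tidy.flow_recon <- function(x, ...) tibble::as_tibble(x$trace)
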