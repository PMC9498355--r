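# shared fixtures: all built in code at test time

# a small flow whose couplings/permutations are genuinely non-trivial
tiny_flow <- function(shape = c(4, 4, 4), levels = 1, depth = 2, width = 8,
                      seed = 42, perturb = 0.05, identity_init = FALSE) {
  cfg <- flow_config(shape, levels = levels, depth = depth, width = width)
  st <- flow_init(cfg, seed = seed, identity_init = identity_init)
  if (perturb > 0) {
    st$params <- with_test_seed(seed + 1, lapply(st$params, function(p)
      p + stats::rnorm(length(p), sd = perturb)))
  }
  st
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

rand_volume <- function(shape, seed = 1) {
  with_test_seed(seed, array(stats::runif(prod(shape)), shape))
}

# central-difference Jacobian of a vector-valued function
fd_jacobian <- function(f, x0, h = 1e-5) {
  n <- length(x0)
  y0 <- f(x0)
  J <- matrix(0, length(y0), n)
  for (i in seq_len(n)) {
    xp <- x0; xm <- x0
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    J[, i] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

fd_logdet <- function(f, x0, h = 1e-5) {
  as.numeric(determinant(fd_jacobian(f, x0, h), logarithm = TRUE)$modulus)
}

flat_z <- function(z) unlist(lapply(unclass(z), as.numeric), use.names = FALSE)

# small phantom population for quick training runs
quick_phantoms <- function(n, size = 8, seed = 3) {
  spec <- phantom_spec(size = size, seed = seed)
  lapply(seq_len(n), function(i) generate_phantom(spec, i))
}
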