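#' Progressive training schedule
#'
#' Training proceeds over stages of increasing bit depth; within each stage
#' the flow minimizes the mean negative log-likelihood of the stage's
#' quantized (and uniformly dequantized) volumes with Adam, warming the
#' learning rate up linearly before holding it at the steady rate. The
#' default stage list `(2, 96), (3, 324), (4, 24), (8, 144)` and steady rate
#' `1e-4` are the full-scale settings; [desk_schedule()] provides a small
#' configuration suitable for CPU-scale experiments.
#'
#' @param stages list of `c(bits, epochs)` pairs with strictly increasing bits.
#' @param lr steady-state learning rate.
#' @param warmup_steps linear warmup length in optimizer steps.
#' @param batch_size minibatch size.
#' @param patience epochs without validation improvement before a stage stops
#'   early.
#' @param clip global gradient-norm clip.
#' @param seed RNG seed for shuffling and dequantization noise.
#' @return an object of class `progressive_schedule`.
#' @export
progressive_schedule <- function(stages = list(c(2, 96), c(3, 324),
                                               c(4, 24), c(8, 144)),
                                 lr = 1e-4, warmup_steps = 10L, batch_size = 4L,
                                 patience = 10L, clip = 100, seed = 1L) {
  bits <- vapply(stages, `[`, numeric(1), 1)
  eps <- vapply(stages, `[`, numeric(1), 2)
  if (any(diff(bits) <= 0)) stop_input("stage bits must be strictly increasing")
  if (any(bits < 1 | bits > 8)) stop_input("stage bits must lie in 1..8")
  if (any(eps < 0)) stop_input("stage epochs must be >= 0")
  structure(list(stages = lapply(stages, function(s) c(bits = s[1], epochs = s[2])),
                 lr = lr, warmup_steps = as.integer(warmup_steps),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience), clip = clip,
                 seed = as.integer(seed)),
            class = "progressive_schedule")
}

#' @rdname progressive_schedule
#' @details `desk_schedule()` uses stages `(2,2), (3,2), (4,2), (8,4)`, a
#'   steady rate of `1e-3` and batch size 4: with a few hundred optimizer
#'   steps in total, the full-scale steady rate would barely move the
#'   parameters away from initialization.
#' @export
desk_schedule <- function(seed = 1L, lr = 1e-3,
                          stages = list(c(2, 2), c(3, 2), c(4, 2), c(8, 4))) {
  progressive_schedule(stages = stages, lr = lr, warmup_steps = 20L,
                       batch_size = 4L, patience = 10L, seed = seed)
}

#' Early-stopping monitor over a validation-NLL history
#'
#' Signals a checkpoint save at every new minimum and a stop once no
#' improvement has been seen for `patience` consecutive epochs.
#'
#' @param history numeric vector of per-epoch validation NLL values.
#' @param patience non-improving epochs tolerated before stopping.
#' @return list with `action` (`"continue"` or `"stop-and-save"`),
#'   `best_epoch` (index of the minimum; earliest on ties), and `save`
#'   (logical vector: was each epoch a new minimum).
#' @examples
#' early_stop_monitor(c(5, 4, 4.5, 4.6, 4.7), patience = 3)
#' @export
early_stop_monitor <- function(history, patience = 10L) {
  if (length(history) == 0) stop_input("empty validation history")
  best <- cummin(history)
  save <- history < c(Inf, best[-length(best)])  # strict new minima
  best_epoch <- which.min(history)
  stale <- length(history) - max(which(save))
  list(action = if (stale >= patience) "stop-and-save" else "continue",
       best_epoch = best_epoch, save = save)
}

# quantize + dequantize a list of eightbit volumes into model-space arrays
stage_batch <- function(vols, bits, dequantize) {
  lapply(vols, function(v) {
    q <- quantize_bits(v, bits)
    to_model_space(q, dequantize = dequantize)$voxels
  })
}

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, opt, lr, clip,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  scale <- if (is.finite(clip) && gnorm > clip) clip / gnorm else 1
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]] * scale
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

#' Train the flow for one bit-depth stage
#'
#' Minimizes the batch NLL of `bits`-bit quantized training volumes,
#' monitoring the (dequantization-free) validation NLL each epoch; the
#' checkpoint with the best validation NLL seen during the stage is returned.
#' If the loss ever turns non-finite the stage aborts with the last finite
#' checkpoint.
#'
#' @param state a `flow3d` model (actnorm-initialized or not; initialization
#'   is performed automatically on the first batch of the first stage).
#' @param train,val lists of eightbit [volume8()] volumes.
#' @param bits stage bit depth (1..8).
#' @param epochs number of passes over the training set (0 = no-op).
#' @param schedule a [progressive_schedule()] supplying the optimizer
#'   settings.
#' @param opt optional Adam state carried across stages (reset by default:
#'   the objective changes when the bit depth changes).
#' @param step_offset global step count already taken (for warmup).
#' @param verbose print one line per epoch.
#' @return list with `state` (best checkpoint), `log` (tibble: epoch, bits,
#'   train_nll, val_nll, bits_per_dim, lr) and `opt`.
#' @export
train_stage <- function(state, train, val, bits, epochs, schedule,
                        opt = NULL, step_offset = 0L, verbose = FALSE) {
  stopifnot(inherits(state, "flow3d"), inherits(schedule, "progressive_schedule"))
  cfg <- state$config
  cl <- cfg_list(state)
  tb2 <- bpd_factor(cfg$D, cfg$H, cfg$W)
  log_rows <- list()
  if (epochs == 0)
    return(list(state = state, log = tibble::tibble(), opt = opt))

  with_seed(derive_seed(schedule$seed, 101L + bits), {
    if (!state$meta$actnorm_initialized) {
      xb <- stage_batch(train[seq_len(min(length(train), 16L))], bits, TRUE)
      state$params <- cpp_actnorm_init(xb, state$params, cl)
      state$meta$actnorm_initialized <- TRUE
    }
    if (is.null(opt)) opt <- adam_new(state$params)
    val_arrays <- stage_batch(val, bits, FALSE)
    best <- list(state = state, nll = Inf)
    hist <- numeric(0)
    step <- as.integer(step_offset)

    for (ep in seq_len(epochs)) {
      idx <- sample.int(length(train))
      tr_nll <- 0; nb <- 0
      for (b0 in seq(1, length(idx), by = schedule$batch_size)) {
        take <- idx[b0:min(b0 + schedule$batch_size - 1, length(idx))]
        xb <- stage_batch(train[take], bits, TRUE)
        res <- tryCatch(cpp_nll_grad(xb, state$params, cl, TRUE),
                        error = function(e) e)
        if (inherits(res, "error") || !is.finite(res$nll)) {
          warning(sprintf("non-finite loss at %d-bit stage, epoch %d; keeping last finite checkpoint",
                          bits, ep), call. = FALSE)
          st <- if (is.finite(best$nll)) best$state else state
          st$meta$bits_stage <- as.integer(bits)
          return(list(state = st,
                      log = do.call(rbind, log_rows) %||% tibble::tibble(),
                      opt = opt))
        }
        step <- step + 1L
        lr_t <- schedule$lr * min(1, step / max(1, schedule$warmup_steps))
        upd <- adam_step(state$params, res$grad, opt, lr_t, schedule$clip)
        state$params <- upd$params; opt <- upd$opt
        tr_nll <- tr_nll + res$nll; nb <- nb + 1
      }
      vres <- cpp_nll_grad(val_arrays, state$params, cl, FALSE)
      hist <- c(hist, vres$nll)
      mon <- early_stop_monitor(hist, schedule$patience)
      if (vres$nll <= best$nll) best <- list(state = state, nll = vres$nll)
      log_rows[[ep]] <- tibble::tibble(
        epoch = ep, bits = bits, train_nll = tr_nll / nb, val_nll = vres$nll,
        bits_per_dim = vres$nll * tb2, lr = lr_t, step = step)
      if (verbose)
        message(sprintf("[%d bits] epoch %d: train %.1f, val %.1f (%.3f bpd)",
                        bits, ep, tr_nll / nb, vres$nll, vres$nll * tb2))
      if (mon$action == "stop-and-save") break
    }
    st <- best$state
    st$meta$bits_stage <- as.integer(bits)
    st$meta$epochs <- st$meta$epochs + length(hist)
    list(state = st, log = do.call(rbind, log_rows), opt = opt)
  })
}

#' Run a full progressive schedule
#'
#' Executes the stages in order, each warm-starting from the previous stage's
#' best checkpoint; the optimizer state is reset between stages because the
#' objective (the data's bit depth) changes.
#'
#' @param state a freshly initialized `flow3d`.
#' @param schedule a [progressive_schedule()].
#' @param data list with `train` and `val`: lists of eightbit [volume8()].
#' @param verbose print per-epoch progress.
#' @return list with `state` (final model) and `log` (row-bound stage logs,
#'   class `training_log`).
#' @export
run_schedule <- function(state, schedule, data, verbose = FALSE) {
  stopifnot(is.list(data$train), is.list(data$val))
  logs <- list()
  step_offset <- 0L
  for (stg in schedule$stages) {
    res <- train_stage(state, data$train, data$val, bits = stg["bits"],
                       epochs = stg["epochs"], schedule = schedule,
                       step_offset = step_offset, verbose = verbose)
    state <- res$state
    if (nrow(res$log %||% tibble::tibble())) {
      logs[[length(logs) + 1]] <- res$log
      step_offset <- max(res$log$step)
    }
  }
  log <- if (length(logs)) do.call(rbind, logs) else tibble::tibble()
  class(log) <- c("training_log", class(log))
  list(state = state, log = log)
}
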