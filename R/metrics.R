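#' Volume agreement metrics
#'
#' All metrics operate on the unit `[0, 1]` intensity scale ([volume8()]
#' inputs are converted automatically).
#'
#' * `ssim3()` — mean structural similarity over all fully-interior cubic
#'   windows (default 7^3), uniform weighting, constants `K1 = 0.01`,
#'   `K2 = 0.03`, data range 1.
#' * `psnr()` — `10 * log10(1 / MSE)` in dB; identical volumes return the
#'   cap (default 100 dB) as a finite sentinel for +Inf.
#' * `mae()` — mean absolute error.
#' * `nrmse()` — RMSE divided by the intensity range of the reference
#'   (undefined, hence an error, for a constant reference).
#'
#' @param x,ref volumes to compare; `ref` is the ground truth.
#' @param window SSIM window edge length (voxels).
#' @param K1,K2,data_range SSIM stabilization constants and dynamic range.
#' @param cap finite value reported for infinite PSNR.
#' @return scalar metric value.
#' @examples
#' a <- array(runif(8^3), c(8, 8, 8))
#' ssim3(a, a); psnr(a, a); mae(a, a); nrmse(a, a)
#' @export
ssim3 <- function(x, ref, window = 7L, K1 = 0.01, K2 = 0.03, data_range = 1) {
  ax <- metric_array(x); ar <- metric_array(ref)
  check_same_shape(ax, ar)
  cpp_ssim3(ax, ar, dim(ax), as.integer(window), K1, K2, data_range)
}

#' @rdname ssim3
#' @export
psnr <- function(x, ref, cap = 100) {
  ax <- metric_array(x); ar <- metric_array(ref)
  check_same_shape(ax, ar)
  mse <- mean((ax - ar)^2)
  if (mse == 0) return(cap)
  min(10 * log10(1 / mse), cap)
}

#' @rdname ssim3
#' @export
mae <- function(x, ref) {
  ax <- metric_array(x); ar <- metric_array(ref)
  check_same_shape(ax, ar)
  mean(abs(ax - ar))
}

#' @rdname ssim3
#' @export
nrmse <- function(x, ref) {
  ax <- metric_array(x); ar <- metric_array(ref)
  check_same_shape(ax, ar)
  rng <- diff(range(ar))
  if (rng == 0) stop_input("NRMSE is undefined for a constant reference volume")
  sqrt(mean((ax - ar)^2)) / rng
}

metric_array <- function(x) {
  a <- as_unit_array(x)
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) dim(a) <- dim(a)[1:3]
  a
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop_input("volume shapes differ: %s vs %s",
               paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"))
}

#' Evaluate reconstruction quality over a dataset
#'
#' Computes SSIM, PSNR, MAE and NRMSE per prediction/truth pair plus the
#' dataset mean and population variance of each metric (the layout used for
#' cohort reporting tables).
#'
#' @param pred,truth lists of volumes of equal length (or a single pair).
#' @param case optional case labels.
#' @return an object of class `recon_eval`; `tidy()` gives the per-case
#'   tibble, `glance()` the mean/variance summary row.
#' @export
evaluate_dataset <- function(pred, truth, case = NULL) {
  if (!is.list(pred) || inherits(pred, "volume8")) pred <- list(pred)
  if (!is.list(truth) || inherits(truth, "volume8")) truth <- list(truth)
  if (length(pred) != length(truth) || length(pred) == 0)
    stop_input("pred and truth must be non-empty lists of equal length")
  case <- case %||% seq_along(pred)
  per <- tibble::tibble(
    case = case,
    ssim = mapply(ssim3, pred, truth),
    psnr = mapply(psnr, pred, truth),
    mae = mapply(mae, pred, truth),
    nrmse = mapply(nrmse, pred, truth))
  popvar <- function(v) mean((v - mean(v))^2)
  summary <- tibble::tibble(
    metric = c("ssim", "psnr", "mae", "nrmse"),
    mean = unname(vapply(per[, -1], mean, numeric(1))),
    variance = unname(vapply(per[, -1], popvar, numeric(1))))
  structure(list(per_case = per, summary = summary), class = "recon_eval")
}

#' @export
print.recon_eval <- function(x, ...) {
  cat(sprintf("<recon_eval: %d cases>\n", nrow(x$per_case)))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-6s %10.5f (var %.6g)\n", s$metric[i], s$mean[i], s$variance[i]))
  invisible(x)
}

#' @export
tidy.recon_eval <- function(x, ...) x$per_case

#' @export
glance.recon_eval <- function(x, ...) {
  s <- x$summary
  out <- c(as.list(s$mean), as.list(s$variance))
  names(out) <- c(s$metric, paste0(s$metric, "_var"))
  tibble::as_tibble(out)
}

#' Write an evaluation report
#'
#' Serializes a [evaluate_dataset()] result as JSON plus an aligned
#' plain-text table.
#'
#' @param eval a `recon_eval`.
#' @param path output path (`.json`; a `.txt` twin is written alongside).
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(eval, path) {
  stopifnot(inherits(eval, "recon_eval"))
  jsonlite::write_json(list(per_case = eval$per_case, summary = eval$summary),
                       path, digits = NA, auto_unbox = TRUE)
  txt <- sub("\\.json$", ".txt", path)
  if (identical(txt, path)) txt <- paste0(path, ".txt")
  con <- file(txt, "w")
  on.exit(close(con))
  writeLines(capture.output(print(eval)), con)
  invisible(path)
}

#' @importFrom utils capture.output
NULL
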