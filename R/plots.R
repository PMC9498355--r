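#' Plot a reconstruction trace
#'
#' Shows the 8-bit squared projection residual and the objective value
#' against the iteration number on log-scaled axes.
#'
#' @param object a `recon_trace` tibble (from `reconstruct()$trace` or
#'   `tidy()` of a `flow_recon`).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.recon_trace <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$residual)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "summed squared residual (8-bit)",
                  title = "Latent-descent cycle residual") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.flow_recon <- function(object, ...) autoplot(object$trace, ...)

#' Plot a progressive-training log
#'
#' Validation NLL (in bits per dimension) per epoch, coloured by the stage
#' bit depth.
#'
#' @param object a `training_log` tibble from [run_schedule()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.training_log <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$global_epoch <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$global_epoch,
                                   y = .data$bits_per_dim,
                                   colour = factor(.data$bits))) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "epoch (cumulative)", y = "validation bits/dim",
                  colour = "stage bits",
                  title = "Progressive training") +
    ggplot2::theme_minimal()
}

#' Plot central orthogonal slices of a volume
#'
#' @param vol a [volume8()] or array.
#' @param ... unused.
#' @return a ggplot object with axial/coronal/sagittal central slices.
#' @export
plot_volume_slices <- function(vol, ...) {
  a <- metric_array(vol)
  d <- dim(a)
  mid <- floor(d / 2) + 1
  slice_df <- function(m, lab) {
    tibble::tibble(row = as.vector(row(m)), col = as.vector(col(m)),
                   value = as.vector(m), slice = lab)
  }
  df <- rbind(
    slice_df(a[mid[1], , ], "axial (fixed depth)"),
    slice_df(a[, mid[2], ], "coronal-like (fixed height)"),
    slice_df(a[, , mid[3]], "sagittal-like (fixed width)"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~slice) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "intensity")
}

#' @importFrom ggplot2 .data
NULL
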