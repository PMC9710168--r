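raster_df <- function(m) {
  tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  )
}

#' @rdname make_psf
#' @param object a `psf_kernel`.
#' @param ... unused.
#' @method autoplot psf_kernel
#' @export
autoplot.psf_kernel <- function(object, ...) {
  k <- if (is.list(object$kernel)) object$kernel[[1]] else object$kernel
  df <- raster_df(log10(k + 1e-12))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log10 weight") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s PSF", object$config$mode),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname render_opl
#' @param object an `opl_image`.
#' @param which `"opl"` or `"labels"`.
#' @param ... unused.
#' @method autoplot opl_image
#' @export
autoplot.opl_image <- function(object, which = c("opl", "labels"), ...) {
  which <- match.arg(which)
  m <- object[[which]]
  df <- raster_df(m)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  if (which == "opl") {
    p + ggplot2::scale_fill_viridis_c(name = "OPL (a.u.)")
  } else {
    p + ggplot2::scale_fill_viridis_c(name = "cell id")
  }
}

#' @rdname init_scene
#' @param x a `scene_frame`.
#' @param ... unused.
#' @method tidy scene_frame
#' @export
tidy.scene_frame <- function(x, ...) x$cells
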