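# Plotting helpers (ggplot2).

#' Plot the contours of one axial slice
#'
#' @param object a `structure_set`.
#' @param z slice position (mm); default the slice nearest the isocenter.
#' @param ... unused.
#' @method autoplot structure_set
#' @export
autoplot.structure_set <- function(object, z = NULL, ...) {
  if (is.null(z)) {
    zs <- unique(object$z)
    z <- zs[which.min(abs(zs - isocenter(object)[3]))]
  }
  rows <- object[abs(object$z - z) < 1e-6, ]
  df <- purrr::map_dfr(seq_len(nrow(rows)), function(i) {
    p <- rows$poly[[i]]
    tibble::tibble(structure = rows$structure[i], ring = i,
                   x = c(p[, 1], p[1, 1]), y = c(p[, 2], p[1, 2]))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$structure,
                                   group = .data$ring)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x [mm]", y = "y [mm]", colour = NULL,
                  title = sprintf("z = %g mm", z)) +
    ggplot2::theme_minimal()
}

#' Plot an axial dose slice with optional contours
#'
#' @param dose a `dose_grid`.
#' @param ss optional `structure_set` whose contours are overlaid.
#' @param z slice position (mm); default the central slice.
#' @export
plot_dose_slice <- function(dose, ss = NULL, z = NULL) {
  if (is.null(z)) z <- dose$z[ceiling(length(dose$z) / 2)]
  s <- which.min(abs(dose$z - z))
  df <- expand.grid(x = dose$x, y = dose$y)
  df$dose_Gy <- as.vector(dose$dose[, , s])
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$dose_Gy)) +
    ggplot2::scale_fill_viridis_c(name = "Dose [Gy]") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x [mm]", y = "y [mm]") +
    ggplot2::theme_minimal()
  if (!is.null(ss)) {
    rows <- ss[abs(ss$z - dose$z[s]) < 1e-6, ]
    cdf <- purrr::map_dfr(seq_len(nrow(rows)), function(i) {
      pl <- rows$poly[[i]]
      tibble::tibble(structure = rows$structure[i], ring = i,
                     x = c(pl[, 1], pl[1, 1]), y = c(pl[, 2], pl[1, 2]))
    })
    p <- p + ggplot2::geom_path(
      data = cdf, ggplot2::aes(group = .data$ring, colour = .data$structure),
      linewidth = 0.4) +
      ggplot2::scale_colour_brewer(palette = "Set2", name = NULL)
  }
  p
}
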