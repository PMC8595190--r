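#' Shape factor versus diameter ratio, both placements
#'
#' Plots `S(kappa)` for the concentric (closed form) and wall-touching
#' (interpolated numerical) placements on one panel; the wall-touching
#' curve lies below the concentric one everywhere, i.e. a wall-touching
#' suture obstructs less at equal diameter.
#'
#' @param kappa Grid of diameter ratios in `[0, 1)`.
#' @return A ggplot object.
#' @export
plot_shape_factor_curve <- function(kappa = seq(0, 0.96, by = 0.02)) {
  dat <- dplyr::bind_rows(
    tabulate_shape_factor("concentric", kappa),
    tabulate_shape_factor("wall_touching", kappa)
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$kappa, y = .data$shape_factor,
                                    linetype = .data$placement)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(kappa == D[s] / D[i]),
                  y = "shape factor S",
                  linetype = "suture placement") +
    ggplot2::theme_minimal()
}

#' Plot an IOP-increase sweep
#'
#' One curve of `p_c2 - p_c1` against `p_c1` per suture diameter (for
#' [iop_increase_sweep()] output) or against the implant diameter per
#' starting pressure (for [implant_diameter_sweep()] output).
#'
#' @param object An `iop_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot iop_sweep
#' @export
autoplot.iop_sweep <- function(object, ...) {
  if ("D_i" %in% names(object) && length(unique(object$D_i)) > 1) {
    p <- ggplot2::ggplot(object,
                         ggplot2::aes(x = .data$D_i, y = .data$delta,
                                      colour = factor(.data$p_c1),
                                      linetype = factor(.data$D_s))) +
      ggplot2::geom_line() +
      ggplot2::labs(x = expression(D[i] ~ "(µm)"),
                    colour = expression(p[c]^{(1)} ~ "(mm Hg)"),
                    linetype = expression(D[s] ~ "(µm)"))
  } else {
    p <- ggplot2::ggplot(object,
                         ggplot2::aes(x = .data$p_c1, y = .data$delta,
                                      colour = factor(.data$D_s))) +
      ggplot2::geom_line() +
      ggplot2::labs(x = expression(p[c]^{(1)} ~ "(mm Hg)"),
                    colour = expression(D[s] ~ "(µm)"))
  }
  p + ggplot2::labs(y = expression(p[c]^{(2)} - p[c]^{(1)} ~ "(mm Hg)")) +
    ggplot2::theme_minimal()
}

#' Plot the scaled axial velocity field of a Poisson solve
#'
#' @param object A `shape_factor_result` computed with `keep_field = TRUE`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot shape_factor_result
#' @export
autoplot.shape_factor_result <- function(object, ...) {
  if (is.null(object$field))
    abort("Re-run `poisson_shape_factor()` with `keep_field = TRUE` to plot the field.",
          class = "iopflow_usage_error")
  ggplot2::ggplot(object$field, ggplot2::aes(x = .data$x, y = .data$y,
                                             fill = .data$v)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "scaled axial velocity") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
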