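#' Tidy a steady outflow state
#'
#' @param x A `surgery_state`.
#' @param ... Unused.
#' @return A one-row tibble with `p_c`, `p_b` (mm Hg), `Q_i`, `Q_tm`
#'   (uL/min), `regime` and `boundary`.
#' @method tidy surgery_state
#' @export
tidy.surgery_state <- function(x, ...) {
  tibble(p_c = x$p_c, p_b = x$p_b, Q_i = x$Q_i, Q_tm = x$Q_tm,
         regime = x$regime, boundary = x$boundary)
}

#' @rdname tidy.surgery_state
#' @method glance surgery_state
#' @export
glance.surgery_state <- function(x, ...) {
  tibble(p_c = x$p_c, regime = x$regime,
         implant_share = x$Q_i / (x$Q_i + x$Q_tm))
}

#' Tidy a suture-correction solution
#'
#' @param x A `correction_solution`.
#' @param ... Unused.
#' @return A one-row tibble with the measured and predicted/target IOP, the
#'   suture diameter and placement, the occluded shape factor, the
#'   resistance ratio and the regime case.
#' @method tidy correction_solution
#' @export
tidy.correction_solution <- function(x, ...) {
  tibble(mode = x$mode, p_c1 = x$p_c1, p_c2 = x$p_c2,
         delta = x$p_c2 - x$p_c1, D_s = x$D_s, kappa = x$kappa,
         placement = x$placement, shape_factor_2 = x$shape_factor_2,
         resistance_ratio = x$resistance_ratio, case = x$case,
         upper_bound = x$upper_bound)
}

#' @rdname tidy.correction_solution
#' @method glance correction_solution
#' @export
glance.correction_solution <- function(x, ...) {
  tibble(p_c2 = x$p_c2, delta = x$p_c2 - x$p_c1, D_s = x$D_s, case = x$case)
}

#' Tidy a numerical shape-factor result
#'
#' @param x A `shape_factor_result`.
#' @param ... Unused.
#' @return A one-row tibble with `shape_factor`, `kappa`, `placement`,
#'   `method`, `solver`, `resolution` and `error_estimate`.
#' @method tidy shape_factor_result
#' @export
tidy.shape_factor_result <- function(x, ...) {
  tibble(shape_factor = x$value, kappa = x$kappa, placement = x$placement,
         method = x$method, solver = x$solver, resolution = x$resolution,
         error_estimate = x$error_estimate)
}
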