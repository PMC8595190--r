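#' Flow regime case for a pair of IOP measurements
#'
#' The suture-correction formulas come in three variants depending on
#' whether the IOP before (`p_c1`) and after (`p_c2`) the suture insertion
#' lie above the episcleral venous pressure `p_ev` (the trabecular pathway
#' carries flow) or at/below it (the pathway is shut). An IOP exactly at
#' `p_ev` counts as shut.
#'
#' @param p_c1,p_c2 IOP before / after the suture, mm Hg.
#' @param p_ev Episcleral venous pressure, mm Hg.
#' @return `"both_open"`, `"mixed"` or `"both_closed"`.
#' @export
correction_case <- function(p_c1, p_c2, p_ev) {
  if (p_c1 > p_ev) "both_open" else if (p_c2 > p_ev) "mixed" else "both_closed"
}

# pi * D_i^4 / (128 L_v mu Q_0) in 1/Pa
chi_factor <- function(eye, geometry) {
  pi * um_to_m(geometry$inner_diameter)^4 /
    (128 * mm_to_m(geometry$length) * eye$mu * .MPAS_PAS * ulmin_to_m3s(eye$Q_0))
}

check_correction_pressures <- function(eye, p_c1, p_c2 = NULL) {
  if (p_c1 < eye$p_r || p_c1 >= eye$p_g)
    abort("`p_c1` must satisfy p_r <= p_c1 < p_g.", class = "iopflow_infeasible_error")
  if (!is.null(p_c2)) {
    if (p_c2 < p_c1)
      abort("A suture cannot lower the IOP: `p_c2` must be >= `p_c1`.",
            class = "iopflow_infeasible_error")
    if (p_c2 >= eye$p_g)
      abort("`p_c2` must stay below the pre-surgery IOP `p_g`.",
            class = "iopflow_infeasible_error")
  }
  invisible(TRUE)
}

#' Resistance ratio required to raise the IOP to a target
#'
#' Eliminating the unknown bleb pressure through the constant bleb
#' resistance assumption, the occluded tube must multiply the open tube's
#' hydraulic resistance by `S_2 (1 - D_s/D_i)^(-4)`, a function only of
#' measured pressures and known parameters. With
#' `chi = pi D_i^4 / (128 L_v mu Q_0)` the three regime cases give:
#'
#' * both IOPs above `p_ev`:
#'   `1 + chi (p_c2 - p_c1) (p_g - p_r)(p_g - p_ev) /
#'    ((p_g - p_c1)(p_g - p_c2))`
#' * `p_c1` at or below, `p_c2` above:
#'   `1 + chi ((p_c2 (p_g - p_ev - p_r) + p_ev p_r) / (p_g - p_c2) - p_c1)`
#' * both at or below `p_ev`: `1 + chi (p_c2 - p_c1)`
#'
#' The large-`p_g` approximation (`approximate = TRUE`) uses the last
#' expression in every case; it needs neither `p_r` nor `p_ev`, which are
#' not measured clinically, and converges to the exact both-open formula as
#' `p_g` grows.
#'
#' @param eye An [eye_parameters()].
#' @param geometry An [implant_geometry()].
#' @param p_c1 Measured IOP after implantation, mm Hg.
#' @param p_c2 Target IOP after the suture, mm Hg (`p_c1 <= p_c2 < p_g`).
#' @param approximate Use the large-`p_g` shortcut instead of the exact
#'   case formula.
#' @return The required resistance ratio (`>= 1`, equal to 1 when
#'   `p_c2 == p_c1`).
#' @examples
#' required_resistance_ratio(eye_parameters(), implant_geometry(100, 11),
#'                           p_c1 = 5, p_c2 = 7)
#' @export
required_resistance_ratio <- function(eye, geometry, p_c1, p_c2,
                                      approximate = FALSE) {
  stopifnot(inherits(eye, "eye_parameters"), inherits(geometry, "implant_geometry"))
  check_correction_pressures(eye, p_c1, p_c2)
  chi <- chi_factor(eye, geometry)
  p1 <- mmhg_to_pa(p_c1); p2 <- mmhg_to_pa(p_c2)
  p_g <- mmhg_to_pa(eye$p_g); p_ev <- mmhg_to_pa(eye$p_ev)
  p_r <- mmhg_to_pa(eye$p_r)
  case <- correction_case(p_c1, p_c2, eye$p_ev)
  if (approximate || case == "both_closed") {
    1 + chi * (p2 - p1)
  } else if (case == "both_open") {
    1 + chi * (p2 - p1) * (p_g - p_r) * (p_g - p_ev) /
      ((p_g - p1) * (p_g - p2))
  } else {
    1 + chi * ((p2 * (p_g - p_ev - p_r) + p_ev * p_r) / (p_g - p2) - p1)
  }
}

#' Suture diameter achieving a target IOP (inverse solver)
#'
#' Composes [required_resistance_ratio()] with
#' [invert_resistance_ratio()] for the requested suture placement. The
#' returned diameter is an upper bound: the calculation assumes the
#' conditions of minimum hydraulic resistance, and effects such as bleb
#' cicatrization between interventions or bending of the suture inside the
#' tube only add resistance, so a thinner suture may suffice in practice.
#'
#' @inheritParams required_resistance_ratio
#' @param placement Suture placement, `"wall_touching"` (a dense suture
#'   settles on the tube wall) or `"concentric"`.
#' @return A `correction_solution` with the suture diameter `D_s` (um),
#'   `kappa`, the occluded shape factor, the resistance ratio, the regime
#'   case and an `upper_bound` flag.
#' @examples
#' suture_diameter_for_target(eye_parameters(), implant_geometry(100, 11),
#'                            p_c1 = 5, p_c2 = 7, placement = "concentric")
#' @export
suture_diameter_for_target <- function(eye, geometry, p_c1, p_c2,
                                       placement = c("wall_touching", "concentric"),
                                       approximate = FALSE) {
  placement <- match.arg(placement)
  ratio <- required_resistance_ratio(eye, geometry, p_c1, p_c2, approximate)
  kappa <- invert_resistance_ratio(ratio, placement)
  s2 <- if (kappa == 0) 1 else shape_factor(kappa, placement)
  new_correction_solution(
    mode = "inverse", eye = eye, geometry = geometry,
    p_c1 = p_c1, p_c2 = p_c2,
    D_s = kappa * geometry$inner_diameter, kappa = kappa,
    shape_factor_2 = s2, resistance_ratio = ratio,
    case = correction_case(p_c1, p_c2, eye$p_ev),
    placement = placement, approximate = approximate
  )
}

#' IOP reached after inserting a given suture (forward solver)
#'
#' Evaluates the case-appropriate closed-form prediction for the IOP after
#' partially occluding the tube with a suture of diameter `D_s`, given the
#' measured IOP `p_c1` after implantation. When `p_c1` is at or below
#' `p_ev` the both-closed expression
#' `p_c2 = p_c1 + 128 L_v mu Q_0 (D_i^4 S_2 - D_h^4) / (pi D_i^4 D_h^4)`
#' is tried first; if its result rises above `p_ev` the assumption is
#' inconsistent and the mixed-case expression is used instead. Exactly one
#' case is self-consistent by monotonicity of the network equations.
#'
#' @inheritParams required_resistance_ratio
#' @param suture A [suture_config()].
#' @return A `correction_solution` with the predicted `p_c2` (mm Hg).
#' @examples
#' predicted_iop_after_suture(eye_parameters(), implant_geometry(100, 11),
#'                            p_c1 = 5, suture = suture_config(35, "concentric"))
#' @export
predicted_iop_after_suture <- function(eye, geometry, p_c1, suture) {
  stopifnot(inherits(eye, "eye_parameters"), inherits(geometry, "implant_geometry"),
            inherits(suture, "suture_config"))
  check_correction_pressures(eye, p_c1)
  ts <- tube_section(geometry, suture)
  s2 <- ts$S
  di <- um_to_m(geometry$inner_diameter)
  dh <- um_to_m(ts$Dh)
  A <- pi * di^4 * dh^4
  B <- 128 * mm_to_m(geometry$length) * eye$mu * .MPAS_PAS * ulmin_to_m3s(eye$Q_0)
  G <- dh^4 - di^4 * s2          # <= 0: occlusion adds resistance
  p1 <- mmhg_to_pa(p_c1)
  p_g <- mmhg_to_pa(eye$p_g); p_ev <- mmhg_to_pa(eye$p_ev)
  p_r <- mmhg_to_pa(eye$p_r)

  if (p_c1 > eye$p_ev) {
    case <- "both_open"
    p2 <- (A * p1 * (p_g - p_ev) * (p_g - p_r) + B * p_g * (p1 - p_g) * G) /
      (A * (p_g - p_ev) * (p_g - p_r) + B * (p1 - p_g) * G)
  } else {
    p2 <- p1 + B * (di^4 * s2 - dh^4) / A
    case <- "both_closed"
    if (pa_to_mmhg(p2) > eye$p_ev) {
      case <- "mixed"
      p2 <- (A * (p_ev * p_r - p1 * p_g) + B * p_g * G) /
        (A * (p_ev + p_r - p1 - p_g) + B * G)
    }
  }
  new_correction_solution(
    mode = "forward", eye = eye, geometry = geometry,
    p_c1 = p_c1, p_c2 = pa_to_mmhg(p2),
    D_s = suture$diameter, kappa = ts$kappa,
    shape_factor_2 = s2,
    resistance_ratio = s2 * (1 - ts$kappa)^(-4),
    case = case, placement = suture$placement, approximate = FALSE
  )
}

new_correction_solution <- function(mode, eye, geometry, p_c1, p_c2, D_s,
                                    kappa, shape_factor_2, resistance_ratio,
                                    case, placement, approximate) {
  regime_before <- if (p_c1 > eye$p_ev) "trabecular_open" else "trabecular_closed"
  regime_after <- if (p_c2 > eye$p_ev) "trabecular_open" else "trabecular_closed"
  structure(
    list(mode = mode, p_c1 = p_c1, p_c2 = p_c2, D_s = D_s, kappa = kappa,
         shape_factor_2 = shape_factor_2, resistance_ratio = resistance_ratio,
         case = case, regime_before = regime_before, regime_after = regime_after,
         placement = placement, approximate = approximate,
         upper_bound = TRUE, eye = eye, geometry = geometry),
    class = "correction_solution"
  )
}

#' @export
print.correction_solution <- function(x, ...) {
  cat(sprintf("<correction_solution> (%s, %s case)\n", x$mode, x$case))
  cat(sprintf("  p_c1 = %.4g -> p_c2 = %.4g mm Hg (increase %.4g)\n",
              x$p_c1, x$p_c2, x$p_c2 - x$p_c1))
  cat(sprintf("  D_s = %.4g um (%s, kappa = %.4g), S_2 = %.4g, resistance ratio = %.4g\n",
              x$D_s, x$placement, x$kappa, x$shape_factor_2, x$resistance_ratio))
  if (x$mode == "inverse")
    cat("  D_s is an upper bound: bleb cicatrization or suture bending only add resistance.\n")
  invisible(x)
}

#' Sweep of the IOP increase over suture diameters and starting pressures
#'
#' Evaluates the forward prediction over the Cartesian grid
#' `p_c1 x D_s`. In the both-closed region the increase
#' `p_c2 - p_c1` is independent of `p_c1`; above `p_ev` it decreases with
#' `p_c1` because the bleb resistance inferred from a higher `p_c1` is
#' larger and the implant carries less flow.
#'
#' @inheritParams required_resistance_ratio
#' @param placement Suture placement.
#' @param p_c1 Vector of post-implant IOPs, mm Hg.
#' @param D_s Vector of suture diameters, um.
#' @return A tibble of class `iop_sweep` with columns `p_c1`, `D_s`,
#'   `p_c2`, `delta` (`p_c2 - p_c1`) and `case` (`"error"` with `NA`
#'   pressures where a cell is infeasible).
#' @examples
#' iop_increase_sweep(eye_parameters(), implant_geometry(100, 11),
#'                    placement = "concentric", p_c1 = c(4, 8, 14),
#'                    D_s = c(20, 35, 50))
#' @export
iop_increase_sweep <- function(eye, geometry,
                               placement = c("wall_touching", "concentric"),
                               p_c1, D_s) {
  placement <- match.arg(placement)
  grid <- expand.grid(p_c1 = p_c1, D_s = D_s, KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    tryCatch({
      sol <- predicted_iop_after_suture(
        eye, geometry, grid$p_c1[i],
        suture_config(grid$D_s[i], placement))
      tibble(p_c1 = grid$p_c1[i], D_s = grid$D_s[i], p_c2 = sol$p_c2,
             delta = sol$p_c2 - sol$p_c1, case = sol$case)
    }, error = function(e) {
      tibble(p_c1 = grid$p_c1[i], D_s = grid$D_s[i], p_c2 = NA_real_,
             delta = NA_real_, case = "error")
    })
  })
  out <- dplyr::bind_rows(res)
  attr(out, "placement") <- placement
  attr(out, "inner_diameter") <- geometry$inner_diameter
  class(out) <- c("iop_sweep", class(out))
  out
}

#' Sweep of the IOP increase over implant diameters
#'
#' Forward prediction at fixed suture diameter while the implant inner
#' diameter varies, showing how thin sutures only matter in narrow-bore
#' tubes.
#'
#' @inheritParams iop_increase_sweep
#' @param inner_diameter Vector of implant inner diameters, um.
#' @param D_s Vector of suture diameters, um (cells with `D_s >=
#'   inner_diameter` are marked as errors).
#' @param length Tube length, mm.
#' @return A tibble of class `iop_sweep` with columns `D_i`, `D_s`,
#'   `p_c1`, `p_c2`, `delta` and `case`.
#' @export
implant_diameter_sweep <- function(eye, inner_diameter, D_s, p_c1,
                                   placement = c("concentric", "wall_touching"),
                                   length = 11) {
  placement <- match.arg(placement)
  grid <- expand.grid(D_i = inner_diameter, D_s = D_s, p_c1 = p_c1,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    tryCatch({
      sol <- predicted_iop_after_suture(
        eye, implant_geometry(grid$D_i[i], length), grid$p_c1[i],
        suture_config(grid$D_s[i], placement))
      tibble(D_i = grid$D_i[i], D_s = grid$D_s[i], p_c1 = grid$p_c1[i],
             p_c2 = sol$p_c2, delta = sol$p_c2 - sol$p_c1, case = sol$case)
    }, error = function(e) {
      tibble(D_i = grid$D_i[i], D_s = grid$D_s[i], p_c1 = grid$p_c1[i],
             p_c2 = NA_real_, delta = NA_real_, case = "error")
    })
  })
  out <- dplyr::bind_rows(res)
  attr(out, "placement") <- placement
  class(out) <- c("iop_sweep", class(out))
  out
}
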