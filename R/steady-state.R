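#' Steady-state IOP after implantation of a drainage device
#'
#' Solves the lumped outflow network for one steady state. The ciliary body
#' injects `Q_0` (inflow minus the uveoscleral fraction) into the anterior
#' chamber, which drains through two parallel pathways: the trabecular
#' meshwork / Schlemm's canal branch, a linear resistance
#' `(p_g - p_ev) / Q_0` calibrated from the pre-surgery state and carrying
#' flow only while the IOP exceeds the episcleral venous pressure `p_ev`;
#' and the implant branch, the tube's Hagen-Poiseuille resistance in series
#' with the filtration bleb held at pressure `bleb_pressure`.
#'
#' The trabecular-open balance gives
#' `p_c = (pi D_h^4 p_b (p_g - p_ev) + 128 S L_v p_g Q_0 mu) /
#'        (pi D_h^4 (p_g - p_ev) + 128 S L_v Q_0 mu)`;
#' it is accepted when the resulting `p_c > p_ev`, otherwise the trabecular
#' branch is shut and `p_c = p_b + 128 S L_v mu Q_0 / (pi D_h^4)` with the
#' implant carrying all of `Q_0`. The two branches agree at the boundary
#' `p_c = p_ev`, which is assigned to the closed regime.
#'
#' @param eye An [eye_parameters()].
#' @param geometry An [implant_geometry()].
#' @param suture Optional [suture_config()].
#' @param bleb_pressure Bleb pressure `p_b`, mm Hg (non-negative and below
#'   `p_g`).
#' @return An object of class `surgery_state` with fields `p_c`, `p_b`
#'   (mm Hg), `Q_i`, `Q_tm` (uL/min), `regime`
#'   (`"trabecular_open"` or `"trabecular_closed"`) and `boundary`
#'   (`TRUE` when the state sits exactly at `p_c = p_ev`).
#' @examples
#' post_implant_state(eye_parameters(), implant_geometry(305, 11),
#'                    bleb_pressure = 8)
#' @export
post_implant_state <- function(eye, geometry, suture = NULL, bleb_pressure) {
  stopifnot(inherits(eye, "eye_parameters"), inherits(geometry, "implant_geometry"),
            is.numeric(bleb_pressure), length(bleb_pressure) == 1L)
  if (bleb_pressure < 0)
    abort("`bleb_pressure` must be non-negative.", class = "iopflow_domain_error")
  if (bleb_pressure >= eye$p_g)
    abort("`bleb_pressure` at or above the pre-surgery IOP implies backflow through the implant.",
          class = "iopflow_infeasible_error")
  ts <- tube_section(geometry, suture)
  # SI working variables
  a <- pi * um_to_m(ts$Dh)^4
  b <- 128 * ts$S * mm_to_m(geometry$length) * eye$mu * .MPAS_PAS *
    ulmin_to_m3s(eye$Q_0)
  p_g <- mmhg_to_pa(eye$p_g); p_ev <- mmhg_to_pa(eye$p_ev)
  p_b <- mmhg_to_pa(bleb_pressure)
  Q0 <- ulmin_to_m3s(eye$Q_0)

  p_open <- (a * p_b * (p_g - p_ev) + b * p_g) / (a * (p_g - p_ev) + b)
  if (p_open > p_ev) {
    q_i <- a * Q0 * (p_g - p_b) / (a * (p_g - p_ev) + b)
    st <- list(p_c = p_open, Q_i = q_i, Q_tm = Q0 - q_i,
               regime = "trabecular_open", boundary = FALSE)
  } else {
    p_closed <- p_b + b / a
    boundary <- p_closed > p_ev   # neither assumption strictly consistent
    st <- list(p_c = if (boundary) p_ev else p_closed,
               Q_i = Q0, Q_tm = 0,
               regime = "trabecular_closed", boundary = boundary)
  }
  if (st$Q_i < 0)
    abort("Negative implant flow: `bleb_pressure` is above the achievable IOP.",
          class = "iopflow_infeasible_error")
  structure(
    list(p_c = pa_to_mmhg(st$p_c), p_b = bleb_pressure,
         Q_i = m3s_to_ulmin(st$Q_i), Q_tm = m3s_to_ulmin(st$Q_tm),
         regime = st$regime, boundary = st$boundary),
    class = "surgery_state"
  )
}

#' @export
print.surgery_state <- function(x, ...) {
  cat(sprintf("<surgery_state> p_c = %.4g mm Hg (%s%s)\n", x$p_c, x$regime,
              if (x$boundary) ", boundary" else ""))
  cat(sprintf("  p_b = %.4g mm Hg; Q_i = %.4g, Q_tm = %.4g uL/min\n",
              x$p_b, x$Q_i, x$Q_tm))
  invisible(x)
}

#' Implant dimensions achieving a target IOP
#'
#' Inverts the steady-state balance for the tube dimensions: given the
#' target IOP, the bleb pressure and the shape factor, return the hydraulic
#' diameter at fixed length, or the length at fixed hydraulic diameter.
#' Targets above `p_ev` use the trabecular-open balance; targets at or
#' below `p_ev` the trabecular-closed one. Both satisfy the round trip
#' through [post_implant_state()].
#'
#' @inheritParams post_implant_state
#' @param length Tube length `L_v`, mm (for [design_hydraulic_diameter()]).
#' @param hydraulic_diameter Hydraulic diameter `D_h`, um (for
#'   [design_length()]).
#' @param shape_factor Shape factor of the planned cross-section (1 for an
#'   open tube).
#' @param target_p_c Target IOP, mm Hg; must satisfy
#'   `bleb_pressure < target_p_c < p_g` (open regime) or
#'   `target_p_c > bleb_pressure` (closed regime).
#' @param bleb_pressure Bleb pressure `p_b`, mm Hg.
#' @return `design_hydraulic_diameter()`: `D_h` in um;
#'   `design_length()`: `L_v` in mm.
#' @examples
#' eye <- eye_parameters()
#' dh <- design_hydraulic_diameter(eye, length = 11, target_p_c = 12,
#'                                 bleb_pressure = 8)
#' post_implant_state(eye, implant_geometry(dh, 11), bleb_pressure = 8)$p_c
#' @export
design_hydraulic_diameter <- function(eye, length, shape_factor = 1,
                                      target_p_c, bleb_pressure) {
  check_design_target(eye, target_p_c, bleb_pressure)
  b1 <- 128 * shape_factor * mm_to_m(length) * ulmin_to_m3s(eye$Q_0) *
    eye$mu * .MPAS_PAS
  p_c <- mmhg_to_pa(target_p_c); p_b <- mmhg_to_pa(bleb_pressure)
  p_g <- mmhg_to_pa(eye$p_g); p_ev <- mmhg_to_pa(eye$p_ev)
  dh <- if (target_p_c > eye$p_ev) {
    (b1 * (p_g - p_c) / (pi * (p_c - p_b) * (p_g - p_ev)))^0.25
  } else {
    (b1 / (pi * (p_c - p_b)))^0.25
  }
  dh / .UM_M
}

#' @rdname design_hydraulic_diameter
#' @export
design_length <- function(eye, hydraulic_diameter, shape_factor = 1,
                          target_p_c, bleb_pressure) {
  check_design_target(eye, target_p_c, bleb_pressure, allow_equal = TRUE)
  a <- pi * um_to_m(hydraulic_diameter)^4
  b0 <- 128 * shape_factor * ulmin_to_m3s(eye$Q_0) * eye$mu * .MPAS_PAS
  p_c <- mmhg_to_pa(target_p_c); p_b <- mmhg_to_pa(bleb_pressure)
  p_g <- mmhg_to_pa(eye$p_g); p_ev <- mmhg_to_pa(eye$p_ev)
  lv <- if (target_p_c > eye$p_ev) {
    a * (p_g - p_ev) * (p_c - p_b) / (b0 * (p_g - p_c))
  } else {
    a * (p_c - p_b) / b0
  }
  lv / .MM_M
}

check_design_target <- function(eye, target_p_c, bleb_pressure,
                                allow_equal = FALSE) {
  stopifnot(inherits(eye, "eye_parameters"),
            is.numeric(target_p_c), length(target_p_c) == 1L,
            is.numeric(bleb_pressure), length(bleb_pressure) == 1L)
  low_ok <- if (allow_equal) target_p_c >= bleb_pressure else target_p_c > bleb_pressure
  if (!low_ok)
    abort("`target_p_c` must exceed `bleb_pressure`: the tube can only add resistance.",
          class = "iopflow_infeasible_error")
  if (target_p_c > eye$p_ev && target_p_c >= eye$p_g)
    abort("`target_p_c` must stay below the pre-surgery IOP `p_g` in the trabecular-open regime.",
          class = "iopflow_infeasible_error")
  invisible(TRUE)
}

#' Effective bleb resistance from an observed steady state
#'
#' The filtration bleb and surrounding sub-conjunctival tissue act as an
#' effective linear resistance towards the reference pressure `p_r`:
#' `R_b = (p_b - p_r) / Q_i`. This resistance, assumed unchanged between
#' interventions, is the quantity that lets the suture-correction solvers
#' eliminate the unmeasurable bleb pressure.
#'
#' @param state A [post_implant_state()] result.
#' @param p_r Bleb reference pressure, mm Hg.
#' @return Resistance in mm Hg per uL/min.
#' @export
bleb_resistance_from_state <- function(state, p_r = 0) {
  stopifnot(inherits(state, "surgery_state"))
  if (state$Q_i <= 0)
    abort("Bleb resistance is undefined at zero implant flow.",
          class = "iopflow_domain_error")
  if (state$p_b <= p_r)
    abort("Degenerate state: bleb pressure does not exceed the reference pressure.",
          class = "iopflow_domain_error")
  (state$p_b - p_r) / state$Q_i
}
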