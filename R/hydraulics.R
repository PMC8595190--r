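#' Hagen-Poiseuille pressure drop and resistance of the drainage tube
#'
#' Fully developed creeping flow through the device tube obeys the
#' generalized Hagen-Poiseuille law
#' `dp = 128 * S * L_v * mu * Q / (pi * D_h^4)`, with `S` the shape factor
#' of the cross-section and `D_h = D_i - D_s` the hydraulic diameter
#' (`S = 1`, `D_h = D_i` for an open tube). The entrance length is
#' negligible at these Reynolds numbers, so the law applies over the whole
#' tube length.
#'
#' Inputs are in clinical units (uL/min, um, mm, mPa s); the computation is
#' done in SI and the result converted back, so that `D_h^4` never appears
#' in micrometres.
#'
#' @param flow_rate Volumetric flow rate through the tube, uL/min.
#' @param geometry An [implant_geometry()].
#' @param suture Optional [suture_config()].
#' @param viscosity Dynamic viscosity of aqueous humor, mPa s.
#' @return `tube_pressure_drop()`: pressure drop in mm Hg.
#'   `tube_hydraulic_resistance()`: resistance in mm Hg per uL/min, so that
#'   the drop is exactly resistance times flow.
#' @examples
#' # open Baerveldt-type tube carrying the full ciliary inflow
#' tube_pressure_drop(2, implant_geometry(305, 11))
#' @export
tube_pressure_drop <- function(flow_rate, geometry, suture = NULL,
                               viscosity = 0.75) {
  stopifnot(is.numeric(flow_rate), all(flow_rate >= 0))
  tube_hydraulic_resistance(geometry, suture, viscosity) * flow_rate
}

#' @rdname tube_pressure_drop
#' @export
tube_hydraulic_resistance <- function(geometry, suture = NULL,
                                      viscosity = 0.75) {
  stopifnot(inherits(geometry, "implant_geometry"))
  if (viscosity <= 0) abort("`viscosity` must be positive.", class = "iopflow_domain_error")
  ts <- tube_section(geometry, suture)
  r_si <- 128 * ts$S * mm_to_m(geometry$length) * viscosity * .MPAS_PAS /
    (pi * um_to_m(ts$Dh)^4)                      # Pa per (m^3/s)
  pa_to_mmhg(r_si * .ULMIN_M3S)                  # mm Hg per (uL/min)
}

# effective shape factor and hydraulic diameter (um) of the tube lumen
tube_section <- function(geometry, suture = NULL) {
  kappa <- check_suture(geometry, suture)
  S <- if (kappa == 0) 1 else shape_factor(kappa, suture$placement)
  list(S = S, Dh = geometry$inner_diameter * (1 - kappa), kappa = kappa)
}
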