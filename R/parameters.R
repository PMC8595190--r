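#' Physiological parameters of one eye
#'
#' Bundles the lumped physiological constants that determine steady aqueous
#' humor outflow: the pre-surgery intraocular pressure (IOP) `p_g`, the
#' episcleral venous pressure `p_ev` downstream of the trabecular meshwork
#' and Schlemm's canal, the reference pressure `p_r` towards which the
#' filtration bleb drains, the ciliary inflow `Q_cb`, the fraction of that
#' inflow removed by the pressure-independent uveoscleral pathway, and the
#' dynamic viscosity of aqueous humor. The flow available to the trabecular
#' and implant pathways, `Q_0 = Q_cb * (1 - uveoscleral_fraction)`, is
#' derived and cannot be set independently.
#'
#' The defaults are the reference parameter set used throughout the package:
#' `p_g` = 35 mm Hg, `p_ev` = 10.5 mm Hg, `p_r` = 0, `Q_cb` = 2 uL/min,
#' uveoscleral fraction 0.15 (so `Q_0` = 1.7 uL/min) and viscosity
#' 0.75 mPa s.
#'
#' @param p_g Pre-surgery IOP, mm Hg. Must exceed `p_ev`.
#' @param p_ev Episcleral venous pressure, mm Hg.
#' @param p_r Bleb reference pressure, mm Hg.
#' @param Q_cb Ciliary body inflow, uL/min.
#' @param uveoscleral_fraction Fraction of `Q_cb` removed by the uveoscleral
#'   pathway, in `[0, 1)`.
#' @param mu Dynamic viscosity of aqueous humor, mPa s.
#' @return An object of class `eye_parameters`.
#' @examples
#' eye <- eye_parameters()
#' eye$Q_0   # 1.7 uL/min
#' @export
eye_parameters <- function(p_g = 35, p_ev = 10.5, p_r = 0, Q_cb = 2,
                           uveoscleral_fraction = 0.15, mu = 0.75) {
  stopifnot(
    is.numeric(p_g), length(p_g) == 1L,
    is.numeric(p_ev), length(p_ev) == 1L,
    is.numeric(p_r), length(p_r) == 1L,
    is.numeric(Q_cb), length(Q_cb) == 1L,
    is.numeric(uveoscleral_fraction), length(uveoscleral_fraction) == 1L,
    is.numeric(mu), length(mu) == 1L
  )
  if (p_ev < 0) abort("`p_ev` must be non-negative.", class = "iopflow_domain_error")
  if (p_g <= p_ev) abort("`p_g` must exceed `p_ev`.", class = "iopflow_domain_error")
  if (p_r < 0) abort("`p_r` must be non-negative.", class = "iopflow_domain_error")
  if (Q_cb <= 0) abort("`Q_cb` must be positive.", class = "iopflow_domain_error")
  if (uveoscleral_fraction < 0 || uveoscleral_fraction >= 1)
    abort("`uveoscleral_fraction` must lie in [0, 1).", class = "iopflow_domain_error")
  if (mu <= 0) abort("`mu` must be positive.", class = "iopflow_domain_error")
  structure(
    list(
      p_g = p_g, p_ev = p_ev, p_r = p_r, Q_cb = Q_cb,
      uveoscleral_fraction = uveoscleral_fraction, mu = mu,
      Q_0 = Q_cb * (1 - uveoscleral_fraction)
    ),
    class = "eye_parameters"
  )
}

#' @export
print.eye_parameters <- function(x, ...) {
  cat("<eye_parameters>\n")
  cat(sprintf("  p_g  = %g mm Hg (pre-surgery IOP)\n", x$p_g))
  cat(sprintf("  p_ev = %g mm Hg (episcleral venous pressure)\n", x$p_ev))
  cat(sprintf("  p_r  = %g mm Hg (bleb reference pressure)\n", x$p_r))
  cat(sprintf("  Q_cb = %g uL/min, uveoscleral fraction %g  =>  Q_0 = %g uL/min\n",
              x$Q_cb, x$uveoscleral_fraction, x$Q_0))
  cat(sprintf("  mu   = %g mPa s\n", x$mu))
  invisible(x)
}

#' Drainage-tube geometry
#'
#' Inner bore diameter and total length of the drainage-device tube. The
#' defaults describe a Baerveldt-type non-valved implant (inner diameter
#' 305 um, length 11 mm).
#'
#' @param inner_diameter Tube inner diameter `D_i`, um.
#' @param length Tube length `L_v`, mm.
#' @return An object of class `implant_geometry`.
#' @examples
#' implant_geometry()            # Baerveldt-type tube
#' implant_geometry(100, 11)     # narrow-bore tube
#' @export
implant_geometry <- function(inner_diameter = 305, length = 11) {
  stopifnot(is.numeric(inner_diameter), length(inner_diameter) == 1L,
            is.numeric(length), base::length(length) == 1L)
  if (inner_diameter <= 0) abort("`inner_diameter` must be positive.", class = "iopflow_domain_error")
  if (length <= 0) abort("`length` must be positive.", class = "iopflow_domain_error")
  structure(list(inner_diameter = inner_diameter, length = length),
            class = "implant_geometry")
}

#' @export
print.implant_geometry <- function(x, ...) {
  cat(sprintf("<implant_geometry> D_i = %g um, L_v = %g mm\n",
              x$inner_diameter, x$length))
  invisible(x)
}

#' Intraluminal suture configuration
#'
#' A straight cylindrical suture of diameter `D_s` inside the tube lumen.
#' A suture denser than aqueous humor settles against the tube wall
#' (placement `"wall_touching"`, internally tangent circles); holding it on
#' the tube axis (`"concentric"`) gives the larger hydraulic resistance at
#' equal diameter and admits a closed-form shape factor.
#'
#' @param diameter Suture diameter `D_s`, um. Must be smaller than the tube
#'   inner diameter it is paired with.
#' @param placement `"wall_touching"` or `"concentric"`.
#' @return An object of class `suture_config`.
#' @examples
#' suture_config(35, "concentric")
#' @export
suture_config <- function(diameter, placement = c("wall_touching", "concentric")) {
  placement <- match.arg(placement)
  stopifnot(is.numeric(diameter), length(diameter) == 1L)
  if (diameter < 0) abort("`diameter` must be non-negative.", class = "iopflow_domain_error")
  structure(list(diameter = diameter, placement = placement),
            class = "suture_config")
}

#' @export
print.suture_config <- function(x, ...) {
  cat(sprintf("<suture_config> D_s = %g um, placement = %s\n",
              x$diameter, x$placement))
  invisible(x)
}

# validate a suture against a geometry; returns kappa = D_s / D_i
check_suture <- function(geometry, suture) {
  if (is.null(suture)) return(0)
  if (suture$diameter >= geometry$inner_diameter)
    abort("Suture diameter must be smaller than the tube inner diameter.",
          class = "iopflow_domain_error")
  suture$diameter / geometry$inner_diameter
}
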