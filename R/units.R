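#' Unit conversions between clinical and SI units
#'
#' All public interfaces in this package use the clinical units of ocular
#' hydrodynamics: pressures in mm Hg, flow rates in microlitres per minute,
#' diameters in micrometres, lengths in millimetres and viscosities in
#' millipascal-seconds. Internal computations are carried out in SI units
#' (Pa, m^3/s, m, Pa s) because the fourth power of a diameter expressed in
#' micrometres is an easy way to lose precision. The conversion factor is
#' fixed at 1 mm Hg = 133.322 Pa so that results are bit-stable across
#' platforms.
#'
#' @param x Numeric vector of magnitudes.
#' @return Numeric vector in the target unit.
#' @examples
#' mmhg_to_pa(10.5)
#' pa_to_mmhg(mmhg_to_pa(10.5))
#' @name units
NULL

# fixed conversion constants
.MMHG_PA <- 133.322        # Pa per mm Hg (conventional)
.ULMIN_M3S <- 1e-9 / 60    # m^3/s per uL/min
.UM_M <- 1e-6
.MM_M <- 1e-3
.MPAS_PAS <- 1e-3

#' @rdname units
#' @export
mmhg_to_pa <- function(x) x * .MMHG_PA

#' @rdname units
#' @export
pa_to_mmhg <- function(x) x / .MMHG_PA

#' @rdname units
#' @export
ulmin_to_m3s <- function(x) x * .ULMIN_M3S

#' @rdname units
#' @export
m3s_to_ulmin <- function(x) x / .ULMIN_M3S

#' @rdname units
#' @export
um_to_m <- function(x) x * .UM_M

#' @rdname units
#' @export
mm_to_m <- function(x) x * .MM_M
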