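#' Read a run configuration file
#'
#' YAML (or JSON) configuration for the command-line interface. Every
#' unit-carrying field is either a bare number, read in the canonical
#' clinical unit, or a `{value: ..., unit: ...}` pair converted on load.
#' Canonical units: mm Hg for pressures, uL/min for flows, um for
#' diameters, mm for the tube length, mPa s for the viscosity. Unknown top
#' level keys are rejected.
#'
#' Recognised keys: `scenario` (free text), `eye` (fields of
#' [eye_parameters()]), `implant` (`inner_diameter`, `length`), `suture`
#' (`diameter`, `placement`), `p_c1`, `target_p_c2`, `placement`,
#' `bleb_pressure`.
#'
#' @param path Path to a YAML or JSON file.
#' @return A list with elements `scenario`, `eye` (an [eye_parameters()]),
#'   `implant` (an [implant_geometry()]), and any of `suture`, `p_c1`,
#'   `target_p_c2`, `placement`, `bleb_pressure` that the file provides.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("scenario", "eye", "implant", "suture", "p_c1", "target_p_c2",
             "placement", "bleb_pressure")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0)
    abort(paste0("Unknown configuration keys: ", paste(extra, collapse = ", ")),
          class = "iopflow_usage_error")

  eye_raw <- raw$eye %||% list()
  eye_known <- c("p_g", "p_ev", "p_r", "Q_cb", "uveoscleral_fraction", "mu")
  bad <- setdiff(names(eye_raw), eye_known)
  if (length(bad) > 0)
    abort(paste0("Unknown `eye` keys: ", paste(bad, collapse = ", ")),
          class = "iopflow_usage_error")
  eye_args <- list(
    p_g = quantity_in(eye_raw$p_g, "mmHg"),
    p_ev = quantity_in(eye_raw$p_ev, "mmHg"),
    p_r = quantity_in(eye_raw$p_r, "mmHg"),
    Q_cb = quantity_in(eye_raw$Q_cb, "uL/min"),
    uveoscleral_fraction = quantity_in(eye_raw$uveoscleral_fraction, "1"),
    mu = quantity_in(eye_raw$mu, "mPa s")
  )
  eye <- do.call(eye_parameters, Filter(Negate(is.null), eye_args))

  imp_raw <- raw$implant %||% list()
  imp_args <- list(inner_diameter = quantity_in(imp_raw$inner_diameter, "um"),
                   length = quantity_in(imp_raw$length, "mm"))
  implant <- do.call(implant_geometry, Filter(Negate(is.null), imp_args))

  out <- list(scenario = raw$scenario %||% "unnamed", eye = eye, implant = implant,
              placement = raw$placement,
              p_c1 = quantity_in(raw$p_c1, "mmHg"),
              target_p_c2 = quantity_in(raw$target_p_c2, "mmHg"),
              bleb_pressure = quantity_in(raw$bleb_pressure, "mmHg"))
  if (!is.null(raw$suture)) {
    out$suture <- suture_config(
      quantity_in(raw$suture$diameter, "um"),
      raw$suture$placement %||% "wall_touching")
  }
  out
}

# convert a bare number or {value, unit} pair to the canonical unit
quantity_in <- function(x, target) {
  if (is.null(x)) return(NULL)
  if (is.numeric(x) && length(x) == 1L) return(as.numeric(x))
  if (!is.list(x) || is.null(x$value) || is.null(x$unit))
    abort("Quantities must be a number or a {value, unit} pair.",
          class = "iopflow_usage_error")
  u <- gsub("[ ·µ]", "", tolower(x$unit))
  u <- sub("μ", "u", u)
  v <- as.numeric(x$value)
  conv <- switch(
    target,
    "mmHg" = c(mmhg = 1, pa = 1 / .MMHG_PA, kpa = 1000 / .MMHG_PA),
    "uL/min" = c(`ul/min` = 1, `m3/s` = 1 / .ULMIN_M3S),
    "um" = c(um = 1, mm = 1000, m = 1e6),
    "mm" = c(mm = 1, um = 1e-3, m = 1e3),
    "mPa s" = c(mpas = 1, pas = 1e3),
    "1" = setNames(c(1, 1), c("1", ""))
  )
  if (!u %in% names(conv))
    abort(sprintf("Unit '%s' not valid here (expected one of: %s).",
                  x$unit, paste(names(conv), collapse = ", ")),
          class = "iopflow_usage_error")
  v * conv[[u]]
}
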