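#' Cross-section of a drainage tube with an optional intraluminal suture
#'
#' Describes the flow cross-section: the circular tube bore of diameter
#' `outer_diameter` (`D_i`) minus a circular suture of diameter
#' `suture_diameter` (`D_s`), either coaxial with the tube or resting
#' against the wall (internally tangent, single contact point). The
#' hydraulic diameter is `D_h = D_i - D_s`.
#'
#' @param outer_diameter Tube inner bore `D_i` (any length unit; the shape
#'   factor is dimensionless and scale invariant).
#' @param suture_diameter Suture diameter `D_s` in the same unit; 0 means no
#'   suture.
#' @param placement `"concentric"` or `"wall_touching"`; ignored when
#'   `suture_diameter` is 0.
#' @return An object of class `cross_section` with a `kappa = D_s / D_i`
#'   field.
#' @examples
#' cross_section(100, 35, "concentric")
#' hydraulic_diameter(cross_section(100, 35))
#' @export
cross_section <- function(outer_diameter, suture_diameter = 0,
                          placement = c("concentric", "wall_touching")) {
  placement <- match.arg(placement)
  stopifnot(is.numeric(outer_diameter), length(outer_diameter) == 1L,
            is.numeric(suture_diameter), length(suture_diameter) == 1L)
  if (outer_diameter <= 0)
    abort("`outer_diameter` must be positive.", class = "iopflow_domain_error")
  if (suture_diameter < 0 || suture_diameter >= outer_diameter)
    abort("`suture_diameter` must satisfy 0 <= D_s < D_i.",
          class = "iopflow_domain_error")
  structure(
    list(outer_diameter = outer_diameter, suture_diameter = suture_diameter,
         placement = placement, kappa = suture_diameter / outer_diameter),
    class = "cross_section"
  )
}

#' @rdname cross_section
#' @param section A `cross_section`.
#' @export
hydraulic_diameter <- function(section) {
  stopifnot(inherits(section, "cross_section"))
  section$outer_diameter - section$suture_diameter
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("<cross_section> D_i = %g, D_s = %g (%s), D_h = %g, kappa = %g\n",
              x$outer_diameter, x$suture_diameter,
              if (x$suture_diameter > 0) x$placement else "open tube",
              hydraulic_diameter(x), x$kappa))
  invisible(x)
}

#' Shape factor of a tube with a concentric suture (closed form)
#'
#' The generalized Hagen-Poiseuille law writes the pressure drop across a
#' duct of arbitrary cross-section as
#' `dp = 128 * S * L * mu * Q / (pi * D_h^4)`, where the dimensionless
#' shape factor `S` equals 1 for a circular tube and corrects for the
#' cross-section shape otherwise. For a suture of diameter `D_s` placed
#' coaxially inside a tube of diameter `D_i` (a concentric annulus,
#' `kappa = D_s / D_i`) the classical annulus solution gives
#'
#' `S = (1 - kappa)^4 / (1 - kappa^4 + (1 - kappa^2)^2 / log(kappa))`
#'
#' with the open-tube limit `S = 1` at `kappa = 0` (the logarithmic term
#' vanishes together with its prefactor) and `S -> 0` as `kappa -> 1`.
#'
#' `S` is not monotone in `kappa`: a thin central wire reduces the flow
#' logarithmically while `D_h^4` shrinks only algebraically, so `S` rises
#' above 1 for small `kappa` (up to about 1.24 near `kappa = 0.03`) before
#' decaying towards 0. The physically monotone quantity is the resistance
#' ratio `S * (1 - kappa)^(-4)` (see [resistance_ratio()]), which increases
#' strictly from 1 and diverges as the annular gap closes.
#'
#' @param kappa Diameter ratio `D_s / D_i`, vector of values in `[0, 1)`.
#' @return Shape factor values, strictly positive, with `S(0) = 1`.
#' @examples
#' concentric_shape_factor(0)     # 1, open tube
#' concentric_shape_factor(0.35)
#' @export
concentric_shape_factor <- function(kappa) {
  if (!is.numeric(kappa) || any(!is.finite(kappa)) ||
      any(kappa < 0) || any(kappa >= 1))
    abort("`kappa` must lie in [0, 1).", class = "iopflow_domain_error")
  out <- numeric(length(kappa))
  z <- kappa == 0
  out[z] <- 1
  k <- kappa[!z]
  # evaluated in eps = 1 - kappa: the braces term is an O(eps^3) difference
  # of O(eps) terms, so the naive form loses all digits as kappa -> 1;
  # the exact polynomial rearrangement below stays well conditioned
  eps <- 1 - k
  one_minus_k4 <- eps * (4 - eps * (6 - eps * (4 - eps)))       # 1 - k^4
  one_minus_k2_sq <- eps^2 * (4 - eps * (4 - eps))              # (1 - k^2)^2
  braces <- one_minus_k4 + one_minus_k2_sq / log1p(-eps)
  out[!z] <- eps^4 / braces
  out
}

#' Shape factor for either suture placement
#'
#' Concentric values come from the closed form
#' ([concentric_shape_factor()]); wall-touching values from a monotone
#' spline through a table precomputed with the finite-difference Poisson
#' solver ([poisson_shape_factor()]), anchored at `S(0) = 1` and
#' `S(1) = 0`. The wall-touching curve is monotone decreasing and stays
#' below 1; the concentric curve exceeds 1 for thin sutures (see
#' [concentric_shape_factor()]).
#'
#' @inheritParams concentric_shape_factor
#' @param placement `"concentric"` or `"wall_touching"`.
#' @return Shape factor values, strictly positive.
#' @examples
#' shape_factor(0.5, "wall_touching") < shape_factor(0.5, "concentric")
#' @export
shape_factor <- function(kappa, placement = c("concentric", "wall_touching")) {
  placement <- match.arg(placement)
  if (placement == "concentric") return(concentric_shape_factor(kappa))
  if (!is.numeric(kappa) || any(!is.finite(kappa)) ||
      any(kappa < 0) || any(kappa >= 1))
    abort("`kappa` must lie in [0, 1).", class = "iopflow_domain_error")
  wall_touching_interpolant()(kappa)
}

# monotone (Hyman-filtered) spline through the shipped wall-touching table,
# built once per session
wall_touching_interpolant <- function() {
  if (!is.null(the$wall_spline)) return(the$wall_spline)
  path <- system.file("extdata", "shape_factor_wall_touching.csv",
                      package = "iopflow", mustWork = TRUE)
  tab <- read.csv(path)
  f <- splinefun(tab$kappa, tab$shape_factor, method = "hyman")
  the$wall_spline <- f
  f
}

#' Tabulate the shape factor over a grid of diameter ratios
#'
#' @param placement `"concentric"` or `"wall_touching"`.
#' @param kappa Strictly increasing grid of diameter ratios in `[0, 1)`.
#' @param method `"closed_form"` uses the closed form (concentric) or the
#'   shipped interpolation table (wall-touching); `"poisson_numeric"` runs
#'   the finite-difference solver at every grid point.
#' @param resolution Grid resolution passed to [poisson_shape_factor()] when
#'   `method = "poisson_numeric"`.
#' @return A tibble with columns `kappa`, `shape_factor`, `placement`,
#'   `method` and `error_estimate` (`NA` for interpolated values, 0 for the
#'   closed form).
#' @examples
#' tabulate_shape_factor("concentric", c(0, 0.25, 0.5, 0.75))
#' @export
tabulate_shape_factor <- function(placement = c("concentric", "wall_touching"),
                                  kappa = seq(0, 0.96, by = 0.02),
                                  method = c("closed_form", "poisson_numeric"),
                                  resolution = 192) {
  placement <- match.arg(placement)
  method <- match.arg(method)
  if (length(kappa) == 0)
    return(tibble(kappa = numeric(), shape_factor = numeric(),
                  placement = character(), method = character(),
                  error_estimate = numeric()))
  if (any(diff(kappa) <= 0))
    abort("`kappa` grid must be strictly increasing.", class = "iopflow_domain_error")
  if (method == "closed_form") {
    s <- shape_factor(kappa, placement)
    err <- if (placement == "concentric") rep(0, length(kappa)) else rep(NA_real_, length(kappa))
    meth <- if (placement == "concentric") "closed_form" else "interpolated"
    return(tibble(kappa = kappa, shape_factor = s, placement = placement,
                  method = meth, error_estimate = err))
  }
  res <- lapply(kappa, function(k) {
    r <- poisson_shape_factor(cross_section(1, k, placement), resolution = resolution)
    tibble(kappa = k, shape_factor = r$value, placement = placement,
           method = r$method, error_estimate = r$error_estimate)
  })
  dplyr::bind_rows(res)
}

#' Occluded-to-open hydraulic resistance ratio of the tube
#'
#' Inserting a suture multiplies the tube's hydraulic resistance by
#' `S(kappa) * (1 - kappa)^(-4)`: the shape factor of the occluded section
#' divided by the fourth power of the relative hydraulic diameter. The
#' ratio equals 1 at `kappa = 0`, increases strictly with `kappa` and
#' diverges as the gap closes.
#'
#' @inheritParams shape_factor
#' @return Resistance ratio values `>= 1`.
#' @examples
#' resistance_ratio(0.35, "concentric")
#' @export
resistance_ratio <- function(kappa, placement = c("concentric", "wall_touching")) {
  placement <- match.arg(placement)
  shape_factor(kappa, placement) * (1 - kappa)^(-4)
}

#' Suture diameter ratio achieving a target resistance ratio
#'
#' Inverts [resistance_ratio()] by bracketed root finding on
#' `[0, 1 - 1e-6]` (concentric) or on the range covered by the
#' wall-touching table, exploiting strict monotonicity.
#'
#' @param target_ratio Required resistance ratio, `>= 1`.
#' @param placement `"concentric"` or `"wall_touching"`.
#' @return The unique `kappa` with
#'   `resistance_ratio(kappa, placement) == target_ratio`.
#' @examples
#' invert_resistance_ratio(resistance_ratio(0.6, "concentric"), "concentric")
#' @export
invert_resistance_ratio <- function(target_ratio,
                                    placement = c("concentric", "wall_touching")) {
  placement <- match.arg(placement)
  stopifnot(is.numeric(target_ratio), length(target_ratio) == 1L, is.finite(target_ratio))
  if (target_ratio < 1)
    abort("`target_ratio` must be >= 1: a suture can only raise the tube resistance.",
          class = "iopflow_infeasible_error")
  if (target_ratio == 1) return(0)
  delta <- 1e-6
  # the wall-touching interpolant is only trustworthy over the solved table
  kmax <- if (placement == "concentric") 1 - delta else 31 / 32
  fmax <- resistance_ratio(kmax, placement)
  if (target_ratio > fmax)
    abort(sprintf(paste0("A suture alone cannot provide a resistance ratio of %g ",
                         "(maximum attainable with kappa <= %g is %g)."),
                  target_ratio, kmax, fmax),
          class = "iopflow_infeasible_error")
  # root finding on log(ratio) keeps the bracket well scaled near kappa -> 1
  f <- function(k) log(resistance_ratio(k, placement)) - log(target_ratio)
  uniroot(f, c(0, kmax), tol = 1e-12)$root
}

#' Read or write a kappa/shape-factor table as CSV
#'
#' Two-column CSV with header `kappa,shape_factor`, the exchange format for
#' precomputed shape-factor curves.
#'
#' @param path File path.
#' @param table A data frame with columns `kappa` and `shape_factor`.
#' @return `read_shape_factor_table()` returns a tibble;
#'   `write_shape_factor_table()` returns `path` invisibly.
#' @export
read_shape_factor_table <- function(path) {
  tab <- read.csv(path)
  if (!all(c("kappa", "shape_factor") %in% names(tab)))
    abort("Expected columns `kappa` and `shape_factor`.", class = "iopflow_usage_error")
  as_tibble(tab)
}

#' @rdname read_shape_factor_table
#' @export
write_shape_factor_table <- function(table, path) {
  stopifnot(all(c("kappa", "shape_factor") %in% names(table)))
  write.csv(table[, c("kappa", "shape_factor")], path, row.names = FALSE)
  invisible(path)
}
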