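#' Shape factor from a finite-difference Poisson solve
#'
#' For a duct of arbitrary cross-section the shape factor follows from the
#' fully developed axial momentum balance: solve the Poisson problem
#' `laplacian(v) = -1` with `v = 0` on the section contour, integrate the
#' scaled velocity over the section, and set
#' `S = pi * D_h^4 / (128 * integral(v))` with all lengths in the same
#' units (on a section scaled so that `D_h = 1` this is
#' `S = (pi/128) / integral(v)`). `S` is dimensionless and scale invariant.
#'
#' Two discretizations are provided on a uniform Cartesian grid:
#' `"shortley_weller"` (the production solver; second order, with the
#' boundary intercepts of the stencil arms computed exactly on the circular
#' or polygonal contour) and `"masked"` (a deliberately low-order check
#' that pins the first grid node outside the domain to zero; first order).
#' The relative `error_estimate` comes from a two-level Richardson
#' comparison between resolutions `n` and `n/2`.
#'
#' The wall-touching geometry has a cusp at the tangency point. The axial
#' velocity vanishes rapidly towards the cusp, so its neighbourhood
#' contributes almost nothing to the flow integral and a uniform grid with
#' exact boundary intercepts resolves it; the two-level comparison is the
#' acceptance check.
#'
#' @param section A [cross_section()], or a closed polygon as a two-column
#'   matrix / data frame of planar coordinates (first and last vertex need
#'   not repeat).
#' @param resolution Number of grid cells across the section's bounding box
#'   (the finer of the two Richardson levels). Must be at least 32.
#' @param solver `"shortley_weller"` or `"masked"`.
#' @param tol Relative error tolerance; the solve fails with a
#'   numerical-accuracy error if the Richardson estimate exceeds it.
#' @param keep_field If `TRUE`, attach the scaled velocity field (tibble of
#'   `x`, `y`, `v` at interior grid nodes) for diagnostics and plotting.
#' @return An object of class `shape_factor_result`: a list with `value`,
#'   `method` (`"poisson_numeric"`), `solver`, `resolution`,
#'   `error_estimate`, `kappa`, `placement` and optionally `field`.
#' @examples
#' \donttest{
#' r <- poisson_shape_factor(cross_section(1, 0.35, "concentric"), resolution = 96)
#' abs(r$value - concentric_shape_factor(0.35))
#' }
#' @export
poisson_shape_factor <- function(section, resolution = 192,
                                 solver = c("shortley_weller", "masked"),
                                 tol = 5e-3, keep_field = FALSE) {
  solver <- match.arg(solver)
  if (resolution < 32)
    abort("`resolution` must be at least 32 (two refinement levels).",
          class = "iopflow_usage_error")
  n <- as.integer(resolution)
  if (inherits(section, "cross_section")) {
    geo <- annulus_domain(section)
    kappa <- section$kappa
    placement <- if (section$suture_diameter > 0) section$placement else "open_tube"
    key <- sprintf("%s|%s|%.15g|%d", solver, placement, kappa, n)
  } else {
    geo <- polygon_domain(section)
    kappa <- NA_real_
    placement <- "custom"
    key <- NULL
  }
  cached <- if (!keep_field && !is.null(key)) the$poisson_cache[[key]] else NULL
  if (!is.null(cached)) {
    if (cached$error_estimate > tol)
      abort(sprintf("Richardson error estimate %.2e exceeds tolerance %.2e at resolution %d.",
                    cached$error_estimate, tol, n),
            class = "iopflow_numerical_error")
    return(cached)
  }

  coarse <- poisson_integral(geo, n %/% 2L, solver, keep_field = FALSE)
  fine <- poisson_integral(geo, n, solver, keep_field = keep_field)
  s_f <- pi * geo$Dh^4 / (128 * fine$integral)
  s_c <- pi * geo$Dh^4 / (128 * coarse$integral)
  p <- if (solver == "shortley_weller") 2 else 1
  err <- max(abs(s_f - s_c) / ((2^p - 1) * abs(s_f)), 1e-12)
  if (err > tol)
    abort(sprintf("Richardson error estimate %.2e exceeds tolerance %.2e at resolution %d.",
                  err, tol, n),
          class = "iopflow_numerical_error")
  out <- structure(
    list(value = s_f, method = "poisson_numeric", solver = solver,
         resolution = n, error_estimate = err, kappa = kappa,
         placement = placement, field = fine$field),
    class = "shape_factor_result"
  )
  if (!keep_field && !is.null(key)) the$poisson_cache[[key]] <- out
  out
}

#' @export
print.shape_factor_result <- function(x, ...) {
  cat(sprintf("<shape_factor_result> S = %.6g (%s, %s, n = %d, rel. err <= %.1e)\n",
              x$value, x$method, x$solver, x$resolution, x$error_estimate))
  invisible(x)
}

# --- domain descriptions -----------------------------------------------

# tube bore of diameter 1 centred at the origin, optional suture circle
annulus_domain <- function(section) {
  kappa <- section$kappa
  R <- 0.5
  r <- kappa / 2
  cx <- if (section$placement == "wall_touching" && kappa > 0) R - r else 0
  inside <- function(x, y) {
    ok <- x^2 + y^2 < R^2
    if (r > 0) ok <- ok & ((x - cx)^2 + y^2 > r^2)
    ok
  }
  # smallest t in (0, 1] where p + t*d crosses either circle
  boundary_t <- function(px, py, dx, dy) {
    t <- circle_hit(px, py, dx, dy, 0, 0, R)
    if (r > 0) t <- pmin(t, circle_hit(px, py, dx, dy, cx, 0, r))
    t
  }
  list(inside = inside, boundary_t = boundary_t,
       box = c(-R, R, -R, R), Dh = 1 - kappa,
       min_gap = (1 - kappa) / 2)
}

circle_hit <- function(px, py, dx, dy, cx, cy, rad) {
  a <- dx^2 + dy^2
  b <- 2 * ((px - cx) * dx + (py - cy) * dy)
  cc <- (px - cx)^2 + (py - cy)^2 - rad^2
  disc <- b^2 - 4 * a * cc
  sq <- sqrt(pmax(disc, 0))
  t1 <- (-b - sq) / (2 * a)
  t2 <- (-b + sq) / (2 * a)
  t1[!(disc >= 0) | t1 <= 1e-13] <- Inf
  t2[!(disc >= 0) | t2 <= 1e-13] <- Inf
  pmin(t1, t2)
}

polygon_domain <- function(poly) {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2 || nrow(poly) < 3)
    abort("A custom boundary needs a two-column matrix with at least 3 vertices.",
          class = "iopflow_usage_error")
  # close the polygon
  if (any(poly[1, ] != poly[nrow(poly), ])) poly <- rbind(poly, poly[1, ])
  xs <- poly[, 1]; ys <- poly[, 2]
  m <- length(xs) - 1L
  area2 <- sum(xs[1:m] * ys[2:(m + 1)] - xs[2:(m + 1)] * ys[1:m])
  A <- abs(area2) / 2
  P <- sum(sqrt(diff(xs)^2 + diff(ys)^2))
  scale <- max(diff(range(xs)), diff(range(ys)))
  inside <- function(x, y) {
    wn <- rep(0L, length(x))
    mind <- rep(Inf, length(x))
    for (i in seq_len(m)) {
      x1 <- xs[i]; y1 <- ys[i]; x2 <- xs[i + 1]; y2 <- ys[i + 1]
      up <- (y1 <= y) & (y2 > y)
      dn <- (y1 > y) & (y2 <= y)
      is_left <- (x2 - x1) * (y - y1) - (x - x1) * (y2 - y1)
      wn <- wn + ifelse(up & is_left > 0, 1L, 0L) - ifelse(dn & is_left < 0, 1L, 0L)
      # distance to the segment, to exclude nodes sitting on the contour
      ex <- x2 - x1; ey <- y2 - y1
      tt <- pmin(pmax(((x - x1) * ex + (y - y1) * ey) / (ex^2 + ey^2), 0), 1)
      mind <- pmin(mind, sqrt((x - x1 - tt * ex)^2 + (y - y1 - tt * ey)^2))
    }
    wn != 0L & mind > 1e-9 * scale
  }
  boundary_t <- function(px, py, dx, dy) {
    t <- rep(Inf, length(px))
    for (i in seq_len(m)) {
      x1 <- xs[i]; y1 <- ys[i]; x2 <- xs[i + 1]; y2 <- ys[i + 1]
      ex <- x2 - x1; ey <- y2 - y1
      den <- dx * ey - dy * ex
      tt <- ((x1 - px) * ey - (y1 - py) * ex) / den
      ss <- if (abs(ex) > abs(ey)) (px + tt * dx - x1) / ex else (py + tt * dy - y1) / ey
      bad <- !is.finite(tt) | tt <= 1e-13 | ss < -1e-12 | ss > 1 + 1e-12
      tt[bad] <- Inf
      t <- pmin(t, tt)
    }
    t
  }
  list(inside = inside, boundary_t = boundary_t,
       box = c(range(xs), range(ys)), Dh = 4 * A / P,
       min_gap = Inf)
}

# --- core finite-difference solve --------------------------------------

# Solve -laplacian(u) = 1, u = 0 on the contour, on a uniform grid over the
# bounding box; return the integral of u over the domain.
poisson_integral <- function(geo, n, solver, keep_field = FALSE) {
  box <- geo$box
  L <- max(box[2] - box[1], box[4] - box[3])
  h <- L / n
  if (is.finite(geo$min_gap) && geo$min_gap < 3 * h)
    abort(sprintf("Annular gap (%.3g) below resolvable scale at resolution %d.",
                  geo$min_gap, n),
          class = "iopflow_geometry_error")
  xs <- seq(box[1], box[1] + L, by = h)
  ys <- seq(box[3], box[3] + L, by = h)
  np <- length(xs)
  X <- matrix(xs, np, np)
  Y <- matrix(ys, np, np, byrow = TRUE)
  ins <- matrix(geo$inside(as.vector(X), as.vector(Y)), np, np)
  N <- sum(ins)
  if (N < 12)
    abort("Too few interior nodes; refine the resolution.",
          class = "iopflow_geometry_error")
  id <- matrix(0L, np, np)
  id[ins] <- seq_len(N)
  ii <- which(ins, arr.ind = TRUE)
  px <- X[ins]; py <- Y[ins]

  neighbor <- function(di, dj) {
    i2 <- ii[, 1] + di; j2 <- ii[, 2] + dj
    okr <- i2 >= 1L & i2 <= np & j2 >= 1L & j2 <= np
    nid <- integer(N)
    idx <- cbind(pmax(pmin(i2, np), 1L), pmax(pmin(j2, np), 1L))
    nid[okr] <- id[idx[okr, , drop = FALSE]]
    nid  # 0 when the neighbour is outside the domain
  }
  east <- neighbor(1L, 0L); west <- neighbor(-1L, 0L)
  north <- neighbor(0L, 1L); south <- neighbor(0L, -1L)

  th <- function(nid, dx, dy) {
    t <- rep(1, N)
    if (solver == "shortley_weller") {
      f <- nid == 0L
      if (any(f)) t[f] <- pmin(geo$boundary_t(px[f], py[f], dx, dy), 1)
    }
    t
  }
  thE <- th(east, h, 0); thW <- th(west, -h, 0)
  thN <- th(north, 0, h); thS <- th(south, 0, -h)

  me <- seq_len(N)
  rows <- me; cols <- me
  vals <- 2 / (thE * thW * h^2) + 2 / (thN * thS * h^2)
  link <- function(nid, t1, t2) {
    f <- nid > 0L
    rows <<- c(rows, me[f]); cols <<- c(cols, nid[f])
    vals <<- c(vals, -2 / (t1[f] * (t1[f] + t2[f]) * h^2))
  }
  link(east, thE, thW); link(west, thW, thE)
  link(north, thN, thS); link(south, thS, thN)
  A <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(N, N))
  u <- as.numeric(Matrix::solve(A, rep(1, N)))
  field <- if (keep_field) tibble(x = px, y = py, v = u) else NULL
  list(integral = sum(u) * h^2, field = field, n_interior = N)
}
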