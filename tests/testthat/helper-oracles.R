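# Independent oracles used across the suite. These deliberately do not call
# package internals beyond the public constructors.

# mm Hg <-> Pa constant, restated independently of the package
MMHG <- 133.322

# Explicit solve of the five-equation outflow network (steady states before
# and after the suture, linked by a constant bleb resistance), with the
# occluded shape factor as the unknown. Root-finding replaces the package's
# closed-form elimination of the bleb pressures.
oracle_resistance_ratio <- function(p_g, p_ev, p_r, Q0, mu, Di, Lv, kappa,
                                    p1, p2) {
  p_g <- p_g * MMHG; p_ev <- p_ev * MMHG; p_r <- p_r * MMHG
  p1 <- p1 * MMHG; p2 <- p2 * MMHG
  Q0 <- Q0 * 1e-9 / 60; Di <- Di * 1e-6; Lv <- Lv * 1e-3; mu <- mu * 1e-3
  Dh <- Di * (1 - kappa)
  b <- 128 * Lv * Q0 * mu
  if (p1 > p_ev) {
    a1 <- pi * Di^4 * (p_g - p_ev)
    pb1 <- (p1 * (a1 + b) - b * p_g) / (pi * Di^4 * (p_g - p_ev))
    Q1 <- pi * Di^4 * Q0 * (p_g - pb1) / (a1 + b)
  } else {
    pb1 <- p1 - b / (pi * Di^4)
    Q1 <- Q0
  }
  Rb <- (pb1 - p_r) / Q1
  resid <- function(S2) {
    if (p2 > p_ev) {
      a2 <- pi * Dh^4 * (p_g - p_ev); b2 <- 128 * S2 * Lv * Q0 * mu
      pb2 <- (p2 * (a2 + b2) - b2 * p_g) / (pi * Dh^4 * (p_g - p_ev))
      Q2 <- pi * Dh^4 * Q0 * (p_g - pb2) / (a2 + b2)
    } else {
      pb2 <- p2 - 128 * S2 * Lv * mu * Q0 / (pi * Dh^4)
      Q2 <- Q0
    }
    (pb2 - p_r) / Q2 - Rb
  }
  S2 <- stats::uniroot(resid, c(1e-10, 1e8), tol = 1e-16)$root
  S2 * (1 - kappa)^-4
}

# Low-order brute-force Poisson solve: uniform Cartesian grid, five-point
# stencil, outside nodes pinned to zero (no boundary intercepts). First
# order at the contour; written independently of the package solver.
oracle_masked_shape_factor <- function(kappa, placement, n) {
  R <- 0.5; r <- kappa / 2
  cx <- if (placement == "wall_touching") R - r else 0
  h <- 1 / n
  xs <- seq(-R, R, by = h)
  np <- length(xs)
  X <- matrix(xs, np, np); Y <- matrix(xs, np, np, byrow = TRUE)
  ins <- X^2 + Y^2 < R^2
  if (r > 0) ins <- ins & ((X - cx)^2 + Y^2 > r^2)
  N <- sum(ins)
  id <- matrix(0L, np, np); id[ins] <- seq_len(N)
  ii <- which(ins, arr.ind = TRUE)
  rows <- seq_len(N); cols <- seq_len(N); vals <- rep(4 / h^2, N)
  for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    i2 <- ii[, 1] + d[1]; j2 <- ii[, 2] + d[2]
    ok <- i2 >= 1L & i2 <= np & j2 >= 1L & j2 <= np
    nid <- integer(N)
    nid[ok] <- id[cbind(i2[ok], j2[ok])]
    f <- nid > 0L
    rows <- c(rows, which(f)); cols <- c(cols, nid[f])
    vals <- c(vals, rep(-1 / h^2, sum(f)))
  }
  A <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(N, N))
  u <- as.numeric(Matrix::solve(A, rep(1, N)))
  I <- sum(u) * h^2
  pi * (1 - kappa)^4 / (128 * I)
}

# reference clinical parameter set used throughout the tests
ref_eye <- function() eye_parameters()
baerveldt <- function() implant_geometry(305, 11)
narrow_tube <- function() implant_geometry(100, 11)
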