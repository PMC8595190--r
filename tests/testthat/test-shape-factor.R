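test_that("concentric closed form honours the limits and the frozen midpoint", {
  expect_identical(concentric_shape_factor(0), 1)
  # annular gap closing: resistance diverges, shape factor vanishes
  expect_lt(concentric_shape_factor(1 - 1e-4), 1e-3)
  # midpoint value computed independently from the naive algebraic form
  k <- 0.5
  naive <- (1 - k)^4 / (1 - k^4 + (1 - k^2)^2 / log(k))
  expect_equal(naive, 0.4960945866, tolerance = 1e-9)
  expect_equal(concentric_shape_factor(0.5), naive, tolerance = 1e-12)
})

test_that("the resistance ratio rises strictly from one for both placements", {
  grid <- seq(0, 0.95, by = 0.05)
  for (pl in c("concentric", "wall_touching")) {
    rr <- resistance_ratio(grid, pl)
    expect_equal(rr[1], 1)
    expect_true(all(diff(rr) > 0), info = pl)
    expect_true(all(shape_factor(grid, pl) > 0), info = pl)
  }
})

test_that("the shape factor decays once the suture is thick enough", {
  grid <- seq(0.2, 0.95, by = 0.05)
  expect_true(all(diff(shape_factor(grid, "concentric")) < 0))
  # wall-touching is monotone over the whole range and bounded by one
  full <- seq(0, 0.95, by = 0.05)
  sw <- shape_factor(full, "wall_touching")
  expect_true(all(diff(sw) < 0))
  expect_true(all(sw <= 1))
  # a thin concentric wire cuts flow logarithmically, faster than D_h^4
  # shrinks, so the concentric shape factor transiently exceeds one
  expect_gt(concentric_shape_factor(0.03), 1)
  expect_lt(concentric_shape_factor(0.03), 1.3)
})

test_that("wall-touching placement obstructs less than concentric at every kappa", {
  grid <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(shape_factor(grid, "wall_touching") <
                    shape_factor(grid, "concentric")))
})

test_that("resistance-ratio inversion round-trips and flags infeasible targets", {
  for (k in c(0.1, 0.35, 0.6, 0.85)) {
    for (pl in c("concentric", "wall_touching")) {
      target <- resistance_ratio(k, pl)
      k2 <- invert_resistance_ratio(target, pl)
      expect_equal(resistance_ratio(k2, pl) / target, 1, tolerance = 1e-6,
                   info = sprintf("%s kappa=%g", pl, k))
    }
  }
  expect_identical(invert_resistance_ratio(1, "concentric"), 0)
  expect_error(invert_resistance_ratio(0.5, "concentric"),
               class = "iopflow_infeasible_error")
  expect_error(invert_resistance_ratio(1e30, "wall_touching"),
               class = "iopflow_infeasible_error")
})

test_that("tabulation returns monotone curves and handles the empty grid", {
  tab <- tabulate_shape_factor("concentric", c(0, 0.5, 0.9))
  expect_true(all(diff(tab$shape_factor) < 0))
  expect_identical(tab$error_estimate, c(0, 0, 0))
  wt <- tabulate_shape_factor("wall_touching", c(0.2, 0.5, 0.8))
  expect_true(all(wt$shape_factor <
                    tabulate_shape_factor("concentric", c(0.2, 0.5, 0.8))$shape_factor))
  empty <- tabulate_shape_factor("concentric", numeric(0))
  expect_identical(nrow(empty), 0L)
  expect_error(tabulate_shape_factor("concentric", c(0.5, 0.2)),
               class = "iopflow_domain_error")
})

test_that("kappa tables round-trip through the CSV exchange format", {
  tab <- tabulate_shape_factor("concentric", c(0, 0.3, 0.6))
  path <- withr::local_tempfile(fileext = ".csv")
  write_shape_factor_table(tab, path)
  back <- read_shape_factor_table(path)
  expect_equal(back$kappa, tab$kappa)
  expect_equal(back$shape_factor, tab$shape_factor, tolerance = 1e-12)
})

test_that("cross-section invariants are enforced", {
  cs <- cross_section(100, 35, "wall_touching")
  expect_equal(hydraulic_diameter(cs), 65)
  expect_error(cross_section(100, 100), class = "iopflow_domain_error")
  expect_error(cross_section(100, -1), class = "iopflow_domain_error")
  expect_error(concentric_shape_factor(1), class = "iopflow_domain_error")
  expect_error(shape_factor(-0.1, "wall_touching"), class = "iopflow_domain_error")
})
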