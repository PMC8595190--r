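test_that("the required ratio is one at an unchanged target and grows with it", {
  eye <- ref_eye()
  geo <- narrow_tube()
  for (p1 in c(4, 10.5, 14)) {
    expect_equal(required_resistance_ratio(eye, geo, p1, p1), 1)
  }
  targets <- seq(5, 20, by = 0.5)
  rr <- vapply(targets, function(p2) required_resistance_ratio(eye, geo, 4, p2),
               numeric(1))
  expect_true(all(diff(rr) > 0))
})

test_that("the both-closed ratio matches an independent arithmetic computation", {
  eye <- ref_eye()
  geo <- narrow_tube()
  # hand computation in SI: ratio = 1 + pi Di^4 dp / (128 Lv mu Q0)
  dp <- 2 * 133.322
  chi <- pi * (100e-6)^4 / (128 * 11e-3 * 0.75e-3 * (1.7e-9 / 60))
  expect_equal(required_resistance_ratio(eye, geo, 4, 6), 1 + chi * dp,
               tolerance = 1e-12)
})

test_that("the closed forms reproduce the explicit five-equation network solve", {
  set.seed(42)
  for (case in c("both_open", "mixed", "both_closed")) {
    for (i in 1:8) {
      p_g <- runif(1, 28, 42); p_ev <- runif(1, 8, 12); p_r <- runif(1, 0, 2)
      Di <- runif(1, 80, 320); kappa <- runif(1, 0.1, 0.8)
      Lv <- runif(1, 8, 14)
      p1 <- switch(case,
                   both_open = runif(1, p_ev + 1, p_g - 8),
                   mixed = runif(1, p_r, p_ev),
                   both_closed = runif(1, p_r, p_ev - 1))
      p2 <- switch(case,
                   both_open = runif(1, p1, p_g - 5),
                   mixed = runif(1, p_ev + 0.5, p_g - 5),
                   both_closed = runif(1, p1, p_ev))
      eye <- eye_parameters(p_g, p_ev, p_r)
      geo <- implant_geometry(Di, Lv)
      expect_equal(
        required_resistance_ratio(eye, geo, p1, p2),
        oracle_resistance_ratio(p_g, p_ev, p_r, eye$Q_0, eye$mu, Di, Lv,
                                kappa, p1, p2),
        tolerance = 1e-9, info = case)
    }
  }
})

test_that("the large-p_g approximation converges to the exact both-open ratio", {
  geo <- narrow_tube()
  rel <- vapply(c(40, 160, 640, 2560), function(pg) {
    eye <- eye_parameters(p_g = pg)
    exact <- required_resistance_ratio(eye, geo, 12, 14)
    approx <- required_resistance_ratio(eye, geo, 12, 14, approximate = TRUE)
    abs(approx / exact - 1)
  }, numeric(1))
  expect_true(all(diff(rel) < 0))
  expect_lt(rel[length(rel)], 5e-3)
})

test_that("forward and inverse suture solvers round-trip", {
  set.seed(7)
  eye <- ref_eye()
  for (i in 1:12) {
    geo <- implant_geometry(runif(1, 80, 200), runif(1, 8, 14))
    pl <- sample(c("concentric", "wall_touching"), 1)
    p1 <- runif(1, 2, 16)
    p2 <- p1 + runif(1, 0.2, min(6, eye$p_g - p1 - 8))
    sol <- suture_diameter_for_target(eye, geo, p1, p2, pl)
    expect_true(sol$upper_bound)
    fwd <- predicted_iop_after_suture(eye, geo, p1,
                                      suture_config(sol$D_s, pl))
    expect_equal(fwd$p_c2, p2, tolerance = 1e-4,
                 info = sprintf("%s D_i=%.0f p1=%.2f", pl, geo$inner_diameter, p1))
    expect_identical(fwd$case, sol$case)
  }
})

test_that("a trivial or absent suture leaves the IOP unchanged", {
  eye <- ref_eye()
  geo <- narrow_tube()
  for (p1 in c(4, 10.5, 14)) {
    fwd <- predicted_iop_after_suture(eye, geo, p1, suture_config(0, "concentric"))
    expect_equal(fwd$p_c2, p1, tolerance = 1e-12)
    inv <- suture_diameter_for_target(eye, geo, p1, p1)
    expect_identical(inv$D_s, 0)
  }
})

test_that("thin sutures barely move the IOP in a wide-bore tube", {
  # a free suture settles against the wall; up to 250 um it changes the
  # IOP of a 305 um tube by less than half a mm Hg
  eye <- ref_eye()
  for (p1 in c(2, 5, 10)) {
    for (ds in c(100, 200, 250)) {
      fwd <- predicted_iop_after_suture(eye, baerveldt(), p1,
                                        suture_config(ds, "wall_touching"))
      expect_lt(fwd$p_c2 - p1, 0.5)
    }
  }
  # a rise of several mm Hg needs the suture close to the bore diameter
  big <- predicted_iop_after_suture(eye, baerveldt(), 4,
                                    suture_config(290, "wall_touching"))
  expect_gt(big$p_c2 - big$p_c1, 2)
})

test_that("the both-closed prediction equals the tube drop difference", {
  eye <- ref_eye()
  geo <- narrow_tube()
  sut <- suture_config(35, "concentric")
  fwd <- predicted_iop_after_suture(eye, geo, 4, sut)
  expect_identical(fwd$case, "both_closed")
  delta_direct <- tube_pressure_drop(eye$Q_0, geo, sut) -
    tube_pressure_drop(eye$Q_0, geo)
  expect_equal(fwd$p_c2 - fwd$p_c1, delta_direct, tolerance = 1e-12)
})

test_that("the predicted IOP rises monotonically with the suture diameter", {
  eye <- ref_eye()
  geo <- narrow_tube()
  for (pl in c("concentric", "wall_touching")) {
    p2 <- vapply(seq(5, 90, by = 5), function(ds) {
      predicted_iop_after_suture(eye, geo, 5, suture_config(ds, pl))$p_c2
    }, numeric(1))
    expect_true(all(diff(p2) > 0), info = pl)
  }
})

test_that("forward prediction is continuous in p_c1 across case boundaries", {
  eye <- ref_eye()
  sut <- suture_config(30, "concentric")
  p1 <- seq(2, 20, by = 0.01)
  p2 <- vapply(p1, function(p) {
    predicted_iop_after_suture(eye, narrow_tube(), p, sut)$p_c2
  }, numeric(1))
  cases <- vapply(p1, function(p) {
    predicted_iop_after_suture(eye, narrow_tube(), p, sut)$case
  }, character(1))
  expect_identical(sort(unique(cases)), c("both_closed", "both_open", "mixed"))
  # no jumps anywhere, including at the case switches
  expect_lt(max(abs(diff(p2))), 0.05)
})

test_that("infeasible correction targets raise typed errors", {
  eye <- ref_eye()
  geo <- narrow_tube()
  expect_error(required_resistance_ratio(eye, geo, 8, 5),
               class = "iopflow_infeasible_error")
  expect_error(required_resistance_ratio(eye, geo, 8, eye$p_g),
               class = "iopflow_infeasible_error")
  expect_error(predicted_iop_after_suture(eye, geo, eye$p_g + 1,
                                          suture_config(20, "concentric")),
               class = "iopflow_infeasible_error")
})
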