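test_that("a wide-bore implant pins the IOP to the bleb pressure", {
  eye <- ref_eye()
  for (pb in c(0, 2, 5, 8, 10.5)) {
    st <- post_implant_state(eye, baerveldt(), bleb_pressure = pb)
    expect_lt(st$p_c - st$p_b, 0.01)
    expect_gte(st$p_c, st$p_b)
  }
})

test_that("mass is conserved and the regime flag matches the pressures", {
  eye <- ref_eye()
  for (pb in seq(0, 30, by = 2.5)) {
    for (di in c(60, 100, 305)) {
      st <- post_implant_state(eye, implant_geometry(di, 11), bleb_pressure = pb)
      expect_equal(st$Q_i + st$Q_tm, eye$Q_0, tolerance = 1e-9)
      if (st$regime == "trabecular_closed") {
        expect_lte(st$p_c, eye$p_ev + 1e-9)
        expect_equal(st$Q_tm, 0)
      } else {
        expect_gt(st$p_c, eye$p_ev)
        expect_gt(st$Q_tm, 0)
      }
      expect_gte(st$p_c, st$p_b)
    }
  }
})

test_that("the closed-regime IOP equals bleb pressure plus the tube drop", {
  eye <- ref_eye()
  geo <- implant_geometry(100, 11)
  sut <- suture_config(35, "concentric")
  st <- post_implant_state(eye, geo, sut, bleb_pressure = 2)
  expect_identical(st$regime, "trabecular_closed")
  expect_equal(st$p_c, st$p_b + tube_pressure_drop(eye$Q_0, geo, sut),
               tolerance = 1e-12)
})

test_that("IOP is continuous across the open/closed regime boundary", {
  eye <- ref_eye()
  geo <- implant_geometry(60, 11)
  # locate the bleb pressure at which p_c crosses p_ev, then probe both sides
  f <- function(pb) post_implant_state(eye, geo, bleb_pressure = pb)$p_c - eye$p_ev
  pb_star <- uniroot(f, c(0, eye$p_ev), tol = 1e-12)$root
  eps <- 1e-6
  lo <- post_implant_state(eye, geo, bleb_pressure = pb_star - eps)
  hi <- post_implant_state(eye, geo, bleb_pressure = pb_star + eps)
  expect_lt(abs(lo$p_c - hi$p_c), 1e-4)
  expect_false(lo$regime == hi$regime)
})

test_that("design formulas round-trip through the forward state solver", {
  eye <- ref_eye()
  cases <- list(list(target = 14, pb = 8),   # trabecular open
                list(target = 6, pb = 2))    # trabecular closed
  for (cs in cases) {
    dh <- design_hydraulic_diameter(eye, length = 11, shape_factor = 1,
                                    target_p_c = cs$target, bleb_pressure = cs$pb)
    st <- post_implant_state(eye, implant_geometry(dh, 11), bleb_pressure = cs$pb)
    expect_equal(st$p_c, cs$target, tolerance = 1e-9)
    lv <- design_length(eye, hydraulic_diameter = 150, shape_factor = 1,
                        target_p_c = cs$target, bleb_pressure = cs$pb)
    st2 <- post_implant_state(eye, implant_geometry(150, lv), bleb_pressure = cs$pb)
    expect_equal(st2$p_c, cs$target, tolerance = 1e-9)
  }
})

test_that("design limits behave as the network predicts", {
  eye <- ref_eye()
  # vanishing allowed drop needs an enormous bore; tiny bore nears p_g
  expect_gt(design_hydraulic_diameter(eye, 11, 1, 8 + 1e-9, 8), 1e4)
  expect_lt(design_hydraulic_diameter(eye, 11, 1, eye$p_g - 1e-6, 8), 20)
  expect_equal(design_length(eye, 150, 1, target_p_c = 3, bleb_pressure = 3), 0)
  # closed-regime length is linear in the allowed drop
  l1 <- design_length(eye, 100, 1, target_p_c = 4, bleb_pressure = 2)
  l2 <- design_length(eye, 100, 1, target_p_c = 6, bleb_pressure = 2)
  expect_equal(l2 / l1, 2, tolerance = 1e-12)
  expect_error(design_hydraulic_diameter(eye, 11, 1, 5, 8),
               class = "iopflow_infeasible_error")
  expect_error(design_hydraulic_diameter(eye, 11, 1, eye$p_g + 1, 8),
               class = "iopflow_infeasible_error")
})

test_that("bleb resistance follows from an observed state and scales linearly", {
  eye <- ref_eye()
  st <- post_implant_state(eye, implant_geometry(60, 11), bleb_pressure = 6)
  rb <- bleb_resistance_from_state(st, p_r = 0)
  expect_equal(rb, (st$p_b - 0) / st$Q_i)
  expect_equal(bleb_resistance_from_state(st, p_r = 3) / ((st$p_b - 3) / st$Q_i), 1)
  st0 <- post_implant_state(eye, implant_geometry(60, 11), bleb_pressure = 0)
  expect_error(bleb_resistance_from_state(st0, p_r = 0),
               class = "iopflow_domain_error")
  expect_error(post_implant_state(eye, baerveldt(), bleb_pressure = eye$p_g + 1),
               class = "iopflow_infeasible_error")
})
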