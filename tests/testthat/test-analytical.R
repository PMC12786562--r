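test_that("open-ring model reproduces the reference PTFE pressure table", {
  tab <- pressure_table(c(1.2, 1.4, 1.8))
  expect_equal(tab$loop_pressure_rounded, c(0.405, 0.476, 0.524))
  # closed-ring values from hand evaluation of the thick-ring formula
  expect_equal(round(tab$closed_ring_pressure[1], 4), 0.6757)
  expect_equal(round(tab$closed_ring_pressure[3], 4), 0.8741)
})

test_that("closed-ring pressure scales and degenerates correctly", {
  ptfe <- mat_ptfe()
  r0 <- ring_spec(0.8, 1.2, interference = 0)
  expect_equal(closed_ring_pressure(r0, ptfe), 0)
  # linear in interference and in E
  r1 <- ring_spec(0.8, 1.2, interference = 1e-3)
  r2 <- ring_spec(0.8, 1.2, interference = 2e-3)
  expect_equal(closed_ring_pressure(r2, ptfe),
               2 * closed_ring_pressure(r1, ptfe))
  stiff <- material("x", 2 * ptfe$youngs_modulus, ptfe$poisson)
  expect_equal(closed_ring_pressure(r1, stiff),
               2 * closed_ring_pressure(r1, ptfe))
  # monotone in OD at fixed ID, dr, theta
  p <- vapply(c(1.2, 1.4, 1.6, 1.8), function(od)
    open_ring_pressure(ring_spec(0.8, od), ptfe), 1.0)
  expect_true(all(diff(p) > 0))
})

test_that("compliance factor behaves as split-ring coverage fraction", {
  expect_identical(compliance_factor(360), 1)
  expect_equal(compliance_factor(216), 0.6)
  expect_equal(compliance_factor(180), 0.5)
  expect_error(compliance_factor(0), "domain")
  expect_error(compliance_factor(361), "domain")
  # partial ring never presses harder than the closed ring
  ptfe <- mat_ptfe()
  for (th in seq(10, 360, by = 50)) {
    rg <- ring_spec(0.8, 1.4, coverage_angle = th)
    expect_lte(open_ring_pressure(rg, ptfe),
               closed_ring_pressure(rg, ptfe))
  }
})

test_that("contact length and area match the covered-arc geometry", {
  full <- ring_spec(0.8, 1.2, coverage_angle = 360)
  expect_equal(contact_length(full), 2 * pi * 0.4)
  part <- ring_spec(0.8, 1.2, coverage_angle = 216)
  expect_equal(round(contact_length(part), 4), 1.508)
  expect_equal(round(contact_area(ring_spec(0.8, 1.2, band_width = 0.2)), 5),
               0.30159)
  expect_equal(round(contact_area(ring_spec(0.8, 1.2, band_width = 0.5)), 5),
               0.75398)
  expect_equal(contact_area(ring_spec(0.8, 1.2, band_width = 1,
                                      coverage_angle = 360)),
               2 * pi * 0.4)
})

test_that("pressure-force conversions invert exactly", {
  rg <- ring_spec(0.8, 1.0, band_width = 0.2, interference = 0)
  expect_equal(round(pressure_from_force(0.3, rg), 4), 0.9947)
  expect_equal(pressure_from_force(0, rg), 0)
  rg5 <- ring_spec(0.8, 1.0, band_width = 0.5, interference = 0)
  expect_equal(round(pressure_from_force(0.5, rg5), 4), 0.6631)
  # round trip to machine precision over a range of forces
  for (f in c(1e-4, 0.3, 0.5, 2)) {
    expect_equal(force_from_pressure(pressure_from_force(f, rg), rg), f,
                 tolerance = 1e-12)
  }
  # unit consistency: p = 1 MPa over Ac mm^2 gives Ac newtons
  expect_equal(force_from_pressure(1, rg), contact_area(rg))
  expect_error(force_from_pressure(-1, rg), "non-negative")
  expect_error(pressure_from_force(-0.1, rg), "non-negative")
})

test_that("geometry and material validation rejects bad inputs", {
  expect_error(ring_spec(0.8, 0.8), "outer_diameter")
  expect_error(ring_spec(0, 1.2), "inner_diameter")
  expect_error(ring_spec(0.8, 1.2, band_width = 0), "band_width")
  expect_error(ring_spec(0.8, 1.2, coverage_angle = 0), "domain")
  expect_error(material("x", -1, 0.3), "positive")
  expect_error(material("x", 100, 0.5), "poisson")
  b <- mat_cortical_bone()
  expect_equal(b$youngs_modulus, 14e3)
  expect_equal(b$strength_limits[["von_mises"]], 60)
  expect_equal(mat_ptfe()$strength_limits[["tensile"]], 25)
})

test_that("pressure_result is internally consistent", {
  rg <- ring_spec(0.8, 1.4)
  pr <- pressure_result(rg, mat_ptfe())
  expect_equal(pr$force, pr$loop_pressure * pr$contact_area, tolerance = 1e-14)
  expect_equal(pr$loop_pressure, pr$closed_ring_pressure * pr$compliance_factor)
})
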