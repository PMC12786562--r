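test_that("assembled stiffness is symmetric and kills rigid-body motion", {
  m <- box_mesh(1, 1, 1, 2, 2, 2)
  mats <- list(solid = material("m", 1000, 0.3))
  asm <- fe_assemble(m, mats)
  expect_lt(max(abs(asm$K - Matrix::t(asm$K))), 1e-10 * max(abs(asm$K)))
  # rigid translation carries zero strain energy
  nn <- nrow(m$nodes)
  u_rigid <- as.vector(t(matrix(c(1, 2, -3), nn, 3, byrow = TRUE)))
  energy <- as.numeric(u_rigid %*% (asm$K %*% u_rigid))
  expect_lt(abs(energy), 1e-8 * max(abs(asm$K)))
  expect_error(fe_assemble(m, list()), "missing material")
})

test_that("uniaxial patch test is exact for quadratic elements", {
  fx <- solve_uniaxial_box(sigma = 2, e = 1000, nu = 0.3)
  s <- fx$sol$stress
  expect_equal(max(abs(s[, 3] - 2)), 0, tolerance = 1e-9)
  expect_lt(max(abs(s[, c(1, 2, 4, 5, 6)])), 1e-9)
  # displacement field: uz = sigma/E * z
  uz_top <- fx$sol$u[patch_nodes(fx$mesh, "zmax"), 3]
  expect_equal(unname(uz_top), rep(2 / 1000, length(uz_top)),
               tolerance = 1e-9)
})

test_that("zero load produces zero displacement and stress", {
  m <- box_mesh(1, 1, 1, 1, 1, 1)
  mats <- list(solid = material("m", 1000, 0.3))
  sol <- solve_elastic(m, mats, numeric(3 * nrow(m$nodes)), "zmin")
  expect_equal(max(abs(sol$u)), 0)
  expect_equal(max(sol$von_mises), 0)
})

test_that("pressurized thick-walled cylinder matches the Lame solution", {
  e10 <- lame_cylinder_errors(0.1)
  expect_lt(e10$err_rr, 0.03)
  expect_lt(e10$err_tt, 0.03)
  e15 <- lame_cylinder_errors(0.15)
  expect_lt(e10$err_tt, e15$err_tt)   # converging under refinement
})

test_that("coaxial press-fit reproduces the closed-form interface pressure", {
  pf <- pressfit_result(size = 0.1)
  expect_true(pf$sol$converged)
  expect_equal(pf$total_force, pf$exact_force, tolerance = 0.05)
  # residual penetration below the augmentation tolerance
  expect_lt(pf$sol$contact$max_penetration,
            1e-3 * pf$sol$mesh$h * 1.0000001)
})

test_that("crimp force load integrates to the requested resultant", {
  mesh <- coarse_assembly()
  cf <- apply_crimp_force(mesh, 0.3)
  # integrated traction magnitude equals F exactly
  expect_equal(cf$mean_pressure * cf$area, 0.3, tolerance = 1e-12)
  # mean traction is the analytic F/Ac up to the outer-radius arc vs
  # inner-radius contact-arc ratio of the band geometry
  rg <- ring_spec(0.8, 1.2, band_width = 0.4, interference = 0)
  expect_equal(cf$mean_pressure, pressure_from_force(0.3, rg),
               tolerance = 0.30)
  expect_error(apply_crimp_force(mesh, -1), "non-negative")
})

test_that("contact solve balances reactions against the applied load", {
  sol <- solve_ti_case(force_mN = 300, size = 0.25)
  expect_true(sol$converged)
  f_app <- colSums(matrix(sol$f_ext, ncol = 3, byrow = TRUE))
  r <- reaction_force(sol)
  expect_equal(r, -f_app, tolerance = 0.005 * max(abs(f_app)))
  # the incus body is loaded by contact only: its contact resultant cancels
  # its support reaction
  mesh <- sol$mesh
  incus_nodes <- sort(unique(as.vector(
    mesh$elems[mesh$region == "incus", , drop = FALSE])))
  fc <- matrix(sol$contact$f_contact, ncol = 3, byrow = TRUE)
  fc_incus <- colSums(fc[incus_nodes, , drop = FALSE])
  r_incus <- reaction_force(sol, "fixed_posterior_incus")
  expect_equal(fc_incus, -r_incus, tolerance = 0.02 * max(abs(fc_incus)))
})

test_that("Coulomb friction condition holds pointwise", {
  sol <- solve_ti_case(force_mN = 400, size = 0.25, friction = 0.25)
  pr <- sol$contact$pairs
  act <- pr$active
  expect_true(any(act))
  expect_true(all(pr$tangential_traction[act] <=
                    0.25 * pr$pressure[act] + 1e-6))
})

test_that("doubling the crimp force doubles displacements once contact is closed", {
  s1 <- solve_ti_case(force_mN = 200, size = 0.3)
  s2 <- solve_ti_case(force_mN = 400, size = 0.3)
  i1 <- which.max(abs(s1$u))
  expect_equal(s2$u[i1] / s1$u[i1], 2, tolerance = 0.05)
})

test_that("load-case validation catches inconsistent inputs", {
  expect_error(load_case("crimp_force", pressure = 1), "crimp_force")
  expect_error(load_case("self_crimp_pressure", force = 1), "pressure")
  expect_error(load_case("crimp_force", force = -1), "non-negative")
  lc <- load_case("crimp_force", force = 0.3, large_deformation = TRUE)
  mesh <- coarse_assembly()
  expect_error(solve_contact(mesh, load = lc), "nonlinear")
})
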