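# Shared fixtures: small verification meshes and solves, built in code.

# uniaxial tension patch test on a small box; returns the solution and the
# applied axial stress
solve_uniaxial_box <- function(sigma = 2, e = 1000, nu = 0.3, order = 2) {
  m <- box_mesh(1, 1, 1, 2, 2, 2, order = order)
  mats <- list(solid = material("m", e, nu))
  f <- traction_load(m, "zmax", c(0, 0, sigma))
  tol <- 1e-9
  n <- m$nodes
  org <- which(rowSums(abs(n)) < tol)
  px <- which(abs(n[, 1] - 1) < tol & abs(n[, 2]) < tol & abs(n[, 3]) < tol)
  fixed <- sort(c(3L * patch_nodes(m, "zmin"),
                  3L * org - 2L, 3L * org - 1L, 3L * px - 1L))
  list(mesh = m, materials = mats, sigma = sigma,
       sol = solve_elastic(m, mats, f, fixed))
}

# pressurized thick-walled cylinder (90-degree symmetric sector, free ends:
# plane-stress Lame state); returns element-centroid polar stresses and the
# closed-form values at the centroids
lame_cylinder_errors <- function(size, ri = 0.4, ro = 0.8, p = 1,
                                 e = 14e3, nu = 0.3) {
  m <- tube_mesh(ri, ro, 0.4, size, coverage = 90, phi0 = pi / 4)
  mats <- list(solid = material("bone", e, nu))
  f <- pressure_load(m, "inner", p)
  tol <- 1e-9
  n <- m$nodes
  fix <- c(3L * which(abs(n[, 2]) < tol) - 1L,
           3L * which(abs(n[, 1]) < tol) - 2L,
           3L * which(abs(n[, 3]) < tol))
  sol <- solve_elastic(m, mats, f, fix)
  es <- element_stresses(sol)
  r <- sqrt(es$centroid[, 1]^2 + es$centroid[, 2]^2)
  cth <- es$centroid[, 1] / r
  sth <- es$centroid[, 2] / r
  s <- es$stress
  srr <- s[, 1] * cth^2 + s[, 2] * sth^2 + 2 * s[, 4] * cth * sth
  stt <- s[, 1] * sth^2 + s[, 2] * cth^2 - 2 * s[, 4] * cth * sth
  k <- p * ri^2 / (ro^2 - ri^2)
  stt_max <- k * (1 + ro^2 / ri^2)
  list(sol = sol,
       err_rr = max(abs(srr - k * (1 - ro^2 / r^2))) / p,
       err_tt = max(abs(stt - k * (1 + ro^2 / r^2))) / stt_max)
}

# coaxial press-fit: solid cylinder + interfering tube, frictionless contact;
# returns achieved vs closed-form total interface force
pressfit_result <- function(size = 0.1, R = 0.4, delta = 0.01, ro = 0.8,
                            L = 0.4, e = 14e3, nu = 0.3, friction = 0) {
  cyl <- cylinder_mesh(R, L, size)
  tb <- tube_mesh(R - delta, ro, L, size)
  m <- merge_meshes(cyl, tb, regions = c("inner", "outer"),
                    prefixes = c("c_", "t_"))
  mats <- list(inner = material("m", e, nu), outer = material("m", e, nu))
  n <- m$nodes
  tol <- 1e-9
  fix <- c(3L * which(abs(n[, 3]) < tol),
           3L * which(abs(n[, 2]) < tol & n[, 1] > 0) - 1L)
  sol <- solve_contact(m, mats,
                       load = list(f = numeric(3 * nrow(n)),
                                   fixed_patches = fix),
                       contact = contact_params(friction = friction),
                       pairs = list(c("t_inner", "c_lateral")),
                       nominal_gap = -delta)
  p_exact <- delta / (R * (((ro^2 + R^2) / (ro^2 - R^2) + nu) / e +
                             (1 - nu) / e))
  pr <- sol$contact$pairs
  list(sol = sol,
       total_force = sum(pr$pressure[pr$active] * pr$area[pr$active]),
       exact_force = p_exact * 2 * pi * R * L,
       p_exact = p_exact)
}

# one fast titanium crimp case on a coarse mesh
solve_ti_case <- function(force_mN = 300, width = 0.2, size = 0.25,
                          friction = 0.25) {
  ring <- ring_spec(0.8, 1.0, band_width = width, interference = 0)
  spec <- assembly_spec(ring, loop_material = mat_titanium())
  mesh <- build_assembly(spec, size)
  sol <- solve_contact(mesh,
                       load = load_case("crimp_force", force = force_mN / 1000),
                       contact = contact_params(friction = friction))
  sol
}

# hand-built constant-stress solution object for classification tests
fake_solution <- function(mesh, materials, vm_value = 10,
                          stress_row = c(-5, -5, -15, 0, 0, 0)) {
  nn <- nrow(mesh$nodes)
  stress <- matrix(rep(stress_row, each = nn), nn, 6)
  structure(list(mesh = mesh, materials = materials,
                 u = matrix(0, nn, 3), stress = stress,
                 von_mises = rep(vm_value, nn),
                 f_ext = numeric(3 * nn), fixed = integer(),
                 reactions = numeric(3 * nn), contact = NULL,
                 convergence_log = data.frame(), converged = TRUE),
            class = "stress_solution")
}

# small cached assembly mesh for postprocess tests
coarse_assembly <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- assembly_spec(ring_spec(0.8, 1.2))
      cache <<- build_assembly(spec, 0.3)
    }
    cache
  }
})
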