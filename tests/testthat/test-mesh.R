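test_that("assembly mesh is valid, tagged and deterministic", {
  spec <- assembly_spec(ring_spec(0.8, 1.2))
  mesh <- build_assembly(spec, 0.15)
  expect_s3_class(mesh, "assembly_mesh")
  expect_setequal(unique(mesh$region), c("incus", "loop", "shaft"))
  expect_equal(length(mesh$region), nrow(mesh$elems))
  q <- mesh_quality_report(mesh)
  expect_gt(q$min_volume, 0)
  expect_gt(q$min_scaled_jacobian, 0)
  for (pn in c("contact_inner_loop", "target_incus_surface",
               "fixed_posterior_incus", "fixed_shaft_tip",
               "loop_load_surface")) {
    expect_gt(nrow(mesh$patches[[pn]]$facets), 0)
  }
  # identical inputs give byte-identical meshes
  mesh2 <- build_assembly(spec, 0.15)
  expect_identical(mesh$nodes, mesh2$nodes)
  expect_identical(mesh$elems, mesh2$elems)
})

test_that("refinement grows the mesh monotonically", {
  spec <- assembly_spec(ring_spec(0.8, 1.2))
  coarse <- build_assembly(spec, 0.25)
  fine <- build_assembly(spec, 0.15)
  expect_gt(nrow(fine$elems), nrow(coarse$elems))
  expect_gt(nrow(fine$nodes), nrow(coarse$nodes))
})

test_that("meshed incus volume converges to the analytic cylinder volume", {
  v_exact <- pi * 0.4^2 * 3
  err <- vapply(c(0.15, 0.1), function(s) {
    m <- cylinder_mesh(0.4, 3, s)
    abs(mesh_volume(m) - v_exact) / v_exact
  }, 1.0)
  expect_lt(err[2], 0.02)      # within 2% at 0.1 mm resolution
  expect_lt(err[2], err[1])    # converging under refinement
})

test_that("target patch area matches the analytical contact area", {
  ring <- ring_spec(0.8, 1.2, band_width = 0.4)
  mesh <- build_assembly(assembly_spec(ring), 0.15)
  a_mesh <- sum(mesh$patches$target_incus_surface$area)
  expect_equal(a_mesh, contact_area(ring), tolerance = 0.05)
})

test_that("reference-scale discretization lands at the reported node count scale", {
  mesh <- build_assembly(assembly_spec(ring_spec(0.8, 1.2)), 0.05)
  expect_gt(nrow(mesh$nodes), 0.5 * 105403)
  expect_lt(nrow(mesh$nodes), 2.0 * 105403)
})

test_that("mesh quality report rejects degenerate input", {
  m <- coarse_assembly()
  empty <- m
  empty$elems <- m$elems[0, , drop = FALSE]
  expect_error(mesh_quality_report(empty), "empty")
  q <- mesh_quality_report(m)
  expect_true(q$median_scaled_jacobian >= q$min_scaled_jacobian)
})

test_that("invalid build parameters are rejected with clear errors", {
  spec <- assembly_spec(ring_spec(0.8, 1.2))
  expect_error(build_assembly(spec, 0.01), "target_element_size")
  expect_error(build_assembly(spec, 0.6), "target_element_size")
  expect_error(assembly_spec(ring_spec(0.8, 1.2), crimp_offset = 5),
               "crimp_offset")
  # band wider than the space in front of the crimp site
  wide <- ring_spec(0.8, 1.2, band_width = 2.8)
  expect_error(build_assembly(assembly_spec(wide), 0.15), "band")
})

test_that("MSH round trip preserves nodes, elements and patches", {
  mesh <- coarse_assembly()
  f <- tempfile(fileext = ".msh")
  write_msh(mesh, f)
  back <- read_msh(f)
  expect_equal(back$nodes, unname(mesh$nodes), tolerance = 1e-9)
  expect_equal(unname(back$elems), unname(mesh$elems))
  expect_equal(sort(unique(back$region)), sort(unique(mesh$region)))
  expect_true(all(names(mesh$patches) %in% names(back$patch_facets)))
  expect_equal(nrow(back$patch_facets$target_incus_surface),
               nrow(mesh$patches$target_incus_surface$facets))
  unlink(f)
})

test_that("VTK export writes a structurally complete file", {
  mesh <- coarse_assembly()
  f <- tempfile(fileext = ".vtk")
  write_vtk(mesh, f, point_data = list(field = seq_len(nrow(mesh$nodes))))
  ln <- readLines(f)
  expect_true(any(grepl(sprintf("POINTS %d double", nrow(mesh$nodes)), ln)))
  expect_true(any(grepl(sprintf("CELL_TYPES %d", nrow(mesh$elems)), ln)))
  expect_true(any(grepl("SCALARS field", ln)))
  unlink(f)
})
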