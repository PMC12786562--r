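test_that("principal decomposition handles canonical states", {
  expect_equal(unname(principal_stresses(c(3, 2, 1, 0, 0, 0))), c(3, 2, 1))
  # hydrostatic compression: equal principals, zero von Mises
  p <- principal_stresses(c(-7, -7, -7, 0, 0, 0))
  expect_equal(unname(p), c(-7, -7, -7))
  expect_equal(von_mises_principal(p), 0)
  # pure shear tau = 5 on one plane: (5, 0, -5), von Mises sqrt(3)*tau
  ps <- principal_stresses(c(0, 0, 0, 5, 0, 0))
  expect_equal(unname(ps), c(5, 0, -5), tolerance = 1e-12)
  expect_equal(von_mises_principal(ps), sqrt(3) * 5, tolerance = 1e-12)
  expect_equal(round(von_mises_principal(ps), 4), 8.6603)
  expect_error(principal_stresses(matrix(c(1, 2, 0, 0, 1, 0, 0, 0, 1), 3, 3)),
               "non-symmetric")
  expect_error(principal_stresses(1:4), "Voigt")
})

test_that("principal values are frame-invariant and von Mises-consistent", {
  set.seed(42)
  for (i in 1:20) {
    v <- rnorm(6, sd = 10)
    p <- principal_stresses(v)
    expect_equal(von_mises_principal(p), von_mises(v), tolerance = 1e-9)
    # random rotation Q via QR of a gaussian matrix
    q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    t0 <- matrix(c(v[1], v[4], v[6], v[4], v[2], v[5], v[6], v[5], v[3]), 3, 3)
    tr <- q %*% t0 %*% t(q)
    pr <- principal_stresses((tr + t(tr)) / 2)
    expect_equal(unname(pr), unname(p), tolerance = 1e-9 * max(1, max(abs(p))))
  }
})

test_that("risk classification is total and thresholds are sharp", {
  expect_identical(risk_class(10, 60), "safe")
  expect_identical(risk_class(61, 60), "exceeds_threshold")
  expect_identical(risk_class(0.85 * 60, 60), "near_threshold")
  expect_identical(risk_class(60, 60), "near_threshold")
  expect_identical(risk_class(0, 60), "safe")
  expect_error(risk_class(Inf, 60), "finite")
  expect_error(risk_class(-1, 60), "finite")
})

test_that("solution summary classifies constructed stress fields", {
  mesh <- coarse_assembly()
  mats <- list(incus = mat_cortical_bone(), loop = mat_ptfe(),
               shaft = mat_ptfe())
  # constant 10 MPa field: safe, ratio 1/6
  sol <- fake_solution(mesh, mats, vm_value = 10)
  rep <- summarize_solution(sol, config_id = "const10")
  expect_identical(rep$risk_class, "safe")
  expect_equal(rep$ratio_bone, 10 / 60, tolerance = 1e-12)
  expect_equal(round(rep$ratio_bone, 4), 0.1667)
  expect_equal(rep$peak_incus_von_mises, 10)
  expect_equal(rep$mean_contact_von_mises, 10)
  # one contact-region node at 61 MPa: exceeds threshold
  sol2 <- fake_solution(mesh, mats, vm_value = 10)
  tg <- patch_nodes(mesh, "target_incus_surface")[1]
  sol2$von_mises[tg] <- 61
  rep2 <- summarize_solution(sol2, config_id = "spike")
  expect_identical(rep2$risk_class, "exceeds_threshold")
  # dominant compressive mode from principal signs at the peak
  sol3 <- fake_solution(mesh, mats, vm_value = 10,
                        stress_row = c(5, -10, -50, 0, 0, 0))
  rep3 <- summarize_solution(sol3)
  expect_identical(rep3$dominant_stress_mode, "compressive")
  expect_equal(rep3$principal_s3, -50)
  # unconverged solutions are rejected
  sol4 <- fake_solution(mesh, mats)
  sol4$converged <- FALSE
  expect_error(summarize_solution(sol4), "unconverged|convergence_log")
})
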