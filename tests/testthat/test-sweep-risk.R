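test_that("default grid matches the 12-case study design", {
  grid <- sweep_grid()
  expect_length(grid, 12)
  mats <- vapply(grid, function(g) g$material, "")
  expect_equal(sum(mats == "ptfe"), 3)
  expect_equal(sum(mats == "titanium"), 9)
  # PTFE cases carry the analytical self-crimp pressure
  p <- vapply(grid[mats == "ptfe"], function(g) g$pressure, 1.0)
  expect_equal(round(p, 3), c(0.405, 0.476, 0.524))
  f <- vapply(grid[mats == "titanium"], function(g) g$force_mN, 1.0)
  expect_setequal(unique(f), c(300, 400, 500))
})

test_that("empty grid yields an empty table", {
  out <- run_sweep(structure(list(), class = "sweep_grid"))
  expect_s3_class(out, "sweep_result")
  expect_equal(nrow(out), 0)
})

test_that("piecewise-linear response interpolates and extrapolates", {
  resp <- stress_force_response(c(300, 400, 500), c(30, 40, 50))
  expect_equal(resp(350), 35)
  expect_equal(resp(300), 30)
  expect_equal(resp(600), 60)   # boundary-slope extrapolation
  expect_equal(resp(0), 0)
  expect_error(stress_force_response(c(300, 300), c(1, 2)))
})

test_that("bisection finds the admissible-force window edge", {
  # synthetic linear response 0.12 MPa/mN: 60 MPa at exactly 500 mN
  lin <- function(f) 0.12 * f
  expect_equal(max_safe_force(lin, 60, tol = 0.01), 500, tolerance = 0.02)
  # limit never reached: upper bracket returned
  expect_equal(max_safe_force(lin, Inf), 1300)
  # limit already exceeded at lower bracket
  expect_error(max_safe_force(function(f) f + 100, 50, bracket = c(200, 800)),
               "bracket")
  # non-monotone response aborts
  expect_error(max_safe_force(function(f) sin(f / 50), 0.5), "non-monotone")
  # agreement with a brute-force fine grid scan on a nonlinear response
  nl <- function(f) 1e-4 * f^1.7
  lim <- nl(432.1)
  grid <- seq(0, 1300, by = 0.05)
  brute <- max(grid[nl(grid) <= lim])
  expect_equal(max_safe_force(nl, lim, tol = 0.05), brute, tolerance = 0.2)
})

test_that("truncated-normal draws respect bounds and seeds", {
  d <- force_dist_junior()
  expect_equal(d$mean, 433)
  expect_equal(d$sd, 334)
  set.seed(7)
  f <- draw_forces(d, 5000)
  expect_true(all(f >= 0 & f <= 1300))
  expect_error(force_distribution(100, 0), "sd")
  expect_error(force_distribution(100, 10, lower = 5, upper = 2), "upper")
})

test_that("Monte-Carlo exceedance matches the truncated-normal oracle", {
  d <- force_distribution(433, 334, lower = 0, upper = 1300)
  lin <- function(f) 0.12 * f            # limit at exactly 500 mN
  limit <- lin(500)
  est <- exceedance_probability(d, lin, limit = limit, n_draws = 1e5,
                                seed = 11)
  p_oracle <- ptrunc_exceed(d, 500)
  expect_lt(abs(est$probability - p_oracle), 3 * est$standard_error)
  # reproducibility under a fixed seed
  est2 <- exceedance_probability(d, lin, limit = limit, n_draws = 1e5,
                                 seed = 11)
  expect_identical(est$probability, est2$probability)
  # Monte-Carlo error shrinks with n (binomial SE scaling)
  est_small <- exceedance_probability(d, lin, limit = limit, n_draws = 1e3,
                                      seed = 11)
  expect_lt(est$standard_error, est_small$standard_error)
  expect_lt(abs(est_small$probability - p_oracle),
            3 * est_small$standard_error + 1e-12)
  # degenerate narrow distribution below the window edge: probability 0
  dn <- force_distribution(300, 1e-6)
  expect_equal(exceedance_probability(dn, lin, limit = limit,
                                      n_draws = 1e3, seed = 1)$probability, 0)
  expect_error(exceedance_probability(d, lin, n_draws = 10), "1000")
})

test_that("reference peak table flags threshold-sensitive configurations", {
  ref <- reference_peaks()
  expect_equal(nrow(ref), 12)
  # every 500 mN titanium entry straddles the 60 MPa limit within the band
  s500 <- ref$force_mN == 500 & !is.na(ref$force_mN)
  expect_true(all(ref$threshold_sensitive[s500]))
  # the 400 mN wide-band case (53 MPa) is sensitivity-flagged too
  expect_true(ref$threshold_sensitive[which(ref$force_mN == 400 &
                                              ref$band_width == 0.5)])
  # 300 mN cases are safely below the limit even at the band top
  s300 <- ref$force_mN == 300 & !is.na(ref$force_mN)
  expect_true(all(!ref$threshold_sensitive[s300]))
  expect_true(all(ref$band_lower < ref$reference_peak))
})
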