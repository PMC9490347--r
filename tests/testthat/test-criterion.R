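test_that("kink geometry follows the fixed-length construction", {
  g0 <- kink_geometry(0, n = 3, L = 5)
  expect_equal(g0$D, 0)
  expect_equal(g0$theta_t, 0)
  expect_equal(g0$l_t, 5 / 6)

  g <- kink_geometry(0.1, n = 2, L = 5)
  expect_equal(g$D, sqrt(0.1 * 9.9) / 4)
  expect_equal(g$theta_t, atan(4 * g$D / 4.9))
  expect_equal(g$l_t, 4.9 / 4)

  # the zig-zag conserves arc length: 2n flanks of sqrt(l_t^2 + D^2) sum
  # to L exactly, for any Delta (l_t^2 + D^2 = (L/2n)^2 identically)
  for (Delta in c(1e-3, 0.4, 2)) {
    gg <- kink_geometry(Delta, n = 2, L = 5)
    expect_equal(2 * 2 * sqrt(gg$l_t^2 + gg$D^2), 5, tolerance = 1e-12)
  }

  expect_error(kink_geometry(5, n = 1, L = 5), "Delta")
})

test_that("closed-form kink spring energy matches quadrature of the flank integral", {
  expect_equal(kink_spring_energy(0, 2, 5, 2), 0)
  for (case in list(c(0.2, 2, 5, 2), c(0.05, 1, 3, 1), c(0.6, 4, 5, 3))) {
    cf <- kink_spring_energy(case[1], case[2], case[3], case[4])
    qd <- kink_spring_quadrature(case[1], case[2], case[3], case[4])
    expect_lt(abs(cf - qd) / qd, 1e-8)
  }
  # linear in K
  expect_equal(kink_spring_energy(0.3, 4, 5, 2),
               2 * kink_spring_energy(0.3, 2, 5, 2))
})

test_that("the neighbour-decay factor cancels from the spring strain ratio", {
  # scaling both the deformation and the rest separation by the lateral
  # decay factor leaves the energy unchanged: the criterion cannot depend
  # on the filament count through it
  for (f in c(1 / 9, 1 / 3, 2)) {
    expect_equal(kink_spring_quadrature(0.2, 2, 5, 2, m_factor = f),
                 kink_spring_quadrature(0.2, 2, 5, 2, m_factor = 1),
                 tolerance = 1e-10)
  }
})

test_that("kink bending energy has the printed form and small-displacement slope", {
  expect_equal(kink_bending_energy(0, 1, 5, 2), 0)
  D <- sqrt(0.1 * 9.9) / 4
  expect_equal(kink_bending_energy(0.1, 1, 5, 2),
               (2 * 4 / 4.9) * tan(2 * atan(4 * D / 4.9))^2)
  # d(Eb)/dDelta at 0 equals the bending term of the excess load
  h <- 1e-7
  slope <- kink_bending_energy(h, 1, 5, 2) / h
  expect_equal(slope, 16 * 4 / 25, tolerance = 1e-3)
  # spring slope likewise equals K L / n^2
  slope_e <- kink_spring_energy(h, 2, 5, 2) / h
  expect_equal(slope_e, 2 * 5 / 4, tolerance = 1e-5)
})

test_that("excess load assembles both slopes and has the stated limits", {
  expect_equal(excess_load(2, K = 2, B_in = 1, L = 5), 10 / 4 + 64 / 25)
  expect_equal(excess_load(3, K = 0, B_in = 1, L = 5), 16 * 9 / 25)
  expect_gt(excess_load(40, 2, 1, 5), excess_load(4, 2, 1, 5))  # diverges in n
  # total kink energy slope at Delta = 0 equals N_e(n) (stationarity at the
  # critical excess load), by numerical derivative
  h <- 1e-8
  num <- (kink_spring_energy(h, 2, 5, 2) + kink_bending_energy(h, 1, 5, 2)) / h
  expect_equal(num, excess_load(2, 2, 1, 5), tolerance = 1e-4)
})

test_that("optimal mode minimizes the excess load with prefactor 8", {
  om <- optimal_mode(K = 2, B_in = 1, L = 5)
  expect_equal(om$n_star, 2^0.25 * 5^0.75 / 2, tolerance = 1e-12)
  expect_equal(om$n_star, 1.988, tolerance = 1e-3)
  expect_equal(om$Ne_star, 8 * sqrt(2 / 5), tolerance = 1e-12)

  # brute force over integers never undercuts the continuous minimum, and
  # the best integer is adjacent to n_star
  for (K in c(0.5, 2, 8)) {
    om <- optimal_mode(K, 1, 5)
    expect_gte(om$Ne_int, om$Ne_star)
    expect_lte(abs(om$n_int - om$n_star), 1)
    # numeric minimization agrees with the closed form
    opt <- stats::optimize(function(n) excess_load(n, K, 1, 5), c(0.1, 60))
    expect_equal(opt$minimum, om$n_star, tolerance = 1e-4)
    expect_equal(opt$objective / sqrt(K * 1 / 5), 8, tolerance = 1e-7)
  }
})

test_that("analytic critical load reduces to the Euler load as K -> 0", {
  expect_equal(analytic_critical_load(K = 0, B_in = 1, L = 5, ne = 1),
               pi^2 / 25)
  expect_equal(pi^2 / 25, 0.395, tolerance = 1e-3)
  expect_equal(analytic_critical_load(2, 1, 5, alpha = 10.61, ne = 2),
               10.61 * sqrt(0.4) + 4 * pi^2 / 25)
  expect_equal(euler_mode("pinned"), 1L)
  expect_equal(euler_mode("clamped"), 2L)
})

test_that("alpha fitting inverts exact synthetic records and flags sub-Euler ones", {
  recs <- tidyr::expand_grid(K = c(1, 2, 4), L = c(3, 5)) |>
    dplyr::mutate(B_in = 1, ne = 2,
                  Nc_star = analytic_critical_load(K, B_in, L, alpha = 9, ne = 2))
  fit <- fit_alpha(recs)
  expect_equal(fit$alpha, 9, tolerance = 1e-12)
  expect_true(all(abs(tidy(fit)$alpha - 9) < 1e-12))

  bad <- dplyr::bind_rows(recs,
                          tibble::tibble(K = 1, B_in = 1, L = 5, ne = 2,
                                         Nc_star = 0.1))
  fitb <- fit_alpha(bad)
  expect_equal(sum(tidy(fitb)$excluded), 1)
  expect_equal(fitb$alpha, 9, tolerance = 1e-12)
  expect_error(fit_alpha(tibble::tibble(K = 1)), "missing columns")
})

test_that("the stability probe locates the pinned Euler load sharply", {
  p <- bundle_params(m = 6, n = 80, L = 5, K = 1e-6, boundary = "pinned")
  below <- stability_curvature(update_params(p, Nc = 0.38))
  above <- stability_curvature(update_params(p, Nc = 0.41))
  expect_gt(below, 0)
  expect_lt(above, 0)
  cl <- numerical_critical_load(p, bracket = c(0.3, 0.5), tol = 0.005,
                                mode = "any")
  expect_equal(cl$value, pi^2 / 25, tolerance = 0.02)
  expect_s3_class(cl$trace, "tbl_df")
})

test_that("the detected buckling load converges to the Euler limit with resolution", {
  err <- vapply(c(50, 100, 200), function(n) {
    p <- bundle_params(m = 10, n = n, L = 5, K = 1e-6, B_in = 1, B_r = 1,
                       Np = 0, boundary = "pinned")
    cl <- numerical_critical_load(p, bracket = c(0.3, 0.5), tol = 0.003,
                                  mode = "any")
    abs(cl$value - pi^2 / 25) / (pi^2 / 25)
  }, numeric(1))
  expect_true(all(err < 0.02))
})

test_that("bisection refuses brackets that do not straddle the transition", {
  p <- bundle_params(m = 6, n = 60, L = 5, K = 1e-6, boundary = "pinned")
  expect_error(numerical_critical_load(p, bracket = c(0.05, 0.2), tol = 0.05,
                                       mode = "any"),
               "not buckled")
  expect_error(numerical_critical_load(p, bracket = c(0.6, 0.9), tol = 0.05,
                                       mode = "any"),
               "already buckled")
})
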