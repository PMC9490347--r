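test_that("archetypal seeds have the advertised structure", {
  p <- bundle_params(m = 10, n = 40)
  expect_identical(seed_state(p, "undeformed"), rest_state(p))

  g <- seed_state(p, "global", amplitude = 0.02)
  expect_true(all(apply(g, 2, function(col) length(unique(col)) == 1)))
  expect_equal(pinching_parameter(p, g), 0)
  expect_equal(max(abs(g)), 0.02, tolerance = 1e-3)

  pn <- seed_state(p, "pinched", amplitude = 0.02)
  expect_equal(pinching_parameter(p, pn), 1)

  it <- seed_state(p, "internal", amplitude = 0.02)
  expect_equal(it[1, ], rep(0, p$n))   # outer filaments exactly straight
  expect_equal(it[p$m, ], rep(0, p$n))
  expect_gt(max(abs(it[5, ])), 0)

  expect_error(seed_state(p, "wobbly"))
})

test_that("perturbation is reproducible and leaves the global RNG untouched", {
  p <- small_params()
  set.seed(999)
  before <- .Random.seed
  a <- perturb_state(p, amplitude = 1e-3, seed = 7)
  expect_identical(.Random.seed, before)
  b <- perturb_state(p, amplitude = 1e-3, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, perturb_state(p, amplitude = 1e-3, seed = 8)))
  expect_lte(max(abs(a)), 1e-3)
})

test_that("minimization from rest with no loads stays at rest", {
  p <- bundle_params(m = 6, n = 30, K = 2)
  fit <- minimize_energy(p, rest_state(p))
  expect_true(fit$converged)
  expect_equal(fit$energy$total, 0, tolerance = 1e-10)
  expect_true(all(abs(fit$theta) < 1e-8))
})

test_that("a pinned bundle above the Euler load buckles globally from a perturbed start", {
  # Nc = 0.6 exceeds the pinned Euler criterion pi^2/25 ~ 0.395 (with room
  # for the O(1/n^2) diagonal-spring stiffening of the discrete lattice)
  p <- bundle_params(m = 10, n = 100, L = 5, K = 2, B_in = 1, B_r = 1,
                     Nc = 0.6, Np = 0, boundary = "pinned")
  fit <- minimize_energy(p, perturb_state(p, seed_state(p, "global"),
                                          amplitude = 1e-3, seed = 0),
                         tol = 1e-5, max_iter = 12000)
  cl <- classify_state(p, fit$theta)
  expect_equal(as.character(cl$label), "global")
  expect_lt(fit$energy$total, 10 * 0.6 * 5 - 1e-3)  # below the straight state
  # energy never rises above the seed's
  expect_lte(fit$energy$total, fit$seed_energy + 1e-8)
  # the returned point is stationary by the finite-difference oracle too
  sub <- fd_gradient(p, fit$theta)
  expect_lt(max(abs(sub)), 1e-3)
})

test_that("minimization errors on a non-finite starting state", {
  p <- bundle_params(m = 2, n = 3, L = 1)
  bad <- rbind(c(0, pi / 2, 0), c(0, 0, 0))
  expect_error(minimize_energy(p, bad), "non-finite")
})

test_that("minimization is deterministic for identical inputs", {
  p <- small_params(Nc = 0.8, boundary = "pinned")
  th0 <- perturb_state(p, amplitude = 1e-2, seed = 3)
  f1 <- minimize_energy(p, th0, tol = 1e-6)
  f2 <- minimize_energy(p, th0, tol = 1e-6)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$energy$total, f2$energy$total)
})

test_that("enumerate_minima finds a single undeformed minimum with no loads", {
  p <- bundle_params(m = 6, n = 30, K = 2, Nc = 0, Np = 0, B_r = 1)
  mins <- enumerate_minima(p, tol = 1e-5, max_iter = 6000)
  expect_equal(as.character(mins$label[1]), "undeformed")
  expect_true(all(mins$label == "undeformed"))
  expect_equal(nrow(mins), 1)  # identical-label results merged
  expect_equal(mins$energy[1], 0, tolerance = 1e-8)
})

test_that("clamped bundle below its Euler load keeps the undeformed minimum", {
  # Nc = 0.5 < 4 pi^2 / 25: global buckling suppressed by the clamped ends
  p <- bundle_params(m = 8, n = 50, L = 5, K = 2, Nc = 0.5, B_r = 1,
                     boundary = "clamped")
  mins <- enumerate_minima(p, tol = 1e-5, max_iter = 8000)
  expect_equal(as.character(mins$label[1]), "undeformed")
  expect_equal(mins$energy[1], 8 * 0.5 * 5, tolerance = 1e-6)
})

test_that("each archetypal seed relaxes to its own label inside its phase region", {
  base <- bundle_params(m = 10, n = 100, L = 5, K = 2, B_in = 1,
                        boundary = "clamped")
  cases <- list(
    undeformed = update_params(base, Nc = 0.5, Np = 0, B_r = 1),
    global = update_params(base, Nc = 5, Np = 0, B_r = 1),
    pinched = update_params(base, Nc = 0.5, Np = 0.3, B_r = 1),
    internal = update_params(base, Nc = 10, Np = 0, B_r = 1e4)
  )
  for (kind in names(cases)) {
    p <- cases[[kind]]
    fit <- minimize_energy(p, perturb_state(p, seed_state(p, kind),
                                            amplitude = 1e-3, seed = 0),
                           tol = 1e-5, max_iter = 12000)
    expect_equal(as.character(classify_state(p, fit$theta)$label), kind,
                 info = kind)
  }
})

test_that("glance and tidy summarize a fit", {
  p <- small_params(Nc = 0.2)
  fit <- minimize_energy(p, rest_state(p))
  gl <- glance(fit)
  expect_s3_class(gl, "tbl_df")
  expect_equal(as.character(gl$label), "undeformed")
  expect_equal(gl$energy, 4 * 0.2 * 5, tolerance = 1e-8)
  expect_true(all(c("moment_all", "pinch") %in% names(gl)))
  expect_equal(tidy(fit)$energy[tidy(fit)$term == "total"], gl$energy)
})
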