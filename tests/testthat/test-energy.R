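test_that("all penalty terms vanish at the rest state; loads give m*Nc*L exactly", {
  p <- bundle_params(m = 10, n = 50, L = 5, K = 2, Nc = 2, Np = 0.3)
  e <- bundle_energy(p, rest_state(p))
  for (term in c("Eb", "Ee1", "Ee1_plus", "Ee1_minus", "El2", "Ec1", "Ec2")) {
    expect_equal(e[[term]], 0, info = term)
  }
  expect_lt(e$Ee2, 1e-30)  # C1 exp(-C2) per triangle, utterly negligible
  expect_equal(e$El1, 10 * 2 * 5)
  expect_equal(e$total, 100, tolerance = 1e-12)
})

test_that("bending energy follows (B/2l) tan^2(dtheta) with B_r on outer rows", {
  # m = 2 so both filaments are "outer"; one bent joint each
  p <- bundle_params(m = 2, n = 2, L = 1, K = 0, B_in = 1, B_r = 1)
  l <- 1 / 2
  th <- rbind(c(0, pi / 4), c(0, 0))
  e <- bundle_energy(p, th)
  expect_equal(e$Eb, (1 / (2 * l)) * tan(pi / 4)^2, tolerance = 1e-12)
  expect_equal(e$Eb_filament, c(e$Eb, 0))

  # outer filament costs exactly B_r times an identically bent inner one
  p3 <- bundle_params(m = 3, n = 6, L = 3, K = 0, B_in = 2, B_r = 10)
  bend <- c(0, 0.1, 0.25, 0.2, -0.1, 0)
  outer_only <- rbind(bend, 0, 0)
  inner_only <- rbind(0, bend, 0)
  expect_equal(bundle_energy(p3, outer_only)$Eb,
               10 * bundle_energy(p3, inner_only)$Eb, tolerance = 1e-12)

  # turning angle of pi/2 is the fold singularity
  fold <- rbind(c(0, pi / 2), c(0, 0))
  expect_false(bundle_energy(p, fold)$finite)
})

test_that("spring energies are Hookean in the separation and linear in K", {
  # two filaments rigidly separated to 2*d0: translate the upper one up by d0
  p <- bundle_params(m = 2, n = 10, L = 5, K = 3, B_in = 1)
  d0 <- 1; l <- 0.5
  co <- coordinates_from_angles(p, rest_state(p))
  co$y[2, ] <- co$y[2, ] + d0
  d <- pair_distances(p, rest_state(p), coords = co)
  Ks <- p$K / p$L
  Ee1 <- sum(l * (Ks / 2) * ((d$d - d0) / d0)^2)
  expect_equal(Ee1, (p$n + 1) * l * (Ks / 2) * 1^2)
  dd <- sqrt(d0^2 + l^2)
  Ee1p <- sum(l * (Ks / 2) * ((d$d_plus - dd) / dd)^2)
  expect_equal(Ee1p, p$n * l * (Ks / 2) * ((sqrt(4 + l^2) - dd) / dd)^2,
               tolerance = 1e-12)

  # against the packaged terms on a deformed state: doubling K doubles springs
  ps <- small_params()
  th <- random_state(ps, seed = 2)
  e1 <- bundle_energy(ps, th)
  e2 <- bundle_energy(update_params(ps, K = 2 * ps$K), th)
  expect_equal(e2$Ee1, 2 * e1$Ee1, tolerance = 1e-12)
  expect_equal(e2$Ee1_plus, 2 * e1$Ee1_plus, tolerance = 1e-12)
  expect_equal(e2$Ee1_minus, 2 * e1$Ee1_minus, tolerance = 1e-12)
})

test_that("overlap penalty has the documented amplitude and onset", {
  p <- bundle_params()
  A0 <- param_derived(p)$A0
  g <- function(A) p$C1 * exp(-p$C2 * A / A0)
  expect_equal(g(0), 1e6)
  expect_equal(g(A0), 1e6 * exp(-100))
  # the "10% of rest size" onset at C2 = 100
  expect_equal(g(0.1 * A0), 1e6 * exp(-10), tolerance = 1e-12)
  expect_equal(g(0.1 * A0), 45.4, tolerance = 1e-3)
})

test_that("loading and constraint energies match direct evaluation", {
  p <- bundle_params(m = 10, n = 20, L = 5, Nc = 2, Np = 0)
  expect_equal(bundle_energy(p, rest_state(p))$El1, 100)

  # rigidly tilt the top filament down a touch: El2 responds linearly
  p2 <- bundle_params(m = 3, n = 10, L = 5, K = 0, Np = 0.2)
  th <- rest_state(p2)
  th[3, ] <- -0.01
  co <- coordinates_from_angles(p2, th)
  el2 <- sum(0.2 * (co$y[3, -1] - co$y[3, 1])) - sum(0 * co$y[2, -1])
  expect_equal(bundle_energy(p2, th)$El2, el2, tolerance = 1e-12)
  expect_equal(bundle_energy(update_params(p2, Np = 0), th)$El2, 0)

  # pinned-end penalty: 0.01 end deflection on one filament -> C3 * 1e-4
  p3 <- bundle_params(m = 2, n = 2, L = 2, K = 0, boundary = "pinned")
  delta <- 0.01
  a <- asin(delta / p3$L)  # uniform tilt: y_end - y_0 = L sin(a) = delta
  th3 <- rbind(c(a, a), c(0, 0))
  e3 <- bundle_energy(p3, th3)
  expect_equal(e3$Ec1, 1e5 * delta^2, tolerance = 1e-10)
  expect_equal(e3$Ec2, 0)  # pinned: no clamped term

  e3c <- bundle_energy(update_params(p3, boundary = "clamped"), th3)
  expect_equal(e3c$Ec2, 2 * 1e5 * a^2, tolerance = 1e-10)
})

test_that("breakdown components always sum to the total", {
  p <- small_params(Nc = 1, Np = 0.2, B_r = 7, boundary = "clamped")
  for (seed in 1:4) {
    e <- bundle_energy(p, random_state(p, amplitude = 0.3, seed = seed))
    parts <- e$Eb + e$Ee1 + e$Ee1_plus + e$Ee1_minus + e$Ee2 +
      e$El1 + e$El2 + e$Ec1 + e$Ec2
    expect_equal(e$total, parts, tolerance = 1e-12)
    expect_true(all(c(e$Eb, e$Ee1, e$Ee1_plus, e$Ee1_minus, e$Ee2,
                      e$Ec1, e$Ec2) >= 0))
  }
})

test_that("energy is invariant under the vertical mirror with reversed pinching", {
  # mirror: theta_ij -> -theta_(m+1-i)j together with the antisymmetric
  # pinching pattern is an isometry of the bundle
  p <- small_params(Nc = 0.7, Np = 0.25, boundary = "clamped")
  for (seed in 1:5) {
    th <- random_state(p, amplitude = 0.08, seed = seed)
    mirrored <- -th[rev(seq_len(p$m)), , drop = FALSE]
    a <- bundle_energy(p, th)
    b <- bundle_energy(p, mirrored)
    expect_equal(a$total, b$total, tolerance = 1e-12)
    # the mirror swaps the two diagonal spring families
    expect_equal(a$Ee1_plus, b$Ee1_minus, tolerance = 1e-12)
    expect_equal(a$Ee1_minus, b$Ee1_plus, tolerance = 1e-12)
  }
  # near contact the overlap penalty becomes split-convention dependent
  # (each quad is triangulated along its "+" diagonal, which the mirror
  # maps to the "-" diagonal); every other term remains exactly invariant
  tangle <- random_state(p, amplitude = 0.12, seed = 2)
  mt <- -tangle[rev(seq_len(p$m)), , drop = FALSE]
  a <- bundle_energy(p, tangle)
  b <- bundle_energy(p, mt)
  expect_equal(a$total - a$Ee2, b$total - b$Ee2, tolerance = 1e-12)
})

test_that("tidy() lays out the energy terms as a table", {
  p <- small_params(Nc = 1)
  td <- tidy(bundle_energy(p, rest_state(p)))
  expect_s3_class(td, "tbl_df")
  expect_equal(td$energy[td$term == "total"], 4 * 1 * 5)
})
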