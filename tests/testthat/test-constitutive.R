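test_that("material_params validates its invariants", {
  expect_s3_class(material_params(27.7, 0.774, 0.93, 1.8), "material_params")
  expect_error(material_params(0, 1, 1, 1), "alpha")
  expect_error(material_params(2, -1, 1, 1), "mu")
  expect_error(material_params(2, 1, 0, 1), "beta")
  expect_error(material_params(2, 1, 1, -0.1), "g_visc")
  # two-term Ogden round-trips
  p2 <- material_params(c(2, 5), c(0.5, 0.3), 1, 0)
  expect_equal(p2$n_terms, 2L)
})

test_that("ogden energy and stress match direct evaluation", {
  p <- material_params(2, 1, 1, 0)
  expect_equal(ogden_energy(p, 2), 1.0)          # (1/2)(4 + 2*(1/2) - 3)
  expect_equal(ogden_uniaxial_stress(p, 2), 3.5) # 2^2 - 2^-1
  # identified sclera at lambda = 1.02, frozen from high-precision
  # evaluation of 0.774*(1.02^27.7 - 1.02^-13.85)
  expect_equal(ogden_uniaxial_stress(ref_materials$sclera, 1.02),
               0.75123066, tolerance = 1e-7)
  # multi-term sums the terms
  p2 <- material_params(c(2, 4), c(1, 0.5), 1, 0)
  expect_equal(ogden_uniaxial_stress(p2, 1.3),
               1 * (1.3^2 - 1.3^-1) + 0.5 * (1.3^4 - 1.3^-2))
  expect_error(ogden_energy(p, -1), "stretch")
  expect_error(ogden_uniaxial_stress(p, 0), "stretch")
})

test_that("reference state is stress- and energy-free for random draws", {
  # admissible single-term parameters (mu > 0 pairs with alpha > 0 for a
  # convex energy)
  set.seed(42)
  for (i in 1:25) {
    p <- material_params(alpha = runif(1, 0.5, 40),
                         mu = runif(1, 0.01, 5),
                         beta = runif(1, 0.01, 5),
                         g_visc = runif(1, 0, 5))
    expect_equal(ogden_uniaxial_stress(p, 1), 0)
    expect_equal(ogden_energy(p, 1), 0)
    # energy positive away from the reference
    lam <- exp(runif(1, -0.3, 0.3))
    if (abs(lam - 1) > 1e-3)
      expect_gt(ogden_energy(p, lam), 0)
  }
})

test_that("energy derivative is consistent with the stress", {
  # uniaxial incompressible reduction: dW/dlambda = sigma / lambda
  p <- ref_materials$sclera
  h <- 1e-6
  for (lam in c(1.01, 1.03, 1.05)) {
    dW <- (ogden_energy(p, lam + h) - ogden_energy(p, lam - h)) / (2 * h)
    expect_equal(dW, ogden_uniaxial_stress(p, lam) / lam, tolerance = 1e-7)
  }
})

test_that("deformation_history validates and derives strain", {
  expect_error(deformation_history(c(0, 1, 1), c(1, 1.1, 1.2)),
               "increasing")
  expect_error(deformation_history(0, 1), "2 samples")
  expect_error(deformation_history(c(0, 1), c(1, -2)), "positive")
  h <- deformation_history(c(0, 1), c(1, 1.2))
  expect_equal(h$strain, c(0, 0.2))
  hl <- deformation_history(c(0, 1), c(1, 1.2), strain = "logarithmic")
  expect_equal(hl$strain, c(0, log(1.2)))
})

test_that("viscoelastic stress matches the constant-rate closed form", {
  # sigma_v(t) = (G r / beta) (1 - exp(-beta t)) for constant strain rate
  g <- 1.8; b <- 0.93; r <- 0.01
  err_at <- function(dt) {
    tt <- seq(0, 10, by = dt)
    h <- deformation_history(tt, 1 + r * tt)
    sv <- visco_stress(material_params(27.7, 0.774, b, g), h)
    max(abs(sv - (g * r / b) * (1 - exp(-b * tt))))
  }
  e1 <- err_at(0.02); e2 <- err_at(0.01)
  expect_lt(e1, 1e-6)
  expect_gt(e1 / e2, 3)   # second-order: halving dt ~quarters the error
  expect_lt(e1 / e2, 5)
  # plateau value G r / beta
  tt <- seq(0, 40, by = 0.01)
  sv <- visco_stress(material_params(27.7, 0.774, b, g),
                     deformation_history(tt, 1 + r * tt))
  expect_equal(sv[length(sv)], 0.019355, tolerance = 1e-4)
})

test_that("recursive convolution agrees with direct quadrature", {
  set.seed(3)
  for (i in 1:5) {
    g <- runif(1, 0.5, 3); b <- runif(1, 0.1, 3)
    tt <- seq(0, 4, length.out = 120)
    lam <- 1 + 0.05 * sin(seq(0, 3, length.out = 120)) +
      0.04 * seq(0, 1, length.out = 120)
    h <- deformation_history(tt, lam)
    sv <- visco_stress(material_params(2, 1, b, g), h)
    orc <- visco_direct_oracle(g, b, tt, h$strain)
    expect_lt(max(abs(sv - orc)) / max(abs(orc)), 1e-8)
  }
  # non-uniform grid falls back to the stepwise recursion: same oracle
  tt <- sort(c(0, cumsum(runif(80, 0.01, 0.1))))
  lam <- 1 + 0.02 * tt
  h <- deformation_history(tt, lam)
  sv <- visco_stress(material_params(2, 1, 0.7, 1.2), h)
  orc <- visco_direct_oracle(1.2, 0.7, tt, h$strain)
  expect_lt(max(abs(sv - orc)) / max(abs(orc)), 1e-8)
})

test_that("strain step decays as the analytic impulse response", {
  g <- 2; b <- 1.5; eps0 <- 0.03
  tt <- c(0, 1e-6, seq(0.1, 3, by = 0.1))
  lam <- c(1, rep(1 + eps0, length(tt) - 1))
  sv <- visco_stress(material_params(2, 1, b, g),
                     deformation_history(tt, lam))
  expect_equal(sv[-1], g * eps0 * exp(-b * (tt[-1] - 5e-7)),
               tolerance = 1e-3)
})

test_that("total stress combines parts and respects limits", {
  p0 <- material_params(27.7, 0.774, 0.93, 0)    # no viscous part
  tt <- seq(0, 2, by = 0.01)
  h <- deformation_history(tt, 1 + 0.02 * tt)
  expect_equal(total_uniaxial_stress(p0, h),
               ogden_uniaxial_stress(p0, h$stretch))
  # constant stretch 1: identically zero
  hc <- deformation_history(c(0, 1, 2), c(1, 1, 1))
  expect_equal(total_uniaxial_stress(ref_materials$sclera, hc),
               rep(0, 3))
  # rate stiffening: same final stretch, 1000x rate ratio
  p <- ref_materials$sclera
  slow <- deformation_history(seq(0, 1000, length.out = 400),
                              1 + 0.05 * seq(0, 1, length.out = 400))
  fast <- deformation_history(seq(0, 1, length.out = 400),
                              1 + 0.05 * seq(0, 1, length.out = 400))
  expect_true(all(total_uniaxial_stress(p, fast) >=
                  total_uniaxial_stress(p, slow) - 1e-12))
  # quasi-static limit: stress converges to the Ogden curve as rate -> 0
  ogden_end <- ogden_uniaxial_stress(p, 1.05)
  gap <- sapply(c(10, 100, 1000), function(Tend) {
    hh <- deformation_history(seq(0, Tend, length.out = 500),
                              1 + 0.05 * seq(0, 1, length.out = 500))
    abs(total_uniaxial_stress(p, hh)[500] - ogden_end)
  })
  expect_true(all(diff(gap) < 0))
  expect_lt(gap[3], 1e-3)
})
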