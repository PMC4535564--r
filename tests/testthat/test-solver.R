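test_that("pressure unit conversion is the defined constant", {
  expect_equal(mmhg_to_mpa(0), 0)
  expect_equal(mmhg_to_mpa(10), 1.33322e-3)
  expect_equal(mmhg_to_mpa(100), 1.33322e-2)
  expect_equal(mmhg_to_mpa(c(2, 4)), 2 * mmhg_to_mpa(c(1, 2)))
  expect_error(mmhg_to_mpa(-1), ">= 0")
})

test_that("zero load returns identically zero fields", {
  mesh <- build_sphere_mesh(refinement = 4)
  r <- solve_pressurized(mesh, list(sclera = ref_materials$sclera),
                         pressure_load(0))
  expect_true(all(r$displacement == 0))
  expect_true(all(r$vm_stress == 0))
  expect_true(all(r$eq_strain == 0))
  expect_true(r$diagnostics$converged)
})

test_that("solver validates materials and reports diagnostics", {
  mesh <- build_sphere_mesh(refinement = 4)
  expect_error(solve_pressurized(mesh, list(), pressure_load(10)),
               "no material")
  r <- solve_pressurized(mesh, list(sclera = ref_materials$sclera),
                         pressure_load(10))
  expect_true(r$diagnostics$converged)
  expect_lte(r$diagnostics$residual,
             1e-6 * r$diagnostics$load_resultant * 1.0001)
  expect_true(all(r$vm_stress >= 0))
})

test_that("uniform sphere matches the Laplace law", {
  near_linear <- list(sclera = material_params(2, 30, 1, 0))
  mesh <- build_sphere_mesh(radius = 15, thickness = 1, refinement = 8)
  r <- solve_pressurized(mesh, near_linear, pressure_load(30))
  lap <- mmhg_to_mpa(30) * 15 / 2
  expect_lt(abs(sum(r$vm_stress * r$area) / sum(r$area) / lap - 1), 0.05)
  # principal stresses equibiaxial on the sphere (on average; the most
  # distorted cube-corner facets carry a few-percent anisotropy)
  aniso <- sum(abs(r$stress_1 - r$stress_2) * r$area) / sum(r$area)
  expect_lt(aniso / lap, 0.1)
})

test_that("small-load response is linear", {
  mesh <- build_sphere_mesh(radius = 15, thickness = 1, refinement = 6)
  mats <- list(sclera = ref_materials$sclera)
  r1 <- solve_pressurized(mesh, mats, pressure_load(1))
  r2 <- solve_pressurized(mesh, mats, pressure_load(2))
  m1 <- sum(r1$vm_stress * r1$area) / sum(r1$area)
  m2 <- sum(r2$vm_stress * r2$area) / sum(r2$area)
  expect_lt(abs(m2 / (2 * m1) - 1), 0.02)
})

test_that("net pressure resultant vanishes on the deformed closed shell", {
  mesh <- build_sphere_mesh(radius = 10, thickness = 1, refinement = 6)
  r <- solve_pressurized(mesh, list(sclera = ref_materials$sclera),
                         pressure_load(30))
  x <- mesh$nodes + r$displacement
  q <- mesh$quads
  cr <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                             u[, 3] * v[, 1] - u[, 1] * v[, 3],
                             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  av <- cr(x[q[, 2], ] - x[q[, 1], ], x[q[, 3], ] - x[q[, 1], ]) / 2 +
        cr(x[q[, 3], ] - x[q[, 1], ], x[q[, 4], ] - x[q[, 1], ]) / 2
  net <- colSums(av)
  expect_lt(sqrt(sum(net^2)) / sum(sqrt(rowSums(av^2))), 1e-10)
})

test_that("mesh refinement changes the mean stress by < 3%", {
  mats <- eye_materials_default()
  m1 <- build_eye_mesh(eye_geometry_config(refinement = 18))
  m2 <- build_eye_mesh(eye_geometry_config(refinement = 27))
  r1 <- solve_pressurized(m1, mats, pressure_load(30))
  r2 <- solve_pressurized(m2, mats, pressure_load(30))
  g1 <- sum(r1$vm_stress * r1$area) / sum(r1$area)
  g2 <- sum(r2$vm_stress * r2$area) / sum(r2$area)
  expect_lt(abs(g2 / g1 - 1), 0.03)
})

test_that("quasi-static ramp converges to the static solution", {
  mesh <- build_sphere_mesh(radius = 10, thickness = 1, refinement = 5)
  mats <- list(sclera = ref_materials$sclera)   # g_visc = 1.8, beta = 0.93
  static <- solve_pressurized(mesh, mats, pressure_load(30))
  slow <- solve_pressurized(mesh, mats, pressure_load(30),
                            ramp_steps = 6, ramp_time = 60)
  ms <- sum(static$vm_stress * static$area) / sum(static$area)
  mr <- sum(slow$vm_stress * slow$area) / sum(slow$area)
  expect_lt(abs(mr / ms - 1), 0.02)
  # a fast ramp carries extra viscous stress
  fast <- solve_pressurized(mesh, mats, pressure_load(30),
                            ramp_steps = 6, ramp_time = 0.05)
  mf <- sum(fast$vm_stress * fast$area) / sum(fast$area)
  expect_gt(mf, mr)
})

test_that("regional summary reduces fields correctly", {
  mesh <- build_sphere_mesh(refinement = 4)
  r <- solve_pressurized(mesh, list(sclera = ref_materials$sclera),
                         pressure_load(0))
  s0 <- regional_summary(r)
  expect_true(all(s0[, c("stress_mean", "strain_mean")] == 0))
  # synthetic uniform field
  r$vm_stress[] <- 1
  s1 <- regional_summary(r, stress_threshold = 0.5)
  expect_equal(s1$stress_mean, 1)
  expect_equal(s1$frac_above, 1)
  s2 <- regional_summary(r, stress_threshold = 2)
  expect_equal(s2$frac_above, 0)
})

test_that("peak locator and low-stress fraction operate on eye results", {
  mesh <- build_eye_mesh(eye_geometry_config(refinement = 18))
  r <- solve_pressurized(mesh, eye_materials_default(), pressure_load(30))
  lc <- peak_in_central(r, "lamina_cribrosa")
  expect_type(lc$central, "logical")
  expect_gte(lc$coordinate, 0)
  f <- low_stress_fraction(r, "sclera_posterior")
  expect_true(f >= 0 && f <= 1)
  expect_error(peak_in_central(
    solve_pressurized(build_sphere_mesh(refinement = 4),
                      list(sclera = ref_materials$sclera),
                      pressure_load(0)), "cornea"), "config")
})
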