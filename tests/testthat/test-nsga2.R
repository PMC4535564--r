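test_that("engine solves a known biobjective problem", {
  # Schaffer f1 = x^2, f2 = (x-2)^2: Pareto set is x in [0, 2]
  fn <- function(X) cbind(X[, 1]^2, (X[, 1] - 2)^2)
  r <- nsga2(fn, lower = -5, upper = 5, pop_size = 40,
             generations = 60, seed = 4)
  front <- r$par[r$pareto, 1]
  expect_true(all(front > -0.05 & front < 2.05))
  expect_gt(diff(range(front)), 1)          # spread along the front
  # non-domination by brute force (aggregated pairwise check)
  obj <- r$objectives[r$pareto, , drop = FALSE]
  expect_equal(count_dominated(obj), 0L)
  expect_true(all(diff(r$trace) <= 1e-12))  # elitist monotone trace
  # determinism
  r2 <- nsga2(fn, lower = -5, upper = 5, pop_size = 40,
              generations = 60, seed = 4)
  expect_identical(r$par, r2$par)
})

test_that("non-finite objectives are penalized, not fatal", {
  fn <- function(X) {
    o <- cbind(X[, 1]^2, (X[, 1] - 1)^2)
    o[X[, 1] > 0.5, 1] <- NaN
    o
  }
  r <- nsga2(fn, lower = -2, upper = 2, pop_size = 20, generations = 20,
             seed = 1)
  expect_true(all(is.finite(r$objectives[r$best, ])))
  expect_lt(r$par[r$best, 1], 0.5 + 1e-9)
  fn_bad <- function(X) matrix(NaN, nrow(X), 2)
  expect_error(nsga2(fn_bad, lower = 0, upper = 1, pop_size = 8,
                     generations = 2, seed = 1), "non-finite")
})

test_that("fit input validation", {
  expect_error(nsga2_fit(list()), "at least one")
  curves <- make_sclera_curves(rates = c(0.3, 3))
  other <- simulate_tension(ref_materials$sclera,
                            strip_geometry(2, 14.5, 1.7),
                            loading_protocol(30, 0.75))
  expect_error(nsga2_fit(c(curves, list(other))), "geometry")
  expect_error(fit_config(pop_size = 7), "even")
})

test_that("fit recovers parameters from two-rate data (reduced budget)", {
  # scaled down from the acceptance setting (pop 40 / 25 generations)
  # to keep the unit suite fast; the full setting is exercised in
  # test-acceptance.R
  curves <- make_sclera_curves(rates = c(0.3, 300))
  fit <- nsga2_fit(curves, config = fit_config(pop_size = 40,
                                               generations = 25,
                                               seed = 3))
  expect_s3_class(fit, "fit_result")
  expect_lt(abs(fit$best$alpha / 27.7 - 1), 0.05)
  expect_lt(abs(fit$best$mu / 0.774 - 1), 0.05)
  expect_true(all(diff(fit$trace) <= 1e-12))
  # pareto members are mutually non-dominated
  obj <- as.matrix(fit$pareto[, grep("^rmse_", names(fit$pareto))])
  expect_equal(count_dominated(obj), 0L)
  # best replays: simulating its parameters reproduces the data
  replay <- simulate_tension(fit$best, sclera_strip(),
                             loading_protocol(0.3, 0.75))
  expect_lt(curve_rmse(replay, curves[[1]]), 0.01 * max(curves[[1]]$force))
})

test_that("single quasi-static curve leaves beta and G unconstrained", {
  # brute-force identifiability oracle: at the true (alpha, mu), the
  # objective is flat over the (beta, G) box for relaxation times up to
  # ~10 s (a kernel with a creep time comparable to the test duration is
  # never invisible, so the profile excludes beta < 0.1 /s)
  slow <- simulate_tension(ref_materials$sclera, sclera_strip(),
                           loading_protocol(0.0003, 0.75))
  peak <- max(slow$force)
  grid <- expand.grid(beta = c(0.1, 1, 10),
                      g_visc = c(0.01, 0.1, 1, 10))
  rmse <- apply(grid, 1, function(g) {
    p <- material_params(27.7, 0.774, g[["beta"]], g[["g_visc"]])
    curve_rmse(simulate_tension(p, sclera_strip(),
                                loading_protocol(0.0003, 0.75)), slow)
  })
  expect_lt(max(rmse), 0.01 * peak)   # flat: < 1% of peak force
  # and the single-curve fit still pins (alpha, mu)
  fit <- nsga2_fit(list(slow), config = fit_config(pop_size = 40,
                                                   generations = 25,
                                                   seed = 1))
  expect_lt(abs(fit$best$alpha / 27.7 - 1), 0.05)
  expect_lt(abs(fit$best$mu / 0.774 - 1), 0.05)
})

test_that("fit tolerates measurement noise (reduced budget)", {
  # 2% of peak force, 6 seeds at pop 40 / 25 generations; alpha must be
  # within 15% of truth in >= 5 of 6
  ok <- sum(vapply(1:6, function(s) {
    ds <- gen_tensile_dataset(
      params_by_tissue = ref_materials["sclera"],
      geometries = list(sclera = sclera_strip()),
      rates = list(sclera = c(0.3, 3, 30, 300)),
      noise = noise_model(force_sd = 0.02 * 17, seed = s))
    fit <- nsga2_fit(unname(ds), config = fit_config(pop_size = 40,
                                                     generations = 25,
                                                     seed = s))
    abs(fit$best$alpha / 27.7 - 1) < 0.15
  }, logical(1)))
  expect_gte(ok, 5)
})
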