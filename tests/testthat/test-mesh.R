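test_that("config validates", {
  expect_error(eye_geometry_config(radius = -1))
  expect_error(eye_geometry_config(lc_axes = c(40, 3)))   # > radius
  expect_s3_class(eye_geometry_config(), "eye_geometry_config")
})

test_that("default mesh is watertight, oriented, spherical", {
  mesh <- build_eye_mesh()
  ck <- check_mesh(mesh)
  expect_true(ck$watertight)
  expect_true(ck$consistent_orientation)
  expect_true(ck$outward)
  expect_equal(ck$euler, 2L)
  expect_lt(abs(ck$area / (4 * pi * 15^2) - 1), 0.01)
  expect_true(all(mesh$thickness > 0))
  expect_equal(nrow(mesh$quads), 6 * 24^2)
})

test_that("topology holds across a config sweep", {
  for (cfg in list(
    eye_geometry_config(radius = 12, refinement = 20),
    eye_geometry_config(cornea_half_angle = 55, refinement = 20),
    eye_geometry_config(lc_axes = c(6, 5), refinement = 18))) {
    ck <- check_mesh(build_eye_mesh(cfg))
    expect_true(ck$watertight && ck$consistent_orientation && ck$outward)
    expect_equal(ck$euler, 2L)
  }
})

test_that("LC patch matches the configured ellipse within an element", {
  mesh <- build_eye_mesh()
  helem <- sqrt(mean(.facet_areas(mesh$nodes, mesh$quads)))
  cen <- .facet_centroids(mesh$nodes, mesh$quads)
  lc <- mesh$region == "lamina_cribrosa"
  expect_gte(sum(lc), 8L)
  expect_lt(abs(2 * max(abs(cen[lc, 1])) - 4.60), 2 * helem)
  expect_lt(abs(2 * max(abs(cen[lc, 2])) - 3.68), 2 * helem)
  expect_true(all(cen[lc, 3] < 0))
  expect_equal(mesh$thickness[lc], rep(0.4, sum(lc)))
  # under-resolved LC is an error
  expect_error(build_eye_mesh(eye_geometry_config(refinement = 8)),
               "lamina cribrosa")
})

test_that("thickness map is heterogeneous and continuous at the limbus", {
  mesh <- build_eye_mesh()
  cen <- .facet_centroids(mesh$nodes, mesh$quads)
  theta <- acos(cen[, 3] / sqrt(rowSums(cen^2))) * 180 / pi
  co <- mesh$region == "cornea"
  expect_lt(min(mesh$thickness[co]), 0.85)    # thin centrally
  # near the limbus both sides approach ~1.0 mm
  band <- abs(theta - 40) < 3
  expect_lt(max(abs(mesh$thickness[band] - 1.0)), 0.1)
  # sclera thickens towards the posterior pole
  sp <- mesh$region == "sclera_posterior"
  expect_gt(stats::cor(theta[sp], mesh$thickness[sp]), 0.99)
  expect_lt(max(mesh$thickness[sp]), 1.7 + 1e-9)
})

test_that("refinement convergence of the surface area", {
  a1 <- check_mesh(build_eye_mesh(eye_geometry_config(refinement = 20)))$area
  a2 <- check_mesh(build_eye_mesh(eye_geometry_config(refinement = 40)))$area
  expect_lt(abs(a2 / a1 - 1), 0.005)
})

test_that("mesh quality metrics are exact on reference shapes", {
  square <- structure(list(
    nodes = rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
    quads = matrix(1:4, 1), region = factor("sclera"), thickness = 1),
    class = "eye_mesh")
  q <- mesh_quality(square)
  expect_equal(q$min_scaled_jacobian, 1.0)
  expect_equal(q$min_angle, 90)
  expect_equal(q$n_flagged, 0L)
  # near-collinear corner: interior angle ~1 degree at node 2
  sliver <- structure(list(
    nodes = rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0.02, 0), c(0, 0.02, 0)),
    quads = matrix(1:4, 1), region = factor("sclera"), thickness = 1),
    class = "eye_mesh")
  qs <- mesh_quality(sliver)
  expect_lt(qs$min_scaled_jacobian, 0.05)
  expect_equal(qs$n_flagged, 1L)
})

test_that("default mesh passes the reference quality thresholds", {
  q <- mesh_quality(build_eye_mesh())
  expect_equal(q$n_flagged, 0L)
  expect_gt(q$min_scaled_jacobian, 0.47)
  expect_gt(q$min_angle, 43.53)
})

test_that("VTK export round-trips mesh and fields", {
  mesh <- build_eye_mesh(eye_geometry_config(refinement = 18))
  path <- withr::local_tempfile(fileext = ".vtk")
  fld <- list(vm_stress = seq_len(nrow(mesh$quads)) * 0.001)
  write_mesh_vtk(mesh, path, cell_fields = fld)
  back <- read_mesh_vtk(path)
  expect_lt(max(abs(back$nodes - mesh$nodes)), 1e-8)
  expect_identical(back$quads, mesh$quads)
  expect_equal(as.character(back$region), as.character(mesh$region))
  expect_equal(back$thickness, mesh$thickness, tolerance = 1e-9)
  expect_equal(attr(back, "cell_fields")$vm_stress, fld$vm_stress,
               tolerance = 1e-9)
})
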