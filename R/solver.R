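#' Convert intraocular pressure from mmHg to MPa
#'
#' 1 mmHg = 133.322 Pa = 1.33322e-4 MPa.
#'
#' @param iop pressure in mmHg, >= 0. Vectorized.
#' @return Pressure in MPa.
#' @export
mmhg_to_mpa <- function(iop) {
  if (any(!is.finite(iop)) || any(iop < 0))
    stop("'iop' must be finite and >= 0", call. = FALSE)
  iop * 1.33322e-4
}

#' Pressure load at a given IOP
#'
#' @param iop intraocular pressure in mmHg.
#' @return Object of class `pressure_load` with fields `iop` (mmHg) and
#'   `mpa`.
#' @export
pressure_load <- function(iop) {
  structure(list(iop = iop, mpa = mmhg_to_mpa(iop)),
            class = "pressure_load")
}

#' Dynamic relaxation solver settings
#'
#' @param tol convergence tolerance: the residual force norm must fall
#'   below `tol` times the load resultant (sum of nodal pressure-force
#'   magnitudes).
#' @param max_steps pseudo-time step budget.
#' @param check_every steps between convergence checks.
#' @param mass_safety multiplier on the stiffness-proportional nodal
#'   pseudo-masses (larger is more stable, slower).
#' @param centroid_penalty stiffness fraction of the weak spring pinning
#'   the globe centroid (removes rigid-body drift).
#' @return Object of class `solver_control`.
#' @export
solver_control <- function(tol = 1e-6, max_steps = 60000L,
                           check_every = 25L, mass_safety = 2,
                           centroid_penalty = 1e-3) {
  stopifnot(tol > 0, max_steps >= 1, check_every >= 1, mass_safety > 0)
  structure(list(tol = tol, max_steps = as.integer(max_steps),
                 check_every = as.integer(check_every),
                 mass_safety = mass_safety,
                 centroid_penalty = centroid_penalty),
            class = "solver_control")
}

# Split quads into constant-strain triangles and precompute reference
# quantities (local 2x2 inverse metric, areas, thickness, material).
.prep_tris <- function(mesh, materials) {
  regions <- levels(mesh$region)
  for (r in unique(as.character(mesh$region)))
    if (is.null(materials[[r]]))
      stop("no material supplied for region '", r, "'", call. = FALSE)
  q <- mesh$quads
  tri <- rbind(q[, c(1, 2, 3)], q[, c(1, 3, 4)])
  facet <- rep(seq_len(nrow(q)), 2L)
  X <- mesh$nodes
  E1 <- X[tri[, 2], ] - X[tri[, 1], ]
  E2 <- X[tri[, 3], ] - X[tri[, 1], ]
  cr <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                             u[, 3] * v[, 1] - u[, 1] * v[, 3],
                             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  nrm <- cr(E1, E2)
  a2 <- sqrt(rowSums(nrm^2))
  l1 <- sqrt(rowSums(E1^2))
  d11 <- l1
  d12 <- rowSums(E2 * E1) / l1
  d22 <- a2 / l1                     # |E2 - (E2.e1)e1| since a2 = l1 * h
  det <- d11 * d22
  Di11 <- d22 / det; Di12 <- -d12 / det; Di21 <- 0 * det; Di22 <- d11 / det
  reg <- as.character(mesh$region)[facet]
  alpha <- lapply(materials, `[[`, "alpha")
  mu <- lapply(materials, `[[`, "mu")
  list(tri = tri, facet = facet, A0 = a2 / 2, t0 = mesh$thickness[facet],
       Di11 = Di11, Di12 = Di12, Di22 = Di22,
       reg = reg, alpha = alpha, mu = mu,
       idx = split(seq_along(facet), reg))
}

# Principal Kirchhoff==Cauchy (J=1) stresses and 2nd PK coefficients of
# the incompressible Ogden membrane in plane stress.
.ogden_membrane <- function(l1, l2, alpha, mu) {
  s1 <- 0 * l1; s2 <- s1
  for (j in seq_along(alpha)) {
    a <- alpha[j]; m <- mu[j]
    l12a <- (l1 * l2)^(-a)
    s1 <- s1 + m * (l1^a - l12a)
    s2 <- s2 + m * (l2^a - l12a)
  }
  list(sig1 = s1, sig2 = s2)
}

# One full assembly of internal + pressure nodal forces and the per-tri
# kinematic state, given current node positions. The deformation enters
# only through the current edge metric g = [e_i . e_j]; with
# C = Dinv^T g Dinv the nodal forces are exact energy gradients,
# f_2 = -A0 t0 (q11 e1 + q12 e2), f_3 = -A0 t0 (q12 e1 + q22 e2),
# where Q = Dinv S Dinv^T and S is the 2nd Piola-Kirchhoff stress.
.assemble <- function(x, pp, p_mpa, sv1 = NULL, sv2 = NULL) {
  tri <- pp$tri
  e1 <- x[tri[, 2], , drop = FALSE] - x[tri[, 1], , drop = FALSE]
  e2 <- x[tri[, 3], , drop = FALSE] - x[tri[, 1], , drop = FALSE]
  crn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  a2 <- sqrt(rowSums(crn^2))
  g11 <- rowSums(e1^2); g12 <- rowSums(e1 * e2); g22 <- rowSums(e2^2)
  c11 <- pp$Di11^2 * g11
  c12 <- pp$Di11 * (g11 * pp$Di12 + g12 * pp$Di22)
  c22 <- pp$Di12^2 * g11 + 2 * pp$Di12 * pp$Di22 * g12 + pp$Di22^2 * g22
  tr2 <- (c11 + c22) / 2
  dif <- (c11 - c22) / 2
  disc <- sqrt(dif^2 + c12^2)
  ev1 <- pmax(tr2 + disc, 1e-12)
  ev2 <- pmax(tr2 - disc, 1e-12)
  lam1 <- sqrt(ev1); lam2 <- sqrt(ev2)
  # eigenvector (vx, vy) for ev1 in the reference local frame; of the two
  # algebraic candidates keep the better-conditioned one (larger norm)
  use_b <- dif >= 0
  vx <- ifelse(use_b, dif + disc, c12)
  vy <- ifelse(use_b, c12, disc - dif)
  nv <- sqrt(vx^2 + vy^2)
  degen <- nv < 1e-30                # isotropic stretch: any frame works
  vx[degen] <- 1; vy[degen] <- 0; nv[degen] <- 1
  vx <- vx / nv; vy <- vy / nv
  # principal stresses per region
  sig1 <- numeric(length(lam1)); sig2 <- sig1
  for (r in names(pp$idx)) {
    i <- pp$idx[[r]]
    st <- .ogden_membrane(lam1[i], lam2[i], pp$alpha[[r]], pp$mu[[r]])
    sig1[i] <- st$sig1; sig2[i] <- st$sig2
  }
  if (!is.null(sv1)) { sig1 <- sig1 + sv1; sig2 <- sig2 + sv2 }
  # 2nd PK principal values S_i = sigma_i / lambda_i^2 (J = 1)
  s1 <- sig1 / ev1; s2 <- sig2 / ev2
  s11 <- vx^2 * s1 + vy^2 * s2
  s22 <- vy^2 * s1 + vx^2 * s2
  s12 <- vx * vy * (s1 - s2)
  # Q = Dinv S Dinv^T (Dinv upper triangular: Di21 = 0)
  q11 <- pp$Di11 * (pp$Di11 * s11 + pp$Di12 * s12) +
         pp$Di12 * (pp$Di11 * s12 + pp$Di12 * s22)
  q12 <- pp$Di22 * (pp$Di11 * s12 + pp$Di12 * s22)
  q22 <- pp$Di22^2 * s22
  w <- pp$A0 * pp$t0
  fi2 <- -(e1 * (w * q11) + e2 * (w * q12))
  fi3 <- -(e1 * (w * q12) + e2 * (w * q22))
  fi1 <- -(fi2 + fi3)
  # follower pressure: p * current area vector / 3 to each node
  fp <- p_mpa * crn / 6
  fnode1 <- fi1 + fp; fnode2 <- fi2 + fp; fnode3 <- fi3 + fp
  idx <- c(tri[, 1], tri[, 2], tri[, 3])
  fall <- rbind(fnode1, fnode2, fnode3)
  force <- rowsum(fall, idx)          # ordered by sorted unique idx = 1..V
  pres <- rowsum(rbind(fp, fp, fp), idx)
  list(force = force, pressure_norm = sum(sqrt(rowSums(pres^2))),
       lam1 = lam1, lam2 = lam2, sig1 = sig1, sig2 = sig2,
       area = a2 / 2)
}

#' Solve quasi-static equilibrium of the pressurized eye shell
#'
#' Membrane finite-element solution of the eye wall under uniform
#' internal pressure applied perpendicular to the (deforming) inner
#' surface: each quad facet is split into constant-strain triangles
#' carrying the incompressible Ogden response in plane stress; the
#' pressure is a follower load recomputed from the current surface each
#' step; equilibrium is found by dynamic relaxation (explicit pseudo-time
#' stepping with kinetic damping and stiffness-proportional nodal
#' masses). Only the equilibrium (hyperelastic) part of the material law
#' enters the static solve: the exponential relaxation kernel decays, so
#' the steady state is rate-independent. A transient quasi-static ramp
#' retaining the viscoelastic hereditary stress is available via
#' `ramp_steps > 1`.
#'
#' Rigid-body translation is suppressed by a weak penalty spring on the
#' globe centroid (the closed pressure load exerts no net force, so the
#' penalty carries essentially zero force at convergence).
#'
#' @param mesh an `eye_mesh` from [build_eye_mesh()] or
#'   [build_sphere_mesh()].
#' @param materials named list mapping each region present in the mesh
#'   to a [material_params()]; see [eye_materials_default()].
#' @param load a [pressure_load()] (or IOP in mmHg, coerced).
#' @param control a [solver_control()].
#' @param ramp_steps if > 1, the pressure is ramped in this many equal
#'   quasi-static increments over `ramp_time` seconds with the
#'   viscoelastic convolution stress carried across increments.
#' @param ramp_time physical ramp duration in s (only with
#'   `ramp_steps > 1`).
#' @param init_displacement optional V x 3 warm-start displacement.
#' @return Object of class `field_result`: `displacement` (V x 3, mm),
#'   per-facet `region`, `area` (current, mm^2), `stress_1`, `stress_2`
#'   (principal membrane Cauchy stresses, MPa), `vm_stress` (von Mises,
#'   MPa), `eq_strain` (von Mises equivalent of the logarithmic membrane
#'   strains), `diagnostics` (residual norm, load resultant, steps,
#'   converged), `load`.
#' @export
solve_pressurized <- function(mesh, materials, load,
                              control = solver_control(),
                              ramp_steps = 1L, ramp_time = 1,
                              init_displacement = NULL) {
  stopifnot(inherits(mesh, "eye_mesh"), inherits(control, "solver_control"))
  if (!inherits(load, "pressure_load")) load <- pressure_load(load)
  pp <- .prep_tris(mesh, materials)
  nv <- nrow(mesh$nodes)
  if (load$mpa == 0) {
    nfac <- nrow(mesh$quads)
    return(structure(list(
      displacement = matrix(0, nv, 3), region = mesh$region,
      area = .facet_areas(mesh$nodes, mesh$quads),
      stress_1 = numeric(nfac), stress_2 = numeric(nfac),
      vm_stress = numeric(nfac), eq_strain = numeric(nfac),
      diagnostics = list(residual = 0, load_resultant = 0, steps = 0L,
                         converged = TRUE),
      load = load, mesh = mesh), class = "field_result"))
  }
  x0 <- mesh$nodes
  x <- if (is.null(init_displacement)) x0 else x0 + init_displacement
  if (ramp_steps > 1L) {
    sv1 <- numeric(length(pp$facet)); sv2 <- sv1
    le1_prev <- NULL; le2_prev <- NULL
    dt_phys <- ramp_time / ramp_steps
    beta <- vapply(pp$reg, function(r) materials[[r]]$beta, numeric(1))
    gv <- vapply(pp$reg, function(r) materials[[r]]$g_visc, numeric(1))
    for (k in seq_len(ramp_steps)) {
      pk <- load$mpa * k / ramp_steps
      sol <- .dr_solve(x, x0, pp, pk, control, sv1, sv2)
      x <- sol$x
      le1 <- log(sol$state$lam1); le2 <- log(sol$state$lam2)
      if (is.null(le1_prev)) { le1_prev <- 0 * le1; le2_prev <- 0 * le2 }
      ef <- exp(-beta * dt_phys); em <- exp(-beta * dt_phys / 2)
      sv1 <- ef * sv1 + gv * (le1 - le1_prev) * em
      sv2 <- ef * sv2 + gv * (le2 - le2_prev) * em
      le1_prev <- le1; le2_prev <- le2
    }
    st <- sol$state
  } else {
    sol <- .dr_solve(x, x0, pp, load$mpa, control)
    x <- sol$x
    st <- sol$state
  }
  eps1 <- log(st$lam1); eps2 <- log(st$lam2); eps3 <- -(eps1 + eps2)
  eqs <- sqrt(2 / 3 * (eps1^2 + eps2^2 + eps3^2))
  vms <- sqrt(st$sig1^2 - st$sig1 * st$sig2 + st$sig2^2)
  # aggregate the two triangles of each quad, area-weighted
  agg <- function(v) {
    as.numeric(rowsum(v * st$area, pp$facet) / rowsum(st$area, pp$facet))
  }
  structure(list(
    displacement = x - x0, region = mesh$region,
    area = as.numeric(rowsum(st$area, pp$facet)),
    stress_1 = agg(st$sig1), stress_2 = agg(st$sig2),
    vm_stress = agg(vms), eq_strain = agg(eqs),
    diagnostics = sol$diag, load = load, mesh = mesh),
    class = "field_result")
}

# dynamic relaxation to static equilibrium at fixed pressure
.dr_solve <- function(x, x0, pp, p_mpa, control, sv1 = NULL, sv2 = NULL) {
  nv <- nrow(x)
  # stiffness-proportional pseudo-masses (membrane: ~ E * t per node)
  e_scale <- vapply(seq_along(pp$facet), function(i) {
    r <- pp$reg[i]
    sum(abs(pp$mu[[r]]) * (abs(pp$alpha[[r]]) + 2))
  }, numeric(1))
  kball <- 3 * e_scale * pp$t0
  m <- as.numeric(rowsum(c(kball, kball, kball),
                         c(pp$tri[, 1], pp$tri[, 2], pp$tri[, 3])))
  m <- m * control$mass_safety
  v <- matrix(0, nv, 3)
  ke_prev <- 0
  cen0 <- colMeans(x0)
  kc <- control$centroid_penalty * mean(m)
  res <- Inf; refn <- 1; step <- 0L; converged <- FALSE
  while (step < control$max_steps) {
    step <- step + 1L
    asm <- .assemble(x, pp, p_mpa, sv1, sv2)
    f <- asm$force
    drift <- colMeans(x) - cen0
    f <- sweep(f, 2, kc * drift)
    v <- v + f / m
    ke <- sum(m * rowSums(v^2))
    if (ke < ke_prev) { v[] <- 0; ke <- 0 }
    ke_prev <- ke
    x <- x + v
    if (step %% control$check_every == 0L) {
      res <- sqrt(sum(f^2))
      refn <- max(asm$pressure_norm, 1e-300)
      if (res <= control$tol * refn) { converged <- TRUE; break }
    }
  }
  if (!converged) {
    stop(sprintf(paste("dynamic relaxation did not converge: residual",
                       "%.3e vs tolerance %.3e after %d steps"),
                 res, control$tol * refn, step), call. = FALSE)
  }
  asm <- .assemble(x, pp, p_mpa, sv1, sv2)
  list(x = x, state = asm,
       diag = list(residual = sqrt(sum(asm$force^2)),
                   load_resultant = asm$pressure_norm,
                   steps = step, converged = TRUE))
}

#' Default material map for the labelled eye mesh
#'
#' Cornea and sclera from [bovine_eye_materials()]; anterior and
#' posterior sclera share the scleral parameters; the lamina cribrosa
#' uses [lc_material()].
#'
#' @param lc_soften softening factor passed to [lc_material()].
#' @return Named list of [material_params()] keyed by mesh region.
#' @export
eye_materials_default <- function(lc_soften = 0.5) {
  m <- bovine_eye_materials()
  list(cornea = m$cornea, sclera = m$sclera,
       sclera_anterior = m$sclera, sclera_posterior = m$sclera,
       lamina_cribrosa = lc_material(m$sclera, soften = lc_soften))
}

#' Area-weighted per-region field statistics
#'
#' Summarizes a [solve_pressurized()] result per region: facet-area
#' totals, area-weighted min/mean/max of the equivalent (von Mises)
#' stress and strain, and, when `stress_threshold` is given, the area
#' fraction of each region whose equivalent stress exceeds it (the
#' quantitative version of an expanding or narrowing stress-concentration
#' "scope").
#'
#' @param result a `field_result`.
#' @param stress_threshold optional threshold in MPa.
#' @return data.frame, one row per region present.
#' @export
regional_summary <- function(result, stress_threshold = NULL) {
  stopifnot(inherits(result, "field_result"))
  regs <- levels(droplevels(result$region))
  rows <- lapply(regs, function(r) {
    i <- result$region == r
    a <- result$area[i]; s <- result$vm_stress[i]; e <- result$eq_strain[i]
    d <- data.frame(region = r, area_mm2 = sum(a),
                    stress_min = min(s),
                    stress_mean = sum(s * a) / sum(a),
                    stress_max = max(s),
                    strain_min = min(e),
                    strain_mean = sum(e * a) / sum(a),
                    strain_max = max(e))
    if (!is.null(stress_threshold))
      d$frac_above <- sum(a[s > stress_threshold]) / sum(a)
    d
  })
  do.call(rbind, rows)
}

#' Is the regional stress peak in the central part of its region?
#'
#' For the lamina cribrosa: the peak-stress facet centroid must lie
#' inside the concentric ellipse enclosing `area_fraction` of the LC
#' area. For the cornea: inside the concentric spherical sub-cap
#' enclosing `area_fraction` of the cap area. Operationalizes the
#' "stress concentrated in the central part" finding.
#'
#' @param result a `field_result` from a mesh built by
#'   [build_eye_mesh()] (its geometry config supplies the LC axes and
#'   cap angle).
#' @param region `"lamina_cribrosa"` or `"cornea"`.
#' @param area_fraction central-area fraction defining "central".
#' @return List: `central` (logical), `coordinate` (the normalized
#'   radial position in [0, 1], by area), `peak_stress`.
#' @export
peak_in_central <- function(result, region = c("lamina_cribrosa", "cornea"),
                            area_fraction = 0.5) {
  stopifnot(inherits(result, "field_result"))
  region <- match.arg(region)
  cfg <- result$mesh$config
  if (is.null(cfg))
    stop("result's mesh carries no geometry config", call. = FALSE)
  i <- which(result$region == region)
  if (length(i) == 0L) stop("region absent from mesh", call. = FALSE)
  ipk <- i[which.max(result$vm_stress[i])]
  cen <- .facet_centroids(result$mesh$nodes,
                          result$mesh$quads[ipk, , drop = FALSE])
  if (region == "lamina_cribrosa") {
    a <- cfg$lc_axes[1] / 2; b <- cfg$lc_axes[2] / 2
    # concentric ellipse of area fraction q has semi-axes scaled sqrt(q)
    coord <- (cen[1] / a)^2 + (cen[2] / b)^2
  } else {
    theta <- acos(pmin(pmax(cen[3] / sqrt(sum(cen^2)), -1), 1))
    thc <- cfg$cornea_half_angle * pi / 180
    coord <- (1 - cos(theta)) / (1 - cos(thc))
  }
  list(central = coord <= area_fraction, coordinate = as.numeric(coord),
       peak_stress = result$vm_stress[ipk])
}

#' Area fraction of a region in the lowest whole-globe stress band
#'
#' Computes the threshold `min + quantile * (max - min)` of the
#' equivalent stress over the entire globe and returns the area fraction
#' of the given region at or below it. Tracks whether the low-stress
#' "scope" of a region widens or narrows across IOP levels.
#'
#' @param result a `field_result`.
#' @param region region name.
#' @param quantile band width as a fraction of the globe stress range.
#' @return Area fraction in [0, 1].
#' @export
low_stress_fraction <- function(result, region = "sclera_posterior",
                                quantile = 0.25) {
  stopifnot(inherits(result, "field_result"))
  thr <- min(result$vm_stress) +
    quantile * (max(result$vm_stress) - min(result$vm_stress))
  i <- result$region == region
  sum(result$area[i & result$vm_stress <= thr]) / sum(result$area[i])
}

#' Sweep a mesh over several IOP levels
#'
#' Solves [solve_pressurized()] at each pressure, warm-starting each
#' level from the previous solution scaled by the pressure ratio (the
#' response is nearly linear at these strains, so this cuts relaxation
#' time substantially).
#'
#' @param mesh an `eye_mesh`.
#' @param materials region material map.
#' @param iops numeric vector of pressures in mmHg.
#' @param control a [solver_control()].
#' @return Named list of `field_result`, names `iop_<value>`.
#' @export
pressure_sweep <- function(mesh, materials, iops = c(10, 30, 60, 100),
                           control = solver_control()) {
  stopifnot(length(iops) >= 1)
  out <- list(); prev <- NULL; prev_iop <- NULL
  for (p in iops) {
    init <- if (!is.null(prev)) prev$displacement * (p / prev_iop)
    r <- solve_pressurized(mesh, materials, pressure_load(p),
                           control = control, init_displacement = init)
    out[[paste0("iop_", format(p, trim = TRUE))]] <- r
    prev <- r; prev_iop <- p
  }
  out
}
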