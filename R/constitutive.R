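#' Uniaxial deformation history
#'
#' A sampled stretch history \eqn{\lambda(t)} along the loading axis of an
#' incompressible uniaxial test. Transverse stretches are implied as
#' \eqn{\lambda^{-1/2}} so the volume ratio is J = 1 throughout. The scalar
#' strain driving the viscoelastic hereditary integral is derived from the
#' stretch under a declared convention: engineering strain
#' \eqn{\epsilon = \lambda - 1} (default) or logarithmic strain
#' \eqn{\epsilon = \log\lambda}. The identified viscoelastic constants
#' depend on this choice, so it travels with the history.
#'
#' @param time numeric vector of sample times in seconds, strictly
#'   increasing from 0.
#' @param stretch numeric vector of axial stretches, same length as
#'   `time`, all positive, `stretch[1]` typically 1.
#' @param strain one of `"engineering"` or `"logarithmic"`.
#' @return Object of class `deformation_history` with fields `time`,
#'   `stretch`, `strain` (the derived strain series) and
#'   `strain_convention`.
#' @export
deformation_history <- function(time, stretch,
                                strain = c("engineering", "logarithmic")) {
  strain <- match.arg(strain)
  time <- as.numeric(time); stretch <- as.numeric(stretch)
  if (length(time) != length(stretch))
    stop("'time' and 'stretch' must have equal length", call. = FALSE)
  if (length(time) < 2L)
    stop("a deformation history needs at least 2 samples", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("'time' must be strictly increasing", call. = FALSE)
  if (time[1] < 0)
    stop("'time' must start at or after 0", call. = FALSE)
  if (any(stretch <= 0))
    stop("'stretch' must be positive", call. = FALSE)
  eps <- switch(strain, engineering = stretch - 1, logarithmic = log(stretch))
  structure(list(time = time, stretch = stretch, strain = eps,
                 strain_convention = strain),
            class = "deformation_history")
}

#' Ogden strain-energy density for incompressible uniaxial stretch
#'
#' Evaluates the incompressible Ogden energy density
#' \deqn{W(\lambda) = \sum_j \frac{\mu_j}{\alpha_j}
#'   (\lambda^{\alpha_j} + 2\lambda^{-\alpha_j/2} - 3)}
#' where the transverse stretches \eqn{\lambda^{-1/2}} follow from J = 1.
#' W is non-negative and vanishes only in the reference state.
#'
#' @param params a [material_params()] object.
#' @param stretch axial stretch(es), > 0. Vectorized.
#' @return Energy density in MPa (= mJ/mm^3), same length as `stretch`.
#' @export
ogden_energy <- function(params, stretch) {
  stopifnot(inherits(params, "material_params"))
  stretch <- as.numeric(stretch)
  if (any(!is.finite(stretch)) || any(stretch <= 0))
    stop("'stretch' must be finite and > 0", call. = FALSE)
  w <- numeric(length(stretch))
  for (j in seq_len(params$n_terms)) {
    a <- params$alpha[j]; m <- params$mu[j]
    w <- w + (m / a) * (stretch^a + 2 * stretch^(-a / 2) - 3)
  }
  w
}

#' Ogden uniaxial Cauchy stress
#'
#' Axial Cauchy (true) stress of the incompressible Ogden solid in
#' uniaxial tension/compression,
#' \deqn{\sigma(\lambda) = \sum_j \mu_j
#'   (\lambda^{\alpha_j} - \lambda^{-\alpha_j/2}),}
#' obtained from [ogden_energy()] after eliminating the hydrostatic
#' pressure with the traction-free lateral faces. Positive in tension.
#'
#' @inheritParams ogden_energy
#' @return Cauchy stress in MPa, same length as `stretch`.
#' @export
ogden_uniaxial_stress <- function(params, stretch) {
  stopifnot(inherits(params, "material_params"))
  stretch <- as.numeric(stretch)
  if (any(!is.finite(stretch)) || any(stretch <= 0))
    stop("'stretch' must be finite and > 0", call. = FALSE)
  s <- numeric(length(stretch))
  for (j in seq_len(params$n_terms)) {
    a <- params$alpha[j]; m <- params$mu[j]
    s <- s + m * (stretch^a - stretch^(-a / 2))
  }
  s
}

#' Viscoelastic stress from the hereditary integral
#'
#' Evaluates the Christensen-type convolution stress
#' \deqn{\sigma_v(t) = \int_0^t G e^{-\beta (t-\tau)}
#'   \frac{\partial\epsilon}{\partial\tau}\, d\tau}
#' at every sample of a [deformation_history()]. The integral is advanced
#' by the exact-exponential recursive update
#' \deqn{\sigma_v(t_{k+1}) = e^{-\beta\Delta t}\sigma_v(t_k)
#'   + G\,\Delta\epsilon_k\, e^{-\beta\Delta t/2},}
#' i.e. each strain increment enters through the kernel evaluated at the
#' midpoint of its interval. The update is unconditionally stable and
#' second-order accurate in the step size; it is algebraically a
#' midpoint-rule discretization of the convolution, which the test suite
#' checks against a direct quadrature oracle and against the closed form
#' for constant strain rate, \eqn{(G r/\beta)(1 - e^{-\beta t})}.
#'
#' @param params a [material_params()] object (uses `g_visc`, `beta`).
#' @param history a [deformation_history()].
#' @return Stress series in MPa, one value per sample; first value 0.
#' @export
visco_stress <- function(params, history) {
  stopifnot(inherits(params, "material_params"),
            inherits(history, "deformation_history"))
  g <- params$g_visc; b <- params$beta
  t <- history$time; eps <- history$strain
  n <- length(t)
  if (g == 0) return(numeric(n))
  dt <- diff(t)
  deps <- diff(eps)
  # uniform-grid fast path: sigma_k = e^{-b t_k} * cumsum(g*deps*e^{b t_mid})
  # guarded against overflow of e^{b t}; otherwise the O(n) recursion.
  if (max(abs(diff(dt))) < 1e-12 * dt[1] && b * t[n] < 600) {
    tm <- t[-1] - dt / 2
    s <- c(0, exp(-b * t[-1]) * cumsum(g * deps * exp(b * tm)))
  } else {
    s <- numeric(n)
    for (k in seq_len(n - 1L)) {
      s[k + 1L] <- exp(-b * dt[k]) * s[k] +
        g * deps[k] * exp(-b * dt[k] / 2)
    }
  }
  s
}

#' Total uniaxial stress: hyperelastic plus viscoelastic
#'
#' Pointwise sum of the equilibrium Ogden stress along the stretch series
#' and the rate-dependent hereditary-integral stress. With `g_visc = 0`
#' this reduces exactly to the hyperelastic curve; in the quasi-static
#' limit (vanishing loading rate) it converges to it.
#'
#' @inheritParams visco_stress
#' @return Cauchy stress series in MPa, one value per history sample.
#' @export
total_uniaxial_stress <- function(params, history) {
  stopifnot(inherits(params, "material_params"),
            inherits(history, "deformation_history"))
  ogden_uniaxial_stress(params, history$stretch) +
    visco_stress(params, history)
}
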