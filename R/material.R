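#' Constitutive parameters for one ocular tissue
#'
#' Bundles the four constants of the combined Ogden hyperelastic /
#' Christensen viscoelastic law used throughout the package: the Ogden
#' exponent(s) `alpha` (dimensionless) and modulus(es) `mu` (MPa) of the
#' strain-energy density, and the exponential relaxation kernel
#' `g_visc * exp(-beta * t)` (modulus `g_visc` in MPa, decay rate `beta`
#' in 1/s). The hyperelastic part may carry several Ogden terms
#' (`n_terms`); identified bovine tissues use a single term.
#'
#' @param alpha numeric vector of Ogden exponents, none zero.
#' @param mu numeric vector of Ogden moduli in MPa, all positive; same
#'   length as `alpha`.
#' @param beta viscoelastic decay rate in 1/s, positive scalar.
#' @param g_visc viscoelastic modulus in MPa, non-negative scalar.
#' @param n_terms number of Ogden terms; defaults to `length(alpha)`.
#' @param tissue optional tissue label carried through pipelines.
#' @return An object of class `material_params`.
#' @examples
#' material_params(alpha = 27.7, mu = 0.774, beta = 0.93, g_visc = 1.8,
#'                 tissue = "sclera")
#' @export
material_params <- function(alpha, mu, beta, g_visc,
                            n_terms = length(alpha), tissue = NA_character_) {
  alpha <- as.numeric(alpha)
  mu <- as.numeric(mu)
  stopifnot(length(alpha) == length(mu), length(alpha) == n_terms,
            n_terms >= 1L)
  if (any(!is.finite(alpha)) || any(alpha == 0))
    stop("'alpha' must be finite and non-zero", call. = FALSE)
  if (any(!is.finite(mu)) || any(mu <= 0))
    stop("'mu' must be finite and > 0", call. = FALSE)
  if (!is.finite(beta) || beta <= 0)
    stop("'beta' must be finite and > 0", call. = FALSE)
  if (!is.finite(g_visc) || g_visc < 0)
    stop("'g_visc' must be finite and >= 0", call. = FALSE)
  structure(
    list(alpha = alpha, mu = mu, beta = as.numeric(beta),
         g_visc = as.numeric(g_visc), n_terms = as.integer(n_terms),
         tissue = as.character(tissue)),
    class = "material_params")
}

#' @export
print.material_params <- function(x, ...) {
  cat("<material_params>",
      if (!is.na(x$tissue)) paste0(" tissue: ", x$tissue), "\n", sep = "")
  cat(sprintf("  Ogden terms (n=%d): alpha = %s, mu = %s MPa\n", x$n_terms,
              paste(signif(x$alpha, 4), collapse = ", "),
              paste(signif(x$mu, 4), collapse = ", ")))
  cat(sprintf("  Viscoelastic: G = %g MPa, beta = %g 1/s\n",
              x$g_visc, x$beta))
  invisible(x)
}

#' Identified bovine eye-wall materials
#'
#' The single-term Ogden + exponential-kernel parameter sets identified
#' for bovine cornea and sclera by inverse fitting of multi-rate strip
#' tension tests. These are the package defaults for forward tensile
#' simulation, for parameter-recovery ground truth, and for the
#' pressurized-eyeball simulation.
#'
#' The lamina cribrosa has no independently identified parameter set; by
#' convention it inherits the scleral parameters scaled by a softening
#' factor (see [lc_material()]), which is a declared modelling assumption.
#'
#' @return Named list with elements `cornea` and `sclera`, each a
#'   [material_params()] object.
#' @examples
#' bovine_eye_materials()$sclera
#' @export
bovine_eye_materials <- function() {
  list(
    cornea = material_params(alpha = 8.1, mu = 0.675, beta = 0.13,
                             g_visc = 1.641, tissue = "cornea"),
    sclera = material_params(alpha = 27.7, mu = 0.774, beta = 0.93,
                             g_visc = 1.8, tissue = "sclera"))
}

#' Lamina cribrosa material as softened sclera
#'
#' No lamina cribrosa (LC) constitutive parameters were identified from
#' experiment, so the LC is modelled as sclera with its moduli (`mu` and
#' `g_visc`) multiplied by a softening factor. The default factor 0.5
#' reflects that the porous collagenous LC plate is more compliant than
#' dense sclera; it is an assumption, exposed as an argument.
#'
#' @param sclera a [material_params()] object for the sclera.
#' @param soften multiplicative factor on the moduli, in (0, 1].
#' @return A [material_params()] object labelled `"lamina_cribrosa"`.
#' @export
lc_material <- function(sclera = bovine_eye_materials()$sclera,
                        soften = 0.5) {
  stopifnot(is.numeric(soften), length(soften) == 1L, soften > 0,
            soften <= 1)
  material_params(alpha = sclera$alpha, mu = sclera$mu * soften,
                  beta = sclera$beta, g_visc = sclera$g_visc * soften,
                  tissue = "lamina_cribrosa")
}
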