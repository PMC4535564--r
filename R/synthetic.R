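#' Additive Gaussian force-noise model
#'
#' Stand-in for load-cell measurement error on synthetic tensile curves.
#'
#' @param force_sd standard deviation of the additive force noise, N.
#' @param seed integer RNG seed making the dataset reproducible.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(force_sd = 0.2, seed = 1L) {
  stopifnot(is.finite(force_sd), force_sd >= 0)
  structure(list(force_sd = as.numeric(force_sd), seed = as.integer(seed)),
            class = "noise_model")
}

#' Default loading rates per tissue
#'
#' Scleral strips were stretched at 0.3, 3, 30 and 300 mm/s; corneal
#' strips at 0.3 and 30 mm/s.
#' @return Named list of rate vectors in mm/s.
#' @export
default_rates <- function() {
  list(sclera = c(0.3, 3, 30, 300), cornea = c(0.3, 30))
}

default_max_displacement <- function(tissue) {
  switch(tissue, sclera = 0.75, cornea = 1.5,
         stop("no default displacement for tissue '", tissue, "'",
              call. = FALSE))
}

#' Generate a study-like multi-rate tensile dataset
#'
#' Runs the forward strip model for every (tissue, rate) combination and
#' corrupts the forces with i.i.d. Gaussian noise. Pure function of its
#' arguments and the seed: the same call reproduces the same dataset
#' bitwise.
#'
#' @param params_by_tissue named list of [material_params()]; defaults to
#'   the identified bovine cornea/sclera set.
#' @param geometries named list of [strip_geometry()] per tissue.
#' @param rates named list of rate vectors (mm/s) per tissue.
#' @param noise a [noise_model()].
#' @param max_displacement named numeric, final crosshead displacement in
#'   mm per tissue; defaults give peak stretch ~1.05 (sclera) and ~1.15
#'   (cornea).
#' @return Named list of `fd_curve` objects, names `<tissue>_<rate>`.
#' @export
gen_tensile_dataset <- function(params_by_tissue = bovine_eye_materials(),
                                geometries = list(sclera = sclera_strip(),
                                                  cornea = cornea_strip()),
                                rates = default_rates(),
                                noise = noise_model(),
                                max_displacement = NULL) {
  stopifnot(inherits(noise, "noise_model"))
  tissues <- names(params_by_tissue)
  stopifnot(!is.null(tissues), all(tissues %in% names(geometries)),
            all(tissues %in% names(rates)))
  set.seed(noise$seed)
  out <- list()
  for (tis in tissues) {
    md <- if (!is.null(max_displacement) && tis %in% names(max_displacement))
      max_displacement[[tis]] else default_max_displacement(tis)
    for (r in rates[[tis]]) {
      cur <- simulate_tension(params_by_tissue[[tis]], geometries[[tis]],
                              loading_protocol(rate = r,
                                               max_displacement = md))
      if (noise$force_sd > 0)
        cur$force <- cur$force +
          stats::rnorm(length(cur$force), sd = noise$force_sd)
      out[[paste0(tis, "_", format(r, trim = TRUE))]] <- cur
    }
  }
  out
}

#' Generate a lamina cribrosa morphometry table
#'
#' Draws per-eye naso-temporal and longitudinal LC axes from Gaussians
#' truncated at zero and rounds to 0.01 mm, the caliper resolution of the
#' printed tables. Default design: 8 two-year-old, 8 three-year-old and
#' 4 four-year-old eyes, with the measured mean/SD per axis.
#'
#' @param n_per_age named integer vector, eyes per age class (years).
#' @param mean_axes length-2 numeric: mean naso-temporal, longitudinal
#'   axes in mm.
#' @param sd_axes length-2 numeric SDs in mm (>= 0).
#' @param seed integer RNG seed.
#' @return data.frame of class `lc_morphometry` with columns `eye_id`,
#'   `age_years`, `naso_temporal_mm`, `longitudinal_mm`.
#' @export
gen_lc_table <- function(n_per_age = c(`2` = 8L, `3` = 8L, `4` = 4L),
                         mean_axes = c(4.60, 3.68),
                         sd_axes = c(0.081, 0.109), seed = 1L) {
  stopifnot(length(mean_axes) == 2L, length(sd_axes) == 2L,
            all(sd_axes >= 0), all(mean_axes > 0))
  if (any(n_per_age < 0)) stop("negative group sizes", call. = FALSE)
  n <- sum(n_per_age)
  set.seed(seed)
  draw <- function(m, s) {
    x <- stats::rnorm(n, m, s)
    while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), m, s)
    round(x, 2)
  }
  df <- data.frame(
    eye_id = seq_len(n),
    age_years = rep(as.integer(names(n_per_age)), times = n_per_age),
    naso_temporal_mm = draw(mean_axes[1], sd_axes[1]),
    longitudinal_mm = draw(mean_axes[2], sd_axes[2]))
  class(df) <- c("lc_morphometry", "data.frame")
  df
}

#' Load the bundled bovine LC morphometry table
#'
#' Caliper measurements of the lamina cribrosa of 20 bovine eyes
#' (8 two-year-old, 8 three-year-old, 4 four-year-old): naso-temporal
#' width and longitudinal length in mm. Shipped as a package fixture;
#' summary statistics of this table drive the default eye geometry.
#'
#' @return data.frame of class `lc_morphometry`, 20 rows.
#' @export
load_lc_morphometry <- function() {
  path <- system.file("extdata", "lc_morphometry_bovine.csv",
                      package = "eyemech", mustWork = FALSE)
  if (!nzchar(path) || !file.exists(path))
    stop("bundled LC morphometry fixture not found", call. = FALSE)
  df <- utils::read.csv(path)
  need <- c("eye_id", "age_years", "naso_temporal_mm", "longitudinal_mm")
  if (!all(need %in% names(df)) || nrow(df) != 20L)
    stop("LC morphometry fixture is corrupt", call. = FALSE)
  class(df) <- c("lc_morphometry", "data.frame")
  df
}

#' Write and read LC morphometry CSV
#' @param table an `lc_morphometry` data.frame.
#' @param path file path.
#' @export
write_lc_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lc_csv
#' @export
read_lc_csv <- function(path) {
  df <- utils::read.csv(path)
  class(df) <- c("lc_morphometry", "data.frame")
  df
}
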