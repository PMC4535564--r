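#' Strip geometry for uniaxial tension
#'
#' @param width strip width in mm.
#' @param length0 grip-to-grip reference length in mm.
#' @param thickness strip thickness in mm.
#' @return Object of class `strip_geometry`.
#' @export
strip_geometry <- function(width, length0, thickness) {
  vals <- c(width = width, length0 = length0, thickness = thickness)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all strip dimensions must be finite and > 0", call. = FALSE)
  structure(as.list(vals), class = "strip_geometry")
}

#' Default bovine strip geometries
#'
#' Scleral strips measure 3.8 mm x 14.5 mm, corneal strips 9.5 mm x
#' 10 mm. Strip thicknesses were not reported; the defaults are 1.7 mm
#' for sclera (mid-range of the 1.55--1.86 mm wall measured around the
#' optic papilla) and 0.8 mm for cornea, both configurable.
#'
#' @param thickness strip thickness in mm.
#' @return A [strip_geometry()] object.
#' @export
sclera_strip <- function(thickness = 1.7)
  strip_geometry(width = 3.8, length0 = 14.5, thickness = thickness)

#' @rdname sclera_strip
#' @export
cornea_strip <- function(thickness = 0.8)
  strip_geometry(width = 9.5, length0 = 10, thickness = thickness)

#' Constant-rate loading protocol
#'
#' Crosshead displacement ramp at a constant rate, sampled every `dt`
#' seconds. `dt = NULL` picks a step giving ~200 samples. The default
#' amplitudes elsewhere in the package are 0.75 mm for scleral strips
#' (peak stretch ~1.05, peak quasi-static force ~18 N) and 1.5 mm for
#' corneal strips (peak stretch ~1.15).
#'
#' @param rate crosshead speed in mm/s.
#' @param max_displacement final displacement in mm.
#' @param dt sampling step in s, or `NULL` for automatic.
#' @return Object of class `loading_protocol`.
#' @export
loading_protocol <- function(rate, max_displacement, dt = NULL) {
  stopifnot(is.finite(rate), rate > 0,
            is.finite(max_displacement), max_displacement > 0)
  duration <- max_displacement / rate
  if (is.null(dt)) dt <- duration / 200
  stopifnot(is.finite(dt), dt > 0)
  if (dt > duration)
    stop("'dt' exceeds the total loading duration", call. = FALSE)
  structure(list(rate = rate, max_displacement = max_displacement,
                 dt = dt, duration = duration),
            class = "loading_protocol")
}

new_fd_curve <- function(time, displacement, force, geometry, rate,
                         tissue = NA_character_) {
  stopifnot(length(time) == length(displacement),
            length(time) == length(force))
  structure(list(time = time, displacement = displacement, force = force,
                 geometry = geometry, rate = rate, tissue = tissue),
            class = "fd_curve")
}

#' @export
print.fd_curve <- function(x, ...) {
  cat(sprintf(
    "<fd_curve>%s rate %g mm/s, %d samples, peak force %.3g N\n",
    if (!is.na(x$tissue)) paste0(" ", x$tissue, ",") else "",
    x$rate, length(x$time), max(x$force)))
  invisible(x)
}

#' Simulate a uniaxial strip tension experiment
#'
#' Closed-form forward model of the constant-rate strip test: the strip
#' is a homogeneous incompressible uniaxial continuum, so
#' \eqn{\lambda(t) = 1 + v t / L_0}, the Cauchy stress follows
#' [total_uniaxial_stress()], and the recorded force is
#' \eqn{F = \sigma A_0 / \lambda} using the current cross-section
#' \eqn{A(t) = A_0/\lambda} implied by incompressibility. For a uniform
#' strip this closed form coincides with a meshed finite-element solution
#' of the same law, and provides an exact kernel for inverse fitting.
#'
#' @param params a [material_params()] object.
#' @param geom a [strip_geometry()].
#' @param protocol a [loading_protocol()].
#' @param strain strain convention for the viscoelastic integral, see
#'   [deformation_history()].
#' @return A force--displacement curve (class `fd_curve`) with fields
#'   `time` (s), `displacement` (mm), `force` (N), `geometry`, `rate`,
#'   `tissue`.
#' @export
simulate_tension <- function(params, geom, protocol,
                             strain = c("engineering", "logarithmic")) {
  stopifnot(inherits(params, "material_params"),
            inherits(geom, "strip_geometry"),
            inherits(protocol, "loading_protocol"))
  strain <- match.arg(strain)
  tt <- seq(0, protocol$duration, by = protocol$dt)
  if (tt[length(tt)] < protocol$duration - 1e-12 * protocol$duration)
    tt <- c(tt, protocol$duration)
  disp <- protocol$rate * tt
  lam <- 1 + disp / geom$length0
  hist <- deformation_history(tt, lam, strain = strain)
  sigma <- total_uniaxial_stress(params, hist)
  a0 <- geom$width * geom$thickness
  force <- sigma * a0 / lam
  new_fd_curve(tt, disp, force, geom, protocol$rate, params$tissue)
}

#' Root-mean-square force error between two curves
#'
#' Fitness kernel of the inverse-identification loop: the observed curve
#' is resampled onto the simulated displacement grid by linear
#' interpolation and the RMS force difference is returned. The curves
#' must share loading rate and strip geometry; displacement ranges must
#' overlap.
#'
#' @param simulated,observed `fd_curve` objects.
#' @return RMS force error in N (>= 0; 0 iff identical on the grid).
#' @export
curve_rmse <- function(simulated, observed) {
  stopifnot(inherits(simulated, "fd_curve"), inherits(observed, "fd_curve"))
  if (!isTRUE(all.equal(simulated$rate, observed$rate)))
    stop("curves were recorded at different rates", call. = FALSE)
  g1 <- unlist(simulated$geometry); g2 <- unlist(observed$geometry)
  if (!isTRUE(all.equal(g1, g2)))
    stop("curves have different strip geometries", call. = FALSE)
  lo <- max(min(simulated$displacement), min(observed$displacement))
  hi <- min(max(simulated$displacement), max(observed$displacement))
  if (hi <= lo)
    stop("displacement ranges do not overlap", call. = FALSE)
  keep <- simulated$displacement >= lo & simulated$displacement <= hi
  obs_f <- stats::approx(observed$displacement, observed$force,
                         xout = simulated$displacement[keep])$y
  sqrt(mean((simulated$force[keep] - obs_f)^2))
}

#' Read and write force--displacement curves as CSV
#'
#' Plain CSV with columns `time_s`, `displacement_mm`, `force_N`,
#' preceded by a `#`-prefixed header block carrying the strip geometry,
#' rate and tissue label, so a curve round-trips losslessly.
#'
#' @param curve an `fd_curve`.
#' @param path file path.
#' @return `read_curve_csv` returns an `fd_curve`; `write_curve_csv`
#'   returns `path` invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "fd_curve"))
  g <- curve$geometry
  hdr <- c(
    sprintf("# tissue: %s", curve$tissue),
    sprintf("# rate_mm_s: %.17g", curve$rate),
    sprintf("# width_mm: %.17g", g$width),
    sprintf("# length0_mm: %.17g", g$length0),
    sprintf("# thickness_mm: %.17g", g$thickness))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(
    data.frame(time_s = curve$time, displacement_mm = curve$displacement,
               force_N = curve$force),
    con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  need <- c("rate_mm_s", "width_mm", "length0_mm", "thickness_mm")
  if (!all(need %in% names(meta)))
    stop("curve CSV is missing metadata header lines", call. = FALSE)
  df <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  geom <- strip_geometry(as.numeric(meta$width_mm),
                         as.numeric(meta$length0_mm),
                         as.numeric(meta$thickness_mm))
  new_fd_curve(df$time_s, df$displacement_mm, df$force_N, geom,
               as.numeric(meta$rate_mm_s),
               if (is.null(meta$tissue)) NA_character_ else meta$tissue)
}
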