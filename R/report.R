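#' Summary statistics of an LC morphometry table
#'
#' Mean, SD, minimum and maximum of the naso-temporal and longitudinal
#' lamina cribrosa axes. The SD uses the population (n) denominator by
#' default: the printed summary of the reference 20-eye table matches
#' the n-denominator value (0.081 naso-temporal; the n-1 value would be
#' 0.083). The sample (n-1) variant is available via `sd_type`.
#'
#' @param table an `lc_morphometry` data.frame (e.g.
#'   [load_lc_morphometry()] or [gen_lc_table()]).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return data.frame with rows `naso_temporal` and `longitudinal` and
#'   columns `mean`, `sd`, `min`, `max` (mm, unrounded).
#' @export
lc_summary_stats <- function(table, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (is.null(nrow(table)) || nrow(table) == 0L)
    stop("empty morphometry table", call. = FALSE)
  one <- function(x) {
    s <- if (sd_type == "population")
      sqrt(mean((x - mean(x))^2)) else stats::sd(x)
    if (length(x) == 1L) s <- 0
    c(mean = mean(x), sd = s, min = min(x), max = max(x))
  }
  out <- rbind(naso_temporal = one(table$naso_temporal_mm),
               longitudinal = one(table$longitudinal_mm))
  as.data.frame(out)
}

#' Round LC summaries the way the reference table prints them
#'
#' Two decimals for means/min/max, three for SDs.
#' @param stats output of [lc_summary_stats()].
#' @return data.frame of the same shape, rounded.
#' @export
format_lc_summary <- function(stats) {
  out <- stats
  out$mean <- round(stats$mean, 2)
  out$min <- round(stats$min, 2)
  out$max <- round(stats$max, 2)
  out$sd <- round(stats$sd, 3)
  out
}

#' End-to-end pipeline configuration
#'
#' @param seed master RNG seed; every stochastic stage derives from it.
#' @param out_dir output directory (created if missing).
#' @param stages character vector of stages to run, in order, among
#'   `"curves"` (synthetic multi-rate tensile dataset), `"fit"` (inverse
#'   identification per tissue), `"morphometry"` (LC table + summary),
#'   `"mesh"` (eye geometry + quality report), `"pressurize"` (IOP
#'   sweep + regional summaries).
#' @param iops IOP levels in mmHg (non-empty).
#' @param force_sd synthetic force noise SD in N.
#' @param fit_pop,fit_generations GA settings for the fit stage.
#' @param geometry an [eye_geometry_config()].
#' @param use_fitted if `TRUE` (default) the pressurization uses the
#'   stage-fitted parameters; otherwise the reference materials.
#' @param lc_soften LC softening factor, see [lc_material()].
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = "eyemech_run",
                            stages = c("curves", "fit", "morphometry",
                                       "mesh", "pressurize"),
                            iops = c(10, 30, 60, 100), force_sd = 0.2,
                            fit_pop = 100L, fit_generations = 100L,
                            geometry = eye_geometry_config(),
                            use_fitted = TRUE, lc_soften = 0.5) {
  known <- c("curves", "fit", "morphometry", "mesh", "pressurize")
  stopifnot(all(stages %in% known))
  if (length(iops) == 0L) stop("IOP list must be non-empty", call. = FALSE)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 stages = stages, iops = iops, force_sd = force_sd,
                 fit_pop = as.integer(fit_pop),
                 fit_generations = as.integer(fit_generations),
                 geometry = geometry, use_fitted = use_fitted,
                 lc_soften = lc_soften),
            class = "pipeline_config")
}

.log_stage <- function(stage, msg, t0) {
  message(sprintf("[eyemech] %-12s %6.1fs  %s", stage,
                  as.numeric(Sys.time()) - t0, msg))
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order -- synthetic curves, inverse
#' fit, LC morphometry summary, eye mesh with quality report, and the
#' IOP pressure sweep with regional summaries -- writing every artifact
#' as plain text (CSV / VTK / JSON) under `config$out_dir` and returning
#' a manifest of files with MD5 content hashes. Deterministic given the
#' seed: rerunning with the same configuration reproduces identical
#' hashes.
#'
#' @param config a [pipeline_config()].
#' @return data.frame manifest (`file`, `md5`), invisibly also written
#'   to `manifest.csv`. An empty stage list yields an empty manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- as.numeric(Sys.time())
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(path) written <<- c(written, path)
  stage_wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }
  mats <- bovine_eye_materials()
  curves <- NULL; fitted <- NULL
  if ("curves" %in% config$stages) stage_wrap("curves", {
    curves <- gen_tensile_dataset(
      noise = noise_model(force_sd = config$force_sd, seed = config$seed))
    for (nm in names(curves)) {
      p <- file.path(config$out_dir, paste0("curve_", nm, ".csv"))
      write_curve_csv(curves[[nm]], p); emit(p)
    }
    .log_stage("curves", sprintf("%d curves", length(curves)), t0)
  })
  if ("fit" %in% config$stages) stage_wrap("fit", {
    if (is.null(curves))
      stop("'fit' requires the 'curves' stage")
    fitted <- list()
    for (tis in c("sclera", "cornea")) {
      sel <- curves[grep(paste0("^", tis, "_"), names(curves))]
      fr <- nsga2_fit(sel, config = fit_config(
        pop_size = config$fit_pop,
        generations = config$fit_generations,
        seed = config$seed))
      fitted[[tis]] <- fr$best
      pp <- file.path(config$out_dir, paste0("pareto_", tis, ".csv"))
      utils::write.csv(fr$pareto, pp, row.names = FALSE); emit(pp)
      cp <- file.path(config$out_dir, paste0("convergence_", tis, ".csv"))
      utils::write.csv(data.frame(generation = seq_along(fr$trace),
                                  summed_rmse = fr$trace),
                       cp, row.names = FALSE); emit(cp)
      bp <- file.path(config$out_dir, paste0("best_params_", tis, ".json"))
      jsonlite::write_json(
        list(alpha = fr$best$alpha, mu = fr$best$mu,
             beta = fr$best$beta, g_visc = fr$best$g_visc),
        bp, auto_unbox = TRUE, digits = NA)
      emit(bp)
      .log_stage("fit", sprintf("%s: alpha=%.3g mu=%.3g", tis,
                                fr$best$alpha, fr$best$mu), t0)
    }
  })
  if ("morphometry" %in% config$stages) stage_wrap("morphometry", {
    tab <- load_lc_morphometry()
    st <- format_lc_summary(lc_summary_stats(tab))
    p1 <- file.path(config$out_dir, "lc_morphometry.csv")
    write_lc_csv(tab, p1); emit(p1)
    p2 <- file.path(config$out_dir, "lc_summary.csv")
    utils::write.csv(cbind(axis = rownames(st), st), p2,
                     row.names = FALSE); emit(p2)
    .log_stage("morphometry", sprintf("NT mean %.2f mm", st$mean[1]), t0)
  })
  mesh <- NULL
  if ("mesh" %in% config$stages) stage_wrap("mesh", {
    mesh <- build_eye_mesh(config$geometry)
    q <- mesh_quality(mesh)
    p1 <- file.path(config$out_dir, "eye_mesh.vtk")
    write_mesh_vtk(mesh, p1); emit(p1)
    p2 <- file.path(config$out_dir, "mesh_quality.csv")
    utils::write.csv(data.frame(
      min_scaled_jacobian = q$min_scaled_jacobian,
      min_angle_deg = q$min_angle, n_flagged = q$n_flagged),
      p2, row.names = FALSE); emit(p2)
    .log_stage("mesh", sprintf("%d facets, %d flagged",
                               nrow(mesh$quads), q$n_flagged), t0)
  })
  if ("pressurize" %in% config$stages) stage_wrap("pressurize", {
    if (is.null(mesh)) mesh <- build_eye_mesh(config$geometry)
    use <- if (config$use_fitted && !is.null(fitted)) fitted else mats
    matmap <- list(cornea = use$cornea, sclera = use$sclera,
                   sclera_anterior = use$sclera,
                   sclera_posterior = use$sclera,
                   lamina_cribrosa = lc_material(use$sclera,
                                                 config$lc_soften))
    sweep <- pressure_sweep(mesh, matmap, config$iops)
    summaries <- list()
    for (nm in names(sweep)) {
      r <- sweep[[nm]]
      p <- file.path(config$out_dir, paste0("field_", nm, ".vtk"))
      write_mesh_vtk(mesh, p, cell_fields = list(
        vm_stress = r$vm_stress, eq_strain = r$eq_strain))
      emit(p)
      s <- regional_summary(r)
      s$iop_mmhg <- r$load$iop
      summaries[[nm]] <- s
      .log_stage("pressurize",
                 sprintf("%s: peak vm %.4g MPa", nm, max(r$vm_stress)), t0)
    }
    p <- file.path(config$out_dir, "regional_summary.csv")
    utils::write.csv(do.call(rbind, summaries), p, row.names = FALSE)
    emit(p)
  })
  manifest <- data.frame(
    file = basename(written),
    md5 = unname(tools::md5sum(written)))
  utils::write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
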