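# End-to-end orchestration: generate -> preprocess -> measure -> fit ->
# model -> radial statistics -> report, from a single configuration, with
# a reproducibility manifest.

#' Pipeline run configuration
#'
#' Builds the configuration list consumed by [run_pipeline()].  The
#' default acquisition is a reduced-geometry demonstration session (same
#' 5 x 5 mm field and trial structure, coarser sampling) so a full run
#' completes in seconds; pass a full-scale [acquisition_config()] to
#' emulate the recording geometry exactly.
#'
#' @param out Output directory.
#' @param seed Master seed; stage seeds derive from it.
#' @param stages Character vector of stages to run, a subset of
#'   `simulate`, `preprocess`, `measure`, `fit`, `model`, `radial`,
#'   `report` (stage dependencies are pulled in automatically).
#' @param acquisition An [acquisition_config()].
#' @param analysis An [analysis_config()].
#' @param grid_azimuth,grid_elevation Retinotopy grid in degrees.
#' @param magnification Generator magnification, mm/deg.
#' @param model_S,model_alpha Model sweep values.
#' @param radial_n_sites,radial_jitter_sd,radial_n_iter Radial-statistics
#'   settings.
#' @return A named list of class `run_config`.
#' @export
pipeline_config <- function(out = file.path(tempdir(), "proximap-run"),
                            seed = 1,
                            stages = c("simulate", "preprocess", "measure",
                                       "fit", "model", "radial", "report"),
                            acquisition = acquisition_config(
                              frame_rate = 10, trial_duration = 4,
                              image_rows = 40, image_cols = 40,
                              pixel_pitch = 0.125, n_trials = 8),
                            analysis = analysis_config(),
                            grid_azimuth = seq(-40, 40, by = 20),
                            grid_elevation = seq(-30, 30, by = 20),
                            magnification = 0.022,
                            model_S = c(3, 5, 7, 10, 20, 30),
                            model_alpha = 1,
                            radial_n_sites = 20,
                            radial_jitter_sd = 10,
                            radial_n_iter = 200) {
  structure(list(out = out, seed = seed, stages = stages,
                 acquisition = acquisition, analysis = analysis,
                 grid_azimuth = grid_azimuth,
                 grid_elevation = grid_elevation,
                 magnification = magnification,
                 model_S = model_S, model_alpha = model_alpha,
                 radial_n_sites = radial_n_sites,
                 radial_jitter_sd = radial_jitter_sd,
                 radial_n_iter = radial_n_iter),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields override the [pipeline_config()] defaults; the
#' `acquisition` and `analysis` mappings are passed to their
#' constructors.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$acquisition))
    args$acquisition <- do.call(acquisition_config, y$acquisition)
  if (!is.null(y$analysis))
    args$analysis <- do.call(analysis_config, y$analysis)
  for (f in setdiff(names(y), c("acquisition", "analysis")))
    args[[f]] <- if (f == "stages") unlist(y[[f]]) else y[[f]]
  do.call(pipeline_config, args)
}

stage_order <- c("simulate", "preprocess", "measure", "fit", "model",
                 "radial", "report")

session_zmaps <- function(session, cfg) {
  pre <- function(st) temporal_normalize(
    subtract_border_trend(st, cfg$border_width))
  blank <- pre(session$blank)
  lapply(session$stacks, function(st)
    compute_static_zscore_map(pre(st), blank, cfg))
}

#' Run the analysis pipeline
#'
#' Executes the configured stages, writing per-stage outputs and a
#' reproducibility manifest under `cfg$out`.  Reruns with the same
#' configuration reproduce all outputs bit-identically.  A stage failure
#' halts the run with a labelled error; outputs of completed stages are
#' retained.
#'
#' @param cfg A `run_config` (from [pipeline_config()] or
#'   [read_run_config()]), or a YAML path.
#' @return Invisibly, a list of in-memory stage results (metrics table,
#'   fits, model sweep, radial results, manifest).
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  stages <- stage_order[stage_order %in% cfg$stages]
  # pull in upstream dependencies
  need <- function(s) stage_order[seq_len(match(s, stage_order))]
  if (any(c("preprocess", "measure", "fit") %in% stages))
    stages <- union(need("simulate"), stages)
  if (any(c("measure", "fit") %in% stages))
    stages <- union(need("preprocess"), stages)
  stages <- stage_order[stage_order %in% stages]
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  st <- new.env(parent = emptyenv())
  for (stage in stages) {
    res <- tryCatch(run_stage(stage, cfg, st),
                    error = function(e)
                      stop("stage '", stage, "' failed: ",
                           conditionMessage(e), call. = FALSE))
    res
  }
  invisible(as.list(st))
}

run_stage <- function(stage, cfg, st) {
  acfg <- cfg$analysis
  switch(stage,
    simulate = {
      st$retino <- generate_retinotopy_session(
        cfg$acquisition, cfg$grid_azimuth, cfg$grid_elevation,
        magnification = cfg$magnification, seed = cfg$seed)
      st$intensity <- generate_intensity_series(
        cfg$acquisition, seed = cfg$seed + 1000)
      write_session_metadata(st$retino,
                             file.path(cfg$out, "retinotopy_conditions.csv"))
      write_session_metadata(st$intensity,
                             file.path(cfg$out, "intensity_conditions.csv"))
    },
    preprocess = {
      st$retino_z <- session_zmaps(st$retino, acfg)
      st$intensity_z <- session_zmaps(st$intensity, acfg)
    },
    measure = {
      pitch <- cfg$acquisition$pixel_pitch
      st$polar <- build_polar_maps(st$retino_z, st$retino$metadata)
      metrics <- measure_zmaps(st$retino_z, st$retino$metadata, acfg, pitch)
      # positional error against the polar-map expected position
      mag <- magnification_from_metrics(metrics, st$retino$metadata, pitch)
      err <- vapply(seq_len(nrow(metrics)), function(k) {
        if (metrics$empty[k]) return(NA_real_)
        exp_px <- expected_cortical_position(
          st$polar, c(st$retino$metadata$position_deg_x[k],
                      st$retino$metadata$position_deg_y[k]))
        positional_error(exp_px * pitch,
                         c(metrics$com_row_mm[k], metrics$com_col_mm[k]),
                         mag)$error_mm
      }, 0)
      metrics$error_mm <- err
      metrics$error_deg_eq <- err / mag
      st$metrics <- metrics
      st$measured_magnification <- mag
      utils::write.csv(metrics, file.path(cfg$out, "metrics.csv"),
                       row.names = FALSE)
    },
    fit = {
      imet <- measure_zmaps(st$intensity_z, st$intensity$metadata, acfg,
                            cfg$acquisition$pixel_pitch)
      # peak rectified amplitude on the smoothed map: smoothing drops the
      # noise floor that would otherwise compress the low-intensity end
      amp <- -vapply(st$intensity_z, function(z)
        min(smooth_flat(z$values, acfg$smooth_kernel)), 0)
      lev <- st$intensity$metadata$luminance_cd_m2
      st$nr_fit <- fit_naka_rushton(lev, amp)
      st$fits <- list(
        magnification_mm_per_deg = st$measured_magnification,
        naka_rushton = as.list(coef(st$nr_fit)),
        operational_range = operational_range(st$nr_fit))
      jsonlite::write_json(st$fits, file.path(cfg$out, "fits.json"),
                           auto_unbox = TRUE, digits = NA)
      utils::write.csv(data.frame(intensity = lev, amplitude = amp),
                       file.path(cfg$out, "intensity_response.csv"),
                       row.names = FALSE)
    },
    model = {
      st$model_sweep <- model_ar_sweep(cfg$model_S, cfg$model_alpha)
      utils::write.csv(st$model_sweep,
                       file.path(cfg$out, "model_sweep.csv"),
                       row.names = FALSE)
    },
    radial = {
      set <- generate_elongated_set(cfg$radial_n_sites,
                                    od_position = c(0, 0),
                                    angular_jitter_sd = cfg$radial_jitter_sd,
                                    seed = cfg$seed + 2000)
      fit <- optimize_radial_center(set)
      null <- monte_carlo_null(set, n_iter = cfg$radial_n_iter,
                               seed = cfg$seed + 3000)
      p <- gaussian_p(null, fit$median_deviation)
      st$radial <- list(optimal_center = as.list(fit$optimal_center),
                        median_deviation = fit$median_deviation,
                        null_mean = null$mean, null_sd = null$sd,
                        p_empirical = p$p_empirical,
                        p_gaussian = p$p_gaussian, z = p$z)
      jsonlite::write_json(st$radial, file.path(cfg$out, "radial.json"),
                           auto_unbox = TRUE, digits = NA)
    },
    report = {
      if (!is.null(st$metrics)) {
        tab <- make_fig8_table(transform(st$metrics, class = "visual",
                                         size_mm = extent_mm))
        utils::write.csv(tab, file.path(cfg$out, "size_ar_summary.csv"),
                         row.names = FALSE)
        st$size_ar_summary <- tab
      }
      st$manifest <- pipeline_manifest(cfg)
      jsonlite::write_json(st$manifest,
                           file.path(cfg$out, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
    },
    stop("unknown stage: ", stage))
  invisible(NULL)
}

measure_zmaps <- function(zmaps, metadata, acfg, pitch) {
  rows <- lapply(seq_along(zmaps), function(k) {
    z <- zmaps[[k]]
    reg <- extract_activation(z, acfg)
    if (is_empty(reg))
      return(data.frame(label = metadata$label[k], com_row_mm = NA,
                        com_col_mm = NA, extent_mm = NA, ar = NA,
                        orientation_deg = NA, amplitude_z = min(z$values),
                        n_pixels = 0L, empty = TRUE))
    com <- center_of_mass(z, reg)
    ell <- equivalent_ellipse(reg, pitch)
    data.frame(label = metadata$label[k],
               com_row_mm = com[["row"]] * pitch,
               com_col_mm = com[["col"]] * pitch,
               extent_mm = ell$equivalent_diameter,
               ar = ell$aspect_ratio, orientation_deg = ell$orientation,
               amplitude_z = min(z$values),
               n_pixels = reg$n_pixels, empty = FALSE)
  })
  do.call(rbind, rows)
}

# Azimuth-only magnification fit from measured centers of mass: pairs of
# conditions sharing an elevation row.
magnification_from_metrics <- function(metrics, metadata, pitch) {
  ok <- !metrics$empty
  vis <- c(); cort <- c()
  idx <- which(ok)
  for (a in idx) for (b in idx) {
    if (a < b && metadata$position_deg_y[a] == metadata$position_deg_y[b]) {
      vis <- c(vis, abs(metadata$position_deg_x[a] -
                        metadata$position_deg_x[b]))
      cort <- c(cort, sqrt((metrics$com_row_mm[a] - metrics$com_row_mm[b])^2 +
                           (metrics$com_col_mm[a] - metrics$com_col_mm[b])^2))
    }
  }
  fit_magnification(vis, cort, intercept = FALSE)$slope
}

pipeline_manifest <- function(cfg) {
  # hash identifies the scientific configuration, not the output location
  keep <- setdiff(names(cfg), "out")
  canon <- jsonlite::toJSON(cfg[sort(keep)], auto_unbox = TRUE,
                            digits = NA, force = TRUE)
  tf <- tempfile(); writeLines(as.character(canon), tf)
  hash <- unname(tools::md5sum(tf)); unlink(tf)
  list(config_hash = hash, seed = cfg$seed, stages = cfg$stages,
       package_version = as.character(utils::packageVersion("proximap")),
       r_version = paste(R.version$major, R.version$minor, sep = "."))
}

#' Grouped size-vs-aspect-ratio summary
#'
#' Per stimulation class, the mean and standard error of activation size
#' and aspect ratio, and their correlation -- the diagnostic separating
#' visual-like activation (aspect ratio independent of size) from
#' electrically diffused activation (size and aspect ratio inversely
#' related).
#'
#' @param metrics `data.frame` with columns `class`, `size_mm` and `ar`.
#' @return `data.frame`, one row per class: n, mean/sem of size and AR,
#'   Pearson correlation between them, and a `flagged` column for
#'   classes with fewer than 2 observations (sem undefined).
#' @export
make_fig8_table <- function(metrics) {
  stopifnot(all(c("class", "size_mm", "ar") %in% names(metrics)))
  metrics <- metrics[stats::complete.cases(metrics[, c("size_mm", "ar")]), ]
  sem <- function(x) if (length(x) < 2) NA_real_
                     else stats::sd(x) / sqrt(length(x))
  out <- do.call(rbind, lapply(split(metrics, metrics$class), function(g) {
    data.frame(class = g$class[1], n = nrow(g),
               size_mean = mean(g$size_mm), size_sem = sem(g$size_mm),
               ar_mean = mean(g$ar), ar_sem = sem(g$ar),
               size_ar_cor = if (nrow(g) >= 3 && stats::sd(g$size_mm) > 0 &&
                                 stats::sd(g$ar) > 0)
                 stats::cor(g$size_mm, g$ar) else NA_real_,
               flagged = nrow(g) < 2)
  }))
  rownames(out) <- NULL
  out
}
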