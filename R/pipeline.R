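#' Pipeline configuration
#'
#' All stage parameters in one validated structure, grouped by stage. The
#' defaults are the package's working configuration: sigmoid `alpha = -0.5`,
#' `beta = 3`; level-set `c = 2`, `mu = 0.2`, `lam = 5`, phase-1
#' `area_alpha = -1` (phase 2 always drops the area term), `epsilon = 1.5`,
#' 40 inner and 15 outer iterations. Distance scales (`energy.sigma`,
#' `energy.t_d`, `energy.d_t`) and the fast-marching time threshold
#' (`fm.t_star`) are geometry knobs in pixel/time units.
#'
#' The sigmoid `alpha`/`beta` and the energy-tune `tune_alpha`/`tune_beta`
#' are unrelated parameters that happen to share symbol names in the
#' literature; they live in separate groups here.
#'
#' @param ... named overrides as `group.key = value`, e.g.
#'   `fm.t_star = 60`, `mdrls.inner_iters = 20`.
#' @return a nested list of class `pipeline_config`.
#' @examples
#' cfg <- pipeline_config(fm.t_star = 80, preprocess.n_iters = 3)
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    preprocess = list(conductance = 10, time_step = 0.0625, n_iters = 40L,
                      sigma = 1),
    sigmoid = list(alpha = -0.5, beta = 3, out_min = 0, out_max = 1),
    energy = list(sigma = 10, t_d = 1.5, d_t = 2, tune_alpha = 1,
                  tune_beta = 1, boundary_only = FALSE, edge_sigma = 2),
    fm = list(t_star = 100),
    mdrls = list(mu = 0.2, lam = 5, area_alpha = -1, epsilon = 1.5,
                 time_step = 1, inner_iters = 40L, outer_iters = 15L, c = 2),
    post = list(radius = 2L, min_component = 20L)
  )
  cfg <- apply_overrides(cfg, list(...))
  validate_config(cfg)
}

#' Load a pipeline configuration from YAML
#'
#' The file mirrors the [pipeline_config()] groups
#' (`preprocess:`, `sigmoid:`, `energy:`, `fm:`, `mdrls:`, `post:`); keys not
#' present keep their defaults, unknown keys are rejected, and all stage
#' invariants are enforced before any computation.
#'
#' @param path YAML file path.
#' @return a validated `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  doc <- yaml::read_yaml(path)
  flat <- list()
  for (grp in names(doc)) {
    for (key in names(doc[[grp]])) {
      flat[[paste(grp, key, sep = ".")]] <- doc[[grp]][[key]]
    }
  }
  do.call(pipeline_config, flat)
}

#' Write a resolved configuration to YAML
#'
#' @param config a `pipeline_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Segment one slice with the hybrid pipeline
#'
#' Runs the full chain in memory: anisotropic denoising, Gaussian gradient
#' magnitude, sigmoid speed map, energy decrement along the standard line
#' (when one is given), multi-seed fast marching, time-threshold extraction
#' of the initial region, energy tune of the edge map (line-based when a
#' line is given, automatic otherwise), two-phase modified DRLSE, zero-level
#' thresholding and morphological cleanup.
#'
#' Without a standard line the fast-marching stage runs on the raw speed map
#' and the automatic energy tune drives the level-set stage. With
#' `energy_tune = FALSE` the level-set stage uses the plain edge-indicator
#' map — useful for quantifying how much the energy tune suppresses leakage.
#'
#' @param image numeric intensity matrix.
#' @param seeds integer matrix of 1-based `(row, col)` seed pixels inside the
#'   target organ.
#' @param line optional standard-line vertex matrix (1-based), or `NULL`.
#' @param config a [pipeline_config()].
#' @param energy_tune apply the energy-tune re-weighting (default `TRUE`).
#' @param keep_intermediates return intermediate maps as well.
#' @return a list with `mask` (final cleaned mask), `initial_region`, `phi`
#'   (final level-set), `et` (map driving the level-set stage) and, when
#'   `keep_intermediates = TRUE`, `denoised`, `gm`, `speed`, `fm_energy`,
#'   `time_map`.
#' @export
segment_slice <- function(image, seeds, line = NULL,
                          config = pipeline_config(), energy_tune = TRUE,
                          keep_intermediates = FALSE) {
  image <- as_image_matrix(image)
  seeds <- validate_seeds(seeds, dim(image))
  if (!is.null(line)) line <- validate_line(line, dim(image))

  p <- config$preprocess
  den <- stage("preprocess", mcde_denoise(image, p$conductance, p$time_step,
                                          p$n_iters))
  gm <- stage("preprocess", gradient_magnitude(den, p$sigma))

  s <- config$sigmoid
  speed <- stage("feature_maps",
                 sigmoid_speed(gm, s$alpha, s$beta, s$out_min, s$out_max))

  en <- config$energy
  d_line <- NULL
  fm_energy <- speed
  if (!is.null(line)) {
    d_line <- stage("energy", distance_to_line(line, dim(image)))
    fm_energy <- stage("energy", energy_decrement(speed, d_line, en$t_d))
  }

  tm <- stage("fast_marching", solve_eikonal(fm_energy, seeds))
  r0 <- stage("fast_marching", extract_initial_region(tm, config$fm$t_star))

  # the edge chain may use a wider Gaussian than the speed chain: the
  # level-set stage needs a low noise floor in g more than sharp localization
  gm_edge <- if (isTRUE(all.equal(en$edge_sigma, p$sigma))) gm else
    stage("preprocess", gradient_magnitude(den, en$edge_sigma))
  g <- stage("feature_maps", edge_indicator(gm_edge))
  if (isTRUE(energy_tune)) {
    e_src <- stage("energy", source_energy(r0, g, en$sigma, en$boundary_only))
    d_src <- stage("energy", distance_to_mask(r0))
    et <- if (!is.null(line)) {
      stage("energy", energy_tune_line(g, e_src, r0, d_line, d_src,
                                       en$tune_alpha, en$tune_beta))
    } else {
      stage("energy", energy_tune_auto(g, e_src, r0, d_src, en$d_t,
                                       en$tune_alpha, en$tune_beta))
    }
  } else {
    et <- g
  }

  m <- config$mdrls
  params <- mdrls_params(m$mu, m$lam, m$area_alpha, m$epsilon, m$time_step,
                         m$inner_iters, m$outer_iters, m$c)
  phi0 <- stage("mdrls", init_lsf(r0, m$c))
  phi <- stage("mdrls", segment_two_phase(phi0, et, params))

  mask <- stage("postprocess", lsf_to_mask(phi))
  mask <- stage("postprocess",
                morphological_cleanup(mask, config$post$radius,
                                      config$post$min_component))

  out <- list(mask = mask, initial_region = r0, phi = phi, et = et)
  if (isTRUE(keep_intermediates)) {
    out <- c(out, list(denoised = den, gm = gm, speed = speed,
                       fm_energy = fm_energy, time_map = tm))
  }
  out
}

#' Run the pipeline on files and write all artifacts
#'
#' File-level wrapper over [segment_slice()]: reads the image
#' ([read_image()]) and the seeds/standard-line JSON ([read_annotation()]),
#' runs the pipeline, and writes into `out_dir` the final mask
#' (`final_mask.png`), the initial region (`initial_region.png`), the fully
#' resolved configuration (`config_resolved.yaml`), a run log with all
#' effective parameters (`run_log.txt`), optional intermediate maps, and —
#' when a ground-truth mask is supplied — a metrics report
#' (`metrics.json`, appended `metrics.csv`).
#'
#' @param image_path input image file (PNG/NIfTI/CSV).
#' @param annotation_path seeds and optional standard-line JSON.
#' @param out_dir output directory (created if needed).
#' @param config_path optional YAML configuration; defaults used if `NULL`.
#' @param truth_path optional ground-truth mask PNG for evaluation.
#' @param save_intermediates write intermediate maps as PNGs.
#' @param energy_tune apply the energy-tune re-weighting.
#' @param slice NIfTI slice index passed to [read_image()].
#' @return the [segment_slice()] result, with `metrics` attached when truth
#'   is given, invisibly.
#' @export
run_pipeline <- function(image_path, annotation_path, out_dir,
                         config_path = NULL, truth_path = NULL,
                         save_intermediates = FALSE, energy_tune = TRUE,
                         slice = 1L) {
  config <- if (is.null(config_path)) pipeline_config()
            else stage("config", load_config(config_path))
  image <- stage("input", read_image(image_path, slice))
  ann <- stage("input", read_annotation(annotation_path))

  res <- segment_slice(image, ann$seeds, ann$line, config,
                       energy_tune = energy_tune,
                       keep_intermediates = save_intermediates)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_mask_png(res$mask, file.path(out_dir, "final_mask.png"))
  write_mask_png(res$initial_region, file.path(out_dir, "initial_region.png"))
  write_config(config, file.path(out_dir, "config_resolved.yaml"))
  if (isTRUE(save_intermediates)) {
    for (nm in c("gm", "speed", "fm_energy", "et")) {
      v <- res[[nm]]
      rng <- range(v[is.finite(v)])
      norm <- (v - rng[1]) / max(rng[2] - rng[1], 1e-12)
      norm[!is.finite(norm)] <- 1
      png::writePNG(pmin(pmax(norm, 0), 1),
                    file.path(out_dir, paste0(nm, ".png")))
    }
  }

  log_lines <- c(
    sprintf("pancseg run %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("image: %s", image_path),
    sprintf("annotation: %s (standard line: %s)", annotation_path,
            if (is.null(ann$line)) "absent, automatic variant" else "present"),
    sprintf("energy_tune: %s", energy_tune),
    sprintf("initial region: %d px; final mask: %d px",
            sum(res$initial_region), sum(res$mask)),
    "effective parameters:",
    utils::capture.output(utils::str(unclass(config), give.head = FALSE))
  )

  if (!is.null(truth_path)) {
    truth <- stage("input", read_mask_png(truth_path))
    res$metrics <- stage("metrics", compute_metrics(res$mask, truth))
    write_metrics(res$metrics,
                  json_path = file.path(out_dir, "metrics.json"),
                  csv_path = file.path(out_dir, "metrics.csv"),
                  id = basename(image_path))
    log_lines <- c(log_lines,
                   sprintf("metrics: FPE=%.5f FNE=%.5f SI=%.5f",
                           res$metrics$fpe, res$metrics$fne, res$metrics$si))
  }
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(res)
}

# ---- internal ---------------------------------------------------------------

# wrap a stage so failures carry the stage name
stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

apply_overrides <- function(cfg, dots) {
  if (length(dots) == 0L) return(cfg)
  if (is.null(names(dots)) || any(names(dots) == "")) {
    stop("config overrides must be named group.key = value")
  }
  for (nm in names(dots)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2L || is.null(cfg[[parts[1]]]) ||
        !parts[2] %in% names(cfg[[parts[1]]])) {
      stop("unknown configuration key: ", nm)
    }
    cfg[[parts[1]]][[parts[2]]] <- dots[[nm]]
  }
  cfg
}

validate_config <- function(cfg) {
  p <- cfg$preprocess
  if (p$time_step <= 0 || p$time_step > 0.25) {
    stop("preprocess.time_step must be in (0, 0.25]")
  }
  stopifnot(p$conductance > 0, p$n_iters >= 0, p$sigma > 0)
  if (cfg$sigmoid$alpha == 0) stop("sigmoid.alpha must be nonzero")
  if (cfg$sigmoid$out_min >= cfg$sigmoid$out_max) {
    stop("sigmoid.out_min must be smaller than sigmoid.out_max")
  }
  en <- cfg$energy
  stopifnot(en$sigma > 0, en$t_d >= 0, en$d_t > 0, en$edge_sigma > 0)
  if (cfg$fm$t_star < 0) stop("fm.t_star must be non-negative")
  m <- cfg$mdrls
  if (m$mu * m$time_step >= 0.25) {
    stop("mdrls: need mu * time_step < 0.25 for stability")
  }
  stopifnot(m$lam > 0, m$epsilon > 0, m$c > 0,
            m$inner_iters >= 0, m$outer_iters >= 0)
  stopifnot(cfg$post$radius >= 1, cfg$post$min_component >= 1)
  structure(cfg, class = "pipeline_config")
}
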