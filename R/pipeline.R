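#' @title End-to-end pipeline orchestration
#' @description One configuration object (serialisable to YAML) describes
#'   biology, trench geometry, optics, camera and export; [run_pipeline()]
#'   executes simulate -> render -> optics -> camera -> export under a
#'   single seed, writing the dataset, its manifest, and a JSON run log
#'   with per-stage timings.
#' @name cli_config
NULL

#' Assemble a pipeline configuration
#'
#' @param sim a [sim_config()].
#' @param geometry a [trench_geometry()].
#' @param intensities a [render_intensities()].
#' @param psf a [psf_config()].
#' @param camera a [camera_config()].
#' @param n_samples samples to export.
#' @param dialect mask dialect (see [generate_dataset()]).
#' @param jitter_half_width,jitter_distribution parameter jitter settings.
#' @param pixel_size camera pixel size in object space (um).
#' @param tile trenches per sample for the tiled dialect.
#' @param burn_in frames discarded from the start of the simulation before
#'   sampling (the trench fills from a single founder).
#' @param seed global seed; every stage derives its stream from it.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            geometry = trench_geometry(),
                            intensities = render_intensities(),
                            psf = psf_config(),
                            camera = camera_config(),
                            n_samples = 100, dialect = "binary_weightmap",
                            jitter_half_width = 0.05,
                            jitter_distribution = "uniform",
                            pixel_size = 0.065, tile = 1L,
                            burn_in = 20L, seed = 1L) {
  structure(list(sim = sim, geometry = geometry,
                 intensities = intensities, psf = psf, camera = camera,
                 n_samples = n_samples, dialect = dialect,
                 jitter_half_width = jitter_half_width,
                 jitter_distribution = jitter_distribution,
                 pixel_size = pixel_size, tile = as.integer(tile),
                 burn_in = as.integer(burn_in), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML mirrors the constructor arguments, one section per stage.
#'
#' @param path YAML file path.
#' @return `read_pipeline_config` returns a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pick <- function(section, ctor) {
    do.call(ctor, y[[section]] %||% list())
  }
  pipeline_config(
    sim = pick("sim", sim_config),
    geometry = pick("geometry", trench_geometry),
    intensities = pick("intensities", render_intensities),
    psf = pick("psf", psf_config),
    camera = pick("camera", camera_config),
    n_samples = y$export$n_samples %||% 100,
    dialect = y$export$dialect %||% "binary_weightmap",
    jitter_half_width = y$export$jitter_half_width %||% 0.05,
    jitter_distribution = y$export$jitter_distribution %||% "uniform",
    pixel_size = y$export$pixel_size %||% 0.065,
    tile = y$export$tile %||% 1L,
    burn_in = y$export$burn_in %||% 20L,
    seed = y$seed %||% 1L
  )
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  strip <- function(x) {
    x <- unclass(x)
    x[!vapply(x, is.null, logical(1))]
  }
  psf <- strip(config$psf)
  psf$pitch <- NULL   # derived
  y <- list(
    seed = config$seed,
    sim = strip(config$sim),
    geometry = strip(config$geometry)[c("length", "width", "wall")],
    intensities = strip(config$intensities),
    psf = psf,
    camera = strip(config$camera),
    export = list(n_samples = config$n_samples, dialect = config$dialect,
                  jitter_half_width = config$jitter_half_width,
                  jitter_distribution = config$jitter_distribution,
                  pixel_size = config$pixel_size, tile = config$tile,
                  burn_in = config$burn_in)
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

# deterministic per-stage seed below 2^31, derived from the global seed
stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}

with_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)))
  })
}

#' Run the full synthetic-image pipeline
#'
#' Simulates growth, discards the burn-in, exports `n_samples` jittered
#' image / ground-truth pairs, and writes `manifest.csv` plus `run_log.json`
#' (stage timings, seeds and the full configuration) into `outdir`.
#' Identical config and seed reproduce identical manifests.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @return list with `manifest` (tibble), `sim` (the `trench_sim`), and
#'   `log` (the run-log list), invisibly.
#' @export
run_pipeline <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  clock <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- with_stage(name, expr)
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    out
  }
  sim <- clock("simulate",
    run_simulation(config$sim, config$geometry,
                   seed = stage_seed(config$seed, 1L)))
  frames <- sim$frames
  if (config$burn_in > 0 && length(frames) > config$burn_in)
    frames <- frames[-seq_len(config$burn_in)]
  manifest <- clock("export",
    generate_dataset(frames, config$n_samples, outdir,
                     dialect = config$dialect,
                     intensities = config$intensities,
                     psf = config$psf, camera = config$camera,
                     jitter_half_width = config$jitter_half_width,
                     jitter_distribution = config$jitter_distribution,
                     pixel_size = config$pixel_size,
                     supersample = config$psf$supersample,
                     tile = config$tile,
                     seed = stage_seed(config$seed, 2L)))
  log <- list(
    seed = config$seed,
    stage_seeds = list(simulate = stage_seed(config$seed, 1L),
                       export = stage_seed(config$seed, 2L)),
    timings_s = timings,
    n_frames = length(sim$frames),
    n_samples = config$n_samples,
    dialect = config$dialect,
    config = list(sim = unclass(config$sim),
                  geometry = unclass(config$geometry),
                  intensities = unclass(config$intensities),
                  camera = unclass(config$camera))
  )
  jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, sim = sim, log = log))
}
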