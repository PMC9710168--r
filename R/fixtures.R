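#' @title Deterministic test fixtures
#' @description Small generated inputs for the evaluation and camera test
#'   suites: clean and error-injected sawtooth traces, a two-blob
#'   probability map, and a flat-field exposure series. Everything is
#'   produced by the package's own simulator and camera model under a fixed
#'   seed, so fixtures are reproducible and never stored.
#' @name fixtures
NULL

#' Inject one-frame length errors into a clean trace
#'
#' Multiplies the length at `n_errors` non-adjacent interior timepoints by
#' `factor` (a one-frame dip for `factor < 1`), avoiding the neighbourhood
#' of division drops so each injection produces exactly one spurious peak.
#'
#' @param lengths clean numeric trace.
#' @param n_errors number of dips to inject.
#' @param factor multiplicative dip (default 0.8; must not fall in the
#'   division-compatible interval).
#' @return list with `lengths` (corrupted trace) and `positions`.
#' @export
inject_trace_errors <- function(lengths, n_errors, factor = 0.8) {
  n <- length(lengths)
  ratio <- c(1, lengths[-1] / lengths[-n])
  near_division <- which(ratio < 0.75)
  bad <- unique(pmin(pmax(
    rep(near_division, each = 5) + rep(-2:2, length(near_division)), 1), n))
  candidates <- setdiff(3:(n - 2), bad)
  positions <- integer(0)
  while (length(positions) < n_errors && length(candidates) > 0) {
    p <- candidates[sample.int(length(candidates), 1)]
    positions <- c(positions, p)
    candidates <- setdiff(candidates, (p - 2):(p + 2))
  }
  if (length(positions) < n_errors)
    abort("trace too short to place the requested number of errors.")
  out <- lengths
  out[positions] <- out[positions] * factor
  list(lengths = out, positions = sort(positions))
}

# a clean mother trace of exactly `n_points` timepoints from the simulator
clean_trace_lengths <- function(n_points = 500, seed = 1) {
  cfg <- sim_config(regulation = "sizer", n_timepoints = n_points - 1,
                    p_lyse = 0, seed = seed)
  sim <- run_simulation(cfg, trench_geometry())
  tr <- mother_trace(sim)
  stopifnot(!anyNA(tr$length))
  tr$length
}

# two partially merged Gaussian blobs as a probability map: separated at
# high thresholds, connected at low ones
blob_probmap <- function(dim = c(48, 32), centers = rbind(c(19, 16),
                                                          c(29, 16)),
                         sigma = 5, peak = 0.9999) {
  f <- matrix(0, dim[1], dim[2])
  rr <- matrix(seq_len(dim[1]), dim[1], dim[2])
  cc <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  for (k in seq_len(nrow(centers))) {
    f <- pmax(f, exp(-((rr - centers[k, 1])^2 + (cc - centers[k, 2])^2) /
                       (2 * sigma^2)))
  }
  f * peak
}

#' Generate deterministic fixture files
#'
#' @param kind one of `"clean_trace"`, `"error_trace"`, `"blob_probmap"`,
#'   `"flatfield_stack"`.
#' @param seed RNG seed.
#' @param dir output directory (created).
#' @param error_rate for `"error_trace"`: fraction of timepoints corrupted
#'   (default 0.01 on a 500-point trace).
#' @return list with `files` (paths written) and `data` (the in-memory
#'   objects), invisibly.
#' @export
make_fixtures <- function(kind, seed = 1,
                          dir = tempfile("fixtures"),
                          error_rate = 0.01) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  if (kind == "clean_trace") {
    l <- clean_trace_lengths(seed = seed)
    f <- file.path(dir, "clean_trace.csv")
    readr::write_csv(tibble(t = seq_along(l) - 1L, length = l), f)
    return(invisible(list(files = f, data = l)))
  }
  if (kind == "error_trace") {
    l <- clean_trace_lengths(seed = seed)
    inj <- inject_trace_errors(l, n_errors = round(error_rate * length(l)))
    f <- file.path(dir, "error_trace.csv")
    readr::write_csv(tibble(t = seq_along(inj$lengths) - 1L,
                            length = inj$lengths), f)
    fj <- file.path(dir, "error_trace_positions.json")
    jsonlite::write_json(inj$positions, fj)
    return(invisible(list(files = c(f, fj), data = inj)))
  }
  if (kind == "blob_probmap") {
    m <- blob_probmap()
    f <- file.path(dir, "blob_probmap.tif")
    tiff::writeTIFF(m, f, bits.per.sample = 32)
    return(invisible(list(files = f, data = m)))
  }
  if (kind == "flatfield_stack") {
    cfg <- camera_config(photon_scale = 1, read_noise = 2, baseline = 100,
                         gain = 2, bit_depth = 16)
    levels <- c(50, 100, 200, 400, 800)
    files <- character(0)
    imgs <- list()
    for (i in seq_along(levels)) {
      img <- apply_camera(matrix(levels[i], 100, 100), cfg)
      f <- file.path(dir, sprintf("flatfield_%04d.tif", levels[i]))
      write_image16(img, f)
      files <- c(files, f)
      imgs[[i]] <- img
    }
    return(invisible(list(files = files, data = imgs, levels = levels,
                          config = cfg)))
  }
  abort(sprintf("unknown fixture kind '%s'.", kind))
}
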