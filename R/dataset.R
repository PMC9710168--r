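#' @title Training-dataset export
#' @description Turns simulated frames into image / ground-truth pairs in
#'   two mask dialects: `binary_weightmap` (binary non-touching masks plus a
#'   border-emphasis weightmap, U-net style) and `instances_tiled` (labelled
#'   touching instances, optionally tiled over many trenches). Imaging
#'   parameters are jittered around their matched values to emulate
#'   mechanistic drift in image formation.
#' @name dataset_export
NULL

#' Parameter jitter specification
#'
#' @param base named list/vector of strictly scalar base parameter values.
#' @param half_width relative half-width of the jitter window (default
#'   0.05, i.e. +/- 5 percent).
#' @param distribution `"uniform"` (draws in
#'   `[base (1 - h), base (1 + h)]`) or `"gaussian"` (SD `h * base`).
#' @return an object of class `jitter_spec`.
#' @export
jitter_spec <- function(base, half_width = 0.05,
                        distribution = c("uniform", "gaussian")) {
  distribution <- match.arg(distribution)
  if (half_width < 0) abort("`half_width` must be >= 0.")
  base <- as.list(base)
  if (is.null(names(base)) || any(names(base) == ""))
    abort("`base` must be fully named.")
  structure(list(base = base, half_width = half_width,
                 distribution = distribution),
            class = "jitter_spec")
}

#' Draw jittered parameter sets
#'
#' @param spec a [jitter_spec()].
#' @param n number of draws.
#' @return tibble with one row per draw and one column per parameter.
#' @export
jitter_parameters <- function(spec, n = 1) {
  draws <- purrr::map(spec$base, function(b) {
    if (spec$half_width == 0 || !is.finite(b)) return(rep(b, n))
    if (spec$distribution == "uniform")
      runif(n, b * (1 - spec$half_width), b * (1 + spec$half_width))
    else
      rnorm(n, b, abs(b) * spec$half_width)
  })
  as_tibble(draws)
}

shift_mat <- function(m, di, dj, fill = 0L) {
  out <- matrix(fill, nrow(m), ncol(m))
  src_r <- seq_len(nrow(m)) - di
  src_c <- seq_len(ncol(m)) - dj
  keep_r <- src_r >= 1 & src_r <= nrow(m)
  keep_c <- src_c >= 1 & src_c <= ncol(m)
  out[keep_r, keep_c] <- m[src_r[keep_r], src_c[keep_c]]
  out
}

neighbour_shifts8 <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                          c(0, 1), c(1, -1), c(1, 0), c(1, 1))

# connected-component labelling; EBImage::bwlabel is 4-connected, diagonal
# bridges are merged afterwards for 8-connectivity
label_components <- function(mask, connectivity = 8) {
  lab <- EBImage::bwlabel(matrix(as.numeric(mask != 0), nrow(mask)))
  lab <- matrix(as.integer(lab), nrow(mask))
  if (connectivity == 4 || max(lab) <= 1) return(lab)
  parent <- seq_len(max(lab))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (s in neighbour_shifts8[c(1, 3)]) {   # the two diagonal directions
    nb <- shift_mat(lab, s[1], s[2])
    touch <- lab > 0 & nb > 0 & lab != nb
    if (any(touch)) {
      pairs <- unique(cbind(lab[touch], nb[touch]))
      for (k in seq_len(nrow(pairs))) {
        a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
    }
  }
  root <- vapply(seq_along(parent), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- dense[lab[lab > 0]]
  out
}

#' Separate touching labels into a binary non-touching mask
#'
#' Minimal erosion at contact interfaces: every foreground pixel that is
#' 8-adjacent to a different nonzero label is removed (from both sides), so
#' no two components of the output touch. Labels that vanish entirely are
#' skipped with a warning.
#'
#' @param labels integer label matrix (0 = background).
#' @return binary integer matrix (0/1) with one component per surviving
#'   input label.
#' @export
make_nontouching_masks <- function(labels) {
  touch <- matrix(FALSE, nrow(labels), ncol(labels))
  for (s in neighbour_shifts8) {
    nb <- shift_mat(labels, s[1], s[2])
    touch <- touch | (labels > 0 & nb > 0 & nb != labels)
  }
  out <- labels
  out[touch] <- 0L
  gone <- setdiff(unique(labels[labels > 0]), unique(out[out > 0]))
  if (length(gone) > 0)
    warn(sprintf("label(s) %s vanished under the required erosion and were skipped.",
                 paste(gone, collapse = ", ")))
  matrix(as.integer(out > 0), nrow(labels))
}

#' Border-emphasis weightmap for a binary mask
#'
#' U-net style loss weighting:
#' `w(x) = w_class(x) + w0 * exp(-(d1(x) + d2(x))^2 / (2 sigma_w^2))` on the
#' background, where `d1`, `d2` are the distances to the two nearest mask
#' components. The border term peaks in the gap between the two closest
#' components; with fewer than two components it is identically zero.
#'
#' @param mask binary matrix (0/1).
#' @param w0 border weight amplitude (default 10).
#' @param sigma_w border decay length in pixels (default 5).
#' @param class_balance if `TRUE`, `w_class` balances foreground/background
#'   frequency; otherwise `w_class = 1`.
#' @return numeric weight matrix of `dim(mask)`.
#' @export
make_weightmap <- function(mask, w0 = 10, sigma_w = 5,
                           class_balance = FALSE) {
  mask <- matrix(as.integer(mask != 0), nrow(mask))
  w_class <- matrix(1, nrow(mask), ncol(mask))
  if (class_balance) {
    n <- length(mask); nf <- sum(mask)
    if (nf > 0 && nf < n) {
      w_class[mask == 1] <- n / (2 * nf)
      w_class[mask == 0] <- n / (2 * (n - nf))
    }
  }
  comps <- label_components(mask, connectivity = 8)
  k <- max(comps)
  if (k < 2) return(w_class)
  d1 <- matrix(Inf, nrow(mask), ncol(mask))
  d2 <- matrix(Inf, nrow(mask), ncol(mask))
  for (kk in seq_len(k)) {
    src <- matrix(1, nrow(mask), ncol(mask))
    src[comps == kk] <- 0
    d <- as.matrix(EBImage::distmap(src))
    smaller <- d < d1
    d2 <- ifelse(smaller, d1, pmin(d2, d))
    d1 <- pmin(d1, d)
  }
  border <- w0 * exp(-(d1 + d2)^2 / (2 * sigma_w^2))
  border[mask == 1] <- 0
  w_class + border
}

#' A single training sample
#'
#' @param image integer image matrix.
#' @param mask binary or labelled ground-truth matrix, same dims as `image`.
#' @param weightmap optional weight matrix (binary dialect only).
#' @param provenance optional one-row tibble of the parameter draw.
#' @return an object of class `training_sample`.
#' @export
training_sample <- function(image, mask, weightmap = NULL,
                            provenance = NULL) {
  if (!all(dim(image) == dim(mask)))
    abort("`image` and `mask` must have the same dims.")
  if (!is.null(weightmap) && !all(dim(weightmap) == dim(mask)))
    abort("`weightmap` must match the mask dims.")
  structure(list(image = image, mask = mask, weightmap = weightmap,
                 provenance = provenance),
            class = "training_sample")
}

#' Tile several trench samples into one wide sample
#'
#' Horizontally concatenates `n_trenches` single-trench samples (equal
#' heights required); instance labels are re-indexed so ids stay unique
#' across the tile.
#'
#' @param samples list of `training_sample`s with labelled masks.
#' @param n_trenches number to tile (must not exceed `length(samples)`).
#' @return a tiled `training_sample`.
#' @export
tile_trenches <- function(samples, n_trenches = length(samples)) {
  if (n_trenches > length(samples))
    abort("not enough samples to tile.")
  samples <- samples[seq_len(n_trenches)]
  hts <- vapply(samples, function(s) nrow(s$image), integer(1))
  if (length(unique(hts)) > 1)
    abort("all samples must have the same height.")
  images <- lapply(samples, `[[`, "image")
  masks <- lapply(samples, `[[`, "mask")
  offset <- 0L
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    top <- max(0L, max(m))
    m[m > 0] <- m[m > 0] + offset
    offset <- offset + top
    masks[[i]] <- m
  }
  # re-index densely so ids are 1..N across the tile
  tiled_mask <- do.call(cbind, masks)
  ids <- sort(unique(tiled_mask[tiled_mask > 0]))
  tiled_mask[tiled_mask > 0] <- match(tiled_mask[tiled_mask > 0], ids)
  training_sample(do.call(cbind, images), tiled_mask)
}

# jitterable scalars drawn per exported sample
jitter_base_params <- function(intensities, psf, camera) {
  list(
    I_c = intensities$I_c, I_t = intensities$I_t, I_m = intensities$I_m,
    apodisation_sigma = if (is.finite(psf$apodisation_sigma))
      psf$apodisation_sigma else NA_real_,
    defocus = psf$defocus, halo_offset = psf$halo_offset,
    photon_scale = camera$photon_scale, read_noise = camera$read_noise,
    gain = camera$gain
  )
}

render_one_sample <- function(frame, draw, psf_base, camera_base,
                              pixel_size, supersample) {
  ints <- render_intensities(draw$I_c, draw$I_t, draw$I_m)
  opl <- render_opl(frame, ints, pixel_size = pixel_size,
                    supersample = supersample)
  cfg <- psf_base
  if (!is.na(draw$apodisation_sigma))
    cfg$apodisation_sigma <- draw$apodisation_sigma
  cfg$defocus <- draw$defocus
  cfg$halo_offset <- draw$halo_offset
  psf <- make_psf(cfg)
  img <- if (cfg$mode == "phase_contrast") {
    phase_contrast_micrograph(opl, psf)
  } else {
    convolve_and_downsample(opl, psf)
  }
  cam <- camera_base
  cam$photon_scale <- max(draw$photon_scale, 1e-9)
  cam$read_noise <- max(draw$read_noise, 0)
  cam$gain <- max(draw$gain, 1e-9)
  dn <- apply_camera(pmax(img, 0), cam)
  labels <- downsample_labels(opl$labels, supersample)
  list(image = dn, labels = labels)
}

#' Generate a training dataset on disk
#'
#' Draws frames from a simulation (optionally weighting each frame by the
#' reciprocal of its cell count, so the expected number of cells exported
#' per draw is the same whatever the cell-size regime), jitters the imaging
#' parameters per sample, renders image / ground-truth pairs in the chosen
#' dialect, writes them with a manifest recording every parameter draw.
#' Ground-truth masks depend only on the physics: two jitters of the same
#' frame yield pixel-identical masks.
#'
#' @param frames list of `scene_frame`s (e.g. `sim$frames`).
#' @param n_samples number of samples to export.
#' @param outdir output directory (created if missing).
#' @param dialect `"binary_weightmap"` or `"instances_tiled"`.
#' @param intensities a [render_intensities()] (jitter base).
#' @param psf a [psf_config()] (jitter base).
#' @param camera a [camera_config()] (jitter base).
#' @param jitter_half_width,jitter_distribution forwarded to
#'   [jitter_spec()]; half-width 0 disables jitter.
#' @param pixel_size,supersample renderer settings; `supersample` must
#'   match `psf$supersample`.
#' @param tile trenches per exported sample (`instances_tiled` only).
#' @param weight_by_cell_count down-weight crowded frames (see above).
#' @param w0,sigma_w weightmap parameters (binary dialect).
#' @param seed optional RNG seed.
#' @return the manifest tibble, invisibly; written to
#'   `file.path(outdir, "manifest.csv")`.
#' @export
generate_dataset <- function(frames, n_samples, outdir,
                             dialect = c("binary_weightmap",
                                         "instances_tiled"),
                             intensities = render_intensities(),
                             psf = psf_config(),
                             camera = camera_config(),
                             jitter_half_width = 0.05,
                             jitter_distribution = "uniform",
                             pixel_size = 0.065, supersample = 3,
                             tile = 1L, weight_by_cell_count = TRUE,
                             w0 = 10, sigma_w = 5, seed = NULL) {
  dialect <- match.arg(dialect)
  if (!is.null(seed)) set.seed(seed)
  if (supersample != psf$supersample)
    abort("`supersample` must match `psf$supersample`.")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  n_cells <- vapply(frames, function(f) nrow(f$cells), integer(1))
  usable <- which(n_cells > 0)
  if (length(usable) == 0) abort("no non-empty frames available.")
  wts <- if (weight_by_cell_count) 1 / n_cells[usable]
         else rep(1, length(usable))
  spec <- jitter_spec(jitter_base_params(intensities, psf, camera),
                      half_width = jitter_half_width,
                      distribution = jitter_distribution)
  per_tile <- if (dialect == "instances_tiled") as.integer(tile) else 1L
  rows <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    idx <- sample(usable, per_tile, replace = TRUE, prob = wts)
    draw <- jitter_parameters(spec, 1)
    parts <- lapply(idx, function(fi)
      render_one_sample(frames[[fi]], draw, psf, camera,
                        pixel_size, supersample))
    sample_i <- if (per_tile > 1) {
      tile_trenches(lapply(parts, function(p)
        training_sample(p$image, p$labels)), per_tile)
    } else {
      training_sample(parts[[1]]$image, parts[[1]]$labels)
    }
    stem <- sprintf("%05d", i)
    img_file <- file.path(outdir, paste0(stem, "_image.tif"))
    write_image16(sample_i$image, img_file,
                  max_value = 2^camera$bit_depth - 1)
    wm_scale <- NA_real_
    if (dialect == "binary_weightmap") {
      mask <- make_nontouching_masks(sample_i$mask)
      mask_file <- file.path(outdir, paste0(stem, "_mask.png"))
      write_mask_png(mask, mask_file)
      wm <- make_weightmap(mask, w0 = w0, sigma_w = sigma_w)
      wm_file <- file.path(outdir, paste0(stem, "_weightmap.tif"))
      wm_scale <- write_float_tiff(wm, wm_file)
    } else {
      mask_file <- file.path(outdir, paste0(stem, "_labels.tif"))
      write_labels16(sample_i$mask, mask_file)
      wm_file <- NA_character_
    }
    rows[[i]] <- dplyr::bind_cols(
      tibble(sample = i, frame = paste(idx, collapse = ";"),
             dialect = dialect,
             n_labels = length(unique(sample_i$mask[sample_i$mask > 0])),
             image_file = basename(img_file),
             mask_file = basename(mask_file),
             weightmap_file = ifelse(is.na(wm_file), NA_character_,
                                     basename(wm_file)),
             weightmap_scale = wm_scale),
      draw)
  }
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest, file.path(outdir, "manifest.csv"))
  invisible(manifest)
}

#' Read back one exported training sample
#'
#' @param outdir dataset directory containing `manifest.csv`.
#' @param sample sample number.
#' @param bit_depth camera bit depth the images were written with.
#' @return a `training_sample`.
#' @export
read_training_sample <- function(outdir, sample, bit_depth = 16) {
  manifest <- readr::read_csv(file.path(outdir, "manifest.csv"),
                              show_col_types = FALSE)
  row <- manifest[manifest$sample == sample, ]
  if (nrow(row) != 1) abort("sample not found in manifest.")
  image <- read_image16(file.path(outdir, row$image_file),
                        max_value = 2^bit_depth - 1)
  mask <- if (grepl("\\.png$", row$mask_file)) {
    read_mask_png(file.path(outdir, row$mask_file))
  } else {
    read_labels16(file.path(outdir, row$mask_file))
  }
  wm <- NULL
  if (!is.na(row$weightmap_file))
    wm <- read_float_tiff(file.path(outdir, row$weightmap_file),
                          scale = row$weightmap_scale)
  training_sample(image, mask, wm, provenance = row)
}
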