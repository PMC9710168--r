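#' @title Image file I/O
#' @description Thin wrappers around the tiff and png packages with fixed
#'   dialects: 16-bit grayscale TIFF for camera images and instance labels
#'   (values stored over `[0, max_value]`, exact for integers up to 65535),
#'   8-bit PNG for binary masks, and max-normalised 32-bit float TIFF for
#'   continuous fields (OPL, weightmaps, PSF kernels) whose scale is
#'   returned/recorded so reads invert it.
#' @name image_io
NULL

#' @rdname image_io
#' @param image integer matrix.
#' @param path file path.
#' @param max_value full-scale value (default 65535).
#' @export
write_image16 <- function(image, path, max_value = 65535) {
  if (max(image) > max_value) abort("image exceeds `max_value`.")
  tiff::writeTIFF(image / max_value, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname image_io
#' @export
read_image16 <- function(path, max_value = 65535) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * max_value)), nrow(m))
}

#' @rdname image_io
#' @param labels integer label matrix with ids below 65536.
#' @export
write_labels16 <- function(labels, path) {
  if (max(labels) > 65535) abort("label ids exceed the 16-bit range.")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname image_io
#' @export
read_labels16 <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m))
}

#' @rdname image_io
#' @param mask binary (0/1) matrix.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask)), path)
  invisible(path)
}

#' @rdname image_io
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(m > 0.5), nrow(m))
}

#' @rdname image_io
#' @param field numeric matrix with non-negative values.
#' @return `write_float_tiff` returns the normalisation scale (the field
#'   maximum) needed by `read_float_tiff`.
#' @export
write_float_tiff <- function(field, path) {
  scale <- max(field)
  if (scale <= 0) scale <- 1
  tiff::writeTIFF(field / scale, path, bits.per.sample = 32)
  scale
}

#' @rdname image_io
#' @param scale the value returned by `write_float_tiff`.
#' @export
read_float_tiff <- function(path, scale = 1) {
  m <- tiff::readTIFF(path)
  matrix(m * scale, nrow(m))
}

#' Write a rendered frame to disk
#'
#' Writes `"{t}_opl.tif"` (max-normalised float TIFF plus a JSON sidecar
#' with the scale and pixel geometry) and `"{t}_labels.tif"` (16-bit).
#'
#' @param opl an `opl_image`.
#' @param dir output directory.
#' @param t timepoint index used in the filenames.
#' @return named character vector of the files written, invisibly.
#' @export
write_frame_images <- function(opl, dir, t) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- sprintf("%05d", t)
  opl_file <- file.path(dir, paste0(stem, "_opl.tif"))
  lab_file <- file.path(dir, paste0(stem, "_labels.tif"))
  scale <- write_float_tiff(opl$opl, opl_file)
  write_labels16(opl$labels, lab_file)
  jsonlite::write_json(
    list(scale = scale, pixel_size = opl$pixel_size,
         supersample = opl$supersample),
    file.path(dir, paste0(stem, "_opl.json")), auto_unbox = TRUE)
  invisible(c(opl = opl_file, labels = lab_file))
}

#' Write a PSF kernel with its configuration sidecar
#'
#' The kernel goes to a max-normalised 32-bit float TIFF; the generating
#' parameters (including the normalisation scale) to a JSON sidecar.
#'
#' @param psf a `psf_kernel` (2-D).
#' @param path output TIFF path; the sidecar replaces `.tif` with `.json`.
#' @export
write_psf <- function(psf, path) {
  scale <- write_float_tiff(psf$kernel, path)
  side <- unclass(psf$config)
  side$scale <- scale
  jsonlite::write_json(side, sub("\\.tiff?$", ".json", path),
                       auto_unbox = TRUE)
  invisible(path)
}
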