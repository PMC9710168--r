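#' Camera configuration
#'
#' Standard CCD/sCMOS capture model: the incoming (arbitrary-unit) image is
#' scaled to expected photoelectrons, shot noise is Poisson, read noise is
#' additive Gaussian in electrons, then gain, baseline offset and
#' quantisation to the sensor bit depth are applied.
#'
#' @param photon_scale expected photoelectrons per unit of input intensity
#'   (`> 0`).
#' @param read_noise read noise SD in electrons (`>= 0`).
#' @param baseline offset in digital numbers (`>= 0`).
#' @param gain digital numbers per electron (`> 0`).
#' @param bit_depth 8, 12 or 16.
#' @return an object of class `camera_config`.
#' @export
camera_config <- function(photon_scale = 100, read_noise = 2,
                          baseline = 100, gain = 2, bit_depth = 16) {
  if (photon_scale <= 0) abort("`photon_scale` must be > 0.")
  if (read_noise < 0) abort("`read_noise` must be >= 0.")
  if (baseline < 0) abort("`baseline` must be >= 0.")
  if (gain <= 0) abort("`gain` must be > 0.")
  if (!bit_depth %in% c(8L, 12L, 16L)) abort("`bit_depth` must be 8, 12 or 16.")
  structure(list(photon_scale = photon_scale, read_noise = read_noise,
                 baseline = baseline, gain = gain,
                 bit_depth = as.integer(bit_depth)),
            class = "camera_config")
}

#' Simulate image capture
#'
#' `out = clip(round(gain * (Poisson(photon_scale * I) + N(0, read_noise))
#' + baseline), 0, 2^bit_depth - 1)`. Deterministic under a fixed RNG seed.
#'
#' @param image non-negative numeric matrix (a.u.).
#' @param config a [camera_config()].
#' @return integer matrix of the same dims, in digital numbers.
#' @export
apply_camera <- function(image, config) {
  if (any(image < 0)) abort("camera input must be non-negative.")
  n <- length(image)
  electrons <- rpois(n, config$photon_scale * as.vector(image))
  if (config$read_noise > 0)
    electrons <- electrons + rnorm(n, 0, config$read_noise)
  dn <- round(config$gain * electrons + config$baseline)
  dn <- pmin(pmax(dn, 0), 2^config$bit_depth - 1)
  matrix(as.integer(dn), nrow(image), ncol(image))
}

#' Match an image's intensity histogram to a reference
#'
#' Monotone rank mapping: the k-th smallest synthetic pixel is replaced by
#' the k-th smallest reference value (quantile-mapped when sizes differ), so
#' the output's empirical CDF equals the reference's up to ties and the
#' rank order of unequal pixels is preserved. Idempotent.
#'
#' @param synthetic,reference grayscale numeric matrices (any dims).
#' @return matrix of `dim(synthetic)` with reference-distributed values.
#' @export
match_histogram <- function(synthetic, reference) {
  ref <- sort(as.vector(reference))
  if (ref[1] == ref[length(ref)])
    abort("reference image is constant: histogram matching is degenerate.")
  r <- rank(as.vector(synthetic), ties.method = "first")
  idx <- ceiling(r * length(ref) / length(synthetic))
  matrix(ref[idx], nrow(synthetic), ncol(synthetic))
}

# mean Fourier amplitude per integer radial-frequency bin
radial_bins <- function(nr, nc) {
  fftfreq <- function(n) {
    f <- 0:(n - 1)
    f[f > n / 2] <- f[f > n / 2] - n
    f / n
  }
  r <- sqrt(outer(fftfreq(nr)^2, fftfreq(nc)^2, "+"))
  round(r * max(nr, nc))
}

#' Rotationally averaged Fourier amplitude spectrum
#'
#' @param image numeric matrix.
#' @return tibble with `bin` (integer radial frequency index) and
#'   `amplitude` (mean |FFT| in the bin).
#' @export
radial_spectrum <- function(image) {
  amp <- Mod(fft(image))
  b <- radial_bins(nrow(image), ncol(image))
  means <- tapply(as.vector(amp), as.vector(b), mean)
  tibble(bin = as.integer(names(means)), amplitude = as.numeric(means))
}

#' Match an image's rotational Fourier spectrum to a reference
#'
#' Scales every Fourier coefficient of the synthetic image so that the mean
#' amplitude in its radial-frequency bin equals the reference's, keeping the
#' synthetic phases, then inverts the transform. With `reference =
#' synthetic` this is the identity.
#'
#' @param synthetic,reference numeric matrices of identical dims.
#' @return real-valued matrix of `dim(synthetic)`.
#' @export
match_fourier_spectrum <- function(synthetic, reference) {
  if (!all(dim(synthetic) == dim(reference)))
    abort("`synthetic` and `reference` must have the same dims.")
  fs <- fft(synthetic)
  fr <- fft(reference)
  b <- as.vector(radial_bins(nrow(synthetic), ncol(synthetic)))
  amp_s <- tapply(as.vector(Mod(fs)), b, mean)
  amp_r <- tapply(as.vector(Mod(fr)), b, mean)
  scale <- ifelse(amp_s > 0, amp_r / amp_s, 1)
  fs_scaled <- fs * matrix(scale[match(b, as.numeric(names(amp_s)))],
                           nrow(synthetic), ncol(synthetic))
  Re(fft(fs_scaled, inverse = TRUE)) / length(synthetic)
}

#' Per-region intensity and variance error report
#'
#' Compares a synthetic image against a real reference within three coarse
#' regions (cell interiors, the device, the media between cells): the
#' relative error of the mean and of the variance per region. Advisory
#' output for manual intensity matching; empty regions are flagged, not
#' fatal.
#'
#' @param synthetic,real numeric matrices of identical dims.
#' @param masks named list of disjoint logical matrices, e.g.
#'   `list(cells = ..., device = ..., media = ...)`.
#' @return tibble with one row per region: means, variances, relative
#'   errors (`rel_err_mean`, `rel_err_var`) and an `empty` flag.
#' @export
region_error_report <- function(synthetic, real, masks) {
  if (!all(dim(synthetic) == dim(real)))
    abort("`synthetic` and `real` must have the same dims.")
  overlap <- Reduce(`+`, lapply(masks, function(m) as.integer(m)))
  if (any(overlap > 1)) abort("region masks must be disjoint.")
  purrr::map_dfr(names(masks), function(nm) {
    m <- masks[[nm]]
    if (!any(m)) {
      warn(sprintf("region '%s' is empty.", nm))
      return(tibble(region = nm, mean_synthetic = NA_real_,
                    mean_real = NA_real_, rel_err_mean = NA_real_,
                    var_synthetic = NA_real_, var_real = NA_real_,
                    rel_err_var = NA_real_, empty = TRUE))
    }
    ms <- mean(synthetic[m]); mr <- mean(real[m])
    vs <- var(as.vector(synthetic[m])); vr <- var(as.vector(real[m]))
    tibble(region = nm, mean_synthetic = ms, mean_real = mr,
           rel_err_mean = (ms - mr) / mr,
           var_synthetic = vs, var_real = vr,
           rel_err_var = if (vr > 0) (vs - vr) / vr else NA_real_,
           empty = FALSE)
  })
}
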