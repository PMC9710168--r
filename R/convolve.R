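#' @title Convolution and downsampling
#' @description PSF convolution runs at the super-sampled pitch so that
#'   sub-resolution kernel structure (the concentric Airy rings) is
#'   propagated into the image before resampling; the result is then
#'   block-averaged back to camera resolution. Boundaries are handled by
#'   symmetric reflection (edge pixel included), and the FFT path is
#'   required to agree with direct spatial convolution to 1e-8.
#' @name optics_convolution
NULL

# symmetric-reflection index: 1, 2, ..., n, n, n-1, ..., reflected
reflect_index <- function(i, n) {
  period <- 2L * n
  i <- ((i - 1L) %% period + period) %% period + 1L
  ifelse(i > n, period - i + 1L, i)
}

# pad a matrix by (pr, pc) on each side with symmetric reflection
pad_reflect <- function(m, pr, pc) {
  ri <- reflect_index(seq(1L - pr, nrow(m) + pr), nrow(m))
  ci <- reflect_index(seq(1L - pc, ncol(m) + pc), ncol(m))
  m[ri, ci, drop = FALSE]
}

#' 2-D convolution with a centred kernel, reflective boundary
#'
#' Computes `out[i, j] = sum_ab K[a, b] * I[i + a - c, j + b - c]` (the
#' centred sliding-window product) with out-of-range indices reflected
#' symmetrically, via FFT on the reflect-padded image. With a unit-sum
#' kernel a constant image is reproduced exactly.
#'
#' @param image numeric matrix.
#' @param kernel odd-dimensioned numeric matrix.
#' @return matrix of `dim(image)`.
#' @export
convolve2d <- function(image, kernel) {
  nk_r <- nrow(kernel); nk_c <- ncol(kernel)
  if (nk_r %% 2 == 0 || nk_c %% 2 == 0)
    abort("kernel must have odd dimensions.")
  pr <- (nk_r - 1L) / 2L; pc <- (nk_c - 1L) / 2L
  padded <- pad_reflect(image, pr, pc)
  np_r <- nrow(padded); np_c <- ncol(padded)
  kf <- matrix(0, np_r, np_c)
  # flip so the FFT product realises the centred sliding window (correlation)
  kf[seq_len(nk_r), seq_len(nk_c)] <- kernel[nk_r:1, nk_c:1]
  out <- Re(fft(fft(padded) * fft(kf), inverse = TRUE)) / (np_r * np_c)
  # the valid centred window starts after the full kernel has entered
  out[seq_len(nrow(image)) + 2L * pr, seq_len(ncol(image)) + 2L * pc,
      drop = FALSE]
}

#' Block-average downsampling
#'
#' Mean over non-overlapping `factor x factor` blocks; dims must divide.
#'
#' @param image numeric matrix.
#' @param factor integer block size.
#' @return matrix of dims `dim(image) / factor`.
#' @export
block_downsample <- function(image, factor) {
  factor <- as.integer(factor)
  if (factor == 1L) return(image)
  nr <- nrow(image) %/% factor
  nc <- ncol(image) %/% factor
  if (nr * factor != nrow(image) || nc * factor != ncol(image))
    abort("image dims must be divisible by `factor`.")
  dim(image) <- c(factor, nr, factor, nc)
  apply(image, c(2, 4), mean)
}

#' Convolve an OPL image with a PSF and return the camera-resolution image
#'
#' Checks that the kernel was rendered at the OPL image's super-sampled
#' pitch, convolves at super-resolution (reflective boundary), then
#' block-averages down by the supersample factor. For a 3-D kernel stack
#' the planes are convolved individually and averaged (a simplified axial
#' integration).
#'
#' @param opl an `opl_image` from [render_opl()].
#' @param psf a `psf_kernel` from [make_psf()].
#' @return numeric matrix at camera resolution.
#' @export
convolve_and_downsample <- function(opl, psf) {
  if (abs(psf$config$pitch - opl$pixel_size) > 1e-9)
    abort(sprintf(
      "kernel pitch (%.5f um) does not match the OPL pitch (%.5f um).",
      psf$config$pitch, opl$pixel_size))
  img <- if (is.list(psf$kernel)) {
    planes <- lapply(psf$kernel, function(k) convolve2d(opl$opl, k))
    Reduce(`+`, planes) / length(planes)
  } else {
    convolve2d(opl$opl, psf$kernel)
  }
  block_downsample(img, opl$supersample)
}

#' Linearised positive phase-contrast micrograph
#'
#' Phase contrast converts optical path length into intensity contrast: in
#' positive phase contrast, optically dense objects appear dark with a
#' bright halo and shade-off inside large uniform objects. This is modelled
#' linearly as background plus the band-pass residue of the OPL,
#' `out = (1 + c) * (K * opl) - c * opl` with `K` the obscured-Airy kernel
#' and `c` the contrast strength: a flat background is unchanged, cell
#' bodies (where the blurred OPL falls below `c/(1+c)` of the local OPL)
#' turn dark, and the kernel's ring energy spills outside the cell as the
#' bright halo. The kernel's `halo_offset` modulates both artefacts.
#' Negative values are clipped at `floor` before the camera, and the result
#' is block-averaged to camera resolution.
#'
#' @param opl an `opl_image`.
#' @param psf a phase-contrast `psf_kernel` at the OPL pitch.
#' @param contrast phase-contrast strength `c >= 0` (default 3).
#' @param floor clip level (default 0).
#' @return numeric matrix at camera resolution.
#' @export
phase_contrast_micrograph <- function(opl, psf, contrast = 3, floor = 0) {
  if (abs(psf$config$pitch - opl$pixel_size) > 1e-9)
    abort("kernel pitch does not match the OPL pitch.")
  conv <- convolve2d(opl$opl, psf$kernel)
  pc <- (1 + contrast) * conv - contrast * opl$opl
  block_downsample(pmax(pc, floor), opl$supersample)
}

# direct double-loop spatial convolution (sliding window over every output
# pixel); the independent reference used in tests to pin down the FFT path
convolve2d_direct <- function(image, kernel) {
  nk_r <- nrow(kernel); nk_c <- ncol(kernel)
  pr <- (nk_r - 1L) / 2L; pc <- (nk_c - 1L) / 2L
  ri <- reflect_index(seq(1L - pr, nrow(image) + pr), nrow(image))
  ci <- reflect_index(seq(1L - pc, ncol(image) + pc), ncol(image))
  out <- matrix(0, nrow(image), ncol(image))
  for (i in seq_len(nrow(image))) {
    for (j in seq_len(ncol(image))) {
      win <- image[ri[i:(i + 2L * pr)], ci[j:(j + 2L * pc)], drop = FALSE]
      out[i, j] <- sum(win * kernel)
    }
  }
  out
}
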