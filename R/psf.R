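#' Point-spread-function configuration
#'
#' Parameters of the microscope model. The kernel is rendered at the
#' super-sampled pitch `pixel_size / supersample` in object space, where
#' `pixel_size = camera_pixel / magnification`. The fluorescence PSF is the
#' Airy pattern of a circular aperture; the phase-contrast PSF is the
#' obscured Airy pattern of an annular aperture with obscuration ratio
#' `eps = eps_in / eps_out`; a simplified 3-D fluorescence mode stacks
#' defocused 2-D kernels.
#'
#' @param mode `"fluorescence"`, `"phase_contrast"` or `"fluorescence_3d"`.
#' @param na numerical aperture of the objective; `0 < na <= ref_index`.
#' @param wavelength emission wavelength (um).
#' @param ref_index refractive index of the imaging medium.
#' @param camera_pixel physical camera pixel size (um).
#' @param magnification total magnification; object-space pixel is
#'   `camera_pixel / magnification`.
#' @param supersample integer super-sampling factor (match the renderer's).
#' @param eps_in,eps_out phase annulus inner/outer radius fractions in
#'   `(0, 1]` with `eps_in < eps_out`; only their ratio enters the model.
#' @param apodisation_sigma Gaussian apodisation width in super-sampled
#'   pixels; `Inf` disables it.
#' @param defocus axial defocus z (um); 0 is in focus.
#' @param defocus_theta defocus broadening rate: the in-focus kernel is
#'   convolved with a Gaussian of SD `defocus_theta * |z|` um.
#' @param halo_offset small constant added to the phase-contrast kernel
#'   (then renormalised) to modulate halo and shade-off; default 0.
#' @param radius kernel half-width in super-sampled pixels; defaults to
#'   six first-zero radii and must be at least three (enforced).
#' @param z_planes for `"fluorescence_3d"`: vector of z offsets (um).
#' @return an object of class `psf_config`.
#' @export
psf_config <- function(mode = c("phase_contrast", "fluorescence",
                                "fluorescence_3d"),
                       na = 1.45, wavelength = 0.6, ref_index = 1.518,
                       camera_pixel = 6.5, magnification = 100,
                       supersample = 3,
                       eps_in = 0.4, eps_out = 0.9,
                       apodisation_sigma = Inf,
                       defocus = 0, defocus_theta = 0.2,
                       halo_offset = 0,
                       radius = NULL,
                       z_planes = c(-1, 0, 1)) {
  mode <- match.arg(mode)
  if (na <= 0 || na > ref_index)
    abort("require 0 < na <= ref_index.")
  if (eps_in >= eps_out || eps_out > 1 || eps_in <= 0)
    abort("require 0 < eps_in < eps_out <= 1.")
  if (wavelength <= 0 || camera_pixel <= 0 || magnification <= 0)
    abort("wavelength, camera_pixel and magnification must be > 0.")
  pitch <- camera_pixel / magnification / supersample
  first_zero_px <- 0.61 * wavelength / na / pitch
  if (is.null(radius)) radius <- ceiling(6 * first_zero_px)
  if (radius < 3 * first_zero_px)
    abort(sprintf(
      "kernel radius %d px is below 3x the first-zero radius (%.1f px): kernel would be truncated.",
      as.integer(radius), 3 * first_zero_px))
  structure(list(mode = mode, na = na, wavelength = wavelength,
                 ref_index = ref_index, camera_pixel = camera_pixel,
                 magnification = magnification,
                 supersample = as.integer(supersample), pitch = pitch,
                 eps_in = eps_in, eps_out = eps_out,
                 apodisation_sigma = apodisation_sigma,
                 defocus = defocus, defocus_theta = defocus_theta,
                 halo_offset = halo_offset,
                 radius = as.integer(radius), z_planes = z_planes),
            class = "psf_config")
}

new_psf_kernel <- function(kernel, config, normalised = TRUE) {
  structure(list(kernel = kernel, config = config, normalised = normalised),
            class = "psf_kernel")
}

#' @export
print.psf_kernel <- function(x, ...) {
  k <- if (is.list(x$kernel)) x$kernel[[1]] else x$kernel
  cat(sprintf("<psf_kernel> %s, %d x %d at %.4f um/px, sum = %.6f\n",
              x$config$mode, nrow(k), ncol(k), x$config$pitch,
              sum(if (is.list(x$kernel)) x$kernel[[1]] else x$kernel)))
  invisible(x)
}

psf_grid_radius_um <- function(config) {
  r <- config$radius
  d <- seq(-r, r) * config$pitch
  sqrt(outer(d^2, d^2, "+"))
}

# [2 J1(v) / v]^2 with the v -> 0 limit
airy_intensity <- function(v) {
  out <- rep(1, length(v))
  nz <- v != 0
  out[nz] <- (2 * besselJ(v[nz], 1) / v[nz])^2
  out
}

# annular-aperture amplitude with obscuration ratio eps; eps = 0 reduces to
# the circular-aperture amplitude 2 J1(v)/v
obscured_airy_amplitude <- function(v, eps) {
  a <- rep(1, length(v))
  nz <- v != 0
  inner <- if (eps > 0) {
    ji <- rep(0.5, length(v))
    ji[nz] <- besselJ(eps * v[nz], 1) / (eps * v[nz])
    eps^2 * 2 * ji
  } else 0
  outer_t <- rep(1, length(v))
  outer_t[nz] <- 2 * besselJ(v[nz], 1) / v[nz]
  (outer_t - inner) / (1 - eps^2)
}

#' Fluorescence (Airy) PSF kernel
#'
#' Intensity `[2 J1(v) / v]^2` with `v = 2 pi NA rho / lambda`, sampled at
#' the super-sampled pitch and normalised to unit sum. The first radial zero
#' falls at `rho = 0.61 lambda / NA`.
#'
#' @param config a [psf_config()] (mode `"fluorescence"` implied).
#' @return a `psf_kernel`.
#' @export
airy_psf <- function(config) {
  rho <- psf_grid_radius_um(config)
  v <- 2 * pi * config$na * rho / config$wavelength
  k <- matrix(airy_intensity(v), nrow(rho))
  new_psf_kernel(k / sum(k), config)
}

#' Phase-contrast (obscured Airy) PSF kernel
#'
#' Intensity of the annular-aperture diffraction pattern,
#' `|A(v)|^2` with
#' `A(v) = [2/(1 - eps^2)] [J1(v)/v - eps^2 J1(eps v)/(eps v)]`,
#' `eps = eps_in / eps_out`. An optional small uniform `halo_offset` is
#' added and the kernel renormalised, which modulates the halo and
#' shade-off strength characteristic of phase contrast.
#'
#' @param config a [psf_config()].
#' @return a `psf_kernel`.
#' @export
obscured_airy_psf <- function(config) {
  eps <- config$eps_in / config$eps_out
  if (eps >= 1) abort("annulus obscuration ratio must be < 1.")
  rho <- psf_grid_radius_um(config)
  v <- 2 * pi * config$na * rho / config$wavelength
  a <- obscured_airy_amplitude(v, eps)
  k <- matrix(a^2, nrow(rho))
  k <- k / sum(k)
  if (config$halo_offset != 0) {
    k <- k + config$halo_offset
    k <- k / sum(k)
  }
  new_psf_kernel(k, config)
}

#' Gaussian apodisation of a kernel
#'
#' Multiplies the kernel by a centred Gaussian of SD `sigma` (super-sampled
#' pixels) and renormalises; `sigma = Inf` is the identity, `sigma -> 0`
#' approaches a centred delta.
#'
#' @param psf a `psf_kernel`.
#' @param sigma apodisation width in pixels, `> 0` or `Inf`.
#' @return the apodised `psf_kernel`.
#' @export
apodise <- function(psf, sigma) {
  if (is.infinite(sigma)) return(psf)
  if (sigma <= 0) abort("`sigma` must be > 0 or Inf.")
  k <- psf$kernel
  r <- (nrow(k) - 1) / 2
  d2 <- outer(seq(-r, r)^2, seq(-r, r)^2, "+")
  k <- k * exp(-d2 / (2 * sigma^2))
  psf$kernel <- k / sum(k)
  psf
}

# discrete 1-D Gaussian, unit sum
gauss1d <- function(sigma_px) {
  r <- max(1L, ceiling(3 * sigma_px))
  g <- exp(-seq(-r, r)^2 / (2 * sigma_px^2))
  g / sum(g)
}

#' Defocused PSF kernel
#'
#' `z = 0` returns the in-focus kernel unchanged; otherwise the kernel is
#' convolved with a centred Gaussian of SD `defocus_theta * |z|` um
#' (converted to pixels), a monotone broadening model of axial defocus.
#' The unit sum is preserved.
#'
#' @param psf an in-focus `psf_kernel`.
#' @param z axial defocus (um).
#' @param theta broadening rate (um of blur SD per um of defocus); defaults
#'   to the config's `defocus_theta`.
#' @return a `psf_kernel`.
#' @export
defocus_psf <- function(psf, z, theta = psf$config$defocus_theta) {
  if (z == 0) return(psf)
  sigma_px <- theta * abs(z) / psf$config$pitch
  g <- gauss1d(sigma_px)
  k <- psf$kernel
  # separable Gaussian blur with symmetric-reflection boundary
  k <- convolve2d(k, outer(g, g))
  psf$kernel <- k / sum(k)
  psf$config$defocus <- z
  psf
}

#' Build the PSF requested by a configuration
#'
#' Dispatches on `config$mode`, then applies apodisation, defocus and (for
#' phase contrast) the halo offset. `"fluorescence_3d"` returns a kernel
#' whose `kernel` field is a list of defocused planes at `config$z_planes`
#' (a simplified axial stack, not a full vectorial 3-D model).
#'
#' @param config a [psf_config()].
#' @return a `psf_kernel`.
#' @export
make_psf <- function(config) {
  base <- switch(config$mode,
    phase_contrast = obscured_airy_psf(config),
    fluorescence = airy_psf(config),
    fluorescence_3d = airy_psf(config)
  )
  base <- apodise(base, config$apodisation_sigma)
  if (config$mode == "fluorescence_3d") {
    planes <- lapply(config$z_planes, function(z)
      if (z == 0) base$kernel else defocus_psf(base, z)$kernel)
    base$kernel <- planes
    return(base)
  }
  if (config$defocus != 0) base <- defocus_psf(base, config$defocus)
  base
}

#' Full width at half maximum of a kernel's central row profile
#'
#' Linear-interpolated FWHM of the radial profile through the kernel
#' centre, in super-sampled pixels. Used to verify defocus broadening.
#'
#' @param psf a `psf_kernel` (2-D).
#' @return FWHM in pixels.
#' @export
psf_fwhm <- function(psf) {
  k <- psf$kernel
  c0 <- (nrow(k) + 1) / 2
  prof <- k[c0, ]
  half <- max(prof) / 2
  above <- which(prof >= half)
  lo <- min(above); hi <- max(above)
  interp <- function(i, j) {
    if (i < 1 || j > length(prof) || prof[i] == prof[j]) return(0)
    (prof[i] - half) / (prof[i] - prof[j])
  }
  (hi - lo) + interp(lo, lo - 1) + interp(hi, hi + 1)
}
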