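# shared fixtures, all generated in code under fixed seeds

quick_sim <- function(n = 100, seed = 1, ...) {
  run_simulation(sim_config(n_timepoints = n, seed = seed, ...),
                 trench_geometry())
}

# hand-built scene frame for renderer tests
make_test_frame <- function(lengths, widths, xs, bends = 0,
                            geometry = trench_geometry()) {
  n <- length(lengths)
  cells <- tibble::tibble(
    id = seq_len(n), parent_id = NA_integer_,
    length = lengths, width = widths, x = xs, y = 0, angle = 0,
    age = 0, birth_length = lengths, div_threshold = Inf,
    bend_amplitude = rep(bends, length.out = n)
  )
  structure(list(t = 0L, cells = cells, geometry = geometry),
            class = "scene_frame")
}

# maximum pairwise 1-D body overlap within a frame (um)
max_overlap <- function(frame) {
  cells <- frame$cells[order(frame$cells$x), ]
  if (nrow(cells) < 2) return(0)
  lo <- cells$x - cells$length / 2
  hi <- cells$x + cells$length / 2
  max(0, max(utils::head(hi, -1) - utils::tail(lo, -1)))
}

# logical ring of pixels within `px` of a mask but outside it
shell_around <- function(mask, px = 2) {
  sh <- mask
  for (k in seq_len(px)) {
    g <- sh
    g[-1, ] <- g[-1, ] | sh[-nrow(sh), ]
    g[-nrow(sh), ] <- g[-nrow(sh), ] | sh[-1, ]
    g[, -1] <- g[, -1] | sh[, -ncol(sh)]
    g[, -ncol(sh)] <- g[, -ncol(sh)] | sh[, -1]
    sh <- g
  }
  sh & !mask
}

# independent numeric volume oracle: integrate the cross-section area of the
# solid of revolution along the axis (never uses the closed form)
spherocylinder_volume_numeric <- function(l, r) {
  radius2 <- function(s) {
    cyl <- l / 2 - r
    out <- rep(r^2, length(s))
    cap <- abs(s) > cyl
    out[cap] <- pmax(r^2 - (abs(s[cap]) - cyl)^2, 0)
    out
  }
  stats::integrate(function(s) pi * radius2(s), -l / 2, l / 2,
                   rel.tol = 1e-10)$value
}

# fluorescence-appropriate intensities: the device barely fluoresces
fluor_intensities <- function() render_intensities(I_c = 1, I_t = 0.05,
                                                   I_m = 0.02)

small_psf_config <- function(...) {
  psf_config(mode = "fluorescence", na = 1.45, wavelength = 0.6,
             camera_pixel = 6.5, magnification = 100, supersample = 3, ...)
}
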