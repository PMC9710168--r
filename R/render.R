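#' @title Optical-path-length rendering of scene frames
#' @description The renderer turns a `scene_frame` into a super-sampled
#'   optical-path-length (OPL) image and a pixel-perfect integer label
#'   image. Cell bodies are spherocylinders revolved about their major
#'   axis; instead of voxelising and projecting, each pixel receives the
#'   analytic chord length of the hull along the optical axis,
#'   `2 * sqrt(r^2 - d^2)` at perpendicular distance `d` from the (possibly
#'   bowed) medial axis. The image convention is: rows run along the trench
#'   axis (row 1 at the closed-end side), columns across it.
#' @name renderer
NULL

# minimum distance from points (px, py) to the polyline through (cx, cy)
dist_to_polyline <- function(px, py, cx, cy) {
  d2 <- rep(Inf, length(px))
  for (k in seq_len(length(cx) - 1)) {
    ax <- cx[k]; ay <- cy[k]
    bx <- cx[k + 1]; by <- cy[k + 1]
    vx <- bx - ax; vy <- by - ay
    vv <- vx * vx + vy * vy
    t <- if (vv == 0) 0 else pmin(pmax(((px - ax) * vx + (py - ay) * vy) / vv, 0), 1)
    dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

# chord length of the spherocylinder hull at points (px, py) relative to
# the cell centroid, axis along px
chord_field <- function(px, py, length, width, bend) {
  r <- width / 2
  ax <- medial_axis(length, width, bend)
  d <- dist_to_polyline(px, py, ax$x, ax$y)
  2 * sqrt(pmax(r^2 - d^2, 0))
}

# medial-axis polyline of a (possibly bent) spherocylinder centred at the
# origin, axis along x; a single-arc bow with peak deflection `bend`
medial_axis <- function(length, width, bend, n = 33) {
  s_max <- max(length / 2 - width / 2, 0)
  if (s_max == 0 || bend == 0) {
    s <- c(-s_max, s_max)
    if (s_max == 0) s <- c(0, 0)
    return(list(x = s, y = c(0, 0) + ifelse(bend == 0, 0, bend)))
  }
  s <- seq(-s_max, s_max, length.out = n)
  y <- bend * (1 - (s / s_max)^2)
  # keep the arc length equal to the straight axis so the integrated OPL
  # (cell mass) is conserved under bending: bent cells span less x
  arc <- sum(sqrt(diff(s)^2 + diff(y)^2))
  list(x = s * (2 * s_max / arc), y = y)
}

#' Analytic OPL patch of a single spherocylindrical cell
#'
#' Evaluates the chord-length projection of a spherocylinder (total length
#' `l`, diameter `width`) on a pixel grid: each pixel centre at perpendicular
#' distance `d < r` from the medial axis receives `2 * sqrt(r^2 - d^2)`, in
#' the same length unit as `l`; pixels outside the hull are zero. A nonzero
#' `bend` bows the medial axis by that amplitude (um of peak centreline
#' deflection) while conserving the integrated OPL to within a few percent.
#' The patch integrates (sum times pixel area) to the spherocylinder volume.
#'
#' @param length total cell length (um), `>= width`.
#' @param width cell diameter (um).
#' @param pixel_size pixel pitch of the (super-sampled) grid (um); `> 0`.
#' @param bend peak medial-axis deflection (um), `>= 0` bows one way.
#' @return list with `opl` (matrix, rows along the cell axis), `mask`
#'   (logical), and the axis coordinates `x0`, `y0` of pixel `[1, 1]`'s
#'   centre relative to the cell centroid.
#' @export
spherocylinder_opl <- function(length, width, pixel_size, bend = 0) {
  if (pixel_size <= 0) abort("`pixel_size` must be > 0.")
  if (length < width) abort("`length` must be >= `width` (spherocylinder).")
  r <- width / 2
  half_x <- length / 2 + pixel_size
  half_y <- r + abs(bend) + pixel_size
  nx <- ceiling(2 * half_x / pixel_size)
  ny <- ceiling(2 * half_y / pixel_size)
  xs <- (seq_len(nx) - (nx + 1) / 2) * pixel_size
  ys <- (seq_len(ny) - (ny + 1) / 2) * pixel_size
  px <- rep(xs, times = ny)
  py <- rep(ys, each = nx)
  chord <- chord_field(px, py, length, width, bend)
  opl <- matrix(chord, nrow = nx, ncol = ny)
  list(opl = opl, mask = opl > 0, x0 = xs[1], y0 = ys[1])
}

#' Bend an existing OPL patch
#'
#' Re-renders the patch geometry with the requested single-arc bow of the
#' medial axis. Amplitude 0 returns the straight patch; the integrated OPL
#' (hence the mask area) is conserved to within ~2% for physiological bows.
#'
#' @param length,width,pixel_size as in [spherocylinder_opl()].
#' @param amplitude peak centreline deflection (um), `>= 0`.
#' @return as [spherocylinder_opl()].
#' @export
bend_cell <- function(length, width, pixel_size, amplitude) {
  if (amplitude < 0) abort("`amplitude` must be >= 0.")
  spherocylinder_opl(length, width, pixel_size, bend = amplitude)
}

#' Render a scene frame to an OPL image with ground-truth labels
#'
#' Composes the scene in the fixed order: media everywhere at `I_m`, the
#' device (closed-end cap and side walls) at `I_t`, then each cell's chord
#' projection added at `I_c` per unit path length. The label image is
#' painted from the exact analytic hull footprints and never sees the
#' optics: ground truth is bit-identical across any optical or camera
#' parameter change.
#'
#' @param frame a `scene_frame`.
#' @param intensities a [render_intensities()].
#' @param pixel_size target camera pixel size in object space (um).
#' @param supersample integer super-sampling factor (`>= 1`); the OPL grid
#'   pitch is `pixel_size / supersample`.
#' @param media_margin media border beyond the walls and the open end (um).
#' @return object of class `opl_image`: list with `opl` and `labels`
#'   matrices (equal dims), `pixel_size` (super-sampled pitch, um),
#'   `supersample`, `intensities`, and the geometry offsets `origin_row_um`,
#'   `origin_col_um` mapping trench coordinates to the image.
#' @export
render_opl <- function(frame, intensities = render_intensities(),
                       pixel_size = 0.065, supersample = 3,
                       media_margin = 1) {
  if (supersample < 1 || supersample != round(supersample))
    abort("`supersample` must be a positive integer.")
  geom <- frame$geometry
  ps <- pixel_size / supersample
  # image extents in um; rows: [closed-end cap | trench | open media],
  # cols: [media | wall | channel | wall | media]
  h_um <- geom$wall + geom$length + media_margin
  w_um <- 2 * media_margin + 2 * geom$wall + geom$width
  # snap dims to multiples of the supersample factor so the camera-resolution
  # image is an exact block average
  nrow_px <- ceiling(h_um / pixel_size) * supersample
  ncol_px <- ceiling(w_um / pixel_size) * supersample
  x_px <- (seq_len(nrow_px) - 0.5) * ps      # along trench axis
  y_px <- (seq_len(ncol_px) - 0.5) * ps      # across
  y_center <- w_um / 2
  opl <- matrix(intensities$I_m, nrow_px, ncol_px)
  in_cap <- x_px < geom$wall
  in_wall_band <- abs(y_px - y_center) > geom$width / 2 &
    abs(y_px - y_center) <= geom$width / 2 + geom$wall
  in_device_rows <- x_px <= geom$wall + geom$length
  dev_mask <- outer(in_cap, abs(y_px - y_center) <=
                      geom$width / 2 + geom$wall) |
    outer(in_device_rows, rep(TRUE, ncol_px)) &
      outer(rep(TRUE, nrow_px), in_wall_band)
  opl[dev_mask] <- intensities$I_t
  labels <- matrix(0L, nrow_px, ncol_px)
  if (nrow(frame$cells) > 0) {
    for (i in seq_len(nrow(frame$cells))) {
      cell <- frame$cells[i, ]
      # cell centroid in image um coordinates; the chord is evaluated at
      # the absolute pixel centres so footprints inherit the physics'
      # exact disjointness (no pasting quantisation)
      cx <- geom$wall + cell$x
      cy <- y_center + cell$y
      half_x <- cell$length / 2 + ps
      half_y <- cell$width / 2 + cell$bend_amplitude + ps
      rows <- which(abs(x_px - cx) <= half_x)
      cols <- which(abs(y_px - cy) <= half_y)
      if (length(rows) == 0 || length(cols) == 0) next
      px <- rep(x_px[rows] - cx, times = length(cols))
      py <- rep(y_px[cols] - cy, each = length(rows))
      chord <- matrix(chord_field(px, py, cell$length, cell$width,
                                  cell$bend_amplitude),
                      length(rows), length(cols))
      sub_mask <- chord > 0
      if (any(labels[rows, cols][sub_mask] != 0L))
        abort("internal error: overlapping cell footprints after physics.")
      opl[rows, cols] <- opl[rows, cols] + intensities$I_c * chord
      lab <- labels[rows, cols]
      lab[sub_mask] <- as.integer(cell$id)
      labels[rows, cols] <- lab
    }
  }
  structure(list(opl = opl, labels = labels, pixel_size = ps,
                 supersample = as.integer(supersample),
                 intensities = intensities,
                 origin_row_um = geom$wall, origin_col_um = y_center),
            class = "opl_image")
}

#' @export
print.opl_image <- function(x, ...) {
  cat(sprintf(
    "<opl_image> %d x %d at %.4f um/px (supersample %d), %d cell label(s)\n",
    nrow(x$opl), ncol(x$opl), x$pixel_size, x$supersample,
    length(setdiff(unique(as.integer(x$labels)), 0L))))
  invisible(x)
}

#' Smooth pseudorandom background texture (2-D gradient noise)
#'
#' Classic lattice gradient (Perlin) noise for agar-pad style backgrounds:
#' random unit gradients on a coarse lattice, quintic-smoothstep
#' interpolation of the corner dot products. The field is centred to zero
#' mean and scaled to the requested standard deviation; its spatial
#' autocorrelation length grows with `scale`.
#'
#' @param dim `c(nrow, ncol)` of the field.
#' @param scale lattice spacing in pixels (`> 0`); larger is smoother.
#' @param amplitude standard deviation of the returned field.
#' @return a `dim[1] x dim[2]` matrix with mean 0 and SD `amplitude`.
#' @export
perlin_background <- function(dim, scale = 20, amplitude = 1) {
  if (scale <= 0) abort("`scale` must be > 0.")
  nr <- dim[1]; nc <- dim[2]
  gx <- nr / scale; gy <- nc / scale
  nlx <- floor(gx) + 2L; nly <- floor(gy) + 2L
  theta <- matrix(runif(nlx * nly, 0, 2 * pi), nlx, nly)
  gxv <- cos(theta); gyv <- sin(theta)
  u <- (seq_len(nr) - 1) / scale
  v <- (seq_len(nc) - 1) / scale
  iu <- pmin(floor(u), nlx - 2L); fv_u <- u - iu
  iv <- pmin(floor(v), nly - 2L); fv_v <- v - iv
  fade <- function(t) t^3 * (t * (t * 6 - 15) + 10)
  su <- fade(fv_u); sv <- fade(fv_v)
  U <- matrix(fv_u, nr, nc); V <- matrix(fv_v, nr, nc, byrow = TRUE)
  IU <- matrix(iu + 1L, nr, nc); IV <- matrix(iv + 1L, nr, nc, byrow = TRUE)
  corner <- function(di, dj) {
    idx <- cbind(as.vector(IU + di), as.vector(IV + dj))
    gxm <- matrix(gxv[idx], nr, nc)
    gym <- matrix(gyv[idx], nr, nc)
    gxm * (U - di) + gym * (V - dj)
  }
  n00 <- corner(0L, 0L); n10 <- corner(1L, 0L)
  n01 <- corner(0L, 1L); n11 <- corner(1L, 1L)
  SU <- matrix(su, nr, nc); SV <- matrix(sv, nr, nc, byrow = TRUE)
  nx0 <- n00 + SU * (n10 - n00)
  nx1 <- n01 + SU * (n11 - n01)
  field <- nx0 + SV * (nx1 - nx0)
  field <- field - mean(field)
  s <- stats::sd(field)
  if (s > 0) field <- field * (amplitude / s)
  field
}

#' Downsample a label image by block majority vote
#'
#' Reduces a super-sampled label image to camera resolution: each
#' `factor x factor` block takes the most frequent value in the block (ties
#' go to the smaller value, background 0 competes like any other value).
#'
#' @param labels integer matrix with dims divisible by `factor`.
#' @param factor integer block size.
#' @return integer matrix of dims `dim(labels) / factor`.
#' @export
downsample_labels <- function(labels, factor) {
  factor <- as.integer(factor)
  if (factor == 1L) return(labels)
  nr <- nrow(labels) %/% factor
  nc <- ncol(labels) %/% factor
  if (nr * factor != nrow(labels) || nc * factor != ncol(labels))
    abort("label image dims must be divisible by `factor`.")
  bi <- (rep(seq_len(nrow(labels)), times = ncol(labels)) - 1L) %/% factor
  bj <- (rep(seq_len(ncol(labels)), each = nrow(labels)) - 1L) %/% factor
  block <- bi + nr * bj + 1L
  vals <- as.integer(labels)
  lev <- sort(unique(vals))
  vi <- match(vals, lev)
  tab <- table(factor(block, levels = seq_len(nr * nc)),
               factor(vi, levels = seq_along(lev)))
  out <- lev[max.col(tab, ties.method = "first")]
  matrix(out, nr, nc)
}
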