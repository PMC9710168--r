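#' @title Label-free evaluation statistics
#' @description Mother-machine growth traces form a sawtooth: length rises
#'   exponentially and halves at division. Segmentation errors leave a
#'   distinctive signature in the first derivative — a sharp drop-then-rise
#'   (or rise-then-drop) that is not compatible with a division — so
#'   segmentation quality can be scored without ground truth. This module
#'   also provides Jaccard-optimal probability thresholding, seeded
#'   watershed post-processing, precision from quadratic residuals, and
#'   per-label mask geometry.
#' @name evaluation
NULL

#' Per-label mask geometry
#'
#' For every label: the maximal extent along the major principal axis of
#' its pixel cloud (length), and twice the mean half-extent perpendicular to
#' it over the cylindrical mid-section (width). Rotation-invariant to about
#' a pixel. Single-pixel labels are flagged.
#'
#' @param labels integer label matrix.
#' @param pixel_size physical pixel size; output lengths are
#'   `pixels * pixel_size`.
#' @param mid_fraction fraction of the axial extent, centred on the
#'   centroid, used for the width estimate (default 0.5).
#' @return tibble with `label`, `n_pixels`, `length`, `width`,
#'   `row`, `col` (centroid), `flagged`.
#' @export
mask_geometry <- function(labels, pixel_size = 1, mid_fraction = 0.5) {
  ids <- sort(unique(labels[labels > 0]))
  purrr::map_dfr(ids, function(id) {
    w <- which(labels == id, arr.ind = TRUE)
    n <- nrow(w)
    cen <- colMeans(w)
    if (n == 1) {
      return(tibble(label = id, n_pixels = 1L,
                    length = pixel_size, width = pixel_size,
                    row = cen[1], col = cen[2], flagged = TRUE))
    }
    pts <- sweep(w, 2, cen)
    ev <- eigen(stats::cov(pts), symmetric = TRUE)$vectors
    p1 <- pts %*% ev[, 1]
    p2 <- pts %*% ev[, 2]
    len_px <- max(p1) - min(p1) + 1
    mid <- abs(p1 - (max(p1) + min(p1)) / 2) <= (len_px - 1) * mid_fraction / 2
    # over the (rectangular) mid-section the transverse offsets are uniform
    # across the width, so E|v| = width / 4; this estimator is robust to
    # rotation, unlike a max-minus-min extent on a thin slice
    v <- p2[mid]
    wid_px <- 4 * mean(abs(v - mean(v)))
    tibble(label = id, n_pixels = n,
           length = len_px * pixel_size,
           width = wid_px * pixel_size,
           row = cen[1], col = cen[2], flagged = FALSE)
  })
}

#' Mother-cell growth trace from a label-image stack
#'
#' For each timepoint, takes the cell nearest the closed end (smallest row
#' index of its mask, row 1 being the closed-end side) and measures its
#' major-axis extent. Empty frames yield `NA` (gaps are not interpolated).
#'
#' @param label_stack list of integer label matrices, one per timepoint.
#' @param pixel_size physical pixel size (trace lengths in the same unit).
#' @return tibble with `t`, `label`, `length`: a growth trace.
#' @export
extract_mother_trace <- function(label_stack, pixel_size = 1) {
  purrr::imap_dfr(label_stack, function(lab, t) {
    if (all(lab == 0))
      return(tibble(t = t - 1L, label = NA_integer_, length = NA_real_))
    fg <- which(lab > 0, arr.ind = TRUE)
    mother <- lab[fg[which.min(fg[, 1]), , drop = FALSE]]
    geo <- mask_geometry(ifelse(lab == mother, mother, 0L),
                         pixel_size = pixel_size)
    tibble(t = t - 1L, label = as.integer(mother), length = geo$length)
  })
}

#' Sawtooth identification-error rate
#'
#' Flags timepoints whose length derivative shows a spurious peak: a sharp
#' decrease-then-increase or increase-then-decrease that is not a
#' division-compatible drop (a drop to a fraction of the previous length
#' inside `division_interval` is a division and is never flagged). The rate
#' is flagged timepoints over total timepoints.
#'
#' @param trace numeric length vector, or a tibble with a `length` column
#'   (e.g. from [extract_mother_trace()] or [mother_trace()]).
#' @param division_interval drops with `l_t / l_(t-1)` in this interval are
#'   divisions (default `c(0.4, 0.6)`).
#' @param min_step minimum relative step size treated as sharp (default
#'   0.1; ordinary growth between frames is much smaller).
#' @return the error rate, with the flagged timepoint indices attached as
#'   attribute `"flagged"`.
#' @export
identification_error <- function(trace, division_interval = c(0.4, 0.6),
                                 min_step = 0.1) {
  l <- if (is.data.frame(trace)) trace$length else as.numeric(trace)
  if (anyNA(l)) {
    warn("trace contains gaps; NA timepoints dropped.")
    l <- l[!is.na(l)]
  }
  n <- length(l)
  if (n < 3) abort("trace must contain at least 3 timepoints.")
  ratio <- l[-1] / l[-n]               # ratio[t] = l_(t+1) / l_t
  up <- ratio - 1 >= min_step
  down <- 1 - ratio >= min_step
  divisionish <- ratio >= division_interval[1] &
    ratio <= division_interval[2]
  flagged <- integer(0)
  for (t in seq_len(n - 2)) {
    dip <- down[t] && up[t + 1] && !divisionish[t]
    spike <- up[t] && down[t + 1] && !divisionish[t + 1]
    if (dip || spike) flagged <- c(flagged, t + 1L)
  }
  flagged <- unique(flagged)
  structure(length(flagged) / n, flagged = flagged)
}

jaccard_index <- function(pred, truth) {
  inter <- sum(pred & truth)
  uni <- sum(pred | truth)
  if (uni == 0) return(1)
  inter / uni
}

# cumulative intersection of per-cell length and width histograms between
# thresholded and true masks (50 bins over the pooled range)
distribution_intersection <- function(pred_labels, truth_labels,
                                      bins = 50) {
  gp <- mask_geometry(pred_labels)
  gt <- mask_geometry(truth_labels)
  if (nrow(gp) == 0 || nrow(gt) == 0) return(0)
  one <- function(a, b) {
    br <- range(c(a, b))
    if (diff(br) == 0) return(1)
    brks <- seq(br[1], br[2], length.out = bins + 1)
    ha <- hist(a, breaks = brks, plot = FALSE)$counts / length(a)
    hb <- hist(b, breaks = brks, plot = FALSE)$counts / length(b)
    sum(pmin(ha, hb))
  }
  one(gp$length, gt$length) + one(gp$width, gt$width)
}

#' Jaccard-optimal probability threshold
#'
#' Grid search over probability thresholds, maximising the mean Jaccard
#' index between thresholded maps and the true masks; ties return the
#' lowest threshold. Also reports the alternative statistic: the cumulative
#' intersection of the per-cell length and width distributions between the
#' thresholded and true masks.
#'
#' @param maps probability matrix in `[0, 1]`, or a list of them.
#' @param truth matching ground-truth label (or binary) matrix, or list.
#' @param grid thresholds to scan (default 0.50 to 0.995 in steps of
#'   0.005).
#' @param intersection also compute the distribution-intersection curve
#'   (slower; default `TRUE`).
#' @return object of class `threshold_opt`: list with `optimal` (lowest
#'   argmax of the Jaccard curve), `optimal_intersection` (or `NA`), and
#'   `curve`, a tibble of `threshold`, `jaccard`, `intersection`.
#' @export
optimal_threshold <- function(maps, truth,
                              grid = seq(0.50, 0.995, by = 0.005),
                              intersection = TRUE) {
  if (is.matrix(maps)) maps <- list(maps)
  if (is.matrix(truth)) truth <- list(truth)
  rng <- range(unlist(lapply(maps, range)))
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    abort("probability maps must lie in [0, 1].")
  maps <- lapply(maps, function(m) pmin(pmax(m, 0), 1))
  if (rng[2] <= min(grid))
    abort("map has no foreground at any threshold in the grid.")
  curve <- purrr::map_dfr(grid, function(th) {
    jac <- mean(purrr::map2_dbl(maps, truth, function(m, tr)
      jaccard_index(m > th, tr > 0)))
    inter <- if (intersection) {
      mean(purrr::map2_dbl(maps, truth, function(m, tr)
        distribution_intersection(
          label_components(m > th, 8),
          matrix(as.integer(tr), nrow(tr)))))
    } else NA_real_
    tibble(threshold = th, jaccard = jac, intersection = inter)
  })
  structure(list(
    optimal = curve$threshold[which.max(curve$jaccard)],
    optimal_intersection = if (intersection)
      curve$threshold[which.max(curve$intersection)] else NA_real_,
    curve = curve
  ), class = "threshold_opt")
}

#' @export
print.threshold_opt <- function(x, ...) {
  cat(sprintf(
    "<threshold_opt> Jaccard-optimal %.3f; distribution-intersection optimal %s\n",
    x$optimal,
    ifelse(is.na(x$optimal_intersection), "n/a",
           sprintf("%.3f", x$optimal_intersection))))
  invisible(x)
}

#' @rdname optimal_threshold
#' @param x,object a `threshold_opt`.
#' @param ... unused.
#' @method tidy threshold_opt
#' @export
tidy.threshold_opt <- function(x, ...) x$curve

#' @rdname optimal_threshold
#' @method glance threshold_opt
#' @export
glance.threshold_opt <- function(x, ...) {
  tibble(optimal = x$optimal,
         optimal_intersection = x$optimal_intersection,
         max_jaccard = max(x$curve$jaccard))
}

#' @rdname optimal_threshold
#' @method autoplot threshold_opt
#' @export
autoplot.threshold_opt <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$threshold, y = .data$jaccard)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$optimal, linetype = 2) +
    ggplot2::labs(x = "probability threshold", y = "mean Jaccard index") +
    ggplot2::theme_minimal()
}

#' Seeded watershed on a probability map
#'
#' Seeds are the connected components of `map > t_seed` (default 0.999);
#' instances are grown from the seeds over the foreground `map > t_opt` by
#' seeded region growing, splitting masks that merge at the lower
#' threshold.
#'
#' @param map probability matrix in `[0, 1]`.
#' @param t_opt foreground threshold, `0 < t_opt < t_seed`.
#' @param t_seed seed threshold, `< 1`.
#' @return integer label matrix partitioning the `t_opt` foreground; all
#'   zeros (with a warning) when there are no seeds.
#' @export
seeded_watershed <- function(map, t_opt, t_seed = 0.999) {
  if (!(t_opt > 0 && t_opt < t_seed && t_seed < 1))
    abort("require 0 < t_opt < t_seed < 1.")
  seeds <- label_components(map > t_seed, 8)
  if (max(seeds) == 0) {
    warn("no seeds above `t_seed`; returning an empty labelling.")
    return(matrix(0L, nrow(map), ncol(map)))
  }
  out <- EBImage::propagate(EBImage::Image(map), EBImage::Image(seeds),
                            mask = map > t_opt)
  matrix(as.integer(out), nrow(map))
}

#' Segmentation precision from stationary-phase traces
#'
#' During deep stationary phase a cell's true length is essentially
#' constant, so residual fluctuation in the measured length is measurement
#' error. Each trace segment is fitted with a least-squares quadratic in
#' time; the SD of the pooled residuals is the precision. Segments shorter
#' than 4 points are skipped with a warning.
#'
#' @param segments a tibble with columns `segment`, `t`, `length`, or a
#'   list of numeric length vectors.
#' @return object of class `precision_fit`: list with `precision`,
#'   `n_segments`, `n_points`, `residuals`.
#' @export
precision_from_stationary <- function(segments) {
  if (is.data.frame(segments)) {
    segments <- split(segments$length, segments$segment)
  } else if (is.numeric(segments)) {
    segments <- list(segments)
  }
  keep <- vapply(segments, length, integer(1)) >= 4
  if (any(!keep))
    warn(sprintf("%d segment(s) shorter than 4 points skipped.", sum(!keep)))
  segments <- segments[keep]
  if (length(segments) == 0) abort("no usable segments (need >= 4 points).")
  res <- unlist(lapply(segments, function(l) {
    t <- seq_along(l)
    residuals(lm(l ~ t + I(t^2)))
  }))
  structure(list(precision = sd(res), n_segments = length(segments),
                 n_points = length(res), residuals = as.numeric(res)),
            class = "precision_fit")
}

#' @export
print.precision_fit <- function(x, ...) {
  cat(sprintf("<precision_fit> precision %.4f from %d segment(s), %d points\n",
              x$precision, x$n_segments, x$n_points))
  invisible(x)
}

#' @rdname precision_from_stationary
#' @param x a `precision_fit`.
#' @param ... unused.
#' @method glance precision_fit
#' @export
glance.precision_fit <- function(x, ...) {
  tibble(precision = x$precision, n_segments = x$n_segments,
         n_points = x$n_points)
}
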