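#' @title Agent-based growth simulation in a mother-machine trench
#' @description Cells are rows of a tibble (`id`, `parent_id`, `length`,
#'   `width`, `x`, `y`, `angle`, `age`, `birth_length`, `div_threshold`,
#'   `bend_amplitude`): spherocylinders of length `length` and diameter
#'   `width` lying on the trench axis, centroid at `x`. A scene frame pairs
#'   the cell table with the trench geometry at one timepoint.
#' @name growth_sim
NULL

cell_cols <- c("id", "parent_id", "length", "width", "x", "y", "angle",
               "age", "birth_length", "div_threshold", "bend_amplitude")

new_scene_frame <- function(t, cells, geometry) {
  structure(list(t = t, cells = cells, geometry = geometry),
            class = "scene_frame")
}

#' @export
print.scene_frame <- function(x, ...) {
  cat(sprintf("<scene_frame> t = %d, %d cell(s), trench %.1f x %.1f um\n",
              x$t, nrow(x$cells), x$geometry$length, x$geometry$width))
  print(x$cells, ...)
  invisible(x)
}

# draw from N(mean, sd) truncated below at `lower`, via the inverse CDF so a
# single runif() per draw keeps the RNG stream simple and reproducible
rtruncnorm_lower <- function(n, mean, sd, lower) {
  if (sd == 0) return(pmax(rep(mean, n), lower))
  p_lo <- pnorm((lower - mean) / sd)
  u <- runif(n, p_lo, 1)
  mean + sd * qnorm(pmin(u, 1 - 1e-12))
}

draw_widths <- function(n, config) {
  rtruncnorm_lower(n, config$width_mean, config$width_sd,
                   lower = 0.2 * config$width_mean)
}

# per-cell division threshold, drawn once at birth
draw_thresholds <- function(n, config, widths) {
  switch(config$regulation,
    adder = rtruncnorm_lower(n, config$division_mean / 2, config$division_sd,
                             lower = 0.05 * config$division_mean),
    sizer = pmax(rtruncnorm_lower(n, config$division_mean, config$division_sd,
                                  lower = 0), 2 * widths),
    timer = rtruncnorm_lower(n, config$division_time_mean,
                             config$division_time_sd,
                             lower = 0.05 * config$division_time_mean)
  )
}

draw_bends <- function(n, config) {
  if (config$bend_sd == 0) rep(0, n) else abs(rnorm(n, 0, config$bend_sd))
}

#' Initialise a scene with a founder cell
#'
#' Creates frame 0: one founder cell resting against the closed end of the
#' trench, with width, division threshold and bend amplitude drawn from the
#' configured distributions and birth length drawn uniformly between its
#' width and the mean division length.
#'
#' @param config a [sim_config()].
#' @param geometry a [trench_geometry()].
#' @return a `scene_frame` at `t = 0`.
#' @export
init_scene <- function(config, geometry) {
  validate_sim_config(config)
  if (config$width_mean > geometry$width)
    abort("mean cell width exceeds trench width: geometry infeasible.")
  w <- draw_widths(1, config)
  l <- runif(1, min = w, max = max(w * 1.01, 0.9 * config$division_mean))
  cells <- tibble(
    id = 1L, parent_id = NA_integer_,
    length = l, width = w,
    x = l / 2, y = 0, angle = 0,
    age = 0, birth_length = l,
    div_threshold = draw_thresholds(1, config, w),
    bend_amplitude = draw_bends(1, config)
  )
  new_scene_frame(0L, cells, geometry)
}

#' Elongate cells exponentially
#'
#' Applies the single-cell growth law `l' = l * exp(rate * dt)` to every row
#' and advances `age` by `dt`. Width is untouched: cells keep their diameter
#' between birth and division.
#'
#' @param cells a cell tibble (see [growth_sim]).
#' @param rate elongation rate (1/min).
#' @param dt timestep (min); must be `>= 0`.
#' @return the grown cell tibble.
#' @export
grow_cells <- function(cells, rate, dt) {
  if (dt < 0) abort("`dt` must be >= 0.")
  dplyr::mutate(cells,
                length = .data$length * exp(rate * dt),
                age = .data$age + dt)
}

# division predicate per regulation mode
division_due <- function(cells, config) {
  switch(config$regulation,
    adder = cells$length - cells$birth_length >= cells$div_threshold,
    sizer = cells$length >= cells$div_threshold,
    timer = cells$age >= cells$div_threshold
  )
}

#' Divide cells that have reached their threshold
#'
#' Cells whose regulation rule fires (adder: added length since birth; sizer:
#' absolute length; timer: age) are replaced by two daughters sharing the
#' mother's footprint minus a septum gap, each with a fresh id, width,
#' threshold and bend amplitude. Returns the updated cell table plus a log of
#' division/birth events.
#'
#' @param cells cell tibble.
#' @param config a [sim_config()].
#' @param next_id first unused integer id.
#' @return list with `cells`, `next_id`, `events` (tibble), `n_divisions`.
#' @export
divide_cells <- function(cells, config, next_id) {
  due <- division_due(cells, config)
  if (!any(due)) {
    return(list(cells = cells, next_id = next_id,
                events = empty_events(), n_divisions = 0L))
  }
  mothers <- cells[due, ]
  n <- nrow(mothers)
  post <- pmax(mothers$length - config$septum_gap, mothers$width * 2 * 0.5)
  a <- config$asymmetry +
    (if (config$asymmetry_sd > 0) rnorm(n, 0, config$asymmetry_sd) else 0)
  a <- pmin(pmax(a, 0.2), 0.8)
  l1 <- a * post          # daughter nearer the closed end
  l2 <- (1 - a) * post
  left_edge <- mothers$x - mothers$length / 2
  right_edge <- mothers$x + mothers$length / 2
  mk_daughter <- function(ids, l, x) {
    w <- draw_widths(n, config)
    tibble(
      id = ids, parent_id = mothers$id,
      length = l, width = w,
      x = x, y = 0, angle = 0,
      age = 0, birth_length = l,
      div_threshold = draw_thresholds(n, config, w),
      bend_amplitude = draw_bends(n, config)
    )
  }
  ids1 <- next_id + seq_len(n) - 1L
  ids2 <- next_id + n + seq_len(n) - 1L
  d1 <- mk_daughter(ids1, l1, left_edge + l1 / 2)
  d2 <- mk_daughter(ids2, l2, right_edge - l2 / 2)
  events <- dplyr::bind_rows(
    tibble(id = mothers$id, parent_id = mothers$parent_id,
           event = "division", l = mothers$length, x = mothers$x),
    tibble(id = c(ids1, ids2), parent_id = rep(mothers$id, 2),
           event = "birth", l = c(l1, l2), x = c(d1$x, d2$x))
  )
  out <- dplyr::bind_rows(cells[!due, ], d1, d2)
  out <- out[order(out$x), ]
  list(cells = out, next_id = next_id + 2L * n, events = events,
       n_divisions = n)
}

empty_events <- function() {
  tibble(id = integer(), parent_id = integer(),
         event = character(), l = numeric(), x = numeric())
}

#' Resolve overlaps and containment in one trench
#'
#' Deterministic 1-D projection solver: cells are sorted along the trench
#' axis and swept from the rigid closed end outward, each cell displaced
#' toward the open end just enough to clear the closed wall and its inner
#' neighbour. Cells whose centroid crosses the open end are removed and
#' reported as washed out. Axis order is preserved by construction.
#'
#' @param frame a `scene_frame`.
#' @param tol maximum residual pairwise overlap (um).
#' @param max_iter sweep budget before a non-convergence error.
#' @return list with `frame` (resolved) and `events` (washout log).
#' @export
resolve_collisions <- function(frame, tol = 0.01, max_iter = 100L) {
  cells <- frame$cells
  if (nrow(cells) == 0)
    return(list(frame = frame, events = empty_events()))
  cells <- cells[order(cells$x), ]
  l <- cells$length
  x <- cells$x
  for (iter in seq_len(max_iter)) {
    x_new <- x
    x_new[1] <- max(x_new[1], l[1] / 2)
    if (length(x) > 1) {
      for (i in 2:length(x)) {
        x_new[i] <- max(x_new[i], x_new[i - 1] + (l[i - 1] + l[i]) / 2)
      }
    }
    moved <- max(abs(x_new - x))
    x <- x_new
    # converged when no body pokes through the closed wall and every
    # neighbouring pair overlaps by at most `tol`
    ok_wall <- x[1] - l[1] / 2 >= -tol
    ok_pairs <- length(x) < 2 ||
      all(diff(x) - (head(l, -1) + tail(l, -1)) / 2 >= -tol)
    if (ok_wall && ok_pairs) break
    if (iter == max_iter)
      abort(sprintf("collision resolution did not converge at frame %d",
                    frame$t))
  }
  cells$x <- x
  washed <- cells$x > frame$geometry$open_end
  events <- empty_events()
  if (any(washed)) {
    w <- cells[washed, ]
    events <- tibble(id = w$id, parent_id = w$parent_id,
                     event = "washout", l = w$length, x = w$x)
    cells <- cells[!washed, ]
  }
  frame$cells <- cells
  list(frame = frame, events = events)
}

#' Advance the scene by one timestep
#'
#' Applies, in order: exponential growth, threshold-triggered division,
#' Bernoulli lysis (lysed cells removed), and collision resolution with
#' washout at the open end. Returns the new frame, the events logged this
#' step, the id counter, and the summed length increment due to growth
#' (used by the mass audit).
#'
#' @param frame a `scene_frame`.
#' @param config a [sim_config()].
#' @param next_id first unused id.
#' @return list with `frame`, `events`, `next_id`, `growth`.
#' @export
step_scene <- function(frame, config, next_id = max(frame$cells$id, 0L) + 1L) {
  cells <- frame$cells
  grown <- grow_cells(cells, config$growth_rate, config$dt)
  growth <- sum(grown$length) - sum(cells$length)
  div <- divide_cells(grown, config, next_id)
  cells <- div$cells
  events <- div$events
  if (config$p_lyse > 0 && nrow(cells) > 0) {
    lysed <- runif(nrow(cells)) < config$p_lyse
    if (any(lysed)) {
      lys <- cells[lysed, ]
      events <- dplyr::bind_rows(events,
        tibble(id = lys$id, parent_id = lys$parent_id,
               event = "lysis", l = lys$length, x = lys$x))
      cells <- cells[!lysed, ]
    }
  }
  frame$cells <- cells
  frame$t <- frame$t + 1L
  res <- resolve_collisions(frame)
  events <- dplyr::bind_rows(events, res$events)
  list(frame = res$frame, events = events, next_id = div$next_id,
       growth = growth)
}

#' Run a mother-machine growth simulation
#'
#' Orchestrates [init_scene()] and [step_scene()] for
#' `config$n_timepoints` steps under one RNG seed, collecting every frame
#' and a tidy event log (columns `t`, `id`, `parent_id`, `event`, `l`, `x`;
#' events are `birth`, `division`, `lysis`, `washout`).
#'
#' @param config a [sim_config()].
#' @param geometry a [trench_geometry()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return an object of class `trench_sim`: list with `frames` (list of
#'   `scene_frame`), `events` (tibble), `config`, `geometry`, and `audit`
#'   (founder length, total growth, division count) for the mass audit.
#' @export
run_simulation <- function(config, geometry, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  frame <- init_scene(config, geometry)
  frames <- vector("list", config$n_timepoints + 1L)
  frames[[1]] <- frame
  founder_length <- frame$cells$length
  events <- list(tibble(t = 0L, id = frame$cells$id,
                        parent_id = frame$cells$parent_id,
                        event = "birth", l = frame$cells$length,
                        x = frame$cells$x))
  next_id <- 2L
  total_growth <- 0
  n_divisions <- 0L
  t <- 0L
  while (t < config$n_timepoints) {
    st <- step_scene(frame, config, next_id)
    frame <- st$frame
    next_id <- st$next_id
    total_growth <- total_growth + st$growth
    n_divisions <- n_divisions + sum(st$events$event == "division")
    t <- t + 1L
    frames[[t + 1L]] <- frame
    if (nrow(st$events) > 0) {
      ev <- st$events
      ev$t <- t
      events[[length(events) + 1L]] <- dplyr::relocate(ev, "t")
    }
    if (nrow(frame$cells) == 0) {
      frames <- frames[seq_len(t + 1L)]
      break
    }
  }
  structure(list(
    frames = frames,
    events = dplyr::bind_rows(events),
    config = config, geometry = geometry,
    audit = list(founder_length = founder_length,
                 total_growth = total_growth,
                 n_divisions = n_divisions)
  ), class = "trench_sim")
}

#' Mass (length) audit of a simulation
#'
#' Conservation check: the founder length plus all growth increments must
#' equal the length still in the trench, plus the length of every washed-out
#' or lysed cell at removal, plus one septum gap per division.
#'
#' @param sim a `trench_sim`.
#' @return one-row tibble with the terms and the closure `residual`.
#' @export
sim_mass_audit <- function(sim) {
  last <- sim$frames[[length(sim$frames)]]
  removed <- sim$events[sim$events$event %in% c("washout", "lysis"), ]
  supplied <- sim$audit$founder_length + sim$audit$total_growth
  accounted <- sum(last$cells$length) + sum(removed$l) +
    sim$audit$n_divisions * sim$config$septum_gap
  tibble(
    founder = sim$audit$founder_length,
    growth = sim$audit$total_growth,
    in_trench = sum(last$cells$length),
    removed = sum(removed$l),
    septum_loss = sim$audit$n_divisions * sim$config$septum_gap,
    residual = supplied - accounted
  )
}

#' Mother-cell length trace
#'
#' The length of the cell nearest the closed end at every timepoint: the
#' sawtooth trace used by [identification_error()].
#'
#' @param sim a `trench_sim`.
#' @return tibble with `t`, `id`, `length`.
#' @export
mother_trace <- function(sim) {
  purrr::map_dfr(sim$frames, function(fr) {
    if (nrow(fr$cells) == 0)
      return(tibble(t = fr$t, id = NA_integer_, length = NA_real_))
    m <- fr$cells[which.min(fr$cells$x), ]
    tibble(t = fr$t, id = m$id, length = m$length)
  })
}

#' Spherocylinder volume
#'
#' Volume of a spherocylinder of total length `l` and radius `r`:
#' `V = pi * r^2 * (l - 2r/3)`, i.e. a cylinder of length `l - 2r` plus two
#' hemispherical caps. At the sphere limit `l = 2r` this is `4/3 pi r^3`.
#'
#' @param l total length (um); must satisfy `l >= 2r`.
#' @param r radius (um).
#' @return volume (um^3); vectorised over `l` and `r`.
#' @export
cell_volume <- function(l, r) {
  if (any(l < 2 * r - 1e-12))
    abort("`l` must be >= 2r: a spherocylinder is never shorter than its caps.")
  pi * r^2 * (l - 2 * r / 3)
}

#' @export
print.trench_sim <- function(x, ...) {
  cat(sprintf(
    "<trench_sim> %d frames, %d divisions, %d cells in final frame\n",
    length(x$frames), x$audit$n_divisions,
    nrow(x$frames[[length(x$frames)]]$cells)))
  invisible(x)
}

#' @rdname run_simulation
#' @param x a `trench_sim`.
#' @param ... unused.
#' @method tidy trench_sim
#' @export
tidy.trench_sim <- function(x, ...) {
  purrr::map_dfr(x$frames, function(fr) {
    dplyr::mutate(fr$cells, t = fr$t, .before = 1)
  })
}

#' @rdname run_simulation
#' @method glance trench_sim
#' @export
glance.trench_sim <- function(x, ...) {
  ev <- x$events
  tibble(
    n_frames = length(x$frames),
    n_cells_final = nrow(x$frames[[length(x$frames)]]$cells),
    n_divisions = sum(ev$event == "division"),
    n_washouts = sum(ev$event == "washout"),
    n_lysed = sum(ev$event == "lysis"),
    audit_residual = sim_mass_audit(x)$residual
  )
}

#' @rdname run_simulation
#' @param object a `trench_sim`.
#' @method autoplot trench_sim
#' @export
autoplot.trench_sim <- function(object, ...) {
  tr <- mother_trace(object)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$t, y = .data$length)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "timepoint", y = "mother cell length (um)",
                  title = "Mother-cell sawtooth trace") +
    ggplot2::theme_minimal()
}

#' Per-division lineage summary
#'
#' One row per completed division: birth length, division length and the
#' interdivision time of the mother, assembled from the event log. Used to
#' check size-regulation behaviour (e.g. the adder's added-length-vs-birth-
#' length regression).
#'
#' @param sim a `trench_sim`.
#' @return tibble with `id`, `birth_length`, `division_length`,
#'   `added_length`, `interdivision_time`.
#' @export
division_table <- function(sim) {
  ev <- sim$events
  births <- ev[ev$event == "birth", c("t", "id", "l")]
  names(births) <- c("t_birth", "id", "birth_length")
  divs <- ev[ev$event == "division", c("t", "id", "l")]
  names(divs) <- c("t_div", "id", "division_length")
  out <- dplyr::inner_join(births, divs, by = "id")
  dplyr::transmute(out,
    id = .data$id,
    birth_length = .data$birth_length,
    division_length = .data$division_length,
    added_length = .data$division_length - .data$birth_length,
    interdivision_time = (.data$t_div - .data$t_birth) * sim$config$dt
  )
}
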