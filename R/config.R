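#' Simulation configuration
#'
#' Parameters of the agent-based mother-machine growth model. Lengths and
#' widths are in micrometres, times in minutes, rates in 1/minute. The
#' division-size distribution is given as the mean and SD of a cell's length
#' at division; in `adder` mode the per-cell added-length threshold is drawn
#' with mean `division_mean / 2` (so the steady-state division size matches
#' the sizer parameterisation) and SD `division_sd`. In `timer` mode the
#' interdivision time is drawn from `N(division_time_mean, division_time_sd)`
#' truncated at zero.
#'
#' @param regulation size-regulation mode: `"adder"`, `"sizer"` or `"timer"`.
#' @param division_mean,division_sd mean and SD of length at division (um).
#' @param division_time_mean,division_time_sd mean and SD of the
#'   interdivision time (min), used in `timer` mode.
#' @param width_mean,width_sd mean and SD of cell width (diameter, um).
#' @param growth_rate exponential elongation rate (1/min). The default
#'   `log(2)/30` doubles cell length every 30 minutes.
#' @param dt simulation timestep (min).
#' @param p_lyse per-timepoint lysis probability in `[0, 1]`.
#' @param n_timepoints number of steps to simulate after frame 0.
#' @param septum_gap length lost to the septum at division (um).
#' @param asymmetry,asymmetry_sd division asymmetry: fraction of the
#'   post-septum length given to the daughter nearer the closed end.
#' @param bend_sd scale of the half-normal from which each cell's bend
#'   amplitude (um of centreline deflection) is drawn at birth.
#' @param seed optional integer RNG seed used by [run_simulation()].
#'
#' @return an object of class `sim_config` (a validated named list).
#' @seealso [trench_geometry()], [run_simulation()]
#' @export
sim_config <- function(regulation = c("adder", "sizer", "timer"),
                       division_mean = 4, division_sd = 0.2,
                       division_time_mean = 30, division_time_sd = 3,
                       width_mean = 1, width_sd = 0.05,
                       growth_rate = log(2) / 30,
                       dt = 2,
                       p_lyse = 0,
                       n_timepoints = 100,
                       septum_gap = 0.1,
                       asymmetry = 0.5, asymmetry_sd = 0,
                       bend_sd = 0,
                       seed = NULL) {
  regulation <- match.arg(regulation)
  cfg <- list(
    regulation = regulation,
    division_mean = division_mean, division_sd = division_sd,
    division_time_mean = division_time_mean,
    division_time_sd = division_time_sd,
    width_mean = width_mean, width_sd = width_sd,
    growth_rate = growth_rate, dt = dt, p_lyse = p_lyse,
    n_timepoints = n_timepoints, septum_gap = septum_gap,
    asymmetry = asymmetry, asymmetry_sd = asymmetry_sd,
    bend_sd = bend_sd, seed = seed
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$dt <= 0) abort("`dt` must be > 0.")
  if (cfg$p_lyse < 0 || cfg$p_lyse > 1) abort("`p_lyse` must lie in [0, 1].")
  if (cfg$division_sd < 0 || cfg$width_sd < 0 || cfg$division_time_sd < 0)
    abort("standard deviations must be >= 0.")
  if (cfg$division_mean <= 0 || cfg$width_mean <= 0)
    abort("`division_mean` and `width_mean` must be > 0.")
  if (cfg$n_timepoints < 0) abort("`n_timepoints` must be >= 0.")
  if (cfg$septum_gap < 0) abort("`septum_gap` must be >= 0.")
  invisible(cfg)
}

#' Trench geometry
#'
#' A mother-machine trench: a dead-end channel with its closed end at
#' coordinate `x = 0` and its single open end at `x = length`. Cells live on
#' the trench axis; coordinates are micrometres.
#'
#' @param length trench length (um), closed end to open end.
#' @param width trench channel width (um); must exceed the configured cell
#'   width.
#' @param wall wall thickness (um), used by the renderer only.
#' @return an object of class `trench_geometry`.
#' @export
trench_geometry <- function(length = 20, width = 1.5, wall = 1) {
  if (length <= 0 || width <= 0 || wall < 0)
    abort("trench dimensions must be positive.")
  structure(list(length = length, width = width, wall = wall,
                 closed_end = 0, open_end = length),
            class = "trench_geometry")
}

#' Empirical rendering intensities
#'
#' The three empirical intensity factors of the scene composition: cell
#' bodies contribute `I_c` per unit optical path length, trench walls (the
#' device) render at `I_t`, and the media fills the remainder at `I_m`.
#' Arbitrary units; typically matched to a real reference micrograph.
#'
#' @param I_c,I_t,I_m non-negative finite intensities.
#' @return an object of class `render_intensities`.
#' @export
render_intensities <- function(I_c = 1, I_t = 0.6, I_m = 0.2) {
  v <- c(I_c = I_c, I_t = I_t, I_m = I_m)
  if (any(!is.finite(v)) || any(v < 0))
    abort("intensities must be finite and >= 0.")
  structure(list(I_c = I_c, I_t = I_t, I_m = I_m),
            class = "render_intensities")
}
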