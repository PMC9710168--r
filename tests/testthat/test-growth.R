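test_that("scene initialisation is deterministic, contained, and validated", {
  cfg <- sim_config(seed = 1)
  geom <- trench_geometry(length = 20)
  set.seed(1); f1 <- init_scene(cfg, geom)
  set.seed(1); f2 <- init_scene(cfg, geom)
  expect_identical(f1$cells, f2$cells)
  founder <- f1$cells
  expect_gte(founder$x, founder$width / 2)
  expect_lte(founder$x, cfg$division_mean)
  expect_gte(founder$length, founder$width)
  expect_error(init_scene(sim_config(width_mean = 2),
                          trench_geometry(width = 1)),
               "trench width")
})

test_that("exponential growth law: doubling, identity, zero rate", {
  set.seed(1)
  cells <- init_scene(sim_config(), trench_geometry())$cells
  cells$length <- 2
  grown <- grow_cells(cells, rate = log(2), dt = 1)
  expect_equal(grown$length, 4)
  expect_equal(grown$width, cells$width)

  same <- grow_cells(cells, rate = log(2), dt = 0)
  expect_equal(same$length, cells$length)
  expect_equal(same$age, cells$age)

  aged <- grow_cells(cells, rate = 0, dt = 5)
  expect_equal(aged$length, cells$length)
  expect_equal(aged$age, cells$age + 5)

  expect_error(grow_cells(cells, log(2), dt = -1), "dt")
})

make_cell <- function(length, birth_length = length / 2, width = 1,
                      threshold = 4, age = 0) {
  tibble::tibble(id = 1L, parent_id = NA_integer_, length = length,
                 width = width, x = length / 2, y = 0, angle = 0,
                 age = age, birth_length = birth_length,
                 div_threshold = threshold, bend_amplitude = 0)
}

test_that("division rules fire per regulation mode", {
  # sizer at its threshold splits into near-halves
  cfg <- sim_config(regulation = "sizer", division_mean = 4,
                    division_sd = 0, septum_gap = 0.1)
  set.seed(1)
  out <- divide_cells(make_cell(4.01, threshold = 4), cfg, next_id = 2L)
  expect_equal(nrow(out$cells), 2)
  expect_true(all(out$cells$length >= 1.9 & out$cells$length <= 2.1))
  expect_equal(out$cells$parent_id, c(1L, 1L))
  expect_equal(out$cells$age, c(0, 0))
  expect_equal(out$cells$birth_length, out$cells$length)
  expect_setequal(out$events$event, c("division", "birth"))

  # adder below its added-length threshold does not divide
  cfga <- sim_config(regulation = "adder")
  none <- divide_cells(make_cell(3.5, birth_length = 2, threshold = 2),
                       cfga, next_id = 2L)
  expect_equal(nrow(none$cells), 1)
  expect_equal(none$n_divisions, 0L)

  # timer fires on age
  cfgt <- sim_config(regulation = "timer")
  set.seed(1)
  timed <- divide_cells(make_cell(3, threshold = 30, age = 31), cfgt, 2L)
  expect_equal(nrow(timed$cells), 2)
})

test_that("collision solver separates bodies, respects walls and order", {
  geom <- trench_geometry(length = 20)
  fr <- make_test_frame(lengths = c(3, 3), widths = 1, xs = c(2, 4.5),
                        geometry = geom)  # overlap 0.5 um
  res <- resolve_collisions(fr)
  expect_lte(max_overlap(res$frame), 0.01)
  expect_equal(order(res$frame$cells$id), order(res$frame$cells$x))

  # body poking through the closed end is displaced inside
  fr2 <- make_test_frame(3, 1, xs = 0.5, geometry = geom)
  res2 <- resolve_collisions(fr2)
  expect_gte(res2$frame$cells$x - res2$frame$cells$length / 2, -0.01)

  # centroid past the open end is washed out and logged
  fr3 <- make_test_frame(c(3, 3), 1, xs = c(2, 20.5), geometry = geom)
  res3 <- resolve_collisions(fr3)
  expect_equal(nrow(res3$frame$cells), 1)
  expect_equal(res3$events$event, "washout")
})

test_that("stepping handles lysis limits and preserves counts", {
  set.seed(42)
  fr <- init_scene(sim_config(p_lyse = 1), trench_geometry())
  st <- step_scene(fr, sim_config(p_lyse = 1))
  expect_equal(nrow(st$frame$cells), 0)
  expect_true("lysis" %in% st$events$event)

  # no lysis, no divisions due: count is preserved (no washout at low fill)
  set.seed(42)
  fr2 <- init_scene(sim_config(), trench_geometry())
  st2 <- step_scene(fr2, sim_config())
  expect_equal(nrow(st2$frame$cells), 1)
})

test_that("simulations are reproducible and respect n_timepoints", {
  s1 <- quick_sim(50, seed = 7)
  s2 <- quick_sim(50, seed = 7)
  expect_identical(s1$events, s2$events)
  expect_identical(tidy(s1), tidy(s2))

  s0 <- quick_sim(0, seed = 7)
  expect_length(s0$frames, 1)
})

test_that("mother trace is a sawtooth: growth then near-halving drops", {
  sim <- quick_sim(200, seed = 3)
  tr <- mother_trace(sim)
  ratio <- tr$length[-1] / tr$length[-nrow(tr)]
  drops <- ratio < 0.9
  expect_gt(sum(drops), 5)                  # divisions happened
  expect_true(all(ratio[drops] > 0.4 & ratio[drops] < 0.6))
  expect_true(all(ratio[!drops] >= 1))      # otherwise growing
})

test_that("frame invariants hold over a long run", {
  sim <- quick_sim(300, seed = 11)
  for (fr in sim$frames) {
    expect_lte(max_overlap(fr), 0.01)
    if (nrow(fr$cells) > 0)
      expect_gte(min(fr$cells$x - fr$cells$length / 2), -0.01)
  }
  states <- tidy(sim)
  per_cell <- dplyr::summarise(
    dplyr::group_by(states, .data$id),
    width_const = dplyr::n_distinct(.data$width) == 1,
    nondecreasing = all(diff(.data$length) >= 0)
  )
  expect_true(all(per_cell$width_const))
  expect_true(all(per_cell$nondecreasing))
})

test_that("length mass audit closes", {
  sim <- quick_sim(250, seed = 5)
  aud <- sim_mass_audit(sim)
  expect_lt(abs(aud$residual),
            1e-8 * (aud$founder + aud$growth))
})

test_that("spherocylinder volume matches geometry", {
  # sphere limit is exact
  expect_equal(cell_volume(2, 1), 4 * pi / 3, tolerance = 1e-12)
  # numeric solid-of-revolution oracle across shapes
  set.seed(9)
  for (k in 1:20) {
    r <- runif(1, 0.2, 1.5)
    l <- runif(1, 2 * r, 8)
    expect_equal(cell_volume(l, r), spherocylinder_volume_numeric(l, r),
                 tolerance = 1e-8)
  }
  expect_error(cell_volume(0.9, 0.5), "2r")
})

test_that("division table supports size-regulation analysis", {
  sim <- quick_sim(400, seed = 2)
  dt <- division_table(sim)
  expect_gt(nrow(dt), 20)
  expect_true(all(dt$division_length > dt$birth_length))
  expect_true(all(dt$interdivision_time > 0))
})
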