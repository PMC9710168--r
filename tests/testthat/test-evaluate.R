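test_that("mask geometry measures rectangles, rotations and rendered cells", {
  lab <- matrix(0L, 60, 30); lab[10:49, 10:19] <- 1L
  g <- mask_geometry(lab)
  expect_equal(g$length, 40)
  expect_equal(g$width, 10)

  # rotation invariance: the same rectangle tilted by 37 degrees
  th <- 37 * pi / 180
  n <- 101
  idx <- as.matrix(expand.grid(i = 1:n, j = 1:n)) - (n + 1) / 2
  u <- cos(th) * idx[, 1] + sin(th) * idx[, 2]
  v <- -sin(th) * idx[, 1] + cos(th) * idx[, 2]
  rot <- matrix(0L, n, n)
  rot[idx + (n + 1) / 2] <- as.integer(abs(u) <= 19.5 & abs(v) <= 4.5)
  gr <- mask_geometry(rot)
  expect_equal(gr$length, 40, tolerance = 1 / 40)
  expect_equal(gr$width, 10, tolerance = 1 / 10)

  # render-measure round trip: l = 4 um, 2r = 1 um at 0.065 um/px
  fr <- make_test_frame(4, 1, 5)
  labs <- downsample_labels(render_opl(fr, pixel_size = 0.065)$labels, 3)
  gm <- mask_geometry(labs, pixel_size = 0.065)
  expect_lt(abs(gm$length - 4) / 0.065, 2)
  expect_lt(abs(gm$width - 1) / 0.065, 1)

  # degenerate single-pixel label is flagged
  tiny <- matrix(0L, 5, 5); tiny[3, 3] <- 1L
  expect_true(mask_geometry(tiny)$flagged)
})

test_that("mother traces match the simulator's own log", {
  sim <- quick_sim(30, seed = 19)
  ps <- 0.065 / 3
  stack <- lapply(sim$frames, function(fr) render_opl(fr)$labels)
  tr <- extract_mother_trace(stack, pixel_size = ps)
  logged <- mother_trace(sim)
  expect_equal(tr$t, logged$t)
  expect_true(all(abs(tr$length - logged$length) <= 2 * ps + 1e-9))

  static <- stack[[1]]
  const <- extract_mother_trace(list(static, static, static))
  expect_equal(length(unique(const$length)), 1)

  expect_equal(nrow(extract_mother_trace(list())), 0)
  gap <- extract_mother_trace(list(static, matrix(0L, 4, 4), static))
  expect_true(is.na(gap$length[2]))
})

test_that("identification error: clean traces score zero, dips score exactly", {
  lens <- trenchsim:::clean_trace_lengths(n_points = 400, seed = 3)
  expect_equal(as.numeric(identification_error(lens)), 0)

  set.seed(7)
  inj <- inject_trace_errors(lens, n_errors = 4)
  rate <- identification_error(inj$lengths)
  expect_equal(as.numeric(rate), 4 / 400)
  expect_equal(attr(rate, "flagged"), inj$positions)

  expect_equal(as.numeric(identification_error(rep(3, 50))), 0)
  expect_error(identification_error(c(1, 2)), "at least 3")
})

test_that("threshold optimisation matches a brute-force scan", {
  # binary truth as its own map: perfect at every threshold, lowest returned
  truth <- matrix(0L, 30, 20); truth[5:15, 5:15] <- 1L
  opt <- optimal_threshold(truth * 1, truth, intersection = FALSE)
  expect_equal(opt$optimal, 0.5)
  expect_true(all(opt$curve$jaccard == 1))

  # blurred truth: compare the argmax against an independent scan
  g <- outer(dnorm(-7:7, sd = 2.5), dnorm(-7:7, sd = 2.5))
  blurred <- convolve2d(truth * 1, g / sum(g))
  blurred <- blurred / max(blurred)
  opt2 <- optimal_threshold(blurred, truth, intersection = FALSE)
  grid <- seq(0.50, 0.995, by = 0.005)
  jac <- sapply(grid, function(th) {
    p <- blurred > th
    sum(p & truth > 0) / sum(p | truth > 0)
  })
  expect_equal(opt2$optimal, grid[which.max(jac)])
  expect_gte(opt2$optimal, 0.5)

  expect_error(optimal_threshold(matrix(0, 5, 5), truth), "foreground")
  expect_error(optimal_threshold(matrix(2, 5, 5), truth), "\\[0, 1\\]")

  # the distribution-intersection statistic agrees on a rendered scene
  fr <- make_test_frame(c(3, 2.5), 1, c(1.6, 5))
  labs <- downsample_labels(render_opl(fr)$labels, 3)
  bin <- matrix(as.integer(labs > 0), nrow(labs))
  blur2 <- convolve2d(bin * 1, g / sum(g)); blur2 <- blur2 / max(blur2)
  opt3 <- optimal_threshold(blur2, labs)
  expect_false(is.na(opt3$optimal_intersection))
  expect_lt(abs(opt3$optimal_intersection - opt3$optimal), 0.25)
  expect_s3_class(tidy(opt3), "tbl_df")
  expect_equal(glance(opt3)$optimal, opt3$optimal)
})

test_that("seeded watershed splits merged blobs along the ridge", {
  m <- trenchsim:::blob_probmap()
  # merged at the low threshold, two seeds at the high one
  expect_equal(max(trenchsim:::label_components(m > 0.5, 8)), 1)
  ws <- seeded_watershed(m, t_opt = 0.5, t_seed = 0.999)
  expect_equal(max(ws), 2)
  # the labelling partitions the foreground
  expect_true(all((ws > 0) == (m > 0.5)))

  far <- trenchsim:::blob_probmap(centers = rbind(c(10, 16), c(38, 16)),
                                  sigma = 3)
  ws2 <- seeded_watershed(far, t_opt = 0.5, t_seed = 0.999)
  expect_equal(max(ws2), 2)
  expect_equal(max(trenchsim:::label_components(far > 0.5, 8)), 2)

  expect_error(seeded_watershed(m, t_opt = 0.9995, t_seed = 0.999), "t_opt")
  expect_warning(empty <- seeded_watershed(m * 0.5, 0.4, 0.999), "seeds")
  expect_true(all(empty == 0))
})

test_that("precision estimator recovers known noise from quadratic traces", {
  t <- 1:100
  exact <- 5 + 0.01 * t - 1e-4 * t^2
  fit <- precision_from_stationary(list(exact))
  expect_lt(fit$precision, 1e-10)

  set.seed(15)
  noisy <- lapply(1:10, function(k) exact + rnorm(100, 0, 0.04))
  fit2 <- precision_from_stationary(noisy)
  expect_equal(fit2$precision, 0.04, tolerance = 0.1)
  expect_equal(glance(fit2)$n_segments, 10)

  # tibble interface and short-segment skipping
  df <- tibble::tibble(segment = rep(1:2, c(100, 3)),
                       t = c(1:100, 1:3),
                       length = c(noisy[[1]], 1:3))
  expect_warning(fit3 <- precision_from_stationary(df), "skipped")
  expect_equal(fit3$n_segments, 1)
  expect_error(suppressWarnings(
    precision_from_stationary(list(c(1, 2, 3)))), "usable")
})
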