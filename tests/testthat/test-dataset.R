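test_that("uniform jitter stays inside +/- 5% and fills the window", {
  spec <- jitter_spec(list(p = 100), half_width = 0.05)
  set.seed(1)
  d <- jitter_parameters(spec, 10000)
  expect_true(all(d$p >= 95 & d$p <= 105))
  expect_lt(min(d$p) - 95, 0.002 * 95)
  expect_lt(105 - max(d$p), 0.002 * 105)

  frozen <- jitter_parameters(jitter_spec(list(p = 100), half_width = 0), 10)
  expect_true(all(frozen$p == 100))

  set.seed(2)
  g <- jitter_parameters(jitter_spec(list(p = 100), half_width = 0.05,
                                     distribution = "gaussian"), 5000)
  expect_equal(sd(g$p), 5, tolerance = 0.1)
})

test_that("touching labels are separated by minimal erosion", {
  single <- matrix(0L, 10, 10); single[3:7, 3:7] <- 1L
  expect_identical(make_nontouching_masks(single),
                   matrix(as.integer(single > 0), 10))

  two <- matrix(0L, 12, 10)
  two[2:6, 3:8] <- 1L
  two[7:11, 3:8] <- 2L                      # share a row boundary
  sep <- make_nontouching_masks(two)
  comps <- trenchsim:::label_components(sep, 8)
  expect_equal(max(comps), 2)
  # separated by at least one background pixel in every 8-neighbourhood
  for (s in trenchsim:::neighbour_shifts8) {
    nb <- trenchsim:::shift_mat(comps, s[1], s[2])
    expect_false(any(comps > 0 & nb > 0 & comps != nb))
  }

  # component count is conserved across random simulated frames
  sim <- quick_sim(120, seed = 13)
  set.seed(13)
  for (fr in sample(sim$frames[50:121], 8)) {
    labs <- downsample_labels(render_opl(fr)$labels, 3)
    n_in <- length(unique(labs[labs > 0]))
    out <- make_nontouching_masks(labs)
    expect_equal(max(trenchsim:::label_components(out, 8)), n_in)
  }
})

test_that("weightmaps emphasise the gap between close components", {
  empty <- matrix(0L, 10, 10)
  expect_true(all(make_weightmap(empty) == 1))

  one <- matrix(0L, 10, 10); one[3:6, 3:6] <- 1L
  w1 <- make_weightmap(one)
  expect_true(all(w1 == 1))                 # border term absent

  # exhaustive oracle on a 20x20 fixture with a 1-px gap
  m <- matrix(0L, 20, 20)
  m[5:9, 6:14] <- 1L
  m[11:15, 6:14] <- 1L                       # row 10 separates them
  w <- make_weightmap(m, w0 = 10, sigma_w = 5)
  border <- w - 1
  border[m == 1] <- 0
  # direct evaluation of the formula at every background pixel
  cmp <- trenchsim:::label_components(m, 8)
  ref <- matrix(0, 20, 20)
  pix <- which(m == 0, arr.ind = TRUE)
  c1 <- which(cmp == 1, arr.ind = TRUE)
  c2 <- which(cmp == 2, arr.ind = TRUE)
  for (k in seq_len(nrow(pix))) {
    d1 <- min(sqrt((pix[k, 1] - c1[, 1])^2 + (pix[k, 2] - c1[, 2])^2))
    d2 <- min(sqrt((pix[k, 1] - c2[, 1])^2 + (pix[k, 2] - c2[, 2])^2))
    ref[pix[k, 1], pix[k, 2]] <- 10 * exp(-(d1 + d2)^2 / (2 * 25))
  }
  argmax_w <- which(border == max(border), arr.ind = TRUE)
  argmax_ref <- which(ref == max(ref), arr.ind = TRUE)
  expect_true(all(argmax_w[, "row"] == 10))  # peak on the separating row
  expect_true(all(argmax_ref[, "row"] == 10))
  # the distance-transform implementation tracks the exact formula closely
  expect_equal(max(abs(border - ref)), 0, tolerance = 0.6)

  # class balancing reweights foreground and background
  wb <- make_weightmap(one, class_balance = TRUE)
  expect_gt(mean(wb[one == 1]), mean(wb[one == 0]))
})

test_that("tiling concatenates trenches and keeps label ids unique", {
  mk <- function(id_offset) {
    img <- matrix(100L, 30, 10)
    lab <- matrix(0L, 30, 10)
    lab[5:10, 4:7] <- 1L
    lab[15:20, 4:7] <- 2L
    training_sample(img, lab)
  }
  samples <- lapply(1:40, mk)
  tiled <- tile_trenches(samples, 40)
  expect_equal(ncol(tiled$image), 40 * 10)
  ids <- unique(tiled$mask[tiled$mask > 0])
  expect_length(ids, 80)
  expect_false(any(duplicated(ids)))

  one <- tile_trenches(samples[1], 1)
  expect_identical(one$image, samples[[1]]$image)
  bad <- c(samples[1], list(training_sample(matrix(0L, 10, 5),
                                            matrix(0L, 10, 5))))
  expect_error(tile_trenches(bad, 2), "height")
  expect_error(tile_trenches(samples[1:3], 5), "enough")
})

test_that("dataset export: manifest determinism, dialects, round trip", {
  sim <- quick_sim(60, seed = 17)
  frames <- sim$frames[30:61]
  psf <- psf_config(mode = "fluorescence")
  d1 <- withr::local_tempdir()
  m1 <- generate_dataset(frames, 4, d1, dialect = "binary_weightmap",
                         intensities = fluor_intensities(), psf = psf,
                         seed = 99)
  d2 <- withr::local_tempdir()
  m2 <- generate_dataset(frames, 4, d2, dialect = "binary_weightmap",
                         intensities = fluor_intensities(), psf = psf,
                         seed = 99)
  expect_equal(nrow(m1), 4)
  expect_identical(dplyr::select(m1, -dplyr::ends_with("file")),
                   dplyr::select(m2, -dplyr::ends_with("file")))

  s <- read_training_sample(d1, 2)
  expect_identical(dim(s$image), dim(s$mask))
  expect_false(is.null(s$weightmap))
  # integer artefacts round-trip exactly
  expect_true(all(s$mask %in% c(0L, 1L)))
  wm <- make_weightmap(s$mask)
  expect_equal(s$weightmap, wm, tolerance = 1e-6)

  d3 <- withr::local_tempdir()
  m3 <- generate_dataset(frames, 3, d3, dialect = "instances_tiled",
                         intensities = fluor_intensities(), psf = psf,
                         tile = 3, seed = 5)
  expect_true(all(is.na(m3$weightmap_file)))
  s3 <- read_training_sample(d3, 1)
  expect_gt(max(s3$mask), 1)               # labelled instances
  expect_equal(ncol(s3$image), 3 * ncol(s$image))
})

test_that("masks depend on the physics only, never the imaging draw", {
  sim <- quick_sim(50, seed = 23)
  fr <- sim$frames[[40]]
  psf <- psf_config(mode = "fluorescence")
  cam <- camera_config()
  base <- trenchsim:::jitter_base_params(fluor_intensities(), psf, cam)
  spec <- jitter_spec(base, half_width = 0.05)
  set.seed(1); j1 <- jitter_parameters(spec, 1)
  set.seed(2); j2 <- jitter_parameters(spec, 1)
  r1 <- trenchsim:::render_one_sample(fr, j1, psf, cam, 0.065, 3)
  r2 <- trenchsim:::render_one_sample(fr, j2, psf, cam, 0.065, 3)
  expect_identical(r1$labels, r2$labels)
  expect_false(identical(r1$image, r2$image))
})

test_that("cell-count weighting equalises exported cells across regimes", {
  # two regimes: sparse frames (2 cells) and crowded frames (8 cells)
  sparse <- replicate(30, make_test_frame(c(3, 3), 1, c(2, 6)),
                      simplify = FALSE)
  crowded <- replicate(10, make_test_frame(rep(2, 8), 1,
                                           seq(1.2, by = 2.3,
                                               length.out = 8)),
                       simplify = FALSE)
  frames <- c(sparse, crowded)
  n_cells <- vapply(frames, function(f) nrow(f$cells), integer(1))
  wts <- 1 / n_cells
  set.seed(41)
  draws <- sample(seq_along(frames), 1000, replace = TRUE, prob = wts)
  cells_from_sparse <- sum(n_cells[draws[draws <= 30]])
  cells_from_crowded <- sum(n_cells[draws[draws > 30]])
  # expected contribution is proportional to the number of frames per regime
  expect_equal(cells_from_sparse / cells_from_crowded, 3, tolerance = 0.2)
})
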