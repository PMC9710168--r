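test_that("capture model: baseline, determinism, input validation", {
  cfg <- camera_config(photon_scale = 1, read_noise = 0, baseline = 100,
                       gain = 2, bit_depth = 16)
  z <- matrix(0, 10, 10)
  expect_true(all(apply_camera(z, cfg) == 100))

  set.seed(5); a <- apply_camera(matrix(50, 20, 20), cfg)
  set.seed(5); b <- apply_camera(matrix(50, 20, 20), cfg)
  expect_identical(a, b)
  expect_error(apply_camera(matrix(-1, 2, 2), cfg), "non-negative")
  # quantisation range respected
  sat <- apply_camera(matrix(1e6, 5, 5),
                      camera_config(photon_scale = 1, gain = 1,
                                    bit_depth = 8))
  expect_true(all(sat == 255))
})

test_that("photon-transfer curve recovers the gain; dark frames the read noise", {
  cfg <- camera_config(photon_scale = 1, read_noise = 2, baseline = 100,
                       gain = 2, bit_depth = 16)
  set.seed(11)
  levels <- c(50, 100, 200, 400, 800)
  stats_tbl <- t(sapply(levels, function(lv) {
    img <- apply_camera(matrix(lv, 320, 320), cfg)
    c(m = mean(img), v = var(as.vector(img)))
  }))
  slope <- coef(lm(stats_tbl[, "v"] ~ stats_tbl[, "m"]))[2]
  expect_equal(unname(slope), cfg$gain, tolerance = 0.1)

  # read noise from dark frames: SD in DN / gain
  dcfg <- camera_config(photon_scale = 1e-12, read_noise = 3,
                        baseline = 500, gain = 2, bit_depth = 16)
  set.seed(12)
  dark <- apply_camera(matrix(0, 500, 500), dcfg)
  expect_equal(sd(as.vector(dark)) / dcfg$gain, 3, tolerance = 0.05)
})

test_that("high flux converges to gain * image + baseline", {
  cfg <- camera_config(photon_scale = 1e6, read_noise = 0, baseline = 50,
                       gain = 0.01, bit_depth = 16)
  set.seed(3)
  out <- apply_camera(matrix(1, 100, 100), cfg)
  expect_equal(mean(out), 0.01 * 1e6 + 50, tolerance = 0.01)
})

test_that("histogram matching: identity, distribution equality, rank order", {
  set.seed(8)
  syn <- matrix(runif(50 * 40), 50, 40)
  ref <- matrix(rnorm(50 * 40, 100, 15), 50, 40)
  out <- match_histogram(syn, ref)
  expect_equal(sort(as.vector(out)), sort(as.vector(ref)))

  # matching an image to itself is the identity (values are all distinct)
  expect_equal(match_histogram(syn, syn), syn)

  # pairwise rank preservation on sampled pairs
  i <- sample(length(syn), 1000); j <- sample(length(syn), 1000)
  neq <- syn[i] != syn[j]
  expect_true(all((syn[i] < syn[j])[neq] == (out[i] < out[j])[neq]))

  # idempotence
  expect_equal(match_histogram(out, ref), out)
  expect_error(match_histogram(syn, matrix(1, 5, 5)), "constant")
})

test_that("Fourier spectrum matching aligns radial amplitudes", {
  set.seed(21)
  syn <- matrix(rnorm(64 * 64), 64, 64)
  expect_equal(match_fourier_spectrum(syn, syn), syn, tolerance = 1e-6)

  # 1/f-style reference: smooth field with decaying spectrum
  ref <- convolve2d(matrix(rnorm(64 * 64), 64, 64), {
    g <- outer(dnorm(-6:6, sd = 2), dnorm(-6:6, sd = 2)); g / sum(g)
  })
  out <- match_fourier_spectrum(syn, ref)
  expect_true(all(is.finite(out)))
  rs_out <- radial_spectrum(out)
  rs_ref <- radial_spectrum(ref)
  shared <- intersect(rs_out$bin, rs_ref$bin)
  a <- rs_out$amplitude[match(shared, rs_out$bin)]
  b <- rs_ref$amplitude[match(shared, rs_ref$bin)]
  expect_true(all(abs(a / b - 1) < 0.05))
  expect_error(match_fourier_spectrum(syn, matrix(0, 3, 3)), "dims")
})

test_that("region error report isolates per-region shifts", {
  set.seed(31)
  real <- matrix(runif(60 * 60, 10, 20), 60, 60)
  masks <- list(
    cells = outer(1:60, 1:60, function(i, j) i <= 20),
    device = outer(1:60, 1:60, function(i, j) i > 20 & i <= 40),
    media = outer(1:60, 1:60, function(i, j) i > 40)
  )
  same <- region_error_report(real, real, masks)
  expect_true(all(abs(same$rel_err_mean) < 1e-12))
  expect_true(all(abs(same$rel_err_var) < 1e-12))

  # constant shift in the cells region only
  syn <- real
  syn[masks$cells] <- syn[masks$cells] + 3
  rep2 <- region_error_report(syn, real, masks)
  cells_row <- rep2[rep2$region == "cells", ]
  expect_equal(cells_row$rel_err_mean, 3 / mean(real[masks$cells]),
               tolerance = 1e-10)
  expect_equal(cells_row$rel_err_var, 0, tolerance = 1e-10)
  expect_true(all(abs(rep2$rel_err_mean[rep2$region != "cells"]) < 1e-12))

  # overlap and empty-region handling
  bad <- masks; bad$device <- masks$cells
  expect_error(region_error_report(syn, real, bad), "disjoint")
  some <- masks; some$media <- matrix(FALSE, 60, 60)
  expect_warning(r3 <- region_error_report(syn, real, some), "empty")
  expect_true(r3$empty[r3$region == "media"])
})
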