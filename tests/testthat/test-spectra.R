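test_that("amplitude spectrum behaves like a centered DFT modulus", {
  L <- 32
  const <- matrix(0.7, L, L)
  a <- amplitude_spectrum(const)
  ctr <- floor(L / 2) + 1
  expect_equal(a[ctr, ctr], 0.7 * L^2)
  expect_equal(sum(a) - a[ctr, ctr], 0, tolerance = 1e-8)

  set.seed(3)
  img <- matrix(runif(L * L), L, L)
  a <- amplitude_spectrum(img)
  # Parseval: sum |F|^2 = L^2 * sum pixel^2
  expect_equal(sum(a^2), L^2 * sum(img^2), tolerance = 1e-8)

  # circular shift leaves the modulus unchanged
  shifted <- img[c(6:L, 1:5), c(10:L, 1:9)]
  expect_lt(max(abs(amplitude_spectrum(shifted) - a)), 1e-8)

  expect_error(amplitude_spectrum(matrix(0, 4, 6)), "square")
})

test_that("radial average recovers a rotationally symmetric profile", {
  L <- 128
  ctr <- floor(L / 2) + 1
  d <- sqrt(outer((1:L - ctr)^2, rep(1, L)) +
            outer(rep(1, L), (1:L - ctr)^2))
  sigma <- 12
  gauss <- exp(-d^2 / (2 * sigma^2))
  prof <- radial_average(gauss)
  keep <- prof$radial_freq_bins <= L / 2  # corners are sparsely sampled
  expected <- exp(-prof$radial_freq_bins[keep]^2 / (2 * sigma^2))
  err <- abs(prof$mean_amplitude_per_bin[keep] - expected)
  expect_lt(max(err / pmax(expected, 1e-6)), 0.02)

  one <- radial_average(gauss, n_bins = 1)
  expect_equal(length(one$mean_amplitude_per_bin), 1)
  expect_equal(one$mean_amplitude_per_bin, mean(gauss))
  expect_equal(length(radial_average(gauss, n_bins = 7)$mean_amplitude_per_bin), 7)
})

test_that("total power sums the profile with a DC policy", {
  zero <- matrix(0, 64, 64)
  expect_equal(image_total_power(zero), 0)

  set.seed(8)
  img <- matrix(runif(64 * 64), 64, 64)
  tp1 <- image_total_power(img, dc_included = FALSE)
  # scaling contrast about the mean scales DC-excluded amplitude linearly
  img3 <- mean(img) + 3 * (img - mean(img))
  expect_equal(image_total_power(img3, dc_included = FALSE), 3 * tp1,
               tolerance = 1e-9)
  # ... but not the DC-included sum: the unchanged-mean DC term does not
  # triple, so the DC-included total falls short of 3x
  expect_lt(image_total_power(img3, dc_included = TRUE),
            3 * image_total_power(img, dc_included = TRUE) - 1)

  # two disks carry more spectral energy than one
  disk_img <- function(centers) {
    L <- 256
    m <- matrix(1, L, L)
    for (c0 in centers) {
      d2 <- outer((1:L - c0[2])^2, rep(1, L)) +
        outer(rep(1, L), (1:L - c0[1])^2)
      m[d2 <= 20^2] <- 0
    }
    m
  }
  tp_one <- image_total_power(disk_img(list(c(128, 128))))
  tp_two <- image_total_power(disk_img(list(c(90, 90), c(170, 170))))
  expect_gt(tp_two, tp_one)
})

test_that("total-power index is a bounded antisymmetric contrast", {
  expect_equal(total_power_index(5, 5)$index, 0)
  expect_equal(total_power_index(3, 1)$index, 0.5)
  expect_equal(total_power_index(1, 3)$index, -total_power_index(3, 1)$index)
  expect_error(total_power_index(0, 0), "undefined")
  for (i in 1:20) {
    tp <- runif(2, 0, 10)
    expect_lte(abs(total_power_index(tp[1], tp[2])$index), 1)
  }
})

test_that("total power is translation-invariant for in-field dots", {
  arr <- dot_array(c(-12, -2, 8), c(-5, 9, -8), rep(3, 3))
  moved <- dot_array(arr$x + 4, arr$y - 3, arr$r)
  px <- 512 / 60
  tp0 <- image_total_power(render_image(arr, px, draw_outline = FALSE))
  tp1 <- image_total_power(render_image(moved, px, draw_outline = FALSE))
  expect_lt(abs(tp1 - tp0) / tp0, 0.01)
})

test_that("accuracy/spectrum correlation follows the Pearson t convention", {
  x <- c(0.6, 0.65, 0.7, 0.75, 0.8, 0.85)
  out <- accuracy_spectrum_correlation(x, 2 * x + 1)
  expect_equal(out$r, 1, tolerance = 1e-12)
  expect_equal(out$df, 4)   # six conditions give the r(4) convention

  set.seed(13)
  a <- runif(6); b <- runif(6)
  out2 <- accuracy_spectrum_correlation(a, b)
  expect_equal(out2$r, brute_force_pearson(a, b), tolerance = 1e-12)
  tstat <- out2$r * sqrt(4 / (1 - out2$r^2))
  expect_equal(out2$p, 2 * pt(-abs(tstat), 4), tolerance = 1e-12)

  expect_error(accuracy_spectrum_correlation(rep(0.5, 6), b), "constant")
  expect_error(accuracy_spectrum_correlation(a[1:2], b[1:2]), "at least 3")
})

test_that("power-index report covers the full option grid", {
  rep <- power_index_report(2, 3, n_pairs = 2, seed = 4, side_px = 128)
  expect_equal(nrow(rep), 6 * 2 * 2)
  expect_true(all(is.finite(rep$mean_index)))
  expect_true(all(abs(rep$mean_index) <= 1))
  expect_setequal(unique(rep$condition), names(all_conditions()))
})
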