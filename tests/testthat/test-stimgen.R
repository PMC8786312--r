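test_that("solve_geometry equates the prescribed magnitude in closed form", {
  # equal total area: r' = sqrt(sum(r^2)/n)
  expect_equal(solve_geometry(3, rep(4, 3), 6, "area"), rep(4 / sqrt(2), 6))
  # equal total perimeter: r' = sum(r)/n
  expect_equal(solve_geometry(3, rep(4, 3), 6, "perimeter"), rep(2, 6))
  # shared radius is the identity
  expect_equal(solve_geometry(3, rep(4, 3), 6, "radius_fixed"), rep(4, 6))

  expect_error(solve_geometry(3, c(3, 4, 5), 6, "radius_fixed"), "uniform")
  expect_error(solve_geometry(2, rep(2, 2), 9, "perimeter"), "infeasible")
})

test_that("place_dots respects containment, clearance and determinism", {
  a1 <- place_dots(1, 6, field_radius = 30, seed = 11)
  expect_lte(sqrt(a1$x^2 + a1$y^2), 24 + 1e-9)

  a9 <- place_dots(9, rep(1.5, 9), min_gap = 1, seed = 12)
  d <- as.matrix(dist(cbind(a9$x, a9$y)))
  expect_true(all(d[upper.tri(d)] >= 3 + 1 - 1e-9))

  b <- place_dots(9, rep(1.5, 9), min_gap = 1, seed = 12)
  expect_identical(a9, b)

  # 9 dots of radius 9 mm cannot fit a 30 mm field without overlap
  expect_error(place_dots(9, rep(9, 9), max_attempts = 200, restarts = 2,
                          seed = 1),
               "placement failure")
})

test_that("similarity scaling moves spatial metrics exactly as geometry says", {
  arr <- dot_array(c(-8, 8, 8, -8), c(-8, -8, 8, 8), rep(2, 4))
  m0 <- compute_magnitudes(arr)
  k <- 1.3
  scaled <- fishnum:::scale_about_centroid(arr, k)
  m1 <- compute_magnitudes(scaled)
  expect_equal(m1$mean_nn_dist, k * m0$mean_nn_dist, tolerance = 1e-9)
  # hull of disks is polygon + r-buffer, so only the polygon part scales as
  # k^2; compare against the Minkowski closed form instead
  expect_equal(m1$hull_area,
               minkowski_hull_area(scaled$x, scaled$y, scaled$r),
               tolerance = 1e-3)
})

test_that("adjust_spatial reaches identity and doubled targets", {
  arr <- place_dots(4, rep(2, 4), seed = 21)
  m <- compute_magnitudes(arr)

  same <- adjust_spatial(arr, "mean_nn_dist", m$mean_nn_dist, rel_tol = 0.05,
                         seed = 22)
  expect_lte(abs(mean_nn_dist(same) - m$mean_nn_dist) / m$mean_nn_dist, 0.05)

  # compact starting triangle so a doubled hull stays well inside the field
  arr3 <- dot_array(c(-5, 5, 0), c(-3, -3, 4), rep(2, 3))
  target <- 2 * disk_hull_area(arr3)
  adj <- adjust_spatial(arr3, "hull_area", target, rel_tol = 0.05, seed = 24)
  expect_lte(abs(disk_hull_area(adj) - target) / target, 0.05)
  expect_true(all(sqrt(adj$x^2 + adj$y^2) + adj$r <= adj$field_radius + 1e-9))

  # a hull far beyond what the field can hold must fail, not silently return
  expect_error(adjust_spatial(arr3, "hull_area", 1e6, max_iter = 30,
                              seed = 25),
               "adjustment failure")
})

test_that("generate_pair satisfies its constraint report on re-measurement", {
  p1 <- generate_pair(3, 6, "A-ID", seed = 31)
  m_s <- compute_magnitudes(p1$array_small)
  m_l <- compute_magnitudes(p1$array_large)
  expect_lt(abs(m_l$total_area - m_s$total_area) / m_s$total_area, 1e-9)
  expect_lte(abs(m_l$mean_nn_dist - m_s$mean_nn_dist) / m_s$mean_nn_dist, 0.05)

  p2 <- generate_pair(3, 6, "RF-CH", seed = 32)
  expect_equal(unique(p2$array_small$r), unique(p2$array_large$r))
  h_s <- disk_hull_area(p2$array_small)
  h_l <- disk_hull_area(p2$array_large)
  expect_lte(abs(h_l - h_s) / h_s, 0.05)

  expect_error(generate_pair(3, 3, "A-ID"), "numerosities must differ")
})

test_that("identical seeds give bit-identical stimulus pairs", {
  p1 <- generate_pair(2, 3, "P-ID", seed = 77)
  p2 <- generate_pair(2, 3, "P-ID", seed = 77)
  expect_identical(p1, p2)
})

test_that("uncontrolled magnitudes covary with numerosity in closed form", {
  for (seed in 1:5) {
    pa <- generate_pair(3, 6, "A-ID", seed = 100 + seed)
    ma <- lapply(list(pa$array_small, pa$array_large), compute_magnitudes)
    # fixed total area: total perimeter grows by sqrt(n_large/n_small)
    expect_equal(ma[[2]]$total_perimeter / ma[[1]]$total_perimeter, sqrt(2),
                 tolerance = 1e-9)

    pp <- generate_pair(3, 6, "P-CH", seed = 200 + seed)
    mp <- lapply(list(pp$array_small, pp$array_large), compute_magnitudes)
    # fixed total perimeter: total area shrinks by n_small/n_large
    expect_equal(mp[[2]]$total_area / mp[[1]]$total_area, 0.5,
                 tolerance = 1e-9)

    pr <- generate_pair(3, 6, "RF-ID", seed = 300 + seed)
    mr <- lapply(list(pr$array_small, pr$array_large), compute_magnitudes)
    # shared radius: area and perimeter both scale with the numerosity ratio
    expect_equal(mr[[2]]$total_area / mr[[1]]$total_area, 2, tolerance = 1e-9)
    expect_equal(mr[[2]]$total_perimeter / mr[[1]]$total_perimeter, 2,
                 tolerance = 1e-9)
  }
})

test_that("rendering matches analytic ink area and is deterministic", {
  arr <- place_dots(3, rep(3, 3), seed = 41)
  img <- render_image(arr, px_per_mm = 10, draw_outline = FALSE)
  expect_equal(dim(img), c(600, 600))
  ink <- sum(img == 0)
  expect_lt(abs(ink - 27 * pi * 100) / (27 * pi * 100), 0.02)

  expect_identical(img, render_image(arr, px_per_mm = 10, draw_outline = FALSE))

  with_ring <- render_image(arr, px_per_mm = 10, draw_outline = TRUE)
  expect_gt(sum(with_ring == 0), ink)
  expect_error(render_image(arr, px_per_mm = 0), "px_per_mm")
})

test_that("stimulus pairs round-trip to PNG plus JSON sidecar", {
  p <- generate_pair(2, 3, "A-CH", seed = 51)
  d <- withr::local_tempdir()
  paths <- write_stimulus_pair(p, d, px_per_mm = 4)
  expect_true(all(file.exists(unlist(paths))))
  side <- jsonlite::read_json(paths$sidecar, simplifyVector = TRUE)
  expect_equal(side$condition, "A-CH")
  expect_equal(side$array_small$r, p$array_small$r, tolerance = 1e-12)
})

test_that("visual angle follows the closed form and is monotone", {
  # oracle: 2*atan(extent/(2*d))*180/pi evaluated directly
  expect_equal(visual_angle(12, 400), 2 * atan(12 / 800) * 180 / pi)
  expect_equal(round(visual_angle(12, 400), 2), 1.72)
  expect_equal(round(visual_angle(3, 400), 2), 0.43)
  expect_lt(visual_angle(1e-4, 400), 1e-4)
  expect_true(all(diff(visual_angle(1:20, 400)) > 0))
})
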