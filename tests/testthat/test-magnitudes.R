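test_that("area, perimeter and mean radius are exact closed forms", {
  arr <- place_dots(3, rep(3, 3), seed = 1)
  m <- compute_magnitudes(arr)
  expect_equal(m$total_area, 27 * pi)
  expect_equal(m$total_perimeter, 18 * pi)
  expect_equal(m$mean_radius, 3)
  expect_equal(m$density * m$sparsity, 1)
})

test_that("disk hull degenerates correctly for one and two dots", {
  one <- dot_array(0, 0, 1)
  expect_equal(compute_magnitudes(one)$hull_area, pi, tolerance = 1e-4)
  expect_true(is.na(compute_magnitudes(one)$mean_nn_dist))
  expect_error(mean_nn_dist(one), "undefined")

  two <- dot_array(c(-5, 5), c(0, 0), c(1, 1))
  m2 <- compute_magnitudes(two)
  expect_equal(m2$mean_nn_dist, 10)
  # stadium: 2*d*r + pi*r^2
  expect_equal(m2$hull_area, 2 * 10 * 1 + pi, tolerance = 1e-3)
  expect_equal(m2$hull_area, minkowski_hull_area(two$x, two$y, two$r),
               tolerance = 1e-4)
})

test_that("hull area agrees with Minkowski closed form and Monte Carlo", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    arr <- place_dots(n, rep(runif(1, 1.5, 4), n), seed = 500 + i)
    geo <- disk_hull_area(arr)
    expect_equal(geo, minkowski_hull_area(arr$x, arr$y, arr$r),
                 tolerance = 1e-4)
    # MC over the polygonized hull checks the shoelace evaluation
    th <- seq(0, 2 * pi, length.out = 257)[-257]
    px <- as.vector(outer(cos(th), arr$r) + rep(arr$x, each = 256))
    py <- as.vector(outer(sin(th), arr$r) + rep(arr$y, each = 256))
    h <- chull(px, py)
    mc <- mc_polygon_area(px[h], py[h], n_samples = 2e5)
    expect_lt(abs(mc - geo) / geo, 0.01)
  }
})

test_that("magnitudes are scale-equivariant", {
  arr <- place_dots(5, rep(2, 5), seed = 7)
  k <- 1.7
  scaled <- dot_array(k * arr$x, k * arr$y, k * arr$r,
                      field_radius = k * arr$field_radius)
  m0 <- compute_magnitudes(arr)
  m1 <- compute_magnitudes(scaled)
  expect_equal(m1$total_area, k^2 * m0$total_area)
  expect_equal(m1$total_perimeter, k * m0$total_perimeter)
  expect_equal(m1$hull_area, k^2 * m0$hull_area, tolerance = 1e-9)
  expect_equal(m1$mean_nn_dist, k * m0$mean_nn_dist)
})

test_that("congruency coding reproduces the six-condition lookup", {
  levels <- vapply(names(all_conditions()), function(cc)
    congruency_level(cc)$level, integer(1))
  expect_equal(sort(unname(levels)), c(1L, 1L, 2L, 2L, 3L, 3L))

  for (cc in names(all_conditions())) {
    code <- congruency_level(cc)
    # the level counts the congruent variables
    expect_equal(code$level, sum(code$per_variable == "C"))
    # exactly the two controlled variables are equated
    cond <- all_conditions()[[cc]]
    ctrl_geom <- switch(cond$geometry, area = "overall_area",
                        perimeter = "overall_perimeter", radius_fixed = NULL)
    ctrl_spat <- switch(cond$spatial, convex_hull = "convex_hull",
                        inter_distance = "inter_distance")
    expect_true(all(code$per_variable[c(ctrl_geom, ctrl_spat)] == "EQ"))
  }

  pch <- congruency_level("P-CH")
  expect_equal(pch$level, 1L)
  expect_equal(unname(pch$per_variable["overall_area"]), "IC")
  expect_equal(unname(pch$per_variable["inter_distance"]), "C")
  aid <- congruency_level("A-ID")
  expect_equal(aid$level, 2L)
  expect_equal(unname(aid$per_variable["overall_perimeter"]), "C")
  expect_equal(unname(aid$per_variable["convex_hull"]), "C")
  expect_equal(congruency_level("RF-ID")$level, 3L)
})

test_that("empirical congruency directions match the analytic coding", {
  # fixed total area forces perimeter congruent; fixed perimeter forces area
  # incongruent; a pair compared with itself is EQ throughout
  pa <- generate_pair(3, 6, "A-CH", seed = 61)
  expect_equal(congruency_direction(pa, "overall_perimeter"), "C")
  expect_equal(congruency_direction(pa, "overall_area"), "EQ")

  pp <- generate_pair(3, 6, "P-CH", seed = 62)
  expect_equal(congruency_direction(pp, "overall_area"), "IC")

  self_pair <- pa
  self_pair$array_large <- pa$array_small
  for (v in c("overall_area", "overall_perimeter", "convex_hull",
              "inter_distance"))
    expect_equal(congruency_direction(self_pair, v), "EQ")
})

test_that("magnitude report emits one row per array with shared pair ids", {
  pairs <- list(generate_pair(2, 3, "RF-ID", seed = 71),
                generate_pair(3, 6, "A-CH", seed = 72))
  rep <- magnitude_report(pairs)
  expect_equal(nrow(rep), 4)
  expect_equal(rep$pair_id, c(1, 1, 2, 2))
  expect_equal(rep$congruency_level, c(3, 3, 2, 2))
  f <- withr::local_tempfile(fileext = ".csv")
  magnitude_report(pairs, file = f)
  expect_equal(nrow(read.csv(f)), 4)
})
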