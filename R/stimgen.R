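#' Dot array stimuli
#'
#' A dot array is a set of filled circular dots (centers and radii, in mm)
#' confined to a circular field. Coordinates are continuous millimetres with
#' the origin at the field center and y pointing up. The default field radius
#' of 30 mm corresponds to a 6 cm outline circle.
#'
#' @param x,y dot center coordinates (mm).
#' @param r dot radii (mm), all positive.
#' @param field_radius field circle radius (mm).
#' @param min_gap minimum edge-to-edge clearance between dots (mm) enforced at
#'   validation; `0` only forbids interpenetration.
#' @return An object of class `dot_array`: list with `x`, `y`, `r`,
#'   `field_radius`; the numerosity is `length(x)`.
#' @examples
#' a <- dot_array(c(-10, 10), c(0, 0), c(3, 3))
#' numerosity(a)
#' @export
dot_array <- function(x, y, r, field_radius = 30, min_gap = 0) {
  stopifnot(length(x) == length(y), length(x) == length(r), length(x) >= 1)
  if (any(r <= 0)) stop("all dot radii must be positive")
  if (field_radius <= 0) stop("field_radius must be positive")
  arr <- structure(list(x = as.numeric(x), y = as.numeric(y),
                        r = as.numeric(r), field_radius = field_radius),
                   class = "dot_array")
  bad <- which(sqrt(arr$x^2 + arr$y^2) + arr$r > field_radius + 1e-9)
  if (length(bad))
    stop("dot(s) ", paste(bad, collapse = ", "), " not contained in the field")
  ov <- overlapping_pairs(arr, min_gap)
  if (nrow(ov))
    stop("overlapping dots (min_gap = ", min_gap, "): pair ",
         ov$i[1], "-", ov$j[1])
  arr
}

#' @rdname dot_array
#' @param array a `dot_array`.
#' @export
numerosity <- function(array) length(array$x)

#' @export
print.dot_array <- function(x, ...) {
  cat(sprintf("<dot_array> %d dots, radii %.3g-%.3g mm, field radius %g mm\n",
              numerosity(x), min(x$r), max(x$r), x$field_radius))
  invisible(x)
}

# all pairs whose disks come closer than min_gap edge-to-edge
overlapping_pairs <- function(array, min_gap = 0) {
  n <- numerosity(array)
  if (n < 2) return(data.frame(i = integer(), j = integer()))
  idx <- utils::combn(n, 2)
  d <- sqrt((array$x[idx[1, ]] - array$x[idx[2, ]])^2 +
            (array$y[idx[1, ]] - array$y[idx[2, ]])^2)
  need <- array$r[idx[1, ]] + array$r[idx[2, ]] + min_gap
  hit <- which(d < need - 1e-9)
  data.frame(i = idx[1, hit], j = idx[2, hit])
}

#' Solve dot radii under a geometry control
#'
#' Given a reference array's radii, returns the (uniform) radii of an array of
#' different numerosity so that the prescribed geometric magnitude is equated
#' exactly: shared radius (`radius_fixed`), total disk area (`area`, closed
#' form r' = sqrt(sum(r^2)/n)), or total circumference (`perimeter`, closed
#' form r' = sum(r)/n).
#'
#' @param n_ref reference numerosity (>= 1).
#' @param radii_ref reference radii (mm), length `n_ref`.
#' @param n_other numerosity of the array to solve for.
#' @param mode geometry tag: `"radius_fixed"`, `"area"` or `"perimeter"`.
#' @param permitted_radius allowed radius range (mm); a solution outside it is
#'   an infeasible condition and raises an error.
#' @return Numeric vector of `n_other` radii (mm), all equal.
#' @examples
#' solve_geometry(3, rep(4, 3), 6, "area")       # 4 / sqrt(2)
#' solve_geometry(3, rep(4, 3), 6, "perimeter")  # 2
#' @export
solve_geometry <- function(n_ref, radii_ref, n_other,
                           mode = c("radius_fixed", "area", "perimeter"),
                           permitted_radius = c(1.5, 6)) {
  mode <- match.arg(mode)
  stopifnot(n_ref >= 1, n_other >= 1, length(radii_ref) == n_ref)
  if (any(radii_ref <= 0)) stop("reference radii must be positive")
  r_new <- switch(mode,
    radius_fixed = {
      if (diff(range(radii_ref)) > 1e-9)
        stop("radius_fixed requires a uniform reference radius")
      radii_ref[1]
    },
    area = sqrt(sum(radii_ref^2) / n_other),
    perimeter = sum(radii_ref) / n_other)
  if (r_new < permitted_radius[1] - 1e-12 || r_new > permitted_radius[2] + 1e-12)
    stop(sprintf(
      "infeasible condition: solved radius %.3f mm outside permitted [%g, %g]",
      r_new, permitted_radius[1], permitted_radius[2]))
  rep(r_new, n_other)
}

#' Place dots uniformly at random without overlap
#'
#' Uniform rejection sampling of dot centers inside the field, subject to
#' containment and a minimum edge-to-edge gap. On exceeding `max_attempts`
#' for a single dot the whole configuration is resampled, up to `restarts`
#' times.
#'
#' @param n number of dots; must equal `length(radii)`.
#' @param radii dot radii (mm).
#' @param field_radius field circle radius (mm).
#' @param min_gap minimum clearance between dot edges (mm).
#' @param max_attempts per-configuration rejection budget.
#' @param restarts full-resample budget.
#' @param seed optional integer seed for reproducible placement.
#' @return A `dot_array`.
#' @export
place_dots <- function(n, radii, field_radius = 30, min_gap = 1,
                       max_attempts = 10000, restarts = 50, seed = NULL) {
  stopifnot(n >= 1, length(radii) == n)
  if (any(field_radius - radii <= 0))
    stop("placement failure: dot radius exceeds field radius (containment)")
  with_seed_if(seed, {
    for (restart in seq_len(restarts + 1)) {
      x <- y <- numeric(0)
      ok <- TRUE
      attempts <- 0L
      for (i in seq_len(n)) {
        placed <- FALSE
        while (attempts < max_attempts) {
          attempts <- attempts + 1L
          rad <- (field_radius - radii[i]) * sqrt(stats::runif(1))
          th <- stats::runif(1, 0, 2 * pi)
          cx <- rad * cos(th); cy <- rad * sin(th)
          if (i == 1 || all(sqrt((x - cx)^2 + (y - cy)^2) >=
                            radii[seq_len(i - 1)] + radii[i] + min_gap)) {
            x <- c(x, cx); y <- c(y, cy)
            placed <- TRUE
            break
          }
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok)
        return(dot_array(x, y, radii, field_radius, min_gap = min_gap))
    }
    stop("placement failure: non-overlap constraint unsatisfied after ",
         restarts, " restarts (request too dense)")
  })
}

# rigid translate so the center-of-mass sits at the field center
recenter_array <- function(array) {
  array$x <- array$x - mean(array$x)
  array$y <- array$y - mean(array$y)
  array
}

# largest similarity scale about the centroid that keeps every dot in the field
max_scale_in_field <- function(array) {
  cx <- mean(array$x); cy <- mean(array$y)
  d <- sqrt((array$x - cx)^2 + (array$y - cy)^2)
  slack <- array$field_radius - array$r - sqrt(cx^2 + cy^2)
  ratio <- ifelse(d > 1e-12, slack / d, Inf)
  max(min(ratio), 0)
}

scale_about_centroid <- function(array, k) {
  cx <- mean(array$x); cy <- mean(array$y)
  array$x <- cx + k * (array$x - cx)
  array$y <- cy + k * (array$y - cy)
  array
}

# resolve overlaps by rotating offending dots about the centroid (preserves
# each dot's distance from the centroid, so spatial metrics move little);
# returns NULL when it cannot
repair_overlaps <- function(array, min_gap, sweeps = 60, tries = 30) {
  for (s in seq_len(sweeps)) {
    ov <- overlapping_pairs(array, min_gap)
    if (!nrow(ov)) return(array)
    j <- ov$j[1]
    cx <- mean(array$x); cy <- mean(array$y)
    rad <- sqrt((array$x[j] - cx)^2 + (array$y[j] - cy)^2)
    done <- FALSE
    for (t in seq_len(tries)) {
      th <- stats::runif(1, 0, 2 * pi)
      cand <- array
      cand$x[j] <- cx + rad * cos(th)
      cand$y[j] <- cy + rad * sin(th)
      if (sqrt(cand$x[j]^2 + cand$y[j]^2) + cand$r[j] > cand$field_radius)
        next
      if (!nrow(overlapping_pairs(cand, min_gap))) {
        array <- cand; done <- TRUE; break
      }
    }
    if (!done) return(NULL)
  }
  NULL
}

#' Adjust a spatial magnitude by similarity scaling
#'
#' Iteratively rescales the dot centers about their centroid until the chosen
#' spatial metric (convex-hull area of the dot outlines, or mean
#' nearest-neighbor center distance) is within `rel_tol` of `target`. Scaling
#' by a factor k changes `mean_nn_dist` by k and `hull_area` by ~k^2, so the
#' exact similarity update is used, interleaved with containment capping and
#' overlap repair by rotating dots about the centroid.
#'
#' @param array a `dot_array` with numerosity >= 2 and uniform handling of all
#'   radii (radii are never changed).
#' @param metric `"hull_area"` or `"mean_nn_dist"`.
#' @param target desired metric value (mm^2 or mm), positive.
#' @param rel_tol relative tolerance on the achieved metric.
#' @param max_iter iteration budget before an adjustment-failure error.
#' @param min_gap minimum clearance between dot edges (mm).
#' @param seed optional integer seed.
#' @return The adjusted `dot_array`.
#' @export
adjust_spatial <- function(array, metric = c("hull_area", "mean_nn_dist"),
                           target, rel_tol = 0.05, max_iter = 200,
                           min_gap = 1, seed = NULL) {
  metric <- match.arg(metric)
  if (numerosity(array) < 2) stop("spatial adjustment needs numerosity >= 2")
  if (target <= 0) stop("target must be positive")
  measure <- function(a)
    if (metric == "hull_area") disk_hull_area(a) else mean_nn_dist(a)
  with_seed_if(seed, {
    arr <- recenter_array(array)
    rep_arr <- repair_overlaps(arr, min_gap)
    if (!is.null(rep_arr)) arr <- rep_arr
    for (iter in seq_len(max_iter)) {
      cur <- measure(arr)
      if (abs(cur - target) / target <= rel_tol) {
        arr$x <- arr$x  # no-op; keep structure
        return(dot_array(arr$x, arr$y, arr$r, arr$field_radius,
                         min_gap = min_gap))
      }
      k <- if (metric == "mean_nn_dist") target / cur else sqrt(target / cur)
      k <- min(max(k, 0.5), 2)               # damp extreme steps
      k <- min(k, max_scale_in_field(arr))   # containment cap
      if (k <= 0) break
      cand <- scale_about_centroid(arr, k)
      cand <- repair_overlaps(cand, min_gap)
      if (is.null(cand)) {
        # scaling this far packs the dots too tightly; back off
        cand <- repair_overlaps(scale_about_centroid(arr, sqrt(k)), min_gap)
        if (is.null(cand)) break
      }
      arr <- cand
    }
    stop(sprintf(
      "adjustment failure: %s target %.4g not reached within rel_tol %.3g",
      metric, target, rel_tol))
  })
}

#' Generate a numerosity stimulus pair under a control condition
#'
#' Builds two dot arrays of different numerosity whose controlled magnitudes
#' are equated: the geometry constraint (shared radius / total area / total
#' perimeter) is solved analytically and holds exactly; the spatial constraint
#' (convex-hull area or mean nearest-neighbor distance) is equated to within
#' `rel_tol` by similarity adjustment of both arrays toward the geometric mean
#' of their initial metric values. Uncontrolled magnitudes are left free to
#' covary with numerosity.
#'
#' @param n_small,n_large the two numerosities, `1 <= n_small < n_large`.
#' @param condition a `control_condition` (or short code such as `"A-ID"`).
#' @param params generation parameters from [pair_params()].
#' @param seed optional integer seed; the full pair is reproducible from it.
#' @return An object of class `stimulus_pair`: list with `array_small`,
#'   `array_large`, `condition`, `tolerances`, `seed` and `constraint_report`
#'   (achieved relative deviation per controlled magnitude).
#' @examples
#' p <- generate_pair(3, 6, "A-ID", seed = 1)
#' p$constraint_report
#' @export
generate_pair <- function(n_small, n_large, condition, params = pair_params(),
                          seed = NULL) {
  if (is.character(condition)) condition <- condition_from_code(condition)
  stopifnot(inherits(condition, "control_condition"))
  if (!(n_small >= 1 && n_small < n_large))
    stop("numerosities must differ: need 1 <= n_small < n_large")
  with_seed_if(seed, {
    last_err <- NULL
    for (retry in seq_len(params$max_retries)) {
      res <- tryCatch(
        generate_pair_once(n_small, n_large, condition, params),
        error = function(e) e)
      if (!inherits(res, "error")) {
        res$seed <- seed
        return(res)
      }
      last_err <- res
    }
    stop("pair generation failed after ", params$max_retries, " retries: ",
         conditionMessage(last_err))
  })
}

generate_pair_once <- function(n_small, n_large, condition, params) {
  r0 <- stats::runif(1, params$radius_range[1], params$radius_range[2])
  radii_small <- rep(r0, n_small)
  radii_large <- solve_geometry(n_small, radii_small, n_large,
                                condition$geometry, params$permitted_radius)
  a_small <- place_dots(n_small, radii_small, params$field_radius,
                        params$min_gap, params$max_attempts, params$restarts)
  a_large <- place_dots(n_large, radii_large, params$field_radius,
                        params$min_gap, params$max_attempts, params$restarts)
  metric <- if (condition$spatial == "convex_hull") "hull_area" else "mean_nn_dist"
  measure <- function(a)
    if (metric == "hull_area") disk_hull_area(a) else mean_nn_dist(a)
  target <- sqrt(measure(a_small) * measure(a_large))
  a_small <- adjust_spatial(a_small, metric, target, params$rel_tol / 2,
                            min_gap = params$min_gap)
  a_large <- adjust_spatial(a_large, metric, target, params$rel_tol / 2,
                            min_gap = params$min_gap)
  m_s <- compute_magnitudes(a_small)
  m_l <- compute_magnitudes(a_large)
  geom_dev <- switch(condition$geometry,
    radius_fixed = abs(m_l$mean_radius - m_s$mean_radius) / m_s$mean_radius,
    area = abs(m_l$total_area - m_s$total_area) / m_s$total_area,
    perimeter = abs(m_l$total_perimeter - m_s$total_perimeter) / m_s$total_perimeter)
  spat_dev <- if (metric == "hull_area")
    abs(m_l$hull_area - m_s$hull_area) / m_s$hull_area
  else
    abs(m_l$mean_nn_dist - m_s$mean_nn_dist) / m_s$mean_nn_dist
  if (spat_dev > params$rel_tol)
    stop("spatial constraint missed after adjustment")
  report <- c(geometry = geom_dev, spatial = spat_dev)
  names(report) <- c(condition$geometry, condition$spatial)
  structure(list(array_small = a_small, array_large = a_large,
                 condition = condition,
                 tolerances = c(geometry = 0, spatial = params$rel_tol),
                 seed = NULL, constraint_report = report),
            class = "stimulus_pair")
}

#' @export
print.stimulus_pair <- function(x, ...) {
  cat(sprintf("<stimulus_pair> %d vs %d dots, condition %s\n",
              numerosity(x$array_small), numerosity(x$array_large),
              x$condition$code))
  cat("  constraint deviations:",
      paste(sprintf("%s = %.2e", names(x$constraint_report),
                    x$constraint_report), collapse = ", "), "\n")
  invisible(x)
}

#' Stimulus-pair generation parameters
#'
#' Defaults: 30 mm field (6 cm outline circle); base radii drawn uniformly
#' from 3-4 mm so that every geometry solution for comparisons up to 9 dots
#' stays inside the permitted 1.5-6 mm radius band (dot diameters 3-12 mm);
#' 1 mm minimum gap; 5% relative tolerance on the spatial constraint.
#'
#' @param field_radius field circle radius (mm).
#' @param radius_range sampling range for the base (reference) radius (mm).
#' @param permitted_radius feasible radius band for solved radii (mm).
#' @param min_gap minimum edge-to-edge dot clearance (mm).
#' @param rel_tol relative tolerance for spatially controlled magnitudes.
#' @param max_attempts,restarts placement budgets (see [place_dots()]).
#' @param max_retries full pair-generation retries.
#' @return A named list of parameters.
#' @export
pair_params <- function(field_radius = 30, radius_range = c(3, 4),
                        permitted_radius = c(1.5, 6), min_gap = 1,
                        rel_tol = 0.05, max_attempts = 10000, restarts = 50,
                        max_retries = 20) {
  list(field_radius = field_radius, radius_range = radius_range,
       permitted_radius = permitted_radius, min_gap = min_gap,
       rel_tol = rel_tol, max_attempts = max_attempts, restarts = restarts,
       max_retries = max_retries)
}

#' Render a dot array to a grayscale raster
#'
#' White background, black filled disks, optional black outline ring at the
#' field border. Pixels are sampled at their centers with no anti-aliasing, so
#' the black pixel count tracks the analytic ink area closely and renders are
#' bit-reproducible.
#'
#' @param array a `dot_array`.
#' @param px_per_mm raster resolution (pixels per mm), positive.
#' @param draw_outline draw the field outline ring.
#' @param outline_width ring thickness (mm).
#' @return Numeric matrix in `[0, 1]` (0 = black, 1 = white), square with side
#'   `ceiling(2 * field_radius * px_per_mm)`; row 1 is the top of the image.
#' @export
render_image <- function(array, px_per_mm = 10, draw_outline = TRUE,
                         outline_width = 0.5) {
  if (px_per_mm <= 0) stop("px_per_mm must be positive")
  R <- array$field_radius
  side <- ceiling(2 * R * px_per_mm)
  xs <- ((seq_len(side)) - 0.5) / px_per_mm - R
  ys <- rev(xs)
  X <- matrix(xs, side, side, byrow = TRUE)
  Y <- matrix(ys, side, side)
  img <- matrix(1, side, side)
  if (draw_outline) {
    d <- sqrt(X^2 + Y^2)
    img[d <= R & d >= R - outline_width] <- 0
  }
  for (i in seq_along(array$x)) {
    img[(X - array$x[i])^2 + (Y - array$y[i])^2 <= array$r[i]^2] <- 0
  }
  img
}

#' Write a stimulus pair to PNG images plus a JSON sidecar
#'
#' @param pair a `stimulus_pair`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param px_per_mm raster resolution.
#' @param draw_outline draw the field outline ring.
#' @return Invisibly, the paths written (`small`, `large`, `sidecar`).
#' @export
write_stimulus_pair <- function(pair, dir, prefix = "pair", px_per_mm = 10,
                                draw_outline = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    small = file.path(dir, paste0(prefix, "_small.png")),
    large = file.path(dir, paste0(prefix, "_large.png")),
    sidecar = file.path(dir, paste0(prefix, ".json")))
  png::writePNG(render_image(pair$array_small, px_per_mm, draw_outline),
                paths$small)
  png::writePNG(render_image(pair$array_large, px_per_mm, draw_outline),
                paths$large)
  side <- list(
    condition = pair$condition$code,
    seed = pair$seed,
    tolerances = as.list(pair$tolerances),
    constraint_report = as.list(pair$constraint_report),
    array_small = pair$array_small[c("x", "y", "r", "field_radius")],
    array_large = pair$array_large[c("x", "y", "r", "field_radius")])
  jsonlite::write_json(side, paths$sidecar, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Visual angle subtended by an extent
#'
#' @param extent linear extent (mm).
#' @param viewing_distance distance from eye to plane (mm).
#' @return Angle in degrees: `2 * atan(extent / (2 * viewing_distance))`.
#' @examples
#' visual_angle(12, 400)  # about 1.72 degrees
#' @export
visual_angle <- function(extent, viewing_distance) {
  stopifnot(all(extent > 0), all(viewing_distance > 0))
  2 * atan(extent / (2 * viewing_distance)) * 180 / pi
}
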