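#' Non-numerical magnitudes of a dot array
#'
#' Computes the continuous physical magnitudes that covary with numerosity in
#' dot-array stimuli. Total area and total perimeter are exact closed forms
#' over the disks; the convex hull is taken over the dot *outlines* (the union
#' of the disks, so it is well defined even for two dots); inter-distance is
#' the mean over dots of the nearest-neighbor center distance; density and
#' sparsity are numerosity relative to hull area.
#'
#' @param array a `dot_array`.
#' @return An object of class `magnitude_vector`: list with `numerosity`,
#'   `total_area` (mm^2), `total_perimeter` (mm), `mean_radius` (mm),
#'   `hull_area` (mm^2), `mean_nn_dist` (mm, `NA` for a single dot),
#'   `density` (dots/mm^2) and `sparsity` (mm^2/dot).
#' @examples
#' a <- dot_array(c(-10, 10), c(0, 0), c(3, 3))
#' compute_magnitudes(a)
#' @export
compute_magnitudes <- function(array) {
  stopifnot(inherits(array, "dot_array"))
  n <- numerosity(array)
  hull <- disk_hull_area(array)
  structure(list(
    numerosity = n,
    total_area = sum(pi * array$r^2),
    total_perimeter = sum(2 * pi * array$r),
    mean_radius = mean(array$r),
    hull_area = hull,
    mean_nn_dist = if (n >= 2) mean_nn_dist(array) else NA_real_,
    density = n / hull,
    sparsity = hull / n), class = "magnitude_vector")
}

#' @export
print.magnitude_vector <- function(x, ...) {
  cat("<magnitude_vector>\n")
  for (f in names(x))
    cat(sprintf("  %-15s %.4g\n", f, x[[f]]))
  invisible(x)
}

#' @export
as.data.frame.magnitude_vector <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}

#' Convex-hull area of the dot outlines
#'
#' Area of the convex hull of the union of disks, computed by polygonizing
#' each circle (default 512 vertices), taking the planar convex hull of all
#' vertices and applying the shoelace formula. The polygon approximation
#' under-estimates circular arcs by a relative error below 1e-4 at the default
#' resolution. For a single dot this is the disk area.
#'
#' @param array a `dot_array`.
#' @param n_vertices polygon vertices per circle.
#' @return Hull area (mm^2).
#' @export
disk_hull_area <- function(array, n_vertices = 512) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  px <- as.vector(outer(cos(th), array$r) +
                  rep(array$x, each = n_vertices))
  py <- as.vector(outer(sin(th), array$r) +
                  rep(array$y, each = n_vertices))
  h <- grDevices::chull(px, py)
  polygon_area(px[h], py[h])
}

# shoelace; vertices in hull order
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Mean nearest-neighbor center distance
#'
#' @param array a `dot_array` with numerosity >= 2.
#' @return Mean over dots of the distance to the nearest other dot center (mm).
#' @export
mean_nn_dist <- function(array) {
  n <- numerosity(array)
  if (n < 2) stop("inter-distance is undefined for a single dot")
  d <- as.matrix(stats::dist(cbind(array$x, array$y)))
  diag(d) <- Inf
  mean(apply(d, 1, min))
}

# Congruency coding of the six control conditions: which of the four
# magnitude columns covaries positively with numerosity (C), negatively (IC),
# or is equated (EQ). Levels count the C entries; variants a/b distinguish
# the CH/ID member of each level.
congruency_table <- function() {
  rows <- list(
    `P-CH`  = list(overall_area = "IC", overall_perimeter = "EQ",
                   convex_hull = "EQ", inter_distance = "C",
                   level = 1L, variant = "a"),
    `P-ID`  = list(overall_area = "IC", overall_perimeter = "EQ",
                   convex_hull = "C", inter_distance = "EQ",
                   level = 1L, variant = "b"),
    `A-CH`  = list(overall_area = "EQ", overall_perimeter = "C",
                   convex_hull = "EQ", inter_distance = "C",
                   level = 2L, variant = "a"),
    `A-ID`  = list(overall_area = "EQ", overall_perimeter = "C",
                   convex_hull = "C", inter_distance = "EQ",
                   level = 2L, variant = "b"),
    `RF-CH` = list(overall_area = "C", overall_perimeter = "C",
                   convex_hull = "EQ", inter_distance = "C",
                   level = 3L, variant = "a"),
    `RF-ID` = list(overall_area = "C", overall_perimeter = "C",
                   convex_hull = "C", inter_distance = "EQ",
                   level = 3L, variant = "b"))
  rows
}

#' Congruency code of a control condition
#'
#' For a given control condition, reports how each of the four magnitude
#' variables (overall area, overall perimeter, convex hull, inter-distance)
#' relates to numerosity across the pair: congruent (`C`, grows with number),
#' incongruent (`IC`, shrinks with number) or equated (`EQ`). The congruency
#' level is the count of congruent variables (1-3); the a/b variant
#' distinguishes the convex-hull and inter-distance member of each level.
#'
#' @param condition a `control_condition` or short code.
#' @return An object of class `congruency_code`: list with `condition`,
#'   `per_variable` (named character vector over the four variables), `level`
#'   and `variant`.
#' @examples
#' congruency_level("RF-ID")$level  # 3
#' @export
congruency_level <- function(condition) {
  if (is.character(condition)) condition <- condition_from_code(condition)
  row <- congruency_table()[[condition$code]]
  per <- unlist(row[c("overall_area", "overall_perimeter",
                      "convex_hull", "inter_distance")])
  structure(list(condition = condition, per_variable = per,
                 level = row$level, variant = row$variant),
            class = "congruency_code")
}

#' @export
print.congruency_code <- function(x, ...) {
  cat(sprintf("<congruency_code> %s: level %d%s (%s)\n", x$condition$code,
              x$level, x$variant,
              paste(names(x$per_variable), x$per_variable, sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' Empirical congruency direction of a magnitude in a stimulus pair
#'
#' Classifies whether the larger-numerosity array's value of a magnitude
#' exceeds (`C`), falls below (`IC`) or matches within `rel_tol` (`EQ`) the
#' smaller array's value.
#'
#' @param pair a `stimulus_pair`.
#' @param variable one of `"overall_area"`, `"overall_perimeter"`,
#'   `"convex_hull"`, `"inter_distance"`.
#' @param rel_tol relative tolerance for the `EQ` call; defaults to the
#'   generator's constraint tolerance.
#' @return `"C"`, `"IC"` or `"EQ"`.
#' @export
congruency_direction <- function(pair, variable = c("overall_area",
                                                    "overall_perimeter",
                                                    "convex_hull",
                                                    "inter_distance"),
                                 rel_tol = 0.05) {
  variable <- match.arg(variable)
  field <- switch(variable, overall_area = "total_area",
                  overall_perimeter = "total_perimeter",
                  convex_hull = "hull_area", inter_distance = "mean_nn_dist")
  v_s <- compute_magnitudes(pair$array_small)[[field]]
  v_l <- compute_magnitudes(pair$array_large)[[field]]
  rel <- (v_l - v_s) / v_s
  if (abs(rel) <= rel_tol) "EQ" else if (rel > 0) "C" else "IC"
}

#' Export magnitudes and congruency codes for a set of pairs
#'
#' One row per array (two per pair, sharing a pair ID), with the pair's
#' condition, congruency level and the magnitude vector.
#'
#' @param pairs list of `stimulus_pair` objects.
#' @param file optional CSV path; when given the table is also written.
#' @return The assembled `data.frame` (invisibly when `file` is given).
#' @export
magnitude_report <- function(pairs, file = NULL) {
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    lev <- congruency_level(p$condition)
    do.call(rbind, lapply(c("small", "large"), function(which) {
      arr <- p[[paste0("array_", which)]]
      cbind(data.frame(pair_id = i, which = which,
                       condition = p$condition$code,
                       congruency_level = lev$level,
                       variant = lev$variant),
            as.data.frame(compute_magnitudes(arr)))
    }))
  })
  out <- do.call(rbind, rows)
  if (!is.null(file)) {
    utils::write.csv(out, file, row.names = FALSE)
    return(invisible(out))
  }
  out
}
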