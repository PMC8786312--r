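#' Magnitude-control conditions
#'
#' A control condition prescribes which non-numerical magnitudes are equated
#' between the two dot arrays of a comparison. The geometry tag fixes the
#' element geometry (shared radius, equated total area, or equated total
#' perimeter); the spatial tag fixes the spatial disposition (equated
#' convex-hull area or equated inter-distance). Crossing the two gives the six
#' conditions used in a session.
#'
#' @param geometry one of `"radius_fixed"`, `"area"`, `"perimeter"`.
#' @param spatial one of `"convex_hull"`, `"inter_distance"`.
#' @return An object of class `control_condition`: a list with elements
#'   `geometry`, `spatial` and the short `code` (e.g. `"RF-ID"`).
#' @examples
#' control_condition("area", "inter_distance")
#' @export
control_condition <- function(geometry = c("radius_fixed", "area", "perimeter"),
                              spatial = c("convex_hull", "inter_distance")) {
  geometry <- match.arg(geometry)
  spatial <- match.arg(spatial)
  code <- paste0(c(radius_fixed = "RF", area = "A", perimeter = "P")[[geometry]],
                 "-",
                 c(convex_hull = "CH", inter_distance = "ID")[[spatial]])
  structure(list(geometry = geometry, spatial = spatial, code = code),
            class = "control_condition")
}

#' @export
print.control_condition <- function(x, ...) {
  cat("<control_condition>", x$code,
      sprintf("(geometry: %s, spatial: %s)\n", x$geometry, x$spatial))
  invisible(x)
}

#' All six magnitude-control conditions
#'
#' @return A named list of the six `control_condition` objects, named by their
#'   short codes (`RF-ID`, `RF-CH`, `A-ID`, `A-CH`, `P-ID`, `P-CH`).
#' @export
all_conditions <- function() {
  out <- list()
  for (g in c("radius_fixed", "area", "perimeter"))
    for (s in c("inter_distance", "convex_hull")) {
      cc <- control_condition(g, s)
      out[[cc$code]] <- cc
    }
  out
}

#' Parse a condition code
#'
#' @param code short code such as `"RF-ID"` or `"A-CH"` (case-insensitive).
#' @return The corresponding `control_condition`.
#' @export
condition_from_code <- function(code) {
  code <- toupper(code)
  conds <- all_conditions()
  if (!code %in% names(conds))
    stop("unknown condition code: ", code, " (valid: ",
         paste(names(conds), collapse = ", "), ")")
  conds[[code]]
}

# run code under a temporary RNG seed when one is supplied
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}
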