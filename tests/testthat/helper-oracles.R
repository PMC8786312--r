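# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# two-sided exact binomial p by brute-force PMF enumeration
# (minimum-likelihood convention: sum all outcomes no more likely than k)
brute_force_binom_p <- function(k, n, p0 = 0.5) {
  pmf <- dbinom(0:n, n, p0)
  sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)])
}

# Monte-Carlo estimate of the area of a convex polygon (hull vertices in
# order), by uniform sampling over its bounding box and a ray-crossing test
mc_polygon_area <- function(px, py, n_samples = 2e5) {
  xr <- range(px); yr <- range(py)
  qx <- runif(n_samples, xr[1], xr[2])
  qy <- runif(n_samples, yr[1], yr[2])
  nv <- length(px)
  inside <- rep(FALSE, n_samples)
  j <- nv
  for (i in seq_len(nv)) {
    cross <- ((py[i] > qy) != (py[j] > qy)) &
      (qx < (px[j] - px[i]) * (qy - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, cross)
    j <- i
  }
  mean(inside) * diff(xr) * diff(yr)
}

# closed-form hull area for a uniform-radius dot array: centers-hull area +
# r * centers-hull perimeter + pi r^2 (Minkowski sum of a convex polygon
# with a disk); degenerate center sets (n <= 2 or collinear) still work via
# zero-area polygon.
minkowski_hull_area <- function(x, y, r) {
  stopifnot(length(unique(round(r, 12))) == 1)
  r <- r[1]
  if (length(x) == 1) return(pi * r^2)
  h <- chull(x, y)
  hx <- x[h]; hy <- y[h]
  nv <- length(hx)
  if (nv == 2) {
    d <- sqrt(diff(hx)^2 + diff(hy)^2)
    return(2 * d * r + pi * r^2)
  }
  j <- c(nv, seq_len(nv - 1))
  area <- abs(sum(hx[j] * hy - hx * hy[j])) / 2
  perim <- sum(sqrt((hx - hx[j])^2 + (hy - hy[j])^2))
  area + perim * r + pi * r^2
}

# Pearson r via the raw covariance/sd formula
brute_force_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# quick synthetic choice table: n_fish fish, n_trials Bernoulli trials each
# at logit-scale intercept beta plus N(0, sd) per-fish deviation, crossed
# with the six control conditions
make_choice_table <- function(n_fish, n_trials, beta, fish_sd = 0,
                              condition_effects = NULL) {
  conds <- c("RF-ID", "RF-CH", "A-ID", "A-CH", "P-ID", "P-CH")
  geoms <- c(`RF-ID` = "radius_fixed", `RF-CH` = "radius_fixed",
             `A-ID` = "area", `A-CH` = "area",
             `P-ID` = "perimeter", `P-CH` = "perimeter")
  spats <- c(`RF-ID` = "inter_distance", `RF-CH` = "convex_hull",
             `A-ID` = "inter_distance", `A-CH` = "convex_hull",
             `P-ID` = "inter_distance", `P-CH` = "convex_hull")
  levs <- c(`RF-ID` = 3L, `RF-CH` = 3L, `A-ID` = 2L, `A-CH` = 2L,
            `P-ID` = 1L, `P-CH` = 1L)
  rows <- lapply(seq_len(n_fish), function(f) {
    u <- rnorm(1, 0, fish_sd)
    cond <- sample(rep(conds, length.out = n_trials))
    eta <- beta + u
    if (!is.null(condition_effects)) eta <- eta + condition_effects[cond]
    data.frame(fish_id = sprintf("F%d", f), experiment = "exp1",
               phase = "test", session = 1L, trial = seq_len(n_trials),
               geometry_control = unname(geoms[cond]),
               spatial_control = unname(spats[cond]),
               congruency_level = unname(levs[cond]),
               comparison = "3v6",
               chose_target = rbinom(n_trials, 1, plogis(eta)),
               responded = 1L, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
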