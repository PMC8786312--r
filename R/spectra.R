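#' Centered 2D Fourier amplitude spectrum
#'
#' Modulus of the discrete 2D Fourier transform of a square grayscale image,
#' with the zero-frequency (DC) coefficient shifted to the center, at index
#' `(floor(L/2) + 1, floor(L/2) + 1)`.
#'
#' @param image square numeric matrix (grayscale; any real scale).
#' @return Non-negative matrix of the same size.
#' @export
amplitude_spectrum <- function(image) {
  if (!is.matrix(image) || nrow(image) != ncol(image) || nrow(image) < 2)
    stop("image must be a square matrix with side >= 2")
  fftshift2(Mod(stats::fft(image)))
}

# move the DC coefficient of a 2D transform to the matrix center
fftshift2 <- function(m) {
  L <- nrow(m)
  h <- floor(L / 2)
  idx <- c((h + 1):L, 1:h)
  m[idx, idx, drop = FALSE]
}

#' Radially averaged spectrum profile
#'
#' Averages a centered amplitude (or power) spectrum over annuli of equal
#' radial width around the DC coefficient. Bin membership is by
#' integer-rounded radius, so at the default binning (one bin per frequency
#' sample) the first bin contains exactly the DC coefficient.
#'
#' @param amplitude centered spectrum matrix from [amplitude_spectrum()]
#'   (optionally squared for a power spectrum).
#' @param n_bins number of radial bins; default one bin per integer radius out
#'   to the image corner.
#' @param use_power_not_amplitude square the coefficients before averaging.
#' @return An object of class `spectrum_summary`: list with `radial_freq_bins`
#'   (bin centers, cycles/image), `mean_amplitude_per_bin`, `n_per_bin` and an
#'   `options` record. Feed it to [total_power()].
#' @export
radial_average <- function(amplitude, n_bins = NULL,
                           use_power_not_amplitude = FALSE) {
  L <- nrow(amplitude)
  ctr <- floor(L / 2) + 1
  dx <- matrix(seq_len(L) - ctr, L, L, byrow = TRUE)
  dy <- matrix(seq_len(L) - ctr, L, L)
  r_int <- round(sqrt(dx^2 + dy^2))
  r_max <- max(r_int)
  if (is.null(n_bins)) n_bins <- r_max + 1L
  stopifnot(n_bins >= 1)
  vals <- if (use_power_not_amplitude) amplitude^2 else amplitude
  breaks <- seq(-0.5, r_max + 0.5, length.out = n_bins + 1)
  bin <- cut(as.vector(r_int), breaks = breaks, labels = FALSE)
  means <- tapply(as.vector(vals), factor(bin, levels = seq_len(n_bins)), mean)
  counts <- tapply(rep(1, length(bin)), factor(bin, levels = seq_len(n_bins)), sum)
  centers <- (breaks[-length(breaks)] + breaks[-1]) / 2
  structure(list(
    radial_freq_bins = centers,
    mean_amplitude_per_bin = as.numeric(means),
    n_per_bin = as.integer(ifelse(is.na(counts), 0L, counts)),
    options = list(dc_included = NA, use_power_not_amplitude =
                     use_power_not_amplitude, n_bins = as.integer(n_bins))),
    class = "spectrum_summary")
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(sprintf("<spectrum_summary> %d radial bins (%s)\n",
              x$options$n_bins,
              if (isTRUE(x$options$use_power_not_amplitude)) "power"
              else "amplitude"))
  invisible(x)
}

#' Total power of a spectrum profile
#'
#' Sum of the per-bin radially averaged values. The DC bin encodes mean
#' luminance rather than pattern, so it is excluded by default; at the default
#' binning of [radial_average()] the first bin is exactly the DC coefficient.
#'
#' @param summary a `spectrum_summary`.
#' @param dc_included include the first (DC) bin in the sum.
#' @return Non-negative scalar.
#' @export
total_power <- function(summary, dc_included = FALSE) {
  stopifnot(inherits(summary, "spectrum_summary"))
  v <- summary$mean_amplitude_per_bin
  v <- v[!is.na(v)]
  if (!dc_included) v <- v[-1]
  sum(v)
}

#' Total power of an image in one call
#'
#' Convenience wrapper: centered amplitude spectrum, radial average, sum.
#'
#' @param image square grayscale matrix.
#' @param dc_included include the DC bin.
#' @param use_power_not_amplitude average `|F|^2` instead of `|F|`.
#' @return Non-negative scalar.
#' @export
image_total_power <- function(image, dc_included = FALSE,
                              use_power_not_amplitude = FALSE) {
  total_power(radial_average(amplitude_spectrum(image),
                             use_power_not_amplitude = use_power_not_amplitude),
              dc_included = dc_included)
}

#' Normalized total-power index of a comparison
#'
#' Contrast between the total power of the larger-numerosity stimulus and the
#' smaller one: `(tp_large - tp_small) / (tp_large + tp_small)`, in [-1, 1].
#' Positive values mean the more numerous array carries more spectral energy.
#'
#' @param tp_large,tp_small non-negative total-power values; not both zero.
#' @return An object of class `power_index`: list with `tp_large`, `tp_small`,
#'   `index`.
#' @examples
#' total_power_index(3, 1)$index  # 0.5
#' @export
total_power_index <- function(tp_large, tp_small) {
  if (tp_large < 0 || tp_small < 0) stop("total power must be non-negative")
  if (tp_large + tp_small == 0)
    stop("total-power index undefined: both total powers are zero")
  structure(list(tp_large = tp_large, tp_small = tp_small,
                 index = (tp_large - tp_small) / (tp_large + tp_small)),
            class = "power_index")
}

#' @export
print.power_index <- function(x, ...) {
  cat(sprintf("<power_index> %.4f (tp_large = %.4g, tp_small = %.4g)\n",
              x$index, x$tp_large, x$tp_small))
  invisible(x)
}

#' Correlation between behavioral accuracy and spectral index
#'
#' Pearson correlation between per-condition accuracy (choice for the relative
#' numerosity) and the per-condition total-power index, with the two-sided p
#' value from the t transform and `df = n - 2` (so six control conditions give
#' the r(4) convention).
#'
#' @param accuracy_by_condition,index_by_condition equal-length numeric
#'   vectors, length >= 3, neither constant.
#' @return List with `r`, `df`, `p`.
#' @export
accuracy_spectrum_correlation <- function(accuracy_by_condition,
                                          index_by_condition) {
  x <- accuracy_by_condition; y <- index_by_condition
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 3) stop("need at least 3 conditions")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Per-condition total-power indices of freshly generated stimuli
#'
#' Generates `n_pairs` stimulus pairs per control condition for one numerical
#' comparison, renders both arrays (no outline ring, so only the dots
#' contribute), and reports the mean total-power index per condition under a
#' requested grid of spectral options. The direction of the index under each
#' option set is an empirical property of the stimuli, reported rather than
#' asserted.
#'
#' @param n_small,n_large the numerical comparison.
#' @param n_pairs pairs per condition.
#' @param seed top-level seed; per-pair substreams are derived by a fixed
#'   counter.
#' @param side_px rendered image side in pixels (the field is scaled to fill
#'   it).
#' @param dc_options,power_options logical vectors: the option grid to report.
#' @param params generation parameters, see [pair_params()].
#' @return `data.frame` with columns `condition`, `dc_included`,
#'   `use_power_not_amplitude`, `mean_index`, `sd_index`, `n_pairs`.
#' @export
power_index_report <- function(n_small, n_large, n_pairs = 5, seed = 1,
                               side_px = 256,
                               dc_options = c(FALSE, TRUE),
                               power_options = c(FALSE, TRUE),
                               params = pair_params()) {
  px_per_mm <- side_px / (2 * params$field_radius)
  conds <- all_conditions()
  grid <- expand.grid(condition = names(conds), dc_included = dc_options,
                      use_power_not_amplitude = power_options,
                      stringsAsFactors = FALSE)
  grid$mean_index <- NA_real_
  grid$sd_index <- NA_real_
  idx_store <- list()
  counter <- 0L
  for (cc in names(conds)) {
    idx <- matrix(NA_real_, n_pairs, length(dc_options) * length(power_options))
    for (k in seq_len(n_pairs)) {
      counter <- counter + 1L
      pair <- generate_pair(n_small, n_large, conds[[cc]], params,
                            seed = (seed + 7919L * counter) %% .Machine$integer.max)
      img_s <- render_image(pair$array_small, px_per_mm, draw_outline = FALSE)
      img_l <- render_image(pair$array_large, px_per_mm, draw_outline = FALSE)
      o <- 0L
      for (pw in power_options) for (dc in dc_options) {
        o <- o + 1L
        tp_s <- image_total_power(img_s, dc, pw)
        tp_l <- image_total_power(img_l, dc, pw)
        idx[k, o] <- total_power_index(tp_l, tp_s)$index
      }
    }
    o <- 0L
    for (pw in power_options) for (dc in dc_options) {
      o <- o + 1L
      sel <- grid$condition == cc & grid$dc_included == dc &
        grid$use_power_not_amplitude == pw
      grid$mean_index[sel] <- mean(idx[, o])
      grid$sd_index[sel] <- stats::sd(idx[, o])
    }
  }
  grid$n_pairs <- n_pairs
  grid
}
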