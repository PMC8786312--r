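#' Logit and inverse-logit conversions
#'
#' Mixed-model estimates on the log-odds scale are converted to natural units
#' (choice proportions) with the inverse logit `exp(x) / (1 + exp(x))`; the
#' logit is its inverse and requires a proportion strictly inside (0, 1).
#'
#' @param x log-odds.
#' @param p proportion in (0, 1).
#' @return `inv_logit`: proportion; `logit`: log-odds.
#' @examples
#' inv_logit(1.510)  # 0.819..., printing as 0.82
#' @export
inv_logit <- function(x) stats::plogis(x)

#' @rdname inv_logit
#' @export
logit <- function(p) {
  if (any(p <= 0 | p >= 1)) stop("logit requires 0 < p < 1")
  stats::qlogis(p)
}

#' Cohen's g for a proportion against chance
#'
#' The effect size of a binomial proportion versus chance responding is the
#' plain displacement `g = p_hat - 0.5`.
#'
#' @param p_hat sample proportion.
#' @return Cohen's g, in `[-0.5, 0.5]`.
#' @examples
#' cohens_g(0.819)  # 0.319, a large effect
#' @export
cohens_g <- function(p_hat) {
  stopifnot(all(p_hat >= 0 & p_hat <= 1))
  p_hat - 0.5
}

#' Qualitative band of a Cohen's g effect size
#'
#' Bands follow the conventional cut points for g: below 0.05 negligible,
#' 0.1-0.15 small, 0.2-0.25 medium, above 0.25 large (applied to `|g|`,
#' unrounded). Values falling in the gaps the scale leaves (0.05-0.1 and
#' 0.15-0.2) are assigned to the nearer band boundary, ties upward.
#'
#' @param g Cohen's g, `|g| <= 0.5`.
#' @return One of `"negligible"`, `"small"`, `"medium"`, `"large"`.
#' @examples
#' classify_g(0.32)   # large
#' classify_g(0.255)  # large (prints as 0.25 but exceeds the 0.25 bound)
#' @export
classify_g <- function(g) {
  stopifnot(abs(g) <= 0.5 + 1e-12)
  a <- abs(g)
  if (a > 0.25) "large"
  else if (a >= 0.175) "medium"   # gap 0.15-0.2 split at its midpoint
  else if (a >= 0.075) "small"    # gap 0.05-0.1 split at its midpoint
  else "negligible"
}

#' Exact binomial inference for a choice proportion
#'
#' Two-sided exact binomial test against `p0` (minimum-likelihood convention,
#' as in [stats::binom.test()]), exact Clopper-Pearson 95% confidence
#' interval, Cohen's g versus chance and its qualitative band.
#'
#' @param k successes.
#' @param n trials, `n >= 1`.
#' @param p0 null proportion.
#' @param conf_level confidence level of the interval.
#' @return An object of class `proportion_summary`: list with `k`, `n`,
#'   `p_hat`, `ci_low`, `ci_high`, `p_value`, `cohens_g`, `g_band`.
#' @examples
#' exact_binomial(36, 48)
#' @export
exact_binomial <- function(k, n, p0 = 0.5, conf_level = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  bt <- stats::binom.test(k, n, p = p0, conf.level = conf_level)
  g <- cohens_g(k / n)
  structure(list(k = k, n = n, p_hat = k / n,
                 ci_low = bt$conf.int[1], ci_high = bt$conf.int[2],
                 p_value = bt$p.value, cohens_g = g,
                 g_band = classify_g(g)),
            class = "proportion_summary")
}

#' @export
print.proportion_summary <- function(x, ...) {
  cat(sprintf(
    "<proportion_summary> %d/%d = %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
    x$k, x$n, x$p_hat, x$ci_low, x$ci_high, x$p_value))
  cat(sprintf("  Cohen's g = %.3f (%s)\n", x$cohens_g, x$g_band))
  invisible(x)
}

#' Two-sample t test from reported summary statistics
#'
#' Reconstructs a two-sample t test from group means, standard errors of the
#' mean and sample sizes, as needed when only summary statistics are printed.
#' Group variances are recovered as `s^2 = n * SEM^2`. The default pooled
#' variant uses `df = n1 + n2 - 2`; the Welch variant uses the
#' Satterthwaite df.
#'
#' @param m1,m2 group means.
#' @param sem1,sem2 standard errors of the mean, positive.
#' @param n1,n2 group sizes, each >= 2.
#' @param var_equal pooled-variance t (default) or Welch.
#' @return List with `t`, `df`, `p` (two-sided).
#' @examples
#' t_from_summary(451.25, 106.77, 4, 413.25, 73.14, 4)  # t(6) = 0.294
#' @export
t_from_summary <- function(m1, sem1, n1, m2, sem2, n2, var_equal = TRUE) {
  stopifnot(n1 >= 2, n2 >= 2, sem1 > 0, sem2 > 0)
  v1 <- n1 * sem1^2
  v2 <- n2 * sem2^2
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(sem1^2 + sem2^2)
    df <- (sem1^2 + sem2^2)^2 /
      (sem1^4 / (n1 - 1) + sem2^4 / (n2 - 1))
  }
  tval <- (m1 - m2) / se
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}
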