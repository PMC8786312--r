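test_that("choice-table validation enforces the schema invariants", {
  set.seed(1)
  tab <- make_choice_table(3, 24, beta = 1)
  expect_silent(validate_choice_table(tab))

  bad <- tab; bad$congruency_level[1] <- 5L
  expect_error(validate_choice_table(bad), "congruency_level inconsistent")
  bad2 <- tab; bad2$responded[1] <- 0L
  expect_error(validate_choice_table(bad2), "chose_target must be NA")
  bad3 <- tab[, -1]
  expect_error(validate_choice_table(bad3), "missing column")
})

test_that("zero-variance mixed model reduces to the logistic GLM", {
  set.seed(21)
  tab <- make_choice_table(8, 120, beta = 1.2, fish_sd = 0)
  fmm <- fit_binomial_glmm(tab)
  fglm <- fit_binomial_glmm(tab, random_intercept = NULL)
  expect_lt(fmm$random_intercept_variance, 1e-6)
  expect_equal(fmm$fixed_effects$estimate, fglm$fixed_effects$estimate,
               tolerance = 1e-6)
  # and the GLM intercept is exactly the logit of the pooled proportion
  expect_equal(fglm$fixed_effects$estimate,
               logit(mean(tab$chose_target)), tolerance = 1e-12)
  expect_true(fmm$converged)
})

test_that("information criteria are consistent with the Laplace likelihood", {
  set.seed(22)
  tab <- make_choice_table(6, 60, beta = 0.8, fish_sd = 0.4)
  fit <- fit_binomial_glmm(tab, fixed = "geometry_control")
  k <- nrow(fit$fixed_effects) + 1  # + random-intercept variance
  expect_equal(fit$aic, -2 * fit$log_likelihood + 2 * k)
  n <- nrow(fit$data)
  expect_equal(fit$bic, -2 * fit$log_likelihood + log(n) * k)
  expect_gte(fit$bic, fit$aic)  # holds whenever rows > e^2
  expect_gte(fit$random_intercept_variance, 0)
})

test_that("Laplace and adaptive Gauss-Hermite estimates agree", {
  set.seed(23)
  tab <- make_choice_table(8, 100, beta = 1.0, fish_sd = 0.6)
  laplace <- fit_binomial_glmm(tab)
  agh <- fit_binomial_glmm(tab, nAGQ = 15)
  expect_equal(laplace$fixed_effects$estimate, agh$fixed_effects$estimate,
               tolerance = 0.02)
})

test_that("backward elimination respects marginality and trivial cases", {
  set.seed(24)
  tab <- make_choice_table(6, 96, beta = 1.0)
  # single-candidate model comes back unchanged
  only <- backward_select(tab, "1")
  expect_equal(nrow(only$elimination_trace), 1)
  expect_equal(only$elimination_trace$model, "1")

  # an interaction cannot outlive its parents in any elimination path
  full <- backward_select(tab, "geometry_control * spatial_control")
  for (m in full$elimination_trace$model) {
    terms <- trimws(strsplit(m, "+", fixed = TRUE)[[1]])
    if ("geometry_control:spatial_control" %in% terms)
      expect_true(all(c("geometry_control", "spatial_control") %in% terms))
  }
})

test_that("a strong factor effect survives backward elimination", {
  set.seed(25)
  eff <- c(`RF-ID` = 0.75, `RF-CH` = 0.75, `A-ID` = -0.75, `A-CH` = -0.75,
           `P-ID` = 0, `P-CH` = 0)
  kept <- 0L
  n_sim <- 40
  for (i in seq_len(n_sim)) {
    tab <- make_choice_table(8, 250, beta = 0.5, condition_effects = eff)
    sel <- backward_select(tab, "geometry_control + spatial_control")
    if (grepl("geometry_control", utils::tail(sel$elimination_trace$model, 1)))
      kept <- kept + 1L
  }
  expect_gte(kept / n_sim, 0.95)
})

test_that("Tukey contrasts are adjusted monotonically and match per level", {
  set.seed(26)
  tab <- make_choice_table(8, 150, beta = 1.0)
  fit <- fit_binomial_glmm(tab, fixed = "geometry_control")
  tk <- tukey_contrasts(fit, "geometry_control")
  expect_equal(nrow(tk$contrasts), 3)  # 3 levels -> 3 pairs
  expect_equal(nrow(tk$levels), 3)
  expect_true(all(tk$levels$ci_low <= tk$levels$proportion &
                  tk$levels$proportion <= tk$levels$ci_high))

  # with two levels the Tukey adjustment is the identity
  fit2 <- fit_binomial_glmm(tab, fixed = "spatial_control")
  tk2 <- tukey_contrasts(fit2, "spatial_control")
  z <- tk2$contrasts$estimate / tk2$contrasts$se
  expect_equal(tk2$contrasts$p_adj, 2 * pnorm(-abs(z)), tolerance = 1e-6)
})

test_that("congruency analysis finds no structure in exchangeable data", {
  set.seed(27)
  tab <- make_choice_table(8, 200, beta = 1.0)
  out <- congruency_analysis(tab)
  expect_equal(nrow(out$contrasts), 3)
  expect_true(all(out$contrasts$p_adj > 0.001))
  expect_equal(nrow(out$levels), 3)

  # a missing level narrows the analysis with a warning
  sub <- tab[tab$congruency_level != 1, ]
  expect_warning(out2 <- congruency_analysis(sub), "absent")
  expect_equal(nrow(out2$contrasts), 1)
})

test_that("level-dependent accuracy is detected by the congruency contrasts", {
  set.seed(28)
  eff <- c(`RF-ID` = logit(0.9), `RF-CH` = logit(0.9),
           `A-ID` = logit(0.75), `A-CH` = logit(0.75),
           `P-ID` = logit(0.6), `P-CH` = logit(0.6))
  tab <- make_choice_table(8, 400, beta = 0, condition_effects = eff)
  out <- congruency_analysis(tab)
  expect_true(any(out$contrasts$p_adj < 0.05))
})
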