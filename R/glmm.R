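#' Validate a choice table
#'
#' A choice table is the long-format record of a discrimination experiment:
#' one row per trial with the fish, session structure, magnitude-control
#' labels, the numerical comparison and the binary outcome. `chose_target` is
#' the choice of the rewarded numerosity during training and of the
#' relative-rule-consistent set during tests; it is defined only on responded
#' trials. The congruency level must agree with the control condition's
#' coding.
#'
#' @param table a `data.frame` with columns `fish_id`, `experiment`, `phase`,
#'   `session`, `trial`, `geometry_control`, `spatial_control`,
#'   `congruency_level`, `comparison`, `chose_target`, `responded`.
#' @return The table, invisibly, after passing all checks.
#' @export
validate_choice_table <- function(table) {
  need <- c("fish_id", "experiment", "phase", "session", "trial",
            "geometry_control", "spatial_control", "congruency_level",
            "comparison", "chose_target", "responded")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("choice table missing column(s): ", paste(miss, collapse = ", "))
  if (!all(table$responded %in% c(0, 1)))
    stop("responded must be binary")
  resp <- table$responded == 1
  if (any(is.na(table$chose_target[resp])))
    stop("chose_target must be defined on all responded trials")
  if (any(!is.na(table$chose_target[!resp])))
    stop("chose_target must be NA on non-responded trials")
  if (!all(table$chose_target[resp] %in% c(0, 1)))
    stop("chose_target must be binary where defined")
  cond_code <- paste0(
    c(radius_fixed = "RF", area = "A", perimeter = "P")[table$geometry_control],
    "-",
    c(convex_hull = "CH", inter_distance = "ID")[table$spatial_control])
  expected <- vapply(cond_code, function(cc) congruency_level(cc)$level,
                     integer(1))
  if (any(table$congruency_level != expected))
    stop("congruency_level inconsistent with (geometry_control, spatial_control)")
  invisible(table)
}

# aggregate responded trials to binomial counts per grouping x factor cell
aggregate_choices <- function(table, vars, random, response) {
  tab <- table[table$responded == 1, , drop = FALSE]
  keys <- c(random, vars)
  if (!length(keys)) {
    agg <- data.frame(k = sum(tab[[response]]), n = nrow(tab))
  } else {
    split_key <- interaction(tab[keys], drop = TRUE, lex.order = TRUE)
    k <- tapply(tab[[response]], split_key, sum)
    n <- tapply(tab[[response]], split_key, length)
    meta <- unique(tab[keys])
    meta_key <- interaction(meta[keys], drop = TRUE, lex.order = TRUE)
    meta <- meta[order(meta_key), , drop = FALSE]
    agg <- cbind(meta, k = as.numeric(k[levels(split_key)]),
                 n = as.numeric(n[levels(split_key)]))
  }
  rownames(agg) <- NULL
  for (v in vars) agg[[v]] <- factor(agg[[v]])
  if (!is.null(random)) agg[[random]] <- factor(agg[[random]])
  agg
}

#' Fit a random-intercept binomial mixed model to choice data
#'
#' Binomial GLMM with logit link fit by maximum likelihood with the Laplace
#' approximation (lme4), with a random intercept per grouping unit (the fish).
#' Trials are aggregated to binomial counts per grouping-by-factor cell, which
#' leaves the maximum-likelihood estimates and standard errors of factor
#' models unchanged while making refits cheap. A boundary fit (random
#' intercept variance estimated at 0) is legitimate and reduces the estimates
#' to those of the plain logistic GLM; with `random_intercept = NULL` the
#' plain GLM is fit directly.
#'
#' @param table a choice table (see [validate_choice_table()]).
#' @param fixed character vector of fixed-effect terms over the table's
#'   columns (may include interactions such as `"a:b"`); empty for an
#'   intercept-only model.
#' @param random_intercept grouping column for the random intercept
#'   (default `"fish_id"`), or `NULL` for a fixed-effects-only GLM.
#' @param response binary outcome column.
#' @param nAGQ integration order: 1 is the Laplace approximation; values >= 9
#'   give adaptive Gauss-Hermite quadrature (intercept-only random structure),
#'   usable as an internal cross-check.
#' @return An object of class `glmm_fit`: list with `model`, `fixed_effects`
#'   (term/estimate/se table on the log-odds scale),
#'   `random_intercept_variance`, `log_likelihood`, `aic`, `bic`, `converged`,
#'   `n_obs` (binary trials), `formula`, `data` (the aggregated table).
#' @export
fit_binomial_glmm <- function(table, fixed = character(),
                              random_intercept = "fish_id",
                              response = "chose_target", nAGQ = 1) {
  vars <- unique(unlist(strsplit(fixed, "[:*]")))
  vars <- trimws(vars[nzchar(vars)])
  agg <- aggregate_choices(table, vars, random_intercept, response)
  fit_binomial_glmm_agg(agg, fixed, random_intercept, nAGQ = nAGQ)
}

fit_binomial_glmm_agg <- function(agg, fixed, random_intercept, nAGQ = 1) {
  rhs <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
  if (!is.null(random_intercept)) {
    fml <- stats::as.formula(
      paste0("cbind(k, n - k) ~ ", rhs, " + (1 | ", random_intercept, ")"))
    warned <- FALSE
    model <- withCallingHandlers(
      lme4::glmer(fml, data = agg, family = stats::binomial("logit"),
                  nAGQ = nAGQ),
      warning = function(w) {
        warned <<- TRUE
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        # a boundary (singular) fit is a legitimate zero-variance estimate
        if (grepl("boundary|singular", conditionMessage(m)))
          invokeRestart("muffleMessage")
      })
    vc <- lme4::VarCorr(model)
    rvar <- as.numeric(vc[[random_intercept]][1, 1])
    # a boundary (singular) record is a legitimate zero-variance estimate,
    # not a convergence failure
    conv_msgs <- unlist(model@optinfo$conv$lme4)
    conv <- !warned && !any(grepl("failed to converge", conv_msgs,
                                  ignore.case = TRUE))
    coefs <- summary(model)$coefficients
  } else {
    fml <- stats::as.formula(paste0("cbind(k, n - k) ~ ", rhs))
    model <- stats::glm(fml, data = agg, family = stats::binomial("logit"))
    rvar <- 0
    conv <- model$converged
    coefs <- summary(model)$coefficients
  }
  ll <- as.numeric(stats::logLik(model))
  structure(list(
    model = model,
    fixed_effects = data.frame(term = rownames(coefs),
                               estimate = coefs[, 1], se = coefs[, 2],
                               row.names = NULL),
    random_intercept_variance = rvar,
    log_likelihood = ll,
    aic = stats::AIC(model),
    bic = stats::BIC(model),
    converged = conv,
    n_obs = sum(agg$n),
    formula = deparse(fml),
    data = agg), class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("<glmm_fit>", x$formula, "\n")
  cat(sprintf("  logLik %.2f, AIC %.2f, BIC %.2f, random var %.3g%s\n",
              x$log_likelihood, x$aic, x$bic, x$random_intercept_variance,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(x$fixed_effects)
  invisible(x)
}

#' Backward elimination over a binomial mixed model
#'
#' Starting from the full fixed-effect specification, iteratively removes the
#' term (highest-order terms first, respecting marginality) whose removal most
#' improves the information criterion, stopping when no removal improves it.
#' All candidate models are fit on the same aggregated table (cells of the
#' full model's factors), so criterion values are comparable.
#'
#' @param table a choice table.
#' @param full_formula right-hand-side string of the full fixed-effects model,
#'   e.g. `"geometry_control * spatial_control"`.
#' @param criterion `"BIC"` (default; consistent under the null) or `"AIC"`.
#' @param random_intercept,response,nAGQ as in [fit_binomial_glmm()].
#' @return The selected `glmm_fit`, with an `elimination_trace` data.frame
#'   (step, model, criterion value, action) attached.
#' @export
backward_select <- function(table, full_formula, criterion = c("BIC", "AIC"),
                            random_intercept = "fish_id",
                            response = "chose_target", nAGQ = 1) {
  criterion <- match.arg(criterion)
  crit <- function(fit) if (criterion == "BIC") fit$bic else fit$aic
  full_terms <- attr(stats::terms(
    stats::as.formula(paste("~", full_formula))), "term.labels")
  vars <- unique(unlist(strsplit(full_terms, ":")))
  agg <- aggregate_choices(table, vars, random_intercept, response)
  current_terms <- full_terms
  fit <- fit_binomial_glmm_agg(agg, current_terms, random_intercept, nAGQ)
  trace <- data.frame(step = 0L,
                      model = if (length(current_terms))
                        paste(current_terms, collapse = " + ") else "1",
                      criterion = crit(fit), action = "full model",
                      stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    droppable <- droppable_terms(current_terms)
    if (!length(droppable)) break
    cand <- lapply(droppable, function(tm) {
      fit_binomial_glmm_agg(agg, setdiff_terms(current_terms, tm),
                            random_intercept, nAGQ)
    })
    scores <- vapply(cand, crit, numeric(1))
    best <- which.min(scores)
    if (scores[best] >= crit(fit)) break
    step <- step + 1L
    current_terms <- setdiff_terms(current_terms, droppable[best])
    fit <- cand[[best]]
    trace <- rbind(trace, data.frame(
      step = step,
      model = if (length(current_terms))
        paste(current_terms, collapse = " + ") else "1",
      criterion = scores[best],
      action = paste("dropped", droppable[best]),
      stringsAsFactors = FALSE))
  }
  fit$elimination_trace <- trace
  fit$criterion <- criterion
  fit
}

# terms removable under marginality: not contained in any higher-order term
droppable_terms <- function(terms) {
  if (!length(terms)) return(character(0))
  contained <- function(a, b) {
    pa <- strsplit(a, ":")[[1]]; pb <- strsplit(b, ":")[[1]]
    length(pa) < length(pb) && all(pa %in% pb)
  }
  keep <- vapply(terms, function(tm)
    !any(vapply(terms, function(other) contained(tm, other), logical(1))),
    logical(1))
  terms[keep]
}

setdiff_terms <- function(terms, drop) terms[terms != drop]

#' Tukey-adjusted pairwise contrasts for a fitted factor
#'
#' All pairwise level contrasts of a fixed factor on the log-odds scale, with
#' familywise adjustment by the studentized-range (Tukey) method, plus the
#' per-level estimated proportions with 95% confidence intervals.
#'
#' @param fit a `glmm_fit` whose model contains `factor_name`.
#' @param factor_name name of the fixed factor.
#' @return List with `contrasts` (contrast, estimate, se, p_adj) and `levels`
#'   (level, proportion, ci_low, ci_high).
#' @export
tukey_contrasts <- function(fit, factor_name) {
  stopifnot(inherits(fit, "glmm_fit"))
  emm <- emmeans::emmeans(fit$model, specs = factor_name, data = fit$data)
  prs <- summary(emmeans::contrast(emm, method = "pairwise", adjust = "tukey"))
  lev <- summary(emm, type = "response")
  ci_cols <- intersect(c("asymp.LCL", "lower.CL"), names(lev))
  ci_cols2 <- intersect(c("asymp.UCL", "upper.CL"), names(lev))
  list(
    contrasts = data.frame(contrast = as.character(prs$contrast),
                           estimate = prs$estimate, se = prs$SE,
                           p_adj = prs$p.value, row.names = NULL),
    levels = data.frame(level = as.character(lev[[factor_name]]),
                        proportion = lev$prob,
                        ci_low = lev[[ci_cols[1]]],
                        ci_high = lev[[ci_cols2[1]]], row.names = NULL))
}

#' Congruency-level analysis of choice accuracy
#'
#' Fits a random-intercept binomial GLMM of the choice for the target
#' numerosity on the congruency level (1-3, as a factor) and reports all
#' pairwise Tukey-adjusted contrasts between levels together with per-level
#' 95% confidence intervals. Levels absent from the data are dropped with a
#' warning.
#'
#' @param table a choice table with `congruency_level` populated.
#' @param response binary outcome column.
#' @param random_intercept grouping column.
#' @return List with `fit` (a `glmm_fit`), `contrasts` and `levels` (as in
#'   [tukey_contrasts()]).
#' @export
congruency_analysis <- function(table, response = "chose_target",
                                random_intercept = "fish_id") {
  present <- sort(unique(table$congruency_level))
  if (!all(1:3 %in% present))
    warning("congruency level(s) ", paste(setdiff(1:3, present), collapse = ", "),
            " absent; analysis proceeds over levels ",
            paste(present, collapse = ", "))
  fit <- fit_binomial_glmm(table, fixed = "congruency_level",
                           random_intercept = random_intercept,
                           response = response)
  tk <- tukey_contrasts(fit, "congruency_level")
  c(list(fit = fit), tk)
}
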