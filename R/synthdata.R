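#' Generating parameters for one simulated fish
#'
#' Each simulated fish follows a saturating-exponential learning curve on the
#' log-odds scale: the per-trial success probability in session s is
#' `inv_logit(start + (asymptote - start) * (1 - exp(-rate * s)) + offset)`,
#' where the offset is condition-specific. Responding is Bernoulli with
#' `response_prob` (fish typically respond on 70-100% of trials); test
#' performance is a per-comparison log-odds.
#'
#' @param fish_id identifier.
#' @param start_log_odds pre-learning log-odds (0 = chance).
#' @param asymptote_log_odds asymptotic training log-odds.
#' @param learning_rate per-session rate, >= 0.
#' @param condition_offsets named log-odds offsets per condition code; zero
#'   offsets mean accuracy does not depend on the magnitude controls.
#' @param response_prob probability of responding on a trial.
#' @param test_log_odds named log-odds per test comparison label (e.g.
#'   `"2v3"`).
#' @return An object of class `fish_params`.
#' @export
fish_params <- function(fish_id, start_log_odds = 0,
                        asymptote_log_odds = logit(0.82),
                        learning_rate = 0.25,
                        condition_offsets = NULL,
                        response_prob = 0.85,
                        test_log_odds = NULL) {
  stopifnot(learning_rate >= 0, response_prob >= 0, response_prob <= 1)
  if (is.null(condition_offsets)) {
    condition_offsets <- stats::setNames(rep(0, 6), names(all_conditions()))
  }
  structure(list(fish_id = fish_id, start_log_odds = start_log_odds,
                 asymptote_log_odds = asymptote_log_odds,
                 learning_rate = learning_rate,
                 condition_offsets = condition_offsets,
                 response_prob = response_prob,
                 test_log_odds = test_log_odds),
            class = "fish_params")
}

condition_level_lookup <- function(codes) {
  vapply(codes, function(cc) congruency_level(cc)$level, integer(1))
}

#' Simulate the training phase of one fish
#'
#' Builds daily 48-trial sessions with [build_training_session()] and draws
#' Bernoulli choices from the fish's learning curve until the learning
#' criterion (two consecutive sessions at or above `threshold`, accuracy over
#' responded trials) or `max_sessions` is reached.
#'
#' @param params a `fish_params`.
#' @param comparison length-2 integer vector `c(n_small, n_large)`.
#' @param rewarded_rule `"smaller"` or `"larger"`.
#' @param max_sessions session budget.
#' @param experiment experiment label recorded on the rows.
#' @param threshold criterion accuracy.
#' @param seed optional integer seed.
#' @return A choice-table `data.frame` (one row per trial) with attributes
#'   `session_accuracy` (per-session accuracy over responded trials) and
#'   `criterion` (the [criterion_reached()] result).
#' @export
simulate_learning <- function(params, comparison, rewarded_rule,
                              max_sessions = 30, experiment = "exp1",
                              threshold = 0.75, seed = NULL) {
  stopifnot(inherits(params, "fish_params"))
  with_seed_if(seed, {
    rows <- list()
    acc <- numeric(0)
    for (s in seq_len(max_sessions)) {
      plan <- build_training_session(comparison, rewarded_rule,
                                     session_index = s)
      base <- params$start_log_odds +
        (params$asymptote_log_odds - params$start_log_odds) *
        (1 - exp(-params$learning_rate * s))
      p <- inv_logit(base + params$condition_offsets[plan$condition])
      responded <- stats::rbinom(nrow(plan), 1, params$response_prob)
      chose <- ifelse(responded == 1, stats::rbinom(nrow(plan), 1, p),
                      NA_integer_)
      rows[[s]] <- data.frame(
        fish_id = params$fish_id, experiment = experiment,
        phase = "training", session = s, trial = plan$trial_index,
        geometry_control = plan$geometry_control,
        spatial_control = plan$spatial_control,
        congruency_level = condition_level_lookup(plan$condition),
        comparison = plan$comparison, rewarded_rule = rewarded_rule,
        chose_target = chose, responded = responded,
        stimulus_seed = plan$stimulus_seed,
        stringsAsFactors = FALSE)
      acc <- c(acc, mean(chose[responded == 1]))
      cr <- criterion_reached(acc, threshold)
      if (cr$reached) break
    }
    out <- do.call(rbind, rows)
    attr(out, "session_accuracy") <- acc
    attr(out, "criterion") <- criterion_reached(acc, threshold)
    out
  })
}

simulate_test_block <- function(params, test_comparison, training_comparison,
                                rewarded_rule, experiment, label) {
  plans <- build_test_block(test_comparison, training_comparison,
                            rewarded_rule)
  p_test <- inv_logit(params$test_log_odds[[label]])
  rows <- lapply(plans, function(plan) {
    probe <- plan[plan$probe, , drop = FALSE]
    responded <- stats::rbinom(nrow(probe), 1, params$response_prob)
    chose <- ifelse(responded == 1, stats::rbinom(nrow(probe), 1, p_test),
                    NA_integer_)
    data.frame(
      fish_id = params$fish_id, experiment = experiment, phase = "test",
      session = probe$session_index, trial = probe$trial_index,
      geometry_control = probe$geometry_control,
      spatial_control = probe$spatial_control,
      congruency_level = condition_level_lookup(probe$condition),
      comparison = label, rewarded_rule = NA_character_,
      chose_target = chose, responded = responded,
      stimulus_seed = probe$stimulus_seed,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Paper-like generating parameters
#'
#' Named presets whose generating truths are the headline proportions of the
#' emulated study designs: for the 3 vs 6 design (`exp1`) a training
#' asymptote of 0.819 and a uniform test success probability of 0.743 across
#' fish, tests and conditions; for the 2 vs 3 design (`exp2`) 0.755 and
#' 0.698. Learning rate 0.25/session puts the criterion around session 8-10
#' (roughly 400-500 trials), matching the observed trials-to-criterion scale.
#'
#' @param design `"exp1"` or `"exp2"`.
#' @return List of `fish_params`, one per fish (8 for exp1, 4 for exp2).
#' @export
paper_like_params <- function(design = c("exp1", "exp2")) {
  design <- match.arg(design)
  if (design == "exp1") {
    tests <- list(`2v3` = logit(0.743), `6v9` = logit(0.743),
                  `5v8` = logit(0.743))
    lapply(1:8, function(i)
      fish_params(sprintf("F%d", i), asymptote_log_odds = logit(0.819),
                  test_log_odds = tests))
  } else {
    tests <- list(`3v4` = logit(0.698), `3v6` = logit(0.698))
    lapply(1:4, function(i)
      fish_params(sprintf("G%d", i), asymptote_log_odds = logit(0.755),
                  test_log_odds = tests))
  }
}

#' Simulate a full study design
#'
#' `exp1`: eight fish trained on 3 vs 6, four rewarded on the smaller set and
#' four on the larger, then tested on 2 vs 3 or 6 vs 9 (relative rule on the
#' trained side), the reversed comparison, and the novel 5 vs 8. `exp2`: four
#' fish trained on 2 vs 3 (rewarded on the larger set, 3), then tested on
#' 3 vs 4 and 3 vs 6. Sessions are built by the protocol module; choices are
#' Bernoulli draws from each fish's generating parameters.
#'
#' @param design `"exp1"` or `"exp2"`.
#' @param fish_param_sets optional list of `fish_params` (one per fish);
#'   defaults to [paper_like_params()].
#' @param seed top-level seed; all randomness derives from it.
#' @param max_sessions training session budget per fish.
#' @return List with `choices` (validated choice table covering training and
#'   test phases), `manifest` (per-trial stimulus condition and seed) and
#'   `params` (the generating parameters).
#' @export
simulate_study <- function(design = c("exp1", "exp2"),
                           fish_param_sets = NULL, seed = 1,
                           max_sessions = 30) {
  design <- match.arg(design)
  if (is.null(fish_param_sets)) fish_param_sets <- paper_like_params(design)
  n_fish_needed <- if (design == "exp1") 8L else 4L
  if (length(fish_param_sets) != n_fish_needed)
    stop(design, " requires ", n_fish_needed, " fish parameter sets")
  with_seed_if(seed, {
    all_rows <- list()
    for (i in seq_along(fish_param_sets)) {
      fp <- fish_param_sets[[i]]
      if (design == "exp1") {
        rule <- if (i <= 4) "smaller" else "larger"
        training_cmp <- c(3L, 6L)
        tests <- if (rule == "smaller")
          list(`2v3` = c(2L, 3L), `6v9` = c(6L, 9L), `5v8` = c(5L, 8L))
        else
          list(`6v9` = c(6L, 9L), `2v3` = c(2L, 3L), `5v8` = c(5L, 8L))
      } else {
        rule <- "larger"
        training_cmp <- c(2L, 3L)
        tests <- list(`3v4` = c(3L, 4L), `3v6` = c(3L, 6L))
      }
      tr <- simulate_learning(fp, training_cmp, rule,
                              max_sessions = max_sessions,
                              experiment = design)
      te <- lapply(names(tests), function(lb)
        simulate_test_block(fp, tests[[lb]], training_cmp, rule, design, lb))
      all_rows[[i]] <- rbind(tr, do.call(rbind, te))
    }
    choices <- do.call(rbind, all_rows)
    rownames(choices) <- NULL
    validate_choice_table(choices)
    manifest <- choices[, c("fish_id", "phase", "session", "trial",
                            "comparison", "geometry_control",
                            "spatial_control", "stimulus_seed")]
    list(choices = choices, manifest = manifest, params = fish_param_sets)
  })
}
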