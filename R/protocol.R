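#' Build one 48-trial daily training session
#'
#' A daily session comprises 48 trials in which the magnitude controls are
#' crossed with fixed composition: 12 trials each of the two radius-fixed
#' conditions (`RF-ID`, `RF-CH`) and 6 trials each of the four area/perimeter
#' conditions (`A-ID`, `A-CH`, `P-ID`, `P-CH`). The target side is
#' counterbalanced 24 left / 24 right and the whole sequence shuffled.
#'
#' @param comparison length-2 integer vector `c(n_small, n_large)`.
#' @param rewarded_rule `"smaller"` or `"larger"`: which numerosity is
#'   rewarded.
#' @param seed integer seed; the plan is reproducible from it.
#' @param session_index session number recorded on each trial.
#' @return A `data.frame` session plan, one row per trial, with columns
#'   `session_index`, `trial_index`, `phase`, `condition`,
#'   `geometry_control`, `spatial_control`, `comparison`, `rewarded_rule`,
#'   `target_side`, `rewarded`, `probe`, `stimulus_seed`.
#' @export
build_training_session <- function(comparison, rewarded_rule = c("smaller", "larger"),
                                   seed = NULL, session_index = 1L) {
  rewarded_rule <- match.arg(rewarded_rule)
  counts <- c(`RF-ID` = 12L, `RF-CH` = 12L, `A-ID` = 6L, `A-CH` = 6L,
              `P-ID` = 6L, `P-CH` = 6L)
  make_session(comparison, counts, rewarded_rule, phase = "training",
               probe = FALSE, seed = seed, session_index = session_index)
}

#' Build a 3-day probe-test block
#'
#' Each test comprises 24 unrewarded probe trials with the novel comparison,
#' split into three testing days of 8 probes with composition
#' `{RF-ID: 2, RF-CH: 2, A-ID: 1, A-CH: 1, P-ID: 1, P-CH: 1}`. The probes are
#' shuffled among rewarded recall trials of the training comparison
#' (`recall_per_session` per day, default 32, composed in the training
#' proportions) to keep motivation high.
#'
#' @param test_comparison length-2 integer vector for the probe trials.
#' @param training_comparison length-2 integer vector for the recall trials.
#' @param rewarded_rule rewarded rule of the recall trials.
#' @param recall_per_session rewarded recall trials interleaved per day.
#' @param seed integer seed.
#' @return List of three `data.frame` session plans (as in
#'   [build_training_session()]); probe rows have `probe = TRUE`,
#'   `rewarded = FALSE` and `rewarded_rule = NA`.
#' @export
build_test_block <- function(test_comparison, training_comparison = test_comparison,
                             rewarded_rule = c("smaller", "larger"),
                             recall_per_session = 32L, seed = NULL) {
  rewarded_rule <- match.arg(rewarded_rule)
  probe_counts <- c(`RF-ID` = 2L, `RF-CH` = 2L, `A-ID` = 1L, `A-CH` = 1L,
                    `P-ID` = 1L, `P-CH` = 1L)
  # recall trials keep the training proportions (12:12:6:6:6:6 = 2:2:1:1:1:1)
  recall_counts <- round(recall_per_session *
                           c(`RF-ID` = 12, `RF-CH` = 12, `A-ID` = 6,
                             `A-CH` = 6, `P-ID` = 6, `P-CH` = 6) / 48)
  with_seed_if(seed, {
    lapply(1:3, function(day) {
      probes <- make_session(test_comparison, probe_counts,
                             rewarded_rule = NA_character_, phase = "probe",
                             probe = TRUE, seed = NULL, session_index = day,
                             shuffle = FALSE)
      recall <- make_session(training_comparison, recall_counts,
                             rewarded_rule, phase = "recall", probe = FALSE,
                             seed = NULL, session_index = day,
                             shuffle = FALSE)
      plan <- rbind(probes, recall)
      plan <- plan[sample.int(nrow(plan)), , drop = FALSE]
      plan$trial_index <- seq_len(nrow(plan))
      rownames(plan) <- NULL
      plan
    })
  })
}

make_session <- function(comparison, counts, rewarded_rule, phase, probe,
                         seed, session_index, shuffle = TRUE) {
  stopifnot(length(comparison) == 2, comparison[1] < comparison[2])
  n <- sum(counts)
  with_seed_if(seed, {
    condition <- rep(names(counts), counts)
    sides <- rep(c("left", "right"), length.out = n)  # balanced 50/50
    sides <- sample(sides)
    plan <- data.frame(
      session_index = session_index,
      trial_index = seq_len(n),
      phase = phase,
      condition = condition,
      stringsAsFactors = FALSE)
    plan$geometry_control <- vapply(plan$condition, function(cc)
      condition_from_code(cc)$geometry, character(1))
    plan$spatial_control <- vapply(plan$condition, function(cc)
      condition_from_code(cc)$spatial, character(1))
    plan$comparison <- paste0(comparison[1], "v", comparison[2])
    plan$rewarded_rule <- rewarded_rule
    plan$target_side <- sides
    plan$rewarded <- !probe
    plan$probe <- probe
    plan$stimulus_seed <- sample.int(.Machine$integer.max - 1L, n)
    if (shuffle) {
      plan <- plan[sample.int(n), , drop = FALSE]
      plan$trial_index <- seq_len(n)
      rownames(plan) <- NULL
    }
    plan
  })
}

#' Learning-criterion check over daily session accuracies
#'
#' The learning phase is complete at the first session whose accuracy and the
#' preceding session's accuracy are both at least `threshold` (boundary
#' inclusive: "at least 75%" counts 0.75).
#'
#' @param session_accuracies proportions correct per session, in `[0, 1]`,
#'   computed over responded trials.
#' @param threshold criterion accuracy.
#' @return List with `reached` (logical) and `first_session` (index of the
#'   second qualifying session, or `NA`).
#' @examples
#' criterion_reached(c(0.70, 0.76, 0.80))  # reached at session 3
#' @export
criterion_reached <- function(session_accuracies, threshold = 0.75) {
  stopifnot(all(session_accuracies >= 0 & session_accuracies <= 1))
  if (length(session_accuracies) >= 2) {
    hit <- which(session_accuracies[-1] >= threshold &
                 session_accuracies[-length(session_accuracies)] >= threshold)
    if (length(hit))
      return(list(reached = TRUE, first_session = hit[1] + 1L))
  }
  list(reached = FALSE, first_session = NA_integer_)
}

#' One-sided exact binomial tail for criterion performance
#'
#' Probability of at least `k` correct choices in `n` trials under chance
#' responding (p = 0.5), by direct summation of the binomial mass.
#'
#' @param k successes, `0 <= k <= n`.
#' @param n trials.
#' @return Upper-tail probability `P(X >= k)`.
#' @examples
#' criterion_binomial_p(36, 48)  # about 4.3e-4, comfortably below 0.01
#' @export
criterion_binomial_p <- function(k, n) {
  stopifnot(k >= 0, k <= n, n >= 1)
  sum(stats::dbinom(k:n, n, 0.5))
}
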