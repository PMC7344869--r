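#' Run the full analysis pipeline
#'
#' Executes the stages in order: network statistics -> standardization ->
#' BIC model selection -> four-state fit with semantic alignment -> Viterbi
#' decoding -> trajectory classification -> (optionally) the two-level
#' outcome regression. Accepts either a [simulate_cohort()] study or raw
#' edge-list / roster tables as read by [read_networks()].
#'
#' @param edges Edge list (data frame or CSV path), or a `synthetic_cohort`.
#' @param roster Roster table (ignored when `edges` is a study).
#' @param outcomes Optional outcome-record table for the regression stage
#'   (taken from the study when `edges` is a `synthetic_cohort`).
#' @param K_range Candidate state counts for BIC selection.
#' @param n_restarts EM restarts per candidate.
#' @param seed Integer seed controlling all fitting randomness.
#' @param max_iter,tol EM controls, passed to [mhmm_fit()].
#' @return A list of class `pipeline_report`: `seed`, `bic_table`, `best_K`,
#'   `fit` (aligned 4-state `mhmm_fit`), `transition`, `decoded`,
#'   `trajectories`, `trajectory_counts`, and when outcomes are supplied
#'   `outcome` (an `outcome_fit`) and `coefficients`.
#' @export
run_pipeline <- function(edges, roster = NULL, outcomes = NULL,
                         K_range = 2:6, n_restarts = 10L, seed = 1L,
                         max_iter = 300L, tol = 1e-6) {
  if (inherits(edges, "synthetic_cohort")) {
    study <- edges
    networks <- study$networks
    if (is.null(outcomes)) outcomes <- study$outcomes
  } else {
    if (is.null(roster)) abort("`roster` is required when passing an edge list.")
    networks <- read_networks(edges, roster)
  }
  panel <- build_panel(networks, standardize = TRUE)
  sel <- mhmm_select(panel, K_range = K_range, n_restarts = n_restarts,
                     seed = seed, max_iter = max_iter, tol = tol)
  fit4 <- if (!is.null(sel$fits[["4"]])) {
    align_states(sel$fits[["4"]])
  } else {
    mhmm_fit(panel, 4L, n_restarts = n_restarts, seed = seed,
             max_iter = max_iter, tol = tol)
  }
  decoded <- suppressMessages(mhmm_decode(panel, fit4))
  traj <- classify_trajectories(decoded)
  counts <- trajectory_summary(traj)
  report <- list(seed = seed, K_range = K_range, n_restarts = n_restarts,
                 bic_table = sel$table, best_K = sel$best_K, fit = fit4,
                 transition = fit4$params$A, decoded = decoded,
                 trajectories = traj, trajectory_counts = counts,
                 panel = panel)
  if (!is.null(outcomes)) {
    records <- outcomes |>
      dplyr::select(-dplyr::any_of("label")) |>
      dplyr::inner_join(traj[, c("participant_id", "label")],
                        by = "participant_id")
    report$outcome <- outcome_fit(records)
    report$coefficients <- report$outcome$coefficients
  }
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== Network-state pipeline report ==\n")
  cat(sprintf("seed %d; candidate states %s; BIC-selected K = %d\n",
              x$seed, paste(x$K_range, collapse = ","), x$best_K))
  cat("\nBIC table:\n")
  print(dplyr::mutate(x$bic_table,
                      dplyr::across(dplyr::where(is.numeric), ~ round(.x, 2))))
  cat("\nTransition matrix (1 = average, 2 = bridge, 3 = popular, 4 = isolated):\n")
  print(round(x$transition, 3))
  cat("\nTrajectory counts:\n")
  print(x$trajectory_counts)
  if (!is.null(x$coefficients)) {
    cat("\nTwo-level regression (minutes/day of sedentary behavior at follow-up):\n")
    print(dplyr::mutate(x$coefficients,
                        dplyr::across(dplyr::where(is.numeric), ~ round(.x, 2))))
  }
  invisible(x)
}

#' Write a machine-readable pipeline report
#'
#' Serializes the report's tables (BIC table, transition matrix, trajectory
#' counts, coefficient table) plus the seed and selection settings to JSON.
#'
#' @param report A `pipeline_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  payload <- list(
    seed = report$seed, K_range = report$K_range,
    n_restarts = report$n_restarts, best_K = report$best_K,
    bic_table = report$bic_table, transition = report$transition,
    trajectory_counts = report$trajectory_counts,
    state_roles = STATE_ROLES)
  if (!is.null(report$coefficients)) {
    payload$coefficients <- report$coefficients
    payload$n_used <- report$outcome$n_used
    payload$random_intercept_var <- report$outcome$random_intercept_var
    payload$residual_var <- report$outcome$residual_var
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
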