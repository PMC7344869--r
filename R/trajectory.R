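#' Classify three-wave state patterns into network trajectories
#'
#' Maps each participant's pattern of semantic network states across the
#' three waves (1 = average, 2 = bridge, 3 = popular, 4 = isolated, `NA` =
#' missing) onto one of four discrete network trajectories, applying the
#' rules in precedence order:
#'
#' 1. **Bridge** - the bridge state (2) occupied at any observed wave.
#' 2. **Isolated** - the isolated state (4) at all three waves; a missing
#'    wave disqualifies, since the pattern cannot be certified.
#' 3. **Popular** - the popular state (3) occupied at any observed wave and
#'    never the bridge state. (Occupancy at weeks 6 or 12 is the typical
#'    case; a week-3-only occurrence is labelled by the same rule and
#'    flagged in `rule_fired`.)
#' 4. **Average** - everything else: states 1 or 4 only, never prominent.
#'
#' @param patterns Tibble with `participant_id` and integer state columns
#'   `s_w3`, `s_w6`, `s_w12` (values 1-4 or `NA`), e.g. from
#'   [mhmm_decode()] on an aligned fit.
#' @return The input with `label` (factor Isolated/Bridge/Average/Popular)
#'   and `rule_fired` (text naming the matched clause) columns added.
#' @export
classify_trajectories <- function(patterns) {
  cols <- c("s_w3", "s_w6", "s_w12")
  if (!all(c("participant_id", cols) %in% names(patterns))) {
    abort("`patterns` needs columns participant_id, s_w3, s_w6, s_w12.")
  }
  s <- as.matrix(patterns[, cols])
  if (!all(s %in% c(1:4, NA))) abort("States must be in 1..4 or NA.")
  n_obs <- rowSums(!is.na(s))
  if (any(n_obs == 0L)) {
    abort("Participant(s) with all three waves missing; exclude them upstream.")
  }
  any_state <- function(k) rowSums(s == k, na.rm = TRUE) > 0L
  bridge <- any_state(2L)
  isolated <- !bridge & rowSums(s == 4L, na.rm = TRUE) == 3L
  popular <- !bridge & !isolated & any_state(3L)
  pop_late <- rowSums(s[, c("s_w6", "s_w12"), drop = FALSE] == 3L, na.rm = TRUE) > 0L
  label <- dplyr::case_when(bridge ~ "Bridge", isolated ~ "Isolated",
                            popular ~ "Popular", TRUE ~ "Average")
  rule <- dplyr::case_when(
    bridge ~ "bridge state at >=1 wave",
    isolated ~ "isolated state at all three waves",
    popular & pop_late ~ "popular state at week 6 or 12, never bridge",
    popular ~ "popular state at week 3 only, never bridge",
    TRUE ~ "only average/isolated states, never certified all-isolated"
  )
  patterns |>
    dplyr::mutate(
      label = factor(label, levels = c("Isolated", "Bridge", "Average", "Popular")),
      rule_fired = rule
    )
}

#' Trajectory counts and percentages for a cohort
#'
#' @param labels Output of [classify_trajectories()] (any tibble with a
#'   `label` column).
#' @return Tibble with one row per trajectory: `label`, `n`, `percent`
#'   (share of the cohort, one decimal).
#' @export
trajectory_summary <- function(labels) {
  if (nrow(labels) == 0L) abort("`labels` must be nonempty.")
  total <- nrow(labels)
  labels |>
    dplyr::count(.data$label, .drop = FALSE, name = "n") |>
    dplyr::mutate(percent = round(100 * .data$n / total, 1L))
}
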