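#' Daily wear and sedentary-minute summaries from epoch counts
#'
#' Applies the adult sedentary cut point to 1-minute accelerometer epochs: a
#' sedentary minute is a worn epoch with at most 100 counts. Wear within the
#' 05:00-23:59 daily window is tallied separately because the validity screen
#' is defined on that window.
#'
#' @param epochs Tibble with columns `participant_id`, `timestamp` (POSIXct
#'   or ISO-8601 text, strictly increasing at 1-minute spacing per
#'   participant), `counts` (nonnegative integers) and `worn` (0/1).
#' @return One row per participant-day: `participant_id`, `date`,
#'   `wear_minutes`, `sedentary_minutes`, `window_wear_minutes`.
#' @export
accel_daily <- function(epochs) {
  need <- c("participant_id", "timestamp", "counts", "worn")
  if (!all(need %in% names(epochs))) {
    abort(paste0("`epochs` needs columns: ", paste(need, collapse = ", ")))
  }
  ts <- epochs$timestamp
  if (!inherits(ts, "POSIXct")) ts <- as.POSIXct(ts, tz = "UTC")
  if (any(is.na(ts))) abort("Unparseable timestamps in `epochs`.")
  if (any(epochs$counts < 0)) abort("Counts must be nonnegative.")
  epochs <- epochs |>
    dplyr::mutate(.ts = ts) |>
    dplyr::arrange(.data$participant_id, .data$.ts)
  gaps <- epochs |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(bad = any(diff(as.numeric(.data$.ts)) <= 0), .groups = "drop")
  if (any(gaps$bad)) abort("Epoch timestamps must be strictly increasing (1-min spacing).")
  lt <- as.POSIXlt(epochs$.ts)
  minute_of_day <- lt$hour * 60L + lt$min
  epochs |>
    dplyr::mutate(
      date = as.Date(.data$.ts),
      in_window = minute_of_day >= 300L,  # [05:00, 23:59] inclusive
      worn = .data$worn == 1
    ) |>
    dplyr::group_by(.data$participant_id, .data$date) |>
    dplyr::summarise(
      wear_minutes = sum(.data$worn),
      sedentary_minutes = sum(.data$worn & .data$counts <= 100),
      window_wear_minutes = sum(.data$worn & .data$in_window),
      .groups = "drop"
    )
}

#' Wear-validity screen
#'
#' A participant's accelerometer record is valid when at least 3 weekdays and
#' at least 1 weekend day each reach 6 hours (360 minutes) of wear inside the
#' 05:00-23:59 window.
#'
#' @param daily Per-day summaries from [accel_daily()].
#' @return One row per participant: `participant_id`, `valid`, `reason`,
#'   `n_valid_weekdays`, `n_valid_weekend_days`.
#' @export
accel_screen <- function(daily) {
  daily |>
    dplyr::mutate(
      weekend = as.POSIXlt(.data$date)$wday %in% c(0L, 6L),
      qualifies = .data$window_wear_minutes >= 360
    ) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_valid_weekdays = sum(.data$qualifies & !.data$weekend),
      n_valid_weekend_days = sum(.data$qualifies & .data$weekend),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      valid = .data$n_valid_weekdays >= 3L & .data$n_valid_weekend_days >= 1L,
      reason = dplyr::case_when(
        valid ~ "valid",
        n_valid_weekdays < 3L & n_valid_weekend_days < 1L ~
          "fewer than 3 valid weekdays and no valid weekend day",
        n_valid_weekdays < 3L ~ "fewer than 3 valid weekdays",
        TRUE ~ "no valid weekend day"
      )
    )
}

#' Mean daily value over qualifying wear days
#'
#' Averages a per-day field over the days that meet the 6-hour window wear
#' rule (the days that count toward validity). Set `qualifying_only = FALSE`
#' to average over all days with any wear instead.
#'
#' @param daily Per-day summaries from [accel_daily()].
#' @param field Column to average (default `"sedentary_minutes"`).
#' @param qualifying_only Restrict to days with `window_wear_minutes >= 360`.
#' @return One row per participant: `participant_id`, `mean_daily` (`NA`
#'   when no day qualifies), `n_days`.
#' @export
accel_mean_daily <- function(daily, field = "sedentary_minutes",
                             qualifying_only = TRUE) {
  if (!field %in% names(daily)) abort(paste0("No column `", field, "` in `daily`."))
  keep <- if (qualifying_only) daily$window_wear_minutes >= 360 else daily$wear_minutes > 0
  daily[keep, ] |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(mean_daily = mean(.data[[field]]), n_days = dplyr::n(),
                     .groups = "drop") |>
    dplyr::right_join(dplyr::distinct(daily, .data$participant_id),
                      by = "participant_id") |>
    dplyr::mutate(n_days = dplyr::coalesce(.data$n_days, 0L))
}
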