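#' Plot per-state emission profiles
#'
#' Bar chart of the fitted (or configured) standardized means of the five
#' network statistics, one panel row of bars per latent state - the visual
#' signature by which states are interpreted as average, bridge, popular or
#' isolated.
#'
#' @param object An `mhmm_fit` (or `mhmm_params`).
#' @return A ggplot object.
#' @export
plot_state_profiles <- function(object) {
  params <- as_mhmm_params(object)
  aligned <- inherits(object, "mhmm_fit") && isTRUE(object$aligned)
  state_lab <- if (aligned) {
    paste0("State ", 1:4, " (", STATE_ROLES, ")")
  } else paste0("State ", seq_len(params$K))
  df <- tibble::as_tibble(params$mu) |>
    dplyr::mutate(state = factor(state_lab, levels = state_lab)) |>
    tidyr::pivot_longer(-"state", names_to = "statistic", values_to = "mean") |>
    dplyr::mutate(statistic = factor(.data$statistic, levels = STAT_NAMES))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$statistic, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(~state) +
    ggplot2::labs(x = NULL, y = "standardized mean",
                  title = "Latent state profiles of the network statistics") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @rdname plot_state_profiles
#' @param x An `mhmm_fit`.
#' @param ... Unused.
#' @method autoplot mhmm_fit
#' @export
autoplot.mhmm_fit <- function(x, ...) plot_state_profiles(x)

#' Plot latent-state prevalence over the three waves
#'
#' @param decoded Decoded state paths from [mhmm_decode()] (columns `s_w3`,
#'   `s_w6`, `s_w12`); semantic labels are used when states are 1-4.
#' @return A ggplot object.
#' @export
plot_state_prevalence <- function(decoded) {
  df <- decoded |>
    tidyr::pivot_longer(dplyr::all_of(c("s_w3", "s_w6", "s_w12")),
                        names_to = "wave", values_to = "state") |>
    dplyr::mutate(wave = as.integer(sub("s_w", "", .data$wave))) |>
    dplyr::count(.data$wave, .data$state) |>
    dplyr::group_by(.data$wave) |>
    dplyr::mutate(prevalence = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(state = factor(.data$state, levels = 1:4,
                                 labels = STATE_ROLES))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wave, y = .data$prevalence,
                                   colour = .data$state)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = WAVES) +
    ggplot2::labs(x = "intervention week", y = "prevalence (%)",
                  colour = "network state",
                  title = "Prevalence of latent network states over time") +
    ggplot2::theme_minimal()
}

#' Forest plot of the outcome-model coefficients
#'
#' @param object An `outcome_fit`.
#' @return A ggplot object.
#' @export
plot_outcome_effects <- function(object) {
  df <- object$coefficients |>
    dplyr::filter(.data$term != "Intercept") |>
    dplyr::mutate(term = factor(.data$term, levels = rev(.data$term)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lower95,
                                         xmax = .data$upper95), height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "effect on follow-up sedentary minutes/day", y = NULL,
                  title = "Two-level regression estimates (95% Wald CI)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_outcome_effects
#' @param x An `outcome_fit`.
#' @param ... Unused.
#' @method autoplot outcome_fit
#' @export
autoplot.outcome_fit <- function(x, ...) plot_outcome_effects(x)
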