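#' Two-level regression of follow-up sedentary minutes on network trajectory
#'
#' Fits a linear mixed model with a random intercept per intervention group
#' (REML) relating mean daily sedentary minutes at 12-month follow-up to the
#' network trajectory, adjusting for baseline sedentary minutes, sex, age,
#' pregnancy status (weeks pregnant / weeks since birth), follow-up wear
#' time, site and group size. Reference levels are trajectory = Isolated
#' (theoretically least likely to benefit from the group network),
#' sex = male, site = site2.
#'
#' Incomplete records are dropped listwise with a message. Wald 95% CIs and
#' p-values use a residual degrees-of-freedom approximation
#' (`n_used - n_fixed_effects`).
#'
#' @param records Tibble with columns `participant_id`, `group_id`, `label`
#'   (trajectory factor), `sed_12m`, `sed_base`, `sex` ("female"/"male"),
#'   `age`, `weeks_pregnant`, `weeks_since_birth`, `wear_12m`, `site`
#'   ("site1"/"site2"), `group_size`.
#' @return An object of class `outcome_fit`: `coefficients` (tidy table),
#'   `random_intercept_var`, `residual_var`, `n_used`, `n_dropped`, `model`
#'   (the underlying `lmerMod`).
#' @export
outcome_fit <- function(records) {
  need <- c("participant_id", "group_id", "label", "sed_12m", "sed_base", "sex",
            "age", "weeks_pregnant", "weeks_since_birth", "wear_12m", "site",
            "group_size")
  if (!all(need %in% names(records))) {
    abort(paste0("`records` needs columns: ",
                 paste(setdiff(need, names(records)), collapse = ", ")))
  }
  d <- records |>
    dplyr::mutate(
      label = factor(as.character(.data$label),
                     levels = c("Isolated", "Popular", "Bridge", "Average")),
      sex = factor(.data$sex, levels = c("male", "female")),
      site = factor(.data$site, levels = c("site2", "site1")),
      group_id = as.character(.data$group_id)
    )
  complete <- complete.cases(d[, need])
  n_dropped <- sum(!complete)
  if (n_dropped > 0L) {
    inform(sprintf("Dropping %d incomplete record(s) listwise; %d used.",
                   n_dropped, sum(complete)))
  }
  d <- d[complete, ]
  if (dplyr::n_distinct(d$group_id) < 2L) abort("At least 2 groups are required.")
  present <- table(d$label)
  if (any(present == 0L)) {
    abort(paste0("Trajectory level(s) absent from the data (singular design): ",
                 paste(names(present)[present == 0L], collapse = ", ")))
  }
  # near-constant covariates (e.g. an all-female sample, a single site or a
  # uniform group size) cannot be estimated; drop them with a message
  rhs <- c("label", "sed_base", "sex", "age", "weeks_pregnant",
           "weeks_since_birth", "wear_12m", "site", "group_size")
  estimable <- vapply(rhs, function(v) {
    x <- d[[v]]
    if (is.factor(x)) dplyr::n_distinct(droplevels(x)) >= 2L
    else dplyr::n_distinct(x) >= 2L
  }, logical(1))
  if (any(!estimable)) {
    inform(paste0("Dropping constant term(s): ",
                  paste(rhs[!estimable], collapse = ", ")))
    rhs <- rhs[estimable]
  }
  form <- stats::reformulate(c(rhs, "(1 | group_id)"), response = "sed_12m")
  model <- lme4::lmer(form, data = d, REML = TRUE,
                      control = lme4::lmerControl(check.conv.singular = "ignore"))
  beta <- lme4::fixef(model)
  se <- sqrt(diag(as.matrix(stats::vcov(model))))
  n_used <- nrow(d)
  df <- n_used - length(beta)
  tcrit <- qt(0.975, df)
  coefs <- tibble::tibble(
    term = pretty_terms(names(beta)),
    estimate = unname(beta),
    std_error = unname(se),
    lower95 = unname(beta - tcrit * se),
    upper95 = unname(beta + tcrit * se),
    p_value = unname(2 * pt(-abs(beta / se), df))
  )
  vc <- as.data.frame(lme4::VarCorr(model))
  structure(
    list(coefficients = coefs,
         random_intercept_var = vc$vcov[vc$grp == "group_id"],
         residual_var = vc$vcov[vc$grp == "Residual"],
         n_used = n_used, n_dropped = n_dropped, df = df, model = model,
         fixed_terms = rhs),
    class = "outcome_fit"
  )
}

pretty_terms <- function(x) {
  map <- c("(Intercept)" = "Intercept",
           "labelPopular" = "Popular", "labelBridge" = "Bridge",
           "labelAverage" = "Average", "sed_base" = "sed_base",
           "sexfemale" = "female", "age" = "age",
           "weeks_pregnant" = "weeks_pregnant",
           "weeks_since_birth" = "weeks_since_birth", "wear_12m" = "wear_12m",
           "sitesite1" = "site1", "group_size" = "group_size")
  ifelse(x %in% names(map), unname(map[x]), x)
}

#' @export
print.outcome_fit <- function(x, ...) {
  cat(sprintf("<outcome_fit> two-level regression, %d participants used (%d dropped)\n",
              x$n_used, x$n_dropped))
  cat(sprintf("  random-intercept SD = %.2f, residual SD = %.2f min/day\n",
              sqrt(x$random_intercept_var), sqrt(x$residual_var)))
  print(dplyr::mutate(x$coefficients,
                      dplyr::across(dplyr::where(is.numeric), ~ round(.x, 3))))
  invisible(x)
}

#' @rdname outcome_fit
#' @param x,object An `outcome_fit`.
#' @param ... Unused.
#' @method tidy outcome_fit
#' @export
tidy.outcome_fit <- function(x, ...) x$coefficients

#' @rdname outcome_fit
#' @method glance outcome_fit
#' @export
glance.outcome_fit <- function(x, ...) {
  tibble::tibble(n_used = x$n_used, n_dropped = x$n_dropped,
                 random_intercept_var = x$random_intercept_var,
                 residual_var = x$residual_var,
                 REMLcrit = lme4::REMLcrit(x$model))
}

#' Predicted follow-up sedentary minutes
#'
#' Linear predictor for new records; the group random effect is added for
#' groups seen during fitting and set to 0 for unseen groups.
#'
#' @param object An `outcome_fit`.
#' @param newdata Records with the same columns as used in [outcome_fit()].
#' @param ... Unused.
#' @return Numeric vector of expected `sed_12m` values.
#' @export
predict.outcome_fit <- function(object, newdata, ...) {
  d <- newdata |>
    dplyr::mutate(
      label = factor(as.character(.data$label),
                     levels = c("Isolated", "Popular", "Bridge", "Average")),
      sex = factor(.data$sex, levels = c("male", "female")),
      site = factor(.data$site, levels = c("site2", "site1"))
    )
  if (any(is.na(d$label)) || any(is.na(d$sex)) || any(is.na(d$site))) {
    abort("Unknown factor level in `newdata` (trajectory, sex or site).")
  }
  X <- stats::model.matrix(stats::reformulate(object$fixed_terms), data = d)
  beta <- lme4::fixef(object$model)
  X <- X[, names(beta), drop = FALSE]
  eta <- as.vector(X %*% beta)
  re <- lme4::ranef(object$model)$group_id
  offsets <- re[as.character(d$group_id), 1L]
  offsets[is.na(offsets)] <- 0
  eta + offsets
}

#' Write the coefficient table as CSV
#'
#' @param fit An `outcome_fit`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_coefficients_csv <- function(fit, path) {
  readr::write_csv(fit$coefficients, path)
  invisible(path)
}
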