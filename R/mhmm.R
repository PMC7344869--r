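#' Multivariate hidden Markov model parameters
#'
#' Parameters of a K-state hidden Markov chain over the three survey waves,
#' with a multivariate Gaussian emission per state over the five standardized
#' network statistics (diagonal covariance).
#'
#' @param pi Initial state distribution (length K, sums to 1).
#' @param A K x K row-stochastic transition matrix; `A[r, s]` is the
#'   probability of moving from state `r` at one wave to state `s` at the
#'   next.
#' @param mu K x D matrix of emission means (standardized-statistic units).
#' @param sigma2 K x D matrix of emission variances (all > 0).
#' @param dim_names Names of the D emission dimensions.
#'
#' @return An object of class `mhmm_params`.
#' @export
mhmm_params <- function(pi, A, mu, sigma2, dim_names = STAT_NAMES) {
  pi <- as.numeric(pi)
  A <- as.matrix(A)
  mu <- as.matrix(mu)
  sigma2 <- as.matrix(sigma2)
  K <- length(pi)
  if (!all(dim(A) == c(K, K))) abort("`A` must be K x K.")
  if (nrow(mu) != K || nrow(sigma2) != K) abort("`mu` and `sigma2` must have K rows.")
  if (ncol(mu) != ncol(sigma2)) abort("`mu` and `sigma2` must have matching columns.")
  if (abs(sum(pi) - 1) > 1e-9) abort("`pi` must sum to 1.")
  if (any(abs(rowSums(A) - 1) > 1e-9)) abort("Rows of `A` must sum to 1.")
  if (any(pi < 0) || any(A < 0)) abort("Probabilities must be nonnegative.")
  if (any(sigma2 <= 0)) abort("All emission variances must be positive.")
  if (is.null(dim_names)) dim_names <- paste0("d", seq_len(ncol(mu)))
  dimnames(mu) <- dimnames(sigma2) <- list(NULL, dim_names)
  dimnames(A) <- NULL
  pi <- unname(pi)
  structure(list(K = K, pi = pi, A = A, mu = mu, sigma2 = sigma2,
                 dim_names = dim_names),
            class = "mhmm_params")
}

#' @export
print.mhmm_params <- function(x, ...) {
  cat(sprintf("<mhmm_params> %d states, %d emission dimensions\n", x$K, ncol(x$mu)))
  cat("Transition matrix:\n")
  print(round(x$A, 3))
  invisible(x)
}

# ---- internal: panel <-> observation array -------------------------------

# Long panel (participant_id, wave, five statistics) -> N x T x D array with
# NA for unobserved entries. Participants with no observed slot are dropped
# with a message (they are excluded from analysis upstream by design).
panel_to_array <- function(panel, dim_names = STAT_NAMES) {
  if (!all(c("participant_id", "wave") %in% names(panel)) ||
      !all(dim_names %in% names(panel))) {
    abort(paste0("Panel must have participant_id, wave and columns: ",
                 paste(dim_names, collapse = ", ")))
  }
  if (!all(panel$wave %in% WAVES)) abort("Panel `wave` values must be in {3, 6, 12}.")
  if (anyDuplicated(panel[, c("participant_id", "wave")])) {
    abort("Duplicated (participant, wave) rows in panel.")
  }
  vals <- as.matrix(panel[, dim_names])
  if (any(is.infinite(vals)) || any(is.nan(vals))) {
    abort("Panel contains non-finite statistic values.")
  }
  ids <- unique(panel$participant_id)
  N <- length(ids); T_ <- length(WAVES); D <- length(dim_names)
  y <- array(NA_real_, c(N, T_, D), dimnames = list(ids, paste0("w", WAVES), dim_names))
  ni <- match(panel$participant_id, ids)
  ti <- match(panel$wave, WAVES)
  for (d in seq_len(D)) y[cbind(ni, ti, d)] <- vals[, d]
  observed <- apply(!is.na(y), 1L, any)
  if (!all(observed)) {
    inform(sprintf("Dropping %d participant(s) with no observed wave.", sum(!observed)))
    y <- y[observed, , , drop = FALSE]
    ids <- ids[observed]
  }
  list(y = y, ids = ids)
}

# Per-slot emission log-densities: N x T x K. Missing dimensions are
# marginalized out (diagonal covariance makes this a simple drop), so a fully
# missing slot contributes log-likelihood 0.
emission_logdensity <- function(y, params) {
  N <- dim(y)[1L]; T_ <- dim(y)[2L]; D <- dim(y)[3L]; K <- params$K
  logB <- array(0, c(N, T_, K))
  for (k in seq_len(K)) {
    for (d in seq_len(D)) {
      ll <- dnorm(y[, , d, drop = FALSE], params$mu[k, d],
                  sqrt(params$sigma2[k, d]), log = TRUE)
      ll[is.na(ll)] <- 0
      logB[, , k] <- logB[, , k] + ll[, , 1L]
    }
  }
  logB
}

# Forward-backward in log space, vectorised over sequences.
# Returns per-sequence loglik, posteriors gamma (N x T x K) and the summed
# expected transition counts (K x K).
forward_backward <- function(y, params) {
  N <- dim(y)[1L]; T_ <- dim(y)[2L]; K <- params$K
  logB <- emission_logdensity(y, params)
  logpi <- log(params$pi); logA <- log(params$A)
  alpha <- vector("list", T_); beta <- vector("list", T_)
  alpha[[1L]] <- matrix(logpi, N, K, byrow = TRUE) + logB[, 1L, , drop = TRUE]
  if (N == 1L) alpha[[1L]] <- matrix(alpha[[1L]], 1L, K)
  for (t in 2:T_) {
    at <- matrix(0, N, K)
    for (k in seq_len(K)) {
      at[, k] <- row_log_sum_exp(alpha[[t - 1L]] +
                                   matrix(logA[, k], N, K, byrow = TRUE))
    }
    bt <- logB[, t, , drop = TRUE]
    if (N == 1L) bt <- matrix(bt, 1L, K)
    alpha[[t]] <- at + bt
  }
  loglik <- row_log_sum_exp(alpha[[T_]])
  beta[[T_]] <- matrix(0, N, K)
  for (t in (T_ - 1L):1L) {
    bt1 <- logB[, t + 1L, , drop = TRUE]
    if (N == 1L) bt1 <- matrix(bt1, 1L, K)
    nxt <- beta[[t + 1L]] + bt1
    bt <- matrix(0, N, K)
    for (j in seq_len(K)) {
      bt[, j] <- row_log_sum_exp(nxt + matrix(logA[j, ], N, K, byrow = TRUE))
    }
    beta[[t]] <- bt
  }
  gamma <- array(0, c(N, T_, K))
  for (t in seq_len(T_)) {
    gamma[, t, ] <- exp(alpha[[t]] + beta[[t]] - loglik)
  }
  xi <- matrix(0, K, K)
  for (t in seq_len(T_ - 1L)) {
    bt1 <- logB[, t + 1L, , drop = TRUE]
    if (N == 1L) bt1 <- matrix(bt1, 1L, K)
    for (j in seq_len(K)) {
      for (k in seq_len(K)) {
        xi[j, k] <- xi[j, k] + sum(exp(alpha[[t]][, j] + logA[j, k] +
                                         bt1[, k] + beta[[t + 1L]][, k] - loglik))
      }
    }
  }
  list(loglik = loglik, gamma = gamma, xi = xi)
}

#' Posterior state probabilities per participant-wave
#'
#' Runs the exact log-space forward-backward recursion and returns the
#' posterior probability of each latent state at each wave, together with the
#' participant's log-likelihood contribution. Waves with no observed
#' statistics are marginalized (the chain prior propagates through them).
#'
#' @param panel A (standardized) person-wave panel as from [build_panel()]
#'   or [mhmm_simulate()].
#' @param object An `mhmm_params` or fitted `mhmm_fit` object.
#' @return Tibble with `participant_id`, `wave`, one `gamma_<k>` column per
#'   state, and `loglik` (the per-participant contribution, repeated across
#'   that participant's rows).
#' @export
mhmm_posterior <- function(panel, object) {
  params <- as_mhmm_params(object)
  dat <- panel_to_array(panel, params$dim_names)
  fb <- forward_backward(dat$y, params)
  N <- length(dat$ids); T_ <- length(WAVES)
  out <- tidyr::expand_grid(participant_id = dat$ids, wave = WAVES)
  for (k in seq_len(params$K)) {
    out[[paste0("gamma_", k)]] <- as.vector(t(fb$gamma[, , k]))
  }
  out$loglik <- rep(fb$loglik, each = T_)
  out
}

as_mhmm_params <- function(object) {
  if (inherits(object, "mhmm_fit")) return(object$params)
  if (inherits(object, "mhmm_params")) return(object)
  abort("Expected an `mhmm_params` or `mhmm_fit` object.")
}

# ---- EM ------------------------------------------------------------------

n_mhmm_params <- function(K, D) (K - 1) + K * (K - 1) + 2 * K * D

rdirichlet1 <- function(K) {
  g <- stats::rgamma(K, shape = 1)
  g / sum(g)
}

init_params <- function(y, K, restart) {
  D <- dim(y)[3L]
  flat <- matrix(aperm(y, c(2, 1, 3)), ncol = D)
  colnames(flat) <- dimnames(y)[[3L]]
  cc <- flat[complete.cases(flat), , drop = FALSE]
  if (nrow(cc) < 2L * K) {
    # too few complete rows: mean-impute for initialisation only
    cc <- apply(flat, 2L, function(col) {
      col[is.na(col)] <- mean(col, na.rm = TRUE); col
    })
  }
  centers <- tryCatch(
    kmeans(cc, centers = K, nstart = 1L, iter.max = 25L)$centers,
    error = function(e) cc[sample.int(nrow(cc), K), , drop = FALSE]
  )
  mu <- centers + matrix(rnorm(K * D, 0, 0.1), K, D)
  v <- apply(cc, 2L, var)
  v[!is.finite(v) | v <= 0] <- 1
  sigma2 <- matrix(rep(v, each = K), K, D)
  pi <- rdirichlet1(K)
  A <- t(sapply(seq_len(K), function(i) rdirichlet1(K)))
  if (K == 1L) A <- matrix(1, 1, 1)
  mhmm_params(pi, A, mu, sigma2, dim_names = dimnames(y)[[3L]])
}

em_single <- function(y, K, init, tol, max_iter, var_floor = 1e-4) {
  N <- dim(y)[1L]; T_ <- dim(y)[2L]; D <- dim(y)[3L]
  params <- init
  obs <- !is.na(y)
  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    fb <- forward_backward(y, params)
    ll <- sum(fb$loglik)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_prev) && abs(ll - ll_prev) <= tol * abs(ll_prev)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    g <- fb$gamma
    state_mass <- apply(g, 3L, sum)
    if (any(state_mass < 1e-6)) {
      return(list(degenerate = TRUE))
    }
    pi_new <- colMeans(g[, 1L, , drop = FALSE][, 1L, ])
    if (K == 1L) pi_new <- 1
    rs <- rowSums(fb$xi)
    A_new <- params$A  # rows with no expected occupancy keep their prior value
    ok_rows <- rs > 1e-10
    A_new[ok_rows, ] <- fb$xi[ok_rows, , drop = FALSE] / rs[ok_rows]
    if (K == 1L) A_new <- matrix(1, 1, 1)
    mu_new <- params$mu
    s2_new <- params$sigma2
    for (k in seq_len(K)) {
      for (d in seq_len(D)) {
        w <- g[, , k] * obs[, , d]
        sw <- sum(w)
        if (sw < 1e-10) next
        yk <- y[, , d]
        m <- sum(w * yk, na.rm = TRUE) / sw
        v <- sum(w * (yk - m)^2, na.rm = TRUE) / sw
        mu_new[k, d] <- m
        s2_new[k, d] <- max(v, var_floor)
      }
    }
    params <- mhmm_params(pi_new / sum(pi_new), A_new, mu_new, s2_new,
                          dim_names = params$dim_names)
  }
  list(degenerate = FALSE, params = params, loglik = ll_trace[length(ll_trace)],
       ll_trace = ll_trace, n_iter = length(ll_trace), converged = converged)
}

#' Fit a K-state multivariate hidden Markov model by EM
#'
#' Baum-Welch EM with multiple seeded random restarts. Emission means are
#' initialised k-means-style on the pooled person-wave observations; the
#' initial distribution and transition rows are drawn Dirichlet(1). Missing
#' waves (and individually missing statistics within a wave) are marginalized
#' in the likelihood under a missing-at-random assumption. Emission variances
#' are floored at `var_floor` to prevent degenerate collapse.
#'
#' When `K = 4` the fitted states are automatically relabeled to the
#' canonical semantic order (1 = average, 2 = bridge, 3 = popular,
#' 4 = isolated) via [align_states()].
#'
#' @param panel Standardized person-wave panel (see [build_panel()]).
#' @param K Number of latent states.
#' @param n_restarts Number of random restarts (best log-likelihood wins).
#' @param seed Integer seed controlling all restarts.
#' @param tol Relative log-likelihood change declaring convergence.
#' @param max_iter Maximum EM iterations per restart.
#' @param var_floor Lower bound on emission variances (standardized scale).
#' @param align Relabel states semantically when `K == 4` (default `TRUE`).
#' @param pi_zero_states Optional state indices whose initial-distribution
#'   mass is constrained to zero (e.g. a state known to be unoccupied at
#'   the first wave). Off by default; the initial distribution is otherwise
#'   estimated freely.
#'
#' @return An object of class `mhmm_fit` with elements `params`, `loglik`,
#'   `bic`, `n_iter`, `converged`, `restarts_used`, `seed`, `N`, `ll_trace`,
#'   and (when aligned) `roles`.
#' @export
mhmm_fit <- function(panel, K, n_restarts = 20L, seed = 1L, tol = 1e-6,
                     max_iter = 500L, var_floor = 1e-4, align = TRUE,
                     pi_zero_states = integer(0)) {
  if (K < 1L) abort("`K` must be a positive integer.")
  dat <- panel_to_array(panel)
  N <- dim(dat$y)[1L]
  if (N < 10L * K) {
    warn(sprintf("Only %d sequences for K = %d states; at least %d recommended.",
                 N, K, 10L * K))
  }
  best <- NULL
  degenerate_all <- TRUE
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    init <- init_params(dat$y, K, r)
    if (length(pi_zero_states) > 0L) {
      # zero initial mass is absorbing under EM, so constraining the
      # initialization constrains every iteration
      pi0 <- init$pi
      pi0[pi_zero_states] <- 0
      if (sum(pi0) <= 0) pi0 <- rep(1, K) * !(seq_len(K) %in% pi_zero_states)
      init <- mhmm_params(pi0 / sum(pi0), init$A, init$mu, init$sigma2,
                          dim_names = init$dim_names)
    }
    res <- em_single(dat$y, K, init, tol = tol, max_iter = max_iter,
                     var_floor = var_floor)
    if (isTRUE(res$degenerate)) next
    degenerate_all <- FALSE
    if (is.null(best) || res$loglik > best$loglik) best <- res
  }
  if (degenerate_all) {
    abort(sprintf("All %d restarts produced a degenerate (empty) state; try a smaller K.",
                  n_restarts))
  }
  D <- dim(dat$y)[3L]
  p <- n_mhmm_params(K, D)
  fit <- structure(
    list(params = best$params, loglik = best$loglik,
         bic = -2 * best$loglik + p * log(N),
         n_params = p, n_iter = best$n_iter, converged = best$converged,
         restarts_used = n_restarts, seed = seed, N = N,
         ll_trace = best$ll_trace, aligned = FALSE, roles = NULL),
    class = "mhmm_fit"
  )
  if (align && K == 4L) fit <- align_states(fit)
  fit
}

#' @export
print.mhmm_fit <- function(x, ...) {
  cat(sprintf("<mhmm_fit> K = %d states, N = %d sequences\n", x$params$K, x$N))
  cat(sprintf("  loglik = %.2f, BIC = %.2f, %d EM iterations (%s)\n",
              x$loglik, x$bic, x$n_iter,
              if (x$converged) "converged" else "not converged"))
  if (x$aligned) {
    cat("  states: 1 = average, 2 = bridge, 3 = popular, 4 = isolated\n")
  }
  invisible(x)
}

#' @rdname mhmm_fit
#' @param x,object An `mhmm_fit`.
#' @param matrix For `tidy()`: which component to tidy, `"means"` (emission
#'   means, long), `"transition"` or `"initial"`.
#' @param ... Unused.
#' @method tidy mhmm_fit
#' @export
tidy.mhmm_fit <- function(x, matrix = c("means", "transition", "initial"), ...) {
  matrix <- match.arg(matrix)
  p <- x$params
  state_lab <- if (x$aligned) STATE_ROLES else as.character(seq_len(p$K))
  switch(matrix,
    means = tibble::as_tibble(p$mu) |>
      dplyr::mutate(state = state_lab, .before = 1L) |>
      tidyr::pivot_longer(-"state", names_to = "statistic", values_to = "mean") |>
      dplyr::left_join(
        tibble::as_tibble(p$sigma2) |>
          dplyr::mutate(state = state_lab) |>
          tidyr::pivot_longer(-"state", names_to = "statistic", values_to = "variance"),
        by = c("state", "statistic")
      ),
    transition = tidyr::expand_grid(from = state_lab, to = state_lab) |>
      dplyr::mutate(probability = as.vector(t(p$A))),
    initial = tibble::tibble(state = state_lab, probability = p$pi)
  )
}

#' @rdname mhmm_fit
#' @method glance mhmm_fit
#' @export
glance.mhmm_fit <- function(x, ...) {
  tibble::tibble(K = x$params$K, loglik = x$loglik, bic = x$bic,
                 n_params = x$n_params, n_iter = x$n_iter,
                 converged = x$converged, N = x$N, seed = x$seed)
}

#' Select the number of latent states by BIC
#'
#' Fits the model over a range of K and reports, for each K, the BIC
#' (`-2 loglik + p log N`, with N the number of participant sequences)
#' alongside the secondary parsimony diagnostics used to judge candidate
#' solutions: the smallest state occupancy (share of decoded person-waves in
#' the least-used state) and the smallest pairwise separation of emission
#' means. The minimal-BIC K is returned; the diagnostics let the analyst
#' apply substantive parsimony judgment when BIC values are close.
#'
#' @param panel Standardized person-wave panel.
#' @param K_range Integer vector of candidate state counts (default 2:6).
#' @inheritParams mhmm_fit
#' @return A list with `best_K` (minimal BIC), `table` (one row per K) and
#'   `fits` (named list of `mhmm_fit` objects for the Ks that fit).
#' @export
mhmm_select <- function(panel, K_range = 2:6, n_restarts = 20L, seed = 1L,
                        tol = 1e-6, max_iter = 500L) {
  if (length(K_range) == 0L) abort("`K_range` must be nonempty.")
  fits <- list()
  rows <- purrr::map(seq_along(K_range), function(i) {
    K <- K_range[[i]]
    res <- tryCatch(
      mhmm_fit(panel, K, n_restarts = n_restarts, seed = seed + 1000L * i,
               tol = tol, max_iter = max_iter, align = FALSE),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      return(tibble::tibble(K = K, loglik = NA_real_, bic = NA_real_,
                            converged = NA, min_occupancy = NA_real_,
                            min_separation = NA_real_,
                            error = conditionMessage(res)))
    }
    fits[[as.character(K)]] <<- res
    paths <- suppressMessages(mhmm_decode(panel, res))
    decoded <- unlist(paths[, c("s_w3", "s_w6", "s_w12")])
    occ <- tabulate(decoded, nbins = K) / length(decoded)
    seps <- if (K >= 2L) {
      min(stats::dist(res$params$mu))
    } else NA_real_
    tibble::tibble(K = K, loglik = res$loglik, bic = res$bic,
                   converged = res$converged, min_occupancy = min(occ),
                   min_separation = seps, error = NA_character_)
  })
  table <- dplyr::bind_rows(rows)
  ok <- !is.na(table$bic)
  if (!any(ok)) abort("No candidate K could be fitted.")
  best_K <- table$K[ok][which.min(table$bic[ok])]
  list(best_K = best_K, table = table, fits = fits)
}

#' Viterbi decoding of latent state paths
#'
#' Maximum-probability state path per participant, computed in log space;
#' ties are broken toward the lowest state index. Missing waves are
#' marginalized, so every participant gets a full three-wave path.
#'
#' @inheritParams mhmm_posterior
#' @return Tibble with `participant_id` and state columns `s_w3`, `s_w6`,
#'   `s_w12` (semantic indices if the fit was aligned).
#' @export
mhmm_decode <- function(panel, object) {
  params <- as_mhmm_params(object)
  dat <- panel_to_array(panel, params$dim_names)
  y <- dat$y
  N <- dim(y)[1L]; T_ <- dim(y)[2L]; K <- params$K
  logB <- emission_logdensity(y, params)
  logpi <- log(params$pi); logA <- log(params$A)
  delta <- matrix(logpi, N, K, byrow = TRUE) + logB[, 1L, , drop = TRUE]
  if (N == 1L) delta <- matrix(delta, 1L, K)
  psi <- array(0L, c(N, T_, K))
  for (t in 2:T_) {
    newd <- matrix(0, N, K)
    for (k in seq_len(K)) {
      cand <- delta + matrix(logA[, k], N, K, byrow = TRUE)
      arg <- max.col(cand, ties.method = "first")
      psi[, t, k] <- arg
      newd[, k] <- cand[cbind(seq_len(N), arg)] + logB[, t, k]
    }
    delta <- newd
  }
  path <- matrix(0L, N, T_)
  path[, T_] <- max.col(delta, ties.method = "first")
  for (t in (T_ - 1L):1L) {
    path[, t] <- psi[cbind(seq_len(N), t + 1L, path[, t + 1L])]
  }
  tibble::tibble(participant_id = dat$ids,
                 s_w3 = path[, 1L], s_w6 = path[, 2L], s_w12 = path[, 3L])
}

#' Simulate observation sequences from an MHMM
#'
#' States are drawn from the initial distribution and transition matrix;
#' observations from the state Gaussians. Whole waves are masked missing
#' independently at `missing_rate`, emulating survey non-response.
#'
#' @param object `mhmm_params` or `mhmm_fit`.
#' @param n_seq Number of participant sequences.
#' @param missing_rate Probability a wave's observation is missing.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list with `panel` (long tibble: `participant_id`, `wave`, one
#'   column per emission dimension) and `states` (tibble of true paths:
#'   `s_w3`, `s_w6`, `s_w12`).
#' @export
mhmm_simulate <- function(object, n_seq, missing_rate = 0, seed = 1L) {
  params <- as_mhmm_params(object)
  if (missing_rate < 0 || missing_rate >= 1) abort("`missing_rate` must be in [0, 1).")
  set.seed(seed)
  K <- params$K; T_ <- length(WAVES); D <- ncol(params$mu)
  states <- matrix(0L, n_seq, T_)
  states[, 1L] <- sample.int(K, n_seq, replace = TRUE, prob = params$pi)
  for (t in 2:T_) {
    u <- runif(n_seq)
    cum <- t(apply(params$A, 1L, cumsum))
    states[, t] <- vapply(seq_len(n_seq), function(n) {
      which(u[n] <= cum[states[n, t - 1L], ])[1L]
    }, integer(1))
  }
  ids <- sprintf("sim%05d", seq_len(n_seq))
  rows <- tidyr::expand_grid(participant_id = ids, wave = WAVES)
  s_flat <- as.vector(t(states))
  obs <- matrix(rnorm(n_seq * T_ * D,
                      mean = params$mu[s_flat, , drop = FALSE],
                      sd = sqrt(params$sigma2[s_flat, , drop = FALSE])),
                ncol = D)
  colnames(obs) <- params$dim_names
  mask <- runif(n_seq * T_) < missing_rate
  obs[mask, ] <- NA_real_
  panel <- dplyr::bind_cols(rows, tibble::as_tibble(obs))
  list(panel = panel,
       states = tibble::tibble(participant_id = ids, s_w3 = states[, 1L],
                               s_w6 = states[, 2L], s_w12 = states[, 3L]))
}

#' Relabel a fitted four-state model into semantic roles
#'
#' Assigns roles from the fitted emission means on the standardized scale:
#' the bridge state has the highest mean betweenness; among the remainder the
#' popular state has the highest mean indegree + outdegree; among the
#' remainder the isolated state has the lowest mean
#' indegree + outdegree + density; the last state is average. States are then
#' renumbered 1 = average, 2 = bridge, 3 = popular, 4 = isolated.
#'
#' @param object `mhmm_fit` or `mhmm_params` with exactly 4 states.
#' @return The same class of object with permuted states; fits gain a
#'   `roles` tibble mapping new index, role and original index.
#' @export
align_states <- function(object) {
  params <- as_mhmm_params(object)
  if (params$K != 4L) abort("Semantic alignment is defined for 4-state models only.")
  mu <- params$mu
  idx <- seq_len(4L)
  bridge <- idx[which.max(mu[, "betweenness"])]
  rest <- setdiff(idx, bridge)
  popular <- rest[which.max(mu[rest, "indegree"] + mu[rest, "outdegree"])]
  rest <- setdiff(rest, popular)
  isolated <- rest[which.min(mu[rest, "indegree"] + mu[rest, "outdegree"] +
                               mu[rest, "density"])]
  average <- setdiff(rest, isolated)
  ord <- c(average, bridge, popular, isolated)
  if (anyDuplicated(ord)) {
    abort(paste0("State role collision during alignment; emission means:\n",
                 paste(utils::capture.output(print(round(mu, 3))), collapse = "\n")))
  }
  new_params <- mhmm_params(params$pi[ord], params$A[ord, ord, drop = FALSE],
                            params$mu[ord, , drop = FALSE],
                            params$sigma2[ord, , drop = FALSE],
                            dim_names = params$dim_names)
  roles <- tibble::tibble(state = 1:4, role = STATE_ROLES, original_state = ord)
  if (inherits(object, "mhmm_fit")) {
    object$params <- new_params
    object$aligned <- TRUE
    object$roles <- roles
    object
  } else {
    attr(new_params, "roles") <- roles
    new_params
  }
}

#' Serialize / read MHMM parameters as JSON
#'
#' The round trip is lossless to full double precision.
#'
#' @param object `mhmm_fit` or `mhmm_params`.
#' @param path File path.
#' @return `write_mhmm()` returns `path` invisibly; `read_mhmm()` returns an
#'   `mhmm_params` (with `loglik`/`bic`/`seed` attributes when present).
#' @export
write_mhmm <- function(object, path) {
  params <- as_mhmm_params(object)
  payload <- list(K = params$K, pi = params$pi, A = params$A,
                  means = params$mu, vars = params$sigma2,
                  dim_names = params$dim_names)
  if (inherits(object, "mhmm_fit")) {
    payload$loglik <- object$loglik
    payload$bic <- object$bic
    payload$seed <- object$seed
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mhmm
#' @export
read_mhmm <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- mhmm_params(x$pi, x$A, x$means, x$vars, dim_names = x$dim_names)
  for (field in c("loglik", "bic", "seed")) {
    if (!is.null(x[[field]])) attr(params, field) <- x[[field]]
  }
  params
}
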