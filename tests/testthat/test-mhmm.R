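test_that("forward-backward log-likelihood equals brute-force path sums", {
  set.seed(101)
  for (K in c(2, 4, 5)) {
    params <- random_mhmm_params(K, D = 5, seed = K)
    for (rep in 1:8) {
      obs <- matrix(rnorm(15), 3, 5)
      if (rep %% 2 == 0) obs[sample(3, 1), ] <- NA       # missing wave
      if (rep %% 3 == 0) obs[1, sample(5, 2)] <- NA      # missing statistics
      panel <- obs_to_panel(obs)
      post <- mhmm_posterior(panel, params)
      expect_equal(post$loglik[1], brute_hmm_loglik(obs, params),
                   tolerance = 1e-8)
      gam <- as.matrix(post[, paste0("gamma_", 1:K)])
      expect_equal(unname(rowSums(gam)), rep(1, 3), tolerance = 1e-9)
    }
  }
})

test_that("posteriors reduce to trivial answers in closed-form cases", {
  # K = 1: gamma all ones, loglik = sum of emission log-densities
  p1 <- mhmm_params(1, matrix(1, 1, 1), matrix(0, 1, 5),
                    matrix(1, 1, 5), dim_names = paste0("d", 1:5))
  obs <- matrix(rnorm(15), 3, 5)
  post <- mhmm_posterior(obs_to_panel(obs), p1)
  expect_equal(post$gamma_1, rep(1, 3))
  expect_equal(post$loglik[1], sum(dnorm(obs, 0, 1, log = TRUE)))

  # only wave 3 observed: later waves are prior propagation through A
  params <- random_mhmm_params(3, D = 5, seed = 9)
  obs <- matrix(NA_real_, 3, 5)
  obs[1, ] <- rnorm(5)
  post <- mhmm_posterior(obs_to_panel(obs), params)
  g <- as.matrix(post[, paste0("gamma_", 1:3)])
  expect_equal(unname(g[2, ]), unname(as.vector(g[1, ] %*% params$A)),
               tolerance = 1e-9)
  expect_equal(unname(g[3, ]), unname(as.vector(g[2, ] %*% params$A)),
               tolerance = 1e-9)
})

test_that("Viterbi decoding equals brute-force argmax over all paths", {
  set.seed(33)
  params <- random_mhmm_params(4, D = 5, seed = 5)
  for (rep in 1:10) {
    obs <- matrix(rnorm(15, 0, 1.5), 3, 5)
    if (rep > 7) obs[2, ] <- NA
    dec <- mhmm_decode(obs_to_panel(obs), params)
    expect_equal(unname(unlist(dec[1, c("s_w3", "s_w6", "s_w12")])),
                 brute_viterbi(obs, params))
  }

  # separation limit: noiseless observations at the state means
  sep <- mhmm_params(rep(0.25, 4), matrix(0.25, 4, 4),
                     mu = diag(4) %*% matrix(5, 4, 1) %*% t(c(1, 0, 0, 0, 0)) +
                       outer(1:4, rep(1, 5)),
                     sigma2 = matrix(0.01, 4, 5),
                     dim_names = paste0("d", 1:5))
  path <- c(2L, 4L, 1L)
  obs <- sep$mu[path, ]
  dec <- mhmm_decode(obs_to_panel(obs), sep)
  expect_equal(unname(unlist(dec[1, 2:4])), path)

  # K = 1 gives the only possible path
  p1 <- mhmm_params(1, matrix(1, 1, 1), matrix(0, 1, 5), matrix(1, 1, 5),
                    dim_names = paste0("d", 1:5))
  dec <- mhmm_decode(obs_to_panel(matrix(rnorm(15), 3, 5)), p1)
  expect_equal(unname(unlist(dec[1, 2:4])), c(1L, 1L, 1L))
})

test_that("EM increases the log-likelihood monotonically and refit is a fixed point", {
  sim <- simulate_sequences(cohort_config(), n_seq = 150, missing_rate = 0.05,
                            seed = 21)
  fit <- mhmm_fit(sim$panel, 3, n_restarts = 3, seed = 2, max_iter = 100,
                  align = FALSE)
  expect_true(all(diff(fit$ll_trace) > -1e-6))
  expect_equal(fit$bic,
               -2 * fit$loglik + fit$n_params * log(fit$N))

  # one more EM pass from the fitted parameters barely moves the loglik
  dat <- netstates:::panel_to_array(sim$panel)
  res <- netstates:::em_single(dat$y, 3, fit$params, tol = 1e-6, max_iter = 2)
  expect_lt(abs(res$ll_trace[length(res$ll_trace)] - fit$loglik),
            1e-4 * abs(fit$loglik))
})

test_that("EM recovers the parameters of a well-separated 2-state model", {
  truth <- mhmm_params(
    pi = c(0.6, 0.4),
    A = matrix(c(0.8, 0.2, 0.3, 0.7), 2, 2, byrow = TRUE),
    mu = rbind(c(1.5, 1.5, 0, 0, 0), c(-1.5, -1.5, 0, 0, 0)),
    sigma2 = matrix(0.25, 2, 5))
  sim <- mhmm_simulate(truth, n_seq = 1000, missing_rate = 0, seed = 4)
  fit <- mhmm_fit(sim$panel, 2, n_restarts = 4, seed = 8, max_iter = 200,
                  align = FALSE)
  ord <- order(-fit$params$mu[, 1])   # undo label switching
  A_hat <- fit$params$A[ord, ord]
  expect_true(all(abs(A_hat - truth$A) < 0.03))
  expect_true(all(abs(fit$params$mu[ord, ] - truth$mu) < 0.1))
})

test_that("simulation is reproducible and matches the transition law", {
  params <- mhmm_params(cohort_config()$initial_dist, cohort_config()$transition,
                        default_emission_means(), matrix(0.25, 4, 5))
  s1 <- mhmm_simulate(params, 200, missing_rate = 0.1, seed = 99)
  s2 <- mhmm_simulate(params, 200, missing_rate = 0.1, seed = 99)
  expect_identical(s1, s2)

  # law of large numbers on the wave-to-wave transition frequencies
  big <- mhmm_simulate(params, 30000, missing_rate = 0, seed = 17)
  st <- as.matrix(big$states[, c("s_w3", "s_w6", "s_w12")])
  emp <- prop.table(table(factor(c(st[, 1], st[, 2]), 1:4),
                          factor(c(st[, 2], st[, 3]), 1:4)), 1)
  expect_true(all(abs(as.matrix(emp) - params$A) < 0.02))

  # degenerate identity transitions freeze every path
  frozen <- mhmm_params(rep(0.25, 4), diag(4), default_emission_means(),
                        matrix(0.25, 4, 5))
  sim <- mhmm_simulate(frozen, 100, missing_rate = 0, seed = 1)
  expect_true(all(sim$states$s_w3 == sim$states$s_w6 &
                    sim$states$s_w6 == sim$states$s_w12))
})

test_that("semantic label alignment is idempotent and undoes permutations", {
  cfg <- cohort_config()
  canonical <- mhmm_params(cfg$initial_dist, cfg$transition,
                           cfg$emission_means, cfg$emission_sd^2)
  aligned <- align_states(canonical)
  expect_equal(aligned$mu, canonical$mu, ignore_attr = TRUE)
  expect_equal(aligned$A, canonical$A, ignore_attr = TRUE)

  perm <- c(3, 1, 4, 2)
  shuffled <- mhmm_params(canonical$pi[perm], canonical$A[perm, perm],
                          canonical$mu[perm, ], canonical$sigma2[perm, ])
  recovered <- align_states(shuffled)
  expect_equal(recovered$mu, canonical$mu, ignore_attr = TRUE)
  expect_equal(recovered$pi, canonical$pi, ignore_attr = TRUE)
  expect_equal(recovered$A, canonical$A, ignore_attr = TRUE)

  k3 <- random_mhmm_params(3, D = 5, seed = 2)
  expect_error(align_states(k3), "4-state")
})

test_that("model selection validates input and reports diagnostics", {
  expect_error(mhmm_select(tibble::tibble(), K_range = integer(0)), "nonempty")
  sim <- simulate_sequences(cohort_config(), n_seq = 120, seed = 5)
  sel <- suppressWarnings(
    mhmm_select(sim$panel, K_range = 2:3, n_restarts = 3, seed = 1,
                max_iter = 100))
  expect_equal(nrow(sel$table), 2L)
  expect_true(sel$best_K %in% 2:3)
  expect_true(all(c("bic", "min_occupancy", "min_separation") %in%
                    names(sel$table)))
})

test_that("fitted parameters survive a JSON round trip losslessly", {
  sim <- simulate_sequences(cohort_config(), n_seq = 120, seed = 6)
  fit <- mhmm_fit(sim$panel, 2, n_restarts = 2, seed = 3, max_iter = 60,
                  align = FALSE)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_mhmm(fit, path)
  back <- read_mhmm(path)
  expect_equal(back$pi, fit$params$pi, tolerance = 1e-12)
  expect_equal(back$A, fit$params$A, tolerance = 1e-12)
  expect_equal(back$mu, fit$params$mu, tolerance = 1e-12)
  expect_equal(back$sigma2, fit$params$sigma2, tolerance = 1e-12)
  expect_equal(attr(back, "loglik"), fit$loglik, tolerance = 1e-12)
})

test_that("tidy and glance methods expose the fit as tibbles", {
  sim <- simulate_sequences(cohort_config(), n_seq = 150, seed = 8)
  fit <- mhmm_fit(sim$panel, 4, n_restarts = 3, seed = 5, max_iter = 100)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(tidy(fit)), 20L)                 # 4 states x 5 statistics
  expect_equal(nrow(tidy(fit, matrix = "transition")), 16L)
  expect_equal(sum(tidy(fit, matrix = "initial")$probability), 1,
               tolerance = 1e-9)
  g <- glance(fit)
  expect_equal(g$K, 4L)
  expect_s3_class(autoplot(fit), "ggplot")
})
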