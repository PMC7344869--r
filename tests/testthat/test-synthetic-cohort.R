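test_that("the generator is deterministic under a seed", {
  s1 <- simulate_cohort(cohort_config(n_groups = 6), seed = 42)
  s2 <- simulate_cohort(cohort_config(n_groups = 6), seed = 42)
  expect_identical(s1$edges, s2$edges)
  expect_identical(s1$true_states, s2$true_states)
  expect_identical(s1$outcomes, s2$outcomes)
  s3 <- simulate_cohort(cohort_config(n_groups = 6), seed = 43)
  expect_false(identical(s1$edges, s3$edges))
})

test_that("state paths follow the configured chain marginally", {
  cfg <- cohort_config(n_groups = 200)   # 2000 participants
  set.seed(1)
  states <- netstates:::simulate_state_paths_grouped(rep(1:200, each = 10), cfg)
  expect_lt(max(abs(prop.table(table(factor(states[, 1], 1:4))) -
                      cfg$initial_dist)), 0.02)
  emp <- prop.table(table(factor(c(states[, 1], states[, 2]), 1:4),
                          factor(c(states[, 2], states[, 3]), 1:4)), 1)
  expect_true(all(abs(as.matrix(emp) - cfg$transition) < 0.05))
})

test_that("covariates and outcomes match the configured moments", {
  cfg <- cohort_config()
  records <- simulate_outcomes(cfg, n_participants = 10000, n_groups = 100,
                               seed = 8)
  expect_equal(mean(records$sed_base), 475, tolerance = 5)
  expect_equal(sd(records$sed_base), 131, tolerance = 5)
  expect_equal(mean(records$wear_12m), 962, tolerance = 6)
  expect_equal(mean(records$sex == "female"), 0.985, tolerance = 0.01)
  expect_equal(mean(records$age), 32.5, tolerance = 0.3)
  # calibrated residual keeps the follow-up SD near its target
  expect_equal(sd(records$sed_12m), cfg$followup_sd_target, tolerance = 6)
})

test_that("statistics-only emission draws match the configured profiles", {
  cfg <- cohort_config()
  sim <- simulate_sequences(cfg, n_seq = 4000, missing_rate = 0, seed = 3)
  long <- dplyr::left_join(
    sim$panel,
    tidyr::pivot_longer(sim$states, -"participant_id",
                        names_to = "wv", values_to = "state") |>
      dplyr::mutate(wave = c(s_w3 = 3L, s_w6 = 6L, s_w12 = 12L)[.data$wv]),
    by = c("participant_id", "wave"))
  for (k in c(1, 2, 4)) {   # popular has no wave-3 mass but still appears later
    rows <- long$state == k
    m <- colMeans(long[rows, netstates:::STAT_NAMES])
    expect_equal(unname(m), unname(cfg$emission_means[k, ]), tolerance = 0.02)
  }

  # near-zero emission noise collapses draws onto the state means
  tight <- cohort_config(emission_sd = 1e-6)
  sim0 <- simulate_sequences(tight, n_seq = 50, missing_rate = 0, seed = 4)
  st <- tidyr::pivot_longer(sim0$states, -"participant_id",
                            names_to = "wv", values_to = "state")
  vals <- as.matrix(sim0$panel[, netstates:::STAT_NAMES])
  expect_equal(vals, tight$emission_means[st$state, ], tolerance = 1e-4,
               ignore_attr = TRUE)

  # requested missingness rate is realized
  simm <- simulate_sequences(cfg, n_seq = 4000, missing_rate = 0.05, seed = 5)
  expect_lt(abs(mean(is.na(simm$panel$indegree)) - 0.05), 0.01)
})

test_that("realized networks express the latent roles structurally", {
  cfg <- cohort_config()
  set.seed(11)
  # all isolated: essentially empty network
  iso <- realize_network(rep(4L, 10), cfg)
  expect_lt(group_stats(iso)$density, 0.05)
  expect_true(all(betweenness_scores(iso)$betweenness < 0.05))

  # one bridge between two otherwise disconnected clusters of average members
  set.seed(12)
  hits <- 0
  for (r in 1:20) {
    states <- c(2L, rep(1L, 8))
    net <- realize_network(states, cfg)
    b <- betweenness_scores(net)$betweenness
    if (which.max(b) == 1L && b[1] > 0) hits <- hits + 1
  }
  expect_gte(hits, 15)   # the bridge member usually has the top betweenness

  # an all-popular group is dense and still respects the nomination cap
  set.seed(13)
  pop <- realize_network(rep(3L, 10), cfg)
  expect_gt(group_stats(pop)$density, 0.3)
  expect_true(all(rowSums(pop$adjacency) <= 7))

  expect_error(realize_network(rep(1L, 2), cfg), "3 members")
  expect_error(cohort_config(group_size = 3), "group_size")
})

test_that("the zero-outdegree calibration hits its target", {
  study <- simulate_cohort(cohort_config(), seed = 1)
  panel <- build_panel(study$networks, standardize = FALSE)
  expect_lt(abs(mean(panel$outdegree == 0, na.rm = TRUE) - 0.34), 0.04)
})

test_that("written study CSVs round-trip through read_networks", {
  study <- simulate_cohort(cohort_config(n_groups = 5), seed = 2)
  dir <- tempfile()
  on.exit(unlink(dir, recursive = TRUE))
  paths <- write_study_csv(study, dir)
  nets <- read_networks(paths[["edges"]], paths[["roster"]])
  expect_equal(nrow(nets), 15L)
  reread <- build_panel(nets, standardize = FALSE)
  direct <- build_panel(study$networks, standardize = FALSE)
  reread <- dplyr::arrange(reread, .data$participant_id, .data$wave)
  direct <- dplyr::arrange(direct, .data$participant_id, .data$wave)
  expect_equal(as.data.frame(reread), as.data.frame(direct))
  truth <- readr::read_csv(paths[["truth"]], show_col_types = FALSE)
  expect_true(all(truth$label %in% c("Isolated", "Bridge", "Average", "Popular")))
})

test_that("true trajectories arise from the classification rules", {
  study <- simulate_cohort(cohort_config(n_groups = 10), seed = 6)
  labs <- classify_trajectories(study$true_states)
  expect_identical(as.character(study$outcomes$label[
    match(labs$participant_id, study$outcomes$participant_id)]),
    as.character(labs$label))
})
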