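test_that("read_networks assembles adjacency matrices from edge lists", {
  roster <- tibble::tibble(
    group_id = "g1", member_id = LETTERS[1:10], site = "site1",
    responded_w3 = c(1, 1, 1, 1, 1, 1, 1, 0, 1, 1),
    responded_w6 = 1, responded_w12 = 1
  )
  # empty edge list: all-zero adjacency, non-respondents flagged from roster
  empty <- tibble::tibble(group_id = character(), wave = integer(),
                          ego_id = character(), alter_id = character())
  nets <- read_networks(empty, roster)
  expect_equal(nrow(nets), 3L)
  w3 <- nets$network[[which(nets$wave == 3)]]
  expect_true(all(w3$adjacency == 0))
  expect_equal(w3$respondent_missing, "H")
  expect_equal(length(w3$members), 10L)

  # a symmetric pair of directed ties
  edges <- tibble::tibble(group_id = "g1", wave = c(3, 3),
                          ego_id = c("A", "B"), alter_id = c("B", "A"))
  w3 <- read_networks(edges, roster)$network[[1]]
  expect_equal(sum(w3$adjacency), 2)
  expect_equal(w3$adjacency["A", "B"], 1)
  expect_equal(w3$adjacency["B", "A"], 1)
})

test_that("read_networks drops self-nominations with a warning and rejects bad input", {
  roster <- tibble::tibble(group_id = "g1", member_id = LETTERS[1:5],
                           site = "site1")
  edges <- tibble::tibble(group_id = "g1", wave = 3,
                          ego_id = c("A", "A"), alter_id = c("A", "B"))
  expect_warning(nets <- read_networks(edges, roster), "self-nomination")
  adj <- nets$network[[1]]$adjacency
  expect_equal(diag(adj), setNames(rep(0, 5), LETTERS[1:5]))
  expect_equal(sum(adj), 1)

  bad_id <- tibble::tibble(group_id = "g1", wave = 3, ego_id = "Z", alter_id = "A")
  expect_error(read_networks(bad_id, roster), "row")

  roster8 <- tibble::tibble(group_id = "g1", member_id = LETTERS[1:9], site = "s")
  over8 <- tibble::tibble(group_id = "g1", wave = 3, ego_id = "A",
                          alter_id = LETTERS[2:9])
  expect_error(read_networks(over8, roster8), "7 nominations")
})

test_that("degree statistics count incoming and outgoing ties", {
  # empty network
  net <- make_net(5)
  d <- degree_stats(net)
  expect_true(all(d$indegree == 0) && all(d$outdegree == 0))

  # star: 4 members nominate C
  star <- make_net(5, list(c("A", "C"), c("B", "C"), c("D", "C"), c("E", "C")))
  d <- degree_stats(star)
  expect_equal(d$indegree[d$participant_id == "C"], 4L)
  expect_equal(d$outdegree[d$participant_id == "C"], 0L)
  expect_true(all(d$outdegree[d$participant_id != "C"] == 1L))
  expect_true(all(d$indegree[d$participant_id != "C"] == 0L))

  # complete digraph on 5 members
  pairs <- expand.grid(LETTERS[1:5], LETTERS[1:5], stringsAsFactors = FALSE)
  pairs <- pairs[pairs[, 1] != pairs[, 2], ]
  full <- make_net(5, split(as.matrix(pairs), seq_len(nrow(pairs))))
  d <- degree_stats(full)
  expect_true(all(d$indegree == 4L) && all(d$outdegree == 4L))

  # sum of indegrees equals sum of outdegrees equals tie count
  expect_equal(sum(d$indegree), sum(d$outdegree))
  expect_equal(sum(d$indegree), sum(full$adjacency))
})

test_that("betweenness matches the hand-worked path example", {
  net <- make_net(3, list(c("A", "B"), c("B", "C")))
  b <- betweenness_scores(net)
  expect_equal(b$betweenness, c(0, 0.5, 0))  # raw 1 / ((3-1)(3-2))
  expect_equal(betweenness_scores(make_net(4))$betweenness, rep(0, 4))
  expect_equal(betweenness_scores(make_net(2, list(c("A", "B"))))$betweenness,
               rep(0, 2))
})

test_that("betweenness equals brute-force path enumeration on random digraphs", {
  set.seed(421)
  for (rep in 1:25) {
    n <- sample(3:6, 1)
    adj <- matrix(rbinom(n * n, 1, runif(1, 0.2, 0.6)), n, n)
    diag(adj) <- 0
    dimnames(adj) <- list(LETTERS[1:n], LETTERS[1:n])
    net <- advice_network(adj, "g1", 3)
    expect_equal(betweenness_scores(net)$betweenness, brute_betweenness(adj),
                 tolerance = 1e-10)
  }
})

test_that("density and transitivity follow the directed definitions", {
  pairs <- expand.grid(LETTERS[1:4], LETTERS[1:4], stringsAsFactors = FALSE)
  pairs <- pairs[pairs[, 1] != pairs[, 2], ]
  full <- make_net(4, split(as.matrix(pairs), seq_len(nrow(pairs))))
  g <- group_stats(full)
  expect_equal(g$density, 1)
  expect_equal(g$transitivity, 1)

  g <- group_stats(make_net(10))
  expect_equal(g$density, 0)
  expect_true(is.na(g$transitivity))  # no two-path: missing, never 0

  g <- group_stats(make_net(3, list(c("A", "B"), c("B", "C"))))
  expect_equal(g$density, 2 / 6)
  expect_equal(g$transitivity, 0)    # one open two-path
})

test_that("density and transitivity are invariant under node relabeling", {
  set.seed(7)
  for (rep in 1:10) {
    n <- 6
    adj <- matrix(rbinom(n * n, 1, 0.4), n, n); diag(adj) <- 0
    dimnames(adj) <- list(LETTERS[1:n], LETTERS[1:n])
    perm <- sample(n)
    relabeled <- adj[perm, perm]
    g1 <- group_stats(advice_network(adj, "g1", 3))
    g2 <- group_stats(advice_network(relabeled, "g1", 3))
    expect_equal(g1$density, g2$density)
    expect_equal(g1$transitivity, g2$transitivity)
  }
})

test_that("build_panel standardizes, flags missing respondents and round-trips", {
  study <- simulate_cohort(cohort_config(n_groups = 6), seed = 3)
  raw <- build_panel(study$networks, standardize = FALSE)
  panel <- standardize_panel(raw)
  for (s in c("indegree", "outdegree", "betweenness", "density", "transitivity")) {
    expect_equal(mean(panel[[s]], na.rm = TRUE), 0, tolerance = 1e-9)
    expect_equal(sd(panel[[s]], na.rm = TRUE), 1, tolerance = 1e-9)
  }
  back <- destandardize_panel(panel)
  for (s in c("indegree", "outdegree", "betweenness", "density", "transitivity")) {
    expect_equal(back[[s]], raw[[s]], tolerance = 1e-9)
  }

  # a flagged non-respondent keeps indegree but loses outdegree/betweenness
  net <- make_net(5, list(c("A", "B"), c("C", "B")), respondent_missing = "B")
  p <- build_panel(list(net), standardize = FALSE)
  row_b <- p[p$participant_id == "B", ]
  expect_equal(row_b$indegree, 2)
  expect_true(is.na(row_b$outdegree))
  expect_true(is.na(row_b$betweenness))

  # duplicated (group, wave) is a hard error
  expect_error(build_panel(list(net, net)), "Duplicated")
})

test_that("two identical groups yield identical standardized rows", {
  ties <- list(c("A", "B"), c("B", "C"), c("C", "A"), c("D", "A"))
  n1 <- make_net(5, ties, group_id = "g1")
  n2 <- make_net(5, ties, group_id = "g2")
  n3 <- make_net(5, list(c("A", "B"), c("B", "C"), c("A", "C")),
                 group_id = "g3")  # breaks degeneracy in every statistic
  p <- build_panel(list(n1, n2, n3))
  g1 <- p[p$group_id == "g1", -(1:4)]
  g2 <- p[p$group_id == "g2", -(1:4)]
  expect_equal(as.data.frame(g1), as.data.frame(g2))
})
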