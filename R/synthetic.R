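#' Configuration for the synthetic study generator
#'
#' Bundles every parameter of the synthetic cohort: the latent state chain
#' (initial distribution and transition matrix over the four semantic states
#' average / bridge / popular / isolated), the per-state emission profiles of
#' the five standardized network statistics, the tie-probability rules used
#' to realize group networks from member states, covariate moments, and the
#' outcome-model coefficients.
#'
#' Defaults emulate the published study conditions: 30 groups of 10 adults
#' observed at weeks 3, 6 and 12; baseline sedentary 475 (131) min/day;
#' follow-up wear 962 (173) min/day; 98.5% female; age 32.5 (6.2); the
#' printed four-state transition matrix (rows renormalized to sum exactly to
#' 1) with zero initial mass on the popular state; outcome coefficients set
#' to the published multilevel estimates (Bridge -31.26 min/day versus
#' Isolated, etc.). The isolated-state nomination probability is calibrated so
#' the overall zero-outdegree share matches `zero_outdegree_target` (34%),
#' and the residual SD is calibrated by variance bookkeeping so the
#' follow-up sedentary SD is near `followup_sd_target` (132 min/day); see
#' the methods vignette for both formulas. Emission-mean profiles are
#' module-chosen qualitative shapes, freely overridable.
#'
#' @param n_groups Number of intervention groups.
#' @param group_size Members per group.
#' @param initial_dist Length-4 initial state distribution
#'   (average, bridge, popular, isolated).
#' @param transition 4 x 4 transition matrix (rows renormalized).
#' @param emission_means 4 x 5 matrix of standardized-statistic means.
#' @param emission_sd Scalar or 4 x 5 matrix of emission SDs.
#' @param outcome_coefs Named vector of outcome-model coefficients (min/day).
#' @param covariates Named list of covariate moments.
#' @param tie_probs Named list of nomination rules for network realization:
#'   quotas `q_average` and `q_bridge_cross`, the group-wave sociability
#'   noise ceiling `noise_max`, receive probabilities `p_popular_receive`,
#'   `p_bridge_receive_cross`, `p_nominate_isolated`, and `p_iso_active`
#'   (probability an isolated member nominates anyone; `NULL` requests
#'   calibration to `zero_outdegree_target`).
#' @param group_ri_sd Group random-intercept SD (min/day).
#' @param residual_sd Outcome residual SD; `NULL` requests calibration to
#'   `followup_sd_target`.
#' @param followup_sd_target Marginal SD of follow-up sedentary minutes.
#' @param zero_outdegree_target Share of person-waves nominating no one.
#' @param missing_rate Per person-wave probability of survey non-response.
#' @param n_clusters Number of within-group clusters of average-state members.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(
    n_groups = 30L,
    group_size = 10L,
    initial_dist = c(average = 0.40, bridge = 0.15, popular = 0.00, isolated = 0.45),
    transition = published_transition(),
    emission_means = default_emission_means(),
    emission_sd = 0.5,
    outcome_coefs = c(intercept = -152.76, popular = -7.94, bridge = -31.26,
                      average = 6.89, sed_base = 0.33, female = 44.89,
                      age = -3.46, weeks_pregnant = 0.39,
                      weeks_since_birth = 0.17, wear_12m = 0.51,
                      site1 = -2.57, group_size = 3.03),
    covariates = list(age_mean = 32.5, age_sd = 6.2,
                      sed_base_mean = 475, sed_base_sd = 131,
                      wear_mean = 962, wear_sd = 173,
                      female_prop = 0.985,
                      pregnant_prop = 0.10, weeks_pregnant_range = c(4, 40),
                      birth_prop = 0.20, weeks_since_birth_range = c(0, 52)),
    tie_probs = list(q_average = 2L, q_bridge_cross = 4L,
                     noise_max = 0.10, p_popular_receive = 0.95,
                     p_bridge_receive_cross = 0.30,
                     p_nominate_isolated = 0.05, p_iso_active = NULL),
    group_ri_sd = 10,
    residual_sd = NULL,
    followup_sd_target = 132,
    zero_outdegree_target = 0.34,
    missing_rate = 0.05,
    n_clusters = 2L) {
  transition <- as.matrix(transition)
  transition <- transition / rowSums(transition)
  initial_dist <- initial_dist / sum(initial_dist)
  if (length(initial_dist) != 4L || !all(dim(transition) == c(4L, 4L))) {
    abort("The state chain must have exactly 4 states.")
  }
  if (is.null(dim(emission_sd))) {
    emission_sd <- matrix(emission_sd, 4L, length(STAT_NAMES))
  }
  if (any(emission_sd <= 0)) abort("Emission SDs must be positive.")
  if (group_size < 4L) abort("Bridge-state topology needs group_size >= 4.")
  cfg <- structure(
    list(n_groups = as.integer(n_groups), group_size = as.integer(group_size),
         initial_dist = unname(initial_dist), transition = unname(transition),
         emission_means = emission_means, emission_sd = emission_sd,
         outcome_coefs = outcome_coefs, covariates = covariates,
         tie_probs = tie_probs, group_ri_sd = group_ri_sd,
         residual_sd = residual_sd, followup_sd_target = followup_sd_target,
         zero_outdegree_target = zero_outdegree_target,
         missing_rate = missing_rate, n_clusters = as.integer(n_clusters)),
    class = "cohort_config")
  if (is.null(cfg$tie_probs$p_iso_active)) {
    cfg$tie_probs$p_iso_active <- calibrate_iso_active(cfg)
  }
  if (is.null(cfg$residual_sd)) {
    cfg$residual_sd <- calibrate_residual_sd(cfg)
  }
  cfg
}

#' Published four-state transition matrix
#'
#' Transition probabilities between the four latent network states, in
#' semantic order (average, bridge, popular, isolated). Entry `[r, s]` is
#' the probability of moving from state r to state s between consecutive
#' waves; the popular-state row is identified from the week 6 to week 12
#' transitions only, since that state is unoccupied at week 3.
#'
#' @return A 4 x 4 matrix (rows sum to 1 within printed rounding).
#' @export
published_transition <- function() {
  m <- matrix(c(0.51, 0.16, 0.23, 0.09,
                0.32, 0.40, 0.21, 0.08,
                0.21, 0.00, 0.79, 0.00,
                0.25, 0.11, 0.04, 0.60),
              nrow = 4L, byrow = TRUE,
              dimnames = list(STATE_ROLES, STATE_ROLES))
  m
}

#' Default per-state emission profiles
#'
#' Standardized means of the five network statistics per semantic state:
#' the average state sits at the pooled mean on everything; the bridge state
#' is distinguished by high betweenness; the popular state by high indegree
#' and outdegree (with slightly depressed betweenness and elevated density);
#' the isolated state by low degrees, betweenness and density. These are
#' qualitative profile shapes chosen for this generator, not published
#' numbers.
#'
#' @return 4 x 5 matrix (states x statistics).
#' @export
default_emission_means <- function() {
  m <- rbind(average  = c(0,    0,    0,    0,   0),
             bridge   = c(0,    0,    1.5,  0,   0),
             popular  = c(1.5,  1.5, -0.3,  0.5, 0),
             isolated = c(-1.0, -1.0, -0.7, -1.0, 0))
  colnames(m) <- STAT_NAMES
  m
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> %d groups x %d members, 3 waves\n",
              x$n_groups, x$group_size))
  cat(sprintf("  residual SD %.1f (target follow-up SD %.0f); isolated nomination p %.4f (target zero-outdegree %.0f%%)\n",
              x$residual_sd, x$followup_sd_target, x$tie_probs$p_iso_active,
              100 * x$zero_outdegree_target))
  invisible(x)
}

# Average state prevalence across the three waves implied by the chain.
state_prevalence <- function(config) {
  p1 <- config$initial_dist
  p2 <- as.vector(p1 %*% config$transition)
  p3 <- as.vector(p2 %*% config$transition)
  (p1 + p2 + p3) / 3
}

# Exact trajectory-label probabilities under the chain: enumerate all 4^3
# state paths, weight by pi[s1] A[s1,s2] A[s2,s3], classify each path.
trajectory_path_probs <- function(config) {
  grid <- expand.grid(s_w3 = 1:4, s_w6 = 1:4, s_w12 = 1:4)
  prob <- config$initial_dist[grid$s_w3] *
    config$transition[cbind(grid$s_w3, grid$s_w6)] *
    config$transition[cbind(grid$s_w6, grid$s_w12)]
  grid$participant_id <- seq_len(nrow(grid))
  labs <- classify_trajectories(tibble::as_tibble(grid))
  tibble::tibble(label = labs$label, prob = prob) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(prob = sum(.data$prob), .groups = "drop")
}

# Calibrate the probability that an isolated-state member nominates anyone.
# Members in the other three states always use their nomination quotas, so
# essentially all zero-outdegree person-waves come from isolated members:
# the expected zero-outdegree share is prev(isolated) * (1 - p_iso_active).
# Solving for the target and clamping to (0.005, 1) gives the closest
# feasible calibration when the target exceeds the isolated prevalence.
calibrate_iso_active <- function(config) {
  prev <- state_prevalence(config)
  p <- 1 - config$zero_outdegree_target / prev[4L]
  min(max(p, 0.005), 1)
}

# Variance bookkeeping: the marginal variance of the follow-up outcome is
# the sum of the fixed-effect contributions (independent covariates), the
# trajectory-effect variance under the chain-implied label mix, the group
# random-intercept variance and the residual variance. The residual SD is
# set so the total matches the target follow-up SD.
calibrate_residual_sd <- function(config) {
  b <- config$outcome_coefs
  cv <- config$covariates
  unif_var <- function(r) diff(r)^2 / 12
  mix_var <- function(p, r) {
    m <- mean(r); v <- unif_var(r)
    p * (v + m^2) - (p * m)^2
  }
  traj <- trajectory_path_probs(config)
  eff <- c(Isolated = 0, Popular = unname(b["popular"]),
           Bridge = unname(b["bridge"]), Average = unname(b["average"]))
  pe <- traj$prob[match(names(eff), as.character(traj$label))]
  pe[is.na(pe)] <- 0
  v_traj <- sum(pe * eff^2) - sum(pe * eff)^2
  v_fixed <- b["sed_base"]^2 * cv$sed_base_sd^2 +
    b["wear_12m"]^2 * cv$wear_sd^2 +
    b["age"]^2 * cv$age_sd^2 +
    b["female"]^2 * cv$female_prop * (1 - cv$female_prop) +
    b["weeks_pregnant"]^2 * mix_var(cv$pregnant_prop, cv$weeks_pregnant_range) +
    b["weeks_since_birth"]^2 * mix_var(cv$birth_prop, cv$weeks_since_birth_range) +
    b["site1"]^2 * 0.25 +
    b["group_size"]^2 * 2        # group sizes drawn nominal +/- 2 (var 2)
  v_resid <- config$followup_sd_target^2 - unname(v_fixed) - v_traj -
    config$group_ri_sd^2
  if (v_resid < 100) {
    warn("Calibrated residual variance fell below the floor (SD 10); flooring.")
    v_resid <- 100
  }
  sqrt(v_resid)
}

#' Realize one group's advice network from member states
#'
#' Draws a directed nomination network whose computed statistics reflect the
#' members' latent roles. Members are dealt into two within-group clusters
#' balanced by state. Each member nominates according to their state:
#' isolated members nominate anyone only with a small calibrated
#' probability; average members nominate a fixed quota of active
#' (non-isolated) cluster-mates, preferring popular ones - so nominations
#' concentrate on populars without raising overall density; popular members
#' nominate every active cluster-mate (high degrees, little brokerage: they
#' never send across clusters); bridge members nominate only across
#' clusters and are nominated from both sides, making them the systematic
#' cluster connectors and hence the top-betweenness members. A per
#' group-wave "sociability" rate adds extra within-cluster ties so group
#' density varies between groups the way real small groups differ in
#' cohesion. Nomination lists longer than the 7-name instrument cap are
#' down-sampled at random.
#'
#' @param states Integer vector of member states (1 = average, 2 = bridge,
#'   3 = popular, 4 = isolated), length >= 3.
#' @param config A [cohort_config()].
#' @param members Member ids (defaults to `m1..mn`).
#' @param group_id,wave,site Network identifiers.
#' @param respondent_missing Ids whose survey rows should be zeroed/flagged.
#' @return An [advice_network()].
#' @export
realize_network <- function(states, config, members = NULL, group_id = "g1",
                            wave = 3L, site = "site1",
                            respondent_missing = character()) {
  n <- length(states)
  if (n < 3L) abort("Network realization needs at least 3 members.")
  if (is.null(members)) members <- paste0("m", seq_len(n))
  tp <- config$tie_probs
  active <- states %in% 1:3
  resample <- function(x, size) {
    if (length(x) == 0L || size <= 0L) return(integer(0))
    x[sample.int(length(x), min(size, length(x)))]
  }
  # state-balanced clusters: deal members of each state alternately
  cluster <- integer(n)
  for (st_k in 1:4) {
    idx <- which(states == st_k)
    cluster[idx] <- (seq_along(idx) - 1L) %% config$n_clusters + 1L
  }
  adj <- matrix(0L, n, n)
  r_gw <- runif(1, 0, tp$noise_max)
  for (i in seq_len(n)) {
    same <- which(cluster == cluster[i] & seq_len(n) != i)
    other <- which(cluster != cluster[i])
    same_active <- same[active[same]]
    targets <- integer(0)
    if (states[i] == 4L) {
      if (runif(1) < tp$p_iso_active) {
        targets <- resample(setdiff(seq_len(n), i), 1L)
      }
    } else {
      if (states[i] == 3L) {
        targets <- same_active
      } else if (states[i] == 2L) {
        targets <- resample(other[active[other]], tp$q_bridge_cross)
      } else {
        pops <- same[states[same] == 3L]
        pref <- pops[runif(length(pops)) < tp$p_popular_receive]
        targets <- c(pref, resample(setdiff(same_active, pref),
                                    tp$q_average - length(pref)))
      }
      extra <- setdiff(same_active, targets)
      targets <- c(targets, extra[runif(length(extra)) < r_gw])
      brs <- other[states[other] == 2L]
      targets <- union(targets,
                       brs[runif(length(brs)) < tp$p_bridge_receive_cross])
      iso_same <- same[!active[same]]
      if (length(iso_same) > 0L && runif(1) < tp$p_nominate_isolated) {
        targets <- union(targets, resample(iso_same, 1L))
      }
    }
    targets <- setdiff(targets, i)
    if (length(targets) > 7L) targets <- resample(targets, 7L)
    adj[i, targets] <- 1L
  }
  miss_idx <- match(respondent_missing, members)
  if (length(miss_idx) > 0L) adj[miss_idx, ] <- 0L
  dimnames(adj) <- list(members, members)
  advice_network(adj, group_id = group_id, wave = wave, site = site,
                 respondent_missing = respondent_missing)
}

simulate_state_paths <- function(n, config) {
  states <- matrix(0L, n, 3L)
  states[, 1L] <- sample.int(4L, n, replace = TRUE, prob = config$initial_dist)
  cum <- t(apply(config$transition, 1L, cumsum))
  for (t in 2:3) {
    u <- runif(n)
    states[, t] <- vapply(seq_len(n), function(i) {
      which(u[i] <= cum[states[i, t - 1L], ])[1L]
    }, integer(1))
  }
  states
}

# Randomized rounding of n draws from probability vector p: floor(n * p)
# guaranteed seats plus remainder seats sampled proportional to the
# fractional parts. Each individual draw still has marginal distribution p.
allocate_counts <- function(n, p) {
  exp_counts <- n * p / sum(p)
  base <- floor(exp_counts)
  seats <- n - sum(base)
  if (seats > 0L) {
    rem <- exp_counts - base
    extra <- sample.int(length(p), seats, prob = pmax(rem, 1e-12))
    base[extra] <- base[extra] + 1L
  }
  base
}

# State paths with composition balanced within each group: at wave 3 each
# group receives a stratified allocation of the initial distribution, and
# each within-group set of members sharing a state transitions by a
# stratified allocation of the corresponding transition row. Every member's
# marginal chain law is unchanged (initial_dist then transition), but group
# compositions track the population prevalences instead of drifting apart,
# which emulates facilitated groups with comparable social mixes.
simulate_state_paths_grouped <- function(group_index, config) {
  n <- length(group_index)
  states <- matrix(0L, n, 3L)
  for (g in unique(group_index)) {
    rows <- which(group_index == g)
    counts <- allocate_counts(length(rows), config$initial_dist)
    states[rows[sample.int(length(rows))], 1L] <- rep.int(1:4, counts)
    for (t in 2:3) {
      for (r in 1:4) {
        members <- rows[states[rows, t - 1L] == r]
        if (length(members) == 0L) next
        counts <- allocate_counts(length(members), config$transition[r, ])
        states[members[sample.int(length(members))], t] <- rep.int(1:4, counts)
      }
    }
  }
  states
}

gen_covariates <- function(ids, config) {
  n <- length(ids)
  cv <- config$covariates
  pregnant <- runif(n) < cv$pregnant_prop
  gave_birth <- !pregnant & runif(n) < cv$birth_prop
  tibble::tibble(
    participant_id = ids,
    sex = ifelse(runif(n) < cv$female_prop, "female", "male"),
    age = rnorm_trunc(n, cv$age_mean, cv$age_sd, lower = 18.5),
    sed_base = rnorm_trunc(n, cv$sed_base_mean, cv$sed_base_sd, 1, 1439),
    wear_12m = rnorm_trunc(n, cv$wear_mean, cv$wear_sd, 1, 1439),
    weeks_pregnant = ifelse(pregnant,
                            runif(n, cv$weeks_pregnant_range[1L],
                                  cv$weeks_pregnant_range[2L]), 0),
    weeks_since_birth = ifelse(gave_birth,
                               runif(n, cv$weeks_since_birth_range[1L],
                                     cv$weeks_since_birth_range[2L]), 0)
  )
}

#' Linear predictor of follow-up sedentary minutes
#'
#' Applies the configured outcome coefficients to a record table (no random
#' effects, no noise) - the generator's systematic component.
#'
#' @param records Tibble with `label`, `sed_base`, `sex`, `age`,
#'   `weeks_pregnant`, `weeks_since_birth`, `wear_12m`, `site`, `group_size`.
#' @param config A [cohort_config()].
#' @return Numeric vector of expected minutes/day.
#' @export
outcome_linear_predictor <- function(records, config) {
  b <- config$outcome_coefs
  eff <- c(Isolated = 0, Popular = unname(b["popular"]),
           Bridge = unname(b["bridge"]), Average = unname(b["average"]))
  unname(b["intercept"]) +
    eff[as.character(records$label)] +
    b["sed_base"] * records$sed_base +
    b["female"] * (records$sex == "female") +
    b["age"] * records$age +
    b["weeks_pregnant"] * records$weeks_pregnant +
    b["weeks_since_birth"] * records$weeks_since_birth +
    b["wear_12m"] * records$wear_12m +
    b["site1"] * (records$site == "site1") +
    b["group_size"] * records$group_size
}

#' Generate a complete synthetic study
#'
#' Simulates the full study: groups and rosters, a latent state path per
#' participant, a realized advice network per group and wave (with survey
#' non-response), covariates, true trajectory labels derived from the true
#' state paths, and follow-up sedentary minutes from the configured
#' two-level outcome model. Fully reproducible under `seed`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return A list of class `synthetic_cohort` with elements `config`,
#'   `seed`, `roster`, `edges`, `networks` (tibble with `network`
#'   list-column), `true_states`, and `outcomes` (covariates, true `label`,
#'   `sed_12m`).
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L) {
  set.seed(seed)
  n_g <- config$n_groups
  # groups of "approximately" the nominal size: nominal +/- 2 members
  sizes <- pmax(4L, config$group_size + sample(-2:2, n_g, replace = TRUE))
  group_ids <- sprintf("g%02d", seq_len(n_g))
  sites <- ifelse(seq_len(n_g) <= ceiling(n_g / 2), "site1", "site2")
  ids <- unlist(lapply(seq_len(n_g), function(g) {
    sprintf("%s_m%02d", group_ids[g], seq_len(sizes[g]))
  }))
  group_of <- rep(group_ids, times = sizes)
  site_of <- rep(sites, times = sizes)

  states <- simulate_state_paths_grouped(rep(seq_len(n_g), times = sizes), config)
  missing <- matrix(runif(length(ids) * 3L) < config$missing_rate,
                    ncol = 3L)
  # every participant answers at least one wave (the inclusion rule)
  none <- which(rowSums(!missing) == 0L)
  for (i in none) missing[i, sample.int(3L, 1L)] <- FALSE

  nets <- list(); k <- 0L
  for (g in seq_len(n_g)) {
    rows <- which(group_of == group_ids[g])
    for (w in seq_along(WAVES)) {
      k <- k + 1L
      nets[[k]] <- realize_network(
        states[rows, w], config, members = ids[rows],
        group_id = group_ids[g], wave = WAVES[w], site = sites[g],
        respondent_missing = ids[rows][missing[rows, w]])
    }
  }
  networks <- tibble::tibble(
    group_id = purrr::map_chr(nets, "group_id"),
    wave = purrr::map_int(nets, "wave"),
    site = purrr::map_chr(nets, "site"),
    network = nets)

  edges <- purrr::map_dfr(nets, function(net) {
    idx <- which(net$adjacency == 1L, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(NULL)
    tibble::tibble(group_id = net$group_id, wave = net$wave,
                   ego_id = net$members[idx[, 1L]],
                   alter_id = net$members[idx[, 2L]])
  })
  roster <- tibble::tibble(
    group_id = group_of, member_id = ids, site = site_of,
    responded_w3 = as.integer(!missing[, 1L]),
    responded_w6 = as.integer(!missing[, 2L]),
    responded_w12 = as.integer(!missing[, 3L]))

  true_states <- tibble::tibble(participant_id = ids, s_w3 = states[, 1L],
                                s_w6 = states[, 2L], s_w12 = states[, 3L])
  labels <- classify_trajectories(true_states)

  cov <- gen_covariates(ids, config)
  records <- cov |>
    dplyr::mutate(group_id = group_of, site = site_of,
                  group_size = sizes[match(group_of, group_ids)],
                  label = labels$label[match(.data$participant_id,
                                             labels$participant_id)])
  lp <- outcome_linear_predictor(records, config)
  b_g <- rnorm(n_g, 0, config$group_ri_sd)
  mu_i <- lp + b_g[match(records$group_id, group_ids)]
  sed_12m <- mu_i + rnorm(length(mu_i), 0, config$residual_sd)
  redraw <- which(sed_12m <= 0 | sed_12m >= 1440)
  while (length(redraw) > 0L) {
    sed_12m[redraw] <- mu_i[redraw] + rnorm(length(redraw), 0, config$residual_sd)
    redraw <- redraw[sed_12m[redraw] <= 0 | sed_12m[redraw] >= 1440]
  }
  outcomes <- dplyr::mutate(records, sed_12m = sed_12m)

  structure(list(config = config, seed = seed, roster = roster, edges = edges,
                 networks = networks, true_states = true_states,
                 outcomes = outcomes),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d participants in %d groups, %d networks, seed %d\n",
              nrow(x$outcomes), x$config$n_groups, nrow(x$networks), x$seed))
  invisible(x)
}

#' Draw statistic sequences directly from the state emissions
#'
#' Bypasses network realization: latent state paths are drawn from the
#' configured chain and the five statistics straight from the per-state
#' Gaussians - the clean input for model-recovery experiments.
#'
#' @param config A [cohort_config()].
#' @param n_seq Number of participant sequences.
#' @param missing_rate Per-wave missingness probability (defaults to the
#'   config's rate).
#' @param seed Integer seed.
#' @return As [mhmm_simulate()]: list with `panel` and `states`.
#' @export
simulate_sequences <- function(config = cohort_config(), n_seq = 300L,
                               missing_rate = config$missing_rate, seed = 1L) {
  params <- mhmm_params(config$initial_dist, config$transition,
                        config$emission_means, config$emission_sd^2)
  mhmm_simulate(params, n_seq = n_seq, missing_rate = missing_rate, seed = seed)
}

#' Generate outcome records only
#'
#' Draws trajectory labels from the chain-implied path distribution together
#' with covariates and outcomes, skipping network realization; used for
#' large-sample recovery checks of the regression stage.
#'
#' @param config A [cohort_config()].
#' @param n_participants Total participants.
#' @param n_groups Number of groups to spread them over.
#' @param seed Integer seed.
#' @return Tibble of outcome records (one per participant).
#' @export
simulate_outcomes <- function(config = cohort_config(), n_participants = 5000L,
                              n_groups = 100L, seed = 1L) {
  set.seed(seed)
  ids <- sprintf("p%05d", seq_len(n_participants))
  states <- simulate_state_paths(n_participants, config)
  labels <- classify_trajectories(
    tibble::tibble(participant_id = ids, s_w3 = states[, 1L],
                   s_w6 = states[, 2L], s_w12 = states[, 3L]))
  group_ids <- sprintf("g%03d", seq_len(n_groups))
  grp <- sample(group_ids, n_participants, replace = TRUE)
  sites <- setNames(ifelse(seq_len(n_groups) <= ceiling(n_groups / 2),
                           "site1", "site2"), group_ids)
  sizes <- setNames(pmax(4L, config$group_size +
                           sample(-2:2, n_groups, replace = TRUE)), group_ids)
  records <- gen_covariates(ids, config) |>
    dplyr::mutate(group_id = grp, site = unname(sites[grp]),
                  group_size = unname(sizes[grp]), label = labels$label)
  lp <- outcome_linear_predictor(records, config)
  b_g <- setNames(rnorm(n_groups, 0, config$group_ri_sd), group_ids)
  records$sed_12m <- lp + unname(b_g[grp]) +
    rnorm(n_participants, 0, config$residual_sd)
  records
}

#' Write a synthetic study to the pipeline's CSV dialects
#'
#' Writes `edges.csv`, `roster.csv`, `outcomes.csv` and a `truth.csv` (true
#' states and trajectory labels) for scoring.
#'
#' @param study A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study_csv <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(edges = file.path(dir, "edges.csv"),
             roster = file.path(dir, "roster.csv"),
             outcomes = file.path(dir, "outcomes.csv"),
             truth = file.path(dir, "truth.csv"))
  readr::write_csv(study$edges, paths["edges"])
  readr::write_csv(study$roster, paths["roster"])
  readr::write_csv(study$outcomes, paths["outcomes"])
  truth <- study$true_states |>
    dplyr::left_join(
      classify_trajectories(study$true_states)[, c("participant_id", "label")],
      by = "participant_id")
  readr::write_csv(truth, paths["truth"])
  invisible(paths)
}
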