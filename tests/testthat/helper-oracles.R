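# Independent oracles and small fixture builders used across the suite.

# Build an advice network from a list of ego -> alter pairs.
make_net <- function(n, ties = list(), wave = 3, group_id = "g1",
                     members = NULL, respondent_missing = character()) {
  if (is.null(members)) members <- LETTERS[seq_len(n)]
  adj <- matrix(0, n, n, dimnames = list(members, members))
  for (tie in ties) adj[tie[1], tie[2]] <- 1
  advice_network(adj, group_id = group_id, wave = wave,
                 respondent_missing = respondent_missing)
}

# Brute-force normalized directed betweenness by explicit shortest-path
# counting (Floyd-Warshall distances + path-count DP). Independent of igraph.
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  if (n < 3) return(rep(0, n))
  d <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)          # number of shortest paths
  d[adj == 1] <- 1
  sigma[adj == 1] <- 1
  diag(d) <- 0
  diag(sigma) <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j || i == k || j == k) next
        nd <- d[i, k] + d[k, j]
        if (nd < d[i, j]) {
          d[i, j] <- nd
          sigma[i, j] <- sigma[i, k] * sigma[k, j]
        } else if (nd == d[i, j] && is.finite(nd)) {
          sigma[i, j] <- sigma[i, j] + sigma[i, k] * sigma[k, j]
        }
      }
    }
  }
  # recompute path counts cleanly by DP over increasing distance to avoid
  # double counting through multiple pivots
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    ord <- order(d[s, ])
    sigma[s, s] <- 1
    for (v in ord) {
      if (v == s || !is.finite(d[s, v])) next
      preds <- which(adj[, v] == 1 & d[s, ] + 1 == d[s, v])
      sigma[s, v] <- sum(sigma[s, preds])
    }
  }
  bet <- numeric(n)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s == t || s == v || t == v) next
        if (!is.finite(d[s, t]) || sigma[s, t] == 0) next
        if (d[s, v] + d[v, t] == d[s, t]) {
          tot <- tot + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
    bet[v] <- tot
  }
  bet / ((n - 1) * (n - 2))
}

# Brute-force HMM log-likelihood of one length-3 sequence by summing over
# all K^3 state paths. obs: 3 x D matrix with NA for missing entries.
brute_hmm_loglik <- function(obs, params) {
  K <- params$K
  total <- 0
  emis <- function(t, k) {
    x <- obs[t, ]
    ok <- !is.na(x)
    if (!any(ok)) return(1)
    prod(dnorm(x[ok], params$mu[k, ok], sqrt(params$sigma2[k, ok])))
  }
  for (s1 in 1:K) for (s2 in 1:K) for (s3 in 1:K) {
    total <- total + params$pi[s1] * params$A[s1, s2] * params$A[s2, s3] *
      emis(1, s1) * emis(2, s2) * emis(3, s3)
  }
  log(total)
}

# Brute-force Viterbi path with ties broken toward the lexicographically
# smallest path (enumeration order guarantees it).
brute_viterbi <- function(obs, params) {
  K <- params$K
  best <- -Inf
  best_path <- c(1L, 1L, 1L)
  emis <- function(t, k) {
    x <- obs[t, ]
    ok <- !is.na(x)
    if (!any(ok)) return(0)
    sum(dnorm(x[ok], params$mu[k, ok], sqrt(params$sigma2[k, ok]), log = TRUE))
  }
  for (s1 in 1:K) for (s2 in 1:K) for (s3 in 1:K) {
    lp <- log(params$pi[s1]) + log(params$A[s1, s2]) + log(params$A[s2, s3]) +
      emis(1, s1) + emis(2, s2) + emis(3, s3)
    if (lp > best + 1e-12) {
      best <- lp
      best_path <- c(s1, s2, s3)
    }
  }
  best_path
}

random_mhmm_params <- function(K, D = 5, seed = 1) {
  set.seed(seed)
  pi <- rgamma(K, 1); pi <- pi / sum(pi)
  A <- matrix(rgamma(K * K, 1), K, K); A <- A / rowSums(A)
  mu <- matrix(rnorm(K * D, 0, 1.5), K, D)
  sigma2 <- matrix(runif(K * D, 0.2, 1.5), K, D)
  mhmm_params(pi, A, mu, sigma2, dim_names = paste0("d", seq_len(D)))
}

# Panel tibble from a 3 x D observation matrix for a single participant.
obs_to_panel <- function(obs, id = "p1", dim_names = paste0("d", seq_len(ncol(obs)))) {
  out <- tibble::tibble(participant_id = id, wave = c(3L, 6L, 12L))
  for (d in seq_along(dim_names)) out[[dim_names[d]]] <- obs[, d]
  out
}

# Regular 1-minute epoch series starting at `start` (UTC).
make_epochs <- function(counts, worn = rep(1, length(counts)),
                        start = "2015-03-02 08:00:00", id = "p1") {
  tibble::tibble(
    participant_id = id,
    timestamp = as.POSIXct(start, tz = "UTC") + 60 * (seq_along(counts) - 1),
    counts = counts,
    worn = worn
  )
}
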