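#' Construct a single-group advice network
#'
#' An advice network is one intervention group's directed adjacency matrix at
#' one measurement wave. A tie `i -> j` means member `i` reported that they
#' would seek health advice from member `j` outside sessions. The survey
#' instrument caps nominations at 7 per respondent.
#'
#' @param adjacency Square 0/1 matrix with members in roster order. Row and
#'   column names must carry the member ids.
#' @param group_id Group identifier.
#' @param wave Intervention week of measurement; one of 3, 6, 12.
#' @param site Recreation-centre site label for the group.
#' @param respondent_missing Character vector of member ids with no survey at
#'   this wave. Their outgoing ties are unknown (rows are zero but flagged),
#'   not genuinely empty.
#'
#' @return An object of class `advice_network`.
#' @export
advice_network <- function(adjacency, group_id, wave, site = NA_character_,
                           respondent_missing = character()) {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (n != ncol(adjacency)) abort("`adjacency` must be square.")
  if (is.null(rownames(adjacency))) {
    rownames(adjacency) <- colnames(adjacency) <- paste0("m", seq_len(n))
  }
  if (!identical(rownames(adjacency), colnames(adjacency))) {
    abort("`adjacency` row and column names must match (roster order).")
  }
  if (!all(adjacency %in% c(0, 1))) abort("`adjacency` entries must be 0 or 1.")
  if (any(diag(adjacency) != 0)) abort("Self-ties are not allowed (diagonal must be zero).")
  if (any(rowSums(adjacency) > 7)) {
    abort("A respondent has more than 7 nominations; the instrument caps at 7.")
  }
  if (!wave %in% WAVES) abort("`wave` must be one of 3, 6, 12.")
  bad <- setdiff(respondent_missing, rownames(adjacency))
  if (length(bad) > 0L) abort(paste0("Unknown ids in `respondent_missing`: ",
                                     paste(bad, collapse = ", ")))
  structure(
    list(adjacency = adjacency, group_id = group_id, wave = as.integer(wave),
         site = site, members = rownames(adjacency),
         respondent_missing = as.character(respondent_missing)),
    class = "advice_network"
  )
}

#' @export
print.advice_network <- function(x, ...) {
  cat(sprintf("<advice_network> group %s, wave %d: %d members, %d ties, %d non-respondent(s)\n",
              x$group_id, x$wave, length(x$members), sum(x$adjacency),
              length(x$respondent_missing)))
  invisible(x)
}

#' Read roster-based advice networks from edge lists
#'
#' Assembles one directed advice network per (group, wave) from a long edge
#' list and a roster table. Groups with no reported ties at a wave still yield
#' an (all-zero) network, with non-respondents flagged from the roster's
#' per-wave response indicators.
#'
#' @param edges Data frame or CSV path with columns `group_id`, `wave`,
#'   `ego_id`, `alter_id`; one row per nomination.
#' @param roster Data frame or CSV path with columns `group_id`, `member_id`,
#'   `site`, and optionally `responded_w3`, `responded_w6`, `responded_w12`
#'   (0/1). Missing response columns are treated as all-responded.
#'
#' @details Self-nominations are dropped with a warning; duplicated
#'   nominations are collapsed. Ids absent from the roster, or more than 7
#'   distinct nominations by one respondent at one wave, are hard errors
#'   because they violate the instrument.
#'
#' @return A tibble with columns `group_id`, `wave`, `site` and a `network`
#'   list-column of [advice_network()] objects.
#' @export
read_networks <- function(edges, roster) {
  if (is.character(edges)) edges <- readr::read_csv(edges, show_col_types = FALSE)
  if (is.character(roster)) roster <- readr::read_csv(roster, show_col_types = FALSE)
  edges <- tibble::as_tibble(edges)
  roster <- tibble::as_tibble(roster)

  need_e <- c("group_id", "wave", "ego_id", "alter_id")
  need_r <- c("group_id", "member_id")
  if (!all(need_e %in% names(edges))) {
    abort(paste0("Edge list must have columns: ", paste(need_e, collapse = ", ")))
  }
  if (!all(need_r %in% names(roster))) {
    abort(paste0("Roster must have columns: ", paste(need_r, collapse = ", ")))
  }
  if (!"site" %in% names(roster)) roster$site <- NA_character_
  for (w in WAVES) {
    col <- paste0("responded_w", w)
    if (!col %in% names(roster)) roster[[col]] <- 1L
  }
  dup <- roster |>
    dplyr::count(.data$group_id, .data$member_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) abort("Roster member ids must be unique within group.")
  if (!all(edges$wave %in% WAVES)) abort("Edge list `wave` values must be in {3, 6, 12}.")

  # validate ids against the roster, naming offending rows
  key <- paste(roster$group_id, roster$member_id)
  bad_ego <- which(!paste(edges$group_id, edges$ego_id) %in% key)
  bad_alt <- which(!paste(edges$group_id, edges$alter_id) %in% key)
  bad <- sort(unique(c(bad_ego, bad_alt)))
  if (length(bad) > 0L) {
    abort(paste0("Edge list rows with ids not on the group roster: row(s) ",
                 paste(head(bad, 5L), collapse = ", "),
                 if (length(bad) > 5L) " ..." else ""))
  }

  n_self <- sum(edges$ego_id == edges$alter_id)
  if (n_self > 0L) {
    warn(sprintf("Dropped %d self-nomination(s) from the edge list.", n_self))
    edges <- dplyr::filter(edges, .data$ego_id != .data$alter_id)
  }
  edges <- dplyr::distinct(edges, .data$group_id, .data$wave, .data$ego_id, .data$alter_id)

  over <- edges |>
    dplyr::count(.data$group_id, .data$wave, .data$ego_id) |>
    dplyr::filter(.data$n > 7L)
  if (nrow(over) > 0L) {
    abort(paste0("More than 7 nominations by one respondent at one wave (instrument cap): ",
                 paste(sprintf("group %s wave %s ego %s", over$group_id, over$wave,
                               over$ego_id), collapse = "; ")))
  }

  groups <- split(roster, roster$group_id)
  grid <- tidyr::expand_grid(group_id = names(groups), wave = WAVES)
  nets <- purrr::pmap(grid, function(group_id, wave) {
    ros <- groups[[group_id]]
    members <- as.character(ros$member_id)
    if (length(members) < 3L) {
      warn(sprintf("Group %s has fewer than 3 members; statistics will be degenerate.",
                   group_id))
    }
    if (length(members) > 15L) {
      warn(sprintf("Group %s has %d members; typical groups have ~10 (instrument designed for <= 15).",
                   group_id, length(members)))
    }
    adj <- matrix(0, length(members), length(members),
                  dimnames = list(members, members))
    ew <- dplyr::filter(edges, .data$group_id == !!group_id, .data$wave == !!wave)
    if (nrow(ew) > 0L) {
      adj[cbind(as.character(ew$ego_id), as.character(ew$alter_id))] <- 1
    }
    responded <- ros[[paste0("responded_w", wave)]] == 1L
    missing_ids <- members[!responded]
    answered <- intersect(missing_ids, as.character(ew$ego_id))
    if (length(answered) > 0L) {
      warn(sprintf("Group %s wave %d: id(s) %s flagged non-respondent but have nominations; treating as respondents.",
                   group_id, wave, paste(answered, collapse = ", ")))
      missing_ids <- setdiff(missing_ids, answered)
    }
    advice_network(adj, group_id = group_id, wave = wave,
                   site = as.character(ros$site[[1L]]),
                   respondent_missing = missing_ids)
  })
  grid |>
    dplyr::mutate(site = purrr::map_chr(nets, "site"), network = nets) |>
    dplyr::arrange(.data$group_id, .data$wave)
}

#' Indegree and outdegree of every group member
#'
#' Indegree is the column sum of the adjacency matrix (advice nominations
#' received); outdegree is the row sum (nominations sent, capped at 7 by the
#' instrument).
#'
#' @param net An [advice_network()].
#' @return Tibble with columns `participant_id`, `indegree`, `outdegree`.
#' @export
degree_stats <- function(net) {
  stopifnot(inherits(net, "advice_network"))
  tibble::tibble(
    participant_id = net$members,
    indegree = as.integer(colSums(net$adjacency)),
    outdegree = as.integer(rowSums(net$adjacency))
  )
}

#' Normalized directed betweenness centrality
#'
#' For each ordered pair (s, t) of other members, the fraction of shortest
#' directed paths from s to t passing through the focal member, summed over
#' pairs and divided by (n-1)(n-2). Unreachable pairs contribute zero. Groups
#' with fewer than 3 members get all-zero scores.
#'
#' @param net An [advice_network()].
#' @return Tibble with columns `participant_id`, `betweenness`.
#' @export
betweenness_scores <- function(net) {
  stopifnot(inherits(net, "advice_network"))
  n <- length(net$members)
  if (n < 3L) {
    return(tibble::tibble(participant_id = net$members, betweenness = 0))
  }
  g <- igraph::graph_from_adjacency_matrix(net$adjacency, mode = "directed")
  b <- igraph::betweenness(g, directed = TRUE, normalized = TRUE)
  tibble::tibble(participant_id = net$members, betweenness = unname(b))
}

#' Group-level density and transitivity
#'
#' Density is the number of observed directed ties over the number possible.
#' Transitivity is the fraction of directed two-paths `i -> j -> k` (i != k)
#' closed by a direct tie `i -> k`; when the network has no two-path it is
#' returned as `NA`, never 0. When some members did not answer the survey at
#' this wave their unknown outgoing rows are excluded from the density
#' denominator; two-paths require observed rows for both `i` and `j`, which
#' the zeroed rows enforce automatically.
#'
#' @param net An [advice_network()].
#' @return Tibble with one row: `density`, `transitivity`.
#' @export
group_stats <- function(net) {
  stopifnot(inherits(net, "advice_network"))
  a <- net$adjacency
  n <- nrow(a)
  n_obs <- n - length(net$respondent_missing)
  dens <- if (n >= 2L && n_obs >= 1L) sum(a) / (n_obs * (n - 1)) else NA_real_
  a2 <- a %*% a
  two_paths <- sum(a2) - sum(diag(a2))
  trans <- if (two_paths > 0) sum(a2 * a) / two_paths else NA_real_
  tibble::tibble(density = dens, transitivity = trans)
}

#' Assemble the person-wave panel of the five network statistics
#'
#' Computes indegree, outdegree, betweenness, density and transitivity for
#' every member of every network and stacks them into a long person-wave
#' panel, the input to the hidden Markov model. Group-level density and
#' transitivity are broadcast to every member so each person-wave carries a
#' full 5-vector.
#'
#' Members flagged as non-respondents at a wave keep their indegree (reported
#' by others) but get missing outdegree and betweenness, since their outgoing
#' ties are unknown; missing values are never imputed with zeros.
#'
#' @param networks Tibble from [read_networks()] (or a list of
#'   [advice_network()] objects).
#' @param standardize If `TRUE` (default), each statistic is z-scored across
#'   all non-missing person-waves, pooled over groups and waves.
#' @return A tibble with columns `participant_id`, `group_id`, `wave`,
#'   `site` and the five statistics. When standardized, the per-statistic
#'   means/SDs used are stored in `attr(, "standardization")` and
#'   `attr(, "standardized")` is `TRUE`.
#' @export
build_panel <- function(networks, standardize = TRUE) {
  nets <- if (is.data.frame(networks)) networks$network else networks
  if (!all(purrr::map_lgl(nets, inherits, "advice_network"))) {
    abort("`networks` must contain advice_network objects.")
  }
  keys <- purrr::map_chr(nets, ~ paste(.x$group_id, .x$wave))
  if (anyDuplicated(keys)) {
    abort(paste0("Duplicated (group, wave) networks: ",
                 paste(unique(keys[duplicated(keys)]), collapse = "; ")))
  }
  panel <- purrr::map_dfr(nets, function(net) {
    deg <- degree_stats(net)
    bet <- betweenness_scores(net)
    grp <- group_stats(net)
    out <- deg |>
      dplyr::left_join(bet, by = "participant_id") |>
      dplyr::mutate(
        group_id = net$group_id, wave = net$wave, site = net$site,
        density = grp$density, transitivity = grp$transitivity,
        outdegree = ifelse(.data$participant_id %in% net$respondent_missing,
                           NA_real_, as.numeric(.data$outdegree)),
        betweenness = ifelse(.data$participant_id %in% net$respondent_missing,
                             NA_real_, .data$betweenness),
        indegree = as.numeric(.data$indegree)
      )
    out[, c("participant_id", "group_id", "wave", "site", STAT_NAMES)]
  })
  attr(panel, "standardized") <- FALSE
  if (standardize) panel <- standardize_panel(panel) else panel
}

#' Z-score the five network statistics of a panel
#'
#' Statistics are standardized pooled across all non-missing person-waves.
#' The means and SDs used are kept as an attribute so the transform is
#' invertible with [destandardize_panel()].
#'
#' @param panel A panel tibble from [build_panel()].
#' @return The panel with standardized statistic columns.
#' @export
standardize_panel <- function(panel) {
  if (isTRUE(attr(panel, "standardized"))) abort("Panel is already standardized.")
  params <- purrr::map_dfr(STAT_NAMES, function(s) {
    x <- panel[[s]]
    tibble::tibble(statistic = s, mean = mean(x, na.rm = TRUE),
                   sd = sd(x, na.rm = TRUE))
  })
  if (any(!is.finite(params$sd) | params$sd == 0)) {
    abort("A statistic has zero or undefined variance; cannot standardize.")
  }
  for (i in seq_len(nrow(params))) {
    s <- params$statistic[[i]]
    panel[[s]] <- (panel[[s]] - params$mean[[i]]) / params$sd[[i]]
  }
  attr(panel, "standardized") <- TRUE
  attr(panel, "standardization") <- params
  panel
}

#' Invert panel standardization
#'
#' @param panel A standardized panel carrying a `standardization` attribute.
#' @return The panel on the raw statistic scale.
#' @export
destandardize_panel <- function(panel) {
  params <- attr(panel, "standardization")
  if (!isTRUE(attr(panel, "standardized")) || is.null(params)) {
    abort("Panel is not standardized.")
  }
  for (i in seq_len(nrow(params))) {
    s <- params$statistic[[i]]
    panel[[s]] <- panel[[s]] * params$sd[[i]] + params$mean[[i]]
  }
  attr(panel, "standardized") <- FALSE
  attr(panel, "standardization") <- NULL
  panel
}

#' Write one adjacency-matrix CSV per (group, wave)
#'
#' @param networks Tibble from [read_networks()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_adjacency_csv <- function(networks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::map_chr(networks$network, function(net) {
    path <- file.path(dir, sprintf("adjacency_%s_w%d.csv", net$group_id, net$wave))
    df <- tibble::as_tibble(net$adjacency, rownames = "member_id")
    readr::write_csv(df, path)
    path
  })
  invisible(paths)
}
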