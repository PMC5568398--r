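# Proximal networks and communities: adjacency, community membership,
# behavior histories, and the aggregation of individual behaviors into the
# social exposures that feed the intention update.

#' Social structure: proximal network, communities, behavior history
#'
#' Holds the undirected proximal-network adjacency (friends, relatives),
#' the community membership of every agent (a geographically bounded
#' population), and a ring buffer of each agent's last `behavior_window`
#' binary behaviors, from which social exposures are computed.
#'
#' @param adjacency Either a symmetric 0/1 adjacency matrix (dense or
#'   sparse, zero diagonal), an edge data frame with columns
#'   `source, target`, or `"complete"` for an all-to-all network.
#' @param community_of Integer vector mapping each agent to its community;
#'   defaults to a single community.
#' @param n_agents Number of agents; required when `adjacency` is an edge
#'   list or `"complete"`.
#' @param behavior_window Length of the behavior ring buffer (periods).
#' @return An object of class `social_structure`.
#' @export
social_structure <- function(adjacency, community_of = NULL,
                             n_agents = NULL, behavior_window = 1L) {
  behavior_window <- check_scalar_count(behavior_window, "behavior_window")
  complete <- FALSE
  if (is.character(adjacency) && length(adjacency) == 1 &&
      adjacency == "complete") {
    if (is.null(n_agents)) stop_config("n_agents required for complete network")
    n <- check_scalar_count(n_agents, "n_agents", min = 2)
    complete <- TRUE
    adj <- NULL
  } else if (is.data.frame(adjacency)) {
    if (!all(c("source", "target") %in% names(adjacency))) {
      stop_config("edge list needs columns source and target")
    }
    if (is.null(n_agents)) n_agents <- max(adjacency$source, adjacency$target, 0)
    n <- check_scalar_count(n_agents, "n_agents", min = 2)
    e <- unique(data.frame(
      i = pmin(adjacency$source, adjacency$target),
      j = pmax(adjacency$source, adjacency$target)))
    e <- e[e$i != e$j, , drop = FALSE]  # drop self-loops
    if (nrow(e) && (min(e$i) < 1 || max(e$j) > n)) {
      stop_config("edge endpoints must be agent ids in 1..n_agents")
    }
    adj <- Matrix::sparseMatrix(i = c(e$i, e$j), j = c(e$j, e$i), x = 1,
                                dims = c(n, n))
  } else {
    adj <- methods::as(methods::as(adjacency, "generalMatrix"), "CsparseMatrix")
    n <- nrow(adj)
    if (n < 2) stop_config("n_agents must be >= 2")
    if (ncol(adj) != n) stop_config("adjacency must be square")
    if (!Matrix::isSymmetric(adj)) stop_config("adjacency must be symmetric")
    if (any(Matrix::diag(adj) != 0)) stop_config("self-loops are not allowed")
    adj <- (adj != 0) * 1
  }
  if (is.null(community_of)) community_of <- rep(1L, n)
  if (length(community_of) != n || anyNA(community_of)) {
    stop_config("community_of must assign every agent to exactly one community")
  }
  structure(
    list(adjacency = adj, complete = complete, n_agents = n,
         community_of = as.integer(community_of),
         behavior_window = behavior_window,
         history = NULL),
    class = "social_structure"
  )
}

#' @export
print.social_structure <- function(x, ...) {
  deg <- agent_degrees(x)
  cat(sprintf(
    "Social structure: %d agents, %d communities, mean degree %.2f, window %d\n",
    x$n_agents, length(unique(x$community_of)), mean(deg), x$behavior_window))
  invisible(x)
}

agent_degrees <- function(structure) {
  if (structure$complete) {
    rep(structure$n_agents - 1, structure$n_agents)
  } else {
    as.numeric(Matrix::rowSums(structure$adjacency))
  }
}

#' Seed or append behavior histories
#'
#' `init_history()` fills every slot of the ring buffer with the given
#' behaviors (used once at initialization); `push_behavior()` appends the
#' current period's behaviors, discarding the oldest.
#'
#' @param structure A [social_structure()].
#' @param behavior Binary vector, one behavior per agent.
#' @return The updated `social_structure`.
#' @export
init_history <- function(structure, behavior) {
  check_binary(behavior, "behavior")
  if (length(behavior) != structure$n_agents) {
    stop_config("behavior must have one value per agent")
  }
  structure$history <- matrix(as.numeric(behavior), nrow = structure$n_agents,
                              ncol = structure$behavior_window)
  structure
}

#' @rdname init_history
#' @export
push_behavior <- function(structure, behavior) {
  check_binary(behavior, "behavior")
  if (length(behavior) != structure$n_agents) {
    stop_config("behavior must have one value per agent")
  }
  if (is.null(structure$history)) return(init_history(structure, behavior))
  w <- structure$behavior_window
  if (w == 1L) {
    structure$history[, 1] <- as.numeric(behavior)
  } else {
    structure$history <- cbind(structure$history[, -1, drop = FALSE],
                               as.numeric(behavior))
  }
  structure
}

window_behavior <- function(structure) {
  if (is.null(structure$history)) {
    stop_config("behavior history is empty; run init_history() first")
  }
  rowMeans(structure$history)
}

# Vectorized exposures for all agents; the engine's hot path.
# warn = FALSE suppresses the singleton-community warning (the engine warns
# once at initialization instead of every step).
social_exposures <- function(structure, warn = TRUE) {
  wb <- window_behavior(structure)
  n <- structure$n_agents
  # community exposure: prevalence among community members, focal excluded
  com_id <- structure$community_of
  csum <- rowsum(wb, com_id)
  csize <- tabulate(match(com_id, rownames(csum)), nbins = nrow(csum))
  idx <- match(com_id, rownames(csum))
  size_i <- csize[idx]
  com <- ifelse(size_i > 1, (csum[idx] - wb) / (size_i - 1), 0)
  if (warn && any(size_i == 1)) {
    warning("singleton community: community exposure set to 0", call. = FALSE)
  }
  # proximal exposure: mean of neighbors' window-averaged behavior
  if (structure$complete) {
    net <- (sum(wb) - wb) / (n - 1)
  } else {
    deg <- agent_degrees(structure)
    s <- as.numeric(structure$adjacency %*% wb)
    net <- ifelse(deg > 0, s / pmax(deg, 1), com)  # isolated -> community
  }
  list(net = as.numeric(net), com = as.numeric(com))
}

#' Social exposures of an agent
#'
#' `proximal_exposure()` is the mean window-averaged behavior of the agent's
#' proximal-network neighbors (an isolated agent falls back to its community
#' exposure); `community_exposure()` is the window-averaged LTPA prevalence
#' among the agent's community, excluding the agent itself (a singleton
#' community yields 0 with a warning).
#'
#' @param structure A [social_structure()] with populated histories.
#' @param agent_id Agent id(s) in `1..n_agents`; `NULL` returns all agents.
#' @return Numeric vector of exposures in \[0, 1\].
#' @export
proximal_exposure <- function(structure, agent_id = NULL) {
  pick_exposure(structure, agent_id, "net")
}

#' @rdname proximal_exposure
#' @export
community_exposure <- function(structure, agent_id = NULL) {
  pick_exposure(structure, agent_id, "com")
}

pick_exposure <- function(structure, agent_id, which) {
  if (!is.null(agent_id) &&
      any(agent_id < 1 | agent_id > structure$n_agents)) {
    stop_config("unknown agent id")
  }
  ex <- social_exposures(structure)[[which]]
  if (is.null(agent_id)) ex else ex[agent_id]
}

#' Generate a proximal network
#'
#' Builds a symmetric, self-loop-free social structure with one of three
#' topologies: a Watts-Strogatz small world (mean degree `k`, rewiring
#' probability `p`), an Erdos-Renyi random graph (edge probability
#' `p_edge`), or a complete graph. Uses the current RNG state; seed with
#' [set.seed()] for reproducibility.
#'
#' @param n_agents Number of agents, >= 2.
#' @param topology One of `"small-world"`, `"random"`, `"complete"`.
#' @param k Mean degree for the small world (even, `< n_agents`).
#' @param p Rewiring probability for the small world.
#' @param p_edge Edge probability for the random topology.
#' @param community_of Optional community assignment (default: one
#'   community).
#' @param behavior_window Behavior ring-buffer length.
#' @return A [social_structure()].
#' @examples
#' set.seed(1)
#' g <- generate_network(10, "small-world", k = 4, p = 0)
#' @export
generate_network <- function(n_agents,
                             topology = c("small-world", "random", "complete"),
                             k = 6, p = 0.1, p_edge = 0.1,
                             community_of = NULL, behavior_window = 1L) {
  n <- check_scalar_count(n_agents, "n_agents", min = 2)
  topology <- match.arg(topology)
  if (topology == "complete") {
    return(social_structure("complete", community_of, n, behavior_window))
  }
  if (topology == "small-world") {
    if (k %% 2 != 0 || k < 2) stop_config("small-world mean degree k must be even and >= 2")
    if (k >= n) stop_config("small-world mean degree k must be < n_agents")
    if (p < 0 || p > 1) stop_config("rewiring probability p must be in [0, 1]")
    g <- igraph::sample_smallworld(dim = 1, size = n, nei = k / 2, p = p,
                                   loops = FALSE, multiple = FALSE)
  } else {
    if (p_edge < 0 || p_edge > 1) stop_config("p_edge must be in [0, 1]")
    g <- igraph::sample_gnp(n, p_edge)
  }
  adj <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  social_structure(adj, community_of, n, behavior_window)
}

#' Read an edge list or community assignment from CSV
#'
#' `read_edges()` expects a header `source,target` (undirected edges,
#' deduplicated); `read_communities()` expects `agent_id,community_id`.
#'
#' @param path Path to the CSV file.
#' @return `read_edges()` returns a `source,target` data frame;
#'   `read_communities()` an integer vector ordered by agent id.
#' @export
read_edges <- function(path) {
  e <- utils::read.csv(path)
  if (!all(c("source", "target") %in% names(e))) {
    stop_config("edge CSV needs header source,target")
  }
  e
}

#' @rdname read_edges
#' @export
read_communities <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("agent_id", "community_id") %in% names(d))) {
    stop_config("community CSV needs header agent_id,community_id")
  }
  d <- d[order(d$agent_id), ]
  if (!identical(as.integer(d$agent_id), seq_len(nrow(d)))) {
    stop_config("community CSV must cover agent ids 1..n exactly once")
  }
  as.integer(d$community_id)
}
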