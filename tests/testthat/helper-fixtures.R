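# Fixture builders shared across test files. All fixtures are generated in
# code; nothing is read from disk.

# Environment + parameters under which every agent perceives exactly P,
# regardless of position: the access weight is zeroed and quality =
# activities = (P + 1) / 2, so the perception is distance-independent.
homogeneous_perception <- function(P, ...) {
  f <- (P + 1) / 2
  list(
    params = model_params(w_access = 0, ...),
    env = built_environment(data.frame(
      place_id = 1L, x = 5, y = 5,
      access_attr = 0, quality = f, activities = f))
  )
}

# A small hand-built structure: 4 agents, path 1-2-3-4 plus edge 2-4,
# agent 1 in community 1, agents 2-4 in community 2.
toy_structure <- function(behavior = c(1, 0, 1, 0), window = 1L) {
  edges <- data.frame(source = c(1, 2, 3, 2), target = c(2, 3, 4, 4))
  st <- social_structure(edges, community_of = c(1L, 2L, 2L, 2L),
                         n_agents = 4, behavior_window = window)
  init_history(st, behavior)
}

random_params <- function() {
  model_params(
    beta_env = stats::runif(1, 0, 0.25),
    w_self = stats::runif(1), w_net = stats::runif(1),
    w_com = stats::runif(1, 0.01, 1),
    lam = stats::runif(1, 1e-6, 1),
    w_access = stats::runif(1), w_quality = stats::runif(1),
    w_activities = stats::runif(1, 0.01, 1),
    access_scale = stats::runif(1, 0.1, 5))
}
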