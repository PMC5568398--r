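# Initialization, the synchronous schedule, determinism, and run outputs.

test_that("initialization honors the configured intention distribution", {
  cfg <- simulation_config(n_agents = 100, n_steps = 0, seed = 1,
                           init_intention = list(dist = "constant",
                                                 value = 0.5))
  st <- initialize_simulation(cfg)
  expect_equal(st$I, rep(0.5, 100))
  # uniform initial intentions: sample mean within 3 SE of 0.5
  cfg2 <- simulation_config(n_agents = 10000, n_steps = 0, seed = 2,
                            init_intention = list(dist = "uniform",
                                                  min = 0, max = 1))
  st2 <- initialize_simulation(cfg2)
  expect_lt(abs(mean(st2$I) - 0.5), 3 * sqrt(1 / 12 / 10000))
  # same seed twice: identical initial state, bit-exact
  sa <- initialize_simulation(cfg2)
  expect_identical(sa$I, st2$I)
  expect_identical(sa$b, st2$b)
  expect_identical(sa$pos, st2$pos)
})

test_that("intention bounds are absorbing for the whole population", {
  base <- homogeneous_perception(0.5)
  for (v in c(0, 1)) {
    cfg <- simulation_config(n_agents = 40, n_steps = 15, seed = 3,
                             params = base$params, environment = base$env,
                             init_intention = list(dist = "constant",
                                                   value = v))
    r <- run_simulation(cfg)
    expect_equal(r$trajectory$prevalence, rep(v, 16))
    expect_equal(r$trajectory$mean_intention, rep(v, 16))
  }
})

test_that("zero steps yields only the initial record", {
  cfg <- simulation_config(n_agents = 10, n_steps = 0, seed = 4)
  r <- run_simulation(cfg)
  expect_equal(nrow(r$trajectory), 1)
  expect_equal(r$trajectory$step, 0)
})

test_that("identical config and seed reproduce the trajectory bit-exactly", {
  base <- homogeneous_perception(0.3)
  cfg <- simulation_config(n_agents = 80, n_steps = 30, seed = 11,
                           params = base$params, environment = base$env,
                           communities = list(grid = c(2L, 2L)),
                           dump_agents = TRUE)
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$agents, r2$agents)
  d1 <- tempfile(); d2 <- tempfile()
  write_run(r1, d1); write_run(r2, d2)
  expect_identical(readLines(file.path(d1, "trajectory.csv")),
                   readLines(file.path(d2, "trajectory.csv")))
  expect_true(file.exists(file.path(d1, "agents.csv")))
  expect_true(file.exists(file.path(d1, "run_meta.json")))
})

test_that("a homogeneous complete-network state updates every agent alike", {
  # exchangeability: with fixed draws, all agents share exposures and
  # intention updates (synchronous semantics, no ordering effects)
  base <- homogeneous_perception(0.4)
  net <- social_structure("complete", n_agents = 30)
  cfg <- simulation_config(n_agents = 30, n_steps = 1, seed = 5,
                           params = base$params, environment = base$env,
                           network = net,
                           init_intention = list(dist = "constant",
                                                 value = 0.6))
  st <- initialize_simulation(cfg)
  st$b <- rep(1L, 30)  # identical histories for exact exchangeability
  st$structure <- init_history(st$structure, st$b)
  out <- sim_step(st, draws = rep(0.5, 30))
  expect_equal(length(unique(out$I)), 1)
  expect_equal(length(unique(out$b)), 1)
})

test_that("synchronous update is invariant to agent relabeling", {
  base <- homogeneous_perception(0.2)
  set.seed(21)
  net <- generate_network(12, "small-world", k = 4, p = 0.2)
  cfg <- simulation_config(n_agents = 12, n_steps = 1, seed = 6,
                           params = base$params, environment = base$env,
                           network = net,
                           init_intention = list(dist = "uniform"))
  st <- initialize_simulation(cfg)
  u <- runif(12)
  out <- sim_step(st, draws = u)
  # permute agents (state, network, draws) and step again
  perm <- sample(12)
  stp <- st
  stp$I <- st$I[perm]; stp$b <- st$b[perm]; stp$b_prev <- st$b_prev[perm]
  stp$P <- st$P[perm]
  stp$structure <- social_structure(st$structure$adjacency[perm, perm],
                                    community_of = st$structure$community_of[perm])
  stp$structure <- init_history(stp$structure, st$structure$history[perm, 1])
  outp <- sim_step(stp, draws = u[perm])
  expect_equal(outp$I, out$I[perm])
  expect_equal(outp$b, out$b[perm])
})

test_that("invalid configurations are rejected with the offending key named", {
  expect_error(simulation_config(n_agents = 10, n_steps = 5),
               "seed")
  expect_error(simulation_config(10, 5, 1, layout = list(kind = "hexagonal")),
               "layout")
  expect_error(simulation_config(10, 5, 1,
                                 init_intention = list(dist = "beta")),
               "init_intention")
  expect_error(simulation_config(10, 5, 1,
                                 network = list(topology = "lattice")),
               "topology")
  expect_error(simulation_config(10, 5, 1,
                                 communities = list(grids = c(2, 2))),
               "grids")
  expect_error(simulation_config(1, 5, 1), "n_agents")
})

test_that("configuration files round-trip through YAML", {
  base <- homogeneous_perception(0.1)
  cfg <- simulation_config(n_agents = 25, n_steps = 8, seed = 9,
                           params = base$params, environment = base$env,
                           communities = list(grid = c(2L, 1L)))
  f <- file.path(tempfile(), "config.yaml")
  write_sim_config(cfg, f)
  cfg2 <- read_sim_config(f)
  expect_equal(cfg2$n_agents, cfg$n_agents)
  expect_equal(cfg2$seed, cfg$seed)
  expect_equal(unclass(cfg2$params), unclass(cfg$params))
  expect_equal(cfg2$environment$places, cfg$environment$places)
  expect_identical(run_simulation(cfg2)$trajectory,
                   run_simulation(cfg)$trajectory)
  # unknown keys are rejected by name
  raw <- yaml::read_yaml(f)
  raw$typo_key <- 1
  g <- file.path(dirname(f), "bad.yaml")
  yaml::write_yaml(raw, g)
  expect_error(read_sim_config(g), "typo_key")
})

test_that("lagged behavior feedback changes dynamics but stays valid", {
  base <- homogeneous_perception(0.6)
  mk <- function(fb) {
    simulation_config(n_agents = 60, n_steps = 25, seed = 13,
                      params = base$params, environment = base$env,
                      behavior_feedback = fb)
  }
  r_same <- run_simulation(mk("same-period"))
  r_lag <- run_simulation(mk("lagged"))
  for (r in list(r_same, r_lag)) {
    expect_true(all(r$trajectory$prevalence >= 0 &
                    r$trajectory$prevalence <= 1))
    expect_true(all(r$trajectory$mean_intention >= 0 &
                    r$trajectory$mean_intention <= 1))
  }
})
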