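# Networks, communities, behavior histories, and exposure aggregation.

test_that("network generators produce the requested topologies", {
  st <- generate_network(4, "complete")
  h <- init_history(st, c(1, 1, 1, 0))
  # every agent sees the other three
  expect_equal(proximal_exposure(h), c(2, 2, 2, 3) / 3)

  set.seed(3)
  ring <- generate_network(10, "small-world", k = 4, p = 0)
  expect_equal(as.numeric(Matrix::rowSums(ring$adjacency)), rep(4, 10))

  set.seed(4)
  rnd <- generate_network(100, "random", p_edge = 0.5)
  md <- mean(Matrix::rowSums(rnd$adjacency))
  se <- sqrt(99 * 0.5 * 0.5 / 100)  # binomial SE of a mean degree
  expect_lt(abs(md - 49.5), 3 * se)

  expect_error(generate_network(5, "small-world", k = 6), "k")
  expect_error(generate_network(1, "complete"), "n_agents")
})

test_that("structures reject asymmetry and self-loops, edge lists dedupe", {
  a <- matrix(0, 3, 3); a[1, 2] <- 1
  expect_error(social_structure(a), "symmetric")
  b <- diag(3)
  expect_error(social_structure(b), "self-loops")
  e <- data.frame(source = c(1, 2, 2, 3), target = c(2, 1, 3, 3))
  st <- social_structure(e, n_agents = 3)
  expect_equal(as.numeric(Matrix::rowSums(st$adjacency)), c(1, 2, 1))
})

test_that("exposures aggregate window-averaged behaviors correctly", {
  st <- toy_structure(c(1, 1, 0, 1))
  # agent 2's neighbors are 1, 3, 4 with behaviors {1, 0, 1}
  expect_equal(suppressWarnings(proximal_exposure(st, 2)), 2 / 3)
  # community 2 = agents 2..4; focal-excluded prevalence for agent 2
  expect_equal(suppressWarnings(community_exposure(st, 2)), 1 / 2)
  # uniform population: exposure equals the uniform value exactly
  all1 <- init_history(toy_structure(), rep(1, 4))
  expect_equal(suppressWarnings(proximal_exposure(all1)), rep(1, 4))
  all0 <- init_history(toy_structure(), rep(0, 4))
  expect_equal(suppressWarnings(community_exposure(all0))[2:4], rep(0, 3))
  expect_error(proximal_exposure(st, 9), "agent id")
})

test_that("singleton communities warn and isolated agents fall back", {
  st <- toy_structure()  # agent 1 is alone in community 1
  expect_warning(community_exposure(st, 1), "singleton")
  expect_equal(suppressWarnings(community_exposure(st, 1)), 0)
  # isolated agent: no neighbors -> community exposure is substituted
  e <- data.frame(source = 2, target = 3)
  iso <- social_structure(e, community_of = c(1L, 1L, 1L), n_agents = 3)
  iso <- init_history(iso, c(0, 1, 1))
  expect_equal(proximal_exposure(iso, 1), community_exposure(iso, 1))
  expect_equal(proximal_exposure(iso, 1), 1)
})

test_that("behavior window averages over the configured history", {
  st <- toy_structure(c(1, 1, 1, 1), window = 2L)
  st <- push_behavior(st, c(0, 0, 0, 0))
  # each agent's window mean is 0.5 now
  expect_equal(suppressWarnings(proximal_exposure(st)), rep(0.5, 4))
  expect_equal(suppressWarnings(community_exposure(st)), c(0, 0.5, 0.5, 0.5))
})

test_that("relabeling agents leaves the exposure multiset unchanged", {
  set.seed(11)
  st <- generate_network(12, "small-world", k = 4, p = 0.3,
                         community_of = rep(1:3, each = 4))
  b <- rbinom(12, 1, 0.5)
  st <- init_history(st, b)
  perm <- sample(12)
  adj2 <- st$adjacency[perm, perm]
  st2 <- social_structure(adj2, community_of = st$community_of[perm])
  st2 <- init_history(st2, b[perm])
  expect_equal(sort(proximal_exposure(st2)), sort(proximal_exposure(st)))
  expect_equal(sort(community_exposure(st2)), sort(community_exposure(st)))
})

test_that("edge and community CSVs round-trip", {
  e <- data.frame(source = c(1L, 2L), target = c(2L, 3L))
  f <- tempfile(fileext = ".csv")
  utils::write.csv(e, f, row.names = FALSE, quote = FALSE)
  expect_equal(read_edges(f), e)
  cm <- data.frame(agent_id = 3:1, community_id = c(2L, 1L, 1L))
  g <- tempfile(fileext = ".csv")
  utils::write.csv(cm, g, row.names = FALSE, quote = FALSE)
  expect_equal(read_communities(g), c(1L, 1L, 2L))
})
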