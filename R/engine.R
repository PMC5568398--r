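# Orchestration: simulation configuration, seeded initialization, the
# synchronous per-period update schedule, and trajectory recording.
#
# One step is one behavioral period (e.g. a week; the period length is a
# label, not a model quantity). Each period the schedule is: social
# exposures are computed from the previous period's behaviors, every
# agent's intention relaxes toward its social target, the period's behavior
# is drawn from the moderated likelihood at the updated intention, and the
# behavior is appended to the history. All agents update synchronously from
# period-level quantities, so results do not depend on agent ordering.

#' Simulation configuration
#'
#' Validated bundle of everything a run needs: population size and horizon,
#' the root seed, model parameters, the built environment, the network
#' specification, the spatial layout and community grid used to place
#' agents, and the initial-intention distribution.
#'
#' @param n_agents Number of agents, >= 2.
#' @param n_steps Number of periods to simulate, >= 0 (0 records only the
#'   initial state).
#' @param seed Mandatory integer root seed; deterministically split into
#'   independent streams for network generation, initialization, and
#'   behavior draws.
#' @param params A [model_params()] object (or a list of its arguments).
#' @param environment A [built_environment()] (default: empty — worst
#'   perception everywhere).
#' @param network Either a [social_structure()] or a spec list
#'   `list(topology =, k =, p =, p_edge =)` (see [generate_network()]).
#' @param layout Spatial layout spec: `list(kind = "uniform", extent =
#'   c(xmin, xmax, ymin, ymax))` or `list(kind = "clustered", extent =,
#'   sd =)` (clusters centred on the community-grid cells).
#' @param communities `list(grid = c(gx, gy))`: communities are the cells of
#'   a gx-by-gy grid over the layout extent, or `list(assignment = <vector>)`
#'   for an explicit mapping.
#' @param init_intention Initial-intention spec: `list(dist = "constant",
#'   value =)`, `list(dist = "uniform", min =, max =)`, or
#'   `list(dist = "truncnorm", mean =, sd =)` (truncated to \[0, 1\]).
#' @param behavior_feedback Whether the intention update uses the behavior
#'   of the period just completed (`"same-period"`, default) or the one
#'   before it (`"lagged"`).
#' @param dump_agents Record per-agent states at every step.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(n_agents, n_steps, seed,
                              params = model_params(),
                              environment = built_environment(),
                              network = list(topology = "small-world",
                                             k = 6, p = 0.1),
                              layout = list(kind = "uniform",
                                            extent = c(0, 10, 0, 10)),
                              communities = list(grid = c(1L, 1L)),
                              init_intention = list(dist = "uniform",
                                                    min = 0, max = 1),
                              behavior_feedback = c("same-period", "lagged"),
                              dump_agents = FALSE) {
  n_agents <- check_scalar_count(n_agents, "n_agents", min = 2)
  n_steps <- check_scalar_count(n_steps, "n_steps", min = 0)
  if (missing(seed) || is.null(seed)) stop_config("seed is mandatory")
  seed <- check_scalar_count(seed, "seed", min = 0)
  params <- as_model_params(params)
  if (!inherits(environment, "built_environment")) {
    environment <- built_environment(environment)
  }
  behavior_feedback <- match.arg(behavior_feedback)
  layout <- validate_layout(layout)
  communities <- validate_communities(communities, n_agents)
  init_intention <- validate_init_intention(init_intention)
  if (!inherits(network, "social_structure")) {
    network <- validate_network_spec(network)
  }
  structure(
    list(n_agents = n_agents, n_steps = n_steps, seed = seed,
         params = params, environment = environment, network = network,
         layout = layout, communities = communities,
         init_intention = init_intention,
         behavior_feedback = behavior_feedback,
         dump_agents = isTRUE(dump_agents)),
    class = "sim_config"
  )
}

validate_layout <- function(layout) {
  if (!is.list(layout) || is.null(layout$kind)) {
    stop_config("layout must be a list with a 'kind' key")
  }
  known <- c("kind", "extent", "sd")
  bad <- setdiff(names(layout), known)
  if (length(bad)) stop_config("unknown layout key(s): ", paste(bad, collapse = ", "))
  if (!layout$kind %in% c("uniform", "clustered")) {
    stop_config("layout$kind must be 'uniform' or 'clustered'")
  }
  if (is.null(layout$extent)) layout$extent <- c(0, 10, 0, 10)
  ex <- layout$extent
  if (length(ex) != 4 || ex[1] >= ex[2] || ex[3] >= ex[4]) {
    stop_config("layout$extent must be c(xmin, xmax, ymin, ymax), min < max")
  }
  layout
}

validate_communities <- function(communities, n_agents) {
  if (!is.list(communities)) stop_config("communities must be a list")
  bad <- setdiff(names(communities), c("grid", "assignment"))
  if (length(bad)) {
    stop_config("unknown communities key(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(communities$assignment)) {
    if (length(communities$assignment) != n_agents) {
      stop_config("communities$assignment must have one entry per agent")
    }
    return(communities)
  }
  g <- communities$grid
  if (is.null(g)) g <- c(1L, 1L)
  if (length(g) != 2 || any(g < 1) || any(g != floor(g))) {
    stop_config("communities$grid must be two positive integers c(gx, gy)")
  }
  list(grid = as.integer(g))
}

validate_init_intention <- function(spec) {
  if (!is.list(spec) || is.null(spec$dist)) {
    stop_config("init_intention must be a list with a 'dist' key")
  }
  if (spec$dist == "constant") {
    if (is.null(spec$value) || spec$value < 0 || spec$value > 1) {
      stop_config("init_intention constant needs a 'value' in [0, 1]")
    }
  } else if (spec$dist == "uniform") {
    if (is.null(spec$min)) spec$min <- 0
    if (is.null(spec$max)) spec$max <- 1
    if (spec$min < 0 || spec$max > 1 || spec$min > spec$max) {
      stop_config("init_intention uniform bounds must satisfy 0 <= min <= max <= 1")
    }
  } else if (spec$dist == "truncnorm") {
    if (is.null(spec$mean) || is.null(spec$sd) || spec$sd <= 0) {
      stop_config("init_intention truncnorm needs 'mean' and 'sd' > 0")
    }
  } else {
    stop_config("init_intention$dist must be 'constant', 'uniform' or ",
                "'truncnorm'")
  }
  spec
}

validate_network_spec <- function(network) {
  if (!is.list(network) || is.null(network$topology)) {
    stop_config("network must be a social_structure or a list with 'topology'")
  }
  bad <- setdiff(names(network), c("topology", "k", "p", "p_edge"))
  if (length(bad)) stop_config("unknown network key(s): ", paste(bad, collapse = ", "))
  if (!network$topology %in% c("small-world", "random", "complete")) {
    stop_config("network$topology must be 'small-world', 'random' or 'complete'")
  }
  if (is.null(network$k)) network$k <- 6
  if (is.null(network$p)) network$p <- 0.1
  if (is.null(network$p_edge)) network$p_edge <- 0.1
  network
}

place_agents <- function(layout, communities, n) {
  ex <- layout$extent
  if (layout$kind == "uniform") {
    x <- stats::runif(n, ex[1], ex[2])
    y <- stats::runif(n, ex[3], ex[4])
  } else {
    # clusters centred on the community-grid cells
    g <- if (!is.null(communities$grid)) communities$grid else c(1L, 1L)
    cw <- (ex[2] - ex[1]) / g[1]
    ch <- (ex[4] - ex[3]) / g[2]
    centers <- expand.grid(
      cx = ex[1] + (seq_len(g[1]) - 0.5) * cw,
      cy = ex[3] + (seq_len(g[2]) - 0.5) * ch)
    sd <- if (!is.null(layout$sd)) layout$sd else min(cw, ch) / 6
    pick <- sample.int(nrow(centers), n, replace = TRUE)
    x <- pmin(pmax(stats::rnorm(n, centers$cx[pick], sd), ex[1]), ex[2])
    y <- pmin(pmax(stats::rnorm(n, centers$cy[pick], sd), ex[3]), ex[4])
  }
  cbind(x = x, y = y)
}

assign_communities <- function(communities, pos, extent) {
  if (!is.null(communities$assignment)) {
    return(as.integer(communities$assignment))
  }
  g <- communities$grid
  cx <- pmin(floor((pos[, 1] - extent[1]) / (extent[2] - extent[1]) * g[1]),
             g[1] - 1)
  cy <- pmin(floor((pos[, 2] - extent[3]) / (extent[4] - extent[3]) * g[2]),
             g[2] - 1)
  as.integer(cy * g[1] + cx + 1)
}

draw_init_intention <- function(spec, n) {
  switch(spec$dist,
    constant = rep(spec$value, n),
    uniform = stats::runif(n, spec$min, spec$max),
    truncnorm = rtrunc01(n, spec$mean, spec$sd))
}

# Truncated-normal sampling on [0, 1] by resampling (at most `max_tries`
# rounds, then error), so documented means stay approximately correct.
rtrunc01 <- function(n, mean, sd, max_tries = 100) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < 0 | out > 1)
  tries <- 0
  while (length(bad)) {
    tries <- tries + 1
    if (tries > max_tries) {
      stop_config("truncated-normal sampling failed to land in [0, 1] after ",
                  max_tries, " rounds; check mean/sd")
    }
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < 0 | out[bad] > 1]
  }
  out
}

#' Initialize a simulation
#'
#' Splits the root seed into independent streams, generates (or adopts) the
#' social network, places agents according to the layout, assigns
#' communities by spatial grid cell, draws initial intentions, computes the
#' static perceived environment once, and seeds the behavior histories with
#' a behavior drawn from the initial likelihood.
#'
#' @param config A [simulation_config()].
#' @return A `sim_state` list with elements `I` (intentions), `b`
#'   (behaviors), `P` (perceptions), `pos`, `structure`, `params`,
#'   `config`, `step` and the derived stream seeds.
#' @export
initialize_simulation <- function(config) {
  if (!inherits(config, "sim_config")) stop_config("config must be a sim_config")
  n <- config$n_agents
  seeds <- split_seed(config$seed, 3L)  # network / init / dynamics

  if (inherits(config$network, "social_structure")) {
    structure <- config$network
    if (structure$n_agents != n) {
      stop_config("network: social_structure size differs from n_agents")
    }
  } else {
    set.seed(seeds[1])
    structure <- generate_network(
      n, config$network$topology, k = config$network$k, p = config$network$p,
      p_edge = config$network$p_edge,
      behavior_window = config$params$behavior_window)
  }

  set.seed(seeds[2])
  pos <- place_agents(config$layout, config$communities, n)
  structure$community_of <- assign_communities(config$communities, pos,
                                               config$layout$extent)
  structure$behavior_window <- config$params$behavior_window
  I0 <- draw_init_intention(config$init_intention, n)
  P <- perceive_environment(pos, config$environment, config$params)
  L0 <- behavior_likelihood(I0, P, config$params)
  b0 <- draw_behavior(L0)
  structure <- init_history(structure, b0)
  if (any(tabulate(structure$community_of) == 1)) {
    warning("singleton community present: its community exposure will be 0",
            call. = FALSE)
  }

  structure(
    list(config = config, params = config$params, structure = structure,
         pos = pos, I = I0, P = P, b = b0, b_prev = b0,
         step = 0L, seeds = seeds),
    class = "sim_state"
  )
}

#' Advance the simulation by one period
#'
#' Synchronous schedule: exposures are aggregated from the behavior
#' histories (the previous period), every intention relaxes toward its
#' social target, the new period's behavior is drawn from the moderated
#' likelihood at the updated intention, and histories are advanced. All
#' quantities entering the update are period-level, so the result is
#' independent of agent ordering.
#'
#' @param state A `sim_state` from [initialize_simulation()] (or a previous
#'   `sim_step()`).
#' @param draws Optional numeric vector of uniforms in \[0, 1\) to use in
#'   place of fresh random draws (one per agent) — intended for tests.
#' @return The advanced `sim_state`.
#' @export
sim_step <- function(state, draws = NULL) {
  cfg <- state$config
  ex <- social_exposures(state$structure, warn = FALSE)
  b_input <- if (cfg$behavior_feedback == "same-period") state$b else state$b_prev
  I_new <- update_intention(state$I, b_input, ex$net, ex$com, state$params)
  L <- behavior_likelihood(I_new, state$P, state$params)
  if (is.null(draws)) draws <- stats::runif(cfg$n_agents)
  b_new <- as.integer(draws < L)
  state$b_prev <- state$b
  state$b <- b_new
  state$I <- I_new
  state$structure <- push_behavior(state$structure, b_new)
  state$step <- state$step + 1L
  state
}

#' Run a configured simulation
#'
#' Initializes from the config's seed and applies [sim_step()] `n_steps`
#' times under a dedicated dynamics stream, recording population summaries
#' (and per-agent states if requested) at step 0 and after every step. The
#' same config and seed reproduce the trajectory bit-exactly.
#'
#' @param config A [simulation_config()].
#' @param verbose Print step progress every `verbose` steps to stderr
#'   (0 = silent).
#' @return An object of class `ltpa_trajectory`: list with `trajectory`
#'   (data frame `step, prevalence, mean_intention, mean_perceived_env`),
#'   `agents` (long data frame or `NULL`), `community_of`, and the config.
#' @examples
#' cfg <- simulation_config(n_agents = 50, n_steps = 10, seed = 1)
#' run_simulation(cfg)
#' @export
run_simulation <- function(config, verbose = 0) {
  state <- initialize_simulation(config)
  n_rec <- config$n_steps + 1L
  rec <- vector("list", n_rec)
  dump <- if (config$dump_agents) vector("list", n_rec) else NULL
  snap <- function(state) {
    data.frame(step = state$step,
               prevalence = mean(state$b),
               mean_intention = mean(state$I),
               mean_perceived_env = mean(state$P))
  }
  snap_agents <- function(state) {
    data.frame(step = state$step,
               agent_id = seq_len(config$n_agents),
               intention = state$I,
               behavior = state$b,
               perceived_env = state$P)
  }
  rec[[1]] <- snap(state)
  if (config$dump_agents) dump[[1]] <- snap_agents(state)
  set.seed(state$seeds[3])
  for (t in seq_len(config$n_steps)) {
    state <- sim_step(state)
    rec[[t + 1]] <- snap(state)
    if (config$dump_agents) dump[[t + 1]] <- snap_agents(state)
    if (verbose > 0 && t %% verbose == 0) {
      message(sprintf("step %d/%d: prevalence %.3f, mean intention %.3f",
                      t, config$n_steps, rec[[t + 1]]$prevalence,
                      rec[[t + 1]]$mean_intention))
    }
  }
  structure(
    list(trajectory = do.call(rbind, rec),
         agents = if (config$dump_agents) do.call(rbind, dump) else NULL,
         community_of = state$structure$community_of,
         config = config),
    class = "ltpa_trajectory"
  )
}

#' @export
print.ltpa_trajectory <- function(x, ...) {
  tr <- x$trajectory
  cat(sprintf("LTPA trajectory: %d agents, %d step(s)\n",
              x$config$n_agents, nrow(tr) - 1))
  cat(sprintf("  initial prevalence %.3f, mean intention %.3f\n",
              tr$prevalence[1], tr$mean_intention[1]))
  cat(sprintf("  final   prevalence %.3f, mean intention %.3f\n",
              tr$prevalence[nrow(tr)], tr$mean_intention[nrow(tr)]))
  invisible(x)
}

#' Write run outputs
#'
#' Writes `trajectory.csv` (header
#' `step,prevalence,mean_intention,mean_perceived_env`), `agents.csv` when
#' per-agent states were recorded (long format
#' `step,agent_id,intention,behavior,perceived_env`), and `run_meta.json`
#' (config echo, seed, package version) into a directory.
#'
#' @param result An `ltpa_trajectory` from [run_simulation()].
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_run <- function(result, dir) {
  if (!inherits(result, "ltpa_trajectory")) {
    stop_config("result must come from run_simulation()")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$trajectory, file.path(dir, "trajectory.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(result$agents)) {
    utils::write.csv(result$agents, file.path(dir, "agents.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  cfg <- result$config
  meta <- list(
    seed = cfg$seed,
    n_agents = cfg$n_agents,
    n_steps = cfg$n_steps,
    params = unclass(cfg$params),
    layout = cfg$layout,
    communities = cfg$communities,
    init_intention = cfg$init_intention,
    behavior_feedback = cfg$behavior_feedback,
    network = if (inherits(cfg$network, "social_structure")) {
      list(topology = "explicit", n_agents = cfg$network$n_agents)
    } else {
      cfg$network
    },
    n_places = nrow(cfg$environment$places),
    package_version = as.character(utils::packageVersion("ltpasim")))
  jsonlite::write_json(meta, file.path(dir, "run_meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
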