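# Reading simulation configurations from YAML or JSON files, with file
# references (place tables, edge lists, community assignments) resolved
# relative to the configuration file. Unknown keys are rejected by name.

#' Read a simulation configuration file
#'
#' Reads a YAML (`.yaml`/`.yml`) or JSON (`.json`) configuration into a
#' validated [simulation_config()]. Recognized top-level keys:
#' `n_agents`, `n_steps`, `seed`, `params`, `places` (path to a place CSV,
#' relative to the config file), `network` (topology spec, or
#' `list(edges = <csv path>)`), `communities` (`grid` or
#' `list(file = <csv path>)`), `layout`, `init_intention`,
#' `behavior_feedback`, `dump_agents`. Unknown keys raise an error naming
#' the offending key.
#'
#' @param path Path to the configuration file.
#' @return A [simulation_config()].
#' @export
read_sim_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  base <- dirname(path)
  known <- c("n_agents", "n_steps", "seed", "params", "places", "network",
             "communities", "layout", "init_intention", "behavior_feedback",
             "dump_agents")
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop_config("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  for (k in c("n_agents", "n_steps", "seed")) {
    if (is.null(raw[[k]])) stop_config("configuration key '", k, "' is required")
  }
  env <- if (!is.null(raw$places)) {
    read_places(resolve_path(raw$places, base))
  } else {
    built_environment()
  }
  network <- if (!is.null(raw$network$edges)) {
    social_structure(read_edges(resolve_path(raw$network$edges, base)),
                     n_agents = raw$n_agents)
  } else if (!is.null(raw$network)) {
    raw$network
  } else {
    list(topology = "small-world", k = 6, p = 0.1)
  }
  communities <- if (!is.null(raw$communities$file)) {
    list(assignment = read_communities(resolve_path(raw$communities$file, base)))
  } else if (!is.null(raw$communities)) {
    if (!is.null(raw$communities$grid)) {
      raw$communities$grid <- as.integer(unlist(raw$communities$grid))
    }
    raw$communities
  } else {
    list(grid = c(1L, 1L))
  }
  args <- list(n_agents = raw$n_agents, n_steps = raw$n_steps,
               seed = raw$seed, environment = env, network = network,
               communities = communities)
  if (!is.null(raw$params)) args$params <- raw$params
  if (!is.null(raw$layout)) {
    raw$layout$extent <- as.numeric(unlist(raw$layout$extent))
    args$layout <- raw$layout
  }
  if (!is.null(raw$init_intention)) args$init_intention <- raw$init_intention
  if (!is.null(raw$behavior_feedback)) {
    args$behavior_feedback <- raw$behavior_feedback
  }
  if (!is.null(raw$dump_agents)) args$dump_agents <- raw$dump_agents
  do.call(simulation_config, args)
}

resolve_path <- function(p, base) {
  if (file.exists(p)) p else file.path(base, p)
}

#' Write a simulation configuration
#'
#' Writes a [simulation_config()] as a YAML file plus a sibling
#' `places.csv` when the environment is non-empty. The written pair can be
#' read back with [read_sim_config()].
#'
#' @param config A [simulation_config()].
#' @param path Path of the YAML file to write.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  if (!inherits(config, "sim_config")) stop_config("config must be a sim_config")
  base <- dirname(path)
  dir.create(base, recursive = TRUE, showWarnings = FALSE)
  out <- list(n_agents = config$n_agents, n_steps = config$n_steps,
              seed = config$seed, params = unclass(config$params),
              layout = config$layout, communities = config$communities,
              init_intention = config$init_intention,
              behavior_feedback = config$behavior_feedback,
              dump_agents = config$dump_agents)
  if (nrow(config$environment$places) > 0) {
    write_places(config$environment, file.path(base, "places.csv"))
    out$places <- "places.csv"
  }
  if (inherits(config$network, "social_structure")) {
    stop_config("explicit social_structure networks cannot be serialized; ",
                "supply a topology spec or an edge-list file instead")
  }
  out$network <- config$network
  yaml::write_yaml(out, path)
  invisible(path)
}
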