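# Trajectory summaries and the moderation diagram (likelihood of practice
# versus intention, one curve per perceived-environment level).

#' Summarize a simulation trajectory
#'
#' Deterministic aggregation of a trajectory: equilibrium prevalence (the
#' mean over the final `window` recorded prevalences), time to absorption
#' (the first step after which every prevalence change is below `tol`, or
#' `NA` when the series never settles), intention quantiles at the first
#' and last recorded step (when per-agent states were recorded), and
#' per-community prevalence at the final step (likewise).
#'
#' @param result An `ltpa_trajectory` from [run_simulation()], or a bare
#'   trajectory data frame with a `prevalence` column.
#' @param window Number of final records averaged for the equilibrium
#'   prevalence; must not exceed the number of records.
#' @param tol Absorption tolerance on per-step prevalence change.
#' @return A list of class `ltpa_summary` with elements
#'   `equilibrium_prevalence`, `time_to_absorption`,
#'   `intention_quantiles` (or `NULL`), `community_prevalence` (or
#'   `NULL`), `window`, `tol`.
#' @examples
#' cfg <- simulation_config(n_agents = 50, n_steps = 20, seed = 1)
#' summarize_trajectory(run_simulation(cfg), window = 5)
#' @export
summarize_trajectory <- function(result, window = 20, tol = 1e-6) {
  tr <- if (inherits(result, "ltpa_trajectory")) result$trajectory else result
  if (!is.data.frame(tr) || !"prevalence" %in% names(tr)) {
    stop_config("result must be an ltpa_trajectory or a trajectory data frame")
  }
  window <- check_scalar_count(window, "window")
  if (!is.numeric(tol) || tol <= 0) stop_config("tol must be > 0")
  if (window > nrow(tr)) {
    stop_config("window (", window, ") exceeds trajectory length (",
                nrow(tr), ")")
  }
  prev <- tr$prevalence
  eq <- mean(utils::tail(prev, window))
  d <- abs(diff(prev))
  tta <- if (length(d) == 0 || all(d < tol)) {
    0L
  } else {
    k <- max(which(d >= tol))
    if (k == length(d)) NA_integer_ else as.integer(k)
  }
  agents <- if (inherits(result, "ltpa_trajectory")) result$agents else NULL
  iq <- NULL
  cp <- NULL
  if (!is.null(agents)) {
    qs <- c(0.1, 0.25, 0.5, 0.75, 0.9)
    first <- agents[agents$step == min(agents$step), ]
    last <- agents[agents$step == max(agents$step), ]
    iq <- list(first_step = stats::quantile(first$intention, qs),
               last_step = stats::quantile(last$intention, qs))
    if (inherits(result, "ltpa_trajectory") && !is.null(result$community_of)) {
      cp <- tapply(last$behavior, result$community_of[last$agent_id], mean)
    }
  }
  structure(list(equilibrium_prevalence = eq,
                 time_to_absorption = tta,
                 intention_quantiles = iq,
                 community_prevalence = cp,
                 window = window, tol = tol),
            class = "ltpa_summary")
}

#' @export
print.ltpa_summary <- function(x, ...) {
  cat(sprintf("Equilibrium prevalence (last %d records): %.4f\n",
              x$window, x$equilibrium_prevalence))
  cat(sprintf("Time to absorption (tol %g): %s\n", x$tol,
              if (is.na(x$time_to_absorption)) "not absorbed"
              else x$time_to_absorption))
  if (!is.null(x$community_prevalence)) {
    cat("Final per-community prevalence:\n")
    print(round(x$community_prevalence, 4))
  }
  invisible(x)
}

#' Moderation curves: likelihood of practice versus intention
#'
#' Plots [behavior_likelihood()] as a function of intention for several
#' perceived-environment levels. The neutral curve (`P = 0`) is the
#' identity line — the relation with no effect modification; positive
#' perceptions bow the curve upward and negative perceptions downward, all
#' curves coinciding exactly at the intention bounds (0, 0) and (1, 1),
#' where the saturating moderation vanishes.
#'
#' @param params A [model_params()] object.
#' @param P_values Perceived-environment levels in \[-1, 1\] to draw.
#' @param n_points Grid resolution along the intention axis.
#' @return A ggplot object; the underlying data frame (`intention`,
#'   `perceived_env`, `likelihood`) is retrievable via `$data`.
#' @examples
#' plot_moderation_curves(model_params(), c(-1, 0, 1))
#' @export
plot_moderation_curves <- function(params, P_values = c(-1, 0, 1),
                                   n_points = 201) {
  params <- as_model_params(params)
  check_range(P_values, -1, 1, "P_values")
  grid <- seq(0, 1, length.out = n_points)
  df <- do.call(rbind, lapply(P_values, function(P) {
    data.frame(intention = grid,
               perceived_env = P,
               likelihood = behavior_likelihood(grid, P, params))
  }))
  df$perceived_env <- factor(df$perceived_env, levels = sort(P_values))
  ggplot2::ggplot(df, ggplot2::aes(x = intention, y = likelihood,
                                   colour = perceived_env,
                                   linetype = perceived_env)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Intention",
                  y = "Likelihood of LTPA practice",
                  colour = "Perceived\nenvironment",
                  linetype = "Perceived\nenvironment",
                  title = "Moderation of the intention-behavior relation") +
    ggplot2::theme_minimal()
}

#' Write a summary as JSON
#'
#' @param summary An `ltpa_summary` from [summarize_trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  if (!inherits(summary, "ltpa_summary")) {
    stop_config("summary must come from summarize_trajectory()")
  }
  out <- list(
    equilibrium_prevalence = summary$equilibrium_prevalence,
    time_to_absorption = summary$time_to_absorption,
    window = summary$window,
    tol = summary$tol)
  if (!is.null(summary$intention_quantiles)) {
    out$intention_quantiles <- lapply(summary$intention_quantiles, as.list)
  }
  if (!is.null(summary$community_prevalence)) {
    out$community_prevalence <- as.list(summary$community_prevalence)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
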