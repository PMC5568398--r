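# Places where LTPA is practiced and the perception rule mapping their
# features (access, quality, available activities) to a signed perceived
# environment.

place_cols <- c("place_id", "x", "y", "access_attr", "quality", "activities")

#' Built environment of LTPA places
#'
#' A (possibly empty) collection of places where leisure-time physical
#' activity is practiced, each with a location and three feature scores in
#' \[0, 1\]: intrinsic accessibility (everything about access except
#' distance — safety, cost, ease of transportation), quality (maintenance,
#' aesthetics, equipment, lighting, ...), and the amount/variety of
#' available activities.
#'
#' @param places A data frame with columns
#'   `place_id, x, y, access_attr, quality, activities`, or `NULL` for an
#'   environment with no places (agents then perceive the worst possible
#'   environment, -1).
#' @param extent Bounding box `c(xmin, xmax, ymin, ymax)`; defaults to the
#'   range of the place coordinates, or the unit square if empty.
#' @return An object of class `built_environment`.
#' @examples
#' env <- built_environment(data.frame(
#'   place_id = 1, x = 0, y = 0,
#'   access_attr = 0.8, quality = 0.6, activities = 0.7))
#' @export
built_environment <- function(places = NULL, extent = NULL) {
  if (is.null(places) || nrow(as.data.frame(places)) == 0) {
    places <- data.frame(place_id = integer(), x = numeric(), y = numeric(),
                         access_attr = numeric(), quality = numeric(),
                         activities = numeric())
  } else {
    places <- as.data.frame(places)
    missing_cols <- setdiff(place_cols, names(places))
    if (length(missing_cols)) {
      stop_config("places table is missing column(s): ",
                  paste(missing_cols, collapse = ", "))
    }
    places <- places[place_cols]
    if (anyDuplicated(places$place_id)) stop_config("duplicate place_id")
    check_range(places$access_attr, 0, 1, "access_attr")
    check_range(places$quality, 0, 1, "quality")
    check_range(places$activities, 0, 1, "activities")
  }
  if (is.null(extent)) {
    extent <- if (nrow(places)) {
      c(min(places$x), max(places$x), min(places$y), max(places$y))
    } else {
      c(0, 1, 0, 1)
    }
  }
  if (length(extent) != 4 || extent[1] > extent[2] || extent[3] > extent[4]) {
    stop_config("extent must be c(xmin, xmax, ymin, ymax) with min <= max")
  }
  structure(list(places = places, extent = as.numeric(extent)),
            class = "built_environment")
}

#' @export
print.built_environment <- function(x, ...) {
  cat(sprintf("Built environment: %d place(s), extent [%g, %g] x [%g, %g]\n",
              nrow(x$places), x$extent[1], x$extent[2],
              x$extent[3], x$extent[4]))
  invisible(x)
}

#' Distance-decayed effective access to a place
#'
#' Combines a place's intrinsic accessibility with physical proximity:
#' `access_attr * exp(-d / access_scale)`, where `d` is the Euclidean
#' distance between agent and place. Equals `access_attr` at distance zero
#' and decays strictly with distance.
#'
#' @param agent_location Numeric `c(x, y)`, or a matrix/data frame of agent
#'   coordinates (columns `x`, `y`).
#' @param place One or more rows of a place table (see
#'   [built_environment()]).
#' @param params A [model_params()] object (uses `access_scale`).
#' @return A numeric vector (one agent) or matrix (agents x places) of
#'   effective access scores in \[0, 1\].
#' @examples
#' pl <- data.frame(place_id = 1, x = 3, y = 4,
#'                  access_attr = 1, quality = 1, activities = 1)
#' effective_access(c(0, 0), pl, model_params(access_scale = 5))  # exp(-1)
#' @export
effective_access <- function(agent_location, place, params) {
  params <- as_model_params(params)
  xy <- agent_xy(agent_location)
  place <- as.data.frame(place)
  d <- sqrt(outer(xy[, 1], place$x, "-")^2 + outer(xy[, 2], place$y, "-")^2)
  a <- sweep(exp(-d / params$access_scale), 2, place$access_attr, "*")
  if (nrow(xy) == 1) drop(a) else a
}

agent_xy <- function(agent_location) {
  if (is.data.frame(agent_location)) {
    if (!all(c("x", "y") %in% names(agent_location))) {
      stop_config("agent coordinates need columns x and y")
    }
    cbind(agent_location$x, agent_location$y)
  } else if (is.matrix(agent_location)) {
    agent_location
  } else {
    matrix(agent_location, ncol = 2)
  }
}

#' Perceived environment to practice
#'
#' An agent's signed perception of the environment for LTPA, computed from
#' the most salient place — the one maximizing [effective_access()]. That
#' place's effective access, quality and available activities are combined
#' as a weighted mean `s` in \[0, 1\] and mapped to the signed scale
#' `P = 2 s - 1` in \[-1, 1\], so that `P = 0` is a neutral perception with
#' no moderating effect and an empty environment yields the worst
#' perception, -1.
#'
#' @param agent Agent coordinates: `c(x, y)`, a matrix, or a data frame with
#'   columns `x`, `y` (one row per agent).
#' @param env A [built_environment()].
#' @param params A [model_params()] object (perception weights and
#'   `access_scale`).
#' @return Numeric vector of perceptions in \[-1, 1\], one per agent.
#' @examples
#' env <- built_environment(data.frame(
#'   place_id = 1, x = 0, y = 0,
#'   access_attr = 1, quality = 1, activities = 1))
#' perceive_environment(c(0, 0), env, model_params())  # +1
#' perceive_environment(c(0, 0), built_environment(), model_params())  # -1
#' @export
perceive_environment <- function(agent, env, params) {
  params <- as_model_params(params)
  if (!inherits(env, "built_environment")) env <- built_environment(env)
  xy <- agent_xy(agent)
  n <- nrow(xy)
  if (nrow(env$places) == 0) return(rep(-1, n))
  w <- c(params$w_access, params$w_quality, params$w_activities)
  a <- effective_access(xy, env$places, params)
  a <- matrix(a, nrow = n)
  best <- max.col(a, ties.method = "first")
  a_best <- a[cbind(seq_len(n), best)]
  s <- (w[1] * a_best +
        w[2] * env$places$quality[best] +
        w[3] * env$places$activities[best]) / sum(w)
  2 * s - 1
}

#' Read or write a place table as CSV
#'
#' Plain CSV with header `place_id,x,y,access_attr,quality,activities`, one
#' row per place, `.` as the decimal separator.
#'
#' @param path Path to the CSV file.
#' @return `read_places()` returns a [built_environment()];
#'   `write_places()` returns `path` invisibly.
#' @export
read_places <- function(path) {
  built_environment(utils::read.csv(path))
}

#' @param env A [built_environment()] to write.
#' @rdname read_places
#' @export
write_places <- function(env, path) {
  if (!inherits(env, "built_environment")) env <- built_environment(env)
  utils::write.csv(env$places, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
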