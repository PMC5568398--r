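# Internal helpers shared across modules.

clamp01 <- function(x) pmin(1, pmax(0, x))

stop_config <- function(...) stop(..., call. = FALSE)

check_range <- function(x, lo, hi, what) {
  if (!is.numeric(x) || anyNA(x)) {
    stop_config(what, " must be numeric with no missing values")
  }
  if (any(x < lo | x > hi)) {
    stop_config(what, " must lie in [", lo, ", ", hi, "]")
  }
  invisible(x)
}

check_binary <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || !all(x == 0 | x == 1)) {
    stop_config(what, " must be binary (0 or 1)")
  }
  invisible(x)
}

check_scalar_count <- function(x, what, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    stop_config(what, " must be a single integer >= ", min)
  }
  invisible(as.integer(x))
}

#' Derive independent sub-seeds from one root seed
#'
#' Deterministically splits a root seed into `n` sub-seeds so that distinct
#' phases of a simulation (network generation, initialization, dynamics)
#' consume independent random streams. The caller's RNG state is left
#' untouched.
#'
#' @param seed Integer root seed.
#' @param n Number of sub-seeds to derive.
#' @return Integer vector of length `n`, each usable with [set.seed()].
#' @keywords internal
split_seed <- function(seed, n) {
  state <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else {
    NULL
  }
  on.exit({
    if (is.null(state)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
        rm(".Random.seed", envir = .GlobalEnv)
      }
    } else {
      assign(".Random.seed", state, envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  sample.int(2147483646L, n)
}
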