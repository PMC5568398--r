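#' Model parameters for the LTPA behavioral rules
#'
#' Bundles every free coefficient of the update rules: the strength of the
#' perceived-environment moderation of the intention-behavior relation, the
#' social weights and learning rate of the intention update, the perception
#' weights combining place features, the distance-decay scale of access, and
#' the length of the behavior window over which social exposure is averaged.
#'
#' The moderation strength `beta_env` is admissible up to 0.25: within that
#' range the behavior likelihood is provably non-decreasing in intention and
#' the defensive clamp to \[0,1\] is never active. Larger values are accepted
#' with a warning (monotonicity in intention is no longer guaranteed; the
#' likelihood is still clamped).
#'
#' @param beta_env Moderation strength, >= 0. Default 0.2.
#' @param w_self Weight of the agent's own previous behavior in the
#'   intention update, >= 0.
#' @param w_net Weight of proximal-network exposure, >= 0.
#' @param w_com Weight of community exposure, >= 0.
#' @param lam Intention learning rate in (0, 1]. Bounds of the updated
#'   intention are provable for any value in this range.
#' @param w_access,w_quality,w_activities Perception weights combining the
#'   three place features, each >= 0, sum > 0.
#' @param access_scale Distance-decay scale for place access, in the same
#'   spatial units as agent and place coordinates, > 0.
#' @param behavior_window Number of past periods over which social exposure
#'   is averaged, positive integer. Default 1 (most recent period only).
#' @return An object of class `ltpa_params` (a validated list).
#' @examples
#' p <- model_params()
#' behavior_likelihood(0.5, 1, p)
#' @export
model_params <- function(beta_env = 0.2,
                         w_self = 0.4, w_net = 0.4, w_com = 0.2,
                         lam = 0.2,
                         w_access = 1, w_quality = 1, w_activities = 1,
                         access_scale = 2,
                         behavior_window = 1L) {
  num1 <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
      stop_config(what, " must be a single non-missing number")
    }
    x
  }
  for (nm in c("beta_env", "w_self", "w_net", "w_com",
               "w_access", "w_quality", "w_activities")) {
    v <- num1(get(nm), nm)
    if (v < 0) stop_config(nm, " must be >= 0")
  }
  lam <- num1(lam, "lam")
  if (lam <= 0 || lam > 1) stop_config("lam must lie in (0, 1]")
  access_scale <- num1(access_scale, "access_scale")
  if (access_scale <= 0) stop_config("access_scale must be > 0")
  if (w_self + w_net + w_com <= 0) {
    stop_config("social weights w_self + w_net + w_com must sum to > 0")
  }
  if (w_access + w_quality + w_activities <= 0) {
    stop_config("perception weights must sum to > 0")
  }
  behavior_window <- check_scalar_count(behavior_window, "behavior_window")
  if (beta_env > 0.25) {
    warning("beta_env > 0.25: behavior likelihood is no longer guaranteed ",
            "monotone in intention (values are still clamped to [0, 1])",
            call. = FALSE)
  }
  structure(
    list(beta_env = beta_env,
         w_self = w_self, w_net = w_net, w_com = w_com,
         lam = lam,
         w_access = w_access, w_quality = w_quality,
         w_activities = w_activities,
         access_scale = access_scale,
         behavior_window = behavior_window),
    class = "ltpa_params"
  )
}

as_model_params <- function(x) {
  if (inherits(x, "ltpa_params")) return(x)
  if (!is.list(x)) stop_config("params must be a list or model_params()")
  known <- names(formals(model_params))
  bad <- setdiff(names(x), known)
  if (length(bad)) {
    stop_config("unknown parameter key(s): ", paste(bad, collapse = ", "))
  }
  do.call(model_params, x)
}

#' @export
print.ltpa_params <- function(x, ...) {
  cat("LTPA model parameters\n")
  cat(sprintf("  moderation beta_env: %g\n", x$beta_env))
  cat(sprintf("  social weights (self/net/com): %g / %g / %g\n",
              x$w_self, x$w_net, x$w_com))
  cat(sprintf("  learning rate lam: %g\n", x$lam))
  cat(sprintf("  perception weights (access/quality/activities): %g / %g / %g\n",
              x$w_access, x$w_quality, x$w_activities))
  cat(sprintf("  access_scale: %g, behavior_window: %d\n",
              x$access_scale, x$behavior_window))
  invisible(x)
}
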