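# Agent-level behavioral rules: the saturation kernel, the moderated
# intention-behavior likelihood, the Bernoulli behavior draw, and the
# saturating intention update.

#' Saturation kernel of intention
#'
#' The single kernel through which both the environmental moderation of the
#' intention-behavior relation and the social/behavioral influence on
#' intention are attenuated near the intention bounds: `4 I (1 - I)`. It
#' vanishes at `I = 0` and `I = 1`, peaks at 1 when `I = 0.5`, and is
#' symmetric about 0.5, so any influence multiplied by it weakens as
#' intention approaches either limit and disappears exactly at the limits.
#'
#' @param intention Numeric vector of intentions in \[0, 1\].
#' @return Numeric vector in \[0, 1\], `4 * intention * (1 - intention)`.
#' @examples
#' saturation(c(0, 0.25, 0.5, 1))
#' @export
saturation <- function(intention) {
  check_range(intention, 0, 1, "intention")
  4 * intention * (1 - intention)
}

#' Likelihood of practicing LTPA in a period
#'
#' The probability that an agent practices leisure-time physical activity,
#' as a function of intention moderated by the signed perceived environment:
#' `L = clamp(I + beta_env * P * 4 I (1 - I))`. A neutral perception
#' (`P = 0`) leaves the likelihood equal to the intention; favorable
#' perceptions raise it and unfavorable perceptions depress it, most
#' strongly at mid-range intention and not at all at the intention bounds
#' (so `L(0, P) = 0` and `L(1, P) = 1` for every `P`).
#'
#' For `beta_env <= 0.25` the likelihood is non-decreasing in intention and
#' the clamp is provably inactive; larger values trigger a warning.
#'
#' @param intention Numeric vector in \[0, 1\].
#' @param perceived_env Numeric vector in \[-1, 1\]; recycled against
#'   `intention`.
#' @param params A [model_params()] object.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @examples
#' p <- model_params(beta_env = 0.2)
#' behavior_likelihood(0.5, 0, p)   # identity with intention
#' behavior_likelihood(0.5, 1, p)   # 0.5 + 0.2 * 4 * 0.25 = 0.7
#' @export
behavior_likelihood <- function(intention, perceived_env, params) {
  params <- as_model_params(params)
  check_range(intention, 0, 1, "intention")
  check_range(perceived_env, -1, 1, "perceived_env")
  if (params$beta_env > 0.25) {
    warning("beta_env > 0.25: likelihood may be non-monotone in intention",
            call. = FALSE)
  }
  clamp01(intention + params$beta_env * perceived_env * saturation(intention))
}

#' Draw a period's behavior from its likelihood
#'
#' A Bernoulli draw per agent from the current behavior likelihood, using
#' R's global random stream (seed it with [set.seed()] for
#' reproducibility). Likelihoods of exactly 0 and 1 are deterministic.
#'
#' @param likelihood Numeric vector of probabilities in \[0, 1\].
#' @return Integer vector of 0/1 behaviors, same length as `likelihood`.
#' @examples
#' set.seed(1)
#' draw_behavior(c(0, 1, 0.5))
#' @export
draw_behavior <- function(likelihood) {
  check_range(likelihood, 0, 1, "likelihood")
  as.integer(stats::runif(length(likelihood)) < likelihood)
}

#' Saturating intention update
#'
#' Relaxes intention toward a social target, with the pull attenuated by the
#' saturation kernel so the bounds are absorbing. The target is the weighted
#' mean of the agent's own previous behavior, proximal-network exposure, and
#' community exposure:
#' `T = (w_self * b_prev + w_net * net + w_com * com) / (w_self + w_net + w_com)`;
#' the update is `I' = I + lam * 4 I (1 - I) * (T - I)`.
#'
#' For any `lam` in (0, 1] the result stays in \[0, 1\]; `I = 0` and
#' `I = 1` are fixed regardless of the social inputs, `T = I` is a fixed
#' point, and `I'` always moves toward `T` without overshooting it.
#'
#' @param intention Numeric vector in \[0, 1\].
#' @param behavior_prev Binary vector (0/1), the agent's previous behavior.
#' @param net_exposure Numeric vector in \[0, 1\], proximal-network exposure.
#' @param com_exposure Numeric vector in \[0, 1\], community exposure.
#' @param params A [model_params()] object (uses `w_self`, `w_net`,
#'   `w_com`, `lam`).
#' @return Numeric vector of updated intentions in \[0, 1\].
#' @examples
#' p <- model_params(w_self = 1, w_net = 1, w_com = 1, lam = 0.1)
#' update_intention(0.5, 1, 1, 1, p)  # pulled toward 1: 0.55
#' @export
update_intention <- function(intention, behavior_prev,
                             net_exposure, com_exposure, params) {
  params <- as_model_params(params)
  check_range(intention, 0, 1, "intention")
  check_binary(behavior_prev, "behavior_prev")
  check_range(net_exposure, 0, 1, "net_exposure")
  check_range(com_exposure, 0, 1, "com_exposure")
  w <- params$w_self + params$w_net + params$w_com
  if (w <= 0) stop_config("total social weight must be > 0")
  target <- (params$w_self * behavior_prev +
             params$w_net * net_exposure +
             params$w_com * com_exposure) / w
  intention + params$lam * saturation(intention) * (target - intention)
}
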