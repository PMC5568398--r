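# Deterministic mean-field recursion for the homogeneous, fully mixed
# special case (complete network, one community, identical agents sharing
# one perceived environment). Serves as an independent oracle for the
# stochastic engine: under these conditions every exposure expectation
# equals the expected prevalence, so the population aggregates follow a
# two-variable recursion.

#' Mean-field trajectory of the homogeneous model
#'
#' Iterates the deterministic twin of the agent-based dynamics for a
#' homogeneous, fully mixed population with shared perceived environment
#' `P`:
#' \deqn{\pi_t = L(I_t, P), \qquad
#'       I_{t+1} = I_t + \lambda\, 4 I_t (1 - I_t)\,(\pi_t - I_t)}
#' where `L` is [behavior_likelihood()] and the social target collapses to
#' \eqn{\pi_t} because own, network, and community exposure all have
#' expectation \eqn{\pi_t}. The recursion excludes finite-size corrections
#' (e.g. the O(1/N) focal exclusion), which Monte Carlo tolerance bands
#' must absorb when comparing against the stochastic engine.
#'
#' With `P = 0` every `I0` is a fixed point; with `P > 0` the intention
#' iterates increase toward 1 (and with `P < 0` decrease toward 0) for any
#' interior start, reflecting the positive feedback between practice and
#' intention.
#'
#' @param I0 Initial intention in \[0, 1\].
#' @param P Shared perceived environment in \[-1, 1\].
#' @param params A [model_params()] object.
#' @param n_steps Number of iterations, >= 0.
#' @return Data frame with columns `step` (0..n_steps), `prevalence`
#'   (\eqn{\pi_t}) and `mean_intention` (\eqn{I_t}).
#' @examples
#' meanfield_trajectory(0.6, 0.5, model_params(beta_env = 0.2, lam = 0.2), 1)
#' @export
meanfield_trajectory <- function(I0, P, params, n_steps) {
  params <- as_model_params(params)
  check_range(I0, 0, 1, "I0")
  check_range(P, -1, 1, "P")
  n_steps <- check_scalar_count(n_steps, "n_steps", min = 0)
  I <- numeric(n_steps + 1)
  pi <- numeric(n_steps + 1)
  I[1] <- I0
  for (t in seq_len(n_steps + 1)) {
    pi[t] <- behavior_likelihood(I[t], P, params)
    if (t <= n_steps) {
      I[t + 1] <- I[t] + params$lam * saturation(I[t]) * (pi[t] - I[t])
    }
  }
  data.frame(step = 0:n_steps, prevalence = pi, mean_intention = I)
}
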