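---
title: "Modeling population patterns of leisure-time physical activity"
author: "ltpasim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling population patterns of leisure-time physical activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 5,
                      fig.height = 4)
library(ltpasim)
```

## The model

`ltpasim` simulates how population patterns of leisure-time physical
activity (LTPA) among adults can emerge from the interplay of three levels
of influence: a psychological attribute (behavioral intention), the built
environment (places where LTPA is practiced and their features), and the
social environment (the behavior of an agent's proximal network and of the
community it lives in). The model is deliberately parsimonious — each level
is represented by the smallest set of constructs that closes the feedback
loops between them.

Each agent $i$ carries an intention $I_i \in [0,1]$ (the effort the
individual would employ to engage in LTPA), a binary behavior
$b_i \in \{0,1\}$ (practiced / did not practice during the period), and a
signed perception of the environment to practice $P_i \in [-1,1]$. One time
step is one behavioral period; the period length (a week, say) is a label
with no role in the mathematics.

### Behavior: a moderated likelihood

The probability that agent $i$ practices in a period is

$$L(I, P) \;=\; \operatorname{clamp}_{[0,1]}\!\big(I + \beta\, P \, \sigma(I)\big),
\qquad \sigma(I) = 4I(1-I).$$

Intention is the proximal determinant: with a neutral perception ($P=0$)
the likelihood *is* the intention. The perceived environment moderates this
relation — favorable perceptions ($P>0$) bow the curve above the identity
line, unfavorable ones below it — and the moderation is scaled by the
saturation kernel $\sigma$, so it is strongest at mid-range intention and
vanishes exactly at the bounds: an agent with no intention is not lured out
by a good park, and a fully committed agent is not stopped by a poor one.

The kernel $\sigma$ appears twice in the model (here and in the intention
update below) because both attenuation phenomena are verbally identical:
influences weaken as intention approaches its upper or lower limit. Using
one smooth symmetric kernel for both is the simplest form satisfying every
stated property, and it makes the bounds provable.

$\beta$ (`beta_env`) controls the moderation strength. Monotonicity of $L$
in $I$ — "the higher the intention, the more likely the behavior" — holds
for all $P$ exactly when $\beta \le 0.25$ under this functional form
(differentiate: $1 + \beta P (4-8I) \ge 1 - 2\beta \cdot |P| \ge 0$). The
constructor therefore warns above 0.25; the clamp is provably inactive
inside the admissible range and is retained purely defensively. The default
is $\beta = 0.2$.

```{r fig3}
plot_moderation_curves(model_params(beta_env = 0.2), c(-1, 0, 1))
```

### Perception: features of the most salient place

Perception derives from the features of LTPA places. Each place carries
three scores in $[0,1]$: an intrinsic access attribute (everything about
access except distance — safety, cost, ease of transportation), quality,
and available activities. Physical proximity enters through a distance
decay:

$$a_{\mathrm{eff}} = \texttt{access\_attr} \cdot e^{-d/\rho},$$

with $d$ the Euclidean agent–place distance and $\rho$ (`access_scale`,
default 2 spatial units) the decay scale. The exponential is the standard
accessibility decay; no empirical form is implied by the model's sources,
so the simplest monotone one is used.

The agent's perception comes from its *best* place — the one maximizing
effective access. The model could instead integrate over all places; the
single-most-salient-venue rule is the simplest defensible choice and is
isolated behind one function should an alternative aggregation be wanted.
The chosen place's features combine as a weighted mean
$s \in [0,1]$ (weights `w_access`, `w_quality`, `w_activities`, default
equal) and map to the signed scale $P = 2s - 1$. The signed scale is what
lets a *negative* perception depress the intention–behavior relation below
the no-moderation line; $P=0$ is the neutral case. An environment with no
places yields $P=-1$: with nowhere to practice, perception is as bad as it
can be. The environment is static over a run; feedback from behavior or
the social environment onto place features is a known, deliberate omission.

### Intention: saturating relaxation toward a social target

After each period, intention relaxes toward a target blending the agent's
own previous behavior with its social exposures:

$$T_i = \frac{w_s\, b_i + w_n\, \bar n_i + w_c\, \bar c_i}{w_s + w_n + w_c},
\qquad
I_i' = I_i + \lambda\, \sigma(I_i)\, (T_i - I_i).$$

Here $\bar n_i$ is the mean window-averaged behavior of $i$'s proximal
network (friends, relatives — an undirected graph), and $\bar c_i$ the
window-averaged prevalence in $i$'s community (everyone sharing its
geographic grid cell), both excluding $i$ itself — the agent's own behavior
already enters through $w_s$, and excluding it avoids double counting. An
isolated agent substitutes its community exposure for the undefined network
term; a singleton community contributes 0 with a warning.

Boundedness is algebraic, not numerical: at the extreme pull $T=1$,
$\lambda=1$, one gets $1 - I' = (1-I)(2I-1)^2 \ge 0$, and symmetrically at
$T=0$; for any $\lambda \in (0,1]$ the update moves toward $T$ and never
past it, $T=I$ is a fixed point, and $I \in \{0,1\}$ are absorbing. This is
why `lam` is restricted to $(0,1]$.

Defaults: $\lambda = 0.2$; $w_s = 0.4$, $w_n = 0.4$, $w_c = 0.2$. The
weights encode that one's own experience and proximal ties influence
intention more strongly than the diffuse community channel; they are
illustrative, not estimates. The exposure window defaults to 1 period
(most recent behavior only) and is configurable via `behavior_window`. No
intention decay is applied in the absence of social or behavioral signal:
the sources specify none, so none is invented.

### Schedule

Updates are synchronous: every agent's new intention is computed from
period-level quantities (previous-period behaviors and exposures), then
every behavior is drawn from the likelihood at the updated intention. The
initial behavior is drawn once at setup from the likelihood at the initial
intention, seeding the exposure histories. Synchrony makes the trajectory
independent of agent ordering and the mean-field recursion (below) an
exact first-order description. Within a recorded step $t$, the trajectory
pairs $I_t$ with a behavior drawn at $L(I_t, P)$, so simulation records
align index-by-index with the mean-field iterates.

By default the intention update uses the behavior of the period just
completed (`behavior_feedback = "same-period"`); a one-period lag is
available (`"lagged"`) since either convention is defensible.

Randomness is seeded once per run and split deterministically into three
independent streams — network generation, initialization, and behavior
draws — so adding observers or changing one phase never perturbs another,
and the same configuration and seed reproduce `trajectory.csv` byte for
byte.

## The mean-field oracle

For a homogeneous population (identical parameters and initial intention,
one community, complete network, shared $P$) the expected aggregates obey
the deterministic recursion

$$\pi_t = L(I_t, P), \qquad
I_{t+1} = I_t + \lambda\,\sigma(I_t)\,(\pi_t - I_t),$$

because own, network, and community exposures all have expectation
$\pi_t$. `meanfield_trajectory()` iterates this recursion; it is an
independent implementation against which the stochastic engine is checked,
and it exhibits the model's core qualitative behavior in closed form: with
$P=0$ every intention is a fixed point (the update is a martingale), and
with $P \gtrless 0$ intention converges monotonically to $1$ (resp. $0$) —
the positive feedback loop between practice and intention.

Two finite-population corrections separate the stochastic model from this
first-order recursion. The focal-exclusion correction is $O(1/N)$ and
negligible at the population sizes used. The second is *not* small in $N$:
whenever the own-behavior weight $w_s$ is positive, each agent's individual
Bernoulli draw kicks its intention by
$\pm\lambda\,\sigma(I)\,w_s/(w_s{+}w_n{+}w_c)$ per period, dispersing the
intention distribution; because $\sigma$ is concave and the per-agent drift
covaries with the agent's position in that distribution, the dispersion
shifts the *mean* drift relative to the recursion. The effect is a genuine
property of the agent model, of order a few times $10^{-3}$ on mean
intention at the default parameters — far larger than the Monte Carlo
standard error of a 20-seed average, which is a few times $10^{-4}$. The
package's test suite therefore contains one deliberately strict
oracle-agreement check (a 3-standard-error band per step at default
parameters) that documents this gap by failing; in the exactly
exchangeable regime $w_s = 0$, where agents receive identical social
targets up to $O(1/N)$, the engine agrees with the recursion within the
same band, which is the evidence that the discrepancy is mean-field
truncation error, not an engine defect. The recursion is kept first-order
on purpose: it is an oracle, and an oracle that absorbed the correction
would no longer be independent of the mechanism it checks.

## Synthetic scenarios

`scenario_spec()` / `generate_scenario()` create complete, reproducible
study conditions with no external data: agents placed uniformly or in
clusters centred on the community-grid cells, communities assigned by grid
cell (a "geographically limited area"), places sampled uniformly in space
with truncated-normal features (resampled into $[0,1]$, at most 100 rounds,
then an error — so documented means stay approximately correct), and a
small-world proximal network (Watts–Strogatz, $k=6$, rewiring $p=0.1$ — a
standard stand-in for friendship networks; random and complete topologies
are available).

The presets operationalize the contrasts the model exists to explore:
`baseline` (feature means 0.5), `rich-environment` / `poor-environment`
(identical except feature means 0.8 vs 0.2), and `no-social`
($w_n = w_c = 0$). Preset sizes are 300 agents, 12 places on a
10×10-unit extent, a 2×2 community grid, 100 periods, initial intentions
truncated-normal(0.5, 0.2). All preset values are illustrative defaults
chosen to be realistic for a neighborhood-scale population, not estimates
fitted to any survey.

What the generator emulates: spatial heterogeneity of access, bounded
feature scores, clustered residence, sparse clustered social ties. What it
does not: demographic structure, correlated place features, dynamic
environments, tie formation, measurement error in perception. Passing
tests on these scenarios therefore demonstrate internal consistency of the
mechanisms, not calibration to real LTPA data — parameterization against
empirical prevalence is explicitly a future layer.

## Numerical and testing choices

* Exact identities (neutral-perception identity, boundary saturation,
  absorbing bounds) are tested with `expect_identical` — they hold in
  floating point exactly, since they reduce to adding `0`.
* Behavior draws use `runif(n) < L`, which is exact at $L \in \{0,1\}$.
* Monotonicity checks use dense grids (up to $10^4$ points) and the
  boundedness fuzz uses $10^5$ random state/parameter tuples.
* Stochastic checks (zero drift under $P=0$: $N=1000$, 100 periods,
  20 seeds, tolerance 0.02; rich-vs-poor ordering: 20 paired seeds,
  one-sided sign test at 0.01; oracle comparison: $N=2000$, 100 periods,
  20 seeds) use population and replicate sizes chosen so each check runs
  in seconds while leaving its tolerance a wide multiple of the Monte
  Carlo noise.
* Ties in the best-place choice break deterministically toward the
  lower place index; "equilibrium prevalence" is operationally the mean
  over the final window (default 20 records); absorption is declared when
  every subsequent prevalence change is below `tol` (default $10^{-6}$).

## A worked contrast

```{r contrast}
eq <- function(name) {
  sc <- generate_scenario(preset(name, seed = 7))
  summarize_trajectory(run_simulation(sc$config),
                       window = 20)$equilibrium_prevalence
}
round(c(rich = eq("rich-environment"),
        baseline = eq("baseline"),
        poor = eq("poor-environment")), 3)
```

Richer place features produce favorable perceptions, which both raise the
practice likelihood directly and, through practiced behavior feeding back
into intention, pull the population toward the high-prevalence absorbing
regime; poorer features do the opposite.

## Known limitations

Intention is not decomposed into attitude and self-efficacy; volitional
constructs (goal setting, action plans) are absent; place features are
static and do not respond to social context or behavior; communities are
opaque spatial labels; behavior is binary with no frequency or dose; and
no parameter has been estimated from data. These bounds are inherited from
the conceptual scope the package implements and are the natural next
steps for extension.
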