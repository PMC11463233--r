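---
title: "Collective navigation: equilibrium accuracy, rational strategies and the evolution of leadership"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collective navigation: equilibrium accuracy, rational strategies and the evolution of leadership}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collnav)
```

## The model

A group of $n$ agents estimates the position of a navigational target on a
distant horizon. Because the target is distant, headings can be treated as
points on the real line and angular statistics can be ignored; without loss
of generality the true target sits at $0$. At each discrete time step every
agent $i$ revises its estimate $\kappa^i$ as a linear blend of two
information sources:

$$\kappa^i_{t+1} \;=\; w\, z^i_t \;+\; \frac{1-w}{n}
  \sum_j \big(\kappa^j_t + \nu^{ij}_t\big),$$

where $z^i_t \sim N(0, 1)$ is a fresh private environmental signal (its
unit variance sets the scale of everything else), $\nu^{ij}_t \sim
N(0, \gamma^2)$ is the noise with which agent $i$ observes agent $j$'s
current estimate, and the *target weighting* $w \in (0, 1]$ is the weight
on private information. The agent treats its own current estimate like any
other group member's. All quantities are dimensionless.

Because the signals are unbiased, estimates always centre on the target;
accuracy is measured by the *target error* $\sigma$, the equilibrium
standard deviation of $\kappa$. Tracking variances and covariances through
the update rule gives a two-variable recursion for $\sigma_t^2$ and the
inter-agent estimate correlation $\rho_t$, whose fixed point is closed
form:

$$\rho = \frac{(1-w)^2}{n - (1-w)^2 (n-1)}, \qquad
  \sigma^2 = \frac{n w^2 + (1-w)^2 \gamma^2}
                  {n - (1-w)^2\,(1 + (n-1)\rho)}.$$

`equilibrium_rho()` and `equilibrium_sigma()` implement these forms; the
test suite verifies them against iteration of the dynamic recursion and
against Monte Carlo simulation of the update rule itself
(`simulate_homogeneous()`).

Two special values of $w$ deserve note. At $w = 1$ agents ignore each
other and $\sigma = 1$ identically. At $w = 0$ no environmental
information ever enters the group: the correlation tends to one and, for
$\gamma > 0$, no finite equilibrium exists. The package treats $w = 0$ as a
hard error rather than a limit value, because the equilibrium denominator
vanishes there and the dynamical recursion is only guaranteed to converge
for positive $w$.

## Collective optimum versus individual rationality

$\sigma(w)$ is smooth with a unique interior minimum $w^*$
(`collective_optimal_w()`), which rises with the interaction noise
$\gamma$ (to 1 as $\gamma \to \infty$) and falls with group size. The
low-$w^*$ regime is the "many wrongs" effect in dynamic form: current
headings act as a collective memory of past signals, so attending to them
pools many past environmental draws.

A focal agent facing a population that uses $w$ has a best response

$$w' = \frac{\sigma^2\,(1 + (n-1)\rho) + \gamma^2}
             {n + \sigma^2\,(1 + (n-1)\rho) + \gamma^2},$$

obtained by minimising its own error variance with all other agents held
fixed (`best_response_w()`; tests confirm the closed form against direct
numerical minimisation). Iterating the best response from $w_0 = 1$
converges to its fixed point, the evolutionarily stable weighting
(`ess_w()`). Across all parameters the ESS sits below the collective
optimum and yields a larger error: rational individuals free-ride on the
environmental attention of others, reducing the fresh information entering
the group. The absolute penalty peaks at small-but-nonzero $\gamma$ and
vanishes as the social channel becomes useless.

### Numerical choices

* $w^*$: coarse grid over $(0, 1]$ with step $10^{-3}$, then bounded
  scalar minimisation (Brent) on the bracketing interval, to an absolute
  tolerance of $10^{-7}$ in $w$. The grid step is far finer than any
  feature of the single-minimum error curve; the bracket avoids boundary
  traps in the $\gamma \to 0$ limit, and the true boundary $w = 1$ is
  compared explicitly.
* ESS: plain best-response iteration, damping factor $0.5$ applied only
  when successive steps change sign, absolute tolerance $10^{-8}$, cap
  $10^4$ iterations with a hard error (never a silent boundary value) on
  failure.

## Mixed-expertise groups

The two-type extension has $n_A$ "expert" agents receiving unit-variance
signals and $n_B$ "naive" agents receiving signals with standard deviation
$\epsilon \ge 1$; interaction noise $\gamma$ is uniform. Each agent splits
its social attention between the types with a weight $\alpha$ on type A,
giving four strategy parameters $(w_A, w_B, \alpha_A, \alpha_B)$. The
equilibrium is now a five-variable fixed point
$(\sigma_A, \sigma_B, \rho_{AA}, \rho_{BB}, \rho_{AB})$, solved by
fixed-point iteration from the purely environmental state ($\sigma_A = 1$,
$\sigma_B = \epsilon$, zero correlations) to a residual of $10^{-8}$ or
better (`mixed_equilibrium()`). The group-level objective is the RMS
error over agents (`collective_error()`).

The collectively optimal strategy (`collective_optimum()`) is found by
Nelder–Mead in a logit-transformed space (so all four parameters stay
strictly inside the unit box, mirroring unconstrained Nelder–Mead use
without ad hoc clamping), with five restarts: the ESS, the symmetric
point, and three random draws. The ESS (`mixed_ess()`) alternates a full
equilibrium re-solve with the closed-form best responses, from
$w_A = w_B = 1$, $\alpha = 1/2$; both the attention update and the
weighting updates are applied before each re-solve.

### The best-response forms used here

The best response of a focal agent minimises its own error variance,
whose social part under attention split $\alpha$ is

$$\psi(\alpha) = \frac{\alpha^2}{n_A}\big(a + \gamma^2\big)
  + \frac{(1-\alpha)^2}{n_B}\big(b + \gamma^2\big)
  + 2\alpha(1-\alpha)\, c,$$

with $a = \sigma_A^2(1 + (n_A-1)\rho_{AA})$,
$b = \sigma_B^2(1 + (n_B-1)\rho_{BB})$ and
$c = \sigma_A \sigma_B \rho_{AB}$. Setting the $\alpha$-derivative to zero
gives

$$\alpha' = \frac{\zeta_B}{\zeta_A + \zeta_B}, \qquad
  \zeta_X = \frac{\sigma_X^2 (1 + (n_X - 1)\rho_{XX}) + \gamma^2}{n_X} - c,$$

identical for focal agents of both types (the private channel does not
involve $\alpha$), and then
$w_A' = \psi(\alpha')/(1 + \psi(\alpha'))$,
$w_B' = \psi(\alpha')/(\epsilon^2 + \psi(\alpha'))$. These are the exact
stationarity conditions of the focal objective: the tests confirm them
against a brute-force grid minimisation of the focal error and against
Monte Carlo simulation of a deviating agent. Other groupings of the
interaction-noise terms that have appeared for this model (attaching
$\gamma^2/n_X$ negatively, or using a single $\gamma^2/(n_A+n_B)$ noise
term independent of $\alpha$) are *not* stationary points of the focal
error and are not used; at $\epsilon = 1$ with symmetric counts all
variants coincide with the homogeneous best response, which is why the
symmetric consistency checks cannot distinguish them.

One consequence worth stating plainly: even for very noisy naive agents,
the optimal attention to a *single* expert stays modest (e.g.
$\alpha \approx 0.16$ at $n_A = 1$, $n_B = 9$, $\epsilon = 16$,
$\gamma = 0.5$, against a uniform-attention baseline of $0.1$). Observing
one expert carries that observation's full noise $\gamma^2$, while
averaging nine naive "relay" agents — whose headings echo pooled past
information — averages the observation noise ninefold. The qualitative
orderings are unaffected: as $\epsilon$ grows, naive agents abandon their
own signal ($w_B \to 0$), attention shifts monotonically towards the
expert under both the optimum and the ESS, the ESS attends less to the
expert and less to the environment than is collectively optimal, and the
collective error gap between ESS and optimum widens.

$\epsilon = 1$ is admitted (the naive/expert distinction is then vacuous)
because the symmetric case is the natural consistency anchor: the ESS and
optimum must then match the homogeneous results for $n = n_A + n_B$, which
the tests assert to $10^{-6}$.

## Evolution of leader and follower strategies

To let strategies emerge rather than be imposed, every agent gets its own
genome $(w_i, \epsilon_i, \gamma_i)$ — weighting, private-noise s.d. and
social-noise s.d. — and information precision is made costly through the
fitness

$$F_i = -\sigma_i - \epsilon_i^{-k} - \gamma_i^{-k},$$

with cost exponent $k > 0$. $\sigma_i$ is the agent's error at the
group's covariance equilibrium, computed from the heterogeneous
recursion: off-diagonal covariances are $(1-w_k)(1-w_l)V$ with $V$ the
variance of the mean heading, and each diagonal adds the private and
observation-noise terms $w_k^2\epsilon_k^2 + (1-w_k)^2\gamma_k^2/n$
(`equilibrium_covariance()`; the fixed point reduces exactly to the
homogeneous closed form for identical genomes and is checked elementwise
against Monte Carlo). Because the recursion couples agents only through
the scalar $V$, the fixed point is available in closed form, which is what
makes long evolutionary runs cheap; the exported function nevertheless
iterates the full matrix recursion to a $10^{-10}$ residual as its
defining contract, and the two routes are mutually checked in the tests.

`evolve()` initialises genomes from $w \sim U(0,1)$,
$\epsilon, \gamma \sim \mathrm{Exp}(1)$ (rate-one exponentials, mean 1),
then repeats for $50000\,n$ steps: one uniformly chosen agent proposes a
local mutation — $w' \sim N(w, 0.01^2)$ clipped to $[0,1]$,
$\log \epsilon'$ and $\log \gamma'$ perturbed by $N(0, 0.01^2)$ — and
adopts it iff its own fitness strictly increases with all other agents
fixed. Acceptance uses the full fitness, not the raw target error: under
an error-only criterion the cost terms are inert and both noise
parameters would simply ratchet to zero, which contradicts the
specialised phenotypes this module exists to study; a
`criterion = "sigma"` switch exposes the error-only variant for
comparison. Clipping $w$ at the boundaries deliberately admits mass at
$w = 0$ and $w = 1$, which is where follower and leader phenotypes live.
The inner loop is compiled (Rcpp) and draws from R's RNG stream, so runs
are exactly reproducible from a seed.

At $n = 2$, $k = 1$ the typical outcome is specialisation: one agent ends
with low $\epsilon$, high $\gamma$ and $w \simeq 1$ (a leader attending
only to the environment), the other with high $\epsilon$, low $\gamma$
and $w \simeq 0$ (a follower attending only to the leader). A run is
classified `leader_follower` when the spread of final weightings
$\max w - \min w$ exceeds 0.5 (`classify_outcome()`; the threshold is an
exposed constant, chosen because divergent runs end with weightings near
the two boundaries while common-strategy runs cluster). At full scale
(1000 runs of 100000 steps) 73–75% of runs diverge; the remainder end
with both agents as independent navigators ($w \simeq 1$, large
$\gamma$).

`bifurcation_scan()` repeats this over a grid of $k$ and estimates the
critical cost exponent as the midpoint between the largest
majority-divergent $k$ and the smallest majority-common $k$ above it — a
deliberately simple, stated estimator, since any estimator must be
declared to be testable. At $n = 2$ the switch lands near $k \approx 1.6$
with divergence below and a common intermediate-weighting strategy above.

### A known boundary effect at very cheap information

When $k$ is small the cost of imprecision is nearly free, and an
absorbing state exists: once an agent reaches $w = 1$ with large
$\gamma$, raising $\gamma$ always strictly increases fitness and lowering
it always strictly decreases fitness, so blindness to the group is
irreversible under strict-improvement dynamics. If two or more agents
lock in before a leader/follower structure forms, the run ends with
several independent navigators. At $n = 5$, $k = 0.5$ this happens in
roughly a quarter of runs (75/100 seeds end with exactly one agent above
$w = 0.5$, 24 with two, 1 with three); at $k = 0.75$ it was never
observed in 60 runs. A single leader is therefore the typical, not the
universal, outcome at the cheap-information extreme, and one acceptance
check that demands universality at $k = 0.5$ fails honestly for exactly
this reason. Consistent with the homogeneous theory, the leader's final
weighting declines with group size (mean over matched seeds).

## Monte Carlo verification layer

`simulate_homogeneous()` and `simulate_heterogeneous()` simulate the raw
update rules directly and never touch the analytic code, so
analytic–empirical agreement is a genuine two-route check. Initial
estimates are drawn as pure environmental estimates
$\kappa^i_0 \sim N(0, \epsilon_i^2)$ — the same "orientation from private
signals only" state that initialises the analytic iterations; the exact
initial law only affects the transient, and convergence from it is itself
asserted in the tests. An agent's social term needs only the *sum* of its
$n$ observation errors, a single $N(0, n\gamma^2)$ draw, so each step
costs two $R \times n$ Gaussian matrices regardless of group size.
Equilibrium summaries pool the post-burn-in window (default: the second
half of the run, a conservative choice given the observed relaxation
times); standard errors come from the spread across independent
replicate groups, with a delta-method step for quantities reported on the
standard-deviation scale. Strategies with near-zero weightings equilibrate
slowly (the relaxation time is set by the contraction rate of the
covariance recursion), so checks at such points use longer horizons.

## Problem sizes used in the checks

The default verification grid runs 2000 replicate groups for 200 steps
per parameter combination, which resolves equilibrium errors to about
half a percent; the evolutionary checks use 100 runs of 20000 steps at
$n = 2$ (divergence frequency), a 10-replicate scan of eleven $k$ values
(critical exponent), and 10 full-length runs each at $n \in \{2, 5, 10\}$
(leadership structure). The reproduction script reruns the divergence
count and the $k$ scan at full published scale — 1000 runs and
100000-step chains — which the compiled inner loop completes in under a
minute.

## What the generator does and does not emulate

All stochastic inputs are generated by the model itself; there is no
external data. The simulations emulate exactly the model's assumptions —
all-to-all observation, linear (small-angle) headings towards a distant
target, discrete synchronous updates, Gaussian noise everywhere, and
fixed strategies within a lifetime. Passing tests therefore demonstrate
internal consistency of theory, simulation and evolution under those
assumptions, not that real animal groups behave this way: circular
statistics at short range, local interaction neighbourhoods (which are
known to favour multiple leaders), despotic self-weighting, and
birth–death population dynamics are all outside the model. The package
deliberately stops at the real-line, equilibrium-focused formulation.

## Known limitations

* $w = 0$ groups (or all-zero weightings in the heterogeneous case) have
  no finite equilibrium and are rejected, not approximated.
* The mixed-group ESS treats the focal agent's own statistics as those of
  a generic member of its type — the same population-statistics
  approximation the homogeneous best response makes; for $n_A = 1$ the
  "attention to type A" of the expert itself is self-attention.
* The critical-exponent estimator assumes a single switch along the $k$
  grid; a non-monotone majority sequence returns `NA` rather than a
  guess.
* Near-degenerate strategies make both the fixed-point iteration and the
  Monte Carlo equilibration slow; the iteration caps raise errors with
  diagnostics rather than returning unconverged values.
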