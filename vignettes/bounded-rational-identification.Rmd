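---
title: "Bounded-rational analysis of hierarchical absolute identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bounded-rational analysis of hierarchical absolute identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braidr)
```

## The model

A subject identifying the roundness of an ellipse is modeled as an
information channel `p(a|w)` from twelve equiprobable world states to
twenty-one actions arranged in three nested precision levels (3, 6 and 12
buttons paying 0.6, 0.8 and 1 point for a correct response). A
bounded-rational decision-maker maximizes expected utility subject to a
bound on the relative entropy between its prior and posterior policies;
with the prior optimized as the action marginal, the bound becomes the
mutual information `I(W;A)` and the Lagrangian form is

$$\max_{p(a|w)} \; \mathbb{E}[U] - \tfrac{1}{\beta}\, I(W;A).$$

`blahut_arimoto()` solves this by alternating the exponential-tilt
posterior update $p(a|w) \propto p(a)\,e^{\beta U(w,a)}$ with the marginal
update. The rate of the channel is priced by the inverse temperature β;
`efficiency_frontier()` traverses β to trace the utility–information
frontier, and `efficiency()` scores an empirical operating point against
it. Level membership of the action marginal yields the mean abstraction
level with directed standard deviations (`level_statistics()`).

The same problem can be phrased as a two-step decision — first a level,
then a button within the level — with separate temperatures for the two
steps:

$$\max \; \mathbb{E}[U] - \tfrac{1}{\beta_1} I(W;L) - \tfrac{1}{\beta_2} I(W;A|L).$$

`solve_hierarchical()` iterates the coupled fixed-point equations; the
value of committing to level $l$ is its free energy
$\Delta F(w,l) = \tfrac{1}{\beta_2}\log Z(w,l)$, which for the crisp task
utility is state-independent with the closed form
$\tfrac{1}{\beta_2}\log\bigl((e^{\beta_2 u_l}+N_l-1)/N_l\bigr)$
(`delta_F()`). At $\beta_1=\beta_2$ the induced joint channel equals the
flat solution — the package tests this equivalence against the flat solver.

## Conventions and units

* Exponential tilts use natural logarithms, so β carries units of
  1/points and the free energy is in points with information in nats;
  every **reported** information quantity is converted to bits
  (bits = nats / ln 2). This conversion is itself under test.
* Probabilities below 1e-300 are treated as exact zeros and
  $0\log 0 = 0$ throughout.
* Argmax tie-breaks (rational limits, transducer action choice) go to the
  lowest flat action index; level ties in the Gaussian response model go to
  the coarser level.
* Convergence stops when successive objective values differ by less than
  `tol` (default 1e-12), with an iteration cap of 1e5. The cap is sized for
  the slow drift of the action marginal at small β, where each iteration is
  cheap but the fixed point is approached at a rate proportional to β.

## Level transitions and multistart solving

The frontier of this task is concave but not smooth: as β grows the optimal
policy jumps from concentrating on one precision level to the next. Near
such a first-order transition two branches of the fixed-point map have
nearly equal free energy and the iteration slows down critically — a
single warm-started run can satisfy the stopping rule on a metastable
plateau several hundredths of a point below the optimum. `blahut_arimoto()`
therefore restarts from a uniform and from a rational-policy marginal and
keeps the best free energy, and `efficiency_frontier()` sweeps its β grid
both upward and downward (the downward sweep starting from the rational
policy), taking the better solution per β. The downward sweep stops at
β = 0.5: a transition requires β·Δu of the order of the log branch ratio,
which for any payoff variant of this task puts all transitions well above
that. `solve_hierarchical()` applies the same idea with level-concentrated
starting priors. Across the transition gap the frontier's chord is the
exact frontier (mixtures of the two branch policies achieve it), so
piecewise-linear interpolation of the computed points remains valid there.

Two interpolators are exposed deliberately: `frontier_utility_at()`
interpolates chords, which under-estimates a concave frontier and therefore
keeps efficiency scores conservative (ε ≤ 1); `frontier_utility_bound()`
evaluates the dual tangent envelope
$\min_\beta\, F^*(\beta) + I/\beta$, a rigorous upper bound that holds for
*every* channel, which is the right reference when asserting that a
constrained model family cannot beat the frontier.

## Constrained model families

Each family restricts the search space of the optimization and so traces a
curve weakly below the frontier; each is scanned through one resource-like
parameter:

* **Fixed priors** (`frontier_fixed_prior()`): the action prior is held at
  a level-blocked vector `(q1, q2, q3)` with `3q1 + 6q2 + 12q3 = 1`,
  presets uniform-over-actions (1/21) and uniform-over-levels
  (1/9, 1/18, 1/36), instead of adapting to the optimal marginal.
* **Payoff distortion** (`distort_utility()`): 0.6 → V₀.₆ and 0.8 → V₀.₈
  with 0 < V₀.₆ < V₀.₈ < 1, preserving the zero pattern — subjective risk
  attitude without neighborhood structure.
* **Blurred utility** (`blur_utility()`): within each level the payoff
  decays with button distance from the correct response under an
  exponential or Gaussian Shepard kernel normalized to k(0) = 1, valuing
  near misses. No mass crosses levels.
* **Gaussian responses** (`gaussian_response_channel()`): the response is a
  discretized Gaussian over the buttons of one level, centered on the
  correct button with a common scanned σ; each state adopts the level whose
  candidate maximizes expected utility. The curve's mean level is a step
  function of σ — a finer level is adopted only when its performance
  overtakes.
* **Perceptual transducers** (`transducer_channel()`): the observer sees a
  noisy percept x with likelihood p(x|w) — truncated Gaussian on [0,1]
  (Thurstonian, parameter σ) or Binomial counts of T Bernoulli cues with
  success probability w — forms the Bayes posterior over the twelve states,
  and picks the utility-maximizing action. Averaging the deterministic
  choice over percepts yields the channel. The Binomial variance shrinks at
  the ends of the roundness scale, which reproduces the bow effect: extreme
  states earn finer-level responses than central ones.

Design choices where the construction was genuinely open: the Gaussian
response profile lives on within-level button indices (a flat 21-action
support would mix payoff scales across levels and cannot produce the
observed stepwise level changes); the Thurstonian percept space is a
1001-point grid on [0,1], resolution 0.001 ≪ the 1/12 button width; the
Binomial channel uses the discrete uniform prior over the twelve roundness
values (the continuous Beta conjugacy is kept as a test oracle, checked to
1e-6 total variation against brute-force discrete Bayes on a 2001-point
grid).

## Empirical estimators

`estimate_response()` computes plug-in response frequencies per subject and
condition; a world state with no trials is treated as a data defect (50
scheduled repetitions per state make absence an error, not something to
impute). `empirical_information()` is the raw plug-in mutual information —
no bias correction is applied, and its upward finite-sample bias (order
cells/2N ln 2 bits) is the main caveat when reading efficiencies from small
samples. `alternative_information_12()` implements an alternative
accounting in which a coarse button press is equivalent to a uniform press
of its nested precise buttons, so random coarse responding generates
log2 3 rather than log2 21 bits; coarsening can only lower the measure.
`nearest_frontier_channel()` matches an estimate to the closest stored
channel on a curve by elementwise L2 distance — the norm is a package
choice, selectable in principle, and symmetric alternatives would not
change the matched neighborhoods materially.

## Fitting and cross-validation

`grid_fit()` is an exhaustive scan: the objective is the mean absolute
error over all 12 × 21 cells between predicted probabilities and observed
frequencies, with ties to the lexicographically smallest grid point.
Because predicted channels do not depend on the data, `family_channels()`
precomputes them once per family and `crossval()` reuses them across
subjects and folds. Cross-validation partitions each subject × condition
cell into 10 seeded folds (sizes within one trial of each other); held-out
MAE excludes states with no held-out trials, and the level score is the
mean predicted probability of the level containing each held-out response
given its world state. Statistical comparison across models (ANOVA-style
testing) is intentionally out of scope; the per-fold table is the product.

## The synthetic cohort

`simulate_cohort()` emulates the experiment's structure: six conditions
crossing three perceptual difficulties with two response deadlines, 600
trials per condition on a balanced, shuffled schedule of 50 repetitions per
world state. The default generator is a Thurstonian observer with noise
σ = (0.030, 0.045, 0.060, 0.080, 0.110, 0.150) across the six conditions in
difficulty order and per-subject log-normal heterogeneity (sdlog 0.25,
clipped to a factor of 2). These values are stand-ins chosen so that the
implied (information, utility) operating points span the task's resource
range monotonically — roughly 3.1 bits down to 0.8 bits — and are labeled
as such; they are not measured human parameters. What passing tests on this
cohort do show: estimators converge to their generating values, the
generating family wins cross-validation, and parameters are recoverable.
What they cannot show: sequence effects, learning, response-time structure
or any other feature of real data the generator does not model.

## The stimulus simulator

Stimuli are 30-frame dot videos: signal dots ride the boundary of the
invisible ellipse (minor semi-axis $a_i = (2i-1)/48$, major semi-axis 1/2,
so roundness $w_i = (2i-1)/24$ sits at the midpoint of the i-th precise
button) while random dots walk incoherently; per frame a fixed percentage
of signal dots is swapped against the noise pool. The dot dynamics are a
package choice: one boundary revolution per 60 frames with random phases,
noise steps uniform in a disc of radius 0.02 reflecting at the unit-square
walls — smooth coherent motion against incoherent jitter, which is the
property the recognition algorithm exploits. The recognizer pairs
consecutive frames by greedy minimum distance, inverts the ellipse equation
for a minor-axis estimate $\hat a = |x| b / \sqrt{b^2 - y^2}$ per point,
keeps pairs whose two estimates agree within 0.1 (a consistency filter —
points on the ellipse give identical estimates regardless of where on the
boundary they sit, random pairs rarely do), and returns the modal nearest
candidate bin. On hard-condition stimuli (50 signal dots against 450
noise dots at 40% replacement) this identifies all states correctly,
demonstrating that task difficulty lies in perceptual processing, not in
stimulus ambiguity.

## Problem sizes used by the tests

The test suite runs the full 60-point frontier once and caches it; solver
oracles use a 2-state primal simplex grid at step 0.01 and a 3-state dual
marginal grid at step 0.002; recovery tests use 600- and 60,000-trial
samples; the cross-validation tournament uses three synthetic subjects,
three conditions, 240 trials per cell and reduced grids; stimulus tests
recognize one hard video per state plus noise-free batches, while the
acceptance script runs the full 60-video accuracy experiment. These sizes
were chosen as the smallest at which each property is comfortably
non-marginal.

## Known limitations

* The plug-in information estimator's finite-sample bias is documented but
  not corrected; efficiency at 600 trials is mildly underestimated.
* The frontier is computed on a β grid; between grid points the chord is
  exact only across level-transition gaps, elsewhere it is a lower bound
  (the tangent envelope bounds from above).
* Motor execution noise is not modeled, and trial tables carry completed
  trials only — skipped or timed-out trials have no representation.
* The hierarchy is fixed at 3/6/12 nested buttons; the types would
  generalize, but nothing else is tested.
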