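---
title: "Assaying Theory-of-Mind sophistication from dyadic game play"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assaying Theory-of-Mind sophistication from dyadic game play}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomassay)
```

## The problem

How sophisticated is an individual's model of other minds? One operational
answer: let the individual play a repeated two-choice "hide-and-seek" game
against opponents of calibrated sophistication, and ask which *learning
style* best explains the trial-by-trial choice sequence. Learning styles
range from heuristics that ignore the opponent entirely to recursive
belief updating ("I believe that you believe that I believe ..."), and
each style leaves a distinct statistical signature in the choice sequence.
`tomassay` implements the full computational pipeline: the candidate
learning models, the game protocol, Bayesian model inversion and
comparison, a model-free kernel decomposition, group-level statistics, and
a synthetic-cohort generator with known ground truth for validating every
stage.

## The game and the decision rule

Each trial, both players pick one of two hands. The seeker is rewarded
when the hands match (`U(1,1)-U(0,1) = U(0,0)-U(1,0) = 1`), the hider when
they differ; the payoff tables are anti-symmetric, so the game is strictly
competitive. All models share a softmax decision policy

$$P(a^{self}=1) = s\!\left(\frac{\Delta V}{\beta} + b\right), \qquad
\Delta V = p^{op}\,(U(1,1)-U(0,1)) + (1-p^{op})\,(U(1,0)-U(0,0)),$$

with temperature $\beta > 0$ and a choice bias $b$. For the seeker's table
$\Delta V = 2p^{op}-1$. Models differ only in how they form the prediction
$p^{op}$ that the opponent picks hand 1.

## The candidate model set

Four models do not attribute mental states (the *no-ToM* family):

* **BN** (biased Nash) fixes $\Delta V = 0$: random play with a bias, the
  unexploitable equilibrium of the game. Its temperature is
  non-identifiable, so only the bias is fitted.
* **WS** (win-stay/lose-switch) sets the chosen option's value to the last
  reward and the other to its negative.
* **RL** moves the chosen option's value towards the reward by a learning
  rate $\alpha$.
* **0-ToM** tracks the opponent's choice tendency as a hidden log-odds
  $x_t$ drifting with volatility $\sigma^0$, with the Gaussian-posterior
  recursion
  $\Sigma_t = [(\Sigma_{t-1}+\sigma^0)^{-1} + s(\mu)(1-s(\mu))]^{-1}$,
  $\mu_t = \mu_{t-1} + \Sigma_t\,(a^{op}_t - s(\mu_{t-1}))$. At
  $\sigma^0 = 0$ this reduces to fictitious play. Predictions use the
  moment-matched expectation $E[s(x)] \approx s(\mu/\sqrt{1 + a\Sigma})$
  with $a = 3/\pi^2$.

Six models qualify as *ToM-compatible*:

* **Inf** (influence learning, cooperative and competitive variants)
  augments a delta rule with a heuristic term for how one's own action
  shifts the opponent's strategy:
  $p' = p + \eta(a^{op}-p) - \lambda p(1-p)\,[\,2a^{self} +
  (2I^{comp}-1)\beta s^{-1}(p) + I^{comp}\,]$, clamped to
  $[10^{-4}, 1-10^{-4}]$. The grouping of the adjustment term (including
  the un-centred $2a^{self}$ and the sign convention attached to
  $I^{comp}$) is transcribed verbatim from the source formulation. Note
  that under the cooperative reading ($I^{comp}=0$) the own-action term
  still *lowers* the predicted probability, which looks counter-intuitive;
  we deliberately did not "correct" it, and the model-comparison machinery
  treats it purely as a candidate likelihood.
* **1-ToM / 2-ToM** (cooperative and competitive variants) model the
  opponent as a 0-ToM (resp. 0- or 1-ToM) agent and update a posterior
  over the opponent's sophistication level $\lambda^{k,\kappa}$ jointly
  with Gaussian beliefs over each opponent model's hidden states
  $x^\kappa = (\log\sigma, \log\beta)$:
  level posteriors by Bayes rule on each level's predicted probability of
  the observed action, and hidden-state beliefs by a Laplace-style update
  weighted by the level posterior (the level weight appears inside both
  the mean and the covariance update, as in the source formulation). The
  cooperative and competitive variants differ only in the presumed
  opponent payoff table.

## Numerical design of the recursive update

Three implementation choices deserve a record:

* **Gradient by replica simulation.** The update needs the gradient
  $W^\kappa$ of the opponent model's predicted choice log-odds with
  respect to its hidden states. Instead of replaying the opponent model
  from scratch at perturbed parameters every trial (quadratic-to-cubic
  cost in session length), the belief state carries five replica
  simulations of the opponent, propagated throughout the history at
  $\theta = \mu \pm \delta e_i$ with $\delta = 10^{-4}$; the central
  difference of the replicas' predicted log-odds captures the full
  history sensitivity at constant cost per trial.
* **Marginalised predictions.** Each level's predicted probability is
  $s(v(\mu)/\sqrt{1 + a\,W^\top\Sigma W})$, the same moment-matching
  closed form used for the 0-ToM prediction, so wide posteriors give
  appropriately humble predictions. The mean/covariance updates keep the
  point forms $s(v(\mu))$, $s'(v(\mu))$.
* **Guards.** Probabilities entering likelihoods or logits are clamped at
  $10^{-4}$; posterior means of hidden states are soft-bounded at
  $\pm 12$ (beyond which `exp` would overflow the volatility); the
  covariance update carries a $10^{-9}$-scale ridge so a flat prior plus
  rank-one information stays invertible. None of these bind on ordinary
  trajectories.

The whole per-trial recursion is implemented in C++ (`src/engine.cpp`);
the exported R operations (`tom0_update()`, `rl_update()`, `ws_update()`,
`influence_update()`) are independent R implementations that the test
suite replays against the engine.

## Simulation defaults: what the generator emulates

The session protocol mirrors the study design: 12 sessions of 60 trials,
four per opponent condition, counterbalanced by a Latin square across
individuals; sessions shorter than 20 trials are flagged excluded. The
three opponents are a biased-random sequence (65% on a favoured hand,
counterbalanced), and on-line competitive 0-ToM and 1-ToM hiders with
$\sigma = 0.5$, $\beta = 1$ — configuration values of the protocol, not
fitted quantities.

Simulated *subject* agents default to a near-greedy temperature
$\beta = 0.02$ and, for the recursive models, a small own-volatility
$\sigma^k = 0.05$. Both deserve justification. The artificial agents of
the protocol act on their predictions (the hider "hides where it predicts
the seeker will go"), i.e. near-deterministically; and the opponent
parameters a recursive agent estimates are quasi-stationary, so a small
drift variance is the coherent prior. The alternative (temperature near 1,
volatility 0.5) makes the posterior over the opponent's parameters diffuse
faster than the game supplies information; the estimated opponent
temperature then inflates without bound and predictions collapse to 0.5,
which contradicts the qualitative phenomenology this assay is built
around (1-ToM exploiting 0-ToM, influence learning losing to 1-ToM,
recursive agents being largely reducible to choice-history kernels). The
cohort generator samples volatilities per family (around 0.5 for
action-tracking models, 0.05 for recursive ones) and temperatures around
0.05, log-normally.

What the generator does **not** emulate: attention lapses and motivation
drifts beyond optional session truncation, caregiver-identity effects,
learning that transfers across sessions (state resets at each session
boundary), and any real species' parameter distributions — the packaged
species table is synthetic and clearly labelled as such. Passing tests
therefore validate the machinery, not any biological claim.

## Inversion: variational Laplace

Each model is fitted per opponent condition (parameters shared across the
sessions of a condition, free across conditions) on the transformed scale
(log volatilities, temperatures and influence weights; logit rates;
natural-scale bias) with independent Gaussian priors: N(0, 3) on
log/logit parameters, N(0, 10) on the bias. The posterior is Gaussian by
construction: a damped Gauss–Newton ascent using the expected (Fisher)
information — positive definite by construction, computed by finite
differences of the per-trial choice log-odds — accepts a step only if the
Laplace free energy does not decrease, so the free-energy trace is
monotone. Convergence is declared at $|\Delta F| < 10^{-3}$ nats within
64 iterations; four deterministic initialisations (prior mean plus fixed
perturbations) guard against the multi-modal likelihoods of the recursive
models, stopping early once two starts agree. Summing the three
per-condition free energies gives each individual's model evidence.

## Model comparison

Within subject, the ten log-evidences are softmax-normalised under a
uniform prior over models, and `pToM` is the posterior mass on the
ToM-compatible family; equal evidences give 0.6 because the family holds
six of the ten models. A uniform-over-families prior (0.5 at equal
evidence) is available as an option. Species scores average individual
`pToM` (the alternative — refitting at species level — is not what the
averaging description in the source suggests).

At the group level, `rfx_bms()` implements random-effects Bayesian model
selection: a variational Dirichlet-multinomial scheme over subject-wise
model assignments, exceedance probabilities by Monte-Carlo sampling of
the Dirichlet posterior ($10^5$ draws, seeded), and protected exceedance
probabilities through the Bayesian omnibus risk against the
equal-frequency null. Two accuracy notes: the variational posterior is
known to favour the winning model relative to the exact posterior mean —
at unit-scale evidence gaps with five subjects the discrepancy reaches
0.03–0.07 in expected frequency — so the oracle-comparison tests operate
in the weak-evidence regime where the approximation is faithful, and the
qualitative checks (ordering, winner identity) cover the strong-evidence
regime. `between_group_bms()` samples both groups' Dirichlet posteriors
and reports the posterior probability that one group's frequency-weighted
mean sophistication rank (BN < WS < RL < 0-ToM < Inf < 1-ToM < 2-ToM,
variants tied) exceeds the other's.

## Volterra decomposition

`fit_volterra()` regresses each session's choices on exponentially
parameterised kernels over both players' action histories,
$q_t = s(\omega_0 + \sum_\tau A^{op} e^{-\lambda^{op}\tau}(2a^{op}_{t-\tau}-1)
+ \sum_\tau A^{self} e^{-\lambda^{self}\tau}(2a^{self}_{t-\tau}-1))$,
by Laplace-approximated MAP with priors N(0, 10) on the bias, N(0, 3) on
magnitudes and N(log 0.5, 1) on log decays. Lags start at $\tau = 1$ (the
same-trial opponent action is not causally available to the subject) and
run to 15, below 1% of kernel magnitude for decays above about 0.3. Early
trials use the available lags only. Within-sample accuracy thresholds the
fitted probability at 0.5. Because lagged self- and opponent-regressors
are collinear for imitative sequences, exponential-kernel fits show a
compensating opposite-sign weight on the other kernel; tests assert
dominance, not exclusivity. Per-session fits are averaged within
individual and condition downstream.

## Group-level statistics

`adjust_performance()` removes session-repetition and inter-session-gap
effects per individual by OLS, preserving the individual mean
(idempotent). `effects_regression()` analyses the adjusted per-condition
scores in two strata: subject intercepts plus opponent,
species-by-opponent and covariate-by-opponent terms within subjects
(nested-model F tests), and the species effect plus weighted linear
feature contrasts between subjects on individual means. With one species
it reduces exactly to one-way repeated-measures ANOVA; the synthetic
design documents its own degrees of freedom rather than copying any
published ones. `sobel_mediation()` implements the classical product-
of-coefficients z test; it is conservative in small samples (the type-I
calibration tests run at n = 300 where the normal approximation holds).
`species_feature_regression()` correlates and regresses species `pToM`
against log-transformed features; no multiplicity correction is applied,
matching the reporting style of the analyses it mirrors; phylogenetic
correction is out of scope.

## Validation harnesses and problem sizes

`confusion_analysis()` simulates individuals from every generating model,
inverts the full model set and tabulates best-evidence models at both the
model and the ToM/no-ToM family level. One structural boundary case is
worth knowing: a recursive model whose temperature is large reproduces
biased-random play exactly, and since non-identified parameters carry no
Occam penalty under the Laplace evidence, biased-Nash individuals are
attributed to their own family only about three times in four —
evidence margins there are fractions of a nat. Every other generating
model attributes to its own family at 0.8 or better at the full design.
`parameter_recovery()` reports bias and 95%-interval coverage over a
parameter grid. The packaged test
scale — three 40-trial sessions per condition, five individuals per
generating model, 50 games of 200 trials for the kernel-reducibility
computation — was chosen so the full suite exercises every stage at
sizes where the statistical properties are already stable.

## Known limitations

* Recursion depth stops at k = 2; no continuous-action or multi-option
  games.
* The influence-learning equation is used exactly as printed; its
  cooperative variant's sign convention is flagged above.
* The variational BMS inherits the documented winner-favouring bias.
* Free energies are Laplace approximations; no MCMC cross-check beyond
  the one-parameter quadrature oracle.
* The generator's parameter distributions are package choices, not
  estimates from any animal data.
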