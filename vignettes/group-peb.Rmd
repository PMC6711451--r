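---
title: "Hierarchical empirical Bayes over Gaussian parameter posteriors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical empirical Bayes over Gaussian parameter posteriors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peblm)
```

## The problem

Group studies of effective connectivity (and many other model-based analyses)
have a two-level structure. At the first level, a state-space or regression
model is fitted to each subject's timeseries, yielding a multivariate normal
posterior density over that subject's parameters — for connectivity, typically
unitless log-scaling modulations or rates in Hz — together with a log-evidence
(negative variational free energy). At the second level we want to know what
is common across subjects, what varies with measured covariates (a laterality
score, age, drug dose, group membership), and how much unexplained
between-subject variability remains.

Carrying only each subject's posterior *means* to a classical second-level
test discards the estimated uncertainty. `peblm` instead implements a
parametric empirical Bayes (PEB) scheme: the full posterior/prior pair of
every subject enters a hierarchical Gaussian model, so precisely estimated
subjects weigh more than noisy ones, and hypotheses are scored by model
evidence rather than point statistics.

## The model

Writing \(\theta^{(1)}\) for the stacked subject-level parameters (P per
subject, N subjects) and \(\theta^{(2)}\) for the group-level effects:

\[
\begin{aligned}
\theta^{(2)} &= \eta + \varepsilon^{(3)}, &\varepsilon^{(3)} &\sim N(0, \Sigma^{(3)})\\
\theta^{(1)} &= X\theta^{(2)} + \varepsilon^{(2)}, &\varepsilon^{(2)} &\sim N(0, \Sigma^{(2)})\\
Y_i &= \Gamma_i(\theta^{(1)}_i) + \text{nuisance} + \varepsilon^{(1)}_i
\end{aligned}
\]

The design matrix is a Kronecker product \(X = X_B \otimes X_W\): the
between-subjects part \(X_B\) (N × C) holds one column per covariate, with a
leading column of ones for the commonalities; the within-subject part
\(X_W\) (P × P, binary diagonal) selects which parameters receive group-level
effects. Each column of \(X\) is therefore one covariate's effect on one
parameter, and a C-covariate, P-parameter analysis estimates C·P group
effects. Covariates after the constant are mean-centred by default, which
gives the first column the interpretation of the group mean; without
centring it is a baseline.

The package never touches the first level's raw data \(Y_i\): each subject
enters through the exact identity
\(p(Y_i\mid\theta_i) = e^{F_i}\, N(\theta_i;\mu_i,\Sigma_i)/N(\theta_i;\mu_0,\Sigma_0)\),
i.e. the likelihood is reconstructed from the posterior/prior pair (and the
free energy \(F_i\), when available, as a constant offset). This is exact for
conjugate linear first levels and is the standing approximation for
variational posteriors from nonlinear models.

## Priors and hyperparameters

Two ratios govern the default second-level priors, both relative to the
first-level prior variances \(v_j\):

* **alpha** (default 1) — prior variance of each group-level effect is
  \(\alpha\, v_j\). The prior uncertainty about a group effect therefore
  equals the prior uncertainty about the corresponding subject-level
  parameter.
* **beta** (default 16) — the baseline between-subject (RFX) variance is
  \(v_j/\beta\), i.e. one sixteenth of the first-level prior variance. The
  modelling assumption is that random effects have a quarter of the standard
  deviation of the a-priori plausible parameter range; data worth pooling
  across subjects should vary less from subject to subject than our prior
  ignorance about the parameter itself.

The RFX precision is parameterised as
\(\Pi^{(2)}(\gamma) = \sum_j e^{\gamma_j} Q_j\), with baseline components
\(Q_j\) scaled so that \(\gamma = 0\) reproduces the \(v/\beta\) variance,
and a weakly informative hyperprior \(\gamma_j \sim N(0, 1/16)\) on each
log-scaling parameter. By default a single shared component is used
(`rfx = "single"`); `rfx = "all"` gives one component per parameter for
parameter-wise RFX resolution at extra computational cost. The prior mean
\(\eta\) equals the first-level prior mean on the group-mean block and zero
on covariate blocks, so an uninformative group is a priori centred on the
first-level prior. Column norms of \(X_B\) are recorded (and can be used to
rescale covariate-block prior variances via `covariate_scale`), but no
rescaling is applied by default: the effect of a covariate is reported in
the covariate's own units.

## Estimation

At fixed \(\gamma\), everything is linear-Gaussian and the conditional
posterior \(N(m, S)\) over the C·P group effects is exact: each subject
contributes precision \(X_i^\top(\Sigma^{(2)} + \tilde\Sigma_i)^{-1} X_i\),
where \(\tilde\Sigma_i\) is the data uncertainty implied by the subject's
posterior/prior pair; the algebra is arranged so the (possibly indefinite or
singular) data precision \(P_i - P_0\) is never inverted. `fit_peb()`
alternates this conditional step with damped Newton ascent on \(\gamma\)
(finite-difference gradient and Hessian, step halved until the objective does
not decrease; convergence when the objective improves by less than 1e-4 nats,
at most 64 iterations). The reported free energy adds the hyperprior and a
Laplace correction for the posterior uncertainty of \(\gamma\), so it
approximates the log evidence of the entire hierarchical model up to the
subjects' stored first-level accuracy terms. The objective trace is
non-decreasing by construction; a fit that exhausts its iterations is
returned flagged `converged = FALSE` at its best iterate.

`fit_peb()` also returns, per subject, the level-2-implied *empirical prior*
\(N(X_i m, \Sigma^{(2)} + X_i S X_i^\top)\) — the group posterior propagated
down one level, including its own uncertainty. For simulation studies with
the linear toy first level, `refit_with_empirical_priors()` re-inverts each
subject under its empirical prior and re-fits the group model; the group
prior is deliberately frozen at round 0 so iterated refits cannot narrow it.
On exact linear problems the total free energy is invariant across rounds
(the likelihood reconstruction does not depend on the first-level prior), so
the procedure is a fixed point there; its value lies in pulling subject-level
estimates out of bad prior basins, which is exactly what the tests check
(lower subject-level RMSE after refitting under deliberately mis-centred
priors).

## Hypothesis testing by model reduction

A hypothesis is a pattern of group effects switched *off* — fixed at their
prior mean with a near-delta prior variance (`off_floor`, default 1e-8; kept
configurable because "fixed at zero" needs a numerical floor, and reduced
models must stay on the common parameter vector rather than dropping
dimensions). Given the full model's posterior and prior and the reduced
prior, Bayesian model reduction (`bmr_evidence()`) gives the reduced
posterior and the log-evidence change in closed form; on linear-Gaussian
problems this equals explicit re-inversion to machine precision, which the
test suite verifies exhaustively over all \(2^6\) masks of a six-parameter
toy and over all \(2^4\) reductions of a conjugate first-level unit.

On top of this primitive:

* `factorial_space()` enumerates factor-level combinations into on/off masks
  (intersection of the chosen levels' cell sets), appending an all-off null
  model — e.g. three factors × three levels + null = 28 models. Ordering is
  factor-major with the null last, so model indices are reproducible.
* `compare_grid()` crosses a space over the commonalities block with a space
  over a covariate block (nuisance cells always on), scores all pairs
  (28 × 28 = 784) by reduction, and softmaxes to a joint posterior matrix
  with marginals per axis.
* `family_pool()` / `family_grid()` pool model posteriors into families under
  the prior that families are equally likely (model priors reweighted by
  1/family size before normalisation).
* `bma()` computes a Bayesian model average with full mixture moments (not
  mean-stacking — the averaged covariance carries the between-model spread,
  which honest credible intervals need), each cell's posterior probability of
  being present (summed probability of models with the cell on), and an
  optional thresholded view (default 95%).
* `greedy_search()` prunes cells that do not contribute to model evidence
  when no model space is pre-specified. Exhaustive enumeration is hopeless
  (a 5-covariate × 8-parameter GLM has \(2^{40} \approx 1.1\times10^{12}\)
  reduced models), so the search repeatedly evaluates single-cell prunes and
  discards while evidence does not decrease, breaking ties toward the cell
  with the smaller posterior |mean|/sd; multi-cell prunes per iteration are
  deliberately not attempted (single-cell steps plus the terminal enumeration
  below recover jointly-redundant sets in practice, and keep the trace
  interpretable). At termination the K = min(8, remaining) cells with the
  least evidence cost are enumerated exhaustively — up to \(2^8 = 256\)
  terminal models — and returned as a BMA with per-cell on-probabilities.

## Leave-one-out prediction

`loo_cv()` asks whether estimated effects are large enough to predict a
held-out subject's covariate. Per fold, the group model is fitted to N−1
subjects (target covariate mean-centred on the training set); the left-out
subject's value \(x^\*\) receives a Gaussian prior matched to the training
distribution and is inferred on a dense grid (64 points spanning ±4 training
standard deviations — wide enough that the posterior mass is interior, fine
enough that the reported means and 90% intervals are grid-resolution exact).
Each candidate \(x^\*\) implies an empirical prior for the subject; the
evidence of the subject's posterior under it scores the candidate.
Predictions default to using all modelled cells; a `cells` argument restricts
prediction to chosen parameters, since restricting to the cells where an
effect was identified typically sharpens prediction. Performance is
summarised by the out-of-sample Pearson correlation (two-sided p-value)
and by 90% interval coverage.

Two behaviours of LOO with refitting are worth knowing when interpreting
null simulations: correlations of out-of-sample predictions with actual
values are slightly negatively biased (the left-out subject enters the
training mean-centring with negative sign — a generic jackknife effect, not
specific to this implementation), and their spread across replicates exceeds
the naive \(1/\sqrt{N}\) because folds share almost all their training data.

## The synthetic generator

`simulate_study()` draws subjects from the group GLM exactly as the model
reads generatively: sample group effects' predictions, add per-subject
Gaussian random effects, generate T observations through a linear forward
design G (orthonormal columns, shared across subjects, drawn from the seed),
add observation noise, and invert each subject *exactly* by conjugate Bayes —
so first-level posteriors and log evidences are exact, not approximate, and
the group level is exercised on exactly the inputs it assumes. Group-level
and first-level draws use separated seed streams so that consecutive study
seeds give independent replicates.

Defaults mirror a typical group connectivity study: N = 60 subjects, P = 8
parameters, a group-mean column plus one standard-normal covariate of
interest, first-level prior N(0, 1/4) per parameter (the prior variance of a
condition-specific connectivity modulation is not something the framework
prescribes; 1/4 makes the ±1 log-scaling range a-priori plausible), RFX sd
0.125 (= prior sd/4, the beta = 16 assumption), T = 32 observations with
noise sd 0.25. True effects default to zero; studies switch on what they
need.

What the toy does *not* emulate: nonlinear forward models (so variational
approximation error at the first level), haemodynamics, serial correlations,
or heteroscedastic RFX across subjects. Passing tests therefore validate the
group-level machinery exactly, but say nothing about first-level model fit
quality on real timeseries.

## Numerical choices

* Inversions try a plain Cholesky first and only then add a ridge
  \(10^{-8}\cdot\overline{\mathrm{diag}}\cdot I\); log-determinants go through
  Cholesky with an eigenvalue fallback that fails loudly on indefinite input.
* Switched-off cells use the `off_floor` variance (1e-8) rather than exact
  zeros, keeping every reduced model on one aligned parameter vector.
* Design columns that are identically zero (parameters excluded by \(X_W\))
  are clamped at their prior mean with the same floor instead of being
  removed.
* Ties in greedy pruning are broken deterministically by the smaller
  posterior |mean|/sd.
* All internal log quantities are in nats; probabilities appear only at
  reporting time.

## Problem sizes used by the test suite

The suite validates calibration at desk scale: credible-interval coverage
over 100 simulated hierarchies of N = 100 subjects (effect = 3× the RFX sd),
LOO null calibration over 100 replicates of N = 50, greedy-versus-exhaustive
agreement over 25 six-parameter replicates, and structural constants
(28, 784, \(2^{40}\), 40 columns, 256 terminal models, the 1/16 ratio)
recomputed from scratch. `scripts/acceptance.R` re-runs the same battery
end-to-end from a command-line seed.

## Limitations

* Only Gaussian densities are supported end to end; non-Gaussian first-level
  posteriors must be moment-matched before entry.
* The free energy conditions on the Newton mode of \(\gamma\) (with a Laplace
  correction); fully Bayesian hyperparameter averaging is out of scope.
* A single between-subject level: nested designs (PEB-of-PEBs) are not
  modelled.
* Model frequency analyses (random effects over models rather than
  parameters) are a different methodology and are deliberately absent.
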