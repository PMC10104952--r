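---
title: "Measuring and testing context effects in two-triplet choice designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and testing context effects in two-triplet choice designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contextfx)
```

## The measurement problem

Two-triplet experiments embed a core pair of options in two three-option
sets ("contexts") that differ only in the third option. Each trial records
which *role* the chosen option played — target, competitor or decoy — so a
participant's data reduce to six frequencies: `n_t_C1, n_c_C1, n_d_C1,
n_t_C2, n_c_C2, n_d_C2`. `contextfx` works with role counts rather than
raw option identities because every measure below is defined on roles, and
the mapping from options to roles is experiment-specific.

The *relative choice share of the target* exists in two forms. The
collapsed (unequal-weights) form pools counts across contexts,

$$RST_{UW} = \frac{n_{t,C1}+n_{t,C2}}{n_{t,C1}+n_{t,C2}+n_{c,C1}+n_{c,C2}},$$

which is algebraically the *sample-size-weighted* average of the two
within-context shares. The equal-weights form averages the within-context
shares directly,

$$RST_{EW} = \tfrac12\left(\frac{n_{t,C1}}{n_{t,C1}+n_{c,C1}}
          + \frac{n_{t,C2}}{n_{t,C2}+n_{c,C2}}\right).$$

The two coincide exactly when both contexts contribute the same number of
target+competitor choices, and diverge otherwise — the central measurement
point of this package, and the reason `rst_uw()` can signal an effect
(share ≠ 0.5) in data with perfectly mirrored preferences.

Because the attraction effect is a claim about *regularity* rather than
IIA, the package also provides absolute shares computed against all three
roles, `AST` and `ASC`; regularity is satisfied when both are ≤ 0.5, and a
one-sided test (share > 0.5) is the appropriate direction.

## Hierarchical models

Participants differ, so group-level inference uses hierarchies:

* **Collapsed RST.** Pooled target count $y_i \sim
  \mathrm{Binomial}(N_i, \theta_i)$ with $\theta_i \sim
  \mathrm{Beta}(\mu\kappa, (1-\mu)\kappa)$ — $\mu$ is the group mean share
  and $\kappa$ the concentration (larger = more homogeneous participants).
  The null model fixes $\mu = 0.5$.
* **Equal-weights RST.** The same hierarchy duplicated per context
  ($\mu_1, \mu_2, \kappa_1, \kappa_2$); the group share is
  $(\mu_1+\mu_2)/2$. The null model constrains $\mu_2 = 1-\mu_1$, which
  fixes the *average* at 0.5 while leaving both concentrations — and the
  per-context means themselves — free. Mirrored preferences are a null.
* **Absolute shares.** Per context, participant simplex vectors
  $\vec\theta_i \sim \mathrm{Dirichlet}(\vec\mu\kappa)$ with multinomial
  counts; the group AST is the average of the two target components of
  $\vec\mu$. Inference is HDI-based and one-sided; no null variant is
  constructed.

Priors: $\mu \sim \mathrm{Beta}(2,2)$ (the two-alternative analogue of the
Dirichlet(2,2,2) used for $\vec\mu$ — mildly regularising toward 0.5),
$\kappa \sim \mathrm{Gamma}(0.001, 0.001)$ (shape–rate; essentially flat on
the positive axis). All are overridable through `cfx_priors()`. During
sampling $\kappa$ is bounded below at $10^{-6}$ so the beta/Dirichlet
shapes cannot collapse onto the degenerate spike at 0.

## Posterior computation

Sampling exploits conjugacy. Given $(\mu, \kappa)$ the individual rates
drop out analytically (beta-binomial / Dirichlet-multinomial), so the
sampler is a collapsed Metropolis-within-Gibbs: the low-dimensional
group-level block moves by adaptive random-walk Metropolis on the marginal
posterior (several scans per iteration — the marginal evaluations are cheap
next to the conditional draws — see `mcmc_control(scans = )`), and the
individual rates are then drawn *exactly* from their conjugate
conditionals. This is an exact sampler for the full joint posterior with
much better mixing than a joint random walk; defaults of 3 chains × 1500
iterations (500 warm-up) routinely give rank-normalised split-$\hat R$
below 1.01 on all free parameters. $\hat R \ge 1.01$ attaches a warning to
the result rather than failing, and is recorded per cell in simulation
studies.

Everything runs on an unconstrained scale internally — logits for rates
and means, logs for concentrations, additive log-ratios for simplexes,
with the corresponding Jacobians — which is what robust bridge sampling
needs.

## Bayes factors by bridge sampling

`bridge_logml()` implements the iterative optimal-bridge (fixed-point)
estimator: a multivariate-normal proposal is moment-matched to half of the
unconstrained posterior draws (interleaved across chains), the other half
enters the bridge iteration against an equal number of fresh proposal
draws, and the fixed point is iterated to a relative tolerance of
$10^{-10}$ (cap 1000 iterations; these two are this package's choices).
The reported error is the usual relative-MSE approximation assuming
independent draws. Singular proposal covariances are ridge-regularised
with a warning. On conjugate toys (beta-binomial, normal–normal) the
estimator sits within 0.01 nats of the closed form at 10,000 draws — the
acceptance suite checks exactly that.

`context_test()` fits the alternative and null models to the same counts,
bridges both, and reports BF₁₀ with the conventional thresholds 3 and 1/3
(configurable), plus the 95% HDI of the group share (shortest sorted
window; the posteriors here are unimodal by construction) and its
exclusion decision.

## The synthetic-data generator and the bias study

`generator_config()` encodes the reference population: 55 participants,
parent beta concentration $\kappa = 5$ (realistic heterogeneity:
individual shares spread roughly ±0.2 around the mean), 60
target/competitor trials per context, and a per-participant sample-size
difference drawn from a normal distribution centred on the intended
imbalance with SD 5, truncated to $[0, n_{max}-1]$ and rounded so the
depleted context keeps at least one observation. Context 1 is fixed at 60
trials and context 2 depleted (a switch flips this, which mirrors the bias
direction).

`run_study()` turns this into the bias experiment: scenario `null_true`
uses mirrored means $(\mu_1, \mu_2) = (p, 1-p)$ — a genuine null whose
within-context preferences are far from 0.5, the configuration most
sensitive to collapsing — while `alternative_true` sets
$\mu_1 = \mu_2 = p \neq 0.5$. This mirror-pair encoding is the package's
reading of "null with strong attribute preferences"; it is the only
mapping under which the average share is exactly 0.5. Both measures are
fitted to the *identical* dataset per replicate so comparisons are paired.
The frequentist arm (one-sample t tests on per-participant shares) runs
alongside.

At reference scale the study is 59 imbalance levels × 100 datasets — days
of CPU. The packaged default (3 levels × 10 replicates, 3 × 800
iterations) preserves the qualitative findings and is what the acceptance
suite runs: the collapsed measure's mean log BF₁₀ climbs monotonically
with imbalance under a true null, while the equal-weights measure stays
flat. Two behaviours of the scaled study are worth stating plainly:

* With *equal* samples under a true null, both measures' Bayes factors
  correctly accumulate moderate evidence *for* the null (mean log BF₁₀
  near −2 at 55 × 60 observations). "Unbiasedness" of the equal-weights
  measure means its evidence does not drift with imbalance — not that the
  Bayes factor sits at 1.
* As imbalance grows the depleted context carries less information, so the
  equal-weights log BF₁₀ drifts toward 0 from below. That is loss of
  evidence, not bias.

## What the generator does and does not emulate

It reproduces the reference design faithfully: beta-distributed individual
rates, binomial choices, truncated-normal trial imbalance, decoy counts
fixed at zero (the relative-share models ignore decoys). It does not
emulate sequential effects, attribute-level stimulus structure, latent
participant classes, or decoy choices — so passing tests demonstrate
correct inference *under the stated generative model*, not robustness to
those real-data features. Absolute-share analyses need real decoy counts;
the generator cannot exercise them beyond format checks.

## Correlations between effects

`correlate_effects()` models paired per-participant shares as bivariate
normal with a uniform prior on the correlation over $(-1,1)$, flat-normal
priors on the means and half-normal priors on the scales (the likelihood
is the substantive choice; the priors are weakly informative defaults).
Raw per-participant proportions are used rather than posterior-shrunk
estimates — this keeps the analysis self-contained; externally computed
values (e.g. posterior means) can be passed directly as vectors.

## Numerical choices and degenerate inputs

* Log-densities return $-\infty$ outside the support, never `NaN`
  (guarded beta/Dirichlet terms; `NaN` from overflow is coerced).
* Participants with no target/competitor choice in a context make the
  within-set share 0/0; such cells are excluded from fits with a message.
  How the original studies handled them is not documented; exclusion is
  this package's choice.
* Conjugate draws are clamped to $[10^{-12}, 1-10^{-12}]$ so logits stay
  finite.
* Decisions at the thresholds: BF₁₀ exactly 3 (or 1/3) counts as support,
  an HDI endpoint exactly at 0.5 counts as inclusion.
* Per-chain seeds derive deterministically from one master seed; identical
  seed + configuration reproduces every draw, decision and CSV byte.

## Known limitations

Bridge-sampling error estimates assume independent draws and so understate
the Monte Carlo error slightly at short chains. The normal proposal can be
a poor match for very small groups (< 5 participants) where the posterior
of $\log\kappa$ is heavy-tailed; the conjugate toys and self-consistency
checks bound this in practice. The equal-weights null still assumes a
*common* concentration structure per context; participant subpopulations
with opposite effects are outside all models considered here.
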