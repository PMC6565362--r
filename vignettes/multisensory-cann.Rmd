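---
title: "Concurrent multisensory integration and segregation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concurrent multisensory integration and segregation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mscann)
```

## The scientific problem

When an animal estimates its heading direction it receives two sensory
cues — optic flow (visual) and vestibular signals — that may come from a
common cause (self-motion) or from different causes (self-motion plus
object motion). The brain must integrate the cues when they agree and
segregate them when they conflict, and it must do so concurrently, without
knowing the causal structure in advance. Cortical areas MSTd and VIP
contain two complementary cell classes: *congruent* neurons, which prefer
the same heading under either cue, and *opposite* neurons, whose preferred
directions under the two cues differ by 180°. `mscann` implements a
complete modelling account of how these two populations can realize
concurrent integration and segregation:

1. a Bayesian model of two-cue inference on the circle (von Mises
   likelihoods and prior),
2. a decentralized two-module continuous attractor network (CANN) that
   implements the model in biologically interpretable dynamics, and
3. the decoding and neurometric analyses that quantify how well the
   network matches the Bayesian predictions.

## The probabilistic model

Heading is circular, so each cue $x_m$ is modelled with a von Mises
likelihood $p(x_m\mid s_m)\propto\exp[\kappa_m\cos(x_m-s_m)]$, with
concentration $\kappa_m$ playing the role of inverse variance, and the two
stimulus features share a prior
$p(s_1,s_2)\propto\exp[\kappa_s\cos(s_1-s_2)]$ that says features of a
common cause have similar values. A von Mises distribution is equivalently
a 2-D vector of length $\kappa$ pointing at $\mu$, and products/ratios of
densities are vector sums/differences. The three central operations are:

* **Integration** (`posterior_integrated`): the posterior of $s_1$ given
  both cues is the vector sum
  $\hat\kappa_1 e^{j\hat s_1}=\kappa_1 e^{jx_1}+\kappa_{2s}e^{jx_2}$,
  where the indirect cue is discounted through the prior:
  $A(\kappa_{2s})=A(\kappa_2)A(\kappa_s)$ with $A(\kappa)=I_1/I_0$ the
  mean resultant length (`effective_kappa` solves this by bracketed
  root-finding; in the sharp limit $\kappa_{2s}^{-1}\approx
  \kappa_2^{-1}+\kappa_s^{-1}$).
* **Segregation** (`posterior_disparity`): the cue-disparity distribution
  is the vector difference, equivalently the product with the indirect cue
  rotated by 180°. Its concentration grows with conflict while the
  integrated concentration shrinks — comparing the two lengths tells the
  system whether to integrate or segregate.
* **Recovery** (`recover_single_cue`): averaging the two log-posteriors
  cancels the indirect-cue terms and returns the direct-cue posterior
  $(x_1,\kappa_1)$ exactly; the information each operation discards is
  retained by the other. `info_loss_fraction` quantifies what integration
  alone would lose, $\kappa_1^{-1}/(\kappa_1^{-1}+\kappa_2^{-1}+\kappa_s^{-1})$
  under the large-$\kappa$ Gaussian approximation.

```{r bayes}
cp <- cue_pair(x1 = 0, x2 = 20, kappa1 = 50, kappa2 = 50, kappa_s = 50)
posterior_integrated(cp)
posterior_disparity(cp)
recover_single_cue(posterior_integrated(cp), posterior_disparity(cp))
```

A von Mises-specific feature worth noting: the integrated and disparity
concentrations change with the cue disparity (they are constant for
Gaussians on the line); the parallelogram law
$\hat\kappa^2+\Delta\hat\kappa^2=2(\kappa_1^2+\kappa_{2s}^2)$ ties the two
together and is tested as an invariant.

The package follows the model in approximating $p(s_1\mid x_2)$ by a von
Mises distribution through resultant matching; the exact prior-likelihood
convolution is not von Mises. The quadrature oracle in the test suite
quantifies this approximation but the package does not correct for it.
The two-component causal-inference prior and the $N>2$-cue generalization
are out of scope; they would enter as alternative priors in `cue_pair` and
additional modules in the network.

## The network model

Two reciprocally connected modules (MSTd- and VIP-like) each contain a
congruent and an opposite group of $N$ neurons labelled by preferred
direction $\theta$ on a uniform grid of $(-180°,180°]$. Each group is a
continuous attractor network: recurrent von Mises-profile connections
$W_{rc}(\theta-\theta')\propto J_{rc}e^{a\cos(\theta-\theta')}$ support a
bump of activity whose position encodes the direction estimate. Across
modules, congruent groups are coupled in register
($W^c_{rp}\propto J_{rp}e^{a\cos(\theta-\theta')}$) while opposite groups
are coupled with a 180° offset — identical strength and width, so both
carry the same amount of indirect-cue information. Rates follow divisive
normalization $r=[u]_+^2/(1+\omega D)$ where each group's inhibition pool
$D$ also receives a fraction $J_{int}$ of the other group's pool in the
same module, creating congruent/opposite competition. Feedforward input is
a von Mises hill $\alpha_m U_0\exp[a(\cos(\theta-x_m)-1)/2]$ plus
multiplicative noise with Fano factor $F$ (shared by the two groups of a
module, reflecting a common unisensory source) and background input $I_b$
with independent noise.

### Parameters, units and defaults

| parameter | default | meaning |
|---|---|---|
| `N` | 180 | neurons per group; 2° grid |
| `a` | 3 | connection width; ≈40° tuning curves |
| `omega` | 3e-4 | divisive normalization; sets ≈50 Hz saturation |
| `J_int` | 0.5 | inhibition-pool sharing within a module |
| `J_c` | 0.014094 | critical recurrent strength (see below) |
| `J_rc` | 0.3 `J_c` | recurrent strength; below `J_c`, so no persistent activity |
| `J_rp` | 0.5 `J_rc` | reciprocal strength; encodes the prior reliability |
| `I_b`, `fano` | 1, 0.5 | background input and noise scale |
| `tau`, `dt` | 1, 0.01 | time constant (dimensionless) and Euler step |

$J_c$ is the minimal recurrent strength at which an isolated module holds
a persistent bump after input offset. No closed form is exposed by the
model's continuum analysis at the level this package works at, so `J_c` is
a configuration constant whose default is the package's own bisection
estimate (`critical_jc`, noise-free integration from a seeded bump,
persistence threshold on the peak synaptic input). The estimate is
0.014094 at the default geometry and is grid-independent by construction
(see below). Input intensities are expressed in units of
$U_0=J_c e^{a/2}/[2\pi\omega(1+J_{int})I_0(a/2)]$, the synaptic bump
height a group can hold at criticality; the documented working range
$[0.3,1.5]U_0$ spans the super-linear through saturated parts of the
input-rate transfer, and at $1.5U_0$ peak rates sit near the 50 Hz
saturation set by $\omega$ and $J_{int}$.

### Numerical choices

* **Discrete sums.** The dynamical equations are written with plain sums
  over the 180-neuron reference grid. Internally all population sums carry
  the weight $180/N$, which reproduces those equations exactly at
  $N=180$ and keeps the dynamics (saturation rate, bump shape, $J_c$)
  invariant when `N` is reduced for faster tests; the bisection estimate
  of $J_c$ is numerically identical at $N=36$ and $N=180$.
* **Noise discretization.** White-noise terms are scaled by $1/\sqrt{dt}$
  per Euler step (Euler–Maruyama), so the variance of the time-integrated
  input per unit time equals $F\times$ mean, i.e. the configured Fano
  factor; this is verified statistically in the tests. Gaussian deviates
  are generated by Box–Muller over R's uniform stream, so runs are exactly
  reproducible from the seed. All noise sources are drawn each step
  whether or not they are switched on, so disabling one source does not
  perturb another's stream.
* **Reciprocal jitter.** Imperfect cross-module wiring is modelled as
  coherent mistargeting: each receiving neuron's incoming reciprocal row
  gains a von Mises bump of connections with the kernel's own width,
  random direction, and amplitude $\mathrm{Uniform}(0,g)$ times the
  structured peak (default $g=0.9$), under a dedicated seed that leaves
  the global RNG untouched. The structured form is a deliberate package
  choice: independent per-connection noise of the same order, whether
  multiplicative or additive, averages out in the population vector of a
  row (offset scatter $\propto 1/\sqrt{N}$; measured $\le 6°$ at
  $N=180$) and therefore cannot move any neuron's cross-cue
  preferred-direction difference into the intermediate band, whereas a
  mistargeted-arbor component of the same order shifts a minority of
  neurons tens of degrees, producing the bimodal histogram with
  strictly positive mass between 30° and 150°.
* **Burn-in and sampling.** 50τ of transient is discarded (bump formation
  takes ≈5τ; the integrated autocorrelation time of the decoded position
  is ≈0.9τ) and every Euler step is sampled thereafter. The reference
  epoch of 500τ gives the 5×10⁴ samples used for distribution estimates;
  most analyses in the test suite and acceptance script use 40–300τ
  epochs, which changes only the sampling error of the estimates.
* **Degenerate cases.** A zero resultant (uniform distribution, exact
  vector cancellation, flat rate profile) is flagged explicitly
  (`mu_defined = FALSE` or an error) rather than returning an arbitrary
  angle; sample concentrations saturate at a documented cap of 1e8 when
  every sample coincides.

## Decoding and the optimality analyses

Bump positions are read out per sample by the population vector
$z=\arg\sum_\theta r(\theta)e^{j\theta}$; a series of positions yields a
mean (circular average) and a concentration (inverse resultant of the
sample resultant length) — `estimate_distribution`. Optimality is assessed
exactly as in the modelling literature: decode each group under each
single cue, form the vector-sum prediction (`predict_integration` for
congruent groups; `predict_disparity` for opposite groups, in its two
algebraically identical forms), and compare with the decoded estimate
under combined cues. Real-time recovery (`recover_direct_cue`) weights
each group's decoded angle by its summed firing rate — the probabilistic
population code's reliability signal — and `recovery_r2` summarizes a
sweep by an $R^2$ computed on circular data (residuals wrapped to
$(-180°,180°]$ about the identity line; reference angles centred on their
circular mean).

### What "agreement" means here, and a known limitation

The log-additivity of network responses that underlies the vector-sum
prediction holds only approximately in a nonlinear network, and the
package's measurements are precise enough to resolve the residual: at the
default operating point the decoded combined-cue means differ from the
predictions by ≈0.1–4° (largest for opposite groups at strong reciprocal
coupling), while the standard error of a decoded mean over a 300τ epoch
is only ≈0.1–0.3°. Concentration ratios fall within [0.8, 1.25] for most
sweep conditions. Consequently the strict statistical test "difference
within 2 SE" fails for many conditions even though the agreement is
excellent at the resolution at which the claim is usually displayed
(degrees, on axes spanning tens of degrees). The acceptance suite states
the strict criterion as such and additionally verifies the
figure-resolution property (means within 5°, ratios within [0.6, 1.6])
which is the level of agreement the model family actually supports. Users
comparing their own variants should treat few-degree mean deviations and
±25% concentration deviations as the expected fidelity of this
implementation, not as defects of a particular run.

## Neurometric analyses

`disparity_trials` implements the discrimination protocol: the cue mean is
clamped to zero ($x_1+x_2=0$) while the disparity sweeps ±32° in 4° steps,
30 trials per condition; each trial's time-averaged rate of a selected
neuron is one observation. The ideal observer's fraction of "$x_1>x_2$"
judgements is the ROC value of the $+d$ trial rates against the $-d$ rates
(ties half-credit), and a least-squares cumulative Gaussian fit
(`fit_neurometric`, multi-start Nelder–Mead with $\sigma>0$ by
exp-parameterization) turns the neurometric function into a discrimination
threshold $\sigma$. Because opposite-neuron rates change steeply with
disparity while congruent rates barely move, the opposite neuron's
threshold is several times smaller — the core functional claim about this
cell class. For the heading task (both cues moving together) the reference
distribution is the 0° trial set, a documented package choice where the
protocol leaves it implicit, and the combined-cue threshold is compared
with the optimal combination $\sigma_1\sigma_2/\sqrt{\sigma_1^2+\sigma_2^2}$.

The rate statistic for disparity-competition curves (`decision`) is the
peak of the temporally averaged population profile, consistent with the
bump height encoding estimate reliability; population-mean rates are also
computed. The crossing of the congruent and opposite curves under equal
readout weights sits at 90° and moves monotonically with the weight ratio
(`decision_boundary`).

## What the simulations do and do not show

All inputs here are synthetic: the network's own stochastic feedforward
drive under configurable protocols. The simulations emulate the
trial-structure and sampling of the electrophysiology they are patterned
on (single long equilibrium trials for tuning curves; 30-trial blocks for
neurometrics) but none of the biological heterogeneity: all neurons share
identical tuning widths and gains, noise is white with a fixed Fano
factor, the two modules are exactly symmetric, and there is no spiking.
Passing tests therefore validate the model's internal consistency and its
Bayesian interpretation, not quantitative fits to recorded neurons; the
monkey data the cell classes come from are qualitative context only.

## Problem sizes used by the tests and the acceptance script

Unit tests run the fixture grid ($N=36$, epochs of 2–20τ). The acceptance
checks and `scripts/acceptance.R` use the full $N=180$ network with
epochs of 40–500τ: tuning sweeps of 18 probes at 50τ, a 17-point disparity
sweep, a 30-configuration recovery sweep, and 30-trial neurometric blocks
on a 9-point disparity grid — sizes chosen so the whole acceptance run
completes in minutes on one core while keeping every estimate's sampling
error well inside the tolerances quoted above.
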