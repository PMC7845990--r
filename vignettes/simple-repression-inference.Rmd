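---
title: "Models and methods: bursty transcription and repressor kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: bursty transcription and repressor kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstrep)
```

# The system and the questions

The simple-repression motif is the minimal regulatory circuit of bacterial
transcription: a promoter whose only regulation is a single repressor that,
when bound to its operator, excludes RNA polymerase. Two modeling traditions
describe it. *Thermodynamic* (occupancy) models compute the equilibrium
probability of promoter microstates and predict mean expression;
*kinetic* models write a chemical master equation (CME) over promoter states
coupled to mRNA copy number and predict the full single-cell count
distribution. `burstrep` implements both layers and the machinery needed to
confront them with single-molecule mRNA census data (smFISH-style integer
counts per cell):

1. an effective two-parameter fold-change theory onto which every model
   collapses;
2. a generic truncated-CME steady-state solver, used throughout as the
   numerical oracle;
3. closed-form steady-state distributions, including the repressed bursty
   distribution built on a Gauss hypergeometric function;
4. exact stochastic simulation and a synthetic study generator;
5. Bayesian inference of burst parameters and repressor binding/unbinding
   rates by ensemble MCMC, with posterior predictive checking.

All rates are nondimensionalized by the mRNA degradation rate
$\gamma$ (fixed to 1 internally), and all energies are carried in $k_BT$
units, so neither $\gamma$ nor $\beta = (k_BT)^{-1}$ appears as a runtime
quantity. Converting an inferred unbinding rate to s$^{-1}$ requires an
assumed mRNA lifetime (`dissociation_rate_to_physical()`).

# Mean expression: the master curve

The fold-change is the ratio of mean expression with and without repressor.
Every model here — occupancy or kinetic — predicts a Fermi-function form

$$FC = \frac{1}{1 + e^{-\Delta F_R + \log\rho}},$$

where $\Delta F_R$ is an effective repressor free energy and $\rho$
coarse-grains all repressor-free promoter states. In the two-state occupancy
model $\Delta F_R = \epsilon_R - \log(R/N_{NS})$ and $\rho = 1$; adding an
explicit RNAP-bound state ($P$ polymerases, energy $\epsilon_P$) gives
$\rho = 1 + (P/N_{NS})e^{-\epsilon_P}$; in the kinetic picture
$\Delta F_R = -\log(k_{on}/k_{off})$. The structural reason for the collapse
is that the repressor-bound state exchanges with exactly one repressor-free
state, which enforces detailed balance between the repressor-bound group and
everything else.

Two design choices follow from this:

* `effective_rho_numeric()` recovers $\rho$ for any kinetic model by solving
  the CME with and without the repressor state and inverting the master
  curve, rather than transcribing model-specific closed forms. The
  detailed-balance argument predicts the recovered $\rho$ is independent of
  the repressor rates, and the test-suite asserts that invariance to
  $10^{-6}$ relative — a much stronger check than reproducing a formula.
* $R = 0$ is a defined special case ($FC = 1$) at the fold-change level but
  an error of class `burstrep_unregulated` at the $\Delta F_R$ level, where
  the quantity diverges.

# Noise: which constitutive model can carry a repressor?

Five constitutive architectures are available as `promoter_model()` presets.
Their Fano factors (variance/mean of the stationary mRNA distribution)
separate them cleanly:

| preset | structure | Fano |
|---|---|---|
| `poisson` | one state, Poisson initiation | $=1$ |
| `rnap_escape` | empty $\leftrightarrow$ RNAP-bound, irreversible escape | $<1$ |
| `multistep_escape` | adds a closed$\to$open complex step | $<1$ |
| `telegraph` | inactive $\leftrightarrow$ active, Poisson while active | $>1$ |
| `bursty` | one state, instantaneous geometric bursts | $=1+b$ |

The escape models are sub-Poissonian because a multi-step initiation cycle
regularizes the waiting times between transcripts; observed single-cell data
are uniformly super-Poissonian, which rules those models out. The telegraph
model is super-Poissonian,

$$\nu = 1 + \frac{r\,k^-}{(k^+ + k^- + 1)(k^+ + k^-)},$$

but its parameters are not jointly identifiable from snapshot counts: only
$k^+$ and the ratio $r/k^-$ are constrained (the test-suite exhibits the
likelihood ridge directly). Taking $r, k^- \to \infty$ at fixed
$b = r/k^-$ yields the bursty model: transcripts arrive in instantaneous
bursts of geometric size (mean $b$, on $\{0, 1, 2, \dots\}$ — zero-size
bursts are allowed and are no-ops) initiated at rate $k_i$. Its stationary
distribution is negative binomial with mean $k_i b$ and Fano $1 + b$, and
both parameters are identifiable. That model, with a repressor-bound silent
state added, is the package's inference workhorse.

The note on production in the CME engine: transcription in the escape models
is itself a state-changing event (initiation returns the promoter to the
empty state). The `production` specification therefore allows `single`
production with a destination state; without that coupling the
sub-Poissonian behavior cannot be represented.

# The CME engine as oracle

`steady_state_joint()` solves the stationary distribution of any
finite-promoter-state model on a truncated count space. Numerical choices:

* **Truncation**: initial $m_{\max} = \lceil \mu + 10\sqrt{\mu(1+b_{\max})}
  \rceil + 20$ from a moment pre-estimate, doubled until the probability in
  the top 5% of retained count levels falls below `tail_tol` (default
  $10^{-10}$), with a hard cap that produces an explicit resource error
  naming the achieved tail mass.
* **Conservative boundary**: burst jumps that would exceed $m_{\max}$ are
  suppressed together with their diagonal contribution, so the truncated
  generator is a proper rate matrix and the solve has an exact null vector;
  truncation error is surfaced only through the tail mass.
* **Solve**: one sparse LU factorization with the normalization row
  appended; deterministic, no iterative randomness.

Every closed form in the package is tested against this solver:
the Poisson and negative binomial steady states to $10^{-8}$ total
variation, the telegraph Fano factor to $10^{-6}$, and the repressed bursty
distribution to $10^{-6}$ total variation over a parameter grid.

# The repressed bursty distribution and its evaluation

Adding a repressor to the bursty promoter gives the steady state

$$p(m) = \frac{\Gamma(\alpha+m)\,\Gamma(\beta+m)\,\Gamma(k_{on}+k_{off})}
{\Gamma(\alpha)\,\Gamma(\beta)\,\Gamma(k_{on}+k_{off}+m)}\,\frac{b^m}{m!}
\;{}_2F_1(\alpha+m, \beta+m; k_{on}+k_{off}+m; -b),$$

with $\alpha\beta = k_i k_{off}$ and $\alpha + \beta = k_i + k_{on} +
k_{off}$. The shape parameters are computed cancellation-free (larger root
by the quadratic formula, smaller via the product identity); the
discriminant is bounded below by $(k_i - k_{off})^2$, and the root
interlacing $\beta < \min(k_i, k_{off}) \le \max(k_i, k_{off}) < \alpha$
holds for all positive rates.

${}_2F_1$ at negative argument is evaluated through the Pfaff
transformation, which maps the argument to $b/(1+b) \in (0,1)$. The
transformed series has second upper parameter $k_{on} + k_{off} - \beta$,
which the interlacing bound shows is strictly positive — so every term of
the series is positive and a plain accumulation has no cancellation. Double
precision with a geometric tail bound then achieves $10^{-10}$ relative
error without any extended-precision arithmetic; the implementation was
validated against a 40-digit independent evaluation on frozen test points.
Gamma ratios are always log-gamma differences, never factorials. The
vectorized-over-$m$ evaluation used by the likelihood is compiled (C++),
with the scalar R primitive `log_gauss_2f1_neg_arg()` kept as the
documented, independently tested reference; the two agree to $10^{-10}$.

Useful structural facts, all tested: $p(m)$ reduces to the negative binomial
as $k_{on} \to 0$; its mean is $k_i b\,(1 + k_{on}/k_{off})^{-1}$, i.e. the
mean obeys the master curve with $\rho = 1$; at repressor rates comparable
to $k_i$ the Fano factor exceeds the constitutive $1 + b$ — this
intermediate regime is where the data carry information about the rates
separately rather than only their ratio. When both repressor rates are much
*faster* than $k_i$ and $\gamma$, the distribution converges to a negative
binomial with $k_i$ scaled by the fold-change. When both are much *slower*
than $\gamma$, the promoter state freezes over an mRNA lifetime and the
distribution is instead an overdispersed on/off mixture — a fold-change-
scaled negative binomial is *not* the slow limit, and the package's tests
assert the mixture's excess dispersion rather than a false limit.

# Synthetic studies

`generate_study()` emulates the structure of a single-molecule mRNA census:
18 constitutive promoters whose burst rates span two orders of magnitude
(burst sizes roughly one), and nine regulated conditions crossing three
operators with four repressor induction levels over a strong reference
promoter. Ground-truth choices, made once:

* reference promoter $k_i = b = 4.5$, mean $\approx 20$ — the scale of the
  strong *lacUV5*-class promoters such data sets are built on;
* operator unbinding rates $0.5,\ 0.5e^{1.7},\ 0.5e^{3.1}$, so the
  log-ratios equal round binding-energy gaps (1.7 and 1.4 $k_BT$) of the
  classes the operator labels refer to — configuration constants defining
  the synthetic truth, not measured claims;
* binding rates $0.5, 1.5, 4, 12$, spanning weak to strong repression with
  rates comparable to $k_i$ (the informative regime);
* 2500 cells per condition by default, matching the
  hundreds-to-thousands scale of real conditions.

Counts are drawn from the exact stationary distributions (negative binomial
via `rnbinom()`, repressed distribution by inverse-CDF sampling); one count
per cell mirrors the smFISH snapshot measurement. Each condition uses its
own random stream derived from the base seed and the condition label, so
adding a condition never perturbs existing ones, and the generating truth
travels with the dataset as a provenance attribute/sidecar. The SSA
(`ssa_counts()`, compiled Gillespie with instantaneous geometric bursts,
default horizon 20 mRNA lifetimes against a relaxation time of one) provides
an independent route to the same distributions and is held to a
Kolmogorov–Smirnov distance of 0.01 against the CME at $10^5$ cells.

What the generator does *not* emulate — and what green tests therefore do
not establish about real data: fluorescence calibration and spot-calling
error, gene copy-number variation over the cell cycle, extrinsic
(cell-to-cell) parameter variability, and any locus or growth-rate effects.
The generator produces exactly the model the inference assumes; recovery
tests validate the inference machinery, not the model's adequacy for any
particular experiment. Model adequacy on real data is what the posterior
predictive ECDF checks are for.

# Inference

**Likelihoods.** Constitutive counts are products of negative binomials;
regulated datasets factorize over conditions, with one unbinding rate per
operator, one binding rate per induction level, and shared burst parameters
$(k_i, b)$ for the reference promoter (the assumption that regulation
leaves burst rate and size untouched). The per-condition pmf depends only
on that condition's four parameters, so it is evaluated once per condition
per proposal over the observed count range, against tabulated counts. Both
fit modes are provided: co-inference of $(k_i, b)$ with the constitutive
reference data in the likelihood (the nine-dimensional posterior for the
default design), or conditioning on fixed burst parameters
(`fix_burst = TRUE`, seven-dimensional).

**Priors.** Rates are positive and plausibly span orders of magnitude, so
sampling is on the natural-log scale with normal priors there (log-normal on
the rates), location 0 and scale 2 by default — weakly informative, about
four orders of magnitude of support. The prior is truncated at 3.5 prior
standard deviations (removing $\sim 5\times10^{-4}$ of mass); together with
a per-evaluation budget on the hypergeometric series length, this keeps the
sampler out of regions (e.g. $b \to \infty$, where the Pfaff argument
approaches 1) in which likelihood evaluation cost diverges while posterior
mass is negligible.

**Sampler.** An affine-invariant stretch-move ensemble: gradient-free,
invariant under affine reparameterization, and therefore comfortable with
the strong pairwise correlations of the joint rate posterior (each
condition constrains $k_{on}/k_{off}$ much more tightly than either rate).
Walkers number at least $2d + 2$; the first half of iterations is warmup.
By default walkers start in a tight ball (sd 0.1 log-units) around a
posterior mode located by Nelder–Mead from the prior center — with priors
this wide, initializing from the prior itself makes the ensemble spend most
of the run collapsing toward the mode; `init = "prior"` remains available
and is exercised by the prior-recovery test.

**Convergence gating.** Summaries, HPD regions and predictive bands refuse
to compute (without an explicit override) unless split $\hat R \le 1.01$
(walkers as chains, each split in half) and effective sample size $\ge 400$
per parameter (via `coda`). The gate is deliberately stricter than any
convention in the source literature; summaries of unconverged ensembles are
not meaningful.

**HPD regions.** One-dimensional regions are the shortest interval
containing the requested mass; two-dimensional regions are kernel-density
level sets (on the log scale, `MASS::kde2d`) with the threshold set so the
enclosed fraction of draws matches the level.

# Model checking and reconciliation

`posterior_predictive_band()` draws parameters from the posterior,
generates replicate datasets of the *observed* condition size (band width
must reflect the real sampling noise), and reports pointwise ECDF quantile
bands; `band_coverage()` summarizes how much of the observed ECDF falls
inside. Bands are pointwise, not simultaneous — a correctly specified model
leaves the observed ECDF inside a 95% band at roughly 90% or more of
support points, and the test-suite calibrates exactly that. The Poisson
model on overdispersed data exits the band decisively, which is the
qualitative misfit signature the check is designed to expose.

For reconciliation with occupancy-model energetics:
`energy_difference_posterior()` computes, per posterior draw, the
binding-energy difference between two operators as
$\Delta\epsilon_a - \Delta\epsilon_b = \log(k^-_a/k^-_b)$ — binding rates
cancel because they are shared within a condition's repressor copy number.
(The derivation fixes the sign convention: the stronger operator has the
smaller unbinding rate.) `thermo_kinetic_map()` inverts the mean-expression
correspondence $k_i/\gamma = (P/N_{NS})e^{-\epsilon_P}$, $b = r/\gamma$ to
express burst parameters as occupancy-model quantities at an assumed
polymerase copy number; the weak-promoter approximation behind it is good
to better than 1% whenever the occupancy weight is below 0.01. Literature
reference energies and single-molecule rates enter only as user-supplied
configuration constants for comparison tables.

# Problem sizes and determinism

The shipped tests and the acceptance script choose sizes that keep the full
suite comfortable on a single CPU: noise-diagnostic grids of 210–256 CME
solves per model family; SSA checks at $10^5$ cells; constitutive recovery
across 20 synthetic datasets of 2500 cells; and one joint nine-dimensional
fit on a study scaled to 500 cells per condition with 40000 ensemble
iterations, which passes the $\hat R \le 1.01$ gate and recovers all seven
rates within a factor of 1.5 and both imposed energy gaps within their 95%
intervals. Every stochastic step — study generation, SSA, sampling, MCMC,
predictive replication — is seeded, and identical seeds reproduce results
bit-for-bit; per-condition streams make datasets stable under design
extension.

# Known limitations

* Irreversible steps (escape, burst initiation) make the inferred rates
  effective constants, not elementary reaction rates.
* The instantaneous-burst idealization assumes burst duration is short
  compared with repressor association; at very high repressor
  concentrations that separation can fail, and the shared-burst-parameter
  assumption with it.
* The repressed-distribution evaluation targets the parameter family
  arising from this model ($\alpha, \beta$ real and interlaced); it is not
  a general-purpose ${}_2F_1$.
* Protein-level distributions, cell-cycle gene dosage, supercoiling
  mechanics and sequence-level energy matrices are out of scope.
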