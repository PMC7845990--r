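# burstrep

Bursty transcription and repressor kinetics for the bacterial
simple-repression motif.

`burstrep` is for quantitative biologists who work with single-cell mRNA
count data (smFISH-style integer counts per cell) on promoters regulated by
a single transcriptional repressor, and who want to move between the two
standard descriptions of that system: thermodynamic (occupancy) models,
which predict mean expression through binding energies, and kinetic
(chemical master equation) models, which predict the full count
distribution through rates.

## What it computes

**Effective fold-change theory.** Every simple-repression model — two- or
three-state occupancy, or any of the kinetic schemes — predicts a
fold-change of the form

```
FC = 1 / (1 + exp(-ΔF_R + log ρ)),
```

with `ΔF_R = ε_R − log(R/N_NS)` (thermodynamic) or `−log(k_on/k_off)`
(kinetic), and `ρ` a coarse-graining factor for the repressor-free promoter
states. The package computes every model's fold-change, recovers `ρ`
numerically from any kinetic model by solving its master equation with and
without the repressor, and verifies the collapse.

**CME steady states and noise diagnostics.** A generic solver for finite
promoter-state master equations with single-transcript or geometric-burst
production (`promoter_model()`, `steady_state_joint()`). The Fano factor
(variance/mean) separates the candidate constitutive models: 1 for the
Poisson promoter, strictly below 1 for RNAP-escape cycles, above 1 for the
active/inactive telegraph model (`ν = 1 + r k⁻ / ((k⁺+k⁻+1)(k⁺+k⁻))`), and
`1 + b` for the one-state bursty model whose steady state is negative
binomial with burst rate `k_i` and mean burst size `b`.

**The repressed bursty distribution.** Adding a repressor-bound silent
state to the bursty promoter gives a steady state expressed through the
Gauss hypergeometric function ₂F₁ evaluated at `−b`; `burstrep` evaluates
it stably (Pfaff-transformed positive-term series, log-gamma prefactors)
and validates it against the master-equation oracle to 10⁻⁶ total
variation.

**Inference and checking.** Log-normal priors, an affine-invariant ensemble
sampler over log-rates, convergence gating (split R̂ ≤ 1.01, ESS ≥ 400),
posterior summaries, HPD regions, posterior predictive ECDF bands, and the
thermodynamic↔kinetic reconciliation: operator binding-energy differences
from unbinding-rate posteriors via `Δε_a − Δε_b = log(k⁻_a / k⁻_b)`.

**Synthetic studies.** `study_config()` / `generate_study()` build complete
synthetic smFISH-style studies (18 constitutive promoters, nine regulated
operator × repressor-level conditions) with the generating truth carried as
provenance, plus an exact Gillespie simulator (`ssa_counts()`) as an
independent route to the same distributions.

## Worked example

Fit the bursty model to synthetic counts from a strong constitutive
promoter (mean ≈ 20 transcripts/cell), check the fit, and translate the
burst rate into occupancy-model language:

```r
library(burstrep)
set.seed(27)
counts <- rnbinom(2500, size = 4.5, prob = 1 / 5.5)   # truth: k_i = b = 4.5

fit <- fit_constitutive(counts, n_steps = 12000, seed = 1)
posterior_summary(fit)[, c("param", "mean", "sd", "cv_pct", "q2.5", "q97.5")]
#>     param mean    sd cv_pct q2.5 q97.5
#> k_i   k_i 4.69 0.163   3.47 4.37  5.01
#> b       b 4.29 0.157   3.66 4.00  4.62

band <- posterior_predictive_band(fit, "neg_binom", n_cells = length(counts),
                                  observed = counts, seed = 2)
band_coverage(band)
#> [1] 1

thermo_kinetic_map(k_i = 4.69, b = 4.29)$eps_P
#> [1] -8.37
```

Both burst parameters are recovered within a few percent (coefficients of
variation under 4%, truth inside the 95% intervals), the observed ECDF sits
entirely inside the 95% posterior predictive band (coverage 1.0 means no
support point falls outside), and the burst rate corresponds to an RNAP
binding energy of about −8.4 kT at an assumed 5000 polymerases — the kind
of cross-model translation the package exists to make.

The same workflow scales to the joint problem: `fit_regulated()` samples
the nine-dimensional posterior over three operator unbinding rates, four
binding rates, and the shared burst parameters, and
`energy_difference_posterior()` turns unbinding-rate ratios into operator
binding-energy differences with full uncertainty.

A command-line wrapper for the pipeline stages (simulate, fit, check,
compare) ships at `inst/cli/burstrep.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","burstrep.R",package="burstrep"))')" \
    simulate --out study/ --seed 11
```

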