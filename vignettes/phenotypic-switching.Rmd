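---
title: "Quantifying phenotypic switching and pre-existing drug tolerance from surviving-cell statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying phenotypic switching and pre-existing drug tolerance from surviving-cell statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoswitch)
```

## The model and its assumptions

`phenoswitch` models a population of cancer cells in which each cell
carries one of two coarse-grained phenotypes: drug-sensitive,
epithelial-like (E) or drug-tolerant, mesenchymal-like (M). The state
`(E, M)` evolves as a continuous-time Markov branching process with six
per-cell rate constants: birth rates $k_E, k_M$, death rates
$\mu_E, \mu_M$, and reversible switching rates $k_{EM}$ (E$\to$M) and
$k_{ME}$ (M$\to$E). The modelling assumptions are:

* **Linearity.** Rates are per cell and constant: no density dependence,
  no time dependence, no cell-cell interaction. Every cell's lineage
  evolves independently of all others.
* **Two states.** The epithelial-mesenchymal spectrum is collapsed to two
  states. This is a deliberate coarse-graining: what the data identify is
  an effective two-state switch, not the underlying continuum.
* **Spatial homogeneity.** Rates are the same everywhere in the tumor;
  spatial structure enters only through the initial resistant fraction of
  each sample.
* **Drug phase.** Cytotoxic exposure is modelled as complete growth
  suppression, $k_E = k_M = 0$, with death and switching unchanged in
  form. Cells then evolve independently, which makes the drug phase
  analytically solvable.

A *sample* is $N_0$ cells whose initial resistant fraction
$p_0 = M/N_0$ varies from sample to sample with density $\rho(p_0)$,
characterized by its mean $\langle p_0\rangle$ and variance
$\sigma^2_{p_0}$. Quantifying $(\langle p_0\rangle, \sigma^2_{p_0})$ from
surviving-count time courses is the package's central estimation task.

## Drug-phase analytics

Because cells are independent under drug, the population generating
function is the $N_0$-th power of the single-cell one, mixed over
$\rho(p_0)$ (`population_gf()`). The single-cell occupancy
probabilities solve a $2\times 2$ linear system whose eigenvalues are
$-(\gamma_0\pm\alpha_0)/2$ with

$$\gamma_0 = k_{EM}+k_{ME}+\mu_E+\mu_M,\qquad
\alpha_0 = \sqrt{\gamma_0^2-4\bigl(k_{ME}(\mu_E-\mu_M)+(\gamma_0-\mu_M)\mu_M\bigr)}.$$

The mean surviving count is bi-exponential in these composites
(`mean_surviving_drug()`), and the Fano factor of the surviving count is

$$F = 1-\frac{\langle N\rangle}{N_0}
  +\frac{N_0(N_0-1)}{\langle N\rangle}\,X(t)^2\,\sigma^2_{p_0},
  \qquad
  X(t) = \frac{\mu_E-\mu_M}{\alpha_0}
  \left(e^{-t(\gamma_0-\alpha_0)/2}-e^{-t(\gamma_0+\alpha_0)/2}\right),$$

implemented in `fano_drug()`. With $\sigma^2_{p_0}=0$ the surviving count
is a binomial thinning of $N_0$ independent cells, so $F<1$ strictly for
$t>0$; measured super-Poissonian counts ($F>1$) are therefore direct
evidence of pre-existing heterogeneity — a reversible-switching analogue
of the Luria–Delbrück fluctuation argument.

**A sign note.** The regrouped "heterogeneity signal"
$\sigma_{p_0}|X(t)|$ (`heterogeneity_signal_theory()`) appears in the
literature with *growing* exponentials $e^{+t(\gamma_0\mp\alpha_0)/2}$.
That variant diverges in $t$ and is inconsistent with the Fano-factor
expression it was regrouped from; this package uses the decaying
exponents throughout, under which the measured-quantity form
$\sqrt{(F-1+\langle N\rangle/N_0)\,\langle N\rangle/(N_0(N_0-1))}$
(`heterogeneity_signal_empirical()`) round-trips exactly.

## Growth-phase analytics

With births active, the mean obeys the same bi-exponential law with the
effective birth rates $k^f_E = k_E-\mu_E$, $k^f_M = k_M-\mu_M$ replacing
$-\mu_E, -\mu_M$ (`mean_growth()`, `growth_phase_rates()`). The growth
composites are called `gammaG`, `alphaG` in code: the Beta distribution
used for $\rho(p_0)$ already occupies the symbols $\alpha, \beta$, and the
code must not inherit that collision.

First and second moments jointly obey a closed $5\times 5$ linear ODE
system. `moments_growth()` solves it exactly — by eigendecomposition,
falling back to `Matrix::expm` when the eigenvector basis is
ill-conditioned (near-defective generator, e.g. $\alpha \approx 0$) —
rather than transcribing the lengthy closed-form solutions; both routes
are exact, and the solver is cross-checked in the tests against
`Matrix::expm` and against $10^4$-replicate stochastic ensembles.
The total-count variance always satisfies
$\sigma^2_N = \sigma^2_E+\sigma^2_M+2C_{EM}$.

## The estimation protocol

Designed initial conditions make the model fully identifiable:

1. **All-sensitive drug series** ($p_0=0$): weighted nonlinear least
   squares of the mean law identifies $(\mu_E,\gamma_0,\alpha_0)$
   (`fit_drug_mean_curve()`). The fit is box-constrained
   ($0\le\alpha_0\le\gamma_0$ enforced by fitting the ratio), multi-start
   from a latin hypercube plus a slope-based start, and flags
   boundary-pinned estimates and near-single-exponential data (exponent
   gap below 5%), where the composites are weakly identified.
2. **All-resistant drug series** ($p_0=1$): a one-dimensional fit for
   $\mu_M$ (`fit_drug_mu_M()`); the initial slope of
   $\langle N\rangle/N_0$ equals $-\mu_M$.
3. **Inversion for switching rates.** The composite definitions invert in
   closed form (`invert_drug_rates()`); the inversion degenerates when
   $\mu_E=\mu_M$, a structural non-identifiability that is raised as an
   error, not papered over.
4. **Heterogeneity from the mixed condition.** Per time point,
   $$p_0 = \frac{\langle N\rangle-\langle N\rangle_0}
   {\langle N\rangle_1-\langle N\rangle_0},\qquad
   \sigma^2_{p_0} = \frac{N_0\langle N\rangle}
   {(\langle N\rangle_1-\langle N\rangle_0)^2(N_0-1)}
   \Bigl[F-1+\frac{\langle N\rangle}{N_0}\Bigr]$$
   (`estimate_initial_heterogeneity()`). No single measurement time is
   canonical, so the package computes the estimators at every observed
   $t>0$ and combines them by inverse bootstrap-variance weights,
   reporting the per-time values in diagnostics. Estimates are clipped to
   their feasible ranges with an explicit flag; $F$ below the
   zero-heterogeneity floor yields a variance reported as 0 with a flag.

`estimate_drug_protocol()` runs the whole chain and attaches percentile
bootstrap confidence intervals (default `B = 1000`; replicates are the
resampling unit and every resample re-runs the chain, single-start at the
point estimates). The growth phase is analogous: mean curves from the two
pure conditions identify $(k^f_E,k^f_M,k_{EM},k_{ME})$
(`fit_growth_mean_curves()` — mean curves alone can never separate birth
from death), and adding variance trajectories separates $k$ from $\mu$
because the variance depends on $k+\mu$ (`fit_growth_full()`,
`estimate_growth_protocol()`). `compare_phases()` then labels the
pre/post-drug comparison "selection-dominant" (switching CIs overlap,
death rates increased), "adaptation-indicated" (switching CIs disjoint)
or "inconclusive" — a labelled CI comparison, deliberately not a
hypothesis test, since no error model beyond demographic noise is
assumed.

### Tunable parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| rates | — | per unit time | user-declared time unit; no conversion attempted |
| `N0` | 200 | cells | large enough that sampling noise in $p_0$ is negligible relative to biological heterogeneity |
| `n_replicates` | 10^4 | — | makes 3-SE stochastic checks sharp at the reference rates |
| `B` | 1000 (200 in heavy studies) | resamples | percentile-CI calibration; reduced only for runtime |
| `n_starts` | 8 | — | latin-hypercube multi-start; documented box scaled from the observed decay |
| quadrature `rel_tol` | 1e-9 | — | `population_gf` Beta mixing |

## Stochastic simulation

`simulate_ensemble()` runs the exact direct-method Gillespie algorithm
over the six reaction channels, in compiled code, recording the
right-continuous state at each grid time and terminating early on
extinction. Reproducibility is a design contract: each replicate runs on
its own counter-derived stream (`seed * 2^20 + replicate`) of a
self-contained xoshiro256++ generator, so ensembles are bit-identical
given `(params, init, seed, grid)` regardless of R's RNG state; R's RNG
is used only for initial-composition draws and bootstraps, through a
state-preserving wrapper. Initial compositions draw $p_0$ from its
specification and then allocate cells binomially (the i.i.d.-cell
structure the generating function assumes) or deterministically by
rounding.

## Beta characterization of the resistant fraction

The distribution of surviving-replicate fractions $p = M/(E+M)$ is
summarized by the Beta distribution with the *same mean and variance* as
the empirical distribution (`beta_from_moments()`,
`fit_empirical_fractions()`); moment matching, not maximum likelihood, is
the canonical fit because the matched moments are exactly the quantities
the estimation protocol recovers (an ML cross-check is available and
agrees closely away from boundary-concentrated samples, but can diverge
when fractions hit exactly 0 or 1, where the likelihood is unbounded for
shape parameters below 1). Goodness of fit is reported as the
Kolmogorov–Smirnov distance between the empirical CDF (ties handled
exactly) and the fitted Beta CDF. No p-value is attached: the fractions
are discrete ratios of small counts, not i.i.d. continuous draws.

**Discreteness limit.** At early times or small surviving populations,
$p$ lives on a handful of atoms; the KS distance to *any* continuous
distribution is then bounded below by the largest atom mass. In the
reference experiment (ratio $k_{EM}/k_{ME} = 0.1$, $t = 0.1$, 200 cells)
about 82% of replicates still have $M = 0$, so the KS distance cannot
fall below ~0.8 no matter how good the Beta shape is. The acceptance
test asserting KS < 0.05 per panel is therefore red on the four
low-$E[M]$ panels and green on the remaining eight; the diagnostics
report the surviving-$N$ range so users can judge when the KS number is
meaningful. Histogram-level agreement (what `beta_fit_histogram()`
exports) remains good even in those panels.

## The synthetic-data generator

`generate_experiment()` (with `default_experiment_design()`) emulates
replicate designed experiments: the reference growth design uses birth
rates 0.2/0.1, death rates 0.3/0.15, switching ratio
$k_{EM}/k_{ME}\in\{0.1,1,10\}$ sampled at $t=0.1,1,10,20$ from 200
sensitive cells; only the ratio is canonical, so the package fixes
$k_{ME}=0.1$ by convention. The drug companion design runs the three
protocol conditions ($p_0=0$, $p_0=1$, Beta(2,5) mixed — a realistic
right-skewed minority-resistant population) on a 20-point grid over
$[0.5, 10]$, roughly three e-foldings of decay. Histogram replicate
counts are not canonical either; the default is $10^4$.

The generator reproduces what the model states and nothing more:
demographic (birth-death-switching) noise only. Real data add measurement
noise, plating losses, batch effects and possible rate drift; an optional
binomial subsampling layer (off by default) emulates counting a fraction
of each well, and everything else is out of scope. A green recovery test
therefore establishes correctness of the estimators *under the model's
own noise*, not robustness to misspecification. Ground truth is written
to a separate element/file, and the estimation CLI refuses file names
containing "truth", so tests cannot silently train on it.

## Numerical choices

* **Degenerate composites.** The bi-exponential laws divide by $\alpha$;
  the implementation evaluates the exact rearrangement
  $e^{-\gamma t/2}[\cosh(\alpha t/2) + c\,t\,\mathrm{sinhc}(\alpha t/2)]$
  with a series branch for $\mathrm{sinhc}$ below $10^{-4}$, so
  $\alpha\to 0$ limits are smooth to machine precision and need no
  special-casing at call sites.
* **Discriminant clamping.** The composite-rate discriminants are
  mathematically non-negative; round-off negatives within
  $10^{-12}\max(1,\gamma^2)$ are clamped to zero, anything larger is an
  input-validation error.
* **ODE solution.** Eigendecomposition with an `rcond` guard ($>10^{-8}$)
  and `Matrix::expm` fallback; both exact, the former ~100x faster inside
  fitting loops.
* **Generating-function derivatives** in tests use central differences
  with step $10^{-5}$ and one Richardson extrapolation step.
* **Fits** are box-constrained (`nlminb`), multi-start with fixed seeds;
  ties between starts resolve to the lowest objective. Bootstrap refits
  start from the point estimate (standard, and 10-50x cheaper than
  multi-start per resample).
* **KS with ties** uses the exact sup over the empirical jump points, so
  atoms (fractions exactly 0 or 1) contribute their full jump.

## Known limitations

* The full time-dependent distribution $P(E,M,t)$ of the reversible
  model has no known closed form; the package provides moments, the
  generating function, and exact simulation instead.
* Switching rates are non-identifiable from drug-phase data when
  $\mu_E=\mu_M$ (and from growth means when $k^f_E=k^f_M$); the
  inversions raise errors rather than returning arbitrary values.
* The growth-phase full fit needs variance trajectories with many
  replicates; with a single initial condition the objective has a long
  shallow valley in the $k_M+\mu_M$ direction, so the protocol prefers
  both pure initial conditions and initializes from the mean-curve fit.
* Per-time heterogeneity estimates are combined by inverse
  bootstrap-variance weights; with very few replicates those weights are
  themselves noisy, and percentile CIs can undercover slightly (observed
  ~91-96% at nominal 95% in the recovery study).
* Mixtures of Beta distributions, time evolution of $\rho(p_0)$, >2
  phenotypes, spatial structure and treatment-schedule optimization are
  out of scope.
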