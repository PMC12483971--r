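---
title: "Methods: the IMK model for survival and micronuclei in imkmn"
author: "imkmn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the IMK model for survival and micronuclei in imkmn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imkmn)
```

## The model and its assumptions

The integrated microdosimetric-kinetic (IMK) model divides the cell
nucleus into sub-micrometre spherical domains of radius $r_d$. Energy
deposition per domain is described microdosimetrically by the specific
energy; potentially lethal lesions (PLLs) are produced in proportion to
it and subsequently either convert to lethal lesions (LLs) at first- and
second-order rates, or repair. Solving the lesion kinetics for a
piecewise-constant dose-rate history gives the mean LL count per nucleus

$$\langle w\rangle = (\alpha_0 + z^*_{1D}\beta_0)\,D + F\,\beta_0 D^2,
\qquad -\ln S = \langle w\rangle,$$

with $D$ the absorbed dose, $S$ the surviving fraction,
$z^*_{1D} = y^*/(\rho\pi r_d^2)$ the saturation-corrected dose-mean
specific energy carrying the radiation-quality dependence, and $F$ the
Lea–Catcheside protraction factor carrying the dose-rate dependence
through the sublethal-damage repair rate $(a+c)$.

The extension to micronuclei assumes that the misrepair transformation of
an LL produces an MN with probability $h$, so the expected MN per cell is
$F_{MN} = h\langle w\rangle$, i.e. an LQ curve with
$\alpha_{m0}=h\alpha_0$ and $\beta_{m0}=h\beta_0$. Two structural
consequences the package tests heavily: $F_{MN}/\langle w\rangle = h$
exactly for every dose, quality and schedule; and the maximum MN-endpoint
RBE (a ratio of linear coefficients) is independent of $h$, whereas the
survival-endpoint RBE defined through $D_{10}$ ratios is **not**
invariant under the joint rescaling $(\alpha_0,\beta_0)\to
(\alpha_{m0},\beta_{m0})/h$ — recovering survival from MN data therefore
genuinely requires $h$.

Model assumptions worth keeping in mind: lesion yields are linear in
specific energy within a domain; repair rates are constant in time (one
exponential); domains do not interact; and the same $h$ applies to every
LL regardless of quality. Bystander signalling, cell-cycle redistribution
and inverse dose-protraction effects are outside the model.

## Parameters

| Parameter | Units | Default / typical | Meaning |
|---|---|---|---|
| `alpha0` | Gy$^{-1}$ | 0.08–0.6 | intrinsic linear LL coefficient |
| `beta0` | Gy$^{-2}$ | 0.016–0.047 | intrinsic quadratic LL coefficient |
| `a_plus_c` | h$^{-1}$ | 0.37–2.2 | sublethal-damage repair rate; ~19 min half-time at 2.19 h$^{-1}$ |
| `r_d` | µm | 0.40–0.50 | domain radius; sets the LET sensitivity via $z^*_{1D}\propto r_d^{-2}$ |
| `h_mn` | — | 0.275 | MN formation probability per lethal lesion |
| `y0` | keV/µm | 150 | saturation (overkill) scale of the lineal-energy correction |
| `rho` | kg/m$^3$ | 1000 | domain density (water) |

The keV/µm → Gy conversion uses the CODATA constant exposed as
`KEV_TO_JOULE`; the input files never need to carry unit conversions.

## Microdosimetric quantities

Spectra arrive as tabulated $(y, f(y))$ pairs with no promised functional
form, so all integrals use the trapezoidal rule on the supplied grid;
tests verify that halving the grid spacing moves $y^*$ by less than
$10^{-4}$ relative for smooth spectra, and that single-line spectra
reproduce the closed form $y^* = y_0^2(1-e^{-y^2/y_0^2})/y$ to $10^{-8}$.
Both frequency densities $f(y)$ and dose-weighted densities $d(y)$ are
accepted; the latter are converted through $f(y)\propto d(y)/y$ and
renormalized, because both conventions circulate in microdosimetry.

The parametric spectrum generator is a lognormal in $y$ with the median
tied to the nominal LET — any positive unimodal family would do, since
only spectral moments enter $y^*$. It stands in for a Monte Carlo
transport tally and is test scaffolding, not physics: it reproduces the
qualitative rise-and-saturation of $y^*$ with LET but makes no claim
about the absolute spectral shape of any real beam, so LET-axis
placements of RBE predictions are only qualitative.

## The protraction factor

For a single continuous exposure of duration $T$,
$F = 2[(a{+}c)T + e^{-(a{+}c)T} - 1]/((a{+}c)T)^2$. For arbitrary
piecewise-constant schedules the double integral over ordered time pairs
is evaluated in closed form per segment pair: same-segment terms use
$x + e^{-x} - 1$ (computed via `expm1`, with a series switch below
$x = 10^{-4}$ and the exact acute limit $F=1$ below $(a{+}c)T=10^{-9}$,
avoiding catastrophic cancellation), and cross-segment terms factor into
$(1-e^{-\mu\tau_i})(1-e^{-\mu\tau_j})e^{-\mu\,\mathrm{gap}}/\mu^2$.
Instantaneous fractions are represented as short finite segments, never
true deltas, keeping a single code path; the textbook split-dose formula
$\tfrac12(1+e^{-(a+c)\Delta t})$ then serves as an oracle. The test suite
also checks the implementation against an independent midpoint-rule
discretization of the double integral with Richardson extrapolation, to
$10^{-6}$ on randomized schedules.

The four standard dose-rate regimens (continuous 1 Gy/min; 0.5 Gy per
fraction with 30 s beam-on/30 s gaps; 0.1 Gy with 6 s/54 s; 0.05 Gy with
3 s/57 s) are built by `doserate_schedules()`; their nominal average dose
rates are defined over whole fraction cycles, which reproduces 1.0, 0.5,
0.1 and 0.05 Gy/min exactly.

## Bayesian estimation

The likelihood is Gaussian on $-\ln S$ for survival data and on the MN
frequency for MN data. The sampler is plain Metropolis with uniform
priors; the acceptance ratio is the posterior ratio. Two proposal
mechanisms are provided:

* **`independence`** (default): candidates are drawn afresh from the
  uniform prior — the literal reading of generating candidates from the
  prior distribution. It is exact but mixes slowly when the posterior
  occupies a small fraction of the prior box, so it is best for one- or
  two-parameter fits.
* **`walk`**: Gaussian random walk. During burn-in only, the proposal is
  tuned: first a global scalar acceptance-rate tuning, then an
  adaptive-Metropolis covariance estimated from the recent half of the
  burn-in history (the $\alpha_0$–$\beta_0$ posterior is strongly
  anticorrelated, so axis-aligned steps mix poorly). The proposal is
  frozen when sampling starts, so the retained chain is a valid
  Metropolis chain. Joint three-parameter fits should use this proposal.

Default prior boxes are $\alpha_0\in[0,2]$ Gy$^{-1}$,
$\beta_0\in[0,0.5]$ Gy$^{-2}$, $(a{+}c)\in[0.05,10]$ h$^{-1}$,
$h\in[0,1]$, all configurable; informative prior knowledge about
$(a{+}c)$ (e.g. repair rates measured from damage-kinetics assays) can be
expressed by narrowing its box or fixing it outright via
`fit_config(a_plus_c=)`.

**Noise scale.** Three policies are supported because dose-response
sources rarely state their error model. The default, `"fit"`, samples a
single noise SD jointly with the parameters under a Jeffreys-type prior
(uniform in $\log\sigma$ around a preliminary least-squares estimate):
this propagates the noise-scale uncertainty into the credible bands,
which a simulation study in the test suite shows is what keeps 68%/95%
band coverage at its nominal level when the residual degrees of freedom
are small. `"pooled"` plugs in the least-squares residual SD. Per-point
replicate SDs (`"per_point"`) are the right weighting when the noise is
heteroscedastic — MN counts with scatter proportional to the mean are the
package's standard example — but SDs estimated from three replicates are
themselves noisy, so they are floored at a quarter of the pooled scale;
with small replicate counts and homoscedastic noise this policy yields
overconfident posteriors and is deliberately not the default.

**Identifiability of the repair rate.** Acute data contain no information
about $(a{+}c)$ (at $F=1$ it drops out of the model), so it is only
sampled when protracted datasets are present; otherwise it is held fixed.
Designs in which every exposure delivers the same total dose over at most
tens of minutes constrain $(a{+}c)$ only weakly when $\beta_0$ is small
(the $F\beta_0 D^2$ signal is a fraction of the noise), and the posterior
then remains prior-dominated with a large SD; the slow-repair
normal-fibroblast setting is the canonical example. Multi-duration
designs spanning hours identify it well. This is a property of the
designs, not of the sampler, and the package reports the posterior SD so
the two situations are distinguishable.

**MN endpoint dialects.** MN-per-cell data are fitted as the expected
count. MN-bearing-cell fractions are related to the expected count by the
Poisson link $1-e^{-F_{MN}}$; because assay dialects materially change
the absolute scale of $h$, the transform is applied only when the dataset
is explicitly declared `mn_fraction`, never silently.

**Domain-radius calibration** is a deterministic grid search: for each
candidate $r_d$ the $z^*_{1D}$ of every dataset is recomputed from its
spectrum and the summed squared residual on $-\ln S$ recorded; ties break
toward the smaller radius, and a flat residual profile (photon-only data)
triggers a warning rather than a spurious estimate. The iterative manual
loop this replaces converges to the same argmin when the grid contains
it, and the full profile is returned for inspection.

**Uncertainty propagation** evaluates a prediction function over every
posterior draw and reports the pointwise mean and equal-tailed interval.
Equal-tailed quantiles are used rather than highest-density intervals for
reproducibility and monotonic nesting (the 68% band is always inside the
95% band).

## The synthetic-data generator

The generator emulates: clonogenic-survival scatter as lognormal noise on
$S$ with a default CV of 15% and 3 replicates per dose (typical colony
assay conditions), MN scatter as Gaussian noise proportional to the mean
with CV 10% or as Poisson counts over 200 scored cells per replicate
(typical MN-assay scoring depth), dose grids of 0–8 Gy in 1-Gy steps
(the range that identifies both LQ coefficients), and the four standard
dose-rate regimens. Noisy survival is clamped at 1, as when normalizing
to an unirradiated control; because the model curve passes through
$S(0)=1$ for every parameter value, dose-0 residuals are
parameter-independent and the clamp cannot bias a fit.

What the generator does **not** emulate: plating-efficiency drift,
cell-cycle and bystander effects, inter-experiment batch structure, or
real transport-code spectra. Passing the recovery tests therefore shows
that the estimation machinery is correct and calibrated under the stated
noise model — not that any particular real dataset satisfies that noise
model.

Arithmetic means of multiplicative replicate noise carry a small Jensen
bias on the $-\ln S$ scale (about $\sigma^2/2 \approx 0.011$ at CV 15%),
an order of magnitude below the per-point noise; replicate-level records
can be constructed directly with `dose_response()` when this matters.

## Problem sizes and reproducibility

All randomness flows from explicit integer seeds; chains are
bit-reproducible given the seed, and generators draw from a private RNG
stream that leaves the caller's RNG state untouched. The test suite uses
chains of 300–10\,000 retained samples and a 200-replicate coverage study
on an 8-dose, 3-replicate design; the acceptance script uses the default
$10^3$ burn-in and $10^4$ samples for every fit. These sizes were chosen
so the posterior-mean Monte Carlo error is well below the posterior SD in
every reported quantity.

## Known limitations

* The stochastic (domain-level specific-energy distribution) variant of
  the MK family is not implemented; predictions use dose-mean quantities,
  which is the standard regime below a few hundred keV/µm.
* $h$ is assay-protocol dependent; absolute MN predictions transfer
  across laboratories only after re-estimating $h$ under the target
  protocol. Relative quantities (RBE, dose-rate ratios) do not need $h$.
* The parametric spectrum generator supports qualitative LET sweeps only;
  quantitative beam-specific predictions require measured or simulated
  spectra supplied via `read_spectrum()`.
* Uniform priors with hard boundaries can truncate posteriors for
  parameters that approach a boundary (e.g. very small $\beta_0$); widen
  the box via `fit_config(priors=)` when summaries hug an edge.
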