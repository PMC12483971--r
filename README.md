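# imkmn

Biophysical modelling of radiation-induced cell killing and micronucleus
(MN) formation with the integrated microdosimetric-kinetic (IMK) model,
for radiobiologists and medical physicists who need dose-, LET- and
dose-rate-dependent predictions of clonogenic survival, MN frequency and
relative biological effectiveness (RBE) from a single cell-line parameter
set — and Bayesian machinery to estimate that parameter set from
dose-response data.

## The model

The nucleus is pictured as a collection of sub-micrometre domains of
radius r_d. Radiation induces potentially lethal lesions in proportion to
the specific energy deposited per domain; lesions either convert to
lethal lesions (rates a, b_d) or repair (rate c). Solving the lesion
kinetics gives the mean number of lethal lesions per nucleus

    <w> = (alpha0 + z1D* . beta0) D  +  F . beta0 D^2 ,      -ln S = <w>

where D is absorbed dose (Gy), alpha0 (Gy^-1) and beta0 (Gy^-2) are
cell-specific coefficients, and

* **z1D\*** = y\*/(rho pi r_d^2) is the saturation-corrected dose-mean
  specific energy (Gy) carrying the radiation-quality (LET) dependence.
  y\* is computed from the lineal-energy spectrum f(y) as
  y\* = y0^2 &int; [1 - exp(-y^2/y0^2)] f(y) dy / &int; y f(y) dy, with
  saturation parameter y0 (default 150 keV/um) expressing the overkill
  effect at high lineal energy.
* **F** is the Lea-Catcheside dose-protraction factor (in (0,1]),
  computed in closed form for arbitrary piecewise-constant dose-rate
  schedules; it encodes sublethal-damage repair at rate (a+c) during
  protracted or fractionated delivery.

Micronuclei are assumed to form during the misrepair transformation of a
lethal lesion with probability h, so the expected MN per cell is

    F_MN = h <w> = (alpha_m0 + z1D* . beta_m0) D + F . beta_m0 D^2 ,

with alpha_m0 = h alpha0 and beta_m0 = h beta0. Survival and MN therefore
share one parameter set; the RBE for survival (a D10 ratio) and the
maximum RBE for MN (an alpha_m ratio) coincide under matched conditions.

Parameters are estimated by Metropolis MCMC (uniform priors, Gaussian
likelihood on -ln S or on MN frequency, 10^3 burn-in and 10^4 retained
samples by default), and posterior draws propagate to pointwise credible
bands on any prediction.

## Worked example

```r
library(imkmn)

hsg <- cell_parameters(alpha0 = 0.150, beta0 = 0.0467, a_plus_c = 2.19,
                       r_d = 0.42, h_mn = 0.275, label = "HSG")

# radiation quality of an 80 keV/um ion-like beam
sp <- generate_spectrum("ion", let = 80, width = 0.25)
q  <- quality_from_spectrum(sp, domain_geometry(r_d = 0.42))
q$z1dstar
#> [1] 20.94

# acute survival and MN at 2 Gy: photon vs ion
surviving_fraction(hsg, radiation_quality(0), 2)   #> 0.6145899
surviving_fraction(hsg, q, 2)                      #> 0.08692477
mn_frequency(hsg, radiation_quality(0), 2)         #> 0.13387
rbe_mn(hsg, q, radiation_quality(0))               #> 7.519708

# dose-rate sparing: 4 Gy delivered as the four standard regimens
rel <- relative_mn_vs_doserate(hsg, radiation_quality(0), 4,
                               doserate_schedules(4),
                               doserate_schedules(4)[["1.0"]])
round(rel, 3)
#>   1.0   0.5   0.1  0.05
#> 1.000 0.976 0.827 0.721

# fit synthetic photon survival data and recover the parameters
ds  <- simulate_survival_dataset(hsg, doses = 0:8,
         noise = noise_model("lognormal_s", 0.15, replicates = 3, seed = 7))
fit <- mcmc_fit(ds, fit_config(seed = 1, proposal = "walk"))
summary(fit)
#>                  mean          sd         q16         q50         q84
#> alpha0     0.10233253 0.039512475  0.06515878  0.10100858  0.13723047
#> beta0      0.05173311 0.006038152  0.04638067  0.05171274  0.05741781
#> log_sigma -2.01766511 0.288275821 -2.30793574 -2.03504305 -1.72576012
```

The higher z1D\* of the ion beam steepens the survival curve (RBE_MN =
7.5 at the linear-term level), and slower delivery spares MN formation
through the protraction factor. In the fit, the posterior means for this
noise realization sit within roughly one posterior SD of the generating
values (0.150, 0.0467); the `log_sigma` row is the jointly sampled noise
scale on the -ln S residuals. `workflow_survival_to_mn()` chains fit, optional domain-radius
calibration and MN prediction with credible bands; `workflow_mn_to_survival()`
runs the reverse direction.

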