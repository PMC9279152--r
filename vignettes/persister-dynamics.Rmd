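---
title: "Modelling drug-tolerant persister cells and measuring their mutation rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling drug-tolerant persister cells and measuring their mutation rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(persisterdyn)
```

## The biological problem

When a clonal population of cancer cells (for example microsatellite-stable
colorectal cancer lines under EGFR or EGFR/BRAF blockade) is exposed to a
lethal dose of a targeted drug, most cells die within days, but a small
residue survives for weeks to months in a slow-cycling, drug-tolerant
*persister* state. Persisters matter for two reasons: they are the reservoir
from which genetically resistant clones later emerge, and there is evidence
that cells in the persister state mutate faster than untreated cells
(stress-induced mutagenesis), accelerating the acquisition of bona fide
resistance mutations.

`persisterdyn` implements a complete quantitative framework around these
phenomena:

1. a deterministic **transition-to-persister (TP) model** of the kill curve,
   with Bayesian inference and information-criterion model selection that
   asks whether persisters pre-exist treatment or are drug-induced;
2. a fully stochastic **birth--death--switch--mutate branching process**
   that simulates a two-step fluctuation assay over thousands of wells;
3. **analytic estimators** of the spontaneous mutation rate
   $\mu_s$ and the persister mutation rate $\mu_p$ from positive-well
   fractions, with a grid posterior over the pre-existing fraction and the
   fold increase $\mu_p/\mu_s$;
4. **dispersion statistics** that discriminate drug-induced from
   pre-existing persisters by the variance-to-mean ratio of per-well
   persister abundance, in the spirit of the classical fluctuation test.

## The TP model

Under treatment at drug concentration $M$, sensitive cells $X(t)$ and
persister cells $Z(t)$ evolve as

$$
\frac{dX}{dt} = \bigl(B - D(M) - \lambda(M)\bigr)\,X,\qquad
\frac{dZ}{dt} = -D_p\,Z + \lambda(M)\,X,
$$

where $B$ is the sensitive birth rate, $D(M)$ the drug-dependent death
rate, $\lambda(M)$ the switching rate into the persister state, and
$D_p > 0$ the persister death rate under drug. Back-switching of persisters
under treatment is folded into $D_p$: a persister that attempts to divide
before acquiring a resistance mutation dies. Populations are treated as
continuous (deterministic limit); demographic noise is the business of the
stochastic simulator below.

Two structural pieces are not fixed by the dynamics and are configurable:

* **Death response.** Only the two limits are constrained — the
  unperturbed rate $D_0$ at $M = 0$ and a saturation at $D_0 + k_0$. We
  use the simplest monotone form with those limits,
  $D(M) = D_0 + k_0\,aM/(1 + aM)$, where $1/a$ is the characteristic
  concentration (half effect at $M = 1/a$).
* **Switching response.** Four variants span the plausible family:
  `zero` ($\lambda = 0$), `constant` ($\lambda_0$), `linear` ($kM$), and
  `saturating` ($\lambda_0\,aM/(1+aM)$).

Before the drug takes effect (a delay $t_0$ of one to a few days), the
population grows at the observed rate $S_0$ with the persister fraction
frozen at $f_0 = Z(t_0)/N(t_0)$. The defining question of the framework is
whether $f_0 = 0$ (fully drug-induced persistence) or $f_0 > 0$.

`solve_tp()` assembles the exact closed form on every constant-dose
interval (X is exponential; Z is the linear-ODE response to exponential
forcing, with the resonance case $B - D - \lambda = -D_p$ handled by its
limit). Dose schedules are piecewise-constant; ramps are represented by
fine grids (0.1-day steps by default). An adaptive ODE integrator
(`method = "ode"`, via deSolve) is kept as an independent cross-check and
agrees with the closed form to $10^{-6}$ relative tolerance in the test
suite. Because the solution composes exactly over sub-intervals, a
semigroup property test guards the segment bookkeeping.

```{r tp-example}
p <- preset_parameters("widr")$fit
tr <- solve_tp(p, schedule_constant(5), N_init = 1,
               t_grid = seq(0, 30, by = 2))
round(head(tr), 4)
```

The total population shows the characteristic biphasic kill curve: an
early decay at $D(M) + \lambda - B$ and a late tail decaying at $D_p$,
the signature of persister outgrowth. A practical corollary of a
drug-dependent $\lambda(M)$ is that dosing schedules reshape the persister
pool; `predict_persisters_under_schedule()` compares, e.g., a constant
dose with a linear ramp at equal horizon.

## Fitting: likelihood, priors, sampler

Viability readings enter as fold-changes relative to a pre-treatment
reference (`normalize_growth_curves()`; a peak-referenced variant aligns
assays run at different seeding densities). The likelihood is i.i.d.
Gaussian on *log* fold-change with one noise scale per assay — the
natural error model for luminescence data spanning orders of magnitude.
Only the net pre-drug growth rate $G_0 = B - D_0$ is identifiable from
fold-changes, so the fit parameterises $G_0$.

Priors are independent flat distributions on bounded supports.
`prior_bounds()` carries broad defaults (rates up to 5/day);
`physiological_bounds()` is the recommended analysis setting, restricting
rates to ranges plausible for cultured cell lines (net growth below
1.5/day, i.e. doubling slower than ~11 h; drug-effect delay below 3 days;
persister death in 0.001--0.3/day). The restriction matters: with rates
allowed up to 5/day the posterior acquires a spurious mode in which very
fast birth and death nearly cancel, and all samplers struggle. Collapsing
a bound to a point fixes that parameter, which is also how $f_0$ can be
pinned at chosen values.

The posterior surface couples $(G_0, k_0, a)$ along a curved ridge that
defeats naive multi-start local optimisation. The mode search therefore
runs bounded differential evolution on a reduced surface in which the
noise scales are profiled out analytically
($\hat\sigma_i^2 = \mathrm{SS}_i/n_i$), followed by Nelder--Mead and
L-BFGS-B polish. Sampling is multi-chain random-walk Metropolis started
at the mode with a Laplace-approximation proposal, a second adaptation
phase that re-estimates the proposal covariance from burn-in draws, and
split-$\hat R$ convergence monitoring (flagged above 1.01, warned above
1.05). Posterior intervals are 95% highest-density intervals — the
shortest interval containing 95% of the pooled draws, the convention of
the standard MCMC summary stacks (equal-tailed quantiles systematically
under-cover on the dense side of a skewed posterior).
Identical seeds and settings reproduce summaries exactly.

Model selection across the $4 \times 2$ grid (four $\lambda$ forms, each
with $f_0 = 0$ or $f_0$ free) uses maximum likelihood with
$\mathrm{BIC} = k\ln n - 2\log L$ (primary) and
$\mathrm{AIC} = 2k - 2\log L$ (reported); disagreements are flagged. Two
safeguards make the grid robust: fits are warm-started across variants
(shared parameters transfer), and each free-$f_0$ model's likelihood is
floored at its $f_0 = 0$ twin's (the twin is an admissible point of the
free model, so the floor is a mathematical identity, not a heuristic).

## The stochastic fluctuation assay

The two-step assay seeds many independent wells with a small clonal
inoculum, expands them drug-free to a per-well target (500 to ~20,000
cells in the default design, 20 plates of 96 wells = 1,920 replicates),
then treats all wells and watches for resistant colonies. Colonies first
visible within the early cutoff (28 days) are attributed to pre-existing
mutants generated by spontaneous mutation ($\mu_s$) of the expanding or
still-declining sensitive population; colonies first appearing at or
after the late cutoff (70 days) arise from persisters mutating at
$\mu_p$. Colonies between the cutoffs are scored `intermediate` and are
deliberately not used by the estimators, mirroring the two-stage counting
of the laboratory protocol.

The simulator advances every cell class in fixed steps $\Delta t$
(default 0.05 days): each cell experiences at most one event per step,
drawn with probability rate $\times\ \Delta t$ (validity guarded by
$\Delta t \sum \text{rates} \le 0.1$; violating it is an error, and a
step-halving test confirms insensitivity to $\Delta t$). Resistant
lineages are tracked individually (well, origin, founding time, size,
first threshold crossing). A lineage is a visible colony once it reaches
`colony_detection_threshold` cells (default 50 — by-eye visibility is not
sharply defined, so this is an explicit knob). Growing colonies are
frozen at the threshold: a 50-cell supercritical colony goes extinct with
probability $(d/b)^{50} \approx 10^{-31}$, so freezing preserves both the
crossing time and establishment status while keeping sizes bounded.

With mutation switched off, the mean over wells converges to the TP
solution (law of large numbers), which the acceptance suite checks at
every observation time against three standard errors over 1,000 wells
using $\Delta t = 0.002$ days (the per-cell one-event scheme has a
first-order-in-$\Delta t$ mean bias, so this comparison uses a finer step
than production simulations need).

## Establishment, visibility, and the estimators

A new mutant founds a lineage that may drift to extinction. For a
birth--death lineage from one cell,

$$
\psi(\Delta t) = \frac{b - d}{\,b - d\,e^{-(b-d)\Delta t}\,}
$$

is the probability of surviving $\Delta t$ days
(`establishment_probability()`), with $\psi(\infty) = 1 - d/b$. The
expected number of *established* mutants from a population trajectory
$\mathrm{pop}(t)$ over a window $[0, T]$ is
$\mathcal{M} = \mu \int_0^T \mathrm{pop}(t)\,\psi(T - t)\,dt$
(`expected_mutants()`, composite trapezoid on a 0.05-day grid with a
refinement oracle in the tests), and the number per well is Poisson, so
the probability that a well holds at least one established mutant is
$P = 1 - e^{-\mathcal{M}}$. Inverting the observed positive-well
fraction gives the classic fluctuation estimator
$\hat\mu = -\log(1-\hat p)/I$ with Wilson 95% intervals propagated
through the same inversion (`estimate_mutation_rate()`).

Mapping *observed colony windows* to *mutant founding times* needs more
than $\psi$: a founder must also have grown to the visibility threshold.
The exact transient law of the birth--death process gives the visibility
kernel

$$
V(s) = \bigl(1 - \alpha(s)\bigr)\,\beta(s)^{\mathrm{thr}-1},\qquad
\alpha(s) = \frac{d(e^{gs}-1)}{be^{gs}-d},\quad
\beta(s) = \frac{b(e^{gs}-1)}{be^{gs}-d},
$$

the probability that a lineage founded $s$ days ago is visible now
(`colony_visibility()`). `estimate_rates_from_outcomes()` builds three
detection-weighted integrals from the deterministic trajectories: the
sensitive channel for the early window (expansion plus the declining
sensitive population under drug — the latter contributes cell-days
comparable to the expansion and cannot be dropped), the persister channel
for the early window (persister-derived mutants founded early enough to
surface before the cutoff), and the persister channel for the late
window. Because a well is classified by its *first* colony, the late
observable is censored by wells that already showed a colony; the late
fraction is therefore modelled as
$e^{-\Lambda(c_l)}\bigl(1 - e^{-\mu_p I_{\text{late}}}\bigr)$ and the two
rates are solved jointly by a short fixed-point iteration. The one
contamination the estimator deliberately ignores is slow pre-existing
mutants surfacing late: their expected contribution is negligible
(the sensitive channel's visibility kernel is saturated long before the
late window) and quantifying it by simulation is exactly what
`validate_estimators()` does.

```{r assay-example, eval = FALSE}
params <- preset_parameters("widr")$assay
design <- experiment_design(n_plates = 5)        # 480 wells
sim <- simulate_experiment(design, params, master_seed = 1)
estimate_rates_from_outcomes(sim$outcomes, design, params)
```

`joint_posterior_fold()` propagates uncertainty in $f_0$: on a grid over
$(f_0, \mu_p/\mu_s)$ it re-solves the TP model (a pre-existing fraction
adds persisters at treatment start), rebuilds the integrals, profiles
$\mu_s$ out of the early-count equation, and accumulates the binomial
log-likelihood of the observed counts in log space before normalising.
The marginal over the fold answers the headline question — whether an
elevated persister mutation rate is supported across all admissible
$f_0$.

## Dispersion analysis

If persister fate is assigned only *after* drug exposure, per-well
persister numbers are (thinned) Poisson: index of dispersion
(variance/mean) near 1. If persister fate is assigned during the
drug-free expansion, persister clones expand with the population and
per-well counts inherit Luria--Delbrück-type fluctuations: variance far
above the mean. `dispersion_test()` refers $(n-1)\,\hat v/\hat m$ to
$\chi^2_{n-1}$, two-sided at $\alpha = 0.05$; verdicts are
`poisson-consistent`, `overdispersed`, or `underdispersed` (the latter
reported as "not overdispersed" evidence). On true Poisson draws the
test rejects at its nominal ~5% rate (calibration test included).
A viability-to-count calibration factor is exposed for continuous
signals; the chi-square reference is approximate in that case.

`simulate_persister_counts()` generates both scenarios through the same
two-phase simulator, differing *only* in when fate is assigned:
drug-induced uses $\lambda(M)$ under treatment; pre-existing assigns
fate at a constant per-cell rate `nu_pre` during expansion
(`matched_preexisting_rate()` matches the scenario means, so the
variance-to-mean ratio is the only discriminating statistic). The
scenario load defaults to roughly 30 persisters per well at the 3-week
read-out — the low end of the observed residual-viability range — so
that the index test responds to fate-assignment timing rather than to
the ~1% well-to-well variation left by the expansion stopping rule,
which at several hundred persisters per well would masquerade as weak
overdispersion.

## Pre-treatment growth decomposition

The untreated birth and death rates $b$ and $d$ enter everywhere (the
expansion, resistant-colony growth, $\psi$, $V$); they are measured by
combining two assays. `estimate_net_rate()` takes the log-linear slope of
viable-count time series ($g = b - d$, with regression SE).
`estimate_death_birth_ratio()` uses dead-fraction measurements under the
accumulation model — dead cells are produced at rate $d\,N(t)$ from
exponential growth and counted alongside live cells — giving
$\phi(t) = \rho/(1+\rho)$ with $\rho = (d/g)(1 - e^{-gt})$ and asymptote
$\phi_\infty = d/b$; given $g$, the transform $\phi/(1-\phi)$ is linear
through the origin in $(1-e^{-gt})/g$ with slope $d$.
`combine_growth_rates()` closes the algebra: $b = g/(1-r)$,
$d = gr/(1-r)$, which round-trips exactly and propagates both SEs.
Estimates here are *chronological* (per day, not per division)
throughout — the conservative convention for comparing sensitive and
persister mutational processes, since persisters divide rarely.

## Synthetic data: what it emulates, and what it does not

All generators are pure functions of (parameters, seed). Ground-truth
presets `"widr"`-like and `"difi"`-like provide two archetypes with
plausible magnitudes (net growth 0.35--0.5/day, persister death
0.01--0.03/day, $\mu_s = 2\times10^{-6}$, $\mu_p = 2\times10^{-5}$ per
cell per day — a 10-fold increase); they are documentation-level choices,
not measurements. Noteworthy generator decisions:

* **Dose--response panel.** Five doses (1, 3, 8, 20, 40 concentration
  units with $1/a = 2$) over 12 days with triplicates, plus a single-dose
  assay at dose 5 over 30 days in duplicate — a typical dilution series.
  The dose panel deliberately straddles the saturation of $D(M)$:
  dose-dependence of the *persister plateau* is what distinguishes
  drug-induced switching from a pre-existing fraction (a near-linear kill
  response makes the plateau fraction accidentally dose-independent, and
  no criterion can then separate the scenarios).
* **Fit preset plateau.** The single-dose persister plateau is ~15% of
  the peak signal. This keeps the $\lambda$--$f_0$ decoupling property
  meaningful: fixing $f_0$ at small values shifts the fitted $\lambda$ by
  $f_0/\mathrm{plateau}$, so at plateau 0.15 the shift stays under 10%
  for $f_0 \le 0.01$.
* **Assay preset plateau.** The fluctuation-assay parameter set uses a
  ~1.5% persister plateau (300 cells of 20,000) with $D_p = 0.01$/day,
  inside the observed 0.2--2.5% residual-viability band, and an 84-day
  observation horizon.
* **Noise.** Lognormal multiplicative noise with a single scale per
  assay, matching the fitting likelihood by construction; the day-0
  reference reading is generated exactly so that fold-changes carry
  independent errors (dividing by a noisy reference would induce
  within-series correlations the likelihood does not model).

What passing tests on these data do *not* show: robustness to non-Gaussian
or correlated measurement error, plate/edge effects, drug degradation
between media changes, wells lost to contamination, or mixtures of clones
with heterogeneous parameters. The generators emulate the statistical
structure the models assume — they validate the machinery, not the
biology.

## Numerical choices and degenerate inputs

* Closed-form solver: resonance $g + D_p \to 0$ switches to the
  $\tau e^{-D_p\tau}$ limit below $10^{-10}$; negative concentrations,
  non-finite parameters, empty schedules, and nonpositive populations are
  errors, not NaNs.
* Quadrature: composite trapezoid, default 0.05-day step; halving the
  step changes the integrals by well under the Monte-Carlo noise of any
  comparison made with them.
* Estimators: $\hat p = 0$ gives $\hat\mu = 0$; $\hat p = 1$ leaves the
  point estimate undefined and reports the Wilson lower bound only; the
  joint posterior accumulates in log space and fails loudly if the
  likelihood underflows everywhere.
* Simulator: per-cell event probabilities above 1 raise a step-size
  error; counts are integers throughout; extinction is absorbing per
  lineage; per-plate RNG streams are drawn from the master seed, so a
  whole experiment is reproducible from one integer.
* Problem sizes in the acceptance suite — 100 simulated experiments of
  480 wells, 20 fit repetitions, 1,000--2,000-well scenario batches,
  10,000 Monte-Carlo lineages — were chosen so the full study runs
  comfortably on a laptop core while leaving every comparison
  statistically sharp.

## Known limitations

* The sampler is random-walk Metropolis, not gradient-based; it is
  dependable at the ~10-parameter scale used here but would need
  upgrading for much larger models.
* Early/late attribution relies on the colony-growth model for the
  visibility kernel; a drug that slows resistant colonies (rather than
  leaving them at untreated rates) would bias the window mapping.
* The dispersion test is a variance-to-mean screen, not a full
  Luria--Delbrück likelihood fit; it answers "Poisson or not", not "which
  non-Poisson".
* No pharmacokinetics: concentrations are abstract and only meaningful
  relative to $1/a$; no spatial structure or cell-cycle phase structure.
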