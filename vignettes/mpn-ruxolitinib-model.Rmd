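---
title: "Modelling JAK2-mutant haematopoiesis under ruxolitinib: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling JAK2-mutant haematopoiesis under ruxolitinib: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`mpnrux` implements a compartmental ODE model of haematopoiesis in
myeloproliferative neoplasms (MPN). Two cell lineages — healthy wild-type
and malignant JAK2 V617F-mutant — each pass through three maturity stages:
stem cells ($x_0$, $y_0$), progenitors ($x_1$, $y_1$) and mature blood
cells ($x_2$, $y_2$). Two auxiliary compartments close the feedback loop:
cellular debris $a$ produced by dying cells, and a lumped cytokine signal
$s$ produced from debris, degraded at rate $e_s$, and driven by an
external inflammatory load $I$.

Stem cells divide at rate $\alpha$; each division either self-renews, with
probability
$p \,\varphi(x_0, y_0)\, \frac{s}{s_{1/2} + s}$,
or differentiates. The self-renewal probability is modulated by two
feedbacks:

* **niche crowding** $\varphi_x = 1/(1 + c_{xx} x_0 + c_{xy} y_0)$ and
  $\varphi_y = 1/(1 + c_{yx} x_0 + c_{yy} y_0)$ — competition for
  bone-marrow niche space, monotone decreasing in both stem-cell counts;
* **cytokine saturation** $s/(s_{1/2} + s)$, a Michaelis–Menten
  up-regulation with lineage-specific half-saturation constants $s_{x0}$
  and $s_{y0}$.

Differentiating divisions feed the next compartment through lumped
amplification factors $A$ (the many intermediate divisions between named
stages), giving influx terms of the form
$2 A \alpha (1 - p\,\varphi\, s/(s_{1/2}+s))\, n$. Progenitors self-renew
with constant probability and die at rate $d_1$; mature cells die at rate
$d_2$; stem-cell death is neglected. All cell deaths feed the debris pool,
which is cleared at rate $e_a a s$.

The 26 constants default to a calibrated parameterisation describing a
typical disease course: a single mutant stem cell seeded into the healthy
steady state expands over roughly three decades, passing 50% variant
allele frequency (VAF) around year 30, and fixes if untreated. One default
deserves comment: the malignant half-saturation constant is stored as
$s_{y0} = 0.0714$, the value implied (to three digits) by the internal
consistency of the published effective-parameter table, rather than the
two-significant-figure $7.1\times10^{-2}$ of the headline parameter table.

The observable is the VAF estimate $g(x_2,y_2) = y_2/(x_2+y_2)$, exact
under the simplifying assumption that every mutant cell is homozygous.
`homozygous_fraction_bound()` quantifies how strong that assumption is:
a measured VAF $V \ge 0.5$ forces at least a fraction $2V-1$ of cells to
be homozygous even if *all* cells are mutated — 52% at the cohort-average
baseline VAF of 0.76.

### A resolved notational ambiguity

The treated-system equations can be read with the malignant crowding
term as either $\varphi_y(x_0, y_0)$ or $\varphi_y(y_0, y_0)$. We use
$\varphi_y(x_0, y_0)$ everywhere, for two reasons: it is the only reading
consistent with the untreated equations and the definition of
$\varphi_y$, and the alternative produces treated dynamics whose
excursions never return to baseline on the decade scale, contradicting
the reported scenario behaviour.

## Treatment model

Ruxolitinib enters through exactly two constants. With daily dose $c_R$
(mg/day) and patient-specific response strengths
$\rho_{s_{y0}}, \rho_{d_{y1}} \ge 0$ (per mg/day):

$$\tilde s_{y0} = (1 + c_R\, \rho_{s_{y0}})\, s_{y0}, \qquad
  \tilde d_{y1} = (1 + c_R\, \rho_{d_{y1}})\, d_{y1}.$$

Raising $s_{y0}$ blunts the mutant stem cells' cytokine response (pushing
them toward differentiation — the only route to cure in this model);
raising $d_{y1}$ kills mutant progenitors (rapid cytoreduction, but the
untouched stem cells regrow the clone). Only relative dose changes matter:
a rescaling of $c_R$ can be absorbed into the $\rho$'s. Doses are constant
per patient (35 mg/day for the myelofibrosis-trial-like series, 20 mg/day
for the polycythaemia-vera-trial-like ones).

The treated vector field is obtained by substituting the effective
constants into the untreated right-hand side (`effective_parameters()`),
so treated and untreated dynamics share one code path.

## Steady states and stability

Equilibria are enumerated exactly. Each lineage's stem equation vanishes
when either the stem count is zero or the self-renewal balance
$2 p \varphi s/(s_{1/2}+s) = 1$ holds, giving four branches. On a branch,
progenitor and mature levels are linear in the stem influx, and the
debris level follows from the cytokine balance, $a = (e_s s - I)/r_s$.
The remaining debris balance then reduces to a single polynomial in $s$
of degree 2, 3, 3 and 4 on the four branches — twelve roots in total,
found with the companion-matrix solver `polyroot()`. Complex and negative
roots are retained in the census; a root is *biologically feasible* when
all components are real and non-negative (tolerance $10^{-6}$ of each
compartment's typical scale, then clamped). Duplicate feasible roots are
merged at relative distance $10^{-4}$ on `log1p`-transformed states
(counts span twelve decades).

Under the defaults: a locally stable trivial state
($s = I/e_s \approx 0.028$), two unstable healthy states, and a small
unstable plus a large stable malignant state. Stability comes from the
eigenvalues of a central-finite-difference Jacobian (component-relative
steps, absolute floor of one cell); a leading real part within
$10^{-9}$/day of zero is reported `"marginal"` rather than guessed. In
the healthy-only five-variable reduction the calibrated healthy state
($x_0 \approx 10^5$) is stable — the clinically relevant configuration
before mutation.

Exact agreement with the published state table is limited to about 5%
on some components because the published constants are themselves rounded;
the test suite asserts counts, labels and stability exactly, and
continuous components at 5%.

## Simulation, scenarios, basins, sensitivity

The debris compartment relaxes about $10^8$ times faster than the clonal
competition, so the system is stiff at all times. Integration uses
deSolve with a compiled-C right-hand side and the BDF integrator `vode`
at `rtol = 1e-8`, `atol = 1e-6`. Two guards matter in practice and were
chosen after systematic failure analysis: a maximum internal step of 50
days (otherwise the step grows without bound on near-constant stretches
until the stiff corrector fails — e.g. when starting exactly at a steady
state), and an initial step of $10^{-6}$ days (the automatic choice
overshoots the debris boundary layer when the first requested output is
far away). The method-switching `lsoda` was abandoned after reproducible
hard failures in smooth regimes.

`run_scenario()` plays the canonical experiment: 30 untreated years from
the disease-onset state, then six-fold increases of $s_{y0}$ and/or
$d_{y1}$ (scenarios a–d). `time_to_return()` measures the harmful initial
excursion of scenario b: the quantity must first rise strictly above its
level at treatment start and is then followed to the interpolated
downward crossing; monotone declines return `NA`. With the default
constants the mature-malignant excursion lasts 3.05 years and the VAF
excursion 4.07 years; the second agrees with the published "approximately
4 years", while the first is longer than the published "approximately 2
years" — robustly so under tolerance and resolution changes, which we
attribute to the same parameter-rounding propagation as above.

`basin_threshold()` quantifies how small the basin of the trivial state
is: the three cell compartments of one lineage are scaled by $f$ below
their stable steady state ($a$, $s$ kept at steady-state values) and the
attractor is classified after a 200-year horizon, with collapse declared
when fewer than half a cell remains (counts are continuous; below one
cell the population is extinct in any discrete reading — the published
figures come with no stated rule, so this cutoff is our convention).
$f$ is bisected on a log scale to $10^{-3}$ relative width. These runs
integrate the five-variable single-lineage reductions rather than the
full system with zeros: over centuries of stiff integration the dormant
lineage otherwise accumulates $O(\mathrm{atol})$ leaked cells, and since
a fitter clone invades, leaked cells grow and flip the attractor.
Thresholds land at 3.05% (healthy) and 0.086% (malignant), against
published values of 3.24% and 0.10%.

`local_sensitivity()` ranks one-at-a-time relative perturbations (default
1%, central differences) of all 26 constants by normalised effect on the
VAF after 30 untreated years (the supplementary analysis this mirrors did
not state its exact output, so the ranking is asserted only qualitatively).
The two maximal self-renewal fractions dominate, followed by the crowding
constants, the malignant stem proliferation rate and the healthy
half-saturation constant — self-renewal is each clone's fitness.

## Fitting patient VAF series

A patient is a sparse series of VAF measurements $(t_i, y_i)$, $t_1 = 0$,
under a constant dose. The model state at $t_1$ is unobserved;
`baseline_state()` reconstructs it by running the untreated
disease-progression trajectory until the model VAF first reaches the
observed baseline and interpolating the state there (error if never
reached within 100 years). This makes the anchor a deterministic,
patient-specific function of the baseline VAF — the published analysis
does not state its initialisation, so this reproducible convention is our
design choice. Predictions then simulate the treated system from the
anchor and read off $g(x_2, y_2)$; the prediction at $t_1$ equals the
first observation by construction, and fit quality is reported as RMSE in
VAF units.

`fit_patient()` minimises the sum of squared VAF residuals by bounded
Levenberg–Marquardt (`minpack.lm::nls.lm`, $\rho \ge 0$), in one of three
modes: `both`, or the restricted single-effect hypotheses `sy0_only` /
`dy1_only` (the excluded strength pinned at zero; $p$, the number of
fitted parameters, follows the mode). Three numerical choices proved
essential:

* **multi-start**: initial guesses on the log-spaced grid
  $\{0, 10^{-3}, \dots, 10\}$ per free parameter (the objective can be
  multimodal near the boundary); `fit_patient_all_modes()` additionally
  seeds the joint fit with the restricted optima, which makes the
  nested-model inequality hold by construction;
* **an explicit finite-difference Jacobian** with steps
  $\max(10^{-3}|\rho|, 10^{-5})$: minpack's internal machine-epsilon
  steps are smaller than the ODE solver's noise floor and silently stall
  the optimiser at the few-percent-RMSE level;
* **finite penalty residuals** when the integrator breaks down in an
  extreme region probed by a line search, plus upper bounds
  ($10^8$ on $\rho_{s_{y0}}$, whose likelihood genuinely plateaus into
  astronomical values for some patients; $10^4$ on $\rho_{d_{y1}}$,
  beyond which the effect is observationally saturated).

Ordinary (unweighted) least squares is used deliberately; a weighted
variant is a known alternative that changes little here. A boundary
optimum $\rho_{s_{y0}} = 0$ is a result, not a failure: it is how series
that dip and then relapse are classified as showing no stem-cell-level
drug effect.

`approximate_ci()` quantifies uncertainty by the linearised-normal
approximation: covariance $\hat\sigma^2 (J^\top J)^{-1}$ with
$\hat\sigma^2 = \mathrm{SSE}/(m-p)$ and $J$ the finite-difference
residual Jacobian at the optimum. Parameter intervals are the 2.5/97.5
percentiles of 1000 sampled pairs (reported both raw and truncated at 0,
matching the non-negativity constraint); the VAF prediction band
re-simulates every sampled pair after resampling negative draws and takes
the pointwise middle 95%. A near-singular $J^\top J$ (flat likelihood
direction) is flagged and yields the enormous intervals that identify
practically unidentifiable patients. The band's mean width scales with
$\hat\sigma$, so it collapses as measurement noise goes to zero.

`cohort_summary()` aggregates fold changes
$\tilde s_{y0}/s_{y0}$ and $\tilde d_{y1}/d_{y1}$ with a per-parameter
outlier exclusion at fold > 100 (through the saturating cytokine term,
fold estimates beyond that are unidentifiable), and tabulates RMSE at the
conventional 0.02/0.04 cutoffs.

## The synthetic cohort generator

Real trial VAF series are not redistributable, so `generate_cohort()`
emulates their statistical structure, and every downstream claim is
validated against its ground truth. Per patient: 3–8 visits (first at
day 0, the rest uniform over a 0.5–4-year window with a 28-day minimum
gap — trial visits are weeks apart); baseline VAF from a normal with mean
0.76 and sd 0.12 truncated to (0.3, 0.98) (published cohort average 0.76;
the sd is our choice of a realistic spread for patients selected for
substantial responses); $\rho_{d_{y1}}$ log-normal
($e^{\log 0.13 \pm 0.6}$, truncated to [0.01, 1.1]) and $\rho_{s_{y0}}$
log-normal ($e^{\log 0.6 \pm 0.8}$, truncated to [0, 5]) with a 20% point
mass at exactly zero — supports and the zero fraction (5/24) match the
published per-patient estimates outside their named outliers; additive
homoscedastic Gaussian noise, default sd 0.02 VAF units (between the
0.012 and 0.035 reported for qPCR assays at different VAF levels),
clipped to [0, 1]. The default cohort is 24 patients, 18 at 35 mg/day
and 6 at 20 mg/day. A seed fixes the cohort exactly.

What the generator does *not* emulate — dose titration over time,
heteroscedastic assay error, dropout, multiple competing clones,
between-patient variation in the 26 disease constants — bounds what
passing tests show: they validate the estimation machinery under the
model's own assumptions, not the model's adequacy for real patients.

## Problem sizes and runtimes

The shipped analyses use: daily output for the 100-year reference
trajectory; weekly output for scenario runs (30 + 70 years); 200-year
horizons and ~14 log-bisection steps per basin threshold; a 24-patient
default cohort fitted in all three modes; a 20-patient recovery cohort;
1000-sample confidence procedures. The full test suite runs in a few
minutes on one core; `analysis/04_cohort_fits.R` is the heaviest script
at roughly three minutes.

## Known limitations

* The linearised CIs are approximate; their empirical coverage on
  synthetic replicates is checked to be roughly nominal, not exact.
* The anchor construction ties every patient to the single calibrated
  disease trajectory; patients whose pre-treatment course differed from
  the typical one inherit a biased state.
* Fold-change summaries depend on the outlier threshold; the saturating
  cytokine response makes very large $s_{y0}$ folds intrinsically
  unidentifiable.
* The mature-malignant excursion length in the stem-cell-only treatment
  scenario exceeds the published estimate (3.05 vs ≈2 years) for reasons
  traceable to rounded published constants; the companion VAF excursion
  (4.07 vs ≈4 years) and all other headline quantities reproduce.
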