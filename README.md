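# mpnrux

Mechanistic modelling of stem and progenitor cell dynamics in
JAK2 V617F-driven myeloproliferative neoplasms (MPN), and of how
ruxolitinib reshapes them.

MPNs are slowly progressing blood cancers in which a mutant haematopoietic
clone expands over decades, tracked in the clinic through the JAK2 variant
allele frequency (VAF). Ruxolitinib, a JAK1/2 inhibitor, lowers blood
counts and symptom burden, but whether it touches the disease-initiating
mutant *stem* cells — the difference between palliation and potential cure
— cannot be measured directly. This package is for modellers and
quantitative haematologists who want to interrogate that question with a
mechanistic model fitted to VAF time series.

## The model

Eight ODEs track healthy and mutant stem, progenitor and mature cells
($x_0, x_1, x_2$ / $y_0, y_1, y_2$) plus cellular debris $a$ and a lumped
cytokine signal $s$. Stem-cell divisions self-renew with probability
$p\,\varphi(x_0,y_0)\,\frac{s}{s_{1/2}+s}$ — down-regulated by niche
crowding $\varphi = 1/(1 + c\cdot x_0 + c'\cdot y_0)$ and up-regulated by
cytokine saturation — or differentiate, feeding the next compartment
through amplification factors; debris from dying cells drives cytokine
production, closing the inflammation feedback. Therapy enters through two
patient-specific response strengths, scaling dose-dependent increases of

* $\tilde s_{y0} = (1 + c_R\,\rho_{s_{y0}})\,s_{y0}$ — the mutant stem
  cells' cytokine half-saturation constant (a stem-cell level effect), and
* $\tilde d_{y1} = (1 + c_R\,\rho_{d_{y1}})\,d_{y1}$ — the mutant
  progenitor death rate (cytoreduction),

with $c_R$ the daily dose in mg/day. The model VAF is
$g(x_2,y_2) = y_2/(x_2+y_2)$ under an all-homozygous assumption.

The package provides: exact steady-state enumeration with local stability
(`find_steady_states()`), treatment scenario simulation and
excursion-return times (`run_scenario()`, `time_to_return()`),
basin-of-attraction thresholds of the cell-free state
(`basin_threshold()`), local sensitivity ranking (`local_sensitivity()`),
per-patient bounded nonlinear least-squares fitting of
$(\rho_{s_{y0}}, \rho_{d_{y1}})$ with sampling-based approximate 95%
confidence bands (`fit_patient()`, `approximate_ci()`), and a synthetic
patient-cohort generator with ground truth for validating the whole chain
(`generate_cohort()`). The numbered scripts under `analysis/` run the
study end to end and write their tables under `results/`.

## Worked example

```r
library(mpnrux)
params <- mpn_params()

ss <- find_steady_states(params)
subset(as.data.frame(ss), feasible,
       select = c(x0, x2, y0, y2, s, label, stability))
#>       x0       x2     y0       y2      s     label stability
#> 2      0 0.00e+00      0 0.00e+00 0.0278   trivial    stable
#> 3   3059 1.99e+10      0 0.00e+00 0.1867   healthy  unstable
#> 5 100245 6.51e+11      0 0.00e+00 0.9998   healthy  unstable
#> 6      0 0.00e+00    151 2.46e+09 0.0761 malignant  unstable
#> 8      0 0.00e+00 175109 2.85e+12 2.0777 malignant    stable
```

Five of the twelve equilibria are biologically feasible. Untreated, only
the cell-free state and the large malignant state are stable: from one
mutant stem cell the disease fixes unless treated. The VAF passes 50%
about 30 years after disease onset:

```r
traj <- simulate_mpn(disease_onset_state(), params, horizon_days = 30 * 365)
tail(traj$vaf, 1)
#> [1] 0.505
```

Fitting a synthetic patient (35 mg/day, five noisy VAF measurements over
1.9 years) recovers how strongly the drug acts on each cell level:

```r
set.seed(1)
pat <- generate_patient(cohort_spec(n_patients = 1, seed = 1), params,
                        "example", dose = 35)
fit <- fit_patient(pat$series, params, mode = "both")
fit <- approximate_ci(fit, params, n_samples = 1000, seed = 1)
print(fit)
#> Fit (both) patient example: rho_sy0 = 0.5814, rho_dy1 = 0.2475 (mg/day)^-1, RMSE = 0.01658
#>   s_y0: 1.524 (x21.3), d_y1: 0.03575 /day (x9.66)
#>   approx. 95% CI rho_sy0: (0.3971, 0.777), rho_dy1: (0.2206, 0.2746)
#>   mean 95% VAF band width: 0.0574
```

The fitted model says this patient's ruxolitinib response raises the
mutant stem-cell half-saturation constant 21-fold and the mutant
progenitor death rate 10-fold — a stem-cell level effect is needed, and
its confidence interval excludes zero; the typical misfit to the data is
1.7 VAF percentage points, and the 95% prediction band around the VAF
trajectory is about 6 points wide. Patients whose series dip and then
relapse instead come back with $\rho_{s_{y0}} = 0$: cytoreduction alone,
no stem-cell effect, no cure.

See `vignettes/mpn-ruxolitinib-model.Rmd` for the full account of the
model, the fitting machinery and the design decisions.

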