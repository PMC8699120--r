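# oxalipk

Population pharmacokinetics of intact oxaliplatin in rats with acute kidney
injury (AKI): study simulation, non-compartmental analysis, FOCE-ELS
nonlinear mixed-effects estimation, bootstrap/pcVPC qualification, and Monte
Carlo simulation of drug exposure as a function of plasma creatinine.

## What this package is for

Dosing oxaliplatin in patients with impaired kidneys is contentious because
the *intact* parent drug — as opposed to its rapidly formed biotransformation
products — is renally cleared but circulates only briefly. The reference
experiment behind this package measured intact oxaliplatin in plasma and
urine of rats with surgically induced mild or severe AKI (30 rats: 3 renal
groups × 2 IV bolus doses, 3 or 8 mg/kg, × 5 rats; plasma sampled at
3, 5, 10, 20, 30, 45 min, 1, 1.5 and 2 h; urine to 4 h in the 8 mg/kg arms)
and analyzed them with a population pharmacokinetic model. `oxalipk`
re-implements that full analysis chain as tested, reusable R functions, plus
a synthetic-study generator that reproduces the design and its stochastic
components, since the animal dataset itself is not publicly available.

The core model is the two-compartment IV-bolus disposition
`C(t) = A exp(-αt) + B exp(-βt)` parameterized by central and peripheral
volumes `V1`, `V2` (L/kg) and elimination and inter-compartmental clearances
`CL`, `CL2` (L/h/kg), with lognormal inter-individual variability on `V1`,
`CL`, `CL2` and proportional residual error:

    P_i = θ_P · exp(η_P),  η_P ~ N(0, ω_P²)
    y_ij = f(t_ij; P_i) · (1 + ε_ij),  ε ~ N(0, σ²)

Estimation is first-order conditional estimation with extended least squares
(FOCE-ELS, with interaction), written from scratch with a compiled inner
problem; empirical Bayes ("post hoc") estimates, CWRES goodness-of-fit
diagnostics, a stratified nonparametric bootstrap, a prediction-corrected
visual predictive check, and a creatinine→clearance regression driving the
renal-impairment exposure simulation complete the chain. The methods
vignette (`vignettes/oxalipk-methods.Rmd`) documents every model, numerical
choice and limitation.

## Worked example

```r
library(oxalipk)

# a synthetic 30-rat study at the reference design; truth = final estimates
study <- generate_study(seed = 1)

# population fit
fit <- fit_foce(study)
tidy(fit)
#> # A tibble: 10 × 5
#>    block     term       unit   estimate cv_percent
#>    <chr>     <chr>      <chr>     <dbl>      <dbl>
#>  1 theta     V1         L/kg      0.396       6.98
#>  2 theta     V2         L/kg      2.04       12.7
#>  3 theta     CL         L/h/kg    1.72        5.70
#>  4 theta     CL2        L/h/kg    0.989       6.83
#>  5 composite CLtot      L/h/kg    2.71       NA
#>  6 composite Vd         L/kg      2.44       NA
#>  7 omega     IIV_V1     %        36.1        14.4
#>  8 omega     IIV_CL     %        26.8        14.3
#>  9 omega     IIV_CL2    %        26.5        15.2
#> 10 sigma     sigma_prop %        14.4         5.53
glance(fit)
#> # A tibble: 1 × 5
#>   minus2LL n_subjects n_obs converged iterations
#>      <dbl>      <int> <int> <lgl>          <int>
#> 1    -54.2         30   270 TRUE              39
```

The fit recovers the generating truth (`V1` 0.44 L/kg, `CL` 1.76 L/h/kg,
IIV 37.5/30.5/31.5%, σ 14.9%) within sampling error of a 30-subject study;
`cv_percent` is the estimation uncertainty of each parameter. `augment(fit)`
returns the OBS/PRED/IPRED/CWRES table and `autoplot(fit)` the standard
goodness-of-fit panels; `pk_bootstrap(fit)` and `pk_pcvpc(fit)` qualify the
model.

Exposure across renal function, using the creatinine→clearance line anchored
at the reported exposure extremes:

```r
mc <- monte_carlo_exposure(pop_model_oxaliplatin(), anchor_regression(),
                           cr_levels = c(0.3, 0.5, 1.0, 1.5, 2.5),
                           dose = 8, n = 1000, seed = 1)
mc$auc
#> # A tibble: 5 × 5
#>      cr median    p5   p95     n
#>   <dbl>  <dbl> <dbl> <dbl> <dbl>
#> 1   0.3   3.44  2.03  5.80  1000
#> 2   0.5   3.69  2.28  6.07  1000
#> 3   1     4.63  2.86  7.79  1000
#> 4   1.5   6.34  3.98 10.1   1000
#> 5   2.5  21.7  13.1  34.6   1000
```

Median AUC0–∞ rises from ~3.4 µg·h/mL at normal creatinine (0.3 mg/dL) to
~22 µg·h/mL at 2.5 mg/dL — the roughly seven-fold exposure increase in
severe renal failure that motivates the dosing discussion, while mild
impairment (≤ 1.0 mg/dL) changes exposure only modestly.

The whole chain — generate → NCA → fit → bootstrap → pcVPC → regression →
simulate → report — runs as one reproducible pipeline with text artifacts
and a manifest:

```r
res <- run_pipeline(list(seed = 1), out_dir = "run1")
```

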