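# sedch4

Sediment methane formation kinetics in tropical reservoirs: from raw
anoxic-incubation headspace measurements to per-core decay models,
transition ages, lifetime-integrated CH4 budgets, and a global prediction
model.

## What it does, and for whom

Methanogenic microbes in anoxic reservoir sediment convert buried organic
carbon into CH4, a potent greenhouse gas. For biogeochemists running
long-term sediment incubations, `sedch4` implements the complete analysis
chain:

* **Gas mass balance** — headspace mixing ratios, vial pressures and
  volumes become dissolved-plus-gaseous CH4/CO2 amounts via the ideal gas
  law and Henry's law (CH4 solubility per the Wiesenburg–Guinasso Bunsen
  parameterization, CO2 per the Weiss K0), corrected for N2-addition
  dilution, and differenced into net formation rates per dry weight and
  per gram carbon.
* **Age–depth model** — every rate gets a sediment age,
  `age = (slice mid depth / total sediment depth) × reservoir age +
  incubation length`, with TC/TN interpolated linearly over the
  incubation.
* **Per-core decay kinetics** — bounded nonlinear least squares of
  `rate = a·exp(−b·age) + c`, and the *transition age*
  `t* = ln(a·b / tan 1°) / b`, where the fitted curve flattens to a 179°
  tangent and organic carbon can be considered effectively buried.
* **Lifetime integration** — analytic integration of the decay curve over
  100 years of yearly layer deposition, and the share of total CH4 formed
  in sediment older than the transition age.
* **Global model** — OLS of
  `ln(CH4) = β0 + β1·ln(Age) + β2·TN + β3·ln(Age)·TN`
  across all samples, with the lognormal back-transformation bias
  correction `exp(ln_mean + s²/2)` for predictions on the rate scale. The
  frozen reference coefficient set (−0.59, 6.46, −0.99, −3.12; s² = 0.28)
  ships as `default_global_model()`.
* **Synthetic study generator** — seeded emulation of the three-reservoir
  design (17 cores, 42 slices, 3 replicates, 7 occasions over 739 days,
  8.6 % replicate CV) that inverts the vial mass balance, so the whole
  pipeline is testable without field data.

## Worked example

```r
library(sedch4)
run <- run_ch4_pipeline(pipeline_config(seed = 1))
print(run)
#> Sediment CH4 formation pipeline run (seed 1 )
#> vial rows 882 | rate rows 1764 (excluded 132) | cores 17 (13 converged)
#>
#> Per-reservoir summary (mean +/- sd across cores):
#>   CDU: transition 21.8 +/- 27.8 y, depth 17 +/- 6 cm, beyond share 42 +/- 22 %
#>   CUN: transition 16.3 +/- 14.2 y, depth 16 +/- 16 cm, beyond share 42 +/- 39 %
#>   FUN: transition 12.7 +/- 6.6 y, depth 33 +/- 22 cm, beyond share 47 +/- 21 %
#>
#> Global model: intercept    ln_age        tn ln_age_tn
#>    -2.085    -0.858     1.121     0.783
#> s2 = 0.814  R2 = 0.478  n = 272
```

Reading this: 42 synthetic slices × 3 replicates × 7 occasions give 882
vials (1764 CH4+CO2 rates); 132 early measurements of deep low-activity
slices are flagged as possible oxygen carryover. Thirteen cores support a
converged decay fit; on average their CH4 formation flattens out after
~13–22 years (reaching that age at 16–33 cm depth), and over a 100-year
reservoir lifetime roughly 42–47 % of all CH4 still forms in sediment
older than that transition — old layers are not biologically dead. The
global-model block refits the ln(Age) × TN surface on this synthetic run
(its coefficients differ from the reference set because the generator's
truth is the per-core decay curves, not the global surface).

Bias-corrected predictions from the reference model:

```r
predict(default_global_model(), data.frame(age_years = c(2, 10, 40), tn = 0.3))
#>   ln_mean rate_naive rate_corr var_corr
#> 1 -1.7968     0.1658    0.1907   0.0118
#> 2 -3.2244     0.0398    0.0458   0.0007
#> 3 -4.4540     0.0116    0.0134   0.0001
```

A 2-year-old sediment layer with 0.3 % TN is predicted to form 0.19 µmol
CH4 g(dw)^-1 d^-1 (the naive back-transform 0.17 underestimates the
lognormal mean); by 40 years the corrected rate has fallen an order of
magnitude to 0.013.

User-supplied data run through the same chain:
`run_ch4_pipeline(config, slices = "slices.csv", vials = "vials.csv")`
(see `?generate_design` / `?generate_incubation` for the column dialects,
and `validate_inputs()` for schema checks).

## Vignette

`vignettes/sediment-ch4-kinetics.Rmd` documents the models and their
assumptions, the unit conventions, every tunable parameter with its
default and rationale, what the synthetic generator does and does not
emulate, and the package's numerical choices.
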