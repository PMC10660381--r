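# thermoramp

Does the *rate* of temperature change — not just temperature itself — shift
the aerobic metabolism of an aquatic ectotherm? thermoramp is an R package
for answering that question from closed-chamber respirometry. It targets
experiments in which small aquatic animals (the motivating system is a
brackish-water shrimp of 0.05–0.3 g in 200-ml chambers) are measured at
stable temperatures and under continuous heating or cooling ramps, and it
ships a forward simulator of the whole design so that every stage can be
verified against known ground truth.

## The method

For each sealed chamber the probe records dissolved oxygen (DO, mg l⁻¹)
over time. The pipeline:

1. corrects each animal trace with its paired blank chamber's OLS slope
   (bacterial background respiration) and truncates at the 3 mg O₂ l⁻¹
   hypoxia threshold;
2. estimates mass-scaled metabolic rate from stable trials,
   *MO₂ = −m · V_eff / mass⁰·⁸* (m = DO slope, V_eff = chamber volume −
   animal mass), in mg O₂ min⁻¹ kg⁻⁰·⁸;
3. fits the piecewise-Q₁₀ ("Rezende") thermal performance curve

   *pf(T) = C·Q₁₀^(T/10)* for *T ≤ T_th*, multiplied by
   *1 − d(T − T_th)²* above the threshold,

   by multistart bounded Levenberg–Marquardt, comparing candidate models
   with the small-sample AICc;
4. predicts each ramping trial's total consumption as
   *∫ pf(T) dT / λ × mass⁰·⁸* between its start and end temperatures
   (λ = signed ramp rate, °C min⁻¹) and computes log residuals against
   observed totals (first-five minus last-five DO means × V_eff);
5. fits a Bayesian piecewise regression of residuals on λ with the
   breakpoint forced at λ = 0 — a shared intercept with separate heating
   and cooling slopes — using an in-package Gibbs-within-slice MCMC
   sampler, reporting posterior means, credible intervals, tail
   probabilities P(b_heat > 0), P(b_cool < 0) and convergence diagnostics.

Positive slopes on the heating arm mean faster heating costs more oxygen
than static-temperature physiology predicts.

## Worked example

```r
library(thermoramp)

run <- run_full_analysis(list(
  simulate = TRUE, seed = 7, stable_reps = 8L, ramp_reps = 4L,
  sim = list(rate_effect_heat = 7.71, rate_effect_cool = -2.73)))
print(run)
#> <thermoramp_run>
#>          stage heating cooling stable
#> 1     measured      32      32     40
#> 2     analysed      32      32     40
#> 3 budgets_used      32      32     NA
#> <tpc_fit> model 'rezende': n = 40, k = 5, RSS = 1.195, AICc = -128.663
#>      ce     q10    t_th       d
#>  0.2324  3.2490 18.0103  0.0509
#> <breakpoint_posterior> 32 heating + 32 cooling residuals, 4000 draws
#>   parameter    mean     sd    q2.5   q97.5 rhat  ess
#> 1         a -0.1344 0.0372 -0.2089 -0.0624    1 3552
#> 2    b_heat  8.0995 0.4756  7.1513  9.0250    1 3683
#> 3    b_cool -2.8212 0.4743 -3.7577 -1.9076    1 3663
#> 4     sigma  0.1996 0.0187  0.1672  0.2403    1 3416
#> P(b_heat > 0) = 1.000   P(b_cool < 0) = 1.000   converged: TRUE
```

Here 104 trials were simulated from a known thermal performance curve
(Q₁₀ = 3.03, C = 0.26, T_th = 17.93, d = 0.05) with multiplicative
ramp-rate effects of 7.71 (heating) and −2.73 (cooling) injected on the
log scale. The pipeline recovers the curve (q10 ≈ 3.25, t_th ≈ 18.0,
d ≈ 0.05), detects both rate effects with the correct sign and approximate
size (b_heat ≈ 8.1, b_cool ≈ −2.8), and the negative intercept reflects the
two known small-sample artefacts of the observed-consumption estimator
(its first/last-five window and hypoxia-truncated slow trials), both
quantified in the methods vignette.

`vignettes/thermoramp-methods.Rmd` documents the models, priors, simulator
assumptions, numerical choices and limitations. A thin command-line
wrapper lives at `inst/scripts/thermoramp-cli.R` (`simulate` and `run-all`
subcommands).

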