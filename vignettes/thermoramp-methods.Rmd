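---
title: "Metabolic rates under temperature ramps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic rates under temperature ramps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

thermoramp processes closed-chamber respirometry of small aquatic
ectotherms — the motivating system is a hypoxia-tolerant brackish-water
shrimp of 0.05–0.3 g wet mass in 200-ml chambers — measured both at stable
temperatures and under continuous heating or cooling. The question the
pipeline answers is whether the *rate* of temperature change (the signed
ramp rate $\lambda$, in °C min⁻¹) systematically shifts aerobic metabolism
relative to what static-temperature physiology predicts.

## The pipeline

1. **Preprocessing.** Each animal chamber is paired with a blank chamber of
   the same water. An OLS line through the blank's dissolved-oxygen (DO)
   trace estimates the bacterial background slope, which is subtracted,
   sample by sample, from the animal trace
   (`DO_corr(t) = DO_raw(t) - slope * (t - t0)`). Traces are then truncated
   at the 3 mg O₂ l⁻¹ hypoxia threshold: the species tolerates hypoxia by
   switching toward anaerobic pathways, so aerobic estimates below that
   concentration are unreliable. A sample exactly at the threshold is kept;
   the first sample strictly below it ends the usable trace.
2. **MO₂ estimation (stable trials).** The DO slope $m$ of the whole
   corrected trace, converted by effective volume and allometric mass
   scaling: $MO_2 = -m\,V_{eff}/mass^{0.8}$, in mg O₂ min⁻¹ kg⁻⁰·⁸.
   $V_{eff}$ is chamber volume minus animal mass (neutral buoyancy, density
   1). The exponent 0.8 is the conventional crustacean allometry and is a
   configurable parameter.
3. **Thermal performance curve.** Mass-scaled MO₂ versus mean trial
   temperature is fitted with the piecewise-Q₁₀ ("Rezende") model
   $$pf(T) = C\,Q_{10}^{T/10} \times
     \begin{cases} 1 & T \le T_{th} \\ 1 - d\,(T-T_{th})^2 & T > T_{th},
     \end{cases}$$
   by multistart bounded Levenberg–Marquardt least squares. Candidate
   models are pluggable records (name, rate function, bounds) compared by
   the Gaussian small-sample AICc,
   $n\ln(RSS/n) + 2k + 2k(k+1)/(n-k-1)$, with $k$ counting shape
   parameters plus the residual variance (so $k=5$ for the piecewise-Q₁₀
   model).
4. **Ramp prediction.** For a trial ramping from $T_1$ to $T_2$ at rate
   $\lambda$, predicted total consumption is
   $\int_{T_1}^{T_2} pf(T)\,dT \,/\, \lambda \times mass^{0.8}$ (mg O₂).
   The integral is adaptive quadrature split at $T_{th}$, where the
   integrand has a kink. Because $\lambda$ is stored signed, the same
   formula is positive for heating and cooling. Observed consumption is the
   first-five minus last-five DO sample means times $V_{eff}$.
5. **Breakpoint regression.** Log residuals
   $y = \log(\mathrm{obs}) - \log(\mathrm{pred})$ are regressed on
   $\lambda$ with a piecewise-linear model forced through a breakpoint at
   $\lambda = 0$: shared intercept $a$, separate slopes $b_{heat}$
   ($\lambda>0$) and $b_{cool}$ ($\lambda<0$), Gaussian errors. Stable
   trials contribute overlay points at $\lambda = 0$
   (their residual reduces to $\log(MO_2/pf(T))$, duration cancelling) but
   are never part of the fit.

## The Bayesian sampler

Priors are weakly informative: Normal(0, 100) on the three coefficients and
Half-Normal(10) on $\sigma$ — several orders of magnitude wider than the
data scale (residuals are $O(0.1$–$1)$ log units). The posterior is sampled
with four seeded chains of 2000 iterations (1000 warmup): the coefficient
block is conditionally Gaussian and Gibbs-updated in closed form; $\log
\sigma$ is updated by a stepping-out slice sampler. Convergence is gated at
split-$\hat R \le 1.01$ and effective sample size $\ge 400$ per parameter
(Geyer initial-monotone estimator); failing diagnostics flag the result
with a warning rather than returning silently. Tail probabilities
$P(b_{heat}>0)$ and $P(b_{cool}<0)$ are fractions of post-warmup draws. The
tests cross-check the sampler against the piecewise OLS closed form under
flat priors and against an independent JAGS fit of the identical model.

Continuity at the breakpoint (a single shared intercept) is an assumption:
the construction "forced through $\lambda = 0$" does not by itself require
it, but it is the standard piecewise-regression choice and reflects that a
vanishing ramp rate should reproduce stable-temperature behaviour.

## What the simulator emulates

`simulate_experiment()` reproduces the full design: stable trials at 10,
12, 15, 18, 21 °C; ramp regimes 15→21, 10→21, 15→10, 21→10 °C, each at
0.5, 1, 5 and 10 °C hr⁻¹; probe sampling of 0.2, 0.5, 1 and 1 samples
min⁻¹ at those rates (1 min⁻¹ for stable trials); 200-ml chambers; wet
masses uniform on 0.048–0.295 g; one paired blank per trial. A chamber's
DO evolves as
$$\frac{dDO}{dt} = -pf(T(t))\; s_i\; e^{\eta\lambda}\;
  \frac{mass^{0.8}}{V_{eff}} + b,$$
integrated with fixed 0.1-min trapezoid steps (cheap, and the error is
quantified against the quadrature oracle in the tests), then subsampled at
the probe rate and perturbed by Gaussian observation noise.

Defaults, chosen once as field-plausible values where the study reports
none:

* `noise_sd = 0.02` mg l⁻¹ — optical DO probe repeatability.
* `blank_slope = -5e-4` mg l⁻¹ min⁻¹ — bacterial drift of roughly 0.7
  mg l⁻¹ per day.
* `individual_sd = 0.15` — lognormal between-animal scaling $s_i$;
  between-individual variation of resting metabolism in crustaceans is
  commonly 20–40 % CV, and it, not probe noise, dominates the residual
  scatter of real budgets.
* Starting DO defaults to air saturation at the trial's starting
  temperature (Benson–Krause fit, ≈11.3 mg l⁻¹ at 10 °C, ≈8.9 at 21 °C),
  emulating chambers sealed with freshly aerated acclimation-tank water.
  This matters: with a flat, lower starting DO, most slow full-span ramps
  would deplete the chamber to the hypoxia threshold, while under
  saturation starts only a handful do — matching the small number of
  hypoxia-ended trials in real data of this kind.
* The ramp-rate effect is multiplicative, $e^{\eta\lambda}$, so the log
  residual is linear in $\lambda$ with slope $\eta$ — exactly the quantity
  the breakpoint regression estimates; $\eta_h = \eta_c = 0$ (no effect) by
  default.
* Stable trials run 90 min (the 1–2 h protocol window).

### What passing the synthetic checks does and does not show

The simulator shares the pipeline's structural assumptions (the TPC family,
multiplicative rate effects, Gaussian noise). Recovery of injected
parameters therefore verifies the *implementation* — estimator algebra,
integration, sampler correctness — not the biological adequacy of those
assumptions for any real dataset. It also omits handling stress, settling
behaviour, diel rhythms, probe drift and body–water thermal lag.

## Numerical choices and known limitations

* **First/last-five window bias.** The observed-consumption estimator
  averages the first and last five samples, so it measures the drop between
  the two window midpoints, not the full trace span. For slow ramps the
  shortfall is negligible (≈1.5 %), but for the fastest, shortest trials it
  reaches ≈10 % of the total, giving slightly negative residuals whose size
  varies with $|\lambda|$. The tests account for this by comparing observed
  consumption against the integral over the window the estimator actually
  spans; end-to-end slope recovery consequently carries a small, quantified
  artefact (larger on the cooling arm, whose fast trials are shortest).
* **Hypoxia truncation of budgets.** A trial ended at the threshold
  consumed less than the full-ramp prediction; its residual is genuinely
  negative. This is a property of the design, not an error, and it
  predominantly affects the slowest full-span ramps.
* **(T_th, d) ridge.** With stable trials at five temperatures and only one
  clearly above threshold, the decay pair is constrained mainly through its
  combined value at 21 °C, so near-equal-RSS solutions form a ridge (e.g.
  $T_{th}=18, d\approx0.05$ versus $T_{th}=20.4, d=1$). `fit_tpc()`
  resolves exact ties deterministically by minimum parameter norm, which
  prefers the interior, least-decay solution; the threshold location should
  still be read as weakly identified at this design size.
* **Multistart initialisation.** Random starts within the box bounds are
  first polished by solving the conditionally linear parameters
  ($C$ and $C\,d$ given $Q_{10}, T_{th}$) by OLS, then screened by starting
  RSS, and the best ten refined by bounded Levenberg–Marquardt. Without the
  profiling step roughly one start-set in twelve converged to a wrong basin
  at realistic noise; with it, 100/100 seeded datasets recover $Q_{10}$
  within ±20 %.
* **Boundary conventions.** Hypoxia truncation keeps a sample exactly at
  the threshold (reaching the threshold ends the trial, so the reaching
  sample is the last usable one). Auto-exclusion of ramping trials uses
  observed consumption ≤ 0 (log undefined) rather than a magnitude
  heuristic. The background correction applies the blank *slope × elapsed
  time* per sample, the dimensionally consistent reading of
  slope-subtraction. Observed consumption multiplies the concentration drop
  by $V_{eff}$ (mg l⁻¹ × l = mg); an alternative divide-by-volume
  convention is retained behind `mode = "divide"` purely for audit.
* **Problem sizes.** The bundled checks run the full pipeline at the
  analysed-study scale (38 stable + 64 heating + 53 cooling trials), the
  TPC recovery study over 100 seeded datasets of 38 points, and breakpoint
  recovery on 100 budgets with 4 × 2000 MCMC iterations — sizes at which
  every stage's uncertainty is small relative to the tolerances asserted.

## Worked example

```{r, eval = FALSE}
library(thermoramp)

run <- run_full_analysis(list(
  simulate = TRUE, seed = 7,
  stable_reps = 8L, ramp_reps = 4L,
  sim = list(rate_effect_heat = 7.71, rate_effect_cool = -2.73)))

run$tpc_fit        # fitted thermal performance curve + AICc
run$posterior      # breakpoint slopes, tail probabilities, diagnostics
head(run$budgets)  # per-trial observed/predicted totals and residuals
```
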