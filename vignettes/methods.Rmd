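---
title: "Modelling an SSB levy's CHD impact under changing sugar trade regimes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling an SSB levy's CHD impact under changing sugar trade regimes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssbimpact)
```

## The model

`ssbimpact` estimates how a two-rate industry levy on sugar-sweetened
beverages (SSB), possibly combined with a trade-regime change that
alters the wholesale price of sugar, affects coronary heart disease
(CHD) mortality in a single target year. It is a comparative risk
assessment of the IMPACT family: a deterministic chain from prices to
intake to attributable mortality, evaluated on 70 strata (seven 10-year
age groups from 25–34 to 85+, two sexes, five deprivation quintiles)
and wrapped in a Monte Carlo probabilistic sensitivity analysis (PSA).

The chain, per scenario:

1. **Trade regime → sugar price.** The change in the wholesale sugar
   price is `import_share × Σ_k w_k (Δtariff_k + facilitation_k)`,
   summed over import segments (EU, third-country preferential,
   third-country non-preferential) and converted to £/t through the
   exchange rate when inputs are €-denominated. Only the imported share
   of supply is assumed to re-price; a domestic price response is not
   modelled, which makes the trade effect conservative.
2. **Levy and sugar cost → production cost.** The banded levy pools to
   a sales-weighted single rate; a sugar price change Δp (£/t) adds
   `Δp × sugar_content(g/l) × 10⁻⁶` £/l. Costs are carried unrounded:
   the soft- and hard-scenario sugar increments are 0.008556 and
   0.018879 £/l, which display as 1 and 2 p/l but must not be rounded
   before use — relative scenario effects of a few percent would
   otherwise be distorted (0.02/0.23 would overstate the hard-scenario
   increment by roughly half a percentage point).
3. **Pass-through → consumer price.** A fraction of the cost change
   (80, 100 or 120 % in the standard settings; anything in (0, 10) is
   accepted) is passed to the mean consumer price of 0.61 £/l.
4. **Price → intake.** The demand response is linear in the relative
   price change: 6.7 % intake reduction per 10 % price rise, scaled by
   a socio-economic multiplier and capped at −100 %. Linearity is an
   extrapolation when applied to ~38 % price changes; it is the
   functional form this class of model uses, and the cap guards the
   tail.
5. **Intake → mortality.** Per stratum, the reduction in servings/day
   (serving size 250 g by default) enters a two-pathway potential
   impact fraction with per-serving log-linear relative risks:
   `PIF = (1 − RR_adj^(−Δserv)) + (1 − RR_med^(−Δserv)) × p_ow`,
   where `RR_adj` is the BMI-adjusted (direct) risk, `RR_med` the
   BMI-mediated risk and `p_ow` the stratum's overweight prevalence —
   the mediated pathway can only operate in the overweight fraction.
   SSB intake is assumed not to change case fatality, so the incidence
   PIF applies directly to deaths. Deaths prevented or postponed (DPP)
   are `deaths × PIF`; life-years gained (LYG) multiply DPP by the
   median survival a prevented death would have enjoyed, mixed over
   diagnosed-CHD / undiagnosed-CHD / no-CHD decedent groups.

The model is a single-year snapshot: effects are assumed constant over
time, with no lag from intake change to risk change and no multi-year
accumulation.

## Parameters that matter

| Parameter | Default | Units | Why this value |
|---|---|---|---|
| levy band rates | 0.18 / 0.24 | £/l | the implemented two-rate levy (5–8 g and >8 g sugar/100 ml) |
| band sales shares | 1/6, 5/6 | — | reproduce the 0.23 £/l sales-weighted pooled rate; editable because the underlying sales split is proprietary |
| sugar content | 93 | g/l | market-average added sugar of SSB |
| baseline SSB price | 0.61 | £/l | survey-based mean consumer price |
| pass-through | 0.8 / 1.0 / 1.2 | — | the range observed after comparable taxes |
| base price effect | 6.7 | % per 10 % price | meta-analytic demand response |
| responsiveness ratio | 1.65 | — | most-deprived vs most-affluent price responsiveness |
| serving size | 250 | g | a common single-serving definition in the pooled RR literature; configurable |
| RR per serving | 1.20→1.08 (adj), 1.10→1.04 (med) by age | — | package calibration in the range of pooled cohort analyses, declining with age; *not* asserted as any study's values |

### Trade scenario calibration

The packaged "soft" and "hard" scenarios fix the published trade
shares (imports are 64 % of sugar supply; 53 % of imports from the EU;
94 % of third-country imports preferential) and are calibrated to the
published end-points of 92 and 203 £/t: a WTO tariff of 400 €/t applied
to the segments that lose preferential access (third-country
preferential under "soft"; EU and third-country preferential under
"hard"), facilitation costs of 2.9675 and 7.764375 €/t on all imports,
at 0.80 £/€. The segment-level tariff schedule behind the published
totals is not public, so these are one admissible decomposition, kept
fully editable in the config. We denominate the defaults in euros with
an explicit exchange rate — rather than pre-converting to pounds —
because the exchange rate is one of the PSA inputs and would otherwise
be inert.

### SEC multipliers

The three deprivation groups (quintiles 1+2, 3, 4+5) carry price-effect
multipliers with two constraints: the high/low ratio is 1.65, and the
population-intake-weighted mean multiplier is exactly 1, so the
population-average response equals the 6.7 % base effect. The middle
group sits at the arithmetic midpoint. Because the weights depend on
the baseline, `price_effect()` defaults to calibrating the multipliers
against whatever baseline the scenario is run on
(`calibrate_sec_multipliers()`); where no baseline is in scope the
equal-weight solution (0.7547, 1, 1.2453) is used. The overall intake
reduction is reported intake-weighted (whether the published overall
figure was intake- or population-weighted is not stated; intake
weighting is the natural choice given the mean-response calibration).

## The synthetic baseline

No stratum-level inputs are redistributable, so `synthesize_baseline()`
generates baselines with the structure the analysis assumes:

* intake follows a log-linear gradient — ratio 0.82 per 10-year age
  step, men 1.3× women, +8 % per deprivation quintile — with 2 %
  multiplicative lognormal noise, rescaled so the population-weighted
  mean is exactly 99.5 g/day;
* projected CHD deaths total exactly 38 000, distributed over age/sex
  with the steep old-age concentration characteristic of CHD and a
  within-cell deprivation gradient making quintile-5 mortality twice
  quintile-1;
* overweight prevalence rises with age and deprivation within
  [0.3, 0.8]; median survival declines with age from 42 to 4 years
  (no-CHD group), with diagnosed/undiagnosed CHD at 55 %/75 % of that.

Monotone gradients are asserted programmatically on every generated
table. The generator emulates aggregate structure only: it does not
reproduce survey weighting, diary measurement error, or any published
stratum-level value, so passing tests demonstrate correct model
mechanics and calibrated aggregates, not agreement with real stratum
data. Absolute DPP/LYG levels (≈ 330 DPP, ≈ 2 900 LYG for the levy at
full pass-through) therefore depend on this package's calibration;
relative effects — Brexit increments of ≈ 4 % and ≈ 8 %, pass-through
scaling of ≈ ±20 % — are nearly baseline-independent because the PIF is
almost linear at these effect sizes, and those are the quantities the
test suite pins down.

## Uncertainty analysis

Nine inputs are uncertain by default: import share (beta), exchange
rate, SSB price and base price effect (truncated normals), stratum
intake and mortality (truncated-normal multipliers, per stratum),
relative risks (lognormal multipliers, shared across age so RR
uncertainty is fully correlated within each pathway), overweight
prevalence (normal multiplier, clamped to [0,1]) and survival (gamma
multiplier). Families are conventional choices for each quantity type
and editable in the config. Draws use inverse-CDF truncation, so
domain constraints hold exactly. Each parameter has its own RNG stream
keyed on (master seed, parameter name): reordering or adding
parameters never perturbs another parameter's draws, and results are
bit-reproducible given the seed. Uncertainty intervals are empirical
2.5th/97.5th percentiles with linear interpolation (`quantile`
type 7) over the iterations; 10 000 iterations is the production
setting, and the test suite verifies 1.96 σ convergence of the
interval half-width at that count for a linear normal input. A note on
magnitudes: because the log relative risks are small (ln 1.1 ≈ 0.095),
even a ±10 % lognormal multiplier on the RR scale moves the *effect*
scale by ~50 %, so RR uncertainty dominates the interval width under
the defaults.

## Numerical choices and degenerate inputs

* Fractional deaths are kept throughout; rounding (pence half-up,
  integer percent, tens of deaths/life-years) happens only in display
  surfaces.
* The PIF is clamped to [0, 1): a stratum can never lose more deaths
  than it has; intake reductions are capped at −100 %.
* Zero intake, null risks (RR = 1), empty levy and the "none" trade
  scenario all collapse to exactly zero impact (tested).
* Strata are validated on entry — exhaustive 70-stratum coverage,
  proportions summing to 1 within 1e-9, positive survivals — so engine
  code never defends against partial tables.
* `run_scenario` agrees with an independent scalar per-stratum loop to
  1e-9 on randomized baselines (oracle test), and the PIF matches its
  closed-form small-effect limit `ln RR_adj + p_ow ln RR_med`.

## Problem sizes

The test suite runs the full 70-stratum engine throughout; PSA tests
use 300–400 iterations for distributional properties and a single
10 000-iteration run for the percentile-convergence check, which is
also the iteration count configured in the shipped example config.

## Known limitations

* Stroke, diabetes and obesity endpoints are out of scope; the CHD-only
  estimate is conservative by design.
* No substitution toward other beverages beyond what the meta-analytic
  price effect already internalises; no demand-system estimation.
* No industry reformulation response, no retailer-level pass-through
  heterogeneity, no fiscal revenue accounting.
* Single-year snapshot; no time-to-benefit lag or cumulative
  projection.
* The trade model re-prices only the imported share of supply and
  ignores domestic production shifts and sweetener substitution.
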