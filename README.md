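# forestflux

Live-biomass carbon dynamics of long-term tropical forest inventory plots
under short-term climate anomalies.

Networks of permanent forest plots are the only ground-based instrument we
have for asking whether an extreme event — an El Niño year with record heat
and drought — dented the tropical live-biomass carbon sink. Answering that
question from stem censuses takes a long chain of small models: field-error
screening of diameter trajectories, allometric conversion of diameters to
carbon, correction of demographic fluxes for events hidden between
censuses, reconstruction of a continuous plot-level climate record from
partially overlapping gridded datasets, and finally attribution of the
flux changes to climate anomalies. `forestflux` implements that chain as a
tested, reusable pipeline, together with a synthetic-data generator that
emulates a clustered 100-plot African-style network with known ground
truth, so every stage can be validated end to end without any restricted
field data.

## The models at the core

**Carbon accounting.** Each stem of diameter `D` (cm) gets a modelled
height from a three-parameter Weibull curve `H = a(1 − exp(−b D^c))`
fitted to regional height–diameter calibration data, a wood density `ρ`
(g cm⁻³) by species → genus → family → plot-mean fallback, and a dry mass

    AGB = 0.0673 (ρ D² H)^0.976   [kg],   carbon = 0.456 × AGB.

**Census-interval correction.** Gains (AGWP: survivor growth plus
recruitment) and losses (mortality) are increasingly underestimated as the
census interval `T` grows, because stems recruit and die, or grow and die,
unseen. Under constant instantaneous rates per interval —
`m = ln(N₀/S)/T`, `r = ln(N_T/S)/T` — the package adds back the expected
unobserved recruitment, unobserved deaths of those recruits, and the
growth of dying stems up to their truncated-exponential expected death
time. Corrected and observed fluxes carry identical net change; the
correction is validated against a continuous-time birth–death–growth
simulator.

**Drought metric.** The maximum cumulative water deficit (MCWD) runs the
recursion `WDₙ = min(0, WDₙ₋₁ − ETₙ + Pₙ)` through each May→April climate
year with a fixed evapotranspiration of 100 mm mo⁻¹ (a pluggable
provider), after the monthly precipitation and temperature records have
been harmonized across two source datasets (per-calendar-month OLS over
their overlap) and downscaled to the plot (climatology differences for
temperature plus a 0.005 °C m⁻¹ lapse-rate altitude adjustment; climatology
ratios for precipitation).

**Attribution.** Plot-level deltas (event interval minus time-weighted
pre-event mean) are regressed on standardized climate anomalies with
empirically derived sampling-effort weights; all admissible combinations
of main effects and interactions are fitted, ranked by AIC, restricted to
the 95% confidence set, and model-averaged with shrinkage. Confidence
intervals for averaged coefficients use the model-averaged tail-area
construction.

## Worked example

```r
library(forestflux)
study <- run_enso_study(sim_config(seed = 42), responses = "d_net")
print(study)
#> Synthetic El Nino study: 100 plots, metric = carbon, corrected fluxes
#>   pre net  0.144 -> event net -0.300 (per ha per y)
#>   mean anomalies: d_tas +0.34 degC, d_mcwd +89 mm
#>   d_net ~ d_mcwd: -0.3277 [-0.7641, +0.0000] (standardized)

build_report(study)$fluxes[, c(1:2, 4, 6, 8)]
#>           variable pre_mean during_mean pct_change signif
#> 1       net_carbon    0.144       -0.30   -308.071      *
#> 2     carbon_gains    2.160        1.83    -15.292    ***
#> 3    carbon_losses    2.016        2.13      5.635
#> 4        net_stems    1.376        1.14    -16.773
#> 5 stem_recruitment    6.391        6.35     -0.588
#> 6   stem_mortality    5.015        5.21      3.851

print(study$attribution$d_net)
#> Multimodel-averaged attribution for d_net (n = 100 plots)
#>   34 candidate models; 26 in the 95% confidence set; best-model R2 = 0.106
#>   d_tas                    +0.0291  [-0.2389, +0.3968]  (Akaike weight 0.40)
#>   d_mcwd                   -0.3277  [-0.7641, +0.0000]  (Akaike weight 0.82)
#>   ...
```

Reading the output: the synthetic network was generated with a true
drought effect of −0.003 Mg C ha⁻¹ y⁻¹ per mm of deficit intensification
and no temperature effect. The event interval carried a mean +0.34 °C
temperature anomaly and an 89 mm deeper water deficit; plot carbon gains
fell while losses barely moved; and the standardized model-averaged
coefficients attribute the net-carbon change to the drought anomaly
(negative, largest magnitude) rather than to temperature (shrunk toward
zero), which is the qualitative fingerprint the pipeline is designed to
detect. On the raw scale the averaged drought coefficient for this seed is
−0.0056 Mg C ha⁻¹ y⁻¹ per mm (single-network estimates are noisy; the test
suite checks calibration over 100 replicate networks).

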