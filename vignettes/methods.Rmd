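---
title: "Models and methods behind forestflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind forestflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestflux)
```

`forestflux` estimates how the live-biomass carbon balance of a network of
long-term forest inventory plots responded to a short, extreme climate
anomaly — the situation created by an El Niño year inside a multi-year
census interval. This vignette documents the models each stage assumes,
the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
made where more than one defensible option existed.

## 1. Stem-census quality control

Diameter trajectories are screened per interval: an annualized increment
above 40 mm y⁻¹ or a total shrinkage above 5 mm marks the interval as
suspect. The two rules deliberately carry different units (a rate for
growth, a total for shrinkage), and both are strict inequalities —
boundary values pass. When an interval satisfies both rules (possible with
gross data-entry errors) the growth rule is recorded first, purely for
deterministic output.

A flag indicts a *measurement*, not an interval: a measurement that closes
one flagged interval and opens another is a spike and is the sole suspect;
an isolated flagged interval indicts its closing measurement. Suspects are
replaced by linear interpolation in time between the nearest accepted
neighbours, or linear extrapolation from the two nearest accepted
measurements at series ends. Linearity on the diameter scale is the
simplest scheme consistent with interpolation/extrapolation from the same
stem; anything more structured would inject growth-model assumptions into
a data-cleaning step. Stems left with a single accepted measurement get
the plot-population growth rate of their size class: the *mean* rate for
the 100–199 and 200–399 mm classes, the *median* for 400+ mm where few
stems make means unstable.

Point-of-measurement (POM) changes are resolved before the screens are
applied (the screens would otherwise fire on the geometry change, not on
measurement error; the order is switchable by calling the functions
directly). Growth across a POM change is represented by a single common
annualized rate — the mean of the pre- and post-change segment rates, or
the one available rate when a segment is degenerate — and the pre-change
censuses are re-expressed on the new-POM scale by back-projection from the
first post-change measurement, so stock differences never register a
spurious step.

A stem is a recruit in the first interval at whose closing census its
diameter reaches 100 mm; stems already at the threshold at the first
census are initial population. Recruits that die before ever being
censused are invisible here by construction and are restored statistically
by the census-interval correction.

## 2. Allometry

Carbon per stem is `0.456 × 0.0673 (ρ D² H)^0.976` with `ρ` in g cm⁻³,
`D` in cm, `H` in m and AGB in kg; 0.456 is the mean carbon fraction of
dry mass for tropical angiosperms. Heights are always modelled, never
measured, in the carbon equation — measured heights only calibrate the
regional three-parameter Weibull curve `H = a(1 − exp(−b D^c))`, fitted by
Levenberg–Marquardt nonlinear least squares (`minpack.lm::nlsLM`) with
start values from a linearization; non-convergence is an error, never a
silent fallback. Wood density falls back species → genus → family → the
unweighted mean over the plot's taxonomically matched stems; the
unweighted (per-stem, not basal-area-weighted) plot mean is a choice — the
fallback describes "a typical individual", not "typical biomass". Palm
stems are a pluggable hook whose default applies the dicot equation with a
warning, since no palm equation is part of the package's scope.

## 3. Demography and the census-interval correction

Observed per-interval fluxes value survivor growth and recruitment at the
closing census and deaths at the opening census; `net = gains − losses`
holds exactly and equals the rate of change of the live stock, for carbon,
basal area and stem counts alike.

The correction assumes constant instantaneous rates inside each interval:
per-capita mortality `m = ln(N₀/S)/T` and recruitment `r = ln(N_T/S)/T`.
With recruitment influx proportional to population size the total recruit
count is `r N₀ T · (e^{(r−m)T} − 1)/((r−m)T)`; the excess over observed
recruits died inside the interval and is added to both recruitment and
mortality. Dying stems of the initial cohort are assigned growth at the
survivor rate up to the truncated-exponential expected death time
`1/m − T e^{−mT}/(1 − e^{−mT})`; that growth is added to gains *and* to
losses (it was produced, and it died). Unobserved recruits are valued at
the mean observed recruit value minus `g T/6`: an observed recruit's
census value embeds on average `T/2` of post-recruitment growth, while a
recruit that died produced only about `T/3` — the difference nets to
`−T/6`. All corrections vanish as `T → 0` or `m → 0`, never push a flux
below its observed value, and leave net fluxes untouched. The estimators
are isolated in one function so an alternative variant can be swapped in;
their validation oracle is a continuous-time birth–death–growth simulator
in the test suite (500 replicates per census length at `T` = 1, 5 and
10 y), not any external implementation. Degenerate intervals (no
survivors) keep their observed values and are flagged.

Pre-event summaries are time-weighted by interval length; the event
interval is the whole final interval containing the event window. The
census cutoff (default 2000) and all rates are configuration, not
constants.

## 4. Climate reconstruction

Two monthly datasets per variable — a *reference* covering recent decades
and an *auxiliary* reaching further back — are harmonized per calendar
month: OLS of reference on auxiliary over their overlap, the fit applied
only to auxiliary months before the reference span, provenance tracked
per month. At least two overlap years per month are required; adjusted
precipitation is floored at zero.

Downscaling to a plot uses a static monthly climatology: temperature by
difference (`T_plot = T − (T_μ − T_clim)`) plus a lapse-rate altitude
term `0.005 °C m⁻¹ × (A_cell − A_plot)`; precipitation by ratio
(`P_plot = P × P_μ/P_clim`), with the 0/0 month defined as ratio 1 (dry
season in a desert cell) and a zero climatology against nonzero baseline
rain an error. The baseline epoch for `T_μ`/`P_μ` defaults to 1970–2000 to
match the climatology's epoch, and both shifts preserve anomalies by
construction.

MCWD runs `WDₙ = min(0, WDₙ₋₁ − ETₙ + Pₙ)` within each climate-year,
resetting at the year boundary; the annual value is the most negative WD.
Climate-years run May→April by default — the event year is defined as the
12 months with the peak land-surface anomalies — and the start month is
configurable, as is carrying the deficit across year boundaries (set the
start month and split records accordingly). "Maximum" MCWD always means
*most negative* (largest deficit). Evapotranspiration is a pluggable
provider; the default constant 100 mm mo⁻¹ keeps the metric temperature
independent, which is what lets the attribution stage separate drought
from heat. A linear temperature-linked provider (`et_temperature()`) is
included for the robustness variant, calibrated so a typical plot record
averages ≈101 mm mo⁻¹.

Pre-event drought is the mean of annual MCWD over the monitoring span;
event drought is the single most negative annual MCWD inside the event
interval — the most extreme conditions the plot experienced. Regional
summaries compare the event climate-year against the prior decade and
against a fixed 1980–2010 baseline, with 95% CIs across grid cells.

**Sign convention.** Plot-level drought anomalies are expressed as
*deficit intensification* in mm, positive when the event is drier:
`d_mcwd = MCWD_pre − MCWD_event` (both ≤ 0). A negative effect coefficient
therefore means "more drought, less carbon", and −0.003 Mg C ha⁻¹ y⁻¹ per
mm corresponds to 0.3 Mg C ha⁻¹ y⁻¹ lost per 100 mm of intensification.

## 5. Attribution

Responses are plot-level deltas (event minus time-weighted pre-event
mean); predictors are the two anomalies plus pre-event temperature and
MCWD, standardized to zero mean and unit SD for effect-size comparison;
the back-transform to raw scale is exact and exposed in the coefficient
table. Weights acknowledge that larger, longer-monitored plots estimate
fluxes better: candidate weightings `length^p + area^q − 1` over
`p, q ∈ {0, 1/8, 1/6, 1/4, 1/3, 1/2, 1}` are scored by the maximum
absolute Spearman correlation between weighted squared null-model
residuals and either effort variable, and the minimizer is chosen, ties
toward smaller exponents (the a-priori assumption is *no* pattern, so the
flattest weighting that achieves it wins). The stored per-response
defaults are `d_net`: length^1/6 + area^1/8 − 1; `d_gains`: length^1/4;
`d_losses`: length^1/3; `d_stem_net`: length^1/2 + area^1/4 − 1;
recruitment and stem mortality unweighted.

Model selection enumerates every subset of main effects, with
interactions admitted only alongside both their main effects
(marginality); the default interaction set is anomaly×anomaly and each
anomaly×its pre-event level. Models are fitted by weighted least squares
and ranked by AIC (AICc is a switch; with ~100 plots and few terms the
difference is negligible). Akaike weights are renormalized over the
smallest top set reaching 0.95, and coefficients are *full*
model-averaged: a term absent from a model contributes zero, so weakly
supported terms shrink toward zero.

Intervals for averaged coefficients use the model-averaged tail-area
(MATA-Wald) construction: the interval endpoints equate the
weight-mixture tail probability to α/2, with absent-term models
contributing a point mass at zero. The more common adjusted-SE Wald
interval collapses toward a zero-width interval whenever a term is
heavily shrunk, which makes its coverage of small true effects poor; the
tail-area interval keeps near-nominal coverage in exactly that regime,
which the test suite verifies over 100 replicate networks. The adjusted
SE is still reported.

Paired pre/during comparisons are two-sided paired t tests, with exact
equality reported (and no statistic) under zero difference variance. The
scenario partition solves
`overall·total = pre·(total − window) + x·window` for the event-window
rate `x`; regional scaling multiplies a baseline sink by the event/pre
rate ratio; percent-of-stock is `100 × flux/stock`.

## 6. The synthetic-data generator

Defaults encode the emulated study design: 100 plots in 26 clusters,
areas 0.2–1.1 ha with median 1 ha, ~425 stems ha⁻¹ at ≥100 mm, censuses
near 2008.4 / 2014.3 / 2017.1 (two pre-event, one post-event; jittered per
plot with the last pre-event census kept before the event window and the
final census after it), the event window May 2015–April 2016, size-class
growth 0.83 / 1.64 / 2.86 mm y⁻¹, 1.2 % y⁻¹ stem mortality, 6.4 recruits
ha⁻¹ y⁻¹, plot-level anomalies `d_mcwd ~ N(97, 60²)` mm and
`d_tas ~ N(0.28, 0.15²)` °C (half the variance at cluster level), and
effects `beta_mcwd = −0.003` Mg C ha⁻¹ y⁻¹ per mm, `beta_temp = 0`.

Free parameters with no reported counterpart were fixed once on realism
grounds: stem-level growth noise is lognormal with sdlog 0.5 (no
stem-level growth variance is reported anywhere; flagged in the
configuration); initial diameters are shifted-exponential with mean
165 mm above the threshold, capped at 1.5 m, which yields a standing
stock of ≈164 Mg C ha⁻¹ at 425 stems ha⁻¹ — the large-tree-dominated
structure these forests have; the species pool is hierarchical
(family/genus/species wood-density effects around 0.63 ± 0.12 g cm⁻³)
with 15% of species lacking species-level density entries so the
taxonomic fallback is exercised.

Mortality and recruitment are realized as binomial survival and Poisson
entry from annual instantaneous rates, with recruit entry times uniform
and exponential survival to the census — exactly the constant-rates model
the census-interval correction assumes, which makes the correction oracle
exact in expectation. The event effect
`beta_mcwd·d_mcwd + beta_temp·d_tas + noise` is injected through the
growth channel: the event-interval diameter increments are scaled by a
multiplier solved numerically (averaging over the lognormal noise with a
deterministic quantile rule) so the *expected* change in the plot's
carbon-gain rate equals the target. The channel does not matter for
attribution of the net flux, and the growth channel keeps the injected
effect continuous and exactly calibrated, whereas a mortality channel
would quantize it into a handful of random deaths; an event mortality
multiplier is available separately. Per-plot pseudo-random streams are
derived from the seed and the plot index, so results are reproducible and
individual plots are stable when the plot count changes.

The climate generator builds one cell per cluster: a bimodal seasonal
precipitation cycle (two dry seasons, ~1,500 mm y⁻¹), a 0.015 °C y⁻¹
warming trend, the configured additive temperature and multiplicative
precipitation event anomalies, reference/auxiliary dataset pairs related
to the truth by known per-month affine maps plus noise, and a climatology
equal to the 1970–2000 truth mean plus known plot offsets. The stem and
climate generators record their own truths independently;
attribution-recovery tests use the stem generator's recorded anomalies,
end-to-end climate tests the climate generator's.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: African floristics and their trait
structure, spatial autocorrelation of climate beyond cluster-level
offsets, real ENSO teleconnection patterns, delayed (post-census)
mortality, multi-stem individuals, and (unless switched on) field
measurement error. Parameter-recovery results show the *estimators* are
calibrated under the design they assume, not that the design assumptions
hold in any particular forest.

## 7. Validation problem sizes

The suite validates the correction against the continuous-time simulator
at 500 replicates for each census length in {1, 5, 10} y (200-stem
populations at stationarity); attribution calibration over 100 replicate
networks of 100 plots; paired-test type-I error over 1,000 null
simulations of 100 plots; and the harmonization, downscaling and MCWD
identities on exact hand-computed fixtures. The sensitivity harness
(unweighted, basal-area, variable-ET, cooled-cluster-excluded variants)
runs on a network generated with both effects nonzero
(`beta_mcwd = −0.003`, `beta_temp = −0.05`): sign stability is only a
meaningful invariant when the slopes have true signs — the sign of an
exactly-null slope is noise.

## 8. Known limitations

The correction's constant-rates model is first-order in `mT` for the
valuation of within-interval recruit deaths; at `mT ≳ 0.5` the residual
bias becomes visible. Attribution assumes plot-level independence — no
spatial random effects or cluster-level mixed models, matching the
plot-level regression design it implements. The MCWD reset-per-year
convention truncates multi-year droughts at the climate-year boundary;
carrying deficits across years is possible via the configurable start
month but is not the default. Single-network effect estimates are noisy
(demographic loss noise from large-tree deaths is of the same order as
the cross-plot spread of the real network's fluxes); calibrated inference
needs the replicate designs above, and single-seed point estimates should
be read accordingly.
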