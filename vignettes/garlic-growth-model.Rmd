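---
title: "An integrative process-based growth and yield model for hardneck garlic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An integrative process-based growth and yield model for hardneck garlic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(garlicsim)
```

## Scope and model structure

`garlicsim` simulates a single garlic plant (scaled to a stand by plant
density) from planting to a fixed harvest date, driven by hourly weather.
Five interacting processes are stepped through the season:

1. **Phenology** — leaf tips appear by accumulating a leaf tip appearance
   rate (LTAR, d⁻¹) whose ceiling is conditioned by seed-bulb storage and
   converges dynamically over leaf ranks (the *dynamic phyllochron*).
2. **Cold stress** — recoverable *injury* scales leaf elongation down
   through an effect $E(t) \in [0,1]$; irreversible *damage* kills plants
   through a logistic mortality in temperature, permanently reducing
   plant density.
3. **Morphology** — each appeared leaf elongates toward a rank-dependent
   potential length, is translated to blade area, stays green for a
   stay-green-scaled physiological lifespan, and senesces; green areas
   aggregate to canopy LAI.
4. **Carbon assimilation** — a coupled C3 photosynthesis / stomatal
   conductance / energy-balance model integrates net canopy carbon gain
   over sunlit and shaded big-leaf fractions (with a radiation-use
   efficiency fallback).
5. **Allocation** — assimilate enters a carbon pool drained daily:
   maintenance respiration is paid first, the remainder is converted to
   structural growth at efficiency $Y_g$ and split among root, leaf,
   sheath, scape and bulb by a stage × organ partitioning table. Bulb
   mass at harvest, converted to fresh weight at 85 % moisture and
   multiplied by surviving density, is the yield.

The timestep is hybrid: assimilation and leaf-appearance accumulation
integrate the 24 hourly records of each day; cold stress, elongation,
senescence and allocation update once per day, with cold stress driven by
the daily minimum temperature (frost is a nightly phenomenon and the
cold-day counter $D$ is defined in days).

## Dynamic phyllochron

The initial maximal rate is a sigmoid of storage duration $SD$ (days
between seed-bulb harvest, assumed June 30, and planting):

$$r_0 = \frac{LTAR_{max,a}}{1 + e^{-\alpha (SD - SD_m)}},$$

with asymptote $LTAR_{max,a} = 0.4421\ \mathrm{d^{-1}}$, half-saturation
$SD_m = 117.7523$ d and steepness $\alpha = 0.0256\ \mathrm{d^{-1}}$.
After each leaf appearance the ceiling moves linearly toward
$r_1 = LTAR_{max,a}/2$:

$$LTAR_{max}(k) = r_0 + (r_1 - r_0)\,\min(k, N_g)/N_g,$$

completing at the generic leaf number $N_g = 10$; beyond $N_g$ the rate
is held at $r_1$ (the convergence statement does not define behaviour
past $N_g$, and clamping is the only reading that keeps the rate inside
$[\min(r_0,r_1), \max(r_0,r_1)]$). The realized rate each hour is
$LTAR_{max} \times f(T)$ where $f$ is a beta thermal response (zero at or
below 0 °C and at or above 34 °C, one at 22 °C); the temperature response
is inherited machinery from this model family, not restated by the
source of the phyllochron parameters, so its cardinal temperatures are
configurable.

Storage temperature is accepted in the configuration (8 °C default) but
inert: only $SD$ enters the sigmoid. It is retained for forward
compatibility with storage-conditioned leaf-initiation extensions.

A scape appears after three further phyllochron equivalents accumulate
past the onset of the reproductive stage, using the *current* dynamic
rate (accumulating at a rate frozen at onset would be the alternative
reading; the current-rate form keeps scape timing responsive to the same
convergence that motivates the dynamic phyllochron). Reproductive onset
itself is triggered by thermal time after emergence — growing degree
days above 4 °C reaching 1000 °C·d by default. The trigger threshold is
a free parameter of this implementation, chosen once so that scape
initiation and appearance under the subtropical synthetic climate fall
in spring (April), consistent with the cultivar's documented phenology;
a photoperiod gate is deliberately not enabled.

## Cold stress

**Injury** (recoverable). A daily indicator adds one cold day when the
daily minimum is below $T_{c,i} = 0$ °C and subtracts one otherwise,
floored at zero. Apparent injury severity is logarithmic in temperature,

$$C = \max(0, \min(\ln[a(T - T_{c,i}) + b], 1)),$$

with $a = -0.1$, $b = 1.6$. Two interpretation choices matter here.
First, the logarithm is natural: under $\ln$, $C$ saturates at 1 near
−11 °C, consistent with damage peaking around −20 °C; a base-10 reading
never saturates. Second, the attenuation of injury by exposure length is
implemented as

$$E = 1 - C^{1/D}, \qquad E(t) = \begin{cases} 1 & D = 0\\
\min(E, E(t-1)) & D > 0,\end{cases}$$

the only reading under which longer exposure monotonically worsens the
effect while keeping $E \in [0,1]$. It is isolated in `injury_effect()`
so an alternate functional form can be swapped without touching the
episode bookkeeping. Actual leaf elongation is $LER = E(t) \cdot LER_p$.

**Damage** (irreversible). Mortality is logistic about
$T_{c,d} = -15$ °C with shape $s = 0.9$:

$$M = \frac{e^{-s(T - T_{c,d})}}{1 + e^{-s(T - T_{c,d})}},$$

so $M(-15) = 0.5$, $M(-10) \approx 0.011$ and $M(-20) \approx 0.989$.
Survival $S = 1 - M$ is applied multiplicatively to plant density once
per *damage event*, defined as a frost day (daily minimum below
$T_{c,i}$): repeated frosts compound, which is what collapses stand
density — and hence yield — under a continental winter. Restricting
events to frost days also makes a frost-free season exactly equivalent
to a cold-free run ($M(0\,°C) \approx 10^{-6}$, so the restriction is
numerically inconsequential). Mortality is applied regardless of
developmental stage; making dormant plants less vulnerable would require
a vernalization/dormancy state this model intentionally lacks.

## Morphology

Potential final length per rank follows a Gaussian-bell profile peaking
at $LM_{min} = 100$ cm (the longest leaf) around three-quarters of the
leaf series, with a floor of 25 % for the earliest ranks; the profile
shape is configurable since only the maximum is constrained by
observation. Elongation proceeds at
$LER_p = LER_{max} f(T)$ with $LER_{max} = 5.56\ \mathrm{cm\,d^{-1}}$ —
exactly $LM_{min}$ in 18 days at the optimum — scaled by cold injury,
and is truncated at the potential length. Blade area uses
`length × width × form factor` with width proportional to potential
length (defaults 0.03 and 0.75).

Senescence uses a physiological clock: each day a leaf ages by the
thermal response factor, so warm springs age leaves faster. A leaf is
fully green until 70 % of its lifespan `SG × green_span` (defaults
1.5 × 50 physiological days) and declines linearly to zero thereafter.
The stay-green parameter SG multiplies the whole green duration, by
construction. SG is treated as a dimensionless multiplier (its source
lists it unitless in one place and in days in another; the multiplier
reading preserves proportional scaling). This thermal-lifespan rule is a
substitute for the original model's unrestated senescence-onset rule;
it reproduces the qualitative behavior that matters downstream — a
unimodal green-area trajectory peaking near scape appearance, and
earlier peaks plus earlier total senescence under warmer regimes.

## Carbon assimilation

The coupled model uses Farquhar–von Caemmerer–Berry C3 kinetics with
Bernacchi temperature dependencies, Ball–Berry stomatal conductance
($g_s = g_0 + g_1 A\,h_s / C_s$), and a linearized leaf energy balance
with a fixed evaporative fraction (0.5), solved per canopy layer by a
damped fixed-point iteration on intercellular CO₂ (tolerance
10⁻³ µmol mol⁻¹, ≤ 100 iterations; the iterate is clamped to
[1, 2·C_a + 200] µmol mol⁻¹ and the leaf-air temperature offset to
±10 °C to keep extreme winter inputs inside the kinetics' domain). The
canopy is split into sunlit and shaded big leaves by extinction
coefficient $k = 0.6$: sunlit leaf area $(1 - e^{-kL})/k$, sunlit leaves
receiving direct beam $k(1-f_d)I_0$ plus the mean intercepted diffuse
component, shaded leaves the diffuse component only (diffuse fraction
$f_d = 0.2$; beam scattering is neglected). PAR is derived from
shortwave at 2.3 µmol J⁻¹. Net assimilation is converted at
30 g CH₂O mol⁻¹ CO₂ and divided by plant density.

The garlic-specific kinetic constants (`vcmax25 = 90`, `jmax25 = 160`,
`rd25 = 1.2` µmol m⁻² s⁻¹, `g1 = 9`, ...) are documented estimates:
they live in the prior gas-exchange literature for this crop rather
than in the phenology/cold-stress parameter tables, and nothing in the
package's validated behavior depends on their exact values — the
properties that are tested are structural (monotonicity in PAR and CO₂,
convergence and uniqueness of the coupled solution against a bisection
oracle, bounded leaf-air offset). A `carbon_source = "rue"` switch
replaces the whole scheme with Beer-law interception × radiation-use
efficiency (default 2 g MJ⁻¹), keeping downstream modules exercisable
independently of the gas-exchange parameterization.

## Allocation

The pool is drained within the day it is filled (supply rate = pool/Δt),
preventing unbounded accumulation. Maintenance respiration uses a Q10
form, `coefficient × biomass × Q10^((T−25)/10)` (Q10 = 2; per-organ
coefficients 0.002–0.015 g g⁻¹ d⁻¹, with the storage bulb cheapest).
The actual allocation rate is
$\max(\text{supply} - \text{maintenance}, 0) \times Y_g$ with
$Y_g = 0.75$, the standard carbohydrate-synthesis efficiency for this
model lineage; the $(1 - Y_g)$ share is growth respiration. When night
respiration would overdraw an empty pool the shortfall is recorded
(`unmet_respiration`) rather than silently discarded, so the
whole-season balance
$\sum A + \text{unmet} + \text{pool}_0 = \text{maintenance} +
\text{growth}/Y_g + \text{pool}_T$ closes to floating-point precision
on every simulated season.

The partitioning table's numeric coefficients are teleonomic estimates
(the approach its source itself describes): the seed stage feeds root,
leaf and sheath from a small configurable initial pool (2 g, standing in
for unstated clove reserves); the vegetative row is leaf/sheath-heavy
with a 10 % bulb trickle; R1 and R2 shift progressively bulb-dominant
(50 %, then 60 % with a 25 % scape share); after scape removal (R3) the
mature sheath stops growing and 95 % goes to the bulb, which makes the
stalk (sheath + scape) trajectory peak and then fall, as observed when
scapes are removed. Structural invariants — rows summing to one, zero
death row, zero scape share in vegetative and R3 — are validated at
run time, and all conservation tests hold for any valid table.
Remobilization of stored carbon between organs is not modeled.

## Synthetic weather

Because the observation datasets and the national stochastic weather
ensembles behind the original experiments are not redistributable, the
package ships a generator with two named profiles: `subtropical`
(Gosan-like, 33.3°N: annual mean 16.5 °C, amplitude 9.5 °C) and
`continental` (Chuncheon-like, 37.9°N: mean 10 °C, amplitude 17.5 °C).
Daily means follow an annual sinusoid (coldest mid-January) plus AR(1)
residuals (SD 2–3 °C, lag-1 correlation 0.6); a diurnal cosine peaks at
14:00; shortwave is clear-sky radiation from solar geometry times an
AR(1) daily transmissivity; RH varies diurnally against temperature;
wind is lognormal by day. The profile parameters were fixed once so
that, at default severity, the continental profile delivers January
mean daily minima below −10 °C and frost hours below −15 °C every
winter (exercising the mortality pathway), while the subtropical
profile never reaches −5 °C (leaving it untouched). The `severity`
scalar multiplies the seasonal amplitude.

The generator emulates marginal statistics only. It has no weather
fronts, no precipitation (the model consumes none), no
temperature–radiation covariance beyond clear-sky geometry, and no
multi-day cold-spell persistence beyond AR(1). Tests passing on this
synthetic climate therefore demonstrate the simulator's internal
consistency and its qualitative response to climate contrasts — not
predictive skill on real station data, which would require the original
forcing and the prior model's calibrated gas-exchange parameters.

Daily station-style input is downscaled to hourly with a daytime
half-sine from `T_min` at dawn to `T_max` at 14:00 solar time and an
exponential night decay (rate 0.3 h⁻¹) toward the same day's minimum;
daily shortwave totals are spread over the daylength by a normalized
half-sine, making the hourly integral exact. Any curve meeting the
min/max/integral round-trip contract would do; this one is the standard
diurnal scheme in the field. Scenario CO₂ is piecewise-linear between
anchor years with no extrapolation.

## Experiment design

The factorial mirrors the original adaptation study: planting DOY 240 to
350 in 10-day steps (12 dates) × weather datasets, harvest fixed at
May 15 of the following calendar year, immediate scape removal, yield as
bulb fresh mass at 85 % moisture × surviving density. A current-climate
ensemble of 10 stochastic datasets gives 120 runs; a scenario ensemble
of 8 decade windows × 10 replicates gives 80 datasets and 960 runs.
`optimal_planting()` takes the argmax DOY per replicate (ties broken
toward the earlier date — earlier planting is the cheaper practice) and
then summarizes across replicates, reporting both the per-replicate
table and the grouped means ± SD; optimizing the averaged curve instead
is the other defensible convention, and the per-replicate table lets a
user do that too. `period_group()` pools decade windows into the three
reporting periods (1980–2010s, 2020–2050s, 2060–2090s); note that the
two future period labels cover four decade windows each (40 samples
from an 8-window × 10-replicate ensemble), while a pooled data point of
10 seeds over 5 decade windows — 50 samples — is available through the
generic `group` column.

## Numerical choices and degenerate inputs

* Leaf-appearance accumulator: increments of `LTAR_max × f(T) × Δt`;
  an appearance fires when it crosses 1 and the accumulator keeps its
  remainder, so no thermal time is lost at appearance boundaries. Leaf
  initiation is capped at 16 leaves (a plausibility default from field
  observations of this cultivar) but the accumulator keeps running to
  drive scape timing.
* Exact conservation: `partition()` pins the largest coefficient so
  organ increments sum to the allocated mass to machine precision;
  carbon-balance tests assert 10⁻⁶ g over a full season.
* Downscaling degenerate case `T_max = T_min` yields a flat 24-hour
  profile; an empty daily series is an error, as are RH outside
  [0, 100], non-monotone timestamps and gaps (reported with the first
  offending row or missing interval).
* Cold-day counter exactly at `T = T_{c,i}` counts as a warm day
  (strict inequality, matching the accumulation rule's wording).
* `run_season` is fully deterministic given weather and configuration;
  all stochasticity lives in the weather generator, which seeds its own
  RNG stream and restores the caller's state.

## Problem sizes

The shipped tests and the acceptance script use two-calendar-year hourly
synthetic series (17 520 records), single seasons of ~230 simulated
days, 120-run planting-date scans (12 DOYs × 10 stochastic datasets)
per climate profile, 10⁴-point grids for the cold-injury bounds, and
10³ random rows for partition conservation. These sizes were chosen as
the smallest that exercise every pathway — a full winter for the cold
modules, a full factorial for the experiment machinery — while keeping
a complete run of the suite in the low minutes on a laptop.

## Known limitations

* No vernalization or dormancy: winter chilling is assumed adequate,
  and cold-damage vulnerability does not depend on developmental stage.
* No nitrogen or soil-water limitation; the model tracks potential
  growth under non-limiting fertility and irrigation.
* Gas-exchange constants are estimates, not a calibrated garlic
  parameter set; absolute yields are therefore indicative, and the
  package's validated claims are orderings and conservation laws, not
  absolute levels.
* Biomass is cumulative except scape removal: organ senescence reduces
  green *area* but not standing dry mass.
* The synthetic climate reproduces marginal statistics, not real
  weather sequences (see above).
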