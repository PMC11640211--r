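---
title: "Heat-balance ventilation control for broiler houses: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heat-balance ventilation control for broiler houses: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(broilervent)
```

## The control problem

A tunnel-ventilated broiler house holds tens of thousands of birds whose
sensible and latent heat output grows steeply with age. Conventional
controllers pick a fan stage from indoor temperature thresholds that an
operator programs per bird age; the thresholds encode experience, not
physics, and routinely over- or under-ventilate. `broilervent` implements
the alternative: compute, every control tick, the heat that must leave the
building for the indoor temperature `Ti` to reach the age-dependent set
temperature `Td` within a horizon `Δt`, and convert that heat into a
**ventilation rate requirement (VRR)** that is then quantised onto the
discrete fan-stage ladder.

The energy balance over one horizon is

```
Qv = ρ Cp Vb (Ti − Td)/Δt  +  Qa + Ql + Qd
```

where the first term is the sensible heat stored in the house air mass,
`Qa` and `Ql` are the flock's sensible and latent heat (W), and `Qd` is the
envelope exchange `−(Uw·Aw + Uf·Af)(Ti − To)` (negative when the warm house
sheds heat outdoors). The required airflow follows from the
indoor-to-inlet temperature difference:

```
VRR = Qv / (ρ Cp ΔT_eff),       ΔT_eff = Ti − (To − Tc)
```

with `Tc = ε (To − Tow)` the evaporative-pad temperature drop (`ε` the pad
saturation efficiency, `Tow` the outdoor wet-bulb temperature; `Tc = 0`
when the pads are idle).

### The denominator choice

A literal transcription of the rate equation would subtract `Tc` from the
numerator difference (`Ti − To − Tc`), which *shrinks* the denominator when
the pads run and therefore *raises* the requirement exactly when the inlet
air has been made colder — physically inverted. The default mode
`inlet_corrected` uses `Ti − (To − Tc)`: the inlet air enters at `To − Tc`,
so pad operation widens the usable difference and reduces the requirement.
The literal form remains selectable
(`house_config(denominator_mode = "as_printed")`) so both readings can be
compared side by side.

## Flock bioenergetics

Per-bird mass follows a quadratic in age `d` (days),
`m = (−35.783 + 19.098 d + 0.6008 d²)/1000` kg. The polynomial is
evaluated in grams: at 35 days it yields 1368.6, which is only plausible
as grams for a commercial broiler, even though the surrounding equations
use kilograms. It is negative for `d ≤ 1`; by default that errors, and a
hatch-weight floor (`broiler_mass(d, floor_kg = 0.042)`) is available for
runs that start at stocking. The algorithm itself is intended for use from
roughly day 20, so the edge sits outside its operating envelope.

Sensible heat scales with metabolic mass `m^0.75` through a temperature
polynomial in kcal·kg⁻⁰·⁷⁵·day⁻¹, converted by `4184/86400` to watts.
Latent heat assumes 40% of daily water intake evaporates indoors; the
printed form of that equation carries a leading minus sign which would
make evaporation remove negative heat, so the package uses the positive
convention (latent heat is part of the load the ventilation must remove —
it is *added* to `Qv`). Both are modulated by a circadian factor

```
Sc = 1 − a sin(2π (h + 6 − hmin)/24)
```

with `(a, hmin)` = (0.21, 0.38) for sensible and (0.46, 0.67) for latent
heat. This parenthesization — phase shift inside the argument, divided by
the 24 h period — is the only reading that keeps `Sc` dimensionless and
bounded in `[1−a, 1+a]` with mean 1 over a day; the tests verify both
properties by quadrature.

The latent-heat polynomial `583.5 − 17.1 Ti + 25.25 m` crosses zero near
`Ti ≈ 36.6 °C` for market-weight birds. That is outside the formula's
fitted envelope, so the bare operation raises an error there; the
controller, simulator and audit engine instead clamp latent heat at 0 W
(`clamp_negative = TRUE`) so that heat-wave episodes, during which the
indoor temperature of the *conventional* controller can transiently exceed
that bound, remain computable. The clamp only ever removes a term that had
become unphysical.

## Exception clauses and pad hysteresis

Three exception clauses are evaluated in numerical order; the first that
fires suppresses the rest (`decide_vrr()` records which one):

1. **No cooling needed** — `Qv < 0` or `Ti < Td + Tda` (with `Tda = 1.5 °C`
   the allowable band): fan stage 0, i.e. the age-dependent minimum
   ventilation only.
2. **Pad operation** — pads may switch on only when it is genuinely hot
   outside (`To ≥ Td + 3·Tda`) *and* inside (`Ti > Td + 2·Tda + 0.5`), and
   they stay on until `Ti ≤ Td + 2·Tda`. The 0.5 °C separation between the
   on and off thresholds is the hysteresis band: with equal thresholds the
   pads would cycle continuously at the boundary. After a pad decision the
   VRR is recomputed with the cooled inlet (`Tc > 0`) within the same tick
   and staged.
3. **Warm outside, pads idle** — when `To ≥ Td + Tda` the indoor/outdoor
   difference can be small and the rate equation ill-conditioned, so the
   requirement is capped at one full air exchange per horizon,
   `VRR₂ = Vb/Δt` (34.51 m³ s⁻¹ for the reference house).

Independently of the clauses, any `|ΔT_eff|` below a 0.2 °C tolerance is
treated as degenerate and the `VRR₂` fallback applies; the tolerance is a
package choice (the need for a guard is inherent in the division, the
numeric value is not prescribed anywhere).

Whether the air-exchange cap should also bind when the pads run is
genuinely open; the package implements the clauses exactly as ordered, so
a fired pad clause short-circuits the cap. In practice the pad-cooled
inlet keeps the denominator healthy and the requirement finite.

### Stage quantisation

The stage ladder runs 0–5 with 2/4/6/8/10/14 fans of 37,000 m³ h⁻¹;
stage 0 is an intermittent two-fan minimum-ventilation stage whose duty
fraction delivers the age-interpolated minimum rate (1233 m³ h⁻¹ at
day 0 rising linearly to 22,611 m³ h⁻¹ at day 35 — the interpolation shape
is a package choice; only the endpoints are given). `stage_from_vrr()`
computes `n_req = ⌈VRR / capacity⌉` — rounding *up* so the delivered
capacity always covers the requirement — and picks the smallest
*continuous* stage (1–5) with at least `n_req` fans, capped at the top.
Requirements at or below the minimum ventilation map to stage 0. A
requirement of one or two fans therefore maps to stage 1, not stage 0:
stage 0's duty cycle delivers only the minimum rate, which would
under-ventilate.

## The conventional controller

`decide_baseline()` reproduces the installed farm logic: the fan stage is
the highest whose start temperature the indoor temperature has reached
(`≥` comparison, no deadband), and the pads run at a fixed intermittent
duty (default 60 s per 300 s, the midpoint of the 40–80 s per five minutes
observed on the reference farm) above a pad threshold. The default
threshold table is **synthetic** — the real farm's table is not publicly
readable — declining linearly from a 32 °C base at day 0 to 24 °C at
day 28, with stage `k` starting at base + `k` °C and pads at base + 5 °C.
Replications of a specific installation should supply the farm's own table
via `stage_threshold_table()`.

## The simulator

`run_episode()` couples either controller to a single-zone
(complete-mixing) thermal model at the 10 s control interval:

```
dTi/dt = [Qa + Ql + Qd + ρ Cp q ((To − Tc) − Ti)] / (ρ Cp Vb)
```

integrated by explicit Euler. The model carries only the air volume as
thermal mass — no wall storage, no bird body mass, no litter — which is
the same idealisation the control law itself makes. Indoor humidity is
*not* balanced (pad and weather humidity feed the wet-bulb calculation
only), so simulated logs carry outdoor humidity but no indoor channel.
Intermittent devices (stage-0 fan pair, baseline pads) enter the step as
duty-weighted quantities: delivered airflow `q` and an effective inlet
drop `Tc × duty`, which is exact for the interval mean of a linear model.

At the default 10 s step the scheme is comfortably stable: the fastest
time constant is `Vb/q ≈ 36 s` at full ventilation (144 m³ s⁻¹ against
5176.5 m³), and a `substeps` argument provides sub-stepping for
configurations that push `q·dt/Vb` toward 1. The tests confirm first-order
convergence to the closed-form solution of the linear zone equation
(`zone_closed_form()`) at dt = 10/5/2.5 s.

### Synthetic weather

`weather_generate()` produces a sinusoidal diurnal cycle between
`night_min_T` and `day_max_T` peaking at `peak_hour` (15:00 by default),
relative humidity in anti-phase, and optional seeded Gaussian noise. The
`hot_spell` preset (37 °C day maximum, 26 °C night minimum, 52%/90% RH)
emulates a summer heat-wave regime: between 11:00 and 19:00 the noiseless
trace stays within 33–37 °C, and nights remain above 26 °C. Those core
daytime hours also define the `mean_daytime_Ti` episode summary. What the
generator does **not** emulate: weather fronts, cloud bursts, humidity
spikes decoupled from temperature, or multi-day trends — so closed-loop
results demonstrate controller behaviour under a clean, repeatable diurnal
forcing, not performance statistics transferable to any particular farm or
season.

### The restoration property

The construction of the balance makes one Euler step of size `Δt` at
exactly the computed VRR land on `Td` identically (the algebra cancels).
The continuous-time solution instead relaxes exponentially toward the
mixed steady state, and closes the fraction `x(1 − e^{−1/x})` of the gap,
where `x = ΔT_eff ρ Cp Vb / (Δt Qv)`. Closure ≥ 95% therefore needs
`x ≥ 10` — a small gap and a cold inlet. The tests verify 96.2% closure at
`Ti0 = Td + 1.5 °C`, a 0 °C inlet and a constant 20 kW load; in hot
weather (inlet warmer than the setpoint) no ventilation rate can reach
`Td` at all, which is precisely why the pad clause exists.

## The audit engine

`compute_discrepancies()` re-runs the heat balance on each record of an
operation log and reports `VR_disc = VRR − actual` (positive =
under-ventilated) and `T_disc = Td − Ti` (negative = too hot).
`quadrant_summary()` classifies records outside the ±1.5 °C proper band by
the sign pair: under-ventilated/hot and over-ventilated/cold are the two
*fixable* quadrants (their sum with the proper share is the "potential
proper" fraction); over-ventilated/hot is anomalous (typically a
ventilation-to-temperature time lag, which the audit deliberately does not
correct); under-ventilated/cold is rare. Records with the pads running are
excluded by default because pad cooling breaks the monotone link between
airflow and temperature. Sign-boundary records outside the band classify
with the non-negative side — an arbitrary but documented tie rule;
percentages come from exact integer counts and always sum to 100. The
replication cadence is 10 min, but any uniform cadence is accepted
(`read_log(..., cadence_s = )` resamples fine-grained PLC logs by interval
means and time-weighted duties).

Energy accounting is deliberately plain arithmetic: fan-hours are
`Σ n_fans·dt`, energy is fan-hours × 836 W per fan, and reported kWh are
rounded to integers (raw values are retained alongside). Log-based
fan-hours count the stage-0 pair for the whole interval because the log
schema does not carry the duty phase; the simulator's own accumulators are
duty-weighted and exact, and episode comparisons use those.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `Vb` | 5176.5 | m³ | 87 × 14 m floor, 3.5 m eaves, 5 m ridge |
| `Uw`, `Uf` | 0.247, 2.75 | W m⁻² K⁻¹ | measured wall value; typical concrete slab |
| `Aw` | 1973.66 | m² | side walls + gables + roof from the same geometry |
| `Δt` | 150 | s | energy-balance horizon |
| `control_interval` | 10 | s | PLC update rate (distinct from `Δt`) |
| `Tda` | 1.5 | °C | allowable band; drives all exception thresholds |
| `ε` | 0.65 | – | pad saturation efficiency |
| `fan_capacity` | 37,000 | m³ h⁻¹ | per tunnel fan |
| `fan_power_w` | 836 | W | per fan, for energy accounting |
| `pad_power_w` | 1100 | W | pump draw, consistent with reported pad kWh over pad-hours |
| `ρ`, `Cp` | 1.2, 1006 | kg m⁻³, J kg⁻¹ °C⁻¹ | dry air near 20 °C (not prescribed; configurable) |
| `degenerate_tol` | 0.2 | °C | denominator guard (package choice) |

## Problem sizes used in the shipped checks

The test suite and the acceptance script use: a 100-record constructed
discrepancy fixture; an exception-precedence grid of ~1.1 × 10⁴
(Ti, To, Td) points against a brute-force rule interpreter; five-day
closed-loop hot-spell episodes (43,200 control ticks each) over ten seeds
for the controller comparison; and dt = 10/5/2.5 s Richardson triplets for
the integrator order. These sizes give stable percentages and order
estimates while keeping a full run in minutes on one core.

## Known limitations

* Single well-mixed zone: no longitudinal gradients, although tunnel
  ventilation creates exactly such gradients; the audit's anomalous
  quadrant is partly a symptom.
* No indoor moisture balance; pad effectiveness is a single constant
  efficiency, though real pads vary with saturation state.
* No inlet/static-pressure model: inlets are assumed to track negative
  pressure automatically, as on the reference farm; the controllers do not
  command them.
* The growth curve is a population average; flock heterogeneity and
  thermoregulatory responses (panting) are out of scope.
* The baseline threshold table is synthetic unless a farm table is
  supplied, so baseline comparisons characterise the *class* of
  threshold controllers, not a specific installation.
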