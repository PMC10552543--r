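# shoredye

A 1D model of wave-driven alongshore transport and decay of a shoreline
pollution tracer, with a beach-advisory decision-analysis layer — for
coastal water-quality scientists and beach managers dealing with
**dry-weather** point sources (e.g. a wastewater outfall discharging at the
beach), which weekly sampling and rain-triggered advisories routinely miss.

## The model

Tracer concentration `C(t, y)` on an alongshore coordinate `y` (29 km of
straight coastline, source at `y = 0`) obeys an advection–loss equation

    ∂C/∂t + v ∂C/∂y = −(k_P + k_B) C

with physical export `k_P = 1.3e−5 s⁻¹` (cross-shelf exchange out of the
nearshore), biological inactivation `k_B = 1.6e−6 s⁻¹` (norovirus die-off),
and a Dirichlet source `C = C₀` at `y = 0` on inflow. The current is derived
from offshore wave-buoy bulk parameters: the off-diagonal radiation stress
`S_xy = E (c_g/c) sinθ cosθ` (conserved until breaking, so computable at the
buoy) balances a linearized bottom stress integrated across the surf zone,

    v_1D = 4 S_xy √(h_5m/g) / (ρ C_d L H_s,5m)

where `L` is the shoreline-to-5 m-isobath distance and `H_s,5m` the wave
height shoaled/refracted to the 5 m isobath by Snell's law and energy-flux
conservation. The solver is first-order upwind with exact exponential decay
(operator splitting); it can also run in "1DC" mode with an externally
supplied alongshore-varying `v(t, y)`. Exceedance of the advisory threshold
`C_BAC = 5e−4` (a 10% swimmer-illness likelihood) feeds daily-advisory
experiments: ideal, model-informed, and simulated weekly sampling with a
one-day laboratory lag, swept over all 168 possible sampling hours.

A seeded synthetic generator supplies a two-season wave climate (summer
southerly swell → persistent northward flow; winter northwesterlies →
southward flow with episodic reversals) and pseudo-reference fields with
known embedded parameters, so the entire workflow — simulate, calibrate,
evaluate, advise — runs with no external data.

## Worked example

```r
library(shoredye)

waves <- generate_climate(climate_spec(seed = 1))   # one synthetic year, hourly
cmp   <- config_components(default_config())

vel   <- velocity_series(waves, cmp$bathy, cmp$drag)
vel
#> Alongshore velocity series: 8760 records
#>   range -0.425 to 0.523 m/s, rms 0.133 m/s

field <- run_transport(vel, cmp$grid, cmp$loss, cmp$source)
field
#> Tracer field: 8760 times x 291 alongshore locations (y 0-29 km)
#>   concentration range 0 to 0.2

adv <- daily_advisory(exceedance(field, cmp$source))
sum(adv$a[, which.min(abs(adv$y - 15000))])
#> [1] 167
```

The velocity RMS (0.133 m s⁻¹) brackets the 0.1 m s⁻¹ reference scale for
this kind of coast; concentrations stay bounded by the source value
`C₀ = 0.2`; and a beach 15 km downstream would have been under a
model-informed advisory on 167 of 365 days of this (deliberately polluted)
synthetic year. The steady-state e-folding length at 0.1 m s⁻¹ is
`v/(k_P+k_B) ≈ 6.8 km`, which is why plumes reach beaches 20 km away mainly
during persistent summer swell.

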