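---
title: "A 1D wave-driven model of nearshore tracer transport, decay, and beach advisories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A 1D wave-driven model of nearshore tracer transport, decay, and beach advisories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shoredye)
```

## The problem

Dry-weather point sources of sewage — an outfall discharging at the shoreline
of a long, straight, wave-dominated coast — contaminate beaches tens of
kilometres away, because material in the surf zone is carried alongshore
efficiently and exported offshore slowly. Regulatory beach monitoring (weekly
water samples, advisories after rain) does not capture these events.
`shoredye` implements a reduced-physics nearshore model for exactly this
setting: the tracer (a stand-in for wastewater pathogens, nominally
norovirus) is released at a fixed shoreline source and moves along a 29 km
one-dimensional alongshore grid under a wave-driven current, losing mass to
cross-shelf export and to biological die-off. A decision-analysis layer turns
model output into daily beach advisories and compares them against simulated
weekly sampling.

## Governing equation

Tracer concentration $C(t, y)$ (dimensionless, relative to the source) obeys

$$\frac{\partial C}{\partial t} + v\,\frac{\partial C}{\partial y}
  = -(k_P + k_B)\,C,$$

where $y$ is the alongshore coordinate (positive roughly northward from the
source), $v$ the nearshore alongshore current, and the two linear losses are

* $k_P = 1.3\times10^{-5}\,\mathrm{s^{-1}}$, **physical export** from the
  nearshore strip to the inner shelf (rip-current and other cross-shelf
  exchange, parametrized as a uniform monotonic decay), and
* $k_B = 1.6\times10^{-6}\,\mathrm{s^{-1}}$, **biological inactivation**,
  matching norovirus mortality. (This default is conventionally described as
  a 10-day e-folding scale although $1/(10\,\mathrm{d}) =
  1.16\times10^{-6}\,\mathrm{s^{-1}}$; we keep the standard printed value and
  note the discrepancy rather than resolving it.) Export dominates: $k_P$ is
  an order of magnitude larger.

Alongshore diffusivity is neglected. The source enters through a Dirichlet
boundary: $C = C_0$ at $y = 0$ whenever flow is directed into the domain.

## Wave-driven current

On a long straight coast with negligible wind stress, the surf-zone
alongshore momentum balance is between the cross-shore gradient of the wave
radiation stress and bottom stress. $S_{xy}$, the wave-averaged alongshore
flux of cross-shore momentum, is conserved as waves shoal until breaking, so
it can be evaluated directly from offshore buoy bulk parameters with
monochromatic linear theory at the peak period:

$$S_{xy} = E\,\frac{c_g}{c}\,\sin\theta\cos\theta, \qquad
  E = \tfrac{1}{16}\rho g H_s^2,$$

with $\theta$ the incidence angle from shore-normal (positive driving
positive-$y$ transport) and $c_g/c$ evaluated at the buoy depth — the
conservation of $S_{xy}$ is precisely why the buoy location suffices.
Integrating the momentum balance across the surf zone (width $L$, the mean
distance from the shoreline to the 5 m isobath) and linearizing the bottom
stress with the small-angle, weak-current approximation
$\tau_{b,y} = \rho C_d \sigma_u v$, with the shallow-water orbital-velocity
scale $\sigma_u = (H_{s,5m}/4)\sqrt{g/h_{5m}}$, gives the transfer function

$$v_{1D} = \frac{4\,S_{xy}}{\rho\,C_d\,L\,H_{s,5m}}\sqrt{\frac{h_{5m}}{g}}.$$

$H_{s,5m}$, the significant wave height at the 5 m isobath, is obtained from
the buoy record by Snell's law plus conservation of the cross-shore energy
flux over straight parallel isobaths (`shoal_to_isobath()`). The dispersion
relation is solved by Newton iteration on $kh$ (tolerance $10^{-10}$, at
most 50 iterations).

Two solver modes exist: **uniform** ("1D"), with the wave-derived $v_{1D}(t)$
applied everywhere, and **varying** ("1DC"), with an externally supplied
$v(t, y)$ — the mode used when nearshore velocities from a 3D circulation
model (or the synthetic reference generator) are available. The 1DC run
isolates the error of the wave transfer function from the error of the
alongshore-uniform transport assumptions.

## Parameters and defaults

| symbol | meaning | default | unit |
|---|---|---|---|
| $L$ | shoreline to 5 m isobath distance | 250 | m |
| $h_{5m}$ | nearshore outer-edge depth | 5 | m |
| $C_d$ | drag coefficient (tunable) | 0.01 | — |
| $\rho$ | seawater density | 1025 | kg m$^{-3}$ |
| $k_P$ | physical export rate | $1.3\times10^{-5}$ | s$^{-1}$ |
| $k_B$ | biological inactivation rate | $1.6\times10^{-6}$ | s$^{-1}$ |
| $C_0$ | boundary concentration (tunable) | 0.2 | — |
| $C_{BAC}$ | advisory threshold | $5\times10^{-4}$ | — |
| $V_{RMS}$ | reference RMS velocity | 0.1 | m s$^{-1}$ |
| $y_{max}$, $dy$ | domain, grid spacing | 29000, 100 | m |
| $dt$, save cadence | solver step, output | 120, 3600 | s |

$C_d$ and $C_0$ are site-tuned quantities with no universal value; the
defaults are chosen as realistic for a Southern California beach: $C_d =
0.01$ is a typical surf-zone drag coefficient and, with $L = 250$ m,
reproduces an RMS alongshore current near the reference $V_{RMS} =
0.1$ m s$^{-1}$ under the default synthetic climate; $C_0 = 0.2$ represents
an effluent fraction of 0.7 diluted in the immediate near-field of the
outfall. $C_{BAC} = 5\times10^{-4}$ is the concentration associated with a
10% swimmer-illness likelihood for a norovirus-laden source. The grid and
step defaults are CFL-safe for currents up to 0.83 m s$^{-1}$; both are
configuration-exposed, and the solver refuses to run outside the CFL limit
rather than silently destabilize.

## Numerics

The solver is a first-order upwind scheme with operator-split losses:

* **Advection** is donor-cell upwind. Under the CFL condition it preserves
  nonnegativity and (with a single source) boundedness by $C_0$, at the cost
  of numerical diffusion $\sim v\,dy\,(1 - v\,dt/dy)/2$. Since the physical
  model neglects alongshore diffusivity anyway, this is the appropriate
  scheme; the convergence tests confirm first-order decay of the
  steady-state error in $dy$, and at $dy = 50$ m the relative $L_2$ error
  against the analytic steady profile is about 0.2%.
* **Decay** is applied as the exact factor $e^{-(k_P+k_B)\,dt}$ each step, so
  loss integration carries no error at all: with $v \equiv 0$ the solution
  matches $e^{-(k_P+k_B)t}$ to machine precision.
* **Boundaries.** At $y = 0$: the node is held at $C_0$ on strict inflow
  ($v > 0$) and becomes a zero-gradient outflow when $v < 0$ — a pure
  Dirichlet condition would inject mass against the flow during reversals.
  At exactly $v = 0$ the node simply decays: a stagnant ocean is not
  connected to the source by advection. At $y_{max}$: zero-gradient.
* **Forcing** is interpolated linearly in time to solver steps; gaps longer
  than a tolerance (default 6 h) abort the run rather than extrapolate.
* The analytic steady state $C_0\,e^{-(k_P+k_B)\,y/v}$
  (`steady_state_analytic()`) serves as the solver's oracle, with e-folding
  length $v/(k_P+k_B)$ — about 6.8 km at $v = 0.1$ m s$^{-1}$.

## Calibration

Three deterministic bounded scalar searches (Brent), mirroring how the model
would be tuned against a hydrodynamic hindcast or field measurements:

* `tune_cd()` minimizes the RMS misfit between $v_{1D}(t; C_d)$ and a
  reference velocity series. $v_{1D} \propto 1/C_d$ exactly, so the forcing
  chain is evaluated once at $C_d = 1$. Noise-free references are recovered
  to $10^{-4}$ relative; with 2 cm s$^{-1}$ Gaussian noise on a year of
  hourly data, recovery is well within 5% (typically ~0.1%).
* `estimate_kp()` fits $\log\langle C\rangle(y)$ by ordinary least squares
  over 5–25 km (avoiding source-adjacent and far-boundary cells; the choice
  of log-of-mean rather than mean-of-log follows from the exponential form
  of the time-mean profile) and forms $k_{total} = b\,V_{RMS}$, then
  $k_P = k_{total} - k_B$. A $k_{total} < k_B$ yields a flagged negative
  $k_P$, never a silent clamp.
* `tune_c0()` exploits linearity of the transport equation in $C$: one run
  at $C_0 = 1$ is rescaled while maximizing mean Willmott skill over
  $y > 5$ km. The result reports a decade-flatness diagnostic (skill half a
  decade either side of the optimum); on noisy references the skill surface
  is flat within an order of magnitude, while on noise-free self-references
  the bias penalty is directly visible.

## Skill metrics and advisory analysis

Per alongshore location the package computes Pearson's $r$, RMSE normalized
by the time-mean reference (NRMSE), and the classic Willmott index of
agreement $1 - \sum(m_i-o_i)^2 / \sum(|m_i-\bar o| + |o_i-\bar o|)^2$,
bounded in $[0,1]$. The Willmott index is invariant to a common shift of
both series but penalizes shifting or rescaling the model alone; $r$ is
invariant to separate affine maps of either series. Degenerate cases
(constant reference, zero mean) return errors or documented conventions, not
silent values.

Advisory logic uses strict exceedance $C > C_{BAC}$ (a value exactly at the
threshold does not trigger). The **ideal** daily advisory marks a calendar
day and location if the true field exceeds for at least one hour; the
**model-informed** advisory applies the same rule to the model field.
**Simulated weekly sampling** checks the true field at one fixed hour of the
week; an exceedance posts an advisory from the following day (the laboratory
culture lag) for 7 days, until the next sample is processed. All 168
possible sampling hours are swept to produce min/mean/max accuracy
envelopes. Day boundaries are calendar days in the forcing time zone
(configurable; the convention matters at the 23:00/00:00 edge and is
pinned by test). The first advisory cannot precede the first processed
sample; leading days count as no-advisory.

## The synthetic generators

`generate_climate()` emulates a two-season Southern California wave climate
at an offshore buoy in 10 m depth: summer (June 1 – October 1) long-period
swell from south of shore-normal ($H_s \approx 0.8$ m, $T_p \approx 13$ s,
$\theta \approx +15°$) driving persistent northward flow, and winter
shorter-period waves from the northwest ($H_s \approx 1.1$ m, $T_p \approx
11$ s, $\theta \approx -12°$) driving southward flow, interrupted by
episodic multi-day south-swell events that reverse it. Hourly variability is
smooth (AR(1) with coefficient 0.98, a synoptic decorrelation scale of a few
days; lognormal in $H_s$). Under these defaults the derived $v_{1D}$ has an
RMS of 0.13–0.16 m s$^{-1}$ across seeds, bracketing the reference
$V_{RMS} = 0.1$ m s$^{-1}$, with episodic currents beyond 0.5 m s$^{-1}$.

`generate_reference()` stands in for a 3D circulation hindcast: it modulates
the wave-derived current with a static alongshore shape — a smooth random
component with a prescribed correlation length plus a localized Gaussian
slowdown at a mock inlet (an estuary mouth disrupts the alongshore flow) —
runs the varying-mode solver with known true parameters, and applies
multiplicative lognormal observation noise. With zero perturbation and zero
noise it reproduces the uniform run exactly, which anchors the calibration
recovery tests.

What the generators deliberately do **not** emulate: tides (and tidal
modulation of the surf-zone width), estuary discharge events, wind-driven
currents, 3D shelf recirculation, directional wave spreading. Passing tests
therefore demonstrate internal consistency and parameter recoverability
under the stated idealizations — not skill against real coastal data, which
requires a real hindcast or observations.

## Problem sizes used in tests

The test suite and the acceptance script run at deliberately modest sizes
chosen as sufficient for their statistical purpose: steady-state and
convergence checks use a 29 km domain at $dy$ = 50–200 m integrated for
three domain-flushing times; calibration recovery uses one year of hourly
forcing for the velocity-only fit and 1–3 months for fits requiring PDE
runs; the end-to-end seasonal experiment uses one full year (8760 hourly
records, 291 grid nodes), which completes in a few seconds.

## Known limitations

* First-order upwind smears sharp plume fronts over a few cells; front
  arrival times at distant beaches are correspondingly conservative.
* The transfer function assumes saturated breaking of all incident wave
  energy within the surf zone; during very low swell the implied current is
  an overestimate.
* A single uniform $k_P$ cannot represent alongshore-varying export (e.g.
  enhanced exchange at headlands or inlets); the varying-velocity mode
  absorbs some but not all of that structure.
* Weekly-sampling simulation assumes a fixed one-day laboratory lag and
  ignores resampling after exceedances, both of which vary by jurisdiction.
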