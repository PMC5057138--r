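---
title: "Modelling organic-matter supply to cold-water coral mounds"
author: "topopump"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling organic-matter supply to cold-water coral mounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topopump)
```

## The problem

Cold-water corals (CWCs) build carbonate mounds hundreds of meters high in
water 400–1000 m deep, far below the sunlit layer where their food — fresh
organic matter (OM) — is produced. Passive sinking alone delivers far too
little carbon at these depths to sustain the high metabolic rates measured
on CWC reefs. The hypothesis this package lets you explore quantitatively is
a positive feedback: the mounds themselves perturb the tidal flow, driving
episodic downwelling that carries OM-rich surface water down to the corals,
while the suspension-feeding community strips that OM out of the near-bed
flow. Two consequences are testable in the model: *focusing* (deposition on
coral habitat exceeds deposition on the off-reef seafloor at the same water
depth) and a *topographically enhanced pump* (part of the downwelled OM
escapes the reef and settles deeper than passive sinking alone would carry
it).

## The model

Suspended OM is a single non-conservative tracer `C` (mmol C m⁻³) on a
terrain-following (sigma) Arakawa C-grid:

* **Vertical velocity from continuity.** The free surface is held fixed
  (rigid lid) and `w = 0` at the seabed; integrating the horizontal volume
  flux divergence of each layer upward through the column yields `w` on every
  interface. With transport-conserving input flow the residual `w` at the
  surface is round-off (reported by `diagnose_w()` and checked in the
  tests, `< 1e-10` m s⁻¹).
* **Advection.** First-order upwind (donor-cell) fluxes on all faces, in
  conservative form. No explicit diffusion is added; the scheme's numerical
  dispersion plays that role, which is also why a higher-order scheme is
  deliberately not used. Sinking is folded into the vertical face velocity
  (`w − ws`), so a single upwind pass handles advection and settling.
* **Reactions and forcing.** First-order decay at rate `k`, applied
  analytically per step (`exp(−k·dt)`, unconditionally stable, exact
  semigroup). A constant downward OM flux enters through the top layer of
  every column. Lateral and bottom boundaries are zero-gradient; the
  bottom-face settling flux leaves the domain permanently and is recorded
  as deposition.
* **Suspension feeding.** Community filtration is expressed in the same
  units as a settling velocity (m³ m⁻² d⁻¹ = m d⁻¹), so it is modelled by
  multiplying the settling velocity at the *bottom face* of coral columns
  by an enhancement factor. An order-of-magnitude check
  (`capture_efficiency()`): a 0.3 m s⁻¹ current through a 0.2-m feeding
  layer clears 5184 m³ m⁻² d⁻¹, so a 200 m d⁻¹ feeding rate removes under
  4% of what flows past — not an unrealistic efficiency.

### Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `ws` | 20 | m d⁻¹ | background sinking velocity |
| `k_decay` | 0.03 | d⁻¹ | first-order OM decay rate |
| `surface_flux` | 12 | mmol C m⁻² d⁻¹ | export flux at the surface (~53 g C m⁻² yr⁻¹) |
| `enhancement` | 10 | — | suspension-feeding multiplier on `ws` over coral |
| `theta_s`, `theta_b` | 3.4, 1 | — | vertical stretching (refines bed and surface) |
| `n_levels` | 32 (grids), 20 (scenarios) | — | vertical layers |

`ws/k_decay ≈ 667 m` is the e-folding depth of the sinking OM flux, inside
the 500–700 m range commonly used for fresh OM in basin-scale models. With
these values the closed-form quiescent column (`steady_column_solution()`)
has surface concentration `surface_flux/ws = 0.6` mmol C m⁻³ — the
analytic oracle used throughout the tests.

## The synthetic study domain

No hydrodynamic archive ships with the package; `default_domain()` and
`make_tidal_flow()` generate a deterministic, seed-free emulation of the
study conditions:

* **Bathymetry** — a tanh shelf-to-trough slope (200 → 2000 m over a few
  km) with a Gaussian carbonate mound (relief 380 m, radius 1500 m, summit
  600 m) and optionally a shelf-break ridge (crest 450 m). 250-m horizontal
  spacing, 60 × 40 columns in the reference configuration.
* **Habitat** — a stand-in for a habitat-suitability prediction: coral is
  placed where the seabed lies at 400–1000 m *and* rises more than 10 m
  above the background slope (mound summit and flanks) or inside the ridge
  footprint.
* **Tidal flow** — horizontal velocities derive from a depth-integrated
  transport streamfunction, so the depth-integrated flux divergence of
  every column is zero to round-off at every snapshot and all vertical
  motion is topographic. The envelope is a 12.42-h semidiurnal carrier
  modulated by a 14.77-d spring–neap cycle (modulation 0.3, spring/neap
  amplitude ratio exactly 1.86). Snapshots are stored 6-hourly and linearly
  interpolated in time, as in offline coupling to stored hydrodynamic
  output.

### Vertical structure: why it matters and what was chosen

A velocity profile that is a function of sigma alone is terrain-self-similar:
the flow then follows the sigma surfaces exactly and the diagnosed
cross-interface `w` is identically zero, silencing every vertical-velocity
analysis. The generator therefore builds its profile in *dimensional*
coordinates, in two parts, each normalized per face so the depth-integrated
transport is untouched:

1. a **bottom-intensified jet**, `1 + exp(−h/150 m)` in height `h` above the
   bed — near-bottom currents over carbonate mounds are observed to exceed
   the surface currents, and strong near-bed flow is what flushes the reef
   laterally;
2. an **internal-wave mode**, a vertical cosine of 600-m wavelength with its
   depth mean removed (zero net transport), phase-locked to the tidal
   envelope. This is an explicit kinematic stand-in for the tidally
   generated internal lee waves that drive large up/downwelling events over
   abrupt topography. Its amplitude (0.27 m s⁻¹) is set so the peak
   diagnosed downwelling over the mound matches the ~0.28 m s⁻¹ event
   magnitudes reported for such settings.

What the generator does **not** emulate: dynamically evolving (non-linear,
breaking) lee waves and hydraulic jumps, their three-dimensional
localization on the flank, stratification, momentum physics of any kind,
and residual (time-mean) circulation — the flow is purely oscillatory by
default (`background_transport` exists but defaults to 0). These absences
matter quantitatively: event-driven delivery in the emulation is spread
along the whole slope rather than concentrated on the reef, so the
coral/off-reef focusing ratio the scenario analysis computes (~3–4 on the
reference domain) sits below the 5–10 range that fully resolved lee-wave
hydrodynamics can sustain, even though the mechanism — filtration on,
focusing appears; filtration off, the habitat classes collapse onto one
deposition–depth curve within a few percent — is reproduced. Passing tests
on this synthetic flow therefore validate the transport/reaction numerics
and the direction of every scenario contrast, not the absolute magnitude of
event-driven OM supply in nature.

## Scenarios and analyses

`integrate_scenario()` advances the tracer with the fixed per-step sequence
*advect (with diagnosed `w` + sinking) → decay → surface flux*. The three
experiment arms are:

* **baseline** — hydrodynamics on, filtration on;
* **no filtration** — hydrodynamics on, enhancement off;
* **no hydrodynamics** — still water: sinking, decay, surface flux and
  filtration only.

`deposition_vs_depth()` joins each column's post-spinup time-mean deposition
with depth and habitat class and summarises coral versus off-reef means in
100-m depth bins; `focusing_factor()` averages the per-bin ratios over bins
containing both classes ("at similar water depth" is enforced by comparing
within bins only). `scenario_compare()` tabulates the three arms per bin and
class; `velocity_extrema()` and `transect_section()` reproduce the
velocity-event and section views.

## Numerical choices

* **Time step** — selected per 6-h flow interval from the CFL bound over
  all faces (safety 0.8, cap 0.05 d), using both bracketing snapshots;
  linear interpolation keeps intermediate speeds inside their range.
  Because the continuity diagnosis is linear in the velocities, the
  interval-endpoint `w` fields are interpolated directly — an identity, not
  an approximation.
* **Splitting order** — advection, then decay, then surface flux; the
  splitting error is first-order, consistent with the advection scheme.
  With `enhancement = 1` the filtration toggle is bit-identical by
  construction (a regression test enforces this).
* **Initial condition** — the quiescent closed-form profile everywhere; a
  configurable spinup window (5 d in the reference scenario) is excluded
  from deposition averages. The spinup boundary is resolved to step
  boundaries.
* **Stretching** — the classic two-parameter hyperbolic sigma stretching
  with the critical-depth parameter taken as 0, so layer thicknesses are
  purely proportional to the stretched sigma spacing; any monotone
  stretching satisfying the column-closure invariant would do, since the
  physics downstream depends only on `Hz`.
* **Budget** — every run carries a ledger of inventory, cumulative surface
  input, decay, deposition and net lateral export; the closure residual is
  checked at every output time (observed at `~1e-14` of input; the test
  bound is `1e-6`).
* **Convergence** — on a quiescent 1000-m, 32-level column the steady
  state matches the closed form within 2% (L∞ normalized by the profile
  maximum) and the error halves at 64 levels; first-order upwind truncation
  dominates.
* **Degenerate inputs** — zero flow returns the capped time step; an empty
  habitat mask warns and proceeds (filtration is then a no-op);
  non-positive depths, reliefs exceeding local depth and CFL violations
  are errors; NaN detection aborts with a state dump.

## Problem sizes

The reference scenario (60 × 40 × 20 cells, 5 d spinup + two spring–neap
cycles ≈ 34.5 simulated days, ~12–15k CFL-limited steps) integrates in
about a minute; the quiescent column oracle runs in seconds. These sizes
were chosen so the full three-arm experiment remains an interactive
desk-scale computation.

## Known limitations

* One OM lability class; refractory background OM is out of scope, so
  modelled concentrations undershoot field measurements that include it.
* Deposition is permanent — no resuspension, no sediment processes.
* The enhancement applies at the bottom face only; when the bottom layer is
  thin this is indistinguishable from enhancing the whole bottom-cell
  settling path.
* The kinematic flow emulation reproduces transport conservation, tidal
  phasing and event magnitudes, but not event localization or residual
  currents (see above); absolute focusing ratios on synthetic flow are
  conservative.
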