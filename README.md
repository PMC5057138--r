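# topopump

Reaction–transport modelling of suspended organic matter (OM) over
cold-water-coral (CWC) carbonate mounds, for benthic ecologists and marine
biogeochemists who want to quantify how tidal flow over abrupt topography
routes fresh organic carbon to deep suspension-feeding communities — and how
much of it leaks past them to the deep seafloor.

## The model

Organic carbon `C` (mmol C m⁻³) is advected offline on a terrain-following
Arakawa C-grid by stored horizontal velocity snapshots. Under a rigid lid
with `w = 0` at the seabed, continuity fixes the vertical velocity on every
layer interface from the flux divergence of the horizontal flow,

    w(k+1) · A = w(k) · A − ∇·(u Hz Δ) |layer k ,

and the tracer obeys

    ∂C/∂t = −∇·(u C) − ∂[(w − ws) C]/∂z − k C ,

with sinking velocity `ws = 20 m d⁻¹`, first-order decay `k = 0.03 d⁻¹`
(e-folding depth `ws/k ≈ 667 m`), a constant export flux of
`12 mmol C m⁻² d⁻¹` through the surface, zero-gradient lateral and bottom
boundaries, and first-order upwind (donor-cell) differencing with no
explicit diffusion. Suspension feeding by the coral community is an
enhanced settling velocity in coral bottom cells (`10 × ws = 200 m d⁻¹`);
the bottom-face settling flux is recorded as deposition. A deterministic
synthetic generator supplies shelf-slope bathymetry with Gaussian mounds
and a shelf-break ridge, a transport-conserving spring–neap tidal flow at
6-h cadence, and a coral habitat mask, so the three scenario experiments
(baseline / no filtration / no hydrodynamics) run at desk scale. See the
vignette (`vignettes/topographic-carbon-pump.Rmd`) for the full account.

## Worked example

```r
library(topopump)
p <- om_params()
steady_column_solution(p, c(0, 250, 500, 1000))
#>   depth   flux concentration
#> 1     0 12.000        0.6000
#> 2   250  8.247        0.4124
#> 3   500  5.668        0.2834
#> 4  1000  2.678        0.1339
capture_efficiency(0.3, 0.2, p$ws_coral)$efficiency
#> [1] 3.858025
```

The quiescent column holds at most `12/20 = 0.6 mmol C m⁻³` of fresh OM,
and its sinking flux e-folds over 667 m — passive supply to a 600-m seabed
is a few mmol C m⁻² d⁻¹ at best. The capture-efficiency check says the
200 m d⁻¹ feeding rate removes only ~3.9% of the OM carried through a
0.2-m feeding layer by a 0.3 m s⁻¹ current.

A small tidal scenario (40 × 30 columns, 12 layers, 8 days):

```r
dom  <- default_domain(nx = 40, ny = 30, n_levels = 12)
flows <- make_tidal_flow(dom$grid, dom$forcing, 0, 8)
cfg  <- scenario_config(TRUE, TRUE, 0, 8, output_cadence = 0.5, spinup = 2)
run  <- integrate_scenario(dom$grid, flows, dom$mask, p, cfg)
run
#> scenario_run: 3012 steps to t = 8 d (hydrodynamics on) (filtration on)
#>   surface input: 7.2e+09 mmol C; deposited: 3879520000 ; decayed: 4459600000 ; lateral export: 641209000
#>   budget residual: -0.000229 mmol C ( 3.18e-14 of input)
dep <- deposition_vs_depth(run, dom$grid, dom$mask)
subset(dep$summary, is.finite(ratio))
#>   bin_top bin_mid n_coral n_off coral_deposition off_reef_deposition ratio
#> 4     400     450      30    10             23.1                4.89  4.73
#> 5     500     550      32     8             25.0                5.28  4.74
#> 6     600     650      24     8             24.9                5.24  4.75
#> 7     700     750      22     8             24.8                5.18  4.79
#> 8     800     850      26     8             22.5                5.06  4.45
focusing_factor(dep)
#> [1] 4.69
```

Deposition on coral columns is several-fold the off-reef deposition in the
same 100-m depth bin: the tidal flow resupplies the near-bed layer that the
enhanced settling strips, *focusing* OM onto the reef. Toggling
`filtration_on = FALSE` collapses the two classes onto one curve; toggling
`hydrodynamics_on = FALSE` starves the deep bins (see
`scenario_compare()`).

The batch interface mirrors the same steps from a YAML config:
`cmd_make_inputs()` writes `grid.nc`/`flow.nc`, `cmd_run()` integrates a
scenario and writes `run.nc` + `budget.csv`, `cmd_analyze()` emits the
deposition, focusing and comparison CSVs.

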