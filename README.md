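# lignosim

Diffusion–reaction simulation of enzymatic lignocellulose hydrolysis with a
finite enzyme pool.

Enzymatic saccharification of pretreated biomass is routinely limited not by
the enzymes' chemistry but by the substrate's morphology: how much cellulose
surface the cellulases can reach, how fast they get there through the pore
network, and whether there are enough of them to cover it. `lignosim` models
one representative biomass particle as a non-shrinking porous cylinder of
radius *R* in a finite, stirred enzyme bath and integrates three coupled
balances on a radial grid:

* free cellulase in the pore fluid `C_E^F(r,t)` — diffusing with effective
  diffusivity `ε·D_pore/τ`, depleted by adsorption, diluted by growing void;
* bound cellulase `C_E^S(r,t)` — a time-dependent Langmuir isotherm
  `dC_S/dt = k_ads·C_F·(C_max(ε) − C_S) − k_des·C_S` on a site capacity that
  declines linearly as cellulose is consumed;
* porosity `ε(r,t)` — each desorption event carries `M_p` glucose units into
  solution: `dε/dt = k_des·C_S·M_p·MM_glu·H_glu / ρ_C^IV`, up to the
  exhaustion porosity set by the substrate's digestibility.

The bulk concentration obeys the surface flux balance, so enzyme depletion —
decisive at low loadings and large particles — is captured. Accessibility
comes from slit-pore geometry: a pore of width *w* contributes `2v/w` wall
area if a 51 Å cellulase reaches both walls (`w ≥ 2d_E`), `v/w` for one wall
(`d_E ≤ w < 2d_E`), nothing below `d_E`; sites per gram are the accessible
area times σ = 2.1·10⁻¹² mol/cm². The two experimental dials are the enzyme
loading `e_l` (mol enzyme per mol initially accessible sites; 1 = exact
full-coverage stoichiometry) and the biomass loading `b_l` (g dry matter per
cm³). The system — `3(n+1)` stiff ODEs by the Method of Lines — is solved
with a BDF integrator (compiled right-hand side, banded Jacobian) and every
run is audited for enzyme mole conservation.

The package is aimed at bioprocess modellers comparing pretreatments and
designing hydrolysis conditions: it simulates yield curves, sweeps
enzyme/biomass loading and particle size in silico, and calibrates the two
free parameters — the lumped hydrolytic capacity `M_p` (glucose per enzyme
binding cycle, an average intrinsic processivity) and the pore tortuosity
`τ` — to measured early-yield data by bounded multi-start least squares.

## Worked example

```r
library(lignosim)

sp  <- synthetic_substrate("severe", seed = 1)  # pretreated hardwood fixture
derive_substrate(sp)
#> Derived substrate accessibility
#>   accessible surface   421502 cm2/g (42.2 m2/g)
#>   site density         8.85153e-07 mol/g (0.885 umol/g)
#>   initial porosity     0.344931
#>   exhaustion porosity  0.562224
#>   C_S,max(0)           7.08123e-07 mol/cm3 total volume

sim <- simulate_hydrolysis(sp, e_l = 1, b_l = 0.02, n = 50,
                           times = c(0, 30, 60, 600, 1440))
summary(sim)
#> Hydrolysis of 'synthetic_severe_seed1' (e_l = 1, b_l = 0.02, R = 0.00122375 cm)
#>  time_min yield_fraction titer_g_per_L mean_coverage bulk_fraction
#>         0         0.0000         0.000        0.0000        1.0000
#>        30         0.3353         3.726        0.9998        0.4072
#>        60         0.5360         5.955        0.9999        0.6498
#>       600         0.8148         9.054        0.9999        0.9861
#>      1440         0.8149         9.054        0.0000        0.9861
#> enzyme mole-balance drift: 1.17e-07 of initial loading
```

Reading the numbers: at full-coverage stoichiometry this highly accessible
25 µm particle saturates its surface within minutes (`mean_coverage ≈ 1`),
the bulk transiently empties to 41 % while enzymes pile onto the walls, and
glucose yield climbs to the digestibility cap (0.815) within ten hours —
after which the surface is gone (`coverage 0`) and the enzymes sit back in
the bulk. The conservation audit confirms the solver lost no enzyme.

Sweeps and calibration follow the same pattern:

```r
sw  <- sweep_hydrolysis(sp, e_l = c(0.5, 1, 2), b_l = 0.02,
                        radius_cm = c(1.25e-3, 0.02, 0.1),
                        times_min = c(60, 600))   # long-format table

ser <- synthetic_severity_series()                     # severity-series benchmark
fit <- fit_hydrolysis(ser$data, ser$substrates)
coef(fit)
#>        M_p        tau
#> 755.001800   2.000012
```

Substrates, scenarios and datasets also load from files (YAML/JSON substrate
specs, CSV pore-size distributions and yield tables — schemas in the help
pages and `inst/extdata/`), and `inst/cli/lignosim.R` wraps the same
functions for shell use (`simulate`, `sweep`, `fit`, `fixture`, `audit`).
See the vignette `vignettes/hydrolysis-model.Rmd` for the model derivation,
numerical scheme and design choices.

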