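# oxyresp

Mechanistic modelling of aerobic soil heterotrophic respiration limited by
oxygen dissolution and diffusion in pore water.

## The problem

Soil microbes respiring organic carbon need dissolved O₂. Gaseous O₂ first
dissolves at the water–air interfaces inside the pore space and then
diffuses through water to the wetted pore walls where aerobic microbes
sit. Both steps resist transport, and both depend on soil saturation Θ
(which reshapes interfaces, wetted walls and the distance between them)
and on temperature T (which raises microbial demand but lowers O₂
solubility). Most soil-carbon models treat moisture and temperature with
separate multiplicative functions; this package implements a
volumetric-average closure in which the two are nonlinearly coupled, for
researchers studying soil respiration, its optimal moisture, and its
temperature sensitivity (Q₁₀ / activation energy).

## The model

Averaging the pore-scale steady O₂ budget over a sample gives a closed
form for the respiration rate

    Ω(Θ, T) = k · A_ws · C_eq · E_r

where `k` is the potential microbial O₂ demand per wetted-wall area
(Arrhenius in T with intrinsic activation energy E_a, Michaelis–Menten in
dissolved organic carbon), `A_ws = A_w Θ^μ` the wetted pore-wall area,
`A_wa = A_a (1+ε−Θ)^σ Θ^τ` the water–air interfacial area, `C_eq(T)` the
Henry's-law O₂ solubility, and

    E_r = [ 1 + (k/α)( (2αL/D) · A_ws/(A_ws+A_wa) + A_ws/A_wa ) ]⁻¹

the emergent feedback factor (hydraulic distance `L = λ A_ws/A_wa`,
aqueous diffusivity `D(T)`, dissolution coefficient `α`). Because demand
grows with warming faster than transport, `E_r` falls with T, Θ and E_a:
the apparent (bulk) activation energy inferred from respiration data is
systematically below the intrinsic one, and the optimal saturation for
respiration shifts drier as soil warms.

The package provides:

* the closed-form model and its diffusion-/dissolution-limited regimes
  (`respiration_rate()`, `feedback_factor()`, `steady_concentrations()`);
* two O₂-physics dialects (`saturated_o2()`, `o2_diffusivity()`): a
  physically consistent `standard` one and an `as_printed` one retained
  for traceability;
* area–saturation parametrization and fitting (`interfacial_areas()`,
  `fit_area_table()`);
* a 2-D steady reaction–diffusion pore-scale solver on text-mask
  geometries that verifies the closure by brute force (`solve_grid()`,
  `closure_error()`; the 1-D film `solve_film()` is exact);
* calibration to respiration data and estimation of the intrinsic
  activation energy (`fit_moisture_response()`, `fit_intrinsic_Ea()`,
  `predict_temperature_response()`, `apparent_Ea()`);
* scenario studies (`optimal_saturation()`, `attenuation_ratio()`,
  `moisture_function()`, `open_surface_study()`);
* seeded synthetic-data generators with known ground truth
  (`generate_respiration_dataset()`, `generate_area_table()`);
* a command-line workbench (`run_workbench()`, launcher in `inst/cli/`).

## Worked example

```r
library(oxyresp)

soil <- model_from_groups(mu = 3, tau = 1, sigma = 1, eps = 0, A = 1,
                          psi_ref = 0.8, Ea = 48000, T_ref = 15)
evaluate_model(soil, Theta = c(0.3, 0.6, 0.9), T = 15)
#>   Theta A_wa  A_ws      L     Er  omega
#> 1   0.3 0.21 0.027 0.1286 0.9884 0.0004
#> 2   0.6 0.24 0.216 0.9000 0.7457 0.0023
#> 3   0.9 0.09 0.729 8.1000 0.1478 0.0015

optimal_saturation(soil, T = 15)$theta_opt   # 0.719
attenuation_ratio(soil, 0.6, 35)             # 0.591
```

At 30% saturation transport barely limits respiration (`Er ≈ 0.99`); at
90% the shrunken interface and long diffusion path suppress it to 15% of
its potential. Warming this soil from 5 to 35 °C at 60% saturation cuts
the feedback factor to 0.59 of its cold value — the attenuation that a
purely Arrhenius analysis would misread as a low activation energy.

Calibration recovers the identifiable dimensionless groups from noisy
synthetic data:

```r
ds  <- generate_respiration_dataset(recovery_ground_truth(),
                                    noise_model(sd = 0.02, seed = 1))
fit <- fit_moisture_response(ds, fit_spec(seed = 1, loss = "log"))
fit
#> Moisture-response fit (converged)
#>      mu     tau   sigma psi_ref   scale
#> 2.02906 1.04996 1.50661 3.15251 0.98377
#> SSE = 0.0121 at T_ref = 15 degC (10 starts, seed 1)
```

(ground truth: mu = 2, tau = 1, sigma = 1.5, psi_ref = 3).

## Command line

```sh
inst/cli/oxyresp simulate --what respiration --out run1 --seed 7
inst/cli/oxyresp fit --in run1.csv --out fit.json --seed 7
inst/cli/oxyresp oracle --fixture square --out square.json
```

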