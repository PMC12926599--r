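# bhrobust

Robust breath-hold lung SBRT planning and probabilistic evaluation.

## What this package is for

Breath-hold (BH) gating manages respiratory motion in lung stereotactic body
radiotherapy (SBRT), but the tumor does not return to exactly the same
position at every hold. `bhrobust` is for medical-physics researchers who
want to study how much that reproducibility limit costs in target coverage,
and how three robust planning strategies compare for photons and protons:

* **3D-PS** — robust optimization against patient-setup shifts only
  (isotropic 5.7 mm, 15 positions);
* **3D-BH** — enlarged setup shifts (7.0 mm) absorbing BH variability;
* **4D-BH** — setup shifts (5.7 mm) combined with seven deformed BH planning
  images (tumor shifts of 4.1 mm).

Since patient breath-hold CTs are not publicly available, the package ships a
synthetic thorax phantom (body, chest wall, two lungs, heart, esophagus,
aorta, spinal cord, spherical CTV) on which the entire pipeline runs
end-to-end with no downloads.

## The model in brief

Positional errors split into systematic (per course, SD $\Sigma$) and random
(per fraction or per breath-hold, SD $\sigma$) per-axis Gaussians; protons
additionally carry a stopping-power-ratio (SPR) uncertainty realised as
discrete range perturbations of $\pm 4.7\%$. Isotropic planning shift
magnitudes are 90% containment radii of isotropic 3D Gaussians,
$r = \sqrt{\Sigma^2+\sigma^2}\,\sqrt{\chi^2_{3,\,0.90}}$.

Reproduced BH geometries are simulated by harmonic (Laplacian) displacement
vector fields: the tumor translates rigidly, the displacement obeys
$\nabla^2 u = 0$ in the surrounding lung, vanishes at the lung wall, and
shifts are clamped so the tumor never leaves the lung; the inverse field
accumulates scenario dose on the reference geometry. Plans are built by
scenario-based minimax optimization (15/45/105/315 scenarios depending on
strategy) with simplified analytic dose engines — an exponential/penumbra
photon model and an analytic Bragg-curve pencil-beam proton model with
constant RBE 1.1 — and every plan is normalized so its worst robust scenario
has CTV D50% = 54 Gy in 3 fractions.

Each plan is then evaluated probabilistically: simulated treatments draw
systematic and per-fraction/per-BH errors, map them to a probability-weighted
grid of 105 deformed images x 15 setup positions x SPR members, accumulate
dose over 3 fractions and per-breath-hold delivery units, and score DVH
metrics (CTV D50%, D2%, D98%, D0%, HI = (D2%-D98%)/D50%; lung V5Gy/V20Gy;
heart, esophagus, aorta, spinal-cord doses). Summaries include **p90%**: the
10th percentile for CTV dose (reached with 90% probability) and the 90th for
HI and organ metrics (not exceeded with 90% probability). Two BH
reproducibility sets are supported: A (used in planning) and the larger B
(evaluation only).

## Worked example

```r
library(bhrobust)
library(dplyr)

# the three shift magnitudes implied by the error model (mm)
um <- uncertainty_model()
c(setup = round(ci90_radius(max(um$Sigma_PS), max(um$sigma_PS)), 1),
  breath_hold = round(ci90_radius(max(um$Sigma_BH_A), max(um$sigma_BH_A)), 1),
  combined = round(ci90_radius_combined(c(max(um$Sigma_PS), max(um$sigma_PS)),
                                        c(max(um$Sigma_BH_A), max(um$sigma_BH_A))), 1))
#>       setup breath_hold    combined
#>         5.7         4.1         7.0

planning_strategies()[, c("name", "setup_radius", "planning_images",
                          "tumor_shift_radius", "n_scenarios")]
#> # A tibble: 6 × 5
#>   name        setup_radius planning_images tumor_shift_radius n_scenarios
#> 1 proton3D-PS          5.7               1                0            45
#> 2 proton3D-BH          7                 1                0            45
#> 3 proton4D-BH          5.7               7                4.1         315
#> 4 photon3D-PS          5.7               1                0            15
#> 5 photon3D-BH          7                 1                0            15
#> 6 photon4D-BH          5.7               7                4.1         105

# a small phantom (5 mm grid) and one strategy, reduced spot grids
sh <- c(40L, 32L, 34L)
phantom <- generate_phantom(grid = voxel_grid(sh, spacing = c(5, 5, 5),
                                              origin = -(sh - 1) * 5 / 2))
plan <- plan_strategy(phantom, "proton4D-BH",
                      pars = dose_engine_params(layer_spacing_mm = 8,
                                                spot_spacing_mm = 8),
                      obj = objective_config(n_shell = 400, n_cw = 200))
glance(plan)
#> # A tibble: 1 × 7
#>   name        modality n_beams n_weights n_scenarios normalization_scale min_robust_ctv_d50
#> 1 proton4D-BH proton         3       208         315                1.01                 54

# probabilistic evaluation, reproducibility set A, 200 simulated treatments
ev <- evaluate_plan(plan, "A", n_samples = 200, seed = 20)
glance(ev)
#> # A tibble: 1 × 5
#>   plan        eval_set n_samples ctv_d50_p90 ctv_d50_med
#> 1 proton4D-BH A              200        58.5        60.7

filter(ev$summary, structure == "CTV", metric == "D50%")
#> # A tibble: 1 × 10
#>   structure metric     n   avg    sd   med   iqr   min   max   p90
#> 1 CTV       D50%     200  60.6  1.54  60.7  1.70  55.6  64.0  58.5
```

Reading this: after normalization the worst robust scenario sits at exactly
54 Gy (`min_robust_ctv_d50`), so the median evaluated D50% is above
prescription, and `p90 = 58.5 Gy` means 90% of simulated treatments achieve
at least that CTV D50% under reproducibility set A. `autoplot(ev)` shows the
metric distribution; `plot_p90_comparison()` compares plans from a full
`run_experiment()`.

The full experiment driver mirrors the study design
(phantoms x 6 strategies x sets A/B):

```r
cfg <- experiment_config(n_phantoms = 14L, n_samples = 10000L, dry_run = TRUE)
run_experiment(cfg)
#> <bh_experiment> 14 phantom(s) x 6 plan(s) x 2 evaluation set(s) x 10000
#>   samples = 1,680,000 simulated treatments (dry run)
```

## Scope notes

The analytic dose engines are a declared substitution for clinical treatment
planning system engines: they reproduce the sensitivity structure that the
robustness comparison needs (range response to SPR and anatomy, penumbra
response to setup error), not clinical dosimetric accuracy. Patient-specific
dose statistics from the underlying study design are not reproducible without
the private CTs; on the phantom, results are qualitative. See the methods
vignette (`vignettes/breath-hold-robustness.Rmd`) for the model, parameter
and design-decision details.
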