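# reflexgait

Predictive simulation of human walking with reflex-based muscle control, in R.

`reflexgait` synthesizes walking **without motion capture data**. A planar
7-segment, 9 degree-of-freedom skeleton (80 kg, 1.88 m) is driven by 8
Hill-type musculotendon units per leg (ILPSO, GMAX, HAMS, RF, VAS, GAS, SOL,
TA). Muscle excitations come from delayed spinal-reflex-style feedback laws —
force feedback `u = G_F F(t−D)`, stretch feedback `u = G_L [l(t−D) − H]₊`,
and rectified PD control `u = [K_p(θ(t−D) − θ_des) + K_d θ̇(t−D)]₊` — switched
by a per-leg gait-mode machine (stance / early swing / late swing). Foot-ground
contact uses compliant Hunt–Crossley spheres,
`GRF_y = k h^1.5 (1 + 1.5 c ḣ)`, with smooth Stribeck friction.

The free controller parameters and the initial state form a 74-entry design
vector optimized with CMA-ES against

```
R = w_fail J_fail + w_vel J_vel + w_head J_head + w_effort J_effort
```

(fall penalty, deadband velocity tracking at 1.5 m/s, head stabilization,
and mass-normalized metabolic effort with a hyperextension penalty;
`w = 5×10⁵, 50, 25, 1`). Walking at a target speed — and its adaptations to
carrying backpack loads (10–40 % body mass) or climbing inclines (5–20°) —
then *emerge* from the optimization. Post-processing covers stride-cycle
extraction, ±1 SD reference-band coverage, Teager–Kaiser EMG onset detection,
and metabolic summaries.

The intended audience is researchers in computational biomechanics and
neuromechanics who want a small, fully scripted, deterministic testbed for
predictive gait simulation.

## Worked example

Simulate level walking from the shipped optimized controller and score it:

```r
library(reflexgait)

z  <- shipped_warmstart()                      # 74-entry design vector
tr <- simulate_walker(z, walking_scenario(duration = 10))
tr
#> <walker_trajectory> 10.00 s simulated at 100 Hz output (1001 samples)
#>   no fall
#>   heel strikes: 32 (R 11 / L 21)

report <- total_objective(tr)
round(report$terms, 4)
#>   J_fail    J_vel   J_head J_effort
#>   0.0000   0.0406   0.0747  11.9701

gc <- extract_mean_stride(tr)                  # 101-point gait-cycle curves
round(c(strides = gc$n_strides, stride_time = gc$stride_time,
        stride_length = gc$stride_length), 3)
#>       strides   stride_time stride_length
#>         8.000         0.903         1.431

round(metabolic_summary(tr)$power_per_kg, 2)   # W per kg unloaded body mass
#> [1] 12.04
```

`J_fail = 0` says the model never fell; the velocity term is inside its
deadband when steps average 1.45–1.55 m/s; `J_effort` is the whole-body
metabolic power per kilogram of carried mass (basal rate included). Loaded or
inclined walking only changes the scenario:

```r
tr20 <- simulate_walker(z, walking_scenario(load_fraction = 0.2))  # +16 kg
trUp <- simulate_walker(z, walking_scenario(incline_deg = 10))
```

and new scenarios are re-optimized by continuation from the level solution:

```r
sol <- continuation(list(walking_scenario(load_fraction = 0.1),
                         walking_scenario(load_fraction = 0.2)),
                    x0 = z, optimizer_settings(lambda = 16, seed = 1))
```

Command-line entry points wrapping these functions live in `inst/cli/`
(`optimize.R`, `analyze.R`).

## Configuration files

| File | Contents |
| --- | --- |
| `inst/extdata/model_planar.yaml` | segment inertia/geometry, joint limits, contact spheres |
| `inst/extdata/mtu_params.csv` | per-muscle Hill parameters, moment-arm curves, delays |
| `inst/extdata/wiring_default.yaml` | declarative reflex wiring + design-vector bounds |
| `inst/extdata/warmstart_level.yaml` | optimized level-walking design vector |

All defaults are documented reconstructions for a nominal 80 kg adult; every
table is editable and re-loadable (`walker_model()`, `mtu_table()`,
`read_wiring()`, `shipped_warmstart()`).
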