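# senliver

Simulation and analysis of a mechanistic ODE model of **acute
senescence-driven liver injury** — for systems biologists and modellers
studying how an initial burden of senescent hepatocytes is either cleared
by a coordinated macrophage response or tips the liver into uncontrolled
inflammation.

## The model

Six dimensionless state variables track deviations from homeostasis:
senescent cells *T*, pro-inflammatory macrophages *M₁*, pro-regenerative
macrophages *M₂*, activated endothelial cells *E*, ECM concentration *C*
and activated myofibroblasts *F*:

    dT/dt   = −K_T·M₂·T − D·T
    dM₁/dt  = B₁·T + E − [G/((C+1)(F+1))]·M₁ − D·M₁
    dM₂/dt  = B₂·T + [G/((C+1)(F+1))]·M₁ − D·M₂
    dE/dt   = B_E·(1+E)·M₁ − D·E
    dC/dt   = B_C·F − K_C·M₂·C − D·C
    dF/dt   = B_F·M₁ − K_F·M₂·F − D·F

starting from `(T_in, 0, 0, 0, 0, 0)`. Senescent cells recruit both
macrophage phenotypes; activated endothelium amplifies inflammatory
recruitment; the M₁→M₂ switch (rate `G`, damped by scar load) drives
resolution; M₂ clears senescent cells, ECM and myofibroblasts. For
`G > B_E − 1` (at `D = 1`) homeostasis is linearly stable and small
injuries resolve, but the basin is finite: a **critical initial senescence
`T_in*`** separates full resolution from runaway inflammation.

The package provides:

* `simulate_injury()` — adaptive RK45 trajectories with outcome
  classification (`resolved` / `unresolved` / `undetermined`), clearance
  times and peak summaries;
* `find_steady_states()` / `stability()` / `regime()` — steady states and
  linear stability from the analytic Jacobian;
* `critical_senescence()`, `tin_star_surface()`, `clearance_sweep()`,
  `dose_response()` — the threshold bisection and parameter studies;
* `generate_dataset()` / `summarize_dataset()` — a seeded generator of
  synthetic per-animal fold-change datasets (doses × days 3/7/14 × 3–5
  animals, log-normal noise) emulating the in vivo readouts (p21,
  CD80/CD86, CD163/CD206, VCAM-1/ICAM-1/ACKR3, αSMA/PDGFRB,
  COL1A1/COL1A2);
* `qualitative_checks()` / `validate_dataset()` — the qualitative
  model-vs-data validation harness (transient rise, day-14 resolution,
  senescence decline, dose ordering, co-directionality);
* `senliver_cli()` — a command-line front end (`inst/cli/senliver`).

## Worked example

```r
library(senliver)

p <- model_params()                    # reference set: all rates = 1
find_steady_states(p)
#> Steady states (regime: resolving )
#>   trivial    [stable]  T=0 M1=0 M2=0 E=0 C=0 F=0
#>   nontrivial [unstable]  T=0 M1=0.3795 M2=0.2321 E=0.6116 C=0.25 F=0.308

tr <- simulate_injury(p, initial_condition(1.4))   # the "Medium" dose
tr
#> Liver-injury trajectory: T_in = 1.4 | t in [0, 500 ] | 1001 stored points
#> Outcome: resolved
peak_summary(tr)
#>   variable peak_value peak_time
#> 1        T     1.4000    0.0000
#> 2       M1     0.3479    0.8449
#> 3       M2     0.6144    1.1001
#> 4        E     0.3225    2.2778
#> 5        C     0.1285    4.1029
#> 6        F     0.1837    1.8028
clearance_time(tr)
#> [1] 1.571765

thr <- critical_senescence(p)
thr
#> Critical initial senescence T_in* = 2.3312  (bracket [2.3309, 2.3315], tol 0.001)
```

Reading: a medium injury (`T_in = 1.4`) drives transient waves of
inflammation (M₁ peaks first), regeneration (M₂), endothelial activation,
myofibroblast activation and ECM deposition, all returning to baseline —
while the senescent load falls to 10% of its initial value by
`t_c ≈ 1.57`. Homeostasis coexists with an unstable positive steady state,
and bisection puts the tipping dose at `T_in* ≈ 2.33`: a dose of 2.2
still resolves, 2.7 inflames without bound.

Synthetic "mouse experiment" and validation:

```r
d <- generate_dataset(p, design = design_config(params = p, cv = 0.2, seed = 11))
validate_dataset(d)
#> Qualitative validation report: 82 evaluable checks, 82 passed; verdict: PASS
```

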