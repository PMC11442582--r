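---
title: "Modelling senescence-driven acute liver injury: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling senescence-driven acute liver injury: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senliver)
```

## The model

`senliver` simulates a six-variable mass-action ODE model of the liver's
response to an acute bolus of senescent hepatocytes. The state variables are
dimensionless deviations from homeostasis: senescent cells $T$,
pro-inflammatory macrophages $M_1$, pro-regenerative macrophages $M_2$,
activated endothelial cells $E$ (all normalised to the homeostatic
endothelial population), ECM concentration $C$ and activated myofibroblasts
$F$ (each normalised to its own homeostatic level). The governing equations
are

$$
\begin{aligned}
\dot T   &= -K_T M_2 T - D\,T,\\
\dot M_1 &= B_1 T + E - \tfrac{G}{(C+1)(F+1)} M_1 - D\,M_1,\\
\dot M_2 &= B_2 T + \tfrac{G}{(C+1)(F+1)} M_1 - D\,M_2,\\
\dot E   &= B_E (1+E) M_1 - D\,E,\\
\dot C   &= B_C F - K_C M_2 C - D\,C,\\
\dot F   &= B_F M_1 - K_F M_2 F - D\,F,
\end{aligned}
$$

with initial condition $(T_{in}, 0, 0, 0, 0, 0)$: the injury deposits a
senescent load into an otherwise healthy organ. Time is normalised on the
macrophage-recruitment timescale (hence the unit-coefficient $E$ term in the
$M_1$ equation), and all ten rates are dimensionless; the reference
parameter set has every rate equal to 1. Senescent cells recruit both
macrophage phenotypes; activated endothelium amplifies recruitment of
inflammatory macrophages, and its activated pool proliferates
($B_E E M_1$); the inflammatory phenotype converts to the pro-regenerative
one at rate $G$, damped by scar load through $(C+1)(F+1)$; and the
pro-regenerative population clears senescent cells, ECM and myofibroblasts.

Two structural facts shape everything downstream. First, homeostasis (the
zero state) is an exact fixed point, and $\dot T \le -D\,T$ pointwise, so
the senescent population is strictly decreasing along every trajectory and
bounded by $T_{in} e^{-Dt}$. Second, the nonnegative orthant is forward
invariant: on each boundary face the inflowing derivative is nonnegative.
Both are enforced as tested invariants rather than assumed.

## Steady states, regimes and the critical dose

Setting $T = 0$ (forced at any steady state by $\dot T = 0$, $D > 0$), the
system admits the trivial steady state and, depending on parameters, one
non-trivial steady state with all other components positive. For $D = 1$
the trivial state is linearly stable precisely when $G > B_E - 1$ — the
*resolving regime*, where the phenotype switch outcompetes endothelial
self-amplification. Outside it, arbitrarily small injuries inflame without
bound. `find_steady_states()` always reports the trivial state and searches
for the non-trivial one numerically: Levenberg–Marquardt on the reduced
five-variable system in log coordinates (which enforces positivity) from 20
log-uniform multi-starts in $[10^{-2}, 10^2]^5$ under a fixed internal
seed, followed by Newton polishing with the analytic Jacobian; candidates
are accepted only with residual $\max|\dot x| < 10^{-10}$. A closed-form
expression for the non-trivial state is not used anywhere; the numerical
route is verified by its residual and by the finite-difference-Jacobian
cross-check in the test suite. The printed stability condition is asserted
against eigenvalues only at $D = 1$; a hand derivation suggests the general
condition is $D(G + D) > B_E$, which reduces to $G > B_E - 1$ at $D = 1$,
but this generalisation is deliberately not asserted.

Within the resolving regime the trivial state's basin along the $T_{in}$
axis is finite: there is a critical initial senescence $T_{in}^*$ separating
full resolution from uncontrolled inflammation. `critical_senescence()`
locates it by bisection on the outcome classifier; with all rates at 1 the
package computes $T_{in}^* \approx 2.331$, consistent with a tolerated
high dose of 2.2 and a supercritical dose of 2.7.

## Numerical choices

*Integration.* deSolve's adaptive Dormand–Prince RK45 with `rtol = 1e-8`,
`atol = 1e-10`, maximum step 1 and horizon `t_end = 500`. The tolerances
are stricter than trajectory plotting requires because bisection needs
sharp outcome classification near the threshold; the convergence helper
`check_convergence()` (re-solve at tolerances/10) and a fixed-step RK4
cross-check in the tests confirm the solutions are converged. Integration
proceeds in 40 segments so that supercritical runs can be stopped as soon
as any component exceeds the blow-up bound ($10^6$). Supercritical
trajectories blow up in *finite* time (e.g. $t^* \approx 9.2$ at
$T_{in} = 2.7$), and the solver discards a segment it cannot complete, so
after a failed segment the integrator creeps forward with geometrically
shrinking steps to establish whether the state diverges (flagged
`unresolved`) or the solver genuinely failed (an error).

*Classification.* `resolved` means every component is below
`eps_res = 1e-3` at the horizon (homeostasis is exactly zero, so a strictly
positive threshold is needed in finite time). `unresolved` means the
blow-up bound was hit, or all five non-senescence components are still
growing over the final tenth of the horizon; the senescent population
always decays, so including it in a "still growing" test would make the
test vacuous. Anything else is `undetermined`, and the bisection responds
by doubling the horizon (up to 8x) before re-classifying — near the
threshold, resolution times diverge, and an explicit `undetermined` state
is preferable to guessing.

*Bisection.* Default bracket $[0.1, 10]$ with geometric expansion
(x2 / ÷2) up to $[10^{-6}, 10^4]$, tolerance $10^{-3}$ on the bracket
width ($10^{-2}$ inside parameter sweeps, where grid steps dwarf it). The
returned estimate is the bracket midpoint; the invariant
`lo` resolves / `hi` does not is checked on return.

*Sweeps.* The threshold surface defaults to 15 log-spaced values of $G$ and
$B_E$ in $[0.2, 8]$, with the $G \le B_E - 1$ region emitted as
`"no resolution"` rather than computed; contours are extracted with
`grDevices::contourLines()`. Clearance sweeps default to 12 log-spaced
values in $[0.25, 8]$ at the Low/Medium/High doses
$T_{in} \in \{0.6, 1.4, 2.2\}$. Supercritical (value, dose) pairs in
clearance sweeps are computed anyway — senescence decays at rate at least
$D$ regardless of the global outcome — but flagged. The acceptance test
suite exercises the same monotonicities on sweep ranges chosen to keep
$T_{in}^*$ in moderate territory (thresholds grow into the hundreds toward
small $B_E$, which adds nothing qualitative at substantial cost).

## The synthetic in vivo data generator

`generate_dataset()` emulates the structure of the animal study the model
was built against: three dose groups (mild/moderate/severe, mapped to
$T_{in} = 0.6, 1.4, 2.2$), cross-sectional sampling at days 3, 7 and 14
with 3–5 independent animals per group and day, and readouts expressed as
fold changes relative to a healthy-control mean of 1 (qPCR-style) or
%field-of-view-style marker scores. Each model variable is read out through
one or more markers (p21 for senescence; CD80/CD86 for $M_1$; CD206/CD163
for $M_2$; ERG$^+$VCAM-1$^+$ co-staining, ICAM1 and ACKR3 for $E$;
aSMA/PDGFRB for $F$; COL1A1/COL1A2 for $C$) through a linear observation
model, fold change $= 1 + \text{gain} \times \text{variable}$. Per-animal
noise is log-normal with median equal to the expected value — fold changes
are positive and right-skewed — with default coefficient of variation 0.55,
back-calculated from the reference dispersion of the p21 readout
(SEM/mean $= 31.53/114.6$ at $N = 4$). Generation is fully deterministic
given the design seed. Ct-level simulation of the qPCR pipeline is
deliberately omitted: it adds parameters with no downstream effect on
fold-change-level analyses.

*Timescale.* The model offers no intrinsic conversion from normalised time
to days, and its transients are fast relative to its resolution tail: the
slowest stable mode at the origin decays at rate $(3-\sqrt 5)/2 \approx
0.38$, so full resolution to $10^{-3}$ takes roughly 16–18 time units
after a peak that occurs near $t \approx 1$. No single linear timescale
can therefore put the inflammatory peak at day 3 *and* resolution at
day 14. The package anchors the one feature the study treats as cardinal —
resolution of every dose group by day 14 — by setting the default
timescale so that day 14 equals the resolution time of the *highest* dose
in the design (anchoring on the medium dose would leave the severe group
measurably unresolved at day 14, contradicting the observations). Under
this anchor the $M_1$ peak maps to roughly day 1.5, consistent with the
early (day-3) CD80 peak in the data. The timescale is a single documented
configuration value, not a fitted quantity.

*Gains.* The p21 gain is calibrated so the moderate-dose day-7 p21 fold
change equals 114.6, the reference value for this injury model. Because
the model clears senescence much faster (in mapped days) than p21 mRNA
decays in tissue, this anchor makes synthetic day-3 p21 values far larger
than observed ones — a known consequence of the model's qualitative
timescale, not a target of the generator. The remaining gains anchor each
marker's severe-dose peak to a plausible peak fold change (strong CD80
response, order-10 macrophage and collagen markers, modest ICAM1/ACKR3
response), chosen once and fixed.

*What the generator does not emulate.* Biological animal-to-animal
covariance across markers (noise is independent per observation),
censoring/attrition, day-to-day batch effects, the dose–recombination
curve linking viral titre to induced senescence, and any delayed p21
kinetics. Passing validation on synthetic data therefore demonstrates
internal consistency of the pipeline, not fidelity of the model to real
tissue.

## The qualitative validation harness

`qualitative_checks()` operationalises the qualitative comparison logic
used to judge the model against the animal data: transient rise, day-14
resolution, senescence decline, dose ordering, and model–data
co-directionality of the day-3 to day-7 change. Three design decisions
matter:

1. **"Comparable to healthy controls" is error-bar overlap.** The
   resolution check passes when
   $|\bar x - 1| \le k\,(\mathrm{SEM}_{group} + \mathrm{SEM}_{control})$
   with $k = 2$ — the visual rule used when a group mean ± SEM is compared
   with a control band. A one-sided "within $k$ SEM of baseline" rule was
   rejected because it is a t-statistic in disguise: it would fail roughly
   10% of the time per marker by construction, making a joint pass over
   ~36 marker-group scopes essentially impossible for data generated from
   the model itself.
2. **Checks are gated on the model predicting a detectable effect.** The
   transient, co-direction and dose-ordering checks are only *evaluable*
   where the noiseless model prediction exceeds the baseline band (or
   predicts a between-group separation) by a detectability margin of
   $(k + z_{power})$ standard errors, $z_{power} = 1.28$. This mirrors the
   study's own reading: mild-dose markers that the model predicts to stay
   near baseline were reported as "comparable to healthy controls" — that
   is agreement, not a failed transient. A notable case is the senescence
   marker's dose ordering: because higher doses recruit more $M_2$ and
   clear senescence *faster*, the model predicts an inverted p21 ordering
   by day 3, so no dose ordering is evaluable for p21 at the sampled days.
3. **Orderings use weak inequalities with 5% relative slack**, absorbing
   sampling noise at $N = 3$–5.

With these rules, data generated from the model (CV 0.2, $N = 4$) pass all
evaluable checks, and over 100 fixed seeds at CV 0.2 with $N = 5$ the full
battery passes in 97 runs — the harness is sensitive enough that targeted
counterexamples (a senescence marker stuck at 50x baseline on day 14; an
inverted dose ordering at the peak day) each fail exactly the intended
check.

## Problem sizes

The test suite and acceptance script run at desk scale: one bisection is
15–25 ODE solves (~15 s at the default tolerances), the stability grid is
5x5, monotonicity sweeps use 12-point grids, and the Monte-Carlo checks
use 100–200 seeded replicates against cached trajectories.

## Known limitations

The model is qualitative: parameters are not calibrated to data, and the
package deliberately provides no fitting machinery. The stability condition
is only asserted at $D = 1$. The timescale mismatch between senescence
clearance and marker kinetics (above) means synthetic p21 magnitudes at
early days are not comparable to published fold changes. Near the critical
dose, classification cost grows as transients linger near the unstable
non-trivial state; the `undetermined` outcome plus horizon doubling makes
this explicit rather than silently misclassifying. No spatial effects,
stochasticity, or distinction between primary and paracrine-induced
senescent cells are modelled.
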