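---
title: "A lumped-parameter model of the left heart and systemic circulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lumped-parameter model of the left heart and systemic circulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`wkheart` simulates the human left heart coupled to the systemic arterial and
venous system as a zero-dimensional ("Windkessel") electrical analogue:
chamber volumes and compliance charges are the state variables, pressures play
the role of voltages, flows of currents, and the two cardiac valves act as
pressure-controlled diodes. This vignette is the package's own account of the
model: its equations and assumptions, the parameters that matter, the
numerical choices, and the design decisions taken where the formulation was
genuinely open — including the known limitations of the reconstruction.

## The model

### Circuit topology

The closed loop holds six dynamic states: atrial volume $V_A$, ventricular
volume $V_V$, the volumes $q_{a1}, q_{a2}$ stored on two viscoelastic arterial
compliances, the volume $q_v$ on the elastic venous compliance, and the aortic
flow $Q_a$ carried by the blood inertance $L$:

$$
\mathrm{LA} \xrightarrow{\;D_{AV}, R_{DAV}\;} \mathrm{LV}
\xrightarrow{\;D_a, R_{Da}, L\;} \underbrace{(C_{a1}, R_{a1})}_{P_{arc}}
\xrightarrow{\;R_a\;} \underbrace{(C_{a2}, R_{a2})}_{P_a}
\xrightarrow{\;R_p\;} \underbrace{C_v}_{P_v}
\xrightarrow{\;R_v\;} \mathrm{LA}
$$

The two arterial compliances are viscoelastic — their node pressures carry a
resistive term in the charge rate, e.g.
$P_{arc} = q_{a1}/C_{a1} + R_{a1}\,\dot q_{a1}$ — so the node pressures and
branch flows form a pair of algebraic relations that are solved exactly as a
$2\times2$ linear system at every right-hand-side evaluation (six
differential plus two algebraic equations in total). Summing the five volume
derivatives gives zero identically, so total blood volume is conserved by
construction and only integrator error can make it drift (tested to stay
below 0.01% over 60 s).

### Ventricle

The Frank–Starling behaviour is anchored by two polynomial curves of the
end-diastolic volume $V_{Ved}$: a passive cubic
$P_{Ved} = a_V V^3$ and an isovolumic-maximum parabola
$P_{Vivmax} = P_{Vivmax,M} - b_V (V_{Ved} - V_{Ved,M})^2$, with
$a_V = P_{Ved,M}/V_{Ved,M}^3$ and $b_V = P_{Vivmax,M}/V_{Ved,M}^2$
(peak 275 mmHg at 200 ml). Contraction is gated by a twitch
$$
f_{Vc}(t) = \exp\!\big[-(k_{V1}|t - t_{Vmax}|)^{i_{V1}}
                       -(k_{V2}|t - t_{Vmax}|)^{i_{V2}}\big],
$$
which peaks at exactly 1 at $t = t_{Vmax}$ (time measured from the sinoatrial
excitation of each beat, i.e. absolute time modulo the 0.8333 s stimulation
period at 72 beats/min). The second, high-exponent term ($i_{V2} \approx 9$)
makes the twitch compact: $f_{Vc} < 0.01$ beyond 0.35 s from the peak, so the
ventricle relaxes essentially completely within one cycle. As the ventricle
empties, fibre stretch falls and the developed stress is de-rated by
$f_{Ve} = 1 - (1/K_e)(-\ln(V_V/V_{Ved}))^{i_e}$ (clamped to 1 during filling,
when $V_V$ transiently exceeds the latched $V_{Ved}$).

The cavity pressure follows the law of Laplace for a thick-walled sphere of
wall volume $V_m$: with $h/r = (V_m/V_V + 1)^{1/3} - 1$ and area factor
$A_V = 2(h/r) + (h/r)^2$, the package computes

$$
P_V = P_{pass}(V_V) + \big(P_{ivmax}(V_{Ved}) - P_{pass}(V_V)\big)\,
      f_{Vc}\, K_{Vc}\, f_{Ve}\, \frac{A_V(V_V)}{A_V(V_{Ved})} .
$$

The active stress is referenced to the end-diastolic geometry and converted
to pressure through the instantaneous geometry. This grouping was a genuine
design decision — the rendered stress equation is typographically ambiguous —
and it was resolved on two grounds. First, at $V_V = V_{Ved}$ the area ratio
is 1, so the Frank–Starling anchors hold exactly: persistent full activation
yields $P_{ivmax}(V_{Ved})$ and zero activation the passive cubic. Second,
the variant in which the area factor cancels out of $P_V$ altogether cannot
eject to the published end-systolic volume: at $V_V \approx 36$ ml the
de-rated active pressure ($\approx 224 \times 0.224 \approx 50$ mmHg) could
never overcome an aortic pressure near 100 mmHg, and simulations settle at an
ejection fraction of ~45% instead of ~69%. The rising area factor of the
emptying sphere is precisely what sustains cavity pressure through ejection;
the de-rating $f_{Ve}$ counteracts it so that the pressure course stays
physiological. $f_{Ve}$ multiplies only the active term, not the passive
curve, so a fully relaxed ventricle is purely passive at any volume.

$V_{Ved}$ is *latched*: it is sampled at the instant the mitral valve closes
and held until the next closure, making "end-diastolic volume" a genuinely
per-beat quantity.

### Atrium

The atrium is deliberately simpler: a passive quintic
$P_A = a_A V_A^5$ (anchored at 30 mmHg for 100 ml) plus a gated active term
$f_{Ac}\,[P_{Ac,max} - b_A (V_A - V_{A,M})^2]$ with a single-term twitch
$f_{Ac} = \exp[-(k_A |t - t_{Amax}|)^{i_A}]$. With $k_A = 24$ 1/s and
$i_A = 7$ the atrial kick is narrow (half-width ≈ 40 ms) and centred at
$t_{Amax} = 0.12$ s.

For both twitches the rate constants multiply the time difference,
$(k\,|\Delta t|)^i$. The division form $(|\Delta t|/k)^i$ with $k \approx 5$–24
would make the exponent negligible over a whole cycle and the chambers would
never relax — incompatible with any pulsatile pressure trace — so the
multiplicative grouping is the only viable reading.

### Valves

Valves are two-state resistances: the open value from the parameter table,
$10^4$ mmHg·s/ml when closed (a small, deliberate leak; the per-beat backward
volume stays below 0.5% of forward flow). The mitral branch is purely
resistive, so switching on the sign of the forward pressure drop
$P_A - P_V$ coincides with flow reversal. The aortic branch carries the
inertance, and there the pressure rule is ill-posed: the arch node pressure
contains $R_{a1}\dot q_{a1}$, which jumps by $R_{a1} Q_a$ the instant the
branch is interrupted, so closing on $P_V < P_{arc}$ makes the drop jump back
positive and the valve chatters (we observed bursts of six switchings within
a millisecond). The package therefore closes the aortic valve on flow
reversal — $Q_a$ falling through zero, with a −0.5 ml/s root offset so that
the near-zero flow at the opening instant cannot re-fire the root — and
re-opens it when $P_V - P_{arc}$ becomes positive again. At the end-ejection
deceleration of order $10^4$ ml/s² the offset mislocates closure by only
~0.05 ms. This is also the physiological sequence: the aortic valve closes at
flow reversal (the dicrotic notch), slightly after the pressure crossover.

## Numerics

Integration uses `deSolve::lsodar` (stiff-capable, with root finding) on a
compiled right-hand side, segment by segment between valve events: within a
segment the valve states are constants, the integrator stops exactly at the
first root of a switching function, the valve flips (and $V_{Ved}$ latches at
mitral closure), and integration restarts. Exact event times are kept with
the trace, so IVCD and ejection duration are measured from events rather than
from grid samples.

Numerical choices that matter:

* **Tolerances** default to `abs_tol = 1e-5`, `rel_tol = 1e-7` with a maximum
  step of 2 ms. The reference settings for this model family (1e-4 / 5e-6)
  leave valve-event localization noise of ~0.03 ms in IVCD — above the 0.01%
  steady-cycle resolution this package also has to verify. At the defaults the
  60 s vs 120 s steady-cycle difference is ~0.0015% and tightening the
  tolerances a further 5× changes steady metrics by far less than 0.01%.
* **Beat-aligned sampling**: the dense-output interval (default 1 ms) is
  rounded so every beat holds an integer number of samples; successive steady
  beats are then sampled at identical phases and per-beat metrics carry no
  grid-phase jitter.
* **(dP/dt)max** is a centred finite difference over the isovolumic window,
  refined by a local quadratic through the three differences around the
  discrete maximum; halving the sampling interval changes it by < 0.1%.
* **Stroke work** is the shoelace area of the beat's $P_V$–$V_V$ polygon
  (1 mmHg·ml = 1.33322e-4 J, fixed in one place); it agrees with the
  time-integral $\oint P_V\,dV_V$ to better than 0.5%, and LV power is
  area × heart rate.
* **Initial conditions**: 120 ml in the ventricle, 60 ml in the atrium, the
  remaining blood distributed over the compliances proportionally to their
  capacitance. The 60 s run-in erases this choice: the steady-cycle criterion
  (every per-beat index changing < 0.01% from its predecessor) is reached
  around beat 15, and doubling the run-in changes nothing above 0.0015%.
* **Determinism**: there is no randomness anywhere; identical configurations
  produce bit-identical traces.

## Calibration

Three quantities are not fixed by the published parameter table and were
calibrated once, against the control-column steady-cycle indexes, then frozen
as package defaults:

| parameter | value | role |
|---|---|---|
| $P_{Ved,M}$ | 35 mmHg | passive stiffness; sets end-diastolic volume and the diastolic $P_V$ floor |
| $V_m$ | 320 ml | ejection amplification through $A_V(V_V)/A_V(V_{Ved})$; sets end-systolic volume / EF |
| total blood volume | 760 ml | loop filling; sets venous/atrial pressures and the arterial working point |

(The volume is the content of the modelled compartments only, not whole-body
blood volume.) With these defaults the control steady cycle reproduces the
published indexes — 125.9/79.2 mmHg arterial pressure, (dP/dt)max
1797 mmHg/s, 114.2/35.9 ml end-diastolic/systolic volumes, IVCD 60.5 ms, EPD
210 ms, EF 68.6%, CO 5643 ml/min, LV power 1.50 W — each within ~1.3% of the
reference values (IVCD within the ±1 ms band).

## The reduced-TCV experiment

A reduction of transmural conduction velocity desynchronizes the onset of
contraction across the ventricular wall. In this lumped model that upstream
physics is represented by exactly two activation parameters: the time to
peak contraction $t_{Vmax}$ (a later peak lengthens the isovolumic
contraction) and the contractility coefficient $K_{Vc}$ (which scales
(dP/dt)max). `wk_scenario()` + `run_comparison()` run the control and the
adjusted parameterization to their steady cycles and report relative deltas;
`calibrate_activation()` solves the inverse problem — given first-cycle
targets for IVCD and (dP/dt)max, find $(t_{Vmax}, K_{Vc})$ by a damped
finite-difference Newton iteration on first-cycle metrics, with residuals
normalized by 1 ms and 5 mmHg/s and convergence declared below 0.5 ms and
2 mmHg/s. First-cycle metrics are evaluated by continuing the integration
from the stored steady control state with the new parameters for one beat,
as the original experiment prescribes.

With the published 50%-TCV adjustment ($t_{Vmax} = 0.3885$ s,
$K_{Vc} = 0.982$) the package reproduces the direction and, for most indexes,
the size of every published effect: (dP/dt)max 1761 vs 1751 mmHg/s, CO 5548
vs 5538 ml/min, LV power 1.452 vs 1.45 W, systolic pressure 124 vs 122 mmHg,
EF 67.7 vs 67%, EPD and end-systolic volume slightly increased, all arterial
pressures slightly decreased.

### Known limitation: the IVCD prolongation

The one published number this reconstruction does not reproduce is the IVCD
under reduced TCV: 76 ms here versus 71 ms. The mechanism is instructive.
IVCD runs from mitral closure to aortic opening. The opening time tracks
$t_{Vmax}$ essentially one-for-one (the twitch threshold at which $P_V$
reaches diastolic aortic pressure simply shifts). Mitral closure, however, is
the crossing of the *rising* ventricular pressure with the *falling* atrial
pressure at the end of the atrial kick. Delaying activation by 31.7 ms pushes
that crossing into the steep collapse of atrial pressure after the twitch
(whose shape is fixed by the published $k_A$, $i_A$, $t_{Amax}$), where the
crossing becomes atrium-driven and nearly phase-locked: closure shifts by
only ~16 ms. The published values imply a shift of ~21 ms. Across the entire
reachable calibration space ($P_{Ved,M}$ 20–60 mmHg, $V_m$ 120–400 ml, total
volume 615–880 ml) the IVCD prolongation stays within 15.0–15.6 ms, so the
discrepancy is structural — most plausibly a difference between this
reconstruction of the circuit (the original equation system was not printed)
and the original's atrial/mitral details — and is reported as such rather
than absorbed by re-tuning. The same mechanism propagates to the inverse
problem: calibrating to the published first-cycle targets (71 ms,
1750 mmHg/s) recovers $t_{Vmax} \approx 0.382$ s and $K_{Vc} \approx 0.971$
instead of the published (0.3885, 0.982), because in this model a smaller
activation delay suffices to lengthen IVCD by 11 ms.

## Stability

`stability_sweep()` re-runs the model with each of the twelve
contractility/valve/vessel parameters perturbed by ±30% and ±50% (48 runs).
All runs converge to a steady cycle within the 60 s run-in; residual
beat-to-beat changes stay below 0.1% (most below 0.01%; a few perturbed
configurations sit near the event-localization noise floor).

## What the model is not

No right heart or pulmonary loop, no baroreflex or heart-rate control, no
beat-to-beat variability, no fibre-level or transmural mechanics (the
upstream finite-element stage enters only through the two activation
parameters), and no strain-energy bookkeeping. External pressure traces can
be read for comparison, but the only metric extracted from them is
(dP/dt)max, since valve events are not observable in a bare pressure trace.

## Problem sizes used in the test suite

The packaged checks simulate 60 s (72 beats) for steady-cycle reproduction,
120 s for the steadiness check, 45–60 s per arm for scenario comparisons,
and 60 s for each of the 48 perturbation runs; unit tests use 3–20 s runs.
A 60 s simulation takes roughly two seconds on one core.
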