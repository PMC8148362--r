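---
title: "Methods: implicit 0D haemodynamics, run-time control, and Kalman calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: implicit 0D haemodynamics, run-time control, and Kalman calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the model, the numerical choices, and the design
decisions behind `cardiolpn`, in the spirit of a lab notebook for
maintainers: what is computed, why each tunable default has the value it
has, and what the synthetic fixtures do and do not establish about real
data.

## 1. The circuit model and its state

A lumped-parameter network (LPN) represents vascular beds under the
standard hydraulic–electric analogy: pressure P (Pa) ↔ voltage, flow Q
(m³/s) ↔ current, volume V (m³) ↔ charge. The component vocabulary is
resistor, capacitor (vessel compliance), inductor (blood inertance),
ideal-diode valve, pressure source, flow source, and time-varying
elastance chamber. All internal computation is SI; converters to the
clinical set (mmHg, mL, mL/s; 1 mmHg = 133.322 Pa) apply only at the
reporting boundary, so no unit ambiguity can enter the dynamics.

The netlist file format is deliberately minimal and line-oriented
(`node`, `component`, `meta` directives) so that models diff cleanly and
round-trip exactly: `parse_netlist(write_netlist(n))` is the identity,
property-tested over randomly generated netlists. Numbers serialise with
`%.17g`, which round-trips IEEE doubles.

Sign conventions: positive flow runs start → end; diodes conduct start →
end only; a flow source's value is flow driven from start to end (a
single-node source injects into its node). Interface nodes are the
attachment points for external forcing and mirror a Dirichlet-to-Neumann
coupling contract: the external side either prescribes the inflow
(entering the Kirchhoff balance) or pins the node pressure (replacing the
balance row). Exactly one forcing per interface node is enforced at run
time.

## 2. Implicit time stepping by modified nodal analysis

The unknown vector is x = [P; Q; V]: pressures at every non-reference
node, the flow through every component, and every chamber volume. One
step from t to t+dt solves M x = b with rows

* Kirchhoff current law at each non-reference node (algebraic),
* one constitutive row per component, with time derivatives discretised
  by backward Euler or the trapezoidal rule,
* one volume-evolution row per chamber (dV/dt = Q).

Both schemes treat every constraint at t+dt, i.e. the DAE is advanced
fully implicitly; there is no operator splitting between the algebraic
and differential parts. Backward Euler is the default because its strong
damping is robust for switched (valve) systems; trapezoidal is available
where second-order accuracy matters and the circuit is smooth.

Two numerical details matter in practice:

* **Equilibration.** SI hydraulic circuits mix matrix entries spanning
  ~16 orders of magnitude (compliances ~1e−9 m³/Pa against resistances
  ~1e8 Pa·s/m³). Every step matrix is row- then column-scaled to unit
  max-norm before QR factorisation; rank checks run on the equilibrated
  matrix with a 1e−12 relative pivot threshold. Without this, singularity
  detection produces false positives on perfectly healthy physiological
  circuits.
* **Consistent initialisation.** The netlist fixes the differential
  states (capacitor pressure differences, inductor flows, chamber
  volumes) but not the algebraic variables. A backward-Euler micro-step
  (dt × 1e−9) solves the algebraic relations and the initial valve
  configuration before the first real step. This is not cosmetic: an
  inconsistent start costs the trapezoidal scheme a full order of
  convergence (measured slope drops from 2 to 1).

Measured against an independent stiff-ODE oracle (deSolve's `lsoda` at
rtol 1e−10, run on separately hand-derived state equations of random
R/C/L ladder networks), trajectories agree to better than 1e−4 relative,
and measured convergence slopes sit within 20% of the nominal orders
(1 backward Euler, 2 trapezoidal).

Factorisations are cached keyed on (parameters, valve states, dt,
scheme), so linear circuits with constant parameters pay one QR per run.

## 3. Valve state resolution

Ideal diodes make the step system piecewise linear: each step must find
an open/closed assignment whose solution is complementarity-consistent
(open ⇒ Q ≥ −tol, closed ⇒ forward ΔP ≤ tol). The search starts from the
previous assignment and flips every violated diode; on a detected cycle,
a singular sub-solve, or the iteration cap, it falls back to exhaustive
enumeration of all 2^d assignments (d ≤ 8) ordered by fewest-open first —
so exact ties resolve deterministically to closed. Tolerances scale with
the run's current flow and pressure magnitudes (1e−6 relative), which
keeps the chatter guard meaningful across unit systems. Every accepted
step's valve states are recorded in the result, and
`check_complementarity()` re-verifies the whole trajectory post hoc.

## 4. Controllers

Controllers are pure update rules `(t, dt, observations, internal) →
(parameter, internal)` bound to a component by control tag (which must
match exactly one component). They execute once per step, pre-solve, in
registration order: the solve at t+dt uses the parameters the controllers
chose after observing the state at t. This explicit coupling is
deterministic and, at 0D step sizes (≤ 1 ms against ≥ 10 ms physiological
time constants), the first-order lag it introduces is far below
discretisation error; iterating controllers to within-step consistency
was considered and rejected as an unverifiable complication. With all
controllers constant the framework is transparent: output is identical to
an uncontrolled run (tested bit-for-bit).

**Elastance waveform.** Chambers pump through a raised-cosine activation:
E rises from E_min to E_max over [0, t_peak], relaxes over t_relax
(default t_peak/2), and stays diastolic for the rest of the cycle. The
shape is C¹, periodic, and fully specified by four clinical parameters;
any smooth single-peaked activation would serve, and nothing downstream
depends on the exact shape.

**Myocardial hunger.** The oxygen deficit of a perfusion territory
integrates supply against demand:

* demand d(t) = α·max(P_chamber·Q_eject, 0) + β — the ventricular
  pressure–flow product during ejection as a workload proxy, plus a basal
  rate;
* supply k_s·q_cor from coronary flow;
* H' = max(0, H + dt·(d − k_s·q_cor)) — no credit is stored for past
  over-supply;
* feedback R_cor = R₀·g(H), g(H) = max(g_min, 1/(1 + k_f·H)) — a
  non-increasing, clamped dilation of the microvascular resistance.

These are deliberately minimal functional forms with the qualitative
behaviour of myocardial autoregulation; fidelity to any particular
published supply/demand model is not claimed. The default gains
(α = 1 unit/J, β = 0.05 unit/s, k_s = 5.5e5 unit/m³, k_f = 20,
g_min = 0.9) were calibrated once against the baseline closed-loop
preset: k_s gives resting supply a ~7% margin over demand (so baseline
hunger oscillates within a cycle but shows no trend), while the
post-reperfusion perturbation at severity 0.6 produces a ~16% deficit —
beyond the 10% autoregulatory reserve implied by g_min — so hunger grows
without bound. The directional contrast (trendless baseline vs continual
growth) is the modelled phenomenon; the absolute hunger scale is
arbitrary units.

## 5. The closed-loop preset and the PRS scenario

`make_closed_loop()` builds one connected circuit: LV chamber → aortic
valve → proximal resistance → systemic arterial compliance → systemic
resistance → venous compliance → tricuspid valve → RV chamber → pulmonary
valve → pulmonary arterial compliance → pulmonary resistance → pulmonary
venous compliance → mitral valve → LV. A four-element coronary branch
(arterial resistance, intramyocardial compliance, tagged microvascular
resistance, venous resistance) taps the arterial node and returns to the
venous node. The systemic and pulmonary beds are lumped R-C elements
closing the loop — the desk-scale stand-in for full 3D arterial domains,
which is exactly what a pure-0D prototyping mode is for.

Defaults are a generic resting adult in clinical units (period 0.8 s,
LV E_max 2.0 mmHg/mL, SVR 1.0 mmHg·s/mL, arterial compliance
1.5 mL/mmHg, venous compliance 50 mL/mmHg, pulmonary resistance
0.08 mmHg·s/mL, coronary total ~30 mmHg·s/mL, stressed volume 800 mL),
chosen once so the converged loop sits at textbook operating points —
the 20-cycle run lands at mean aortic pressure ≈ 90 mmHg (within the
70–110 mmHg band the preset documents), cardiac output ≈ 5.2 L/min,
coronary flow ≈ 2.8 mL/s. Initialisation distributes the declared total
stressed volume across the compartments (fixed arterial/pulmonary/
intramyocardial starting pressures; the venous compartment absorbs the
remainder), so stored volume at t = 0 equals the declared total exactly,
and the implicit schemes conserve it to solver tolerance thereafter
(drift < 1e−10 relative over 20 cycles).

The post-reperfusion-syndrome map `apply_prs(p, s)` scales systemic
resistance by (1 − 0.5 s), pulmonary resistance by (1 + s), and loads the
venous compartment with 150·s mL of extra volume. s = 0 is the identity
and every effect is monotone in s. The multiplier magnitudes are this
package's own calibration, chosen to produce the defining haemodynamic
signature at moderate severity — lower mean arterial pressure, higher
pulmonary and central venous pressure (verified directionally in the
tests) — not patient-specific values.

## 6. Synthetic observations

`gen_observations()` samples named channels of a simulation on its output
grid and adds i.i.d. zero-mean Gaussian noise per channel, reproducibly
by seed. This emulates time-resolved catheter/flow-probe measurements
well enough to exercise the calibrator. It does **not** emulate real
measurement pathologies: correlated or heteroscedastic noise, baseline
drift, beat-to-beat physiological variability, timing jitter, or model
discrepancy (the filter's forward model is the same family that generated
the data). Passing the recovery tests therefore demonstrates the
estimator's correctness and identifiability behaviour, not clinical
robustness.

## 7. The reduced-order unscented Kalman filter

The calibrator works in the low-dimensional parameter space:

* **Simplex sigma points**: p+1 equally weighted points with exact first
  and second moments (built from an orthogonal complement of the constant
  vector), the minimal set — model runs are the entire cost, so economy
  matters.
* **Log transform** by default: corrections act on log-parameters, so
  physical values stay strictly positive regardless of innovation size.
* **Per-particle persistent state**: each sigma particle carries its own
  model state between corrections; the state is never directly corrected,
  only parameters are. This targets the boundary-condition-parameter
  estimation use case and is robust for stiff switched circuits.
* **Windowed innovations**: one correction consumes the stacked vector of
  all observation samples since the previous correction (default 100
  samples). Single-sample corrections proved information-poor — with a
  periodic signal they can alias onto phases where a parameter is
  unobservable (e.g. sampling a Windkessel's proximal resistance only at
  zero-flow instants) — whereas a window spanning a half-cycle sees every
  phase.
* **Forgetting factor** (default 0.95; the recovery studies use 0.9 and
  the flagship scenario 0.85): the covariance factor is inflated by
  1/√ρ before each correction. Early innovations are dominated by the
  startup transient and by inherited state mismatch; without inflation
  the covariance collapses onto those biased corrections and the filter
  freezes off-truth.
* **State re-centring** (default on): after each correction all particle
  states collapse onto their ensemble mean, so the next window's
  predicted-observation spread reflects parameters only, not divergent
  state histories.

Observation noise handed to the filter scales with the observed signal's
standard deviation (10% of signal sd for noiseless records, the true sd
when noise is present), which keeps draws with different impedance levels
comparably weighted. Convergence is flagged when every estimate changes
by < 1e−3 relative over the last 10 corrections. The covariance update
P⁺ = LLᵀ − K P_zz Kᵀ is re-symmetrised and eigenvalue-floored at 1e−12
before refactoring.

Performance on the package's own study conditions: the flagship
3-element Windkessel scenario (noiseless inlet pressure, 50%-off guesses)
recovers all three parameters to ≈ 0.2% within 50 corrections; over 20
randomised truths (log-uniform within a decade) the median error is
≈ 0.05% noiseless and ≈ 0.25% at 5% noise, with the worst-parameter error
envelope non-increasing over the last half of corrections in every draw.
The exact covariance factorisation used by production ROUKF
implementations is not reproduced here; equivalence is claimed only at
the level of parameter-recovery behaviour, which is what the tests and
the acceptance script measure.

## 8. Problem sizes and runtimes

The test and acceptance workloads are sized for a single CPU: closed-loop
runs use dt = 1 ms for 20 cycles of 0.8 s (16,000 implicit steps, ~15 s);
oracle-equivalence studies use 20 random ladders of ≤ 8 components over
2 s; recovery studies use 20 truths × (p+1) particles × 4,000 steps.
These sizes were chosen as the smallest at which the measured properties
(convergence order, conservation, recovery medians) are stable across
seeds.

## 9. Known limitations

* Valve enumeration caps at 8 diodes (2^8 assignments); larger switched
  systems need a smarter combinatorial search.
* No adaptive time stepping; valve opening instants are resolved to dt.
* Controllers couple explicitly (one-step lag by design); a controller
  with dynamics faster than a few dt would need within-step iteration.
* The calibrator assumes observation times lie on the solver grid and
  that the forward model family matches the data-generating process;
  cycle-averaged observation operators are deliberately deferred.
* The closed-loop preset is a structural analogue of a patient-specific
  closed-loop model, not a reproduction of any patient's parameter set.
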