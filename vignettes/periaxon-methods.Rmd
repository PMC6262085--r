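---
title: "Modelling intermittent axonal block under high-frequency stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling intermittent axonal block under high-frequency stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Deep brain stimulation delivers 50–200 Hz trains of brief cathodic current
pulses. Thin myelinated axons are the neural element most readily driven by
such fields, but they cannot follow every pulse indefinitely: potassium
released through axolemmal channels accumulates in the nanometre-wide
peri-axonal space between the axolemma and the myelin sheath, raises the
local K⁺ reversal potential, depolarizes the fibre, inactivates nodal sodium
channels, and intermittently blocks spike initiation. Because blocking
depends on distance from the electrode, axons in a bundle fall into
different block/recovery rhythms and fire asynchronously.

`periaxon` implements this mechanism end to end: a double-cable compartment
model of a 2 mm, 1 µm myelinated axon (21 nodes of Ranvier, 20 internode
parts, each internode split into paranodal junction PNJ, juxtaparanode JXP
and internode IND sections), explicit peri-axonal K⁺ dynamics with Fickian
diffusion and Na/K-pump clearance, extracellular stimulation by an ideal
monopolar point source, and the two summary metrics used in this literature:
the *induction ratio* (reciprocal of the number of pulses between successive
effective action potentials) and the *synchronization ratio* (percentage of
bundle axons firing an effective spike per pulse, smoothed over 10 pulses).

# Model structure

## Geometry

Sections repeat as `NODE, (PNJ, JXP, IND, JXP, PNJ) × 20, NODE` (121
sections). Printed section lengths sum to 99 µm per internode part; we read
the nominal "100 µm internode length" as node-centre-to-centre spacing
(99 µm of internode + 1 µm node), which makes the printed lengths mutually
consistent and gives a total length of 2001 µm ≈ 2 mm. Each IND section
(83 µm) is subdivided into 4 compartments for spatial accuracy (NODE, PNJ,
JXP use 1 each); the subdivision is a solver setting.

The peri-axonal space is a thin annulus of width 1.8 nm at PNJ and 8 nm at
JXP/IND; its volume per compartment is π·d·w·L. K⁺ moves only axially under
the myelin (the sheath is treated as K⁺-impermeable, following the radial/
axial arrow scheme of the source anatomy) and leaves radially at the nodes,
through a 2.2 µm² path into an infinite bath at 3 mM — an idealization of
perinodal glial buffering. The node "shell" where nodal [K⁺]ₒ is tracked has
a configurable thickness (default 30 nm); because the radial path
equilibrates in microseconds, nodal [K⁺]ₒ stays at ~3 mM regardless of this
choice, and the tests assert that outcome rather than the width.

Axial diffusion areas are the published per-section values (IND and JXP
0.02 µm², PNJ 0.004 µm²); a link between unlike sections takes the smaller
(bottleneck) area, so the PNJ→node-shell link uses 0.004 µm². Link distances
are centre-to-centre (standard finite-volume convention; the source gives
areas but not distances).

## Electrical circuit

Each myelinated compartment is a double cable: the axolemma (1 µF/cm²,
0.1 mS/cm² leak at −66 mV, channels, pump) faces the peri-axonal node, and
the myelin sheath (0.1 µF/cm², 1 mS/cm², whole-sheath effective values — the
15 lamellae are geometric metadata) connects the peri-axonal node to the
imposed extracellular potential. Peri-axonal nodes are linked axially with a
longitudinal resistance computed from the peri-axonal cross-section and a
peri-axonal resistivity defaulting to the axoplasmic 70 Ω·cm (the source
names the double-cable structure but prints no peri-axonal resistivity; the
value is configurable). At nodes the axolemma faces the extracellular
potential directly through the electrically negligible shell.

The stimulus is an ideal monopolar point source in an infinite homogeneous
medium, φ = I/(4πσr) with σ = 0.286 S/m, applied as the extracellular
potential of every compartment during each rectangular cathodic pulse and
zero between pulses.

## Potassium dynamics

Channel K⁺ currents feed the adjacent extracellular compartment (K_M at
nodes → node shell; K_f at JXP → JXP peri-axonal space); the electrogenic
Na/K pump (3 Na⁺ out / 2 K⁺ in, one net charge per cycle, hence a factor 2
between its charge current and its K⁺ flux) removes K⁺ from every adjacent
compartment and appears as a membrane current everywhere. Intracellular
concentrations are constant (K⁺ 106 mM, Na⁺ 10 mM), as the constant
parameter tables of the source imply; the non-specific leak carries no K⁺.
E_K is recomputed from the Nernst equation at 37 °C every step, making
E_K(106→3 mM) ≈ −95 mV initially.

At rest the model is *almost* quiescent: the pump steadily removes K⁺ while
only a small juxtaparanodal rectifier tail releases any, so quiescent
peri-axonal [K⁺]ₒ equilibrates between about 2.6 mM (mid-internode) and
3.9 mM (JXP) rather than exactly at bath. A per-compartment constant
balancing current, computed once at initialization, cancels the residual
electrical rest current so the membrane itself holds −66 mV within a
fraction of a millivolt for seconds of unstimulated integration.

# Channel kinetics: the calibrated part

The source model adopts its Na_T/K_M/K_f rate equations from the pyramidal-
axon literature but does not print them. `periaxon` therefore treats the
kinetics as a data-driven `channel_set()`: every gate has a sigmoid steady
state and a bell-shaped time constant, serializable to YAML so alternative
published kinetics can be dropped in without code changes. The shipped
default, `pyramidal_default`, was calibrated against printed observables:

1. single cathodic 0.1 ms pulses from rest elicit propagating spikes across
   source distances 20–120 µm and intensities 0.1–0.5 mA;
2. sustained baseline depolarization to about −53 mV abolishes initiation
   (the block boundary reported for the intermittent-block regime);
3. with peri-axonal [K⁺]ₒ clamped at 3 mM, 130 Hz / 0.2 mA at 50 µm yields
   one action potential per pulse for the whole train;

with the single-axon intermittent-block observables (steady induction ratio
near 25 %, juxtaparanodal [K⁺]ₒ cycling between ≈16.5 and ≈20.8 mM, rise
beyond 14 mM within the first four pulses) used to select among parameter
sets satisfying 1–3, since three constraints under-determine eight rate
curves.

Salient features of the calibrated set, and why they matter:

* **Na_T activation is deliberately not instantaneous** (τ_m ≈ 0.13 ms,
  midpoint −40.5 mV, m³). During the 0.1 ms stimulus artifact the node is
  driven hundreds of millivolts positive, where sodium current is *outward*;
  instantaneous activation would discharge the membrane during the pulse and
  leave the node too hyperpolarized to launch a spike at strong coupling.
* **Inactivation is steep** (midpoint −62 mV, slope 3 mV, τ fast at spike
  voltages, a few ms around rest). With ḡ_Na = 2 S/cm², even h ≈ 10⁻² leaves
  a conductance far above leak, so genuine depolarization block requires
  deep inactivation over a narrow voltage range just above rest.
* **K_f is a high-order rectifier** (n⁶, midpoint −60.5 mV, per-gate slope
  12.2 mV, τ ≈ 3.5 ms). The depolarized-block state requires roughly
  1.5 mS/cm² of juxtaparanodal K⁺ conductance near −53 mV (the JXP is
  voltage-clamped by the leak-anchored internode, which dilutes its local
  currents ~20-fold), while the resting "foot" of the same curve must stay
  near leak scale or the quiescent axon leaks K⁺ into the peri-axonal space
  and violates quiescence. A 4th-order gate cannot satisfy both ends of that
  ratio (~25× over 12.6 mV); the 6th-order gate with a shallower per-gate
  slope can. This is a deliberate deviation from the conventional n⁴
  rectifier.
* **K_M is fast and modest** (τ ≈ 2–4 ms, midpoint −40 mV, ḡ 3 mS/cm²). It
  stabilizes the blocked baseline at the node (its reversal stays near
  −95 mV because the node shell stays at bath K⁺) and absorbs the
  post-pulse depolarized tail, preventing a self-sustaining sodium-window
  plateau.

# Numerics

* **Electrical subsystem**: θ-scheme (default θ = 0.5, Crank–Nicolson) over
  the banded double-cable system in absolute potentials (bandwidth 2 after
  interleaving axolemmal and peri-axonal unknowns), unconditionally stable,
  direct banded LU each step. Membrane voltages are the state; absolute
  potentials are reconstructed with the stimulus value of the current step,
  so the pulse-edge discontinuity is treated as occurring at the step start.
* **Gates**: exact exponential (Rush–Larsen) updates at the end-of-step
  voltage.
* **Potassium**: backward-Euler tridiagonal solve along the peri-axonal
  chain with bath links at nodes; channel/pump sources evaluated at the step
  midpoint; *sinks* are made implicit (scaled by ko_new/ko_old) so
  concentrations cannot cross zero even under extreme stimulus transients,
  with recursive step halving as a backstop.
* **Time grid**: dt = 0.005 ms by default; integration steps land exactly on
  pulse edges, eliminating width aliasing at dt comparable to the 0.1 ms
  pulse. Spike-time convergence under dt halving is verified in the test
  suite at the refinement pair 2.5 → 1.25 µs (maximum spike-time shift below
  0.01 ms over a 100 ms stimulated run).
* **Initialization**: analytic rest state (V = −66 mV, gates at steady
  state, [K⁺]ₒ = 3 mM, balancing current cancelling the residual rest
  current) followed by a 200 ms unstimulated settle so the potassium
  subsystem reaches its own pump–diffusion equilibrium; an error is raised
  if the membrane drifts ≥ 0.5 mV (an inconsistent parameter set).
* **Determinism**: there is no randomness anywhere; repeated runs are
  bit-identical.

# Problem sizes and reproduction scope

The source stimulated for one minute; its own results stabilize after about
1.5 s. The packaged experiments therefore run 2–2.5 s and average metrics
over a steady-state window from 1.5 s, which keeps a full figure
reproduction (one single-axon run plus four 11-axon bundle runs) around ten
minutes of CPU time. `ci_mode` cuts durations to 0.5 s for quick end-to-end
checks.

With the shipped kinetics the package reproduces, quantitatively: the
one-per-pulse control with clamped [K⁺]ₒ; the single-axon intermittent
block (steady induction ratio ≈ 20 %, juxtaparanodal [K⁺]ₒ cycling
≈ 15.5–20.8 mM with the initial rise beyond 14 mM within four pulses, nodal
[K⁺]ₒ pinned at 3 mM); blocking of the nearest bundle axon (≈ 8 % at
20 µm); and the near-total desynchronization at 200 Hz or 0.5 mA.
Qualitatively — correct orderings but compressed magnitudes — it reproduces
the distance profile of the bundle (far axons fire more than near ones, but
plateau near 30 % instead of 50 %), the bundle synchronization ratio at
130 Hz/0.2 mA (≈ 20 % vs ≈ 36 %), and the frequency/intensity orderings
(50 > 130 > 200 Hz and 0.1 > 0.3 > 0.5 mA, with the 50 Hz bundle saturating
at ~100 % rather than 88 %). The compressed distance gradient traces to the
per-spike K⁺ load being nearly distance-independent in this kinetics family:
each effective spike deposits ≈ 3–5 mM into the juxtaparanodal space
whatever the field strength, so the far axon's recovery clock ticks at
roughly the same rate as the near axon's. Kinetics in which sub-threshold,
field-dependent K⁺ release dominates would steepen the gradient; within the
constraint set above we did not find such a regime, and we report the
discrepancy rather than tune it away.

Other known limitations, inherited from the modelling choices: monophasic
pulses only (no charge-balanced biphasic waveforms); homogeneous isotropic
volume conductor; no ephaptic coupling between bundle axons; no Na⁺
accumulation (constant 10 mM); no stochastic channel gating; and at the
very strongest couplings (0.5 mA at 20 µm) the model fibre is overdriven by
the pulse itself and stops firing entirely, whereas the source reports
continued intermittent firing.

# Using the package

```{r example}
library(periaxon)

# single axon under 130 Hz, -0.2 mA from 50 um above the central node
ts <- simulate_axon(pulse_protocol(130, -0.2, duration_s = 2.5),
                    point_source(50))
m <- axon_metrics(ts)
steady_state_value(m$induction, c(1500, 2510))

# packaged figure-level experiments
res <- run_experiment("fig4_bundle")
res$summary
```
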