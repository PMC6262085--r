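# periaxon

Biophysical simulation of **intermittent conduction block and
desynchronization of thin myelinated brain axons under high-frequency
electrical stimulation (HFS)**, the regime of clinical deep brain
stimulation (50–200 Hz cathodic pulse trains).

The package is for computational neuroscientists studying how axons respond
to extracellular stimulation. Its core is a double-cable compartment model
of a 1 µm, ~2 mm myelinated axon — 21 nodes of Ranvier and 20 internode
parts, each internode split into paranodal junction (PNJ), juxtaparanode
(JXP) and internode (IND) sections — coupled to explicit potassium dynamics
in the nanometre-scale peri-axonal space between axolemma and myelin:

* transient Na⁺ (Na_T, m³h) and M-type K⁺ (K_M) channels at nodes, fast
  rectifying K⁺ (K_f) at juxtaparanodes;
* K⁺ released by K_M and K_f accumulates in the peri-axonal space, diffuses
  axially by Fick's law *J = D·A·d[K⁺]ₒ/dx*, drains radially to the bath at
  nodes, and is pumped back by the electrogenic Na/K pump
  *I_NaK = I_NaKmax ([K⁺]ₒ/([K⁺]ₒ+K_mK)) ([Na⁺]ᵢ^1.5/([Na⁺]ᵢ^1.5+K_mNa^1.5))
  ((V+150)/(V+200))*;
* the K⁺ reversal potential follows Nernst,
  *E_K = (RT/F)·ln([K⁺]ₒ/[K⁺]ᵢ)*, so accumulated K⁺ depolarizes the fibre
  and intermittently blocks spike initiation through Na⁺ inactivation;
* stimulation is an ideal monopolar point source,
  *φ = I/(4πσr)*, above the central node.

Two metrics summarize the dynamics: the **induction ratio** (100 / number of
pulses between successive action potentials that reach both axon ends) and,
for an 11-axon bundle spaced 10 µm from the source plane, the
**synchronization ratio** (percentage of axons firing per pulse, smoothed
over 10 pulses).

## Worked example

```r
library(periaxon)

ts <- simulate_axon(pulse_protocol(130, -0.2, duration_s = 2.5),
                    point_source(50))   # 130 Hz, 0.2 mA, 50 um above Node 11
m  <- axon_metrics(ts)
steady_state_value(m$induction, c(1500, 2510))
#> [1] 20.52198
range(ts$ko$jxp_node_11[ts$time >= 1500])
#> [1] 15.46801 20.83520
range(ts$ko$node_11_shell)
#> [1] 3.000007 3.000628
```

Read: after the stimulus settles (~1.5 s), only about one pulse in five
evokes a propagating spike (induction ratio ≈ 20 %); juxtaparanodal
[K⁺]ₒ saw-tooths between ≈15.5 and ≈20.8 mM — each spike dumps K⁺, diffusion
and the pump clear it, and firing resumes when the fibre repolarizes —
while [K⁺]ₒ just outside the node stays pinned at 3 mM by the fast radial
path. Clamping [K⁺]ₒ at 3 mM (`run_experiment("fig3_fixed_ko")`) restores
one spike per pulse, isolating peri-axonal K⁺ accumulation as the block
mechanism.

Packaged experiments (`packaged_config()`) reproduce the study figures:
single-axon intermittent block, the clamped-[K⁺]ₒ control, the 11-axon
bundle at 130 Hz/0.2 mA, and frequency (50/130/200 Hz at 0.3 mA) and
intensity (0.1/0.3/0.5 mA at 130 Hz) sweeps. A thin CLI is installed at
`inst/exec/periaxon` (verbs: `run`, `sweep`, `metrics`, `fixtures`,
`validate`, `list`).

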