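---
title: "Models and methods in snsim"
author: "snsim developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in snsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snsim)
```

# The model family

snsim simulates synthetic nervous systems: small-to-medium heterogeneous
networks of conductance-based neurons designed by hand, typically as robot
controllers or as models of invertebrate/vertebrate motor circuits. Units
are fixed throughout: current nA, voltage mV, conductance uS, capacitance
nF, time ms. With these units $\Delta t \cdot I / C_m$ is directly in mV,
so no unit conversions appear anywhere in the engine.

## Neurons

Every neuron is a leaky integrator,

$$C_m \dot V = -G_m (V - V_{rest}) + \textstyle\sum I_{syn} + I_{bias} + I_{app},$$

advanced by explicit forward Euler. **Spiking neurons** add an adaptive
threshold $\tau_\theta \dot\theta = -\theta + \theta_0 + m (V - V_{rest})$;
the neuron fires when $V > \theta$ (strictly — the discrete spike variable
is $\mathrm{sign}(\min(0, \theta - V))$, which is 0 at exact equality, an
event of measure zero in floating point), emits an internal spike value of
$-1$, and resets to $V_{rest}$. With $m > 0$ the threshold rises during
sustained firing (spike-frequency adaptation, interspike intervals
non-decreasing); $m < 0$ produces facilitation. **Ion-channel neurons**
are non-spiking neurons with Hodgkin–Huxley-style currents
$I_{ion} = G_{ion} a_\infty(V)^{p_a} b^{p_b} c^{p_c} (E_{ion} - V)$:
gate $a$ is instantaneous, $b$ and $c$ are first-order states with
sigmoid steady state $z_\infty(V) = 1/(1 + K e^{S(E - V)})$ and
voltage-dependent time constant
$\tau_z(V) = \tau_{max} z_\infty(V) K e^{S(E - V)}$ (implemented exactly
in this product form; some related literature uses the square root of the
exponential factor — we keep the product form as our definition). An
exponent of 0 removes a gate. The persistent sodium preset
`channel_nap()` uses instantaneous activation and one slow inactivation
gate.

Spiking neurons may not carry ion channels: the channel model is defined
here only for the continuous-voltage neuron, and silently attaching
channels to a resetting membrane would change their meaning, so the
constructor rejects it.

## Synapses

*Graded (non-spiking) chemical synapses* have conductance piecewise-linear
in the presynaptic voltage,
$G = \mathrm{clamp}(G_{max}(V_{pre} - E_{lo})/(E_{hi} - E_{lo}),\ 0,\ G_{max})$,
and current $G (E_{syn} - V_{post})$. *Spiking chemical synapses* decay as
$G \leftarrow G (1 - \Delta t/\tau_{syn})$ and reset to $G_{max}$
(element-wise max, so overlapping spikes do not sum beyond $G_{max}$) when
the presynaptic spike arrives, optionally delayed an integer number of
steps through a ring buffer with `max(delay) + 1` rows. *Electrical
synapses* pass $G(V_{pre} - V_{post})$; the bidirectional conductance
matrix is symmetric, and rectified gap junctions build a binary mask
$M_{ij} = [V_j > V_i]$ each step, conduct only down the voltage gradient,
and are symmetrised as $M\odot G_{rec} + (M \odot G_{rec})^T$ so the
charge leaving the source equals the charge entering the target.
Electrical self-coupling is meaningless and the compiler zeroes the
diagonal.

Population-level wiring comes in four schemes. `direct` connects
all-to-all with the conductance scaled by $1/n_{src}$ so the summed
conductance into each target equals the preset's $G_{max}$ (this is what
makes a preset reusable at any population width). `one_to_one` gives
diagonal matrices. `matrix` takes explicit per-parameter matrices, zero
meaning "no synapse". `pattern` replicates a small odd-dimension kernel
at every spatial offset between two identically shaped 2-D sheets —
convolution with zero padding and stride 1. Populations are flattened
**row-major** (cell $(r,c)$ of an $R \times C$ sheet is flat index
$(r-1)C + c$); the flattening order is a free design choice, so we fix
one and test its observable consequences. Pattern connections between
unequal shapes are rejected rather than given ad-hoc semantics.

At most one chemical synapse may exist per ordered neuron pair: the dense
matrix storage holds a single reversal potential per pair, so superposed
chemical synapses cannot be represented faithfully and are a compile
error instead of a silent merge.

## The step schedule

The network is executed as one feedforward pass per timestep ("unfolded
in time"): every quantity computed during step $t$ reads only state from
step $t-1$. The fixed order inside a step is: route external currents;
graded conductances from $V_{last}$; decay + delayed-spike reset of
spiking conductances (reading the buffer); chemical, electrical, ionic
currents from $V_{last}$; membrane Euler step; gate Euler step; threshold
update, spike detection, reset; push the new spike vector into the
buffer; read monitors. A consequence worth knowing: a synapse with delay
$d$ affects its target $d + 1$ steps after the presynaptic spike — one
step of base latency from the unfolding plus $d$ buffered steps. The
delay-fidelity test pins this down with a cross-correlation peak at lag
$d+1$.

**Membrane step factor.** The printed discrete update in our source
material multiplies the whole current sum by $G_m \Delta t / C_m$ while
the sum already contains $-G_m(V - V_{rest})$, which double-counts $G_m$
relative to the stated ODE. We implement the exact Euler step of the ODE,
i.e. factor $\Delta t / C_m$ on
$-G_m(V - V_{rest}) + \sum I$. The two coincide at $G_m = 1\,\mu S$,
which is the value used in every quantitative claim we reproduce.

**Numerics.** Double precision throughout. Gate values are clamped to
$[0,1]$ with a warning if Euler oversteps (a signal that $\Delta t$ is
too large, not something to hide). Any non-finite membrane potential
aborts the run naming the neuron and $\Delta t$. Fractional delays are
rejected rather than rounded. $\Delta t \ge \tau_{syn}$ degrades the
spiking-synapse decay factor and triggers a warning at compile time.

## Backends

The dense backend evaluates the matrix forms with vectorised arithmetic;
the iterative backend loops over every neuron, synapse and channel with
scalar arithmetic. Both follow the identical schedule and are
cross-checked to $10^{-9}$ relative tolerance over 1000-step runs of
randomized mixed networks (the two accumulate sums in different orders,
so bitwise equality is not expected; the leaky dynamics keep rounding
differences from growing). The iterative backend exists precisely to be
this in-package oracle, and to extend to very large sparse networks
without materialising $N \times N$ matrices — though no capacity claims
are made.

# Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `Cm` | nF | 5 | with `Gm = 1` gives the 5 ms membrane time constant typical of SNS designs |
| `Gm` | uS | 1 | unit conductance; makes steady-state voltage (mV) equal applied current (nA) |
| `dt` | ms | 0.1 | $\tau/50$; the benchmark step used in the source design studies |
| `tau_theta` | ms | 1000 | slow threshold drift unless adaptation is the point |
| `tau_syn` | ms | 1 | spiking conductance decay; keep `dt < tau_syn` |
| `delay` | steps | 0 | integer; the effective latency is `delay + 1` steps |

# The synthetic worlds

**Benchmark generator.** Emulates the structure used in simulator
performance studies: dense networks connect every ordered non-self pair;
sparse networks give external input to 8% of neurons, record 12%, and
place exactly $N$ synapses uniformly at random over ordered non-self
pairs without duplicates. Percentages round half away from zero; the
generator therefore requires $N \ge 10$. Autapses are excluded from
benchmarks (supported elsewhere by the recurrent unfolding, but not part
of the benchmark structure). Timing output (mean, 5th/95th percentile
per step) is *reported, never asserted* — wall-clock numbers are
hardware facts, not package invariants. A green benchmark test
establishes structural correctness and reproducibility per seed, nothing
about speed.

**Steering world.** The LiDAR controller is exercised with synthetic
corridor scans (two walls at set perpendicular distances, beams over a
270° arc) rather than a robot middleware. The sensory mapping
$I_{app}(D) = (D^{-1} - D_{max}^{-1})/(D_{min}^{-1} - D_{max}^{-1})$
with unit-conductance sensory neurons makes the steady-state sensory
voltage equal the current numerically: exactly 0 mV at $D_{max}$ and
1 mV at $D_{min}$ — the two deterministic acceptance targets. Sensory
neuron parameters ($C_m = 5$, $G_m = 1$, $V_{rest} = 0$, no bias) are
chosen so these claims hold exactly; the heading synapses share one
conductance scaled across each half of the array, and the speed neuron
carries the stated 1 nA bias with an inhibitory reversal at rest. What
the closed-loop test establishes is a *sign* property (turn away from
the nearer wall, slow down near obstacles), not any trajectory of a real
robot.

**Half-centre oscillator.** The reference parameter tables for the CPG
demo are not available in the source text, so the demo's parameters are
package-chosen and frozen: HC neurons with $C_m = 5$ nF, $G_m = 1$ uS,
$V_{rest} = -60$ mV and a persistent sodium channel
($G_{Na} = 2.5$ uS, $E_{Na} = 50$ mV, instantaneous activation
$K = 1, S = 0.05/\mathrm{mV}, E = -40$ mV, slow inactivation
$K = 0.5, S = -0.2/\mathrm{mV}, E = -50$ mV, $\tau_{max} = 300$ ms);
relay interneurons excited at 2 uS toward $-20$ mV over the
$[-60, -40]$ operating range; crossed inhibition of 2 uS toward
$-80$ mV. The steep slow inactivation is what terminates each burst: the
winning side's sodium current fades until the inhibited side escapes.
A 10 mV initial asymmetry breaks the symmetric equilibrium
deterministically. This set yields ~8 mV oscillations with a ~108 ms
period and a phase offset of 0.50 of a period, stable over 5 s. The
acceptance condition is deliberately qualitative — sustained antiphase
alternation and its disappearance when the crossed inhibition is
removed — because there is no published number for this configuration to
match.

**Randomized property networks.** The backend-equivalence and invariant
suites draw mixed networks (graded, spiking with random delays 0–6,
bidirectional and rectified electrical synapses, both neuron kinds,
≤ 50 neurons) under fixed seeds, with random stimulus streams. They
exercise every dynamical term at once; they do not emulate any
particular biological circuit.

# Serialization and the file boundary

Network documents are versioned JSON: presets in registries keyed by
(uniquified) name, populations/connections referencing them, unknown
fields rejected with the version named. Doubles are written with 17
significant digits because the round-trip contract is *trace identity*,
not approximate equality — 15-digit output was measurably insufficient.
Inside the engine spikes are $0/-1$ (which makes the buffer/reset
algebra a max with $-\delta \odot G_{max}$); at the CSV boundary they
are written as $0/1$, the convention users expect.

# Known limitations

- Dense $N \times N$ storage bounds practical network size; the
  iterative backend avoids the matrices' arithmetic but not their
  construction at compile time.
- Chemical synapse pairs are unique per ordered pair; genuinely parallel
  synapses require an intermediate relay neuron.
- Gate and membrane integration share one global $\Delta t$; stiff
  channel kinetics need a small global step.
- The steering and muscle mappings are open-loop input/output maps here;
  no vehicle kinematics or muscle mechanics are simulated, by design.
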