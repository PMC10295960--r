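# snsim — synthetic nervous systems in R

snsim designs, compiles and simulates **synthetic nervous systems (SNS)**:
hand-built networks of conductance-based neurons and synapses of the kind
used to control robots and to model animal motor circuits. It targets the
regime most neural simulators handle poorly — heterogeneous mixtures of
spiking and non-spiking neurons, cyclic topologies, conductance-based
(reversal-potential) chemical synapses, and electrical synapses — in a
plain three-phase workflow: *design* a network from reusable presets,
*compile* it to flat parameter vectors and matrices, *simulate* it one
timestep at a time with a forward-Euler scheme.

Who it is for: neurorobotics and computational-neuroscience work where
networks are designed (not trained), must run in discrete time against an
external system (a controller loop, a physics engine, a CSV of sensor
data), and need every dynamical term to be inspectable.

## The models

All units are fixed: nA, mV, uS, nF, ms. Every neuron is a leaky
integrator

$$C_m \dot V = -G_m (V - V_{rest}) + \sum I_{syn} + I_{bias} + I_{app},$$

optionally extended with an adaptive firing threshold
($\tau_\theta \dot\theta = -\theta + \theta_0 + m(V - V_{rest})$; spike
when $V > \theta$, reset to $V_{rest}$) or with Hodgkin–Huxley-style
channels $I_{ion} = G_{ion}\, a_\infty(V)^{p_a} b^{p_b} c^{p_c}
(E_{ion} - V)$, including a persistent-sodium preset. Synapses are graded
chemical (conductance piecewise-linear in presynaptic voltage between
$E_{lo}$ and $E_{hi}$), spiking chemical (exponential decay, reset to
$G_{max}$ on spike arrival, integer-step propagation delays through a
ring buffer), and electrical (bidirectional or rectified gap junctions).
Population wiring supports scaled all-to-all, one-to-one, explicit
matrices, and convolution-style kernels between 2-D sheets. Two backends
— dense vectorised and synapse-iterating — produce identical
trajectories and cross-check each other.

## Worked example

A non-spiking sensory neuron drives a leaky integrate-and-fire neuron
through a graded synapse:

```r
library(snsim)

net <- sns_network("demo")
net <- add_population(net, neuron_type("sensor", Cm = 5, Gm = 1, Vrest = 0), 1, "s")
net <- add_population(net, neuron_type("lif", Cm = 5, Gm = 1, Vrest = 0,
                                       spiking = TRUE, theta0 = 1), 1, "out")
net <- add_connection(net, "s", "out",
                      nonspiking_synapse(Gmax = 0.1, Esyn = 20, Elo = 0, Ehi = 1))
net <- add_input(net, "s")
net <- add_output(net, "s", "voltage")
net <- add_output(net, "out", "spike")

model <- compile_network(net, dt = 0.1)
res <- sns_run(model, 3000, Iext = 1)          # 300 ms of 1 nA

round(res$output[3000, 1], 4)                  # sensor voltage
#> 1                                            # mV: Vrest + Iapp/Gm
isi <- diff(which(res$output[, 2] != 0)) * 0.1
c(spikes = sum(res$output[, 2] != 0), mean_isi = round(mean(isi), 3))
#> spikes mean_isi
#>     81    3.619                              # ms between spikes
```

With unit membrane conductance the sensor settles at exactly
`Iapp/Gm = 1` mV; that 1 mV drives the synapse to 0.1 uS, whose current
holds the downstream neuron in a steady ~3.6 ms spiking rhythm.

Worked application networks are included: a 723-neuron Braitenberg-style
LiDAR steering controller (`build_steering_network()`, with the
distance-to-current map `distance_to_current()` and synthetic
`corridor_scan()` inputs), a motoneuron-to-muscle activation sigmoid
(`muscle_activation()`), and a persistent-sodium half-centre oscillator
(`build_hco_demo()`) that produces sustained antiphase bursting:

```r
m <- compile_network(build_hco_demo(), 0.1)
r <- sns_run(m, 50000)                          # 5 s
round(diff(range(r$output[25001:50000, 1])), 2) # oscillation amplitude
#> 7.99                                         # mV, period ~108 ms
```

Networks serialize to versioned JSON (`save_network()` /
`load_network()`, bit-identical traces after a round trip), stimuli and
traces to CSV, and everything is drivable from the shell:

```sh
Rscript inst/cli/snsim.R run --network net.json --steps 1000 --dt 0.1 \
    --inputs stim.csv --out traces.csv --backend dense
Rscript inst/cli/snsim.R demo hco --out hco.csv
Rscript inst/cli/snsim.R benchmark --sizes 50,200 --connectivity sparse
```

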