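# Fixture builders shared across the suite.  All networks are generated in
# code; nothing is read from disk.

# isolated leaky integrator with one input and one voltage monitor
single_neuron_net <- function(Cm = 5, Gm = 1, Vrest = 0, Ibias = 0) {
  net <- sns_network("one")
  net <- add_population(net, neuron_type(Cm = Cm, Gm = Gm, Vrest = Vrest,
                                         Ibias = Ibias), 1, "n")
  net <- add_input(net, "n")
  add_output(net, "n")
}

# spiking neuron with one input, voltage and spike monitors
single_lif_net <- function(Cm = 5, Gm = 1, Vrest = 0, theta0 = 1,
                           tau_theta = 1000, m = 0) {
  nt <- neuron_type(Cm = Cm, Gm = Gm, Vrest = Vrest, spiking = TRUE,
                    theta0 = theta0, tau_theta = tau_theta, m = m)
  net <- sns_network("lif")
  net <- add_population(net, nt, 1, "n")
  net <- add_input(net, "n")
  net <- add_output(net, "n", "voltage")
  add_output(net, "n", "spike")
}

# randomized mixed-kind network: non-spiking + spiking populations, graded,
# spiking (with delays), bidirectional and rectified electrical synapses
random_network <- function(seed, max_neurons = 50) {
  set.seed(seed)
  n_ns <- sample(2:(max_neurons %/% 2), 1)
  n_sp <- sample(2:(max_neurons %/% 2), 1)
  ns <- neuron_type("ns", Cm = runif(1, 2, 8), Gm = runif(1, 0.5, 2),
                    Vrest = runif(1, -70, -50), Ibias = runif(1, 0, 2))
  sp <- neuron_type("sp", Cm = runif(1, 2, 8), Gm = runif(1, 0.5, 2),
                    Vrest = runif(1, -70, -50), Ibias = runif(1, 0, 2),
                    spiking = TRUE, theta0 = runif(1, 0.5, 2) + runif(1, -70, -50),
                    tau_theta = runif(1, 20, 200), m = runif(1, -0.5, 0.5))
  # keep theta above rest so neurons do not fire continuously
  sp$theta0 <- sp$Vrest + runif(1, 0.5, 2)
  net <- sns_network(sprintf("rand%d", seed))
  net <- add_population(net, ns, n_ns, "ns",
                        initial_voltage = runif(n_ns, -70, -50))
  net <- add_population(net, sp, n_sp, "sp",
                        initial_voltage = runif(n_sp, -70, -50))
  sparse <- function(nr, nc, p, gscale = 0.5) {
    W <- matrix(0, nr, nc)
    k <- which(stats::runif(nr * nc) < p)
    W[k] <- runif(length(k), 0.05, gscale)
    W
  }
  graded <- nonspiking_synapse(Gmax = 1, Esyn = -40, Elo = -65, Ehi = -45)
  net <- add_connection(net, "ns", "ns", graded, "matrix",
                        sparse(n_ns, n_ns, 0.2))
  net <- add_connection(net, "ns", "sp", graded, "matrix",
                        sparse(n_sp, n_ns, 0.2))
  spk <- spiking_synapse(Gmax = 1, Esyn = -40, tau_syn = runif(1, 1, 5))
  W <- sparse(n_ns, n_sp, 0.3)
  D <- matrix(0, n_ns, n_sp)
  D[W > 0] <- sample(0:6, sum(W > 0), replace = TRUE)
  net <- add_connection(net, "sp", "ns", spk, "matrix",
                        list(Gmax = W, delay = D))
  net <- add_connection(net, "sp", "sp", spk, "matrix",
                        sparse(n_sp, n_sp, 0.15))
  elec <- electrical_synapse(Gmax = runif(1, 0.05, 0.3))
  rect <- electrical_synapse(Gmax = runif(1, 0.05, 0.3), rectified = TRUE)
  Wel <- sparse(n_ns, n_ns, 0.1, 0.2); diag(Wel) <- 0
  net <- add_connection(net, "ns", "ns", elec, "matrix", Wel)
  Wrc <- sparse(n_sp, n_ns, 0.1, 0.2)
  net <- add_connection(net, "ns", "sp", rect, "matrix", Wrc)
  net <- add_input(net, "ns", width = n_ns)
  net <- add_input(net, "sp", width = n_sp)
  net <- add_output(net, "ns", "voltage")
  net <- add_output(net, "sp", "voltage")
  net <- add_output(net, "sp", "spike")
  net
}

# random stimulus matrix for a compiled model
random_stimulus <- function(model, n_steps, seed, amp = 2) {
  set.seed(seed + 10000L)
  matrix(runif(n_steps * model$L, 0, amp), n_steps, model$L)
}

# brute-force pattern-connection oracle: explicit loop over destination and
# source grid coordinates, independent of expand_pattern()
pattern_oracle <- function(kernel, shape) {
  R <- shape[1]; C <- shape[2]
  u <- (nrow(kernel) - 1) / 2
  v <- (ncol(kernel) - 1) / 2
  P <- matrix(0, R * C, R * C)
  for (pr in seq_len(R)) for (pc in seq_len(C)) {
    for (qr in seq_len(R)) for (qc in seq_len(C)) {
      kr <- u + 1 + (qr - pr)
      kc <- v + 1 + (qc - pc)
      if (kr >= 1 && kr <= nrow(kernel) && kc >= 1 && kc <= ncol(kernel)) {
        P[(pr - 1) * C + pc, (qr - 1) * C + qc] <- kernel[kr, kc]
      }
    }
  }
  P
}

# interspike intervals (in steps) from a 0/-1 spike-state trace
spike_isi <- function(spikes) {
  diff(which(spikes != 0))
}
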