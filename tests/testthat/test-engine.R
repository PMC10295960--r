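test_that("initial state matches definitions", {
  net <- sns_network()
  net <- add_population(net, neuron_type(Vrest = -60), 1, "a")
  nap <- channel_nap(Kh = 1, Eh = -60)  # h0 = 0.5 at V0 = Eh when Kh = 1
  net <- add_population(net, neuron_type(Vrest = -60,
                                         channels = list(nap)), 1, "b")
  net <- add_population(net, neuron_type(spiking = TRUE, theta0 = -58,
                                         Vrest = -60), 1, "c")
  model <- compile_network(net, 0.1)
  st <- sns_init(model)
  expect_equal(st$V, rep(-60, 3))
  expect_equal(st$b[1], 0.5)
  expect_equal(st$theta[3], -58)
  expect_true(all(st$G_spike == 0))
  expect_true(all(st$buffer == 0))
})

test_that("external currents are routed by the input map", {
  net <- sns_network()
  for (nm in c("a", "b", "c")) {
    net <- add_population(net, neuron_type(Cm = 5, Gm = 1, Vrest = 0), 1, nm)
  }
  net <- add_input(net, "b")
  net <- add_input(net, "a")  # permuted registration order
  net <- add_output(net, "a"); net <- add_output(net, "b")
  net <- add_output(net, "c")
  model <- compile_network(net, 0.1)
  r <- sns_step(model, sns_init(model), c(2, 5))
  # one Euler step from rest: V = (dt/Cm) * Iapp
  expect_equal(r$output, c("a:v" = 0.1, "b:v" = 0.04, "c:v" = 0),
               tolerance = 1e-12)
  expect_error(sns_step(model, sns_init(model), 1), "length")
})

test_that("single Euler step matches hand calculation", {
  model <- compile_network(single_neuron_net(Cm = 5, Gm = 1, Vrest = 0), 0.1)
  r <- sns_step(model, sns_init(model), 2)
  expect_equal(unname(r$output), 0.04)  # 0 + (0.1/5) * (0 + 2)
})

test_that("graded synaptic conductance interpolates and clamps", {
  mk <- function(vpre) {
    net <- sns_network()
    net <- add_population(net, neuron_type(Vrest = vpre), 1, "pre")
    net <- add_population(net, neuron_type(Cm = 5, Gm = 1, Vrest = 0), 1, "post")
    net <- add_connection(net, "pre", "post",
                          nonspiking_synapse(Gmax = 1, Esyn = 40,
                                             Elo = 0, Ehi = 20))
    net <- add_output(net, "post")
    compile_network(net, 0.1)
  }
  step1 <- function(vpre) {
    model <- mk(vpre)
    unname(sns_step(model, sns_init(model), numeric(0))$output)
  }
  # G = clamp(Gmax (Vpre - Elo)/(Ehi - Elo)): 0.5, 0, 1
  expect_equal(step1(10), 0.1 / 5 * 0.5 * 40)
  expect_equal(step1(-5), 0)
  expect_equal(step1(25), 0.1 / 5 * 1.0 * 40)
})

test_that("chemical current follows G (Esyn - Vpost)", {
  net <- sns_network()
  net <- add_population(net, neuron_type(Vrest = 20), 1, "pre")  # ramp mid
  net <- add_population(net, neuron_type(Cm = 5, Gm = 1, Vrest = -60),
                        1, "post")
  net <- add_connection(net, "pre", "post",
                        nonspiking_synapse(Gmax = 1, Esyn = -40,
                                           Elo = 10, Ehi = 30))
  net <- add_output(net, "post")
  model <- compile_network(net, 0.1)
  r <- sns_step(model, sns_init(model), numeric(0))
  # G = 0.5 uS, I = 0.5 * (-40 - (-60)) = +10 nA
  expect_equal(unname(r$output), -60 + 0.1 / 5 * 10)
  # at the reversal potential the current vanishes
  net2 <- sns_network()
  net2 <- add_population(net2, neuron_type(Vrest = 20), 1, "pre")
  net2 <- add_population(net2, neuron_type(Cm = 5, Gm = 1, Vrest = -40),
                         1, "post")
  net2 <- add_connection(net2, "pre", "post",
                         nonspiking_synapse(Gmax = 1, Esyn = -40,
                                            Elo = 10, Ehi = 30))
  net2 <- add_output(net2, "post")
  m2 <- compile_network(net2, 0.1)
  expect_equal(unname(sns_step(m2, sns_init(m2), numeric(0))$output), -40)
})

test_that("spiking conductances decay geometrically and reset on spikes", {
  nt <- neuron_type(spiking = TRUE, Vrest = 0, theta0 = 1)
  net <- sns_network()
  net <- add_population(net, nt, 1, "pre")
  net <- add_population(net, neuron_type(Vrest = 0), 1, "post")
  net <- add_connection(net, "pre", "post",
                        spiking_synapse(Gmax = 1, tau_syn = 1, delay = 0))
  net <- add_input(net, "pre")
  model <- compile_network(net, 0.1)  # Tsyn = 0.1
  st <- sns_init(model)
  # seed a conductance by hand and decay one silent step
  st$G_spike[2, 1] <- 1
  st <- sns_step(model, st, 0)$state
  expect_equal(st$G_spike[2, 1], 0.9)
  # silent forever: conductance decays geometrically towards 0
  for (k in 1:50) st <- sns_step(model, st, 0)$state
  expect_equal(st$G_spike[2, 1], 0.9 * 0.9^50)
  # drive the presynaptic neuron over threshold; reset arrives next step
  st <- sns_init(model)
  r <- sns_step(model, st, 100)  # V jumps over theta, spikes, resets
  expect_equal(r$state$delta[1], -1)
  expect_equal(r$state$V[1], 0)
  expect_equal(r$state$G_spike[2, 1], 0)  # not yet visible
  r2 <- sns_step(model, r$state, 0)
  expect_equal(r2$state$G_spike[2, 1], 1)  # max(decay, reset to Gmax)
})

test_that("electrical currents are conservative and rectified ones gated", {
  mk <- function(rectified, v1, v2) {
    net <- sns_network()
    net <- add_population(net, neuron_type(Cm = 5, Gm = 1, Vrest = v1), 1, "n1")
    net <- add_population(net, neuron_type(Cm = 5, Gm = 1, Vrest = v2), 1, "n2")
    net <- add_connection(net, "n1", "n2",
                          electrical_synapse(Gmax = 0.5,
                                             rectified = rectified))
    net <- add_output(net, "n1"); net <- add_output(net, "n2")
    compile_network(net, 0.1)
  }
  # bidirectional: I = g (Vj - Vi) -> (-10, +10) nA, sum 0
  m <- mk(FALSE, -40, -60)
  r <- sns_step(m, sns_init(m), numeric(0))
  expect_equal(unname(r$output),
               c(-40 + 0.02 * -10, -60 + 0.02 * 10))
  # rectified, Vpre > Vpost: current flows, conserving charge
  m <- mk(TRUE, -40, -60)
  r <- sns_step(m, sns_init(m), numeric(0))
  expect_equal(unname(r$output),
               c(-40 + 0.02 * -10, -60 + 0.02 * 10))
  # rectified, Vpre < Vpost: no current at all
  m <- mk(TRUE, -60, -40)
  r <- sns_step(m, sns_init(m), numeric(0))
  expect_equal(unname(r$output), c(-60, -40))
})

test_that("ionic currents follow the gated conductance form", {
  # all exponents zero: Iion = Gion (Eion - V)
  ch0 <- channel_type("leaky", Gion = 2, Eion = 50)
  net <- sns_network()
  net <- add_population(net, neuron_type(Cm = 5, Gm = 1, Vrest = -60,
                                         channels = list(ch0)), 1, "n")
  net <- add_output(net, "n")
  model <- compile_network(net, 0.1)
  r <- sns_step(model, sns_init(model), numeric(0))
  expect_equal(unname(r$output), -60 + 0.02 * (2 * (50 + 60)))
  # instantaneous gate at V = Ea with Ka = 1 contributes exactly 0.5
  ch1 <- channel_type("half", Gion = 2, Eion = 50, pa = 1, Ka = 1,
                      Sa = 0.05, Ea = -60)
  net2 <- sns_network()
  net2 <- add_population(net2, neuron_type(Cm = 5, Gm = 1, Vrest = -60,
                                           channels = list(ch1)), 1, "n")
  net2 <- add_output(net2, "n")
  m2 <- compile_network(net2, 0.1)
  r2 <- sns_step(m2, sns_init(m2), numeric(0))
  expect_equal(unname(r2$output), -60 + 0.02 * (2 * 0.5 * 110))
})

test_that("gate dynamics relax exponentially to steady state", {
  # clamp the membrane by resting it with no currents: V stays at Vrest
  V0 <- -50
  nap <- channel_nap(Gna = 0, Km = 1, Em = -40, Kh = 1, Sh = -0.1,
                     Eh = -60, tau_h_max = 100)
  net <- sns_network()
  net <- add_population(net, neuron_type(Vrest = V0,
                                         channels = list(nap)), 1, "n")
  model <- compile_network(net, 0.01)
  st <- sns_init(model)
  z0 <- st$b[1]
  # fixed point: starting at z_inf(V) the gate must not move
  st1 <- sns_step(model, st, numeric(0))$state
  expect_equal(st1$b[1], z0)
  # analytic relaxation from a displaced value at constant V
  zinf <- 1 / (1 + 1 * exp(-0.1 * (-60 - V0)))
  tau <- 100 * zinf * 1 * exp(-0.1 * (-60 - V0))
  st$b[1] <- 0.9
  nsteps <- 2000L  # 20 ms
  for (k in seq_len(nsteps)) st <- sns_step(model, st, numeric(0))$state
  analytic <- zinf + (0.9 - zinf) * exp(-nsteps * 0.01 / tau)
  expect_equal(st$b[1], analytic, tolerance = 1e-3)
})

test_that("spiking threshold dynamics and reset", {
  # m = 0: threshold never moves
  model <- compile_network(single_lif_net(theta0 = 1, m = 0), 0.1)
  st <- sns_init(model)
  for (k in 1:100) st <- sns_step(model, st, 2)$state
  expect_equal(st$theta[1], 1)
  # V crossing theta emits delta = -1 and resets V to Vrest
  r <- sns_step(model, st, 200)
  expect_equal(r$state$delta[1], -1)
  expect_equal(r$state$V[1], 0)
  expect_equal(unname(r$output), c(0, -1))  # voltage then spike monitor
})

test_that("delayed spikes arrive exactly delay + 1 steps later", {
  for (d in c(0L, 3L)) {
    nt <- neuron_type(spiking = TRUE, Vrest = 0, theta0 = 1)
    net <- sns_network()
    net <- add_population(net, nt, 1, "pre")
    net <- add_population(net, neuron_type(Vrest = 0), 1, "post")
    net <- add_connection(net, "pre", "post",
                          spiking_synapse(Gmax = 1, tau_syn = 1000,
                                          delay = d))
    net <- add_input(net, "pre")
    model <- compile_network(net, 0.1)
    st <- sns_init(model)
    # spike exactly at step 1, then silence
    hist <- integer(0)
    st <- sns_step(model, st, 100)$state
    expect_equal(st$delta[1], -1)
    arrived_at <- NA
    for (t in 2:(d + 6)) {
      st <- sns_step(model, st, 0)$state
      if (is.na(arrived_at) && st$G_spike[2, 1] > 0.5) arrived_at <- t
    }
    expect_equal(arrived_at, 1 + d + 1)
  }
})

test_that("empty network and run() plumbing", {
  model <- compile_network(sns_network(), 0.1)
  st <- sns_init(model)
  r <- sns_step(model, st, numeric(0))
  expect_length(r$output, 0)
  res <- sns_run(model, 0)
  expect_equal(dim(res$output), c(0, 0))
  # constant input equals the explicit per-step series
  m1 <- compile_network(single_neuron_net(), 0.1)
  a <- sns_run(m1, 50, Iext = 1.5)
  b <- sns_run(m1, 50, Iext = matrix(1.5, 50, 1))
  expect_identical(a$output, b$output)
  # shape of a longer run
  net <- random_network(5, max_neurons = 20)
  model <- compile_network(net, 0.1)
  res <- sns_run(model, 200, Iext = random_stimulus(model, 200, 5))
  expect_equal(nrow(res$output), 200)
  expect_equal(ncol(res$output), model$n_out)
  expect_error(sns_run(model, 300, Iext = matrix(0, 100, model$L)),
               "steps x inputs")
})

test_that("divergence is reported with a diagnostic", {
  net <- single_neuron_net(Cm = 1e-9, Gm = 1)
  model <- compile_network(net, 1e6)
  st <- sns_init(model)
  expect_error({
    for (k in 1:100) st <- sns_step(model, st, 1)$state
  }, "non-finite|too large")
})

test_that("dense and iterative backends agree on random networks", {
  for (seed in c(1, 2)) {
    net <- random_network(seed, max_neurons = 24)
    model <- compile_network(net, 0.1)
    Iext <- random_stimulus(model, 150, seed)
    rd <- sns_run(model, 150, Iext = Iext, backend = "dense")
    ri <- sns_run(model, 150, Iext = Iext, backend = "iterative")
    expect_equal(rd$output, ri$output, tolerance = 1e-11)
  }
})
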