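test_that("single neuron compiles to trivial model", {
  net <- sns_network()
  net <- add_population(net, neuron_type(Cm = 2, Gm = 0.5, Vrest = -55), 1, "n")
  model <- compile_network(net, 0.25)
  expect_equal(model$N, 1)
  expect_equal(model$Cm, 2)
  expect_equal(model$Tm, 0.25 / 2)
  expect_true(all(model$Gmax_non == 0))
  expect_true(all(model$Gmax_spike == 0))
  expect_true(all(model$G_elec == 0))
  expect_equal(model$D, 1)
})

test_that("time factors satisfy T * tau = dt", {
  nt_sp <- neuron_type(spiking = TRUE, tau_theta = 7, theta0 = 1)
  net <- sns_network()
  net <- add_population(net, nt_sp, 2, "sp")
  net <- add_connection(net, "sp", "sp",
                        spiking_synapse(tau_syn = 1), "one_to_one")
  model <- compile_network(net, 0.1)
  expect_equal(model$Ttheta * 7, rep(0.1, 2))
  expect_equal(model$Tsyn[model$Gmax_spike > 0], rep(0.1, 2))
  # warn when dt is not below tau_syn
  expect_warning(compile_network(net, 1.5), "tau_syn")
})

test_that("buffer depth is max delay + 1", {
  nt_sp <- neuron_type(spiking = TRUE)
  net <- sns_network()
  net <- add_population(net, nt_sp, 3, "sp")
  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 3] <- W[3, 1] <- 1
  D <- matrix(0, 3, 3); D[1, 2] <- 0; D[2, 3] <- 3; D[3, 1] <- 7
  net <- add_connection(net, "sp", "sp", spiking_synapse(), "matrix",
                        list(Gmax = W, delay = D))
  model <- compile_network(net, 0.1)
  expect_equal(model$D, 8)
  expect_equal(nrow(sns_init(model)$buffer), 8)
  # non-integer delay rejected
  D[1, 2] <- 0.5
  net2 <- sns_network()
  net2 <- add_population(net2, nt_sp, 3, "sp")
  net2 <- add_connection(net2, "sp", "sp", spiking_synapse(), "matrix",
                         list(Gmax = W, delay = D))
  expect_error(compile_network(net2, 0.1), "integer")
})

test_that("all-to-all expansion scales conductance by 1/n_src", {
  ty <- nonspiking_synapse(Gmax = 1)
  b <- expand_all_to_all(ty, 5, 3)
  expect_true(all(b$Gmax == 0.2))
  expect_equal(rowSums(b$Gmax), rep(1, 3))
  expect_equal(expand_all_to_all(ty, 1, 1)$Gmax, matrix(1, 1, 1))
  b2 <- expand_all_to_all(nonspiking_synapse(Gmax = 2), 4, 2)
  expect_equal(sum(b2$Gmax > 0), 8)
  expect_true(all(b2$Gmax == 0.5))
})

test_that("one_to_one and matrix expansions", {
  b <- expand_one_to_one(nonspiking_synapse(Gmax = 2), 3)
  expect_equal(b$Gmax, diag(2, 3, 3))
  expect_equal(b$Esyn[b$Gmax > 0], rep(40, 3))
  # zero entries mean no synapse
  net <- sns_network()
  net <- add_population(net, neuron_type(), 2, "a")
  net <- add_population(net, neuron_type(), 2, "b")
  W <- matrix(c(1, 0, 0, 0.5), 2, 2)
  net <- add_connection(net, "a", "b", nonspiking_synapse(Gmax = 1),
                        "matrix", W)
  model <- compile_network(net, 0.1)
  blk <- model$Gmax_non[3:4, 1:2]
  expect_equal(blk, W)
  expect_equal(sum(model$Esyn != 0), 2)
})

test_that("pattern expansion reproduces the printed 3x3 kernel layout", {
  # kernel letters a..i coded as 1..9, row-major
  K <- matrix(1:9, 3, 3, byrow = TRUE)
  P <- expand_pattern(K, c(3, 3))
  a <- 1; b <- 2; c <- 3; d <- 4; e <- 5; f <- 6; g <- 7; h <- 8; i <- 9
  expected <- rbind(
    c(e, f, 0, h, i, 0, 0, 0, 0),
    c(d, e, f, g, h, i, 0, 0, 0),
    c(0, d, e, 0, g, h, 0, 0, 0),
    c(b, c, 0, e, f, 0, h, i, 0),
    c(a, b, c, d, e, f, g, h, i),
    c(0, a, b, 0, d, e, 0, g, h),
    c(0, 0, 0, b, c, 0, e, f, 0),
    c(0, 0, 0, a, b, c, d, e, f),
    c(0, 0, 0, 0, a, b, 0, d, e))
  expect_equal(P, expected)
  expect_equal(sum(P != 0), 49)
  # degenerate 1x1 kernel is a scaled identity
  expect_equal(expand_pattern(matrix(7, 1, 1), c(2, 3)), diag(7, 6, 6))
  expect_error(expand_pattern(matrix(1, 2, 2), c(2, 2)), "odd")
})

test_that("pattern expansion matches the brute-force oracle", {
  set.seed(42)
  for (rep in 1:10) {
    R <- sample(2:5, 1); C <- sample(2:5, 1)
    ku <- sample(c(1, 3, 5), 1); kv <- sample(c(1, 3, 5), 1)
    K <- matrix(runif(ku * kv), ku, kv)
    expect_equal(expand_pattern(K, c(R, C)), pattern_oracle(K, c(R, C)))
  }
})

test_that("compilation is pure and deterministic", {
  net <- random_network(7)
  m1 <- compile_network(net, 0.1)
  m2 <- compile_network(net, 0.1)
  expect_identical(m1, m2)
})

test_that("chemical nonzero structures are disjoint and duplicates rejected", {
  for (seed in c(3, 11)) {
    model <- compile_network(random_network(seed), 0.1)
    expect_false(any(model$Gmax_non > 0 & model$Gmax_spike > 0))
  }
  net <- sns_network()
  net <- add_population(net, neuron_type(), 1, "a")
  net <- add_population(net, neuron_type(), 1, "b")
  net <- add_connection(net, "a", "b", nonspiking_synapse())
  net <- add_connection(net, "a", "b", nonspiking_synapse(Esyn = -70))
  expect_error(compile_network(net, 0.1), "multiple chemical synapses")
})

test_that("spiking synapses require a spiking source", {
  net <- sns_network()
  net <- add_population(net, neuron_type(), 1, "a")  # non-spiking
  net <- add_population(net, neuron_type(), 1, "b")
  net <- add_connection(net, "a", "b", spiking_synapse())
  expect_error(compile_network(net, 0.1), "non-spiking population")
})

test_that("electrical synapses are symmetric with zero diagonal", {
  net <- sns_network()
  net <- add_population(net, neuron_type(), 3, "p")
  W <- matrix(0, 3, 3); W[1, 2] <- 0.5; W[2, 3] <- 0.25
  net <- add_connection(net, "p", "p", electrical_synapse(), "matrix", W)
  model <- compile_network(net, 0.1)
  expect_equal(model$G_elec, t(model$G_elec))
  expect_equal(diag(model$G_elec), rep(0, 3))
  expect_equal(model$G_elec[1, 2], 0.5)
  expect_equal(model$G_elec[2, 1], 0.5)
})

test_that("io maps route correctly", {
  net <- sns_network()
  net <- add_population(net, neuron_type(), 1, "a")
  net <- add_population(net, neuron_type(), 1, "b")
  net <- add_population(net, neuron_type(), 1, "c")
  net <- add_input(net, "b")
  model <- compile_network(net, 0.1)
  expect_equal(drop(model$Cin %*% 2), c(0, 2, 0))
  # no outputs -> empty output vector each step
  st <- sns_init(model)
  expect_length(sns_step(model, st, 2)$output, 0)
  # every Cout row selects exactly one neuron
  net <- add_output(net, "a")
  net <- add_output(net, "c")
  m2 <- compile_network(net, 0.1)
  expect_equal(rowSums(m2$Cout_v + m2$Cout_s), rep(1, 2))
})
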