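# round half away from zero, so e.g. 12.5% of 100 -> 13
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Structural counts of a benchmark network
#'
#' Benchmark networks follow the canonical structure used for simulator
#' performance studies: in the sparse variant 8% of neurons receive
#' external input, 12% are recorded for output, and the number of
#' synapses equals the number of neurons; in the dense variant every
#' neuron is synaptically connected to every other neuron.
#'
#' @param n_neurons total neuron count (>= 10 so that the rounded input
#'   fraction is at least one neuron).
#' @param connectivity `"sparse"` or `"dense"`.
#' @return list with `n_in`, `n_out`, `n_syn`.
#' @export
benchmark_structure <- function(n_neurons,
                                connectivity = c("sparse", "dense")) {
  connectivity <- match.arg(connectivity)
  if (n_neurons < 10) stop("benchmark networks need at least 10 neurons")
  n_in <- as.integer(round_half_up(0.08 * n_neurons))
  n_out <- as.integer(round_half_up(0.12 * n_neurons))
  n_syn <- if (connectivity == "dense") n_neurons * (n_neurons - 1) else n_neurons
  list(n_in = n_in, n_out = n_out, n_syn = n_syn)
}

#' Generate a synthetic benchmark network
#'
#' Builds a network of `n_neurons` identical neurons split into an input
#' population (receiving one external current each), an output population
#' (each monitored), and a hidden population, wired according to
#' [benchmark_structure()].  Sparse synapses are placed uniformly at
#' random over ordered non-self neuron pairs without duplicates;
#' generation is reproducible for a given `seed`.  Self-synapses are
#' excluded in both variants.
#'
#' @inheritParams benchmark_structure
#' @param kind `"nonspiking"` (graded chemical synapses) or `"spiking"`
#'   (spiking chemical synapses).
#' @param seed integer random seed for sparse synapse placement.
#' @return an `sns_network`.
#' @examples
#' net <- benchmark_network(50, "sparse", seed = 1)
#' n_neurons(net)
#' @export
benchmark_network <- function(n_neurons, connectivity = c("sparse", "dense"),
                              kind = c("nonspiking", "spiking"), seed = 1L) {
  connectivity <- match.arg(connectivity)
  kind <- match.arg(kind)
  st <- benchmark_structure(n_neurons, connectivity)
  n_hid <- n_neurons - st$n_in - st$n_out
  spiking <- kind == "spiking"
  nt <- neuron_type("bench", Cm = 5, Gm = 1, Vrest = 0, spiking = spiking,
                    theta0 = 1, tau_theta = 1000, m = 0)
  ct <- if (spiking) spiking_synapse(Gmax = 0.1, Esyn = 20, tau_syn = 1)
        else nonspiking_synapse(Gmax = 0.1, Esyn = 20, Elo = 0, Ehi = 1)
  net <- sns_network(sprintf("bench_%s_%s_%d", connectivity, kind, n_neurons))
  net <- add_population(net, nt, st$n_in, "inp")
  net <- add_population(net, nt, st$n_out, "out")
  if (n_hid > 0) net <- add_population(net, nt, n_hid, "hid")
  net <- add_input(net, "inp", width = st$n_in)
  net <- add_output(net, "out", mode = "voltage")

  N <- n_neurons
  if (connectivity == "dense") {
    pairs <- which(!diag(TRUE, N), arr.ind = TRUE)  # all ordered non-self
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    set.seed(seed)
    k <- sample.int(N * (N - 1L), N)  # without replacement: no duplicates
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    # map linear index over ordered non-self pairs to (dst, src)
    j <- (k - 1L) %/% (N - 1L) + 1L
    r <- (k - 1L) %% (N - 1L) + 1L
    i <- ifelse(r >= j, r + 1L, r)
    pairs <- cbind(i, j)
  }
  # scatter global (dst, src) pairs into per-population-block payloads
  sizes <- c(inp = st$n_in, out = st$n_out,
             if (n_hid > 0) c(hid = n_hid))
  starts <- cumsum(c(0L, sizes))[seq_along(sizes)]
  names(starts) <- names(sizes)
  block_of <- function(idx) {
    b <- findInterval(idx, starts + 1L)
    names(sizes)[b]
  }
  bi <- block_of(pairs[, 1]); bj <- block_of(pairs[, 2])
  for (dn in names(sizes)) for (sn in names(sizes)) {
    sel <- bi == dn & bj == sn
    if (!any(sel)) next
    W <- matrix(0, sizes[[dn]], sizes[[sn]])
    W[cbind(pairs[sel, 1] - starts[[dn]], pairs[sel, 2] - starts[[sn]])] <-
      ct$Gmax
    net <- add_connection(net, sn, dn, ct, scheme = "matrix", weights = W)
  }
  net
}

#' Time the simulation backends on benchmark networks
#'
#' Compiles a benchmark network at each requested size and measures the
#' wall-clock time per simulation step for each backend, reporting the
#' mean and the 5th/95th percentiles.  The numbers are hardware-dependent
#' and are reported for inspection only, never asserted against reference
#' values.
#'
#' @param sizes integer vector of network sizes.
#' @param connectivity,kind,seed forwarded to [benchmark_network()].
#' @param n_steps steps to time per network.
#' @param dt timestep (ms).
#' @param backends subset of `c("dense", "iterative")`.
#' @return data.frame with columns `size`, `backend`, `mean_ms`, `p5_ms`,
#'   `p95_ms`.
#' @export
time_backends <- function(sizes, connectivity = "sparse",
                          kind = "nonspiking", n_steps = 100, dt = 0.1,
                          seed = 1L, backends = c("dense", "iterative")) {
  rows <- list()
  for (n in sizes) {
    net <- benchmark_network(n, connectivity, kind, seed = seed)
    model <- compile_network(net, dt)
    Iext <- rep(1, model$L)
    for (be in backends) {
      state <- sns_init(model)
      elapsed <- numeric(n_steps)
      for (t in seq_len(n_steps)) {
        t0 <- proc.time()[["elapsed"]]
        r <- sns_step(model, state, Iext, backend = be)
        elapsed[t] <- proc.time()[["elapsed"]] - t0
        state <- r$state
      }
      q <- stats::quantile(elapsed, c(0.05, 0.95), names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        size = n, backend = be, mean_ms = mean(elapsed) * 1000,
        p5_ms = q[1] * 1000, p95_ms = q[2] * 1000)
    }
  }
  do.call(rbind, rows)
}
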