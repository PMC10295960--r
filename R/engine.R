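#' Initialise the simulation state of a compiled model
#'
#' Membrane potentials start at the population's initial voltage (default
#' `Vrest`), thresholds at `theta0`, all spiking synaptic conductances and
#' the spike delay buffer at zero, and every dynamic channel gate at its
#' voltage-dependent steady state \eqn{z_\infty(V_0)}.
#'
#' @param model an `sns_model` from [compile_network()].
#' @return an object of class `sns_state`.
#' @export
sns_init <- function(model) {
  stopifnot(inherits(model, "sns_model"))
  V <- model$V0
  ch <- model$channels
  b <- c_ <- numeric(0)
  if (!is.null(ch)) {
    b <- ifelse(ch$pb > 0, gate_inf(V[ch$neuron], ch$Kb, ch$Sb, ch$Eb), 0)
    c_ <- ifelse(ch$pc > 0, gate_inf(V[ch$neuron], ch$Kc, ch$Sc, ch$Ec), 0)
  }
  structure(
    list(V = V, V_last = V, theta = model$theta0,
         delta = numeric(model$N),
         G_spike = matrix(0, model$N, model$N),
         G_spike_iter = numeric(nrow(model$iter$chem_spk)),
         buffer = matrix(0, model$D, model$N),
         b = b, c = c_, step = 0L),
    class = "sns_state")
}

# sigmoid gate steady state, Eq-style: 1 / (1 + K exp(S (E - V)))
gate_inf <- function(V, K, S, E) 1 / (1 + K * exp(S * (E - V)))

# voltage-dependent gate time constant: tau_max * z_inf(V) * K exp(S (E - V))
gate_tau <- function(V, K, S, E, tau_max) {
  tau_max * gate_inf(V, K, S, E) * K * exp(S * (E - V))
}

#' Advance a compiled model by one timestep
#'
#' Executes one forward-Euler step of every neuron and synapse in the
#' network.  All influences are read from the previous step's state
#' (the network is unfolded in time as a feedforward pass per step), in
#' this order: route external currents; update graded synaptic
#' conductances from presynaptic voltages; decay spiking conductances and
#' reset those whose delayed presynaptic spike has arrived; accumulate
#' chemical, electrical and ionic currents; integrate the membrane; update
#' channel gates; update thresholds, detect spikes (`V > theta`, strict)
#' and reset spiked neurons to `Vrest`; push the new spike vector into the
#' delay buffer; read out the monitors.
#'
#' A spike therefore influences its target no earlier than the next step:
#' a synapse with delay `d` resets its conductance `d + 1` steps after the
#' presynaptic spike.
#'
#' @param model an `sns_model`.
#' @param state an `sns_state`.
#' @param Iext external applied currents (nA), length `model$L`.
#' @param backend `"dense"` (vectorised matrix arithmetic) or
#'   `"iterative"` (explicit loop over neurons and synapses).  Both
#'   produce identical trajectories.
#' @return list with elements `state` (advanced state) and `output`
#'   (numeric vector of monitored voltages (mV) and spike states, in
#'   registration order; spikes are reported internally as 0/-1).
#' @export
sns_step <- function(model, state, Iext = numeric(model$L),
                     backend = c("dense", "iterative")) {
  backend <- match.arg(backend)
  if (length(Iext) != model$L) {
    stop(sprintf("Iext must have length %d, got %d", model$L, length(Iext)))
  }
  if (backend == "dense") step_dense(model, state, Iext)
  else step_iterative(model, state, Iext)
}

step_dense <- function(model, state, Iext) {
  N <- model$N
  Vl <- state$V_last
  Iapp <- if (model$L > 0) drop(model$Cin %*% Iext) else numeric(N)

  Isyn <- numeric(N)
  # graded chemical conductances follow the presynaptic (column) voltage
  if (model$has_non) {
    Vpre <- matrix(Vl, N, N, byrow = TRUE)
    G_non <- model$Gmax_non * (Vpre - model$Elo) * model$inv_range
    G_non <- pmin(pmax(G_non, 0), model$Gmax_non)
  } else {
    G_non <- NULL
  }
  # spiking conductances: multiplicative decay, then delayed-spike reset
  if (model$has_spike_syn) {
    G_spike <- state$G_spike * model$decay
    delayed <- matrix(state$buffer[as.vector(model$delay_lin)], N, N)
    G_spike <- pmax(G_spike, -delayed * model$Gmax_spike)
    state$G_spike <- G_spike
  } else {
    G_spike <- NULL
  }
  if (!is.null(G_non) || !is.null(G_spike)) {
    G <- if (is.null(G_non)) G_spike
         else if (is.null(G_spike)) G_non
         else G_non + G_spike
    Isyn <- rowSums(G * model$Esyn) - Vl * rowSums(G)
  }
  # electrical synapses: bidirectional part plus rectified (masked) part
  if (model$has_elec) {
    Isyn <- Isyn + drop(model$G_elec %*% Vl) - Vl * rowSums(model$G_elec)
  }
  if (model$has_rec) {
    M <- outer(Vl, Vl, function(vi, vj) as.numeric(vj > vi))
    MG <- M * model$G_rec
    MD <- MG + t(MG)
    Isyn <- Isyn + drop(MD %*% Vl) - Vl * rowSums(MD)
  }
  # voltage-gated ionic currents (previous-step gates and voltage)
  Iion <- numeric(N)
  ch <- model$channels
  if (!is.null(ch)) {
    Vc <- Vl[ch$neuron]
    fa <- ifelse(ch$pa > 0, gate_inf(Vc, ch$Ka, ch$Sa, ch$Ea)^ch$pa, 1)
    fb <- ifelse(ch$pb > 0, state$b^ch$pb, 1)
    fc <- ifelse(ch$pc > 0, state$c^ch$pc, 1)
    Ich <- ch$Gion * fa * fb * fc * (ch$Eion - Vc)
    for (k in seq_len(nrow(ch))) {
      Iion[ch$neuron[k]] <- Iion[ch$neuron[k]] + Ich[k]
    }
  }
  # membrane integration (exact Euler of the leaky integrator)
  V <- Vl + model$Tm *
    (-model$Gm * (Vl - model$Vrest) + model$Ibias + Isyn + Iion + Iapp)
  check_finite(V, model)
  # gate dynamics at the previous-step voltage
  if (!is.null(ch)) {
    state$b <- advance_gate(state$b, ch$pb, Vc, ch$Kb, ch$Sb, ch$Eb,
                            ch$tau_max_b, model$dt)
    state$c <- advance_gate(state$c, ch$pc, Vc, ch$Kc, ch$Sc, ch$Ec,
                            ch$tau_max_c, model$dt)
  }
  # adaptive thresholds, spike detection, reset
  delta <- numeric(N)
  sp <- model$spiking
  theta <- state$theta
  if (any(sp)) {
    theta[sp] <- theta[sp] + model$Ttheta[sp] *
      (-theta[sp] + model$theta0[sp] + model$m[sp] * (Vl[sp] - model$Vrest[sp]))
    # spike when V > theta (strict); spiked neurons return to rest
    fired <- sp & V > theta
    delta[fired] <- -1
    V[fired] <- model$Vrest[fired]
  }
  # delay buffer: shift rows down, newest spike vector on top
  state$buffer <- rbind(delta, state$buffer[-model$D, , drop = FALSE],
                        deparse.level = 0)
  out <- if (model$n_out > 0) {
    stats::setNames(drop(model$Cout_v %*% V) + drop(model$Cout_s %*% delta),
                    model$output_names)
  } else numeric(0)
  state$theta <- theta
  state$delta <- delta
  state$V <- V
  state$V_last <- V
  state$step <- state$step + 1L
  list(state = state, output = out)
}

advance_gate <- function(z, p, V, K, S, E, tau_max, dt) {
  act <- p > 0
  if (!any(act)) return(z)
  zi <- gate_inf(V[act], K[act], S[act], E[act])
  tau <- tau_max[act] * zi * K[act] * exp(S[act] * (E[act] - V[act]))
  znew <- z[act] + dt * (zi - z[act]) / tau
  if (any(znew < 0) || any(znew > 1)) {
    warning("channel gate clamped to [0, 1]; consider a smaller dt")
    znew <- pmin(pmax(znew, 0), 1)
  }
  z[act] <- znew
  z
}

check_finite <- function(V, model) {
  if (any(!is.finite(V))) {
    bad <- which(!is.finite(V))[1]
    stop(sprintf("non-finite membrane potential at neuron %d ('%s'); dt = %g ms is probably too large",
                 bad, model$neuron_names[bad], model$dt))
  }
}

# Element-iterating backend: same step schedule, but every neuron, synapse
# and channel is advanced with explicit scalar arithmetic.  Serves as an
# in-package cross-check of the dense matrix formulation.
step_iterative <- function(model, state, Iext) {
  N <- model$N
  Vl <- state$V_last
  it <- model$iter
  Iapp <- numeric(N)
  if (model$L > 0) {
    for (i in seq_len(N)) {
      acc <- 0
      for (l in seq_len(model$L)) acc <- acc + model$Cin[i, l] * Iext[l]
      Iapp[i] <- acc
    }
  }
  Isyn <- numeric(N)
  cn <- it$chem_non
  for (k in seq_len(nrow(cn))) {
    g <- cn$Gmax[k] * (Vl[cn$j[k]] - cn$Elo[k]) / (cn$Ehi[k] - cn$Elo[k])
    g <- min(max(g, 0), cn$Gmax[k])
    Isyn[cn$i[k]] <- Isyn[cn$i[k]] + g * (cn$Esyn[k] - Vl[cn$i[k]])
  }
  cs <- it$chem_spk
  Gs <- state$G_spike_iter
  for (k in seq_len(nrow(cs))) {
    g <- Gs[k] * (1 - cs$Tsyn[k])
    arrived <- state$buffer[cs$delay[k] + 1L, cs$j[k]]
    g <- max(g, -arrived * cs$Gmax[k])
    Gs[k] <- g
    Isyn[cs$i[k]] <- Isyn[cs$i[k]] + g * (cs$Esyn[k] - Vl[cs$i[k]])
  }
  state$G_spike_iter <- Gs
  el <- it$elec
  for (k in seq_len(nrow(el))) {
    cur <- el$G[k] * (Vl[el$j[k]] - Vl[el$i[k]])
    Isyn[el$i[k]] <- Isyn[el$i[k]] + cur
    Isyn[el$j[k]] <- Isyn[el$j[k]] - cur
  }
  rc <- it$rec
  for (k in seq_len(nrow(rc))) {
    if (Vl[rc$j[k]] > Vl[rc$i[k]]) {
      cur <- rc$G[k] * (Vl[rc$j[k]] - Vl[rc$i[k]])
      Isyn[rc$i[k]] <- Isyn[rc$i[k]] + cur
      Isyn[rc$j[k]] <- Isyn[rc$j[k]] - cur
    }
  }
  Iion <- numeric(N)
  ch <- model$channels
  if (!is.null(ch)) {
    for (k in seq_len(nrow(ch))) {
      v <- Vl[ch$neuron[k]]
      f <- ch$Gion[k] * (ch$Eion[k] - v)
      if (ch$pa[k] > 0) {
        f <- f * gate_inf(v, ch$Ka[k], ch$Sa[k], ch$Ea[k])^ch$pa[k]
      }
      if (ch$pb[k] > 0) f <- f * state$b[k]^ch$pb[k]
      if (ch$pc[k] > 0) f <- f * state$c[k]^ch$pc[k]
      Iion[ch$neuron[k]] <- Iion[ch$neuron[k]] + f
    }
  }
  V <- numeric(N)
  for (i in seq_len(N)) {
    V[i] <- Vl[i] + model$Tm[i] *
      (-model$Gm[i] * (Vl[i] - model$Vrest[i]) + model$Ibias[i] +
         Isyn[i] + Iion[i] + Iapp[i])
  }
  check_finite(V, model)
  if (!is.null(ch)) {
    for (k in seq_len(nrow(ch))) {
      v <- Vl[ch$neuron[k]]
      if (ch$pb[k] > 0) {
        zi <- gate_inf(v, ch$Kb[k], ch$Sb[k], ch$Eb[k])
        tau <- ch$tau_max_b[k] * zi * ch$Kb[k] * exp(ch$Sb[k] * (ch$Eb[k] - v))
        state$b[k] <- min(max(state$b[k] + model$dt * (zi - state$b[k]) / tau, 0), 1)
      }
      if (ch$pc[k] > 0) {
        zi <- gate_inf(v, ch$Kc[k], ch$Sc[k], ch$Ec[k])
        tau <- ch$tau_max_c[k] * zi * ch$Kc[k] * exp(ch$Sc[k] * (ch$Ec[k] - v))
        state$c[k] <- min(max(state$c[k] + model$dt * (zi - state$c[k]) / tau, 0), 1)
      }
    }
  }
  delta <- numeric(N)
  theta <- state$theta
  for (i in seq_len(N)) {
    if (model$spiking[i]) {
      theta[i] <- theta[i] + model$Ttheta[i] *
        (-theta[i] + model$theta0[i] + model$m[i] * (Vl[i] - model$Vrest[i]))
      if (V[i] > theta[i]) {
        delta[i] <- -1
        V[i] <- model$Vrest[i]
      }
    }
  }
  state$buffer <- rbind(delta, state$buffer[-model$D, , drop = FALSE],
                        deparse.level = 0)
  out <- stats::setNames(numeric(model$n_out), model$output_names)
  for (r in seq_len(model$n_out)) {
    for (i in seq_len(N)) {
      out[r] <- out[r] + model$Cout_v[r, i] * V[i] + model$Cout_s[r, i] * delta[i]
    }
  }
  state$theta <- theta
  state$delta <- delta
  state$V <- V
  state$V_last <- V
  state$step <- state$step + 1L
  list(state = state, output = out)
}

#' Run a compiled model for many steps
#'
#' @param model an `sns_model`.
#' @param n_steps number of timesteps (>= 0).
#' @param Iext external currents: a single vector of length `L` applied on
#'   every step, or an `n_steps x L` matrix of per-step currents.
#' @param backend `"dense"` or `"iterative"`; see [sns_step()].
#' @param state optional initial `sns_state` (default [sns_init()]).
#' @param record_all logical; additionally record the full membrane
#'   potential trace.
#' @return a list with `output` (an `n_steps x n_out` matrix, columns
#'   named after the monitors), `state` (final state) and, when
#'   `record_all`, `V` (an `n_steps x N` matrix).
#' @examples
#' net <- sns_network()
#' net <- add_population(net, neuron_type(Cm = 5, Gm = 1, Vrest = 0), 1, "n")
#' net <- add_input(net, "n")
#' net <- add_output(net, "n")
#' res <- sns_run(compile_network(net, dt = 0.1), 1000, Iext = 2)
#' tail(res$output, 1)  # ~ 2 mV: Vrest + Iapp / Gm
#' @export
sns_run <- function(model, n_steps, Iext = NULL,
                    backend = c("dense", "iterative"), state = NULL,
                    record_all = FALSE) {
  stopifnot(inherits(model, "sns_model"))
  backend <- match.arg(backend)
  n_steps <- as.integer(n_steps)
  stopifnot(n_steps >= 0)
  if (is.null(state)) state <- sns_init(model)
  if (is.null(Iext)) Iext <- matrix(0, n_steps, model$L)
  if (!is.matrix(Iext)) {
    if (length(Iext) != model$L) {
      stop(sprintf("constant Iext must have length %d", model$L))
    }
    Iext <- matrix(rep(Iext, each = n_steps), n_steps, model$L)
  }
  if (nrow(Iext) < n_steps || ncol(Iext) != model$L) {
    stop(sprintf("Iext must be %d x %d (steps x inputs)", n_steps, model$L))
  }
  out <- matrix(0, n_steps, model$n_out,
                dimnames = list(NULL, model$output_names))
  Vtrace <- if (record_all) matrix(0, n_steps, model$N,
                                   dimnames = list(NULL, model$neuron_names))
  for (t in seq_len(n_steps)) {
    r <- sns_step(model, state, Iext[t, ], backend = backend)
    state <- r$state
    if (model$n_out > 0) out[t, ] <- r$output
    if (record_all) Vtrace[t, ] <- state$V
  }
  res <- list(output = out, state = state)
  if (record_all) res$V <- Vtrace
  res
}
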