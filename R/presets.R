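#' Define a neuron type preset
#'
#' A neuron type bundles the membrane parameters shared by every neuron of a
#' population.  All neurons are leaky integrators
#' \deqn{C_m \frac{dV}{dt} = -G_m (V - V_{rest}) + \sum I_{syn} + I_{bias} + I_{app},}
#' optionally extended with an adaptive firing threshold (spiking neurons)
#' \deqn{\tau_\theta \frac{d\theta}{dt} = -\theta + \theta_0 + m (V - V_{rest}),}
#' or with Hodgkin-Huxley style voltage-gated ion channels (non-spiking
#' neurons only; see [channel_type()]).
#'
#' @param name character label for the preset.
#' @param Cm membrane capacitance (nF), > 0.
#' @param Gm membrane conductance (uS), > 0.
#' @param Vrest resting potential (mV).
#' @param Ibias tonic bias current (nA).
#' @param spiking logical; if `TRUE` the neuron fires and resets when
#'   `V > theta`.
#' @param theta0 initial firing threshold (mV); spiking only.
#' @param tau_theta threshold time constant (ms), > 0; spiking only.
#' @param m threshold proportionality constant (dimensionless).  `m = 0`
#'   keeps the threshold fixed at `theta0`; `m > 0` yields spike-frequency
#'   adaptation and `m < 0` facilitation.
#' @param channels list of [channel_type()] objects (non-spiking only).
#'
#' @return an object of class `sns_neuron_type`.
#' @examples
#' nt <- neuron_type("interneuron", Cm = 5, Gm = 1, Vrest = -60)
#' lif <- neuron_type("lif", spiking = TRUE, theta0 = 1, Vrest = 0)
#' @export
neuron_type <- function(name = "neuron", Cm = 5, Gm = 1, Vrest = 0,
                        Ibias = 0, spiking = FALSE, theta0 = 1,
                        tau_theta = 1000, m = 0, channels = list()) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(Cm) || Cm <= 0) stop("Cm must be > 0 (nF)")
  if (!is.numeric(Gm) || Gm <= 0) stop("Gm must be > 0 (uS)")
  if (spiking) {
    if (tau_theta <= 0) stop("tau_theta must be > 0 (ms) for spiking neurons")
    if (length(channels)) {
      stop("spiking neurons may not carry ion channels")
    }
  }
  if (length(channels)) {
    ok <- vapply(channels, inherits, logical(1), what = "sns_channel_type")
    if (!all(ok)) stop("channels must be a list of channel_type() objects")
  }
  structure(
    list(name = name, Cm = Cm, Gm = Gm, Vrest = Vrest, Ibias = Ibias,
         spiking = isTRUE(spiking), theta0 = theta0, tau_theta = tau_theta,
         m = m, channels = channels),
    class = "sns_neuron_type")
}

#' Define a voltage-gated ion channel type
#'
#' A channel contributes the ionic current
#' \deqn{I_{ion} = G_{ion} \, a_\infty(V)^{p_a} \, b^{p_b} \, c^{p_c} \, (E_{ion} - V)}
#' to its neuron.  Gate `a` is instantaneous (always at its steady state);
#' gates `b` and `c` are first-order state variables
#' \deqn{\frac{dz}{dt} = \frac{z_\infty(V) - z}{\tau_z(V)},}
#' with the sigmoid steady state
#' \deqn{z_\infty(V) = \frac{1}{1 + K_z \exp(S_z (E_z - V))}}
#' and voltage-dependent time constant
#' \deqn{\tau_z(V) = \tau_{max,z} \, z_\infty(V) \, K_z \exp(S_z (E_z - V)).}
#' Setting an exponent `p` to 0 removes that gate (its factor becomes 1).
#' `S > 0` gives an activation gate (opens with depolarisation), `S < 0` an
#' inactivation gate.
#'
#' @param name character label.
#' @param Gion maximal ionic conductance (uS), >= 0.
#' @param Eion ionic reversal potential (mV).
#' @param pa,Ka,Sa,Ea instantaneous gate `a`: exponent (>= 0; 0 disables),
#'   shape constant (dimensionless), slope (1/mV) and half-activation
#'   reference potential (mV).
#' @param pb,Kb,Sb,Eb,tau_max_b dynamic gate `b`; `tau_max_b` (ms) is the
#'   maximum of \eqn{\tau_b(V)}.
#' @param pc,Kc,Sc,Ec,tau_max_c dynamic gate `c`.
#'
#' @return an object of class `sns_channel_type`.
#' @seealso [channel_nap()] for the persistent-sodium preset.
#' @export
channel_type <- function(name = "channel", Gion = 0, Eion = 0,
                         pa = 0, Ka = 1, Sa = 0, Ea = 0,
                         pb = 0, Kb = 1, Sb = 0, Eb = 0, tau_max_b = 1,
                         pc = 0, Kc = 1, Sc = 0, Ec = 0, tau_max_c = 1) {
  if (Gion < 0) stop("Gion must be >= 0 (uS)")
  if (pa < 0 || pb < 0 || pc < 0) stop("gate exponents must be >= 0")
  if (pb > 0 && tau_max_b <= 0) stop("tau_max_b must be > 0 when gate b is active")
  if (pc > 0 && tau_max_c <= 0) stop("tau_max_c must be > 0 when gate c is active")
  structure(
    list(name = name, Gion = Gion, Eion = Eion,
         pa = pa, Ka = Ka, Sa = Sa, Ea = Ea,
         pb = pb, Kb = Kb, Sb = Sb, Eb = Eb, tau_max_b = tau_max_b,
         pc = pc, Kc = Kc, Sc = Sc, Ec = Ec, tau_max_c = tau_max_c),
    class = "sns_channel_type")
}

#' Persistent sodium channel preset
#'
#' A slowly inactivating inward sodium current
#' \deqn{I_{NaP} = G_{Na} \, m_\infty(V) \, h \, (E_{Na} - V),}
#' i.e. the generic three-gate channel with the instantaneous activation
#' gate `m` (exponent 1), one dynamic inactivation gate `h` (exponent 1)
#' and the third gate disabled.  This current supports endogenous bursting
#' and is the canonical ingredient of half-centre oscillators.
#'
#' @param Gna maximal conductance (uS).
#' @param Ena sodium reversal potential (mV).
#' @param Km,Sm,Em activation gate steady-state parameters (`Sm > 0`).
#' @param Kh,Sh,Eh inactivation gate steady-state parameters (`Sh < 0`).
#' @param tau_h_max maximal inactivation time constant (ms).
#' @return an `sns_channel_type`.
#' @export
channel_nap <- function(Gna = 1.5, Ena = 50,
                        Km = 1, Sm = 0.05, Em = -40,
                        Kh = 0.5, Sh = -0.05, Eh = -60,
                        tau_h_max = 300) {
  channel_type("NaP", Gion = Gna, Eion = Ena,
               pa = 1, Ka = Km, Sa = Sm, Ea = Em,
               pb = 1, Kb = Kh, Sb = Sh, Eb = Eh, tau_max_b = tau_h_max)
}

#' Chemical and electrical synapse presets
#'
#' Three connection kinds are supported:
#'
#' * **Graded (non-spiking) chemical synapse** — the conductance follows the
#'   presynaptic voltage piecewise-linearly,
#'   \eqn{G(V_{pre}) = \max(0, \min(G_{max} (V_{pre}-E_{lo})/(E_{hi}-E_{lo}), G_{max}))},
#'   and the current is \eqn{G (E_{syn} - V_{post})}.
#' * **Spiking chemical synapse** — the conductance decays with time
#'   constant `tau_syn` and is reset to `Gmax` whenever the presynaptic
#'   spike (optionally delayed by an integer number of timesteps) arrives.
#' * **Electrical synapse (gap junction)** — resistive coupling
#'   \eqn{I = G (V_{pre} - V_{post})}, bidirectional by default; a rectified
#'   variant passes current only when \eqn{V_{pre} > V_{post}}.
#'
#' @param Gmax maximal synaptic conductance (uS), >= 0.
#' @param Esyn synaptic reversal potential (mV); chemical kinds only.
#' @param Elo,Ehi presynaptic voltage bounds (mV) of the linear conductance
#'   ramp; graded synapses only, `Ehi > Elo`.
#' @param tau_syn conductance decay time constant (ms), > 0; spiking only.
#' @param delay spike propagation delay in integer timesteps, >= 0.
#' @param rectified logical; electrical only.
#' @param name character label.
#' @return an object of class `sns_connection_type`.
#' @export
nonspiking_synapse <- function(Gmax = 1, Esyn = 40, Elo = 0, Ehi = 20,
                               name = "nonspiking chemical") {
  if (Gmax < 0) stop("Gmax must be >= 0 (uS)")
  if (Ehi <= Elo) stop("Ehi must be > Elo (mV)")
  structure(
    list(kind = "chemical_nonspiking", name = name, Gmax = Gmax,
         Esyn = Esyn, Elo = Elo, Ehi = Ehi),
    class = "sns_connection_type")
}

#' @rdname nonspiking_synapse
#' @export
spiking_synapse <- function(Gmax = 1, Esyn = 40, tau_syn = 1, delay = 0,
                            name = "spiking chemical") {
  if (Gmax < 0) stop("Gmax must be >= 0 (uS)")
  if (tau_syn <= 0) stop("tau_syn must be > 0 (ms)")
  if (length(delay) != 1L || !is.numeric(delay) || delay < 0 ||
      delay != round(delay)) {
    stop("delay must be a non-negative integer number of timesteps")
  }
  structure(
    list(kind = "chemical_spiking", name = name, Gmax = Gmax, Esyn = Esyn,
         tau_syn = tau_syn, delay = as.integer(delay)),
    class = "sns_connection_type")
}

#' @rdname nonspiking_synapse
#' @export
electrical_synapse <- function(Gmax = 1, rectified = FALSE,
                               name = "electrical") {
  if (Gmax < 0) stop("Gmax must be >= 0 (uS)")
  structure(
    list(kind = "electrical", name = name, Gmax = Gmax,
         rectified = isTRUE(rectified)),
    class = "sns_connection_type")
}

#' @export
print.sns_neuron_type <- function(x, ...) {
  cat(sprintf("<neuron type '%s'> %s, Cm=%g nF, Gm=%g uS, Vrest=%g mV, Ibias=%g nA\n",
              x$name, if (x$spiking) "spiking" else "non-spiking",
              x$Cm, x$Gm, x$Vrest, x$Ibias))
  if (x$spiking) {
    cat(sprintf("  theta0=%g mV, tau_theta=%g ms, m=%g\n",
                x$theta0, x$tau_theta, x$m))
  }
  if (length(x$channels)) {
    cat(sprintf("  %d ion channel(s): %s\n", length(x$channels),
                paste(vapply(x$channels, `[[`, "", "name"), collapse = ", ")))
  }
  invisible(x)
}

#' @export
print.sns_connection_type <- function(x, ...) {
  cat(sprintf("<connection type '%s'> kind=%s, Gmax=%g uS\n",
              x$name, x$kind, x$Gmax))
  invisible(x)
}
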