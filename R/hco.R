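#' Build a persistent-sodium half-centre oscillator demo network
#'
#' Two half-centre (HC) neurons carrying a persistent sodium current
#' ([channel_nap()]) mutually inhibit one another via two non-spiking
#' interneurons: `hc1 -> in1 -| hc2` and `hc2 -> in2 -| hc1`, all
#' connections graded chemical synapses.  The slowly inactivating sodium
#' current makes each HC neuron an endogenous burster; reciprocal
#' inhibition locks the two into sustained antiphase alternation, the
#' canonical rhythm-generation motif of locomotor central pattern
#' generators.
#'
#' Parameter values are package-chosen and documented in the methods
#' vignette; a small initial-voltage asymmetry between the two HC neurons
#' breaks the symmetric equilibrium deterministically.
#'
#' @param g_inhibit maximal conductance (uS) of the interneuron-to-HC
#'   inhibitory synapses; 0 decouples the two half-centres.
#' @return an `sns_network` with voltage outputs on `hc1` and `hc2`
#'   (then `in1`, `in2`).
#' @examples
#' model <- compile_network(build_hco_demo(), dt = 0.1)
#' res <- sns_run(model, 5000)  # 500 ms
#' @export
build_hco_demo <- function(g_inhibit = 2) {
  if (g_inhibit < 0) stop("g_inhibit must be >= 0")
  hc <- neuron_type("half-centre", Cm = 5, Gm = 1, Vrest = -60, Ibias = 0,
                    channels = list(channel_nap(
                      Gna = 2.5, Ena = 50,
                      Km = 1, Sm = 0.05, Em = -40,
                      Kh = 0.5, Sh = -0.2, Eh = -50,
                      tau_h_max = 300)))
  inter <- neuron_type("interneuron", Cm = 5, Gm = 1, Vrest = -60)
  # HC operating range roughly [-60, -40] mV
  excite <- nonspiking_synapse(Gmax = 2, Esyn = -20, Elo = -60, Ehi = -40,
                               name = "hc to interneuron")
  inhibit <- nonspiking_synapse(Gmax = g_inhibit, Esyn = -80,
                                Elo = -60, Ehi = -40,
                                name = "interneuron to hc")
  net <- sns_network("hco")
  net <- add_population(net, hc, 1, "hc1", initial_voltage = -50)
  net <- add_population(net, hc, 1, "hc2", initial_voltage = -60)
  net <- add_population(net, inter, 1, "in1")
  net <- add_population(net, inter, 1, "in2")
  net <- add_connection(net, "hc1", "in1", excite, "direct")
  net <- add_connection(net, "in1", "hc2", inhibit, "direct")
  net <- add_connection(net, "hc2", "in2", excite, "direct")
  net <- add_connection(net, "in2", "hc1", inhibit, "direct")
  net <- add_output(net, "hc1")
  net <- add_output(net, "hc2")
  net <- add_output(net, "in1")
  net <- add_output(net, "in2")
  net
}
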