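#' LiDAR range-to-current mapping
#'
#' `lidar_map()` describes a planar range scanner: `n_beams` distance
#' readings spread over an arc, with measurable range `[Dmin, Dmax]` (m).
#' `distance_to_current()` converts a distance reading into the applied
#' current (nA) for the corresponding sensory neuron,
#' \deqn{I_{app}(D) = \frac{D^{-1} - D_{max}^{-1}}{D_{min}^{-1} - D_{max}^{-1}},}
#' a strictly decreasing map sending `Dmax` to 0 and `Dmin` to 1.
#' Distances outside `[Dmin, Dmax]` are clamped into range first (real
#' scanners return out-of-range codes); non-positive distances are an
#' error.
#'
#' @param Dmin,Dmax minimum/maximum sensor distance (m), `0 < Dmin < Dmax`.
#' @param n_beams number of beams in the scan.
#' @param D numeric vector of distances (m).
#' @param map a `lidar_map`.
#' @return `distance_to_current()` returns currents in nA, same shape as
#'   `D`.
#' @examples
#' m <- lidar_map(Dmin = 1, Dmax = 10)
#' distance_to_current(c(1, 2, 10), m)  # 1, 4/9, 0
#' @export
lidar_map <- function(Dmin = 0.5, Dmax = 10, n_beams = 720) {
  if (!(Dmin > 0 && Dmax > Dmin)) stop("need 0 < Dmin < Dmax")
  if (n_beams < 1) stop("n_beams must be >= 1")
  structure(list(Dmin = Dmin, Dmax = Dmax, n_beams = as.integer(n_beams)),
            class = "sns_lidar_map")
}

#' @rdname lidar_map
#' @export
distance_to_current <- function(D, map = lidar_map()) {
  if (any(D <= 0)) stop("distances must be positive")
  D <- pmin(pmax(D, map$Dmin), map$Dmax)
  (1 / D - 1 / map$Dmax) / (1 / map$Dmin - 1 / map$Dmax)
}

#' Steering controller parameters
#'
#' @param Kang angular gain ((rad/s)/mV) applied to the voltage difference
#'   of the two heading neurons.
#' @param vlin_max maximum linear speed (m/s).
#' @param speed_bias tonic bias current (nA) of the speed neuron.
#' @return a `steering_params` list.
#' @export
steering_params <- function(Kang = 1, vlin_max = 0.5, speed_bias = 1) {
  if (Kang < 0 || vlin_max < 0) stop("gains must be >= 0")
  structure(list(Kang = Kang, vlin_max = vlin_max, speed_bias = speed_bias),
            class = "sns_steering_params")
}

#' Build the Braitenberg-style LiDAR steering network
#'
#' A population of `n_beams` non-spiking sensory neurons (Cm = 5 nF,
#' Gm = 1 uS, Vrest = 0 mV, no bias) each receives the applied current of
#' one beam, so with unit membrane conductance the steady-state sensory
#' voltage in mV equals the beam current in nA: 0 at `Dmax`, 1 at `Dmin`.
#' The left half of the array excites a clockwise heading neuron, the
#' right half a counter-clockwise heading neuron (shared graded synapses,
#' total conductance 1 uS per heading neuron), and all sensory neurons
#' inhibit a speed neuron carrying a 1 nA bias whose synaptic reversal sits
#' at rest, so nearby obstacles pull the speed command toward zero.
#' Outputs monitor the three command neurons (`cw`, `ccw`, `speed`).
#'
#' @param map a [lidar_map()]; `n_beams` must be even.
#' @param params a [steering_params()].
#' @return an `sns_network` with `n_beams + 3` neurons, `n_beams` inputs
#'   and 3 voltage outputs.
#' @export
build_steering_network <- function(map = lidar_map(),
                                   params = steering_params()) {
  n <- map$n_beams
  if (n %% 2L != 0L) stop("n_beams must be even")
  sensory <- neuron_type("sensory", Cm = 5, Gm = 1, Vrest = 0, Ibias = 0)
  command <- neuron_type("command", Cm = 5, Gm = 1, Vrest = 0, Ibias = 0)
  speed_nt <- neuron_type("speed", Cm = 5, Gm = 1, Vrest = 0,
                          Ibias = params$speed_bias)
  # sensory operating range is [0, 1] mV by construction of the current map
  excite <- nonspiking_synapse(Gmax = 1, Esyn = 20, Elo = 0, Ehi = 1,
                               name = "sensory excitation")
  inhibit <- nonspiking_synapse(Gmax = 1, Esyn = 0, Elo = 0, Ehi = 1,
                                name = "speed inhibition")
  net <- sns_network("steering")
  net <- add_population(net, sensory, n, "scan")
  net <- add_population(net, command, 1, "cw")
  net <- add_population(net, command, 1, "ccw")
  net <- add_population(net, speed_nt, 1, "speed")
  half <- n %/% 2L
  g <- excite$Gmax / half  # shared conductance; each half sums to Gmax
  Wcw <- matrix(c(rep(g, half), rep(0, n - half)), 1, n)
  Wccw <- matrix(c(rep(0, half), rep(g, n - half)), 1, n)
  net <- add_connection(net, "scan", "cw", excite, "matrix", Wcw)
  net <- add_connection(net, "scan", "ccw", excite, "matrix", Wccw)
  net <- add_connection(net, "scan", "speed", inhibit, "direct")
  net <- add_input(net, "scan", width = n)
  net <- add_output(net, "cw")
  net <- add_output(net, "ccw")
  net <- add_output(net, "speed")
  net
}

#' Map heading/speed neuron voltages to robot velocity commands
#'
#' \deqn{\nu_{ang} = K_{ang} (V_{CW} - V_{CCW}), \qquad
#'       \nu_{lin} = \nu_{lin,max} V_{Speed},}
#' with voltages relative to rest (the command neurons rest at 0 mV, so
#' absolute and relative voltages coincide).  Positive `v_ang` is a
#' clockwise turn.
#'
#' @param VCW,VCCW,VSpeed command neuron voltages (mV).
#' @param params a [steering_params()].
#' @return list with `v_ang` (rad/s) and `v_lin` (m/s).
#' @export
command_velocities <- function(VCW, VCCW, VSpeed,
                               params = steering_params()) {
  list(v_ang = unname(params$Kang * (VCW - VCCW)),
       v_lin = unname(params$vlin_max * VSpeed))
}

#' Synthetic corridor scan
#'
#' Generates one scan of distances for a robot centred in an infinite
#' straight corridor, walls at perpendicular distances `left` and `right`
#' (m).  Beams sweep a 270 degree arc; beams facing along the corridor
#' saturate at `Dmax`.  Used to exercise the steering controller without
#' any robotics middleware.
#'
#' @param map a [lidar_map()].
#' @param left,right perpendicular wall distances (m).
#' @return numeric vector of `n_beams` distances.
#' @export
corridor_scan <- function(map = lidar_map(), left = 1, right = 3) {
  n <- map$n_beams
  # beams 1..n/2 point into the left half-plane, the rest to the right;
  # angle measured from the corridor axis
  ang <- seq(-3 * pi / 4, 3 * pi / 4, length.out = n)
  d <- rep(map$Dmax, n)
  lt <- ang < 0
  d[lt] <- pmin(map$Dmax, left / pmax(sin(-ang[lt]), 1e-9))
  d[!lt] <- pmin(map$Dmax, right / pmax(sin(ang[!lt]), 1e-9))
  pmax(d, map$Dmin)
}

#' Motoneuron-to-muscle activation sigmoid
#'
#' Converts a motoneuron potential (mV) into a dimensionless muscle
#' activation in `[0, 1]`:
#' \deqn{act = \frac{1}{1 + e^{s (x_{offset} - stim)}} + y_{offset},}
#' clamped to `[0, 1]` after the vertical offset is applied.
#'
#' @param stim motoneuron potential(s), mV.
#' @param s sigmoid steepness (1/mV), > 0.
#' @param xoffset half-activation potential (mV).
#' @param yoffset vertical offset (dimensionless).
#' @return activation value(s) in `[0, 1]`.
#' @examples
#' muscle_activation(-50, s = 0.2, xoffset = -50)  # 0.5 at midpoint
#' @export
muscle_activation <- function(stim, s = 0.2, xoffset = -50, yoffset = 0) {
  if (s <= 0) stop("sigmoid steepness s must be > 0")
  act <- 1 / (1 + exp(s * (xoffset - stim))) + yoffset
  pmin(pmax(act, 0), 1)
}
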