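#' Create an empty network
#'
#' A network is an editable container of named neuron populations, the
#' connections between them, and the registered external inputs and output
#' monitors.  It is assembled incrementally with [add_population()],
#' [add_connection()], [add_input()] and [add_output()], may embed other
#' networks via [include_network()], and is turned into an executable form
#' by [compile_network()].
#'
#' @param name character label for the network.
#' @return an object of class `sns_network`.
#' @examples
#' net <- sns_network("demo")
#' net <- add_population(net, neuron_type(), shape = c(3, 3), name = "grid")
#' n_neurons(net)
#' @export
sns_network <- function(name = "network") {
  structure(
    list(name = name, populations = list(), connections = list(),
         inputs = list(), outputs = list()),
    class = "sns_network")
}

#' Number of neurons in a network
#' @param net an `sns_network`.
#' @return integer total across populations.
#' @export
n_neurons <- function(net) {
  stopifnot(inherits(net, "sns_network"))
  sum(vapply(net$populations, function(p) p$size, numeric(1)), 0)
}

pop_names <- function(net) {
  vapply(net$populations, `[[`, "", "name")
}

# Accept a bare conductance matrix/kernel or a named list of per-parameter
# matrices/kernels; always return a named list containing Gmax.
normalize_payload <- function(weights, type) {
  allowed <- switch(type$kind,
    chemical_nonspiking = c("Gmax", "Esyn", "Elo", "Ehi"),
    chemical_spiking = c("Gmax", "Esyn", "tau_syn", "delay"),
    electrical = "Gmax")
  if (is.matrix(weights)) weights <- list(Gmax = weights)
  if (!is.list(weights) || is.null(weights$Gmax)) {
    stop("weights must be a conductance matrix or a named list containing 'Gmax'")
  }
  bad <- setdiff(names(weights), allowed)
  if (length(bad)) {
    stop(sprintf("parameter(s) %s not admitted for kind '%s'",
                 paste(bad, collapse = ", "), type$kind))
  }
  weights
}

find_pop <- function(net, name) {
  idx <- match(name, pop_names(net))
  if (is.na(idx)) stop(sprintf("unknown population '%s'", name))
  net$populations[[idx]]
}

#' Add a population of neurons
#'
#' @param net an `sns_network`.
#' @param type a [neuron_type()] preset shared by every neuron.
#' @param shape population geometry: a single length, or `c(rows, cols)`
#'   for a 2-D sheet.  2-D populations are flattened row-major for
#'   simulation, i.e. neuron `(r, c)` of an `R x C` population sits at flat
#'   offset `(r - 1) * C + c`.
#' @param name unique population name; connections, inputs and outputs are
#'   addressed by these names.
#' @param initial_voltage optional per-neuron initial potential vector (mV,
#'   recycled if scalar); defaults to `Vrest`.
#' @return the updated network.
#' @export
add_population <- function(net, type, shape = 1, name = NULL,
                           initial_voltage = NULL) {
  stopifnot(inherits(net, "sns_network"), inherits(type, "sns_neuron_type"))
  if (is.null(name)) name <- sprintf("pop%d", length(net$populations) + 1L)
  if (name %in% pop_names(net)) {
    stop(sprintf("population name '%s' already in use", name))
  }
  if (!is.numeric(shape) || !length(shape) %in% 1:2 ||
      any(shape < 1) || any(shape != round(shape))) {
    stop("shape must be a positive integer length or c(rows, cols)")
  }
  shape <- as.integer(shape)
  size <- prod(shape)
  if (!is.null(initial_voltage)) {
    if (!length(initial_voltage) %in% c(1L, size)) {
      stop("initial_voltage must have length 1 or the population size")
    }
    initial_voltage <- rep_len(as.numeric(initial_voltage), size)
  }
  net$populations[[length(net$populations) + 1L]] <-
    list(name = name, shape = shape, size = size, type = type,
         initial_voltage = initial_voltage)
  net
}

#' Connect two populations (or single neurons)
#'
#' @param net an `sns_network`.
#' @param source,destination population names.
#' @param type an `sns_connection_type` preset.
#' @param scheme connectivity scheme:
#'   * `"direct"` — single synapse for 1-to-1 populations; for larger
#'     populations, all-to-all with the conductance scaled by `1/n_src` so
#'     the total conductance into each postsynaptic neuron equals the
#'     preset's `Gmax`;
#'   * `"one_to_one"` — equal-size populations, neuron `k` to neuron `k`,
#'     all synapses sharing the preset parameters;
#'   * `"matrix"` — explicit per-synapse conductance matrix
#'     (`dest size x source size`; a zero entry means no synapse);
#'   * `"pattern"` — a small odd-dimension kernel replicated at every
#'     spatial offset between two 2-D populations of identical shape
#'     (convolution-style, zero padding, stride 1).
#' @param weights for `"matrix"`: the conductance matrix (uS); for
#'   `"pattern"`: the conductance kernel (uS).  Either may instead be a
#'   named list of per-parameter matrices/kernels (names among `Gmax`,
#'   `Esyn`, `Elo`, `Ehi`, `tau_syn`, `delay`, as admitted by the
#'   connection kind); parameters not listed are taken uniformly from the
#'   preset wherever `Gmax > 0`.
#' @return the updated network.
#' @export
add_connection <- function(net, source, destination, type,
                           scheme = c("direct", "one_to_one", "matrix",
                                      "pattern"),
                           weights = NULL) {
  stopifnot(inherits(net, "sns_network"),
            inherits(type, "sns_connection_type"))
  scheme <- match.arg(scheme)
  src <- find_pop(net, source)
  dst <- find_pop(net, destination)
  if (scheme == "one_to_one" && src$size != dst$size) {
    stop("one_to_one requires equal source and destination sizes")
  }
  if (scheme %in% c("matrix", "pattern")) {
    weights <- normalize_payload(weights, type)
  }
  if (scheme == "matrix") {
    for (nm in names(weights)) {
      w <- weights[[nm]]
      if (!is.matrix(w) || !is.numeric(w)) {
        stop("matrix scheme requires numeric parameter matrices")
      }
      if (nrow(w) != dst$size || ncol(w) != src$size) {
        stop(sprintf("'%s' matrix must be %d x %d (destination x source), got %d x %d",
                     nm, dst$size, src$size, nrow(w), ncol(w)))
      }
    }
    if (any(weights$Gmax < 0)) stop("negative conductances in weights matrix")
  }
  if (scheme == "pattern") {
    if (length(src$shape) != 2L || length(dst$shape) != 2L ||
        !all(src$shape == dst$shape)) {
      stop("pattern connections require 2-D populations of identical shape")
    }
    kdim <- dim(weights$Gmax)
    for (nm in names(weights)) {
      w <- weights[[nm]]
      if (!is.matrix(w) || any(dim(w) %% 2L == 0L)) {
        stop("pattern kernels must be matrices with odd dimensions")
      }
      if (!all(dim(w) == kdim)) stop("pattern kernels must share one shape")
    }
    if (any(weights$Gmax < 0)) stop("negative conductances in pattern kernel")
  }
  net$connections[[length(net$connections) + 1L]] <-
    list(source = source, destination = destination, type = type,
         scheme = scheme, weights = weights)
  net
}

#' Register an external input source
#'
#' External applied currents (nA) are supplied per step as a vector of
#' length `L`, the total input width, and routed to their target neurons by
#' a binary mask at simulation time.  An input of width 1 on a
#' multi-neuron population broadcasts the same current to every neuron of
#' the population; an input of width equal to the population size routes
#' element-wise.
#'
#' @param net an `sns_network`.
#' @param target population name.
#' @param width 1 or the population size.
#' @return the updated network.
#' @export
add_input <- function(net, target, width = 1) {
  stopifnot(inherits(net, "sns_network"))
  pop <- find_pop(net, target)
  if (!width %in% c(1L, pop$size)) {
    stop(sprintf("input width must be 1 or the population size (%d)",
                 pop$size))
  }
  net$inputs[[length(net$inputs) + 1L]] <-
    list(target = target, width = as.integer(width))
  net
}

#' Register an output monitor
#'
#' Outputs are assigned one-to-one to each neuron of the source population:
#' one monitor on a population of five neurons yields five output records
#' per step.  Voltage monitors report the membrane potential (mV); spike
#' monitors report the spike state.
#'
#' @param net an `sns_network`.
#' @param source population name.
#' @param mode `"voltage"` or `"spike"` (spiking populations only).
#' @return the updated network.
#' @export
add_output <- function(net, source, mode = c("voltage", "spike")) {
  stopifnot(inherits(net, "sns_network"))
  mode <- match.arg(mode)
  pop <- find_pop(net, source)
  if (mode == "spike" && !pop$type$spiking) {
    stop(sprintf("spike output requested on non-spiking population '%s'",
                 source))
  }
  net$outputs[[length(net$outputs) + 1L]] <-
    list(source = source, mode = mode)
  net
}

#' Embed one network inside another
#'
#' Copies every population, connection, input and output of `sub` into
#' `net`, prefixing all population names with `prefix` so that large
#' networks can be composed from reusable subnetworks.
#'
#' @param net host `sns_network`.
#' @param sub subnetwork to copy in.
#' @param prefix string prepended to every population name of `sub`
#'   (separator `"."`).
#' @return the updated host network.
#' @export
include_network <- function(net, sub, prefix = sub$name) {
  stopifnot(inherits(net, "sns_network"), inherits(sub, "sns_network"))
  rename <- function(nm) paste0(prefix, ".", nm)
  new_names <- vapply(pop_names(sub), rename, "")
  clash <- intersect(new_names, pop_names(net))
  if (length(clash)) {
    stop(sprintf("population name collision after prefixing: %s",
                 paste(clash, collapse = ", ")))
  }
  for (p in sub$populations) {
    p$name <- rename(p$name)
    net$populations[[length(net$populations) + 1L]] <- p
  }
  for (cn in sub$connections) {
    cn$source <- rename(cn$source)
    cn$destination <- rename(cn$destination)
    net$connections[[length(net$connections) + 1L]] <- cn
  }
  for (inp in sub$inputs) {
    inp$target <- rename(inp$target)
    net$inputs[[length(net$inputs) + 1L]] <- inp
  }
  for (out in sub$outputs) {
    out$source <- rename(out$source)
    net$outputs[[length(net$outputs) + 1L]] <- out
  }
  net
}

#' @export
print.sns_network <- function(x, ...) {
  cat(sprintf("<sns_network '%s'> %d population(s), %d neuron(s), %d connection(s), %d input(s), %d output monitor(s)\n",
              x$name, length(x$populations), n_neurons(x),
              length(x$connections), length(x$inputs), length(x$outputs)))
  invisible(x)
}
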