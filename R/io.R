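DOC_FORMAT <- "snsim-network"
DOC_VERSION <- 1L

NEURON_FIELDS <- c("name", "Cm", "Gm", "Vrest", "Ibias", "spiking",
                   "theta0", "tau_theta", "m", "channels")
CHANNEL_FIELDS <- c("name", "Gion", "Eion", "pa", "Ka", "Sa", "Ea",
                    "pb", "Kb", "Sb", "Eb", "tau_max_b",
                    "pc", "Kc", "Sc", "Ec", "tau_max_c")
CONN_FIELDS <- list(
  chemical_nonspiking = c("kind", "name", "Gmax", "Esyn", "Elo", "Ehi"),
  chemical_spiking = c("kind", "name", "Gmax", "Esyn", "tau_syn", "delay"),
  electrical = c("kind", "name", "Gmax", "rectified"))

#' Save and load networks as JSON documents
#'
#' Networks are serialised to a versioned JSON document holding the
#' neuron/connection presets by registry key, the populations, connections,
#' inputs and outputs.  All quantities keep the package's fixed units
#' (nA, mV, uS, nF, ms).  Saving the same network twice produces an
#' identical file, and `load_network(save_network(net))` reconstructs the
#' network field-for-field, so simulations before and after a round trip
#' are identical.
#'
#' @param net an `sns_network`.
#' @param path file path.
#' @return `save_network()` returns `path` invisibly; `load_network()`
#'   returns the reconstructed `sns_network`.  Malformed documents,
#'   unknown fields and version mismatches raise errors naming the
#'   offending field.
#' @export
save_network <- function(net, path) {
  stopifnot(inherits(net, "sns_network"))
  doc <- network_to_doc(net)
  # 17 significant digits so every double round-trips exactly
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                           pretty = TRUE, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  if (!file.exists(path)) stop(sprintf("network file '%s' not found", path))
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = TRUE),
    error = function(e) stop(sprintf("malformed network document '%s': %s",
                                     path, conditionMessage(e))))
  doc_to_network(doc, path)
}

network_to_doc <- function(net) {
  nt_reg <- list()
  ct_reg <- list()
  register <- function(reg, obj) {
    for (k in names(reg)) {
      if (identical(reg[[k]], obj)) return(list(reg = reg, key = k))
    }
    key <- make.unique(c(names(reg), obj$name), sep = "#")[length(reg) + 1L]
    reg[[key]] <- obj
    list(reg = reg, key = key)
  }
  populations <- lapply(net$populations, function(p) {
    ty <- unclass(p$type)
    ty$channels <- lapply(ty$channels, unclass)
    r <- register(nt_reg, ty)
    nt_reg <<- r$reg
    list(name = p$name, shape = p$shape, neuron_type = r$key,
         initial_voltage = p$initial_voltage)
  })
  connections <- lapply(net$connections, function(cn) {
    r <- register(ct_reg, unclass(cn$type))
    ct_reg <<- r$reg
    list(source = cn$source, destination = cn$destination,
         connection_type = r$key, scheme = cn$scheme, weights = cn$weights)
  })
  list(format = DOC_FORMAT, version = DOC_VERSION, name = net$name,
       neuron_types = nt_reg, connection_types = ct_reg,
       populations = populations, connections = connections,
       inputs = net$inputs, outputs = net$outputs)
}

check_fields <- function(x, allowed, what) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    stop(sprintf("unknown field(s) in %s: %s (document version %d)",
                 what, paste(bad, collapse = ", "), DOC_VERSION))
  }
}

doc_to_network <- function(doc, path = "<document>") {
  top <- c("format", "version", "name", "neuron_types", "connection_types",
           "populations", "connections", "inputs", "outputs")
  check_fields(doc, top, "document root")
  if (!identical(doc$format, DOC_FORMAT)) {
    stop(sprintf("'%s' is not a %s document", path, DOC_FORMAT))
  }
  if (!identical(as.integer(doc$version), DOC_VERSION)) {
    stop(sprintf("unsupported document version %s (this build reads version %d)",
                 doc$version, DOC_VERSION))
  }
  ntypes <- lapply(doc$neuron_types, function(nt) {
    check_fields(nt, NEURON_FIELDS, "neuron type")
    chans <- lapply(nt$channels, function(ch) {
      check_fields(ch, CHANNEL_FIELDS, "channel type")
      do.call(channel_type, ch)
    })
    nt$channels <- chans
    do.call(neuron_type, nt)
  })
  ctypes <- lapply(doc$connection_types, function(ct) {
    kind <- ct$kind
    if (is.null(kind) || !kind %in% names(CONN_FIELDS)) {
      stop(sprintf("unknown connection kind '%s'", kind))
    }
    check_fields(ct, CONN_FIELDS[[kind]], "connection type")
    ct$kind <- NULL
    ctor <- switch(kind, chemical_nonspiking = nonspiking_synapse,
                   chemical_spiking = spiking_synapse,
                   electrical = electrical_synapse)
    do.call(ctor, ct)
  })
  net <- sns_network(doc$name)
  for (p in doc$populations) {
    check_fields(p, c("name", "shape", "neuron_type", "initial_voltage"),
                 "population")
    ty <- ntypes[[p$neuron_type]]
    if (is.null(ty)) stop(sprintf("population '%s' references unknown neuron type '%s'",
                                  p$name, p$neuron_type))
    net <- add_population(net, ty, shape = p$shape, name = p$name,
                          initial_voltage = p$initial_voltage)
  }
  for (cn in doc$connections) {
    check_fields(cn, c("source", "destination", "connection_type",
                       "scheme", "weights"), "connection")
    ty <- ctypes[[cn$connection_type]]
    if (is.null(ty)) stop(sprintf("connection references unknown connection type '%s'",
                                  cn$connection_type))
    w <- cn$weights
    if (!is.null(w) && is.list(w)) w <- lapply(w, as.matrix)
    net <- add_connection(net, cn$source, cn$destination, ty,
                          scheme = cn$scheme, weights = w)
  }
  for (inp in doc$inputs) {
    check_fields(inp, c("target", "width"), "input")
    net <- add_input(net, inp$target, inp$width)
  }
  for (out in doc$outputs) {
    check_fields(out, c("source", "mode"), "output")
    net <- add_output(net, out$source, out$mode)
  }
  net
}

#' Read and write simulation time series as CSV
#'
#' `read_input_series()` reads a CSV of external applied currents (nA),
#' one header row naming the inputs and one row per timestep, and returns
#' a numeric `steps x L` matrix.  `write_output_series()` writes a matrix
#' of monitor outputs (one row per step).  At this file boundary spike
#' states are converted from the internal 0/-1 convention to 0/1: pass
#' the model's `output_modes` so spike columns are recognised.
#'
#' @param path CSV file path.
#' @param x numeric matrix of outputs (`steps x n_out`).
#' @param modes optional character vector (`"voltage"`/`"spike"`) per
#'   column, as stored in `sns_model$output_modes`.
#' @return `read_input_series()` a numeric matrix with column names;
#'   `write_output_series()` the path, invisibly.
#' @export
read_input_series <- function(path) {
  if (!file.exists(path)) stop(sprintf("input series '%s' not found", path))
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) == 0L) stop("input series has no columns")
  for (j in seq_len(ncol(df))) {
    if (!is.numeric(df[[j]])) {
      stop(sprintf("non-numeric values in input column '%s'", names(df)[j]))
    }
  }
  m <- as.matrix(df)
  if (anyNA(m)) stop("missing values in input series")
  m
}

#' @rdname read_input_series
#' @export
write_output_series <- function(path, x, modes = NULL) {
  stopifnot(is.matrix(x) || is.data.frame(x))
  x <- as.matrix(x)
  if (!is.null(modes)) {
    if (length(modes) != ncol(x)) {
      stop("modes must have one entry per output column")
    }
    sp <- modes == "spike"
    x[, sp] <- -x[, sp]  # internal 0/-1 -> user-facing 0/1
  }
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
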