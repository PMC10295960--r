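#' Expand a population-to-population connection preset into matrices
#'
#' These helpers build the dense parameter blocks that [compile_network()]
#' scatters into the global \eqn{N \times N} synaptic matrices (columns =
#' presynaptic neuron, rows = postsynaptic neuron).
#'
#' `expand_all_to_all()` connects every (dst, src) pair and scales the
#' per-synapse conductance to `Gmax / n_src`, so the total conductance into
#' each postsynaptic neuron equals the preset's `Gmax`.
#'
#' `expand_one_to_one()` yields diagonal parameter matrices with every
#' synapse sharing the preset values.
#'
#' `expand_pattern()` replicates a small odd-dimension kernel at every
#' spatial offset between two identically shaped 2-D populations (zero
#' padding, stride 1, row-major flattening): with a
#' \eqn{(2u+1)\times(2v+1)} kernel `K`, entry `P[p, q]` for destination
#' grid cell `p` and source grid cell `q` is
#' `K[u + 1 + (q_row - p_row), v + 1 + (q_col - p_col)]` when both offsets
#' lie within the kernel, else 0.
#'
#' @param type an `sns_connection_type`.
#' @param n_src,n_dst source/destination population sizes.
#' @param n common size for one-to-one connections.
#' @param kernel numeric matrix with odd dimensions (one synaptic
#'   parameter).
#' @param shape `c(rows, cols)` of both populations.
#' @return for the type-based helpers, a named list of parameter matrices
#'   (`Gmax` plus the kind's other parameters); for `expand_pattern()`, a
#'   single `prod(shape) x prod(shape)` matrix.
#' @examples
#' expand_pattern(matrix(1, 1, 1) * 5, c(2, 2))  # 5 * identity
#' @export
expand_all_to_all <- function(type, n_src, n_dst) {
  stopifnot(n_src >= 1, n_dst >= 1)
  uniform_params(type, matrix(type$Gmax / n_src, n_dst, n_src))
}

#' @rdname expand_all_to_all
#' @export
expand_one_to_one <- function(type, n) {
  stopifnot(n >= 1)
  uniform_params(type, diag(type$Gmax, n, n))
}

#' @rdname expand_all_to_all
#' @export
expand_pattern <- function(kernel, shape) {
  if (!is.matrix(kernel) || any(dim(kernel) %% 2L == 0L)) {
    stop("pattern kernel must have odd dimensions")
  }
  if (length(shape) != 2L) stop("shape must be c(rows, cols)")
  R <- shape[1]; C <- shape[2]
  u <- (nrow(kernel) - 1L) %/% 2L
  v <- (ncol(kernel) - 1L) %/% 2L
  n <- R * C
  P <- matrix(0, n, n)
  # row-major flat index: cell (r, c), 0-based, sits at r * C + c + 1
  for (pr in 0:(R - 1L)) for (pc in 0:(C - 1L)) {
    p <- pr * C + pc + 1L
    for (qr in 0:(R - 1L)) for (qc in 0:(C - 1L)) {
      dr <- qr - pr
      dc <- qc - pc
      if (abs(dr) <= u && abs(dc) <= v) {
        P[p, qr * C + qc + 1L] <- kernel[u + 1L + dr, v + 1L + dc]
      }
    }
  }
  P
}

# Parameter matrices where every synapse in a conductance block shares the
# preset's non-conductance parameters.
uniform_params <- function(type, Gmax) {
  out <- list(Gmax = Gmax)
  fill <- function(value) {
    m <- matrix(0, nrow(Gmax), ncol(Gmax))
    m[Gmax > 0] <- value
    m
  }
  if (type$kind == "chemical_nonspiking") {
    out$Esyn <- fill(type$Esyn)
    out$Elo <- fill(type$Elo)
    # keep Ehi > Elo even at absent synapses so the ramp stays well defined
    out$Ehi <- out$Elo
    out$Ehi[Gmax > 0] <- type$Ehi
    out$Ehi[Gmax <= 0] <- out$Elo[Gmax <= 0] + 1
  } else if (type$kind == "chemical_spiking") {
    out$Esyn <- fill(type$Esyn)
    out$tau_syn <- fill(type$tau_syn)
    out$delay <- fill(type$delay)
  }
  out
}

# Complete a user payload (matrix scheme) with preset defaults at synapses.
complete_payload <- function(payload, type) {
  Gmax <- payload$Gmax
  defaults <- uniform_params(type, Gmax)
  for (nm in names(defaults)) {
    if (!is.null(payload[[nm]])) defaults[[nm]] <- payload[[nm]]
  }
  defaults
}

#' Compile a network into an executable model
#'
#' Flattens an [sns_network()] into per-neuron parameter vectors, dense
#' \eqn{N \times N} synaptic parameter matrices (columns = presynaptic,
#' rows = postsynaptic), precomputed dimensionless time factors
#' (\eqn{T_\theta = \Delta t/\tau_\theta}, \eqn{T_{syn} = \Delta t/\tau_{syn}}),
#' a spike delay buffer of depth `max(delay) + 1`, a channel instance
#' table, and binary input/output routing maps.  Compilation is pure and
#' deterministic: the same network and timestep always produce an
#' identical model.
#'
#' The membrane update applies the exact forward-Euler step of the leaky
#' integrator, using the per-neuron factor \eqn{\Delta t / C_m} on the
#' total current \eqn{-G_m (V - V_{rest}) + \sum I}; see the methods
#' vignette for the rationale.
#'
#' @param net an `sns_network`.
#' @param dt simulation timestep (ms), > 0.  A warning is issued when `dt`
#'   is not smaller than some spiking synapse's `tau_syn` (the discrete
#'   decay factor `1 - dt/tau_syn` would be non-positive).
#' @return an object of class `sns_model`.
#' @export
compile_network <- function(net, dt = 0.1) {
  stopifnot(inherits(net, "sns_network"))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("dt must be a positive timestep in ms")
  }
  pops <- net$populations
  sizes <- vapply(pops, function(p) p$size, numeric(1))
  starts <- cumsum(c(0, sizes))[seq_along(pops)]
  N <- as.integer(sum(sizes))
  pop_tab <- data.frame(
    name = vapply(pops, `[[`, "", "name"),
    start = as.integer(starts), size = as.integer(sizes),
    stringsAsFactors = FALSE)
  range_of <- function(name) {
    k <- match(name, pop_tab$name)
    if (is.na(k)) stop(sprintf("unknown population '%s'", name))
    if (pop_tab$size[k] == 0L) integer(0)
    else (pop_tab$start[k] + 1L):(pop_tab$start[k] + pop_tab$size[k])
  }

  # --- per-neuron parameter vectors --------------------------------------
  Cm <- Gm <- Vrest <- Ibias <- theta0 <- Ttheta <- m_vec <- V0 <- numeric(N)
  spiking <- logical(N)
  neuron_names <- character(N)
  channels <- list()
  for (k in seq_along(pops)) {
    p <- pops[[k]]
    idx <- range_of(p$name)
    ty <- p$type
    Cm[idx] <- ty$Cm; Gm[idx] <- ty$Gm
    Vrest[idx] <- ty$Vrest; Ibias[idx] <- ty$Ibias
    spiking[idx] <- ty$spiking
    theta0[idx] <- if (ty$spiking) ty$theta0 else Inf
    Ttheta[idx] <- if (ty$spiking) dt / ty$tau_theta else 0
    m_vec[idx] <- if (ty$spiking) ty$m else 0
    V0[idx] <- if (is.null(p$initial_voltage)) ty$Vrest else p$initial_voltage
    neuron_names[idx] <- if (p$size == 1L) p$name else
      paste0(p$name, "[", seq_len(p$size), "]")
    for (ch in ty$channels) {
      for (i in idx) {
        channels[[length(channels) + 1L]] <- c(list(neuron = i), ch)
      }
    }
  }
  chan_tab <- if (length(channels)) {
    do.call(rbind, lapply(channels, function(ch) {
      data.frame(neuron = ch$neuron, name = ch$name, Gion = ch$Gion,
                 Eion = ch$Eion, pa = ch$pa, Ka = ch$Ka, Sa = ch$Sa,
                 Ea = ch$Ea, pb = ch$pb, Kb = ch$Kb, Sb = ch$Sb,
                 Eb = ch$Eb, tau_max_b = ch$tau_max_b, pc = ch$pc,
                 Kc = ch$Kc, Sc = ch$Sc, Ec = ch$Ec,
                 tau_max_c = ch$tau_max_c, stringsAsFactors = FALSE)
    }))
  } else NULL

  # --- synaptic parameter matrices ---------------------------------------
  zero <- function() matrix(0, N, N)
  Gmax_non <- zero(); Elo <- zero(); Ehi <- zero()
  Gmax_spike <- zero(); Tsyn <- zero(); delay <- matrix(0L, N, N)
  Esyn <- zero()
  G_elec <- zero(); G_rec <- zero()
  chem_mask <- matrix(FALSE, N, N)

  place_chemical <- function(block, rows, cols, kind) {
    sub <- chem_mask[rows, cols, drop = FALSE]
    new <- block$Gmax > 0
    if (any(sub & new)) {
      stop("multiple chemical synapses onto one ordered neuron pair; ",
           "merge them into a single connection (dense storage cannot ",
           "superpose reversal potentials)")
    }
    chem_mask[rows, cols] <<- sub | new
    sel <- which(new)
    if (kind == "chemical_nonspiking") {
      g <- Gmax_non[rows, cols, drop = FALSE]; g[sel] <- block$Gmax[sel]
      Gmax_non[rows, cols] <<- g
      e <- Elo[rows, cols, drop = FALSE]; e[sel] <- block$Elo[sel]
      Elo[rows, cols] <<- e
      e <- Ehi[rows, cols, drop = FALSE]; e[sel] <- block$Ehi[sel]
      Ehi[rows, cols] <<- e
      if (any(block$Ehi[sel] <= block$Elo[sel])) {
        stop("Ehi must exceed Elo at every graded synapse")
      }
    } else {
      g <- Gmax_spike[rows, cols, drop = FALSE]; g[sel] <- block$Gmax[sel]
      Gmax_spike[rows, cols] <<- g
      ts <- block$tau_syn[sel]
      if (any(ts <= 0)) stop("tau_syn must be > 0 at every spiking synapse")
      if (any(dt >= ts)) {
        warning(sprintf("dt = %g ms is not smaller than tau_syn; spiking conductance decay is degenerate", dt))
      }
      tf <- Tsyn[rows, cols, drop = FALSE]; tf[sel] <- dt / ts
      Tsyn[rows, cols] <<- tf
      dl <- block$delay[sel]
      if (any(dl < 0) || any(dl != round(dl))) {
        stop("spike delays must be non-negative integer timesteps")
      }
      d <- delay[rows, cols, drop = FALSE]; d[sel] <- as.integer(dl)
      delay[rows, cols] <<- d
    }
    e <- Esyn[rows, cols, drop = FALSE]; e[sel] <- block$Esyn[sel]
    Esyn[rows, cols] <<- e
  }

  for (cn in net$connections) {
    ty <- cn$type
    rows <- range_of(cn$destination)
    cols <- range_of(cn$source)
    n_dst <- length(rows); n_src <- length(cols)
    block <- switch(cn$scheme,
      direct = expand_all_to_all(ty, n_src, n_dst),
      one_to_one = {
        if (n_src != n_dst) stop("one_to_one requires equal sizes")
        expand_one_to_one(ty, n_src)
      },
      matrix = complete_payload(cn$weights, ty),
      pattern = {
        shp <- find_pop(net, cn$destination)$shape
        ker <- lapply(cn$weights, expand_pattern, shape = shp)
        complete_payload(ker, ty)
      })
    if (any(block$Gmax < 0)) stop("negative synaptic conductance")
    if (ty$kind %in% c("chemical_nonspiking", "chemical_spiking")) {
      if (ty$kind == "chemical_spiking") {
        src_pop <- find_pop(net, cn$source)
        if (!src_pop$type$spiking) {
          stop(sprintf("spiking synapse from non-spiking population '%s'",
                       cn$source))
        }
      }
      place_chemical(block, rows, cols, ty$kind)
    } else {
      g <- block$Gmax
      if (ty$rectified) {
        gr <- G_rec[rows, cols, drop = FALSE]
        G_rec[rows, cols] <- gr + g
      } else {
        ge <- G_elec[rows, cols, drop = FALSE]
        G_elec[rows, cols] <- ge + g
        ge <- G_elec[cols, rows, drop = FALSE]
        G_elec[cols, rows] <- ge + t(g)
      }
    }
  }
  # electrical self-coupling is meaningless; force diagonals to zero
  diag(G_elec) <- 0
  diag(G_rec) <- 0

  has_spike_syn <- any(Gmax_spike > 0)
  D <- if (has_spike_syn) max(delay[Gmax_spike > 0]) + 1L else 1L
  # linear index into the D x N buffer for the delayed spike of pair (i, j)
  delay_lin <- (col(delay) - 1L) * D + delay + 1L

  inv_range <- zero()
  nz <- Gmax_non > 0
  inv_range[nz] <- 1 / (Ehi[nz] - Elo[nz])

  # --- input / output maps -----------------------------------------------
  widths <- vapply(net$inputs, function(x) x$width, integer(1))
  L <- as.integer(sum(widths, 0L))
  Cin <- matrix(0, N, max(L, 0L))
  col0 <- 0L
  for (inp in net$inputs) {
    idx <- range_of(inp$target)
    if (inp$width == 1L) {
      Cin[idx, col0 + 1L] <- 1
    } else {
      Cin[cbind(idx, col0 + seq_len(inp$width))] <- 1
    }
    col0 <- col0 + inp$width
  }
  out_rows <- list()
  out_names <- character(0)
  out_modes <- character(0)
  for (out in net$outputs) {
    idx <- range_of(out$source)
    for (i in idx) {
      out_rows[[length(out_rows) + 1L]] <- c(i, out$mode == "voltage")
      out_modes <- c(out_modes, out$mode)
    }
    out_names <- c(out_names,
                   paste0(neuron_names[idx], ":",
                          substr(out$mode, 1, 1)))
  }
  n_out <- length(out_rows)
  Cout_v <- matrix(0, n_out, N)
  Cout_s <- matrix(0, n_out, N)
  for (r in seq_len(n_out)) {
    i <- out_rows[[r]][1]
    if (out_rows[[r]][2] == 1) Cout_v[r, i] <- 1 else Cout_s[r, i] <- 1
  }

  model <- structure(
    list(dt = dt, N = N, L = L, n_out = n_out,
         pop_tab = pop_tab, neuron_names = neuron_names,
         Cm = Cm, Gm = Gm, Vrest = Vrest, Ibias = Ibias, V0 = V0,
         spiking = spiking, theta0 = theta0, Ttheta = Ttheta, m = m_vec,
         Tm = dt / Cm,
         Gmax_non = Gmax_non, Elo = Elo, Ehi = Ehi, inv_range = inv_range,
         Gmax_spike = Gmax_spike, Tsyn = Tsyn, decay = 1 - Tsyn,
         delay = delay, D = D, delay_lin = delay_lin, Esyn = Esyn,
         G_elec = G_elec, G_rec = G_rec,
         has_non = any(Gmax_non > 0), has_spike_syn = has_spike_syn,
         has_elec = any(G_elec > 0), has_rec = any(G_rec > 0),
         channels = chan_tab,
         Cin = Cin, Cout_v = Cout_v, Cout_s = Cout_s,
         output_names = out_names, output_modes = out_modes,
         iter = NULL),
    class = "sns_model")
  model$iter <- build_iter_tables(model)
  model
}

# Flat synapse/pair tables for the synapse-iterating backend.
build_iter_tables <- function(model) {
  nz <- function(M) which(M > 0, arr.ind = TRUE)
  it <- list()
  idx <- nz(model$Gmax_non)
  it$chem_non <- data.frame(
    i = idx[, 1], j = idx[, 2],
    Gmax = model$Gmax_non[idx], Esyn = model$Esyn[idx],
    Elo = model$Elo[idx], Ehi = model$Ehi[idx])
  idx <- nz(model$Gmax_spike)
  it$chem_spk <- data.frame(
    i = idx[, 1], j = idx[, 2],
    Gmax = model$Gmax_spike[idx], Esyn = model$Esyn[idx],
    Tsyn = model$Tsyn[idx], delay = model$delay[idx])
  eu <- which(upper.tri(model$G_elec) & model$G_elec > 0, arr.ind = TRUE)
  it$elec <- data.frame(i = eu[, 1], j = eu[, 2], G = model$G_elec[eu])
  ru <- nz(model$G_rec)
  it$rec <- data.frame(i = ru[, 1], j = ru[, 2], G = model$G_rec[ru])
  it
}

#' @export
print.sns_model <- function(x, ...) {
  cat(sprintf("<sns_model> N=%d neurons, dt=%g ms, L=%d input(s), %d output(s)\n",
              x$N, x$dt, x$L, x$n_out))
  cat(sprintf("  synapses: %d graded, %d spiking (buffer depth %d), %d electrical pair(s), %d rectified\n",
              sum(x$Gmax_non > 0), sum(x$Gmax_spike > 0), x$D,
              nrow(x$iter$elec), nrow(x$iter$rec)))
  invisible(x)
}
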