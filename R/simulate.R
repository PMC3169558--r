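#' Simulate the two-field network
#'
#' Advances the coupled somatic (Izhikevich), dendritic (truncated
#' Morris-Lecar), synaptic-drive and global-inhibition equations with
#' classical 4th-order Runge-Kutta at step `dt`, in compiled code. External
#' currents (noise held constant within each step) and the inhibitory
#' conductance are frozen during a step; spike resets, synaptic increments,
#' inhibitory increments and dendritic truncation are applied at step
#' boundaries. The run is fully deterministic given `seed`.
#'
#' @param conn A [build_connectivity()] map (carries the geometry).
#' @param protocol A [stimulus_protocol()].
#' @param duration Simulated time, ms.
#' @param dt Integration step, ms; must be positive and at most 0.25 ms
#'   (stability guard).
#' @param soma,dend,inh Parameter objects.
#' @param init Optional [network_state()] to continue from; defaults to the
#'   resting state with 1 mV somatic jitter (seeded from `seed`).
#' @param seed Integer seed for the noise stream (and default init jitter).
#' @param snapshot_dt Cadence (ms) at which the somatic adaptation field `u`,
#'   the dendritic potential `V` and gate `w` are recorded; 0 disables.
#' @param trace_soma,trace_dend Unit indices whose full per-step traces are
#'   recorded.
#' @return Object of class `sim_result`: `spikes` (data frame `time_ms`,
#'   `soma_row`, `soma_col`, `unit`), `snapshots` (list with `t` and one
#'   `n x n x k` array per recorded field), `state` (final
#'   [network_state()]), `traces`, plus the geometry, parameters, protocol,
#'   `dt` and `seed` of the run.
#' @examples
#' \donttest{
#' g <- field_geometry(16)
#' k <- gaussian_kernel(0.4, 0.15)
#' conn <- build_connectivity(g, k, k, seed = 1)
#' prot <- stimulus_protocol(stim_segment(0, 100, "soma", kind = "constant",
#'                                        amplitude = 5))
#' sim <- simulate_network(conn, prot, duration = 100, seed = 1)
#' nrow(sim$spikes)
#' }
#' @export
simulate_network <- function(conn, protocol, duration, dt = 0.1,
                             soma = soma_params(), dend = dendrite_params(),
                             inh = inhibition_params(), init = NULL,
                             seed = 1L, snapshot_dt = 10,
                             trace_soma = integer(0),
                             trace_dend = integer(0)) {
  if (dt <= 0 || dt > 0.25) stop("dt must be in (0, 0.25] ms")
  geometry <- conn$geometry
  if (is.null(init))
    init <- network_state(geometry, soma, dend, v_jitter = 1, seed = seed)
  ax <- conn_csr(conn$axon_targets)
  br <- conn_csr(conn$soma_branches)
  segs <- compile_protocol(protocol, geometry, dt)

  out <- with_seed(seed + protocol$rng_seed, {
    sim_network_cpp(geometry$n_soma_side^2, geometry$n_dend_side^2,
                    ax$ptr, ax$idx, br$ptr, br$idx,
                    soma_par_vec(soma), dend_par_vec(dend), inh_par_vec(inh),
                    dend$g_ds, segs$soma, segs$dendrite,
                    init$t, duration, dt,
                    init$v, init$u, init$V, init$w, init$S, init$V_I,
                    snapshot_dt,
                    as.integer(trace_soma) - 1L, as.integer(trace_dend) - 1L)
  })

  n <- geometry$n_soma_side
  rc <- unit_to_rowcol(out$spike_unit, n)
  spikes <- data.frame(time_ms = out$spike_time,
                       soma_row = rc[, "row"], soma_col = rc[, "col"],
                       unit = out$spike_unit)
  nd <- geometry$n_dend_side
  to_arr <- function(m, side) {
    if (nrow(m) == 0) return(array(0, dim = c(side, side, 0)))
    array(t(m), dim = c(side, side, nrow(m)))
  }
  snapshots <- if (snapshot_dt > 0)
    list(t = out$snap_t, u = to_arr(out$snap_u, n),
         V = to_arr(out$snap_V, nd), w = to_arr(out$snap_w, nd))
  else NULL
  state <- structure(c(out$state[c("v", "u", "V", "w", "S", "V_I", "t")],
                       list(spikes = spikes)), class = "network_state")
  structure(list(spikes = spikes, snapshots = snapshots, state = state,
                 traces = list(t = out$trace_t, V_I = out$trace_VI,
                               v = out$trace_v, u = out$trace_u,
                               V = out$trace_V, w = out$trace_w,
                               S = out$trace_S),
                 geometry = geometry,
                 params = list(soma = soma, dend = dend, inh = inh),
                 protocol = protocol, dt = dt, seed = seed),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %.0f ms at dt = %g ms on %dx%d somata: %d spikes (%.2f spikes/ms network rate)\n",
              x$state$t, x$dt, x$geometry$n_soma_side, x$geometry$n_soma_side,
              nrow(x$spikes),
              if (x$state$t > 0) nrow(x$spikes) / x$state$t else 0))
  invisible(x)
}

#' @export
plot.sim_result <- function(x, what = c("raster", "rate_map"), t_range = NULL,
                            ...) {
  what <- match.arg(what)
  sp <- x$spikes
  if (!is.null(t_range))
    sp <- sp[sp$time_ms >= t_range[1] & sp$time_ms < t_range[2], ]
  if (what == "raster") {
    plot(sp$time_ms, sp$unit, pch = ".", xlab = "time (ms)",
         ylab = "somatic unit", ...)
  } else {
    n <- x$geometry$n_soma_side
    counts <- matrix(0, n, n)
    if (nrow(sp)) {
      tb <- table(factor(sp$unit, levels = seq_len(n * n)))
      counts <- matrix(as.numeric(tb), n, n)
    }
    graphics::image(seq_len(n), seq_len(n), counts, xlab = "row",
                    ylab = "col", ...)
  }
  invisible(x)
}

#' Advance a network state by one integration step
#'
#' Single-step interface over the same compiled path as
#' [simulate_network()]: one RK4 step, then spike resets, synaptic and
#' inhibitory increments, and dendritic truncation.
#'
#' @inheritParams simulate_network
#' @param state A [network_state()].
#' @return The advanced `network_state` (spikes appended to `state$spikes`).
#' @export
network_step <- function(state, conn, protocol, dt = 0.1,
                         soma = soma_params(), dend = dendrite_params(),
                         inh = inhibition_params(), seed = 1L) {
  res <- simulate_network(conn, protocol, duration = dt, dt = dt, soma = soma,
                          dend = dend, inh = inh, init = state, seed = seed,
                          snapshot_dt = 0)
  out <- res$state
  out$spikes <- rbind(state$spikes, res$spikes)
  out
}

#' Write / read a spike raster as CSV
#'
#' @param spikes Raster data frame (`time_ms`, `soma_row`, `soma_col`, and
#'   optionally `unit`).
#' @param path CSV path.
#' @return `read_raster()` returns the raster data frame.
#' @export
write_raster <- function(spikes, path) {
  utils::write.csv(spikes[c("time_ms", "soma_row", "soma_col")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @param n_side Lattice side used to reconstruct unit indices.
#' @export
read_raster <- function(path, n_side) {
  r <- utils::read.csv(path)
  r$unit <- rowcol_to_unit(r$soma_row, r$soma_col, n_side)
  r
}
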