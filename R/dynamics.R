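#' Somatic right-hand side
#'
#' Time derivatives of the somatic potential and adaptation current:
#' `dv/dt = 0.04 v^2 + 5 v + 140 - u + I_dend + I_ext - G_inh (v - E_inh)`,
#' `du/dt = a (b v - u)`. Vectorized over units. This is the reference
#' implementation used for testing; the network stepper evaluates the same
#' expressions in compiled code.
#'
#' @param v Somatic potential(s), mV.
#' @param u Adaptation current(s).
#' @param I_dend Dendro-somatic current(s), pA.
#' @param I_ext External current(s), pA.
#' @param G_inh Global inhibitory conductance (scalar).
#' @param params A [soma_params()].
#' @return List with `dv`, `du` (per ms).
#' @export
soma_rhs <- function(v, u, I_dend = 0, I_ext = 0, G_inh = 0, params) {
  if (!all(is.finite(v), is.finite(u), is.finite(I_dend), is.finite(I_ext),
           is.finite(G_inh)))
    stop("non-finite input to soma_rhs")
  list(dv = 0.04 * v^2 + 5 * v + 140 - u + I_dend + I_ext -
         G_inh * (v - params$E_inh),
       du = params$a * (params$b * v - u))
}

#' Morris-Lecar gating curves of the dendritic unit
#'
#' @param V Dendritic potential(s), mV.
#' @param params A [dendrite_params()].
#' @return List with `m_inf` (instantaneous Ca activation), `w_inf`
#'   (steady-state K gate) and `lambda` (gate rate factor).
#' @export
dendrite_gates <- function(V, params) {
  list(m_inf = 0.5 * (1 + tanh((V - params$V1) / params$V2)),
       w_inf = 0.5 * (1 + tanh((V - params$V3) / params$V4)),
       lambda = cosh((V - params$V3) / (2 * params$V4)))
}

#' Dendritic right-hand side
#'
#' Truncated Morris-Lecar dynamics with conductance-based synaptic drive (see
#' [dendrite_params()] for the equations). The `g_K * w` term is the
#' dendritic K+ conductance: an intrinsic hyperpolarizing current that
#' eventually terminates the plateau against the excitatory drive.
#'
#' @param V Dendritic potential(s), mV.
#' @param w K+ gate value(s) in `[0, 1]`.
#' @param S Synaptic drive(s).
#' @param params A [dendrite_params()].
#' @param I_ext Optional external current injected into the dendrite, pA.
#' @return List with `dV`, `dw` (per ms).
#' @export
dendrite_rhs <- function(V, w, S, params, I_ext = 0) {
  if (any(w < 0 | w > 1)) stop("gate variable w outside [0, 1]")
  g <- dendrite_gates(V, params)
  dV <- (-params$g_Ca * g$m_inf * (V - params$V_Ca) -
           params$g_K * w * (V - params$V_K) -
           params$g_L * (V - params$V_L) +
           params$g_syn * S * (params$E_syn - params$kappa * V) +
           I_ext) / params$C_d
  dw <- g$lambda * (g$w_inf - w) / params$tau_d
  list(dV = dV, dw = dw)
}

#' Initial network state
#'
#' All units start at their unforced resting points with zero synaptic drive
#' and a silent inhibitory unit. An optional uniform jitter on the somatic
#' potentials breaks the translational symmetry of the lattice so a bump can
#' nucleate somewhere under spatially uniform drive.
#'
#' @param geometry A [field_geometry()].
#' @param soma,dend Parameter objects.
#' @param v_jitter Half-width (mV) of uniform jitter added to the somatic
#'   resting potential.
#' @param seed Seed for the jitter (required when `v_jitter > 0`).
#' @return Object of class `network_state` with fields `v`, `u`, `V`, `w`,
#'   `S`, `V_I`, `t` and an empty, time-ordered `spikes` data frame.
#' @export
network_state <- function(geometry, soma = soma_params(),
                          dend = dendrite_params(), v_jitter = 0,
                          seed = NULL) {
  ns <- geometry$n_soma_side^2
  nd <- geometry$n_dend_side^2
  v <- rep(soma$v_rest, ns)
  if (v_jitter > 0) {
    if (is.null(seed)) stop("seed is required when v_jitter > 0")
    v <- v + with_seed(seed, stats::runif(ns, -v_jitter, v_jitter))
  }
  structure(list(v = v, u = rep(soma$u_rest, ns),
                 V = rep(dend$V_rest, nd), w = rep(dend$w_rest, nd),
                 S = rep(0, nd), V_I = 0, t = 0,
                 spikes = empty_raster()),
            class = "network_state")
}

empty_raster <- function()
  data.frame(time_ms = numeric(0), soma_row = integer(0),
             soma_col = integer(0), unit = integer(0))

#' Spike detection and reset
#'
#' Every somatic unit at or above `v_peak` is recorded as a spike at the
#' current state time, then reset (`v <- c`, `u <- u + d`). Events are
#' appended in unit-index order, keeping the raster time-ordered.
#'
#' @param state A [network_state()].
#' @param params A [soma_params()].
#' @param geometry A [field_geometry()] (to map unit index to row/col).
#' @return The updated state; `attr(, "spiked")` holds the indices reset in
#'   this call.
#' @export
apply_spike_resets <- function(state, params, geometry) {
  hit <- which(state$v >= params$v_peak)
  if (length(hit)) {
    state$v[hit] <- params$c
    state$u[hit] <- state$u[hit] + params$d
    rc <- unit_to_rowcol(hit, geometry$n_soma_side)
    state$spikes <- rbind(state$spikes,
                          data.frame(time_ms = state$t, soma_row = rc[, "row"],
                                     soma_col = rc[, "col"], unit = hit))
  }
  attr(state, "spiked") <- hit
  state
}

#' Truncate the dendritic after-hyperpolarization
#'
#' The plain Morris-Lecar unit overshoots into a deep after-hyperpolarization
#' once the plateau ends, which real dendrites do not show. Any dendritic
#' unit below `V_rest` is clamped back to `V_rest` with its gate reset to
#' `w_inf(V_rest)` (without the gate reset, residual K conductance would
#' immediately re-hyperpolarize the unit). Idempotent.
#'
#' @param state A [network_state()].
#' @param params A [dendrite_params()].
#' @return The updated state.
#' @export
truncate_hyperpolarization <- function(state, params) {
  below <- state$V < params$V_rest
  state$V[below] <- params$V_rest
  state$w[below] <- params$w_rest
  state
}

#' First-order synaptic drive update
#'
#' `S` decays exponentially with `tau_syn` over the step and gains one unit
#' per presynaptic somatic spike delivered through the axon adjacency
#' (spikes detected at a step's end are credited at that boundary).
#'
#' @param S Current drive value(s), >= 0.
#' @param n_spikes Number of presynaptic spikes arriving at this unit.
#' @param dt Step, ms (> 0).
#' @param params A [dendrite_params()].
#' @return Updated drive, always >= 0.
#' @export
synaptic_drive_update <- function(S, n_spikes, dt, params) {
  if (dt <= 0) stop("dt must be > 0")
  S * exp(-dt / params$tau_syn) + n_spikes
}

#' Global inhibitory unit update
#'
#' `V_I` decays with `tau_I` and jumps by `drive_gain` per somatic spike in
#' the whole network this step; the feedback conductance applied uniformly to
#' all somata is the rectified-linear `G_inh = g_I * max(V_I, 0)`.
#'
#' @param V_I Inhibitory unit potential.
#' @param n_spikes Network-wide somatic spike count this step.
#' @param dt Step, ms (> 0).
#' @param params An [inhibition_params()].
#' @return List with updated `V_I` and `G_inh`.
#' @export
inhibition_update <- function(V_I, n_spikes, dt, params) {
  if (dt <= 0) stop("dt must be > 0")
  V_I <- V_I * exp(-dt / params$tau_I) + params$drive_gain * n_spikes
  list(V_I = V_I, G_inh = params$g_I * max(V_I, 0))
}

#' Dendro-somatic current
#'
#' Each soma receives from every dendritic unit that is one of its branches a
#' current proportional to the voltage difference between the (rescaled)
#' branch potential and the soma: `I_D,i = g_ds * sum_j (kappa V_j - v_i)`.
#' Signal flow is one-way: no reciprocal current is applied to the dendrite.
#'
#' @param state A [network_state()].
#' @param conn A [build_connectivity()] map.
#' @param params A [dendrite_params()] (supplies `g_ds` and `kappa`).
#' @return Numeric vector of currents, one per somatic unit.
#' @export
dendrosomatic_current <- function(state, conn, params) {
  vapply(seq_along(conn$soma_branches), function(i) {
    br <- conn$soma_branches[[i]]
    if (!length(br)) return(0)
    params$g_ds * sum(params$kappa * state$V[br] - state$v[i])
  }, numeric(1))
}

#' Simulate one isolated dendritic unit
#'
#' Integrates a single dendritic unit from rest under a square current pulse
#' and/or an initial synaptic drive, with truncation applied. Used to study
#' the all-or-none plateau and its duration.
#'
#' @param params A [dendrite_params()].
#' @param duration Total time, ms.
#' @param dt Step, ms.
#' @param pulse_amp Pulse amplitude, pA.
#' @param pulse_t0,pulse_t1 Pulse window, ms.
#' @param S_init Initial synaptic drive.
#' @return Data frame with columns `t`, `V`, `w`, `S`.
#' @export
simulate_dendrite <- function(params, duration = 1000, dt = 0.1,
                              pulse_amp = 0, pulse_t0 = 50, pulse_t1 = 100,
                              S_init = 0) {
  out <- sim_dendrite_cpp(dend_par_vec(params), duration, dt,
                          pulse_amp, pulse_t0, pulse_t1, S_init)
  data.frame(t = out$t, V = out$V, w = out$w, S = out$S)
}

#' Plateau amplitude and duration of a pulse response
#'
#' @param trace Data frame from [simulate_dendrite()].
#' @param params The [dendrite_params()] used.
#' @return List with `amplitude` (max depolarization above rest, mV) and
#'   `duration` (time spent above half the maximum depolarization, ms).
#' @export
plateau_stats <- function(trace, params) {
  dep <- trace$V - params$V_rest
  amp <- max(dep)
  dt <- trace$t[2] - trace$t[1]
  list(amplitude = amp, duration = sum(dep > amp / 2) * dt)
}

#' Smallest pulse amplitude that triggers a plateau
#'
#' Bisection on the pulse amplitude of a fixed-width current pulse into one
#' isolated dendritic unit; the all-or-none property makes the threshold
#' sharp.
#'
#' @param params A [dendrite_params()].
#' @param pulse_width Pulse width, ms.
#' @param lo,hi Bracketing amplitudes, pA.
#' @param amp_criterion Depolarization (mV above rest) that counts as a
#'   plateau.
#' @param tol Bisection tolerance, pA.
#' @return Threshold amplitude, pA.
#' @export
plateau_threshold <- function(params, pulse_width = 5, lo = 0, hi = 400,
                              amp_criterion = 40, tol = 0.5) {
  fires <- function(a) {
    tr <- simulate_dendrite(params, duration = 300, pulse_amp = a,
                            pulse_t0 = 10, pulse_t1 = 10 + pulse_width)
    plateau_stats(tr, params)$amplitude > amp_criterion
  }
  if (fires(lo)) return(lo)
  if (!fires(hi)) stop("upper bracket does not trigger a plateau")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
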