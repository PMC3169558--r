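#' Somatic unit parameters
#'
#' The soma is the quadratic adaptive spiking unit of Izhikevich, a minimal
#' one-auxiliary-variable extension of the integrate-and-fire model:
#' `dv/dt = 0.04 v^2 + 5 v + 140 - u + I`, `du/dt = a (b v - u)`, with reset
#' `v <- c`, `u <- u + d` when `v` reaches `v_peak`. The adaptation variable
#' `u` plays the role of a somatic K+ current: it accumulates with every
#' spike and decays with time constant `1/a`, giving after-spike adaptation
#' that is central to bump motion. Defaults are the standard regular-spiking
#' parameterization (`1/a = 50` ms).
#'
#' @param a Adaptation rate, 1/ms.
#' @param b Adaptation voltage coupling (dimensionless).
#' @param c Reset potential, mV.
#' @param d Adaptation increment per spike.
#' @param v_peak Spike cutoff, mV.
#' @param E_inh Reversal potential of the global inhibitory conductance, mV.
#' @return Object of class `soma_params`; includes the resting point
#'   (`v_rest`, `u_rest`) of the unforced unit.
#' @export
soma_params <- function(a = 0.02, b = 0.2, c = -65, d = 8, v_peak = 30,
                        E_inh = -75) {
  if (a <= 0) stop("a must be > 0")
  if (v_peak <= c) stop("v_peak must exceed the reset potential c")
  # resting point: 0.04 v^2 + 5 v + 140 = u = b v, lower root
  disc <- (5 - b)^2 - 4 * 0.04 * 140
  if (disc < 0) stop("no subthreshold resting point for these (a, b)")
  v_rest <- (-(5 - b) - sqrt(disc)) / (2 * 0.04)
  structure(list(a = a, b = b, c = c, d = d, v_peak = v_peak, E_inh = E_inh,
                 v_rest = v_rest, u_rest = b * v_rest),
            class = "soma_params")
}

#' Dendritic unit parameters
#'
#' Each dendritic unit follows Morris-Lecar dynamics with the K+ recovery
#' gate slowed by `tau_d` and the after-hyperpolarization truncated at the
#' resting potential, producing all-or-none plateau potentials whose duration
#' is set by `tau_d`:
#' \deqn{C_d dV/dt = -g_{Ca} m_\infty(V)(V - V_{Ca}) - g_K w (V - V_K)
#'   - g_L (V - V_L) + g_{syn} S (E_{syn} - \kappa V)}
#' \deqn{dw/dt = \lambda(V) (w_\infty(V) - w) / \tau_d}
#' with `m_inf(V) = (1 + tanh((V - V1)/V2))/2`,
#' `w_inf(V) = (1 + tanh((V - V3)/V4))/2`,
#' `lambda(V) = cosh((V - V3)/(2 V4))`. The synaptic drive `S` jumps by one
#' per presynaptic somatic spike and decays with `tau_syn`. Wherever the
#' dendritic potential drives a current (the synaptic term above and the
#' dendro-somatic current) it enters rescaled as `kappa * V`, moderating the
#' plateau's effect downstream.
#'
#' The resting potential `V_rest` (stable fixed point of the unforced
#' dynamics) and `w_rest = w_inf(V_rest)` are located numerically at
#' construction and verified by a short relaxation run.
#'
#' Conductance defaults are a canonical Morris-Lecar set; `tau_d` is the one
#' swept parameter (the principal determinant of plateau duration), with
#' values of hundreds of ms giving the "slow dendrite" regime.
#'
#' @param C_d Capacitance-like scale.
#' @param g_Ca,g_K,g_L Conductances (mS/uF).
#' @param V_Ca,V_K,V_L Reversal potentials (mV).
#' @param V1,V2,V3,V4 Activation-curve parameters (mV).
#' @param tau_d Dendritic K+ gate time constant (ms); sets plateau duration.
#' @param kappa Rescaling of the dendritic potential where it drives
#'   currents, in (0, 1].
#' @param tau_syn Synaptic-drive decay time constant (ms).
#' @param g_syn Synaptic conductance scale.
#' @param E_syn Synaptic reversal potential (mV).
#' @param g_ds Dendro-somatic coupling conductance (per branch).
#' @param validate If `TRUE`, verify numerically that `V_rest` is stable.
#' @return Object of class `dendrite_params`, including `V_rest`, `w_rest`.
#' @export
dendrite_params <- function(C_d = 20, g_Ca = 4.4, g_K = 8, g_L = 2,
                            V_Ca = 120, V_K = -84, V_L = -60,
                            V1 = -1.2, V2 = 18, V3 = 2, V4 = 30,
                            tau_d = 200, kappa = 0.73, tau_syn = 5,
                            g_syn = 2, E_syn = 0, g_ds = 0.0125,
                            validate = TRUE) {
  if (tau_d <= 0) stop("tau_d must be > 0")
  if (kappa <= 0 || kappa > 1) stop("kappa must be in (0, 1]")
  if (tau_syn <= 0) stop("tau_syn must be > 0")
  p <- list(C_d = C_d, g_Ca = g_Ca, g_K = g_K, g_L = g_L, V_Ca = V_Ca,
            V_K = V_K, V_L = V_L, V1 = V1, V2 = V2, V3 = V3, V4 = V4,
            tau_d = tau_d, kappa = kappa, tau_syn = tau_syn, g_syn = g_syn,
            E_syn = E_syn, g_ds = g_ds)
  # unforced fixed point: dV = 0 with w = w_inf(V), lowest root
  f <- function(V) {
    m <- 0.5 * (1 + tanh((V - V1) / V2))
    wi <- 0.5 * (1 + tanh((V - V3) / V4))
    -g_Ca * m * (V - V_Ca) - g_K * wi * (V - V_K) - g_L * (V - V_L)
  }
  root <- stats::uniroot(f, lower = V_K + 1e-6, upper = 0, tol = 1e-10)
  p$V_rest <- root$root
  p$w_rest <- 0.5 * (1 + tanh((p$V_rest - V3) / V4))
  p <- structure(p, class = "dendrite_params")
  if (validate) {
    tr <- sim_dendrite_cpp(dend_par_vec(p), duration = 200, dt = 0.1,
                           pulse_amp = 0, pulse_t0 = 0, pulse_t1 = 0,
                           S_init = 0)
    # perturbed relaxation back to rest
    if (max(abs(tr$V - p$V_rest)) > 1e-6)
      stop("V_rest is not a fixed point of the unforced dendritic dynamics")
  }
  p
}

#' Global inhibitory unit parameters
#'
#' One rate-based unit represents the pooled inhibitory population. Its
#' potential `V_I` decays with `tau_I` and jumps by `drive_gain` for every
#' somatic spike anywhere in the network, so under a steady network rate `r`
#' (spikes/ms) it settles at `drive_gain * r * tau_I`. Feedback is a uniform
#' conductance `G_inh = g_I * max(V_I, 0)` onto every soma.
#'
#' @param tau_I Membrane time constant, ms.
#' @param drive_gain Increment of `V_I` per somatic spike.
#' @param g_I Conductance gain mapping rectified `V_I` to `G_inh`.
#' @return Object of class `inhibition_params`.
#' @export
inhibition_params <- function(tau_I = 10, drive_gain = 1, g_I = 0.02) {
  if (tau_I <= 0) stop("tau_I must be > 0")
  if (drive_gain < 0 || g_I < 0) stop("gains must be >= 0")
  structure(list(tau_I = tau_I, drive_gain = drive_gain, g_I = g_I),
            class = "inhibition_params")
}

# flat parameter vectors in the order the C++ stepper expects
soma_par_vec <- function(p)
  c(p$a, p$b, p$c, p$d, p$v_peak, p$E_inh)
dend_par_vec <- function(p)
  c(p$C_d, p$g_Ca, p$g_K, p$g_L, p$V_Ca, p$V_K, p$V_L, p$V1, p$V2, p$V3,
    p$V4, p$tau_d, p$kappa, p$tau_syn, p$g_syn, p$E_syn, p$V_rest, p$w_rest)
inh_par_vec <- function(p) c(p$tau_I, p$drive_gain, p$g_I)
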