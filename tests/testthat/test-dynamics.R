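test_that("somatic RHS vanishes at the quadratic resting point", {
  sp <- soma_params()
  # resting point located independently by root finding on the nullclines
  f <- function(v) 0.04 * v^2 + 5 * v + 140 - sp$b * v
  v0 <- uniroot(f, c(-80, -60), tol = 1e-12)$root
  rhs <- soma_rhs(v0, sp$b * v0, params = sp)
  expect_equal(rhs$dv, 0, tolerance = 1e-9)
  expect_equal(rhs$du, 0, tolerance = 1e-12)
  expect_equal(sp$v_rest, v0, tolerance = 1e-9)
  # direct substitution at v = 0, u = 0, no inputs
  expect_equal(soma_rhs(0, 0, params = sp)$dv, 140)
  # u relaxes to b v with time constant 1/a (exact linear ODE)
  v <- -60; u0 <- 3
  ts <- seq(0, 200, by = 0.1)
  u <- u0
  for (i in seq_len(length(ts) - 1)) {
    # trapezoidal integration of du/dt = a (b v - u)
    k1 <- soma_rhs(v, u, params = sp)$du
    u1 <- u + 0.1 * k1
    u <- u + 0.05 * (k1 + soma_rhs(v, u1, params = sp)$du)
  }
  expect_equal(u, sp$b * v + (u0 - sp$b * v) * exp(-sp$a * 200),
               tolerance = 1e-4)
  expect_error(soma_rhs(NaN, 0, params = sp), "non-finite")
})

test_that("dendritic RHS gates and fixed point behave as specified", {
  dp <- dend_slow()
  g <- dendrite_gates(dp$V3, dp)
  expect_equal(g$w_inf, 0.5)
  expect_equal(g$lambda, 1)
  # unforced fixed point located at construction
  rhs <- dendrite_rhs(dp$V_rest, dp$w_rest, 0, dp)
  expect_equal(rhs$dV, 0, tolerance = 1e-8)
  expect_equal(rhs$dw, 0, tolerance = 1e-10)
  expect_error(dendrite_rhs(-60, 1.5, 0, dp), "outside")
})

test_that("plateau response is all-or-none with an empty amplitude band", {
  dp <- dend_fast()
  amps <- vapply(seq(20, 160, length.out = 30), function(a) {
    tr <- simulate_dendrite(dp, duration = 400, pulse_amp = a,
                            pulse_t0 = 20, pulse_t1 = 70)
    plateau_stats(tr, dp)$amplitude
  }, numeric(1))
  # two clusters separated by a wide empty band
  lo <- amps[amps < 60]; hi <- amps[amps >= 60]
  expect_gt(length(lo), 0)
  expect_gt(length(hi), 0)
  expect_gt(min(hi) - max(lo), 30)
})

test_that("plateau duration grows monotonically with tau_d over 100x", {
  durs <- vapply(c(5, 25, 100, 500), function(td) {
    dp <- dendrite_params(tau_d = td)
    tr <- simulate_dendrite(dp, duration = 4000, pulse_amp = 300,
                            pulse_t0 = 20, pulse_t1 = 25)
    plateau_stats(tr, dp)$duration
  }, numeric(1))
  expect_true(all(diff(durs) > 0))
})

test_that("after-hyperpolarization is truncated at V_rest and idempotent", {
  dp <- dend_fast()
  tr <- simulate_dendrite(dp, duration = 2000, pulse_amp = 300,
                          pulse_t0 = 20, pulse_t1 = 25)
  expect_gte(min(tr$V), dp$V_rest - 1e-12)
  # trajectory actually returns to the floor after the plateau
  expect_equal(min(tr$V), dp$V_rest, tolerance = 1e-9)
  st <- network_state(geom16(), dend = dp)
  st$V[3] <- dp$V_rest - 10
  st$w[3] <- 0.5
  st2 <- truncate_hyperpolarization(st, dp)
  expect_equal(st2$V[3], dp$V_rest)
  expect_equal(st2$w[3], dp$w_rest)
  expect_identical(truncate_hyperpolarization(st2, dp)[c("V", "w")],
                   st2[c("V", "w")])
  st3 <- truncate_hyperpolarization(st2, dp)  # all V >= V_rest: unchanged
  expect_identical(st3$V, st2$V)
})

test_that("synaptic drive decays exponentially and sums spike increments", {
  dp <- dend_fast()
  expect_equal(synaptic_drive_update(2, 0, 7, dp), 2 * exp(-7 / dp$tau_syn))
  expect_equal(synaptic_drive_update(0, 1, 1e-9, dp), 1, tolerance = 1e-6)
  expect_equal(synaptic_drive_update(1, 3, 5, dp), exp(-1) + 3)
})

test_that("global inhibition integrates spikes with rectified output", {
  ip <- inhibition_params(tau_I = 10, drive_gain = 1, g_I = 0.5)
  # exponential decay without spikes
  expect_equal(inhibition_update(4, 0, 5, ip)$V_I, 4 * exp(-0.5))
  # rectification below zero
  expect_equal(inhibition_update(-2, 0, 1, ip)$G_inh, 0)
  # steady state under constant rate r: V_I -> drive_gain * r * tau_I
  r <- 0.8; dt <- 0.1
  V <- 0
  for (i in 1:20000) V <- inhibition_update(V, rpois(1, r * dt), dt, ip)$V_I
  set.seed(5)
  Vs <- numeric(5000)
  for (i in 1:5000) { V <- inhibition_update(V, rpois(1, r * dt), dt, ip)$V_I
    Vs[i] <- V }
  expect_equal(mean(Vs), ip$drive_gain * r * ip$tau_I, tolerance = 0.1)
})

test_that("dendro-somatic current equals the brute-force edge sum", {
  conn <- conn16()
  dp <- dend_fast()
  st <- network_state(geom16(), dend = dp)
  set.seed(3)
  st$V <- runif(length(st$V), dp$V_rest, 20)
  st$v <- runif(length(st$v), -75, -50)
  got <- dendrosomatic_current(st, conn, dp)
  brute <- numeric(length(st$v))
  for (j in seq_along(conn$branch_owners))     # explicit per-edge loop
    for (i in conn$branch_owners[[j]])
      brute[i] <- brute[i] + dp$g_ds * (dp$kappa * st$V[j] - st$v[i])
  expect_equal(got, brute, tolerance = 1e-12)
  # soma with no branches receives zero
  iso <- which(lengths(conn$soma_branches) == 0)
  if (length(iso)) expect_true(all(got[iso] == 0))
  # single branch at kappa V = v gives zero
  st$V[conn$soma_branches[[1]][1]] <- st$v[1] / dp$kappa
  one <- conn
  one$soma_branches <- lapply(seq_along(one$soma_branches), function(i)
    if (i == 1) one$soma_branches[[1]][1] else integer(0))
  expect_equal(dendrosomatic_current(st, one, dp)[1], 0, tolerance = 1e-12)
})

test_that("spike resets record events and reset state in unit order", {
  g <- geom16()
  sp <- soma_params()
  st <- network_state(g)
  st$t <- 12
  st2 <- apply_spike_resets(st, sp, g)
  expect_identical(nrow(st2$spikes), 0L)
  st$v[c(5, 2)] <- sp$v_peak + c(0, 1)
  st3 <- apply_spike_resets(st, sp, g)
  expect_equal(st3$spikes$unit, c(2L, 5L))  # unit-index order
  expect_true(all(st3$spikes$time_ms == 12))
  expect_equal(st3$v[c(2, 5)], rep(sp$c, 2))
  expect_equal(st3$u[c(2, 5)], st$u[c(2, 5)] + sp$d)
  st$v[] <- sp$v_peak
  st4 <- apply_spike_resets(st, sp, g)
  expect_equal(nrow(st4$spikes), g$n_soma_side^2)
})

test_that("the network stepper holds the rest state and matches closed forms", {
  g <- field_geometry(6, extent = 5)
  tiny <- gaussian_kernel(0.5, 1e-12)
  conn0 <- build_connectivity(g, tiny, tiny, seed = 1)   # empty adjacency
  dp <- dend_fast()
  st0 <- network_state(g, dend = dp)
  prot <- stimulus_protocol(list())
  sim <- simulate_network(conn0, prot, duration = 50, init = st0, dend = dp,
                          snapshot_dt = 0)
  expect_lt(max(abs(sim$state$v - st0$v)), 1e-9)
  expect_lt(max(abs(sim$state$V - st0$V)), 1e-9)
  expect_lt(max(abs(sim$state$w - st0$w)), 1e-9)
  expect_equal(nrow(sim$spikes), 0L)
  # S decays exactly exponentially through the RK4 path (linear subproblem)
  st0$S[] <- 2
  sim2 <- simulate_network(conn0, prot, duration = 20, init = st0, dend = dp,
                           snapshot_dt = 0, trace_dend = 1)
  expect_equal(sim2$traces$S[, 1], 2 * exp(-sim2$traces$t / dp$tau_syn),
               tolerance = 1e-7)
})

test_that("halving dt changes a spike-free trajectory by < 1e-4 (RK4 convergence)", {
  g <- field_geometry(8, extent = 5)
  k <- gaussian_kernel(0.9, 0.3)
  conn <- build_connectivity(g, k, k, seed = 2)
  dp <- dend_fast()
  prot <- stimulus_protocol(stim_segment(0, 100, "soma", region_all(),
                                         "constant", amplitude = 1))
  st <- network_state(g, dend = dp)
  run <- function(dt) simulate_network(conn, prot, duration = 100, dt = dt,
                                       init = st, dend = dp, snapshot_dt = 0)
  a <- run(0.1); b <- run(0.05)
  expect_equal(nrow(a$spikes) + nrow(b$spikes), 0)  # subthreshold regime
  rel <- max(abs(a$state$v - b$state$v)) / max(abs(b$state$v))
  expect_lt(rel, 1e-4)
  relV <- max(abs(a$state$V - b$state$V)) / max(abs(b$state$V))
  expect_lt(relV, 1e-4)
})

test_that("coupling is one-way: somatic perturbation leaves dendrites unchanged", {
  conn <- conn16()
  dp <- dend_fast()
  st <- network_state(geom16(), dend = dp)
  prot <- stimulus_protocol(list())
  base <- network_step(st, conn, prot, dend = dp)
  st2 <- st
  st2$v <- st2$v + 10   # subthreshold perturbation, no spikes emitted
  pert <- network_step(st2, conn, prot, dend = dp)
  expect_identical(nrow(pert$spikes), 0L)
  expect_equal(pert$V, base$V, tolerance = 1e-15)
  expect_equal(pert$w, base$w, tolerance = 1e-15)
})

test_that("divergent dynamics raise an informative error", {
  g <- field_geometry(6, extent = 5)
  tiny <- gaussian_kernel(0.5, 1e-12)
  conn0 <- build_connectivity(g, tiny, tiny, seed = 1)
  prot <- stimulus_protocol(stim_segment(0, 1e9, "soma", region_all(),
                                         "constant", amplitude = 1e7))
  sp <- soma_params(v_peak = 1e9)  # disable the reset so v blows up
  expect_error(simulate_network(conn0, prot, duration = 10, soma = sp),
               "divergence")
  expect_error(simulate_network(conn0, prot, duration = 10, dt = 0.5), "dt")
})

test_that("identical seeds and configs give identical spike rasters", {
  conn <- conn16()
  prot <- stimulus_protocol(stim_segment(0, 1e9, "soma", region_all(),
                                         "white_noise", variance = 30))
  a <- simulate_network(conn, prot, duration = 150, seed = 9, snapshot_dt = 0)
  b <- simulate_network(conn, prot, duration = 150, seed = 9, snapshot_dt = 0)
  expect_identical(a$spikes, b$spikes)
  c2 <- simulate_network(conn, prot, duration = 150, seed = 10,
                         snapshot_dt = 0)
  expect_false(identical(a$spikes, c2$spikes))
})

test_that("w stays in [0, 1] and V at or above V_rest through a noisy run", {
  conn <- conn16()
  dp <- dend_fast()
  prot <- stimulus_protocol(stim_segment(0, 1e9, "soma", region_all(),
                                         "white_noise", variance = 40))
  sim <- simulate_network(conn, prot, duration = 300, dend = dp, seed = 4,
                          snapshot_dt = 10)
  expect_true(all(sim$snapshots$w >= 0 & sim$snapshots$w <= 1))
  expect_true(all(sim$snapshots$V >= dp$V_rest - 1e-9))
  expect_true(!is.unsorted(sim$spikes$time_ms))
})
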