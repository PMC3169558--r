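test_that("periodic Gaussian smoothing conserves mass", {
  set.seed(2)
  m <- matrix(rpois(256, 2), 16, 16)
  sm <- gauss_smooth_periodic(m, 2.5)
  expect_equal(sum(sm), sum(m), tolerance = 1e-9)
  expect_identical(gauss_smooth_periodic(m, 0), m)
})

test_that("spike snapshots count, smooth and conserve spikes", {
  g <- geom16()
  empty <- data.frame(time_ms = numeric(0), unit = integer(0))
  s0 <- spike_snapshot(empty, 50, geometry = g)
  expect_true(all(s0 == 0))
  one <- data.frame(time_ms = 50, unit = 35L)
  # sigma -> 0: delta at the spiking soma
  sd0 <- spike_snapshot(one, 50, filter_sigma = 0, geometry = g)
  expect_equal(which(sd0 == 1), 35L)
  expect_equal(sum(sd0), 1)
  # finite sigma: unit mass, maximal at the spike site
  s1 <- spike_snapshot(one, 50, filter_sigma = 2, geometry = g)
  expect_equal(sum(s1), 1, tolerance = 1e-9)
  expect_equal(which.max(s1), 35L)
  # oracle: direct wrapped-kernel convolution
  rc <- unit_to_rowcol(35L, 16)
  gr <- expand.grid(row = 1:16, col = 1:16)
  dr <- pmin(abs(gr$row - rc[, "row"]), 16 - abs(gr$row - rc[, "row"]))
  dc <- pmin(abs(gr$col - rc[, "col"]), 16 - abs(gr$col - rc[, "col"]))
  kern <- exp(-(dr^2 + dc^2) / (2 * 4))
  expect_equal(as.vector(unclass(s1)), kern / sum(kern), tolerance = 1e-9)
  expect_error(spike_snapshot(one, 500, geometry = g), "span")
})

test_that("lag inner product equals the nested-loop oracle on small rasters", {
  set.seed(4)
  n <- 8; nt <- 12
  arr <- array(runif(n * n * nt), dim = c(n, n, nt))
  ser <- structure(arr, t = seq(0, by = 5, length.out = nt), hop = 5,
                   class = "snapshot_series")
  for (lag in c(0, 5, 25)) {
    k <- lag / 5
    oracle <- 0; cnt <- 0
    for (i in seq_len(nt - k)) {        # brute-force nested loops
      acc <- 0
      for (r in 1:n) for (cc in 1:n) acc <- acc + arr[r, cc, i] * arr[r, cc, i + k]
      oracle <- oracle + acc; cnt <- cnt + 1
    }
    oracle <- oracle / cnt
    got <- lag_inner_product(ser, lag)
    expect_equal(got, oracle, tolerance = 1e-12)
  }
  # non-averaged mode anchors at the first reference time
  k <- 1
  acc <- sum(arr[, , 1] * arr[, , 2])
  expect_equal(lag_inner_product(ser, 5, average = FALSE), acc,
               tolerance = 1e-12)
  expect_error(lag_inner_product(ser, 7), "multiple")
  # identical constant snapshots: product independent of lag
  cser <- structure(array(2, dim = c(4, 4, 6)), t = seq(0, 50, 10), hop = 10,
                    class = "snapshot_series")
  vals <- inner_product_raw(cser, c(0, 10, 30))
  expect_true(all(vals == vals[1]))
  expect_equal(unname(vals[1]), sum(array(2, c(4, 4))^2))
  # orthogonal (disjoint-support) snapshots give zero
  a <- matrix(0, 4, 4); a[1, 1] <- 3
  b <- matrix(0, 4, 4); b[4, 4] <- 2
  oser <- structure(array(c(a, b), dim = c(4, 4, 2)), t = c(0, 10), hop = 10,
                    class = "snapshot_series")
  expect_equal(lag_inner_product(oser, 10), 0)
})

test_that("translating blob inner product follows the Gaussian overlap form", {
  n <- 32; sig <- 2; s <- 0.2; hop <- 10   # blob speed s units/ms
  centers <- cbind(16, 10 + s * hop * (0:19))
  ser <- blob_series(n, centers, sigma = sig, hop = hop)
  lags <- seq(0, 80, 10)
  raw <- inner_product_raw(ser, lags)
  # overlap of two unit Gaussians displaced by s*lag: ~ exp(-(s lag)^2/(4 sig^2))
  pred <- exp(-(s * lags)^2 / (4 * sig^2))
  expect_lt(max(abs(unname(raw / raw[1]) - pred)), 0.01)
})

test_that("normalization subtracts the baseline and pins the peak at one", {
  raw <- c(`0` = 5, `10` = 2.5, `20` = 0)
  cur <- normalize_curve(raw, baseline = 0)
  expect_equal(cur$value, c(1, 0.5, 0))
  cur2 <- normalize_curve(c(`0` = 7, `10` = 3, `20` = 3), baseline = 3)
  expect_equal(cur2$value, c(1, 0, 0))
  expect_error(normalize_curve(c(`0` = 3), baseline = 3), "degenerate")
  expect_error(normalize_curve(c(`10` = 3), baseline = 0), "lag 0")
  # cross-trial baseline of independent blobs equals their mean overlap
  n <- 24
  s1 <- blob_series(n, cbind(6, 6)[rep(1, 3), ])
  s2 <- blob_series(n, cbind(18, 18)[rep(1, 3), ])
  base <- cross_trial_baseline(list(s1, s2))
  expect_equal(base, sum(s1[, , 1] * s2[, , 1]), tolerance = 1e-9)
})

test_that("exponential fitting recovers tau and neglects negative points", {
  lags <- seq(0, 200, 10)
  tau <- 42
  raw <- exp(-lags / tau); names(raw) <- lags
  cur <- normalize_curve(raw, 0)
  fit <- fit_decay_constant(cur)
  expect_equal(fit$tau_decay, tau, tolerance = 1e-6)
  expect_gt(fit$r_squared, 0.999999)
  # injecting negative points changes nothing (neglect rule)
  cur2 <- cur
  cur2$value[c(8, 15)] <- -0.05
  cur_clean <- cur[-c(8, 15), ]
  expect_equal(fit_decay_constant(cur2)$tau_decay,
               fit_decay_constant(cur_clean)$tau_decay, tolerance = 1e-9)
  expect_error(fit_decay_constant(cur[1:2, ]), "3 non-negative")
})

test_that("time-to-fraction matches the closed form and flags censoring", {
  lags <- seq(0, 300, 10); tau <- 55
  cur <- normalize_curve(setNames(exp(-lags / tau), lags), 0)
  t50 <- time_to_fraction(cur, 0.5)
  expect_equal(as.numeric(t50), tau * log(2), tolerance = 0.15)
  expect_false(attr(t50, "censored"))
  flat <- normalize_curve(setNames(rep(1, 5), seq(0, 40, 10)), 0)
  tc <- time_to_fraction(flat, 0.5)
  expect_true(attr(tc, "censored"))
  expect_equal(as.numeric(tc), 40)
  expect_error(time_to_fraction(cur, 1.2), "fraction")
  # protocol ranking by time-to-fraction agrees with ranking by tau
  set.seed(8)
  taus <- sort(runif(6, 10, 300))
  t_half <- vapply(taus, function(tu) {
    cc <- normalize_curve(setNames(exp(-lags / tu), lags), 0)
    as.numeric(time_to_fraction(cc, 0.5))
  }, numeric(1))
  expect_equal(order(t_half), order(taus))
})

test_that("clustering index has its closed-form values and orders blobs above uniform", {
  g <- geom16()
  # uniform constant field series -> CV 0
  ser <- structure(array(3, dim = c(16, 16, 4)), t = seq(0, 30, 10), hop = 10,
                   class = "snapshot_series")
  expect_equal(as.numeric(clustering_index(ser, cell_side = 4)), 0)
  # all activity in one cell of k cells -> sqrt(k - 1)
  raster1 <- data.frame(time_ms = rep(5, 6), soma_row = c(1, 2, 3, 1, 2, 4),
                        soma_col = c(1, 1, 2, 3, 4, 2),
                        unit = rowcol_to_unit(c(1, 2, 3, 1, 2, 4),
                                              c(1, 1, 2, 3, 4, 2), 16))
  k <- (16 / 4)^2
  ci <- clustering_index(raster1, g, cell_side = 4, bin_width = 10,
                         t_range = c(0, 10))
  expect_equal(as.numeric(ci), sqrt(k - 1), tolerance = 1e-12)
  expect_error(clustering_index(raster1, g, cell_side = 5), "divide")
  # localized blob beats a uniform raster of equal total rate
  set.seed(6)
  blob <- generate_blob_raster(0, profile_sigma = 2, rate_scale = 0.5,
                               duration = 200, geometry = g, seed = 2)$spikes
  m <- nrow(blob)
  unif <- data.frame(time_ms = runif(m, 0, 200),
                     soma_row = sample(16, m, TRUE),
                     soma_col = sample(16, m, TRUE))
  unif$unit <- rowcol_to_unit(unif$soma_row, unif$soma_col, 16)
  expect_gt(as.numeric(clustering_index(blob, g, t_range = c(0, 200))),
            as.numeric(clustering_index(unif, g, t_range = c(0, 200))))
})

test_that("core extraction finds centroid, axes and degeneracy", {
  n <- 32
  # isotropic Gaussian: centroid at its center, degenerate axes flagged
  iso <- blob_series(n, cbind(10, 21))[, , 1]
  core <- extract_core(iso, threshold = 0.5, smooth_sigma = 1)
  expect_equal(core$centroid, c(9, 20), tolerance = 0.05) # 0-based coords
  expect_true(core$degenerate)
  # constant field: mask everything; total variance is the uniform-torus
  # value (origin-dependent within [2*5.25, 2*5.5] for n = 8)
  cf <- matrix(1, 8, 8)
  corec <- extract_core(cf, threshold = 0.5, smooth_sigma = 1)
  expect_true(all(corec$mask))
  expect_gte(sum(corec$eigenvalues), 2 * 5.25 - 1e-9)
  expect_lte(sum(corec$eigenvalues), 2 * 5.5 + 1e-9)
  # anisotropic Gaussian: axes recovered within 2 degrees
  th <- 25 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  S <- R %*% diag(c(5^2, 1.5^2)) %*% t(R)
  P <- solve(S)
  gr <- expand.grid(row = 0:(n - 1), col = 0:(n - 1))
  dx <- gr$row - 15; dy <- gr$col - 15
  an <- matrix(exp(-(P[1, 1] * dx^2 + 2 * P[1, 2] * dx * dy +
                       P[2, 2] * dy^2) / 2), n, n)
  corea <- extract_core(an, threshold = 0.3, smooth_sigma = 0.5)
  ang <- atan2(corea$axes[2, 1], corea$axes[1, 1])
  ang <- ang %% pi
  expect_lt(abs(ang - th) %% pi, 2 * pi / 180)
  expect_false(corea$degenerate)
  # empty core signals bump absence
  expect_error(extract_core(matrix(0, 8, 8)), class = "dendrofield_no_core")
})

test_that("axis skewness is zero for symmetric fields and signs the tail", {
  n <- 32
  gr <- expand.grid(row = 0:(n - 1), col = 0:(n - 1))
  sym <- matrix(exp(-((gr$row - 15)^2 / 18 + (gr$col - 15)^2 / 8)), n, n)
  core <- extract_core(sym, threshold = 0.2, smooth_sigma = 0.5)
  expect_lt(abs(axis_skewness(sym, core, axis = 1)), 1e-6)
  expect_lt(abs(axis_skewness(sym, core, axis = 2)), 1e-6)
  # one-sided exponential tail along +row: positive skew on the tail axis
  dx <- gr$row - 10
  tailf <- matrix(ifelse(dx >= 0, exp(-dx / 6), exp(-dx^2 / 2)) *
                    exp(-(gr$col - 15)^2 / 6), n, n)
  coret <- extract_core(tailf, threshold = 0.15, smooth_sigma = 0.5)
  ax <- which.max(abs(coret$axes[1, ]))   # axis most aligned with rows
  sk <- axis_skewness(tailf, coret, axis = ax)
  sign_along_row <- sign(coret$axes[1, ax])
  expect_gt(sk * sign_along_row, 0.1)
  # zero variance along an axis is an explicit error
  line <- matrix(0, 8, 8); line[4, ] <- 1
  corel <- extract_core(line, threshold = 0.9, smooth_sigma = 0)
  expect_error(axis_skewness(line, corel, axis = 2),
               class = "dendrofield_undefined_skewness")
})

test_that("trajectories unwrap across the boundary and mark gaps", {
  n <- 24
  # stationary blob: near-zero speed
  st <- blob_series(n, cbind(rep(12, 10), rep(12, 10)))
  trs <- bump_trajectory(st)
  expect_lt(attr(trs, "speed"), 1e-6)
  # 1 unit/frame crossing the periodic boundary: constant speed, no jumps
  cols <- ((20 + 0:11) %% n) + 1
  mv <- blob_series(n, cbind(12, cols), hop = 10)
  trm <- bump_trajectory(mv)
  steps <- sqrt(diff(trm$row)^2 + diff(trm$col)^2)
  expect_equal(max(abs(steps - 1)), 0, tolerance = 0.02)
  expect_equal(attr(trm, "speed"), 0.1, tolerance = 0.02)
  # a frame without a core is gap-marked, not interpolated
  gap <- mv
  gap[, , 5] <- 0
  trg <- bump_trajectory(gap)
  expect_true(is.na(trg$row[5]))
  expect_false(anyNA(trg$row[-5]))
})

test_that("immobilization score is the product of min-max scaled curves", {
  tau <- c(1, 3, 5, 3, 1)
  clus <- c(5, 5, 5, 5, 5)
  expect_warning(sc0 <- immobilization_score(tau, clus), "constant")
  expect_equal(sc0, rep(0, 5))
  tau2 <- c(1, 2, 5, 5)
  clus3 <- c(4, 4, 4, 0)
  sc <- immobilization_score(tau2, clus3)
  expect_equal(sc, (tau2 - 1) / 4 * clus3 / 4)
  expect_equal(which.max(sc), 3L)
  expect_equal(sc[4], 0)  # suppressed where clustering collapses to zero
  expect_error(immobilization_score(tau, clus3[-1]), "grid")
})
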