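#' Periodic Gaussian smoothing of a lattice field
#'
#' Circular convolution with a wrapped 2D Gaussian kernel normalized to unit
#' mass, computed by FFT, so the field total is conserved exactly.
#'
#' @param mat Numeric matrix.
#' @param sigma Kernel width in lattice units; `sigma <= 0` returns the input
#'   unchanged.
#' @return Smoothed matrix of the same dimensions.
#' @export
gauss_smooth_periodic <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  n <- nrow(mat); m <- ncol(mat)
  dx <- pmin(0:(n - 1), n - 0:(n - 1))
  dy <- pmin(0:(m - 1), m - 0:(m - 1))
  kern <- exp(-outer(dx^2, dy^2, `+`) / (2 * sigma^2))
  kern <- kern / sum(kern)
  out <- Re(stats::fft(stats::fft(mat) * stats::fft(kern), inverse = TRUE)) /
    (n * m)
  # zap FFT round-off so non-negative fields stay non-negative
  tol <- 1e-12 * max(abs(out), 1)
  out[abs(out) < tol] <- 0
  out
}

#' Smoothed spike-count snapshot
#'
#' Counts, for every soma, the spikes falling in a window of `window` ms
#' centered at `t_center`, then applies a periodic spatial Gaussian filter so
#' that lattice neighborhood structure enters the comparison of activity
#' patterns. The filter conserves the total spike count.
#'
#' @param spikes Raster data frame with `time_ms` and `unit` (or `soma_row`,
#'   `soma_col`).
#' @param t_center Window center, ms.
#' @param window Window length, ms (default 10).
#' @param filter_sigma Gaussian filter width, lattice units.
#' @param geometry A [field_geometry()].
#' @return Object of class `snapshot`: the smoothed `n x n` matrix with
#'   attributes `t_center`, `window`, `filter_sigma`.
#' @export
spike_snapshot <- function(spikes, t_center, window = 10, filter_sigma = 2,
                           geometry) {
  if (window <= 0) stop("window must be > 0")
  n <- geometry$n_soma_side
  lo <- t_center - window / 2; hi <- t_center + window / 2
  if (nrow(spikes) > 0 &&
      (hi <= min(spikes$time_ms) || lo > max(spikes$time_ms)))
    stop("snapshot window lies outside the raster span")
  sel <- spikes$time_ms >= lo & spikes$time_ms < hi
  unit <- if ("unit" %in% names(spikes)) spikes$unit[sel]
          else rowcol_to_unit(spikes$soma_row[sel], spikes$soma_col[sel], n)
  counts <- matrix(tabulate(unit, nbins = n * n), n, n)
  structure(gauss_smooth_periodic(counts, filter_sigma),
            t_center = t_center, window = window, filter_sigma = filter_sigma,
            class = c("snapshot", "matrix"))
}

#' Series of snapshots on a regular time grid
#'
#' @inheritParams spike_snapshot
#' @param t_centers Window centers, ms (must be equally spaced).
#' @return Object of class `snapshot_series`: an `n x n x k` array with
#'   attributes `t` (centers) and `hop` (grid interval, ms).
#' @export
snapshot_series <- function(spikes, t_centers, window = 10, filter_sigma = 2,
                            geometry) {
  n <- geometry$n_soma_side
  arr <- array(0, dim = c(n, n, length(t_centers)))
  for (k in seq_along(t_centers))
    arr[, , k] <- spike_snapshot(spikes, t_centers[k], window, filter_sigma,
                                 geometry)
  hop <- if (length(t_centers) > 1) t_centers[2] - t_centers[1] else NA_real_
  structure(arr, t = t_centers, hop = hop, window = window,
            filter_sigma = filter_sigma, class = "snapshot_series")
}

#' Lag-dependent inner product of snapshots
#'
#' The similarity between activity patterns separated by a time lag: the
#' elementwise-product sum of snapshot pairs, averaged over reference times
#' (sliding window). The sliding average is only meaningful under stationary
#' activity; with `average = FALSE` the product anchored at the first
#' reference time is returned instead.
#'
#' @param series A [snapshot_series()].
#' @param lag Time lag, ms; must be a multiple of the series' grid interval.
#' @param average Average over reference times (`TRUE`, stationary mode)?
#' @return The (averaged) inner product value.
#' @export
lag_inner_product <- function(series, lag, average = TRUE) {
  hop <- attr(series, "hop")
  k <- lag / hop
  if (abs(k - round(k)) > 1e-8)
    stop("lag must be a multiple of the snapshot interval")
  k <- as.integer(round(k))
  nt <- dim(series)[3]
  if (k >= nt) stop("lag exceeds the series span")
  refs <- if (average) seq_len(nt - k) else 1L
  mean(vapply(refs, function(i) sum(series[, , i] * series[, , i + k]),
              numeric(1)))
}

#' Inner-product curve over a set of lags
#'
#' @inheritParams lag_inner_product
#' @param lags Lags, ms.
#' @return Named numeric vector of raw (unnormalized) products.
#' @export
inner_product_raw <- function(series, lags, average = TRUE) {
  vals <- vapply(lags, lag_inner_product, numeric(1), series = series,
                 average = average)
  names(vals) <- lags
  vals
}

#' Cross-trial baseline of the inner product
#'
#' The chance-level similarity: the average inner product between snapshots
#' taken from different trials in the same condition.
#'
#' @param series_list List of >= 2 [snapshot_series()] from independent
#'   trials.
#' @return Scalar baseline.
#' @export
cross_trial_baseline <- function(series_list) {
  if (length(series_list) < 2) stop("need at least 2 trials for a baseline")
  vals <- c()
  for (a in seq_along(series_list)) for (b in seq_along(series_list)) {
    if (a >= b) next
    sa <- series_list[[a]]; sb <- series_list[[b]]
    nt <- min(dim(sa)[3], dim(sb)[3])
    vals <- c(vals, vapply(seq_len(nt), function(i)
      sum(sa[, , i] * sb[, , i]), numeric(1)))
  }
  mean(vals)
}

#' Baseline-subtract and peak-normalize an inner-product curve
#'
#' Subtracts the cross-trial baseline and rescales so that the value at zero
#' lag is exactly one (the difference between the zero-lag peak and the
#' baseline becomes unity).
#'
#' @param raw Named numeric vector from [inner_product_raw()] (must include
#'   lag 0).
#' @param baseline Scalar from [cross_trial_baseline()] (0 for a single
#'   trial, where no baseline is defined).
#' @return Object of class `ip_curve`: data frame `lag`, `value`, with the
#'   baseline and normalization recorded as attributes.
#' @export
normalize_curve <- function(raw, baseline = 0) {
  lags <- as.numeric(names(raw))
  if (!any(lags == 0)) stop("raw curve must include lag 0")
  peak <- raw[lags == 0] - baseline
  if (abs(peak) < .Machine$double.eps * max(1, abs(baseline)))
    stop("degenerate normalization: zero-lag value equals the baseline")
  structure(data.frame(lag = lags, value = as.numeric((raw - baseline) / peak)),
            baseline = baseline, normalized = TRUE, class = c("ip_curve",
                                                              "data.frame"))
}

#' Fit the exponential decay constant of an inner-product curve
#'
#' Least-squares fit of `A * exp(-lag / tau)` on the linear scale to the
#' non-negative points of a normalized curve (negative values, which arise
#' from small normalization errors, are neglected). The amplitude is profiled
#' out in closed form and `tau` found by 1-D optimization.
#'
#' @param curve An [normalize_curve()] result (or data frame with `lag`,
#'   `value`).
#' @return Object of class `decay_fit`: `tau_decay` (ms), `r_squared`, and
#'   the points used.
#' @export
fit_decay_constant <- function(curve) {
  pts <- curve[curve$value >= 0, ]
  if (nrow(pts) < 3)
    stop("need at least 3 non-negative points for the exponential fit")
  sse <- function(log_tau) {
    e <- exp(-pts$lag / exp(log_tau))
    A <- sum(pts$value * e) / sum(e^2)
    sum((pts$value - A * e)^2)
  }
  span <- max(pts$lag) - min(pts$lag)
  opt <- stats::optimize(sse, interval = log(c(span / 1e3, span * 1e3)),
                         tol = 1e-10)
  tau <- exp(opt$minimum)
  e <- exp(-pts$lag / tau)
  A <- sum(pts$value * e) / sum(e^2)
  ss_tot <- sum((pts$value - mean(pts$value))^2)
  r2 <- if (ss_tot > 0) 1 - opt$objective / ss_tot else NA_real_
  structure(list(tau_decay = tau, amplitude = A, r_squared = r2,
                 points = pts), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> tau_decay = %.4g ms (R^2 = %.3f, %d points)\n",
              x$tau_decay, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' Time to a given fractional reduction
#'
#' First lag at which a normalized inner-product curve falls below
#' `1 - fraction`, linearly interpolated between samples. For an exponential
#' curve this equals `-tau * log(1 - fraction)`.
#'
#' @param curve An `ip_curve`.
#' @param fraction Fractional reduction in (0, 1).
#' @return Time in ms; if the curve never falls below the level, the maximum
#'   lag with attribute `censored = TRUE`.
#' @export
time_to_fraction <- function(curve, fraction) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  level <- 1 - fraction
  lag <- curve$lag[order(curve$lag)]
  val <- curve$value[order(curve$lag)]
  below <- which(val < level)
  if (!length(below))
    return(structure(max(lag), censored = TRUE))
  i <- below[1]
  if (i == 1) return(structure(lag[1], censored = FALSE))
  x <- lag[i - 1] + (level - val[i - 1]) * (lag[i] - lag[i - 1]) /
    (val[i] - val[i - 1])
  structure(x, censored = FALSE)
}

#' Spatial clustering index
#'
#' The somatic field is divided into square cells of `cell_side` units. In
#' count mode the number of distinct spiking somata per cell is counted in
#' each time bin; in sum mode a per-unit field series (first min-max
#' normalized to `[0, 1]` over the whole series) is summed per cell. The
#' coefficient of variation across cells is computed per bin and averaged
#' over time; bins whose mean is zero are skipped (CV undefined). High values
#' mean spatially clustered, bump-like activity; a spatially uniform field
#' gives 0.
#'
#' @param x A spike raster data frame (count mode) or a `snapshot_series` /
#'   `n x n x k` array with attribute `t` (sum mode).
#' @param geometry A [field_geometry()] (count mode).
#' @param cell_side Cell side, lattice units; must divide the lattice side.
#' @param bin_width Time bin, ms (count mode).
#' @param t_range Analysis window (count mode); defaults to the raster span.
#' @return Object of class `clustering_index`: the time-averaged CV, with the
#'   per-bin CVs as attribute `per_bin`.
#' @export
clustering_index <- function(x, geometry = NULL, cell_side = 4,
                             bin_width = 10, t_range = NULL) {
  if (is.data.frame(x)) {
    n <- geometry$n_soma_side
    if (n %% cell_side != 0) stop("cell_side must divide the lattice side")
    if (is.null(t_range))
      t_range <- if (nrow(x)) range(x$time_ms) else c(0, bin_width)
    breaks <- seq(t_range[1], t_range[2] + bin_width, by = bin_width)
    cell <- cell_of(x$soma_row, x$soma_col, n, cell_side)
    bin <- findInterval(x$time_ms, breaks, rightmost.closed = FALSE)
    n_cells <- (n / cell_side)^2
    cvs <- vapply(seq_len(length(breaks) - 1), function(b) {
      sel <- bin == b
      # distinct spiking somata per cell in this bin
      counts <- tabulate(cell[sel][!duplicated(x$unit[sel])], nbins = n_cells)
      cv_or_na(counts)
    }, numeric(1))
  } else {
    arr <- unclass(x)
    n <- dim(arr)[1]
    if (n %% cell_side != 0) stop("cell_side must divide the lattice side")
    rng <- range(arr)
    # a constant positive field is spatially uniform: CV must be 0, so map it
    # to ones rather than collapsing it to zeros
    arr <- if (diff(rng) > 0) (arr - rng[1]) / diff(rng) else (arr > 0) * 1
    n_cells <- (n / cell_side)^2
    g <- expand.grid(row = seq_len(n), col = seq_len(n))
    cell <- cell_of(g$row, g$col, n, cell_side)
    cvs <- vapply(seq_len(dim(arr)[3]), function(k) {
      sums <- as.numeric(rowsum(as.vector(arr[, , k]), cell))
      cv_or_na(sums)
    }, numeric(1))
  }
  structure(mean(cvs, na.rm = TRUE), per_bin = cvs,
            class = "clustering_index")
}

cell_of <- function(row, col, n, cell_side) {
  per <- n / cell_side
  cr <- (row - 1) %/% cell_side
  cc <- (col - 1) %/% cell_side
  cc * per + cr + 1
}

# population (n-denominator) coefficient of variation; NA when the mean is 0
# (one-hot activity over k cells then gives exactly sqrt(k - 1))
cv_or_na <- function(x) {
  m <- mean(x)
  if (m == 0) return(NA_real_)
  sqrt(mean((x - m)^2)) / m
}

#' Extract the core of a scalar field
#'
#' Smooths the field with a periodic Gaussian, rescales it to `[0, 1]`, and
#' keeps the region at or above `threshold` — the "core", the significantly
#' thick part of (e.g.) the adaptation-current distribution. Returns the
#' value-weighted center of gravity (computed with circular means on the
#' torus) and the principal axes of the value-weighted spatial covariance of
#' the core about it.
#'
#' @param field Non-negative `n x n` matrix.
#' @param threshold Core threshold in (0, 1) after rescaling.
#' @param smooth_sigma Smoothing bandwidth, lattice units.
#' @return Object of class `core_geometry`: `mask`, `centroid` (continuous
#'   lattice coordinates in `[0, n)`), `axes` (columns are the first and
#'   second principal directions), `eigenvalues`, `degenerate` (TRUE when the
#'   eigenvalues are nearly equal and the axes arbitrary), and the smoothed
#'   rescaled `values`. Signals a classed error (`dendrofield_no_core`) when
#'   the mask is empty.
#' @export
extract_core <- function(field, threshold = 0.5, smooth_sigma = 2) {
  if (any(field < 0)) stop("field must be non-negative")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (max(field) == 0)
    stop(structure(class = c("dendrofield_no_core", "error", "condition"),
                   list(message = "no core: field has no mass", call = NULL)))
  sm <- gauss_smooth_periodic(field, smooth_sigma)
  rng <- range(sm)
  if (diff(rng) == 0)
    sm01 <- matrix(1, nrow(sm), ncol(sm))
  else sm01 <- (sm - rng[1]) / diff(rng)
  mask <- sm01 >= threshold
  if (!any(mask))
    stop(structure(class = c("dendrofield_no_core", "error", "condition"),
                   list(message = "no core: bump absent", call = NULL)))
  n <- nrow(field)
  w <- sm01 * mask
  g <- expand.grid(row = seq_len(n), col = seq_len(n))
  wv <- as.vector(w)
  centroid <- c(circ_mean(g$row - 1, wv, n), circ_mean(g$col - 1, wv, n))
  dr <- wrap_signed(g$row - 1, centroid[1], n)
  dc <- wrap_signed(g$col - 1, centroid[2], n)
  W <- sum(wv)
  cov <- matrix(c(sum(wv * dr * dr), sum(wv * dr * dc),
                  sum(wv * dr * dc), sum(wv * dc * dc)), 2, 2) / W
  eg <- eigen(cov, symmetric = TRUE)
  degenerate <- (eg$values[1] - eg$values[2]) <
    1e-6 * max(eg$values[1], .Machine$double.eps)
  structure(list(mask = mask, centroid = centroid, axes = eg$vectors,
                 eigenvalues = eg$values, degenerate = degenerate,
                 values = sm01, n = n),
            class = "core_geometry")
}

# weighted circular mean of coordinates x (in [0, n)) on a ring of length n
circ_mean <- function(x, w, n) {
  th <- 2 * pi * x / n
  ang <- atan2(sum(w * sin(th)), sum(w * cos(th)))
  (ang / (2 * pi) * n) %% n
}

#' Value-weighted skewness along a core principal axis
#'
#' Projects the core's unit positions (wrapped displacements from the
#' centroid) onto a principal axis and returns the value-weighted third
#' standardized moment of the projected distribution. Positive skew means the
#' long tail points along the positive axis direction. A trailing tail of
#' adaptation current behind a moving bump shows up as nonzero skewness along
#' the motion axis.
#'
#' @param field Non-negative `n x n` matrix (same field the core was
#'   extracted from, or a companion field to weight by).
#' @param core An [extract_core()] result.
#' @param axis 1 (first principal axis) or 2 (second).
#' @return Dimensionless skewness.
#' @export
axis_skewness <- function(field, core, axis = 2) {
  n <- core$n
  g <- expand.grid(row = seq_len(n), col = seq_len(n))
  sel <- as.vector(core$mask)
  w <- as.vector(field)[sel]
  dr <- wrap_signed(g$row[sel] - 1, core$centroid[1], n)
  dc <- wrap_signed(g$col[sel] - 1, core$centroid[2], n)
  proj <- dr * core$axes[1, axis] + dc * core$axes[2, axis]
  W <- sum(w)
  mu <- sum(w * proj) / W
  m2 <- sum(w * (proj - mu)^2) / W
  if (m2 <= .Machine$double.eps)
    stop(structure(class = c("dendrofield_undefined_skewness", "error",
                             "condition"),
                   list(message = "zero variance along axis: skewness undefined",
                        call = NULL)))
  m3 <- sum(w * (proj - mu)^3) / W
  m3 / m2^1.5
}

#' Bump trajectory and speed from a snapshot series
#'
#' Per-snapshot value-weighted centroid (circular means) of the core;
#' positions are unwrapped across the periodic boundary by accumulating
#' signed minimal-image steps, so boundary crossings cause no jumps. Frames
#' without a core are gap-marked (`NA`), never interpolated. The speed is the
#' mean frame-to-frame unwrapped displacement divided by the frame interval,
#' over consecutive non-gap frames.
#'
#' @param series A [snapshot_series()] (or array with attributes `t`, `hop`).
#' @param threshold,smooth_sigma Passed to [extract_core()].
#' @param stride Frames between positions used for the speed estimate.
#'   Centroid estimates carry sampling jitter from the finite spike count per
#'   window; differencing over `stride` frames (an effective interval of
#'   `stride * hop` ms) suppresses that jitter relative to genuine drift.
#' @return Object of class `bump_trajectory`: data frame `t`, `row`, `col`
#'   (unwrapped continuous lattice coordinates), with `speed` (lattice
#'   units/ms) and `core_radius` (mean RMS core radius) as attributes.
#' @export
bump_trajectory <- function(series, threshold = 0.5, smooth_sigma = 2,
                            stride = 1) {
  nt <- dim(series)[3]
  n <- dim(series)[1]
  pos <- matrix(NA_real_, nt, 2)
  radii <- rep(NA_real_, nt)
  for (k in seq_len(nt)) {
    core <- tryCatch(extract_core(series[, , k], threshold, smooth_sigma),
                     dendrofield_no_core = function(e) NULL)
    if (!is.null(core)) {
      pos[k, ] <- core$centroid
      radii[k] <- sqrt(sum(core$eigenvalues))
    }
  }
  # unwrap
  un <- pos
  for (k in 2:max(nt, 2)) {
    if (k > nt) break
    if (anyNA(pos[k, ]) || anyNA(pos[k - 1, ])) next
    step <- c(wrap_signed(pos[k, 1], pos[k - 1, 1], n),
              wrap_signed(pos[k, 2], pos[k - 1, 2], n))
    un[k, ] <- un[k - 1, ] + step
  }
  hop <- attr(series, "hop")
  stride <- max(1L, as.integer(stride))
  steps <- sqrt(diff(un[, 1], lag = stride)^2 + diff(un[, 2], lag = stride)^2)
  ok <- !is.na(steps)
  speed <- if (any(ok) && !is.na(hop)) mean(steps[ok]) / (stride * hop)
           else NA_real_
  structure(data.frame(t = attr(series, "t"), row = un[, 1], col = un[, 2]),
            speed = speed, core_radius = mean(radii, na.rm = TRUE),
            class = c("bump_trajectory", "data.frame"))
}

#' Destruction-corrected immobilization score
#'
#' Combines the decay-constant curve (immobility) and the clustering-index
#' curve (bump integrity) over a common noise grid: each curve is min-max
#' scaled to `[0, 1]` and the two are multiplied pointwise. An interior peak
#' marks noise that immobilizes the bump without destroying it.
#'
#' @param tau_curve Numeric vector: `tau_decay` per noise level.
#' @param clustering_curve Numeric vector: clustering index per noise level
#'   (same grid).
#' @return Numeric score per noise level (all zeros, with a warning, if
#'   either curve is constant).
#' @export
immobilization_score <- function(tau_curve, clustering_curve) {
  if (length(tau_curve) != length(clustering_curve))
    stop("curves must share the same noise grid")
  scale01 <- function(x) {
    r <- range(x)
    if (diff(r) == 0) return(NULL)
    (x - r[1]) / diff(r)
  }
  a <- scale01(tau_curve); b <- scale01(clustering_curve)
  if (is.null(a) || is.null(b)) {
    warning("constant curve: immobilization score degenerates to zeros")
    return(rep(0, length(tau_curve)))
  }
  a * b
}
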