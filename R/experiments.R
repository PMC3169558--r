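#' Package default configuration
#'
#' All calibrated model defaults live in one flat YAML file
#' (`inst/extdata/config-defaults.yaml`): geometry, connection kernels,
#' somatic/dendritic/inhibitory parameters, the stimulus regime anchors
#' (constant drive, weak/moderate/strong noise variances, inhibitory
#' amplitude) and the mode-classification thresholds. See the package
#' vignette for how each value was calibrated.
#'
#' @return Nested list of defaults.
#' @export
dendrofield_defaults <- function() {
  yaml::read_yaml(system.file("extdata", "config-defaults.yaml",
                              package = "dendrofield"))
}

#' Experiment configuration
#'
#' Bundles everything a reproducible run needs: geometry, kernels and
#' connectivity seed, dynamics parameters, a stimulus protocol, duration and
#' step, snapshot cadence, analysis warmup, and per-trial seeds.
#'
#' @param n_side Lattice side for both fields.
#' @param tau_d Dendritic time constant, ms.
#' @param protocol A [stimulus_protocol()], or `NULL` for the default
#'   constant-drive protocol over the whole run.
#' @param duration Simulated time, ms.
#' @param dt Step, ms.
#' @param snapshot_dt Snapshot cadence, ms.
#' @param warmup Initial segment discarded from analysis, ms.
#' @param conn_seed Connectivity seed.
#' @param trial_seeds Integer vector of per-trial noise/init seeds (distinct).
#' @param defaults Output of [dendrofield_defaults()] (override to rescale).
#' @param ... Overrides for dynamics parameters: any argument of
#'   [soma_params()], [dendrite_params()] or [inhibition_params()].
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(n_side = 48, tau_d = NULL, protocol = NULL,
                              duration = 1000, dt = 0.1, snapshot_dt = 10,
                              warmup = 200, conn_seed = 101,
                              trial_seeds = c(1, 2), defaults = dendrofield_defaults(),
                              ...) {
  if (duration < warmup) stop("duration must cover the warmup")
  if (anyDuplicated(trial_seeds)) stop("trial seeds must be distinct")
  geometry <- field_geometry(n_side, n_side, extent = defaults$geometry$extent)
  dots <- list(...)
  pick <- function(ctor, def) {
    fml <- names(formals(ctor))
    args <- def[names(def) %in% fml]
    args[names(dots)[names(dots) %in% fml]] <- dots[names(dots) %in% fml]
    do.call(ctor, args)
  }
  soma <- pick(soma_params, defaults$soma)
  dend <- local({ d <- defaults$dendrite; if (!is.null(tau_d)) d$tau_d <- tau_d
    fml <- names(formals(dendrite_params))
    args <- d[names(d) %in% fml]
    args[names(dots)[names(dots) %in% fml]] <- dots[names(dots) %in% fml]
    do.call(dendrite_params, args) })
  inh <- pick(inhibition_params, defaults$inhibition)
  if (is.null(protocol))
    protocol <- stimulus_protocol(stim_segment(0, duration, "soma",
                                               region_all(), "constant",
                                               amplitude = defaults$stimulus$const_amplitude))
  structure(list(geometry = geometry,
                 kernels = list(axon = do.call(gaussian_kernel,
                                               defaults$kernels$axon),
                                branch = do.call(gaussian_kernel,
                                                 defaults$kernels$branch)),
                 conn_seed = conn_seed, soma = soma, dend = dend, inh = inh,
                 protocol = protocol, duration = duration, dt = dt,
                 snapshot_dt = snapshot_dt, warmup = warmup,
                 trial_seeds = trial_seeds,
                 thresholds = defaults$classification,
                 snapshot = defaults$snapshot),
            class = "experiment_config")
}

#' Run one experiment
#'
#' Builds the connectivity, integrates the network once per trial seed,
#' computes the standard metric set on the post-warmup segment (snapshot
#' series, clustering index, bump trajectory and speed, and — when at least
#' two trials are available — the baseline-corrected inner-product curve and
#' its decay constant), and optionally writes artifacts (raster CSV, metrics
#' CSV, JSON manifest) to `output_dir`.
#'
#' @param config An [experiment_config()].
#' @param lags Lags (ms) for the inner-product curve; defaults to snapshot
#'   multiples up to half the analysis span.
#' @param output_dir Optional directory for artifacts.
#' @param average Sliding-window averaging of inner products (disable for
#'   non-stationary protocols).
#' @return Object of class `experiment_result`: `trials` (list with spikes,
#'   series, clustering, trajectory per trial), `ip_curve`, `decay_fit`,
#'   `metrics` (tidy data frame), `conn`, `config`.
#' @export
run_experiment <- function(config, lags = NULL, output_dir = NULL,
                           average = TRUE) {
  conn <- build_connectivity(config$geometry, config$kernels$axon,
                             config$kernels$branch, config$conn_seed)
  snap <- config$snapshot
  t0 <- config$warmup; t1 <- config$duration
  centers <- if (t1 - t0 >= snap$window)
    seq(t0 + snap$window / 2, t1 - snap$window / 2, by = config$snapshot_dt)
  else numeric(0)
  trials <- lapply(config$trial_seeds, function(s) {
    sim <- simulate_network(conn, config$protocol, config$duration,
                            dt = config$dt, soma = config$soma,
                            dend = config$dend, inh = config$inh, seed = s,
                            snapshot_dt = config$snapshot_dt)
    post <- sim$spikes[sim$spikes$time_ms >= t0, ]
    series <- if (length(centers))
      snapshot_series(post, centers, snap$window, snap$filter_sigma,
                      config$geometry)
    else NULL
    clus <- if (nrow(post)) clustering_index(post, config$geometry,
                                             cell_side = 4, bin_width = 10,
                                             t_range = c(t0, t1))
            else structure(NA_real_, class = "clustering_index")
    traj <- if (!is.null(series))
      bump_trajectory(series, threshold = snap$core_threshold,
                      smooth_sigma = snap$filter_sigma)
    else NULL
    list(sim = sim, spikes = post, series = series, clustering = clus,
         trajectory = traj)
  })
  ip <- NULL; fit <- NULL
  serieses <- Filter(Negate(is.null), lapply(trials, `[[`, "series"))
  if (length(serieses) >= 1 && length(centers) > 3) {
    if (is.null(lags)) {
      max_lag <- (length(centers) - 1) %/% 2 * config$snapshot_dt
      lags <- seq(0, max_lag, by = config$snapshot_dt)
    }
    raws <- lapply(serieses, inner_product_raw, lags = lags,
                   average = average)
    raw <- Reduce(`+`, raws) / length(raws)
    base <- if (length(serieses) >= 2) cross_trial_baseline(serieses) else 0
    ip <- tryCatch(normalize_curve(raw, base), error = function(e) NULL)
    fit <- if (!is.null(ip))
      tryCatch(fit_decay_constant(ip), error = function(e) NULL)
  }
  metrics <- data.frame(
    trial = seq_along(trials),
    n_spikes = vapply(trials, function(tr) nrow(tr$spikes), numeric(1)),
    clustering = vapply(trials, function(tr) as.numeric(tr$clustering),
                        numeric(1)),
    speed = vapply(trials, function(tr)
      if (is.null(tr$trajectory)) NA_real_ else attr(tr$trajectory, "speed"),
      numeric(1)),
    tau_decay = if (is.null(fit)) NA_real_ else fit$tau_decay)
  res <- structure(list(trials = trials, ip_curve = ip, decay_fit = fit,
                        metrics = metrics, conn = conn, config = config),
                   class = "experiment_result")
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(trials))
      write_raster(trials[[i]]$spikes,
                   file.path(output_dir, sprintf("raster_trial%02d.csv", i)))
    utils::write.csv(metrics, file.path(output_dir, "metrics.csv"),
                     row.names = FALSE)
    manifest <- list(conn_seed = config$conn_seed,
                     trial_seeds = config$trial_seeds,
                     n_side = config$geometry$n_soma_side,
                     duration = config$duration, dt = config$dt,
                     tau_d = config$dend$tau_d)
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %d trial(s); mean clustering %.3f; mean speed %.4g units/ms; tau_decay %s ms\n",
              nrow(x$metrics), mean(x$metrics$clustering, na.rm = TRUE),
              mean(x$metrics$speed, na.rm = TRUE),
              if (is.null(x$decay_fit)) "NA"
              else sprintf("%.4g", x$decay_fit$tau_decay)))
  invisible(x)
}

#' Classify the bump mode
#'
#' Applies the calibrated thresholds: `broken` when the clustering index is
#' below its floor (no spatial structure left), otherwise `immobile` when the
#' centroid speed is below the speed ceiling (with a core present), otherwise
#' `mobile`; `none` when there is no activity at all.
#'
#' @param evidence List (or one row of a metrics table) with `tau_decay`,
#'   `clustering`, `speed`, and optionally `n_spikes`.
#' @param thresholds List with `clustering_broken` and `speed_immobile`
#'   (lattice units/ms); defaults from [dendrofield_defaults()].
#' @return Object of class `mode_label`: the label string with the evidence
#'   attached.
#' @export
classify_mode <- function(evidence,
                          thresholds = dendrofield_defaults()$classification) {
  lab <- if (!is.null(evidence$n_spikes) && evidence$n_spikes == 0) "none"
  else if (is.na(evidence$clustering) ||
           evidence$clustering < thresholds$clustering_broken) "broken"
  else if (!is.na(evidence$speed) &&
           evidence$speed < thresholds$speed_immobile) "immobile"
  else "mobile"
  structure(lab, evidence = evidence, class = "mode_label")
}

#' Parameter sweep
#'
#' Runs [run_experiment()] over the Cartesian product of the supplied axes
#' (any of `tau_d`, `noise_sigma2` — the white-noise variance of a full-run
#' noisy protocol — or other dynamics parameter names) and returns a tidy
#' table with one row per cell. Failures in a cell are recorded and the sweep
#' continues.
#'
#' @param base An [experiment_config()] (its protocol is replaced by a
#'   full-run white-noise protocol when `noise_sigma2` is swept).
#' @param axes Named list of value vectors.
#' @param average Passed to [run_experiment()].
#' @return Data frame: axis values, mean clustering, mean speed, `tau_decay`,
#'   spike counts, and an `error` column (NA on success).
#' @export
sweep_experiments <- function(base, axes, average = TRUE) {
  grid <- do.call(expand.grid, c(axes, KEEP.OUT.ATTRS = FALSE))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cell <- as.list(grid[i, , drop = FALSE])
    out <- tryCatch({
      cfg <- base
      if (!is.null(cell$tau_d)) {
        dp <- cfg$dend; dp$tau_d <- cell$tau_d
        cfg$dend <- do.call(dendrite_params,
                            dp[names(dp) %in% names(formals(dendrite_params))])
      }
      if (!is.null(cell$noise_sigma2))
        cfg$protocol <- stimulus_protocol(
          stim_segment(0, cfg$duration, "soma", region_all(), "white_noise",
                       variance = cell$noise_sigma2))
      r <- run_experiment(cfg, average = average)
      data.frame(cell,
                 clustering = mean(r$metrics$clustering, na.rm = TRUE),
                 speed = mean(r$metrics$speed, na.rm = TRUE),
                 tau_decay = if (is.null(r$decay_fit)) NA_real_
                             else r$decay_fit$tau_decay,
                 n_spikes = mean(r$metrics$n_spikes), error = NA_character_)
    }, error = function(e)
      data.frame(cell, clustering = NA_real_, speed = NA_real_,
                 tau_decay = NA_real_, n_spikes = NA_real_,
                 error = conditionMessage(e)))
    out
  })
  do.call(rbind, rows)
}

#' Success rate of spatio-temporal integration into a bump
#'
#' For every cell of an input-radius x input-duration grid, delivers sparse
#' random dendritic pulses (see [make_dendritic_pulse_protocol()]) and counts
#' the fraction of trials in which a persistent bump exists after input
#' offset (somatic spiking present, clustering above the broken floor, core
#' present). Long dendritic plateaus extend the time window over which
#' scattered pulses can summate, so slow dendrites succeed where fast ones
#' fail.
#'
#' @param config An [experiment_config()]; its protocol is replaced per cell.
#' @param input_radii Disk radii, lattice units.
#' @param input_durations Input period lengths, ms.
#' @param n_inputs Pulses per trial.
#' @param n_trials Trials per cell.
#' @param amplitude Pulse amplitude, pA.
#' @param pulse_width Pulse width, ms.
#' @param post_window Persistence check window after input offset, ms.
#' @param background Constant somatic holding current, pA. The default -5
#'   holds the otherwise tonically driven network just below threshold, so a
#'   bump can only ignite from the injected dendritic plateaus — the premise
#'   of the integration experiment.
#' @return Data frame: `input_radius`, `input_duration`, `success_rate`, `n`.
#' @export
integration_success_rate <- function(config, input_radii, input_durations,
                                     n_inputs = 12, n_trials = 8,
                                     amplitude = 150, pulse_width = 5,
                                     post_window = 200, background = -5) {
  grid <- expand.grid(input_radius = input_radii,
                      input_duration = input_durations)
  conn <- build_connectivity(config$geometry, config$kernels$axon,
                             config$kernels$branch, config$conn_seed)
  thr <- config$thresholds
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    rad <- grid$input_radius[i]; dur <- grid$input_duration[i]
    succ <- vapply(seq_len(n_trials), function(trial) {
      seed <- config$conn_seed + 1000L * i + trial
      prot <- make_dendritic_pulse_protocol(rad, dur, n_inputs, pulse_width,
                                            amplitude, seed = seed,
                                            geometry = config$geometry)
      total <- dur + post_window
      if (background != 0)
        prot <- combine_protocols(prot,
                                  stim_segment(0, total, "soma", region_all(),
                                               "constant",
                                               amplitude = background),
                                  rng_seed = prot$rng_seed)
      sim <- simulate_network(conn, prot, total, dt = config$dt,
                              soma = config$soma, dend = config$dend,
                              inh = config$inh, seed = seed,
                              snapshot_dt = config$snapshot_dt)
      post <- sim$spikes[sim$spikes$time_ms >= dur + post_window / 2, ]
      if (nrow(post) < 5) return(FALSE)
      clus <- clustering_index(post, config$geometry, cell_side = 4,
                               bin_width = 10,
                               t_range = c(dur + post_window / 2, total))
      as.numeric(clus) >= thr$clustering_broken
    }, logical(1))
    data.frame(input_radius = rad, input_duration = dur,
               success_rate = mean(succ), n = n_trials)
  })
  do.call(rbind, rows)
}

#' Synthetic moving-blob raster with ground truth
#'
#' Fixture generator for metric validation: an inhomogeneous Poisson raster
#' whose per-unit rate is a Gaussian profile translating at a known constant
#' speed on the torus. Returns the raster together with the ground-truth
#' center trajectory, so trajectory and decay-constant estimators can be
#' checked against known values.
#'
#' @param speed Center speed, lattice units/ms (>= 0).
#' @param profile_sigma Gaussian profile width, lattice units.
#' @param rate_scale Peak rate at the blob center, spikes/ms per unit.
#' @param duration Raster length, ms.
#' @param geometry A [field_geometry()].
#' @param seed RNG seed.
#' @param direction Unit motion direction (lattice `(row, col)`).
#' @param frame_dt Rate-update interval, ms.
#' @return List with `spikes` (raster data frame) and `truth` (data frame
#'   `t`, `row`, `col` of the blob center, 1-based lattice coordinates).
#' @export
generate_blob_raster <- function(speed, profile_sigma = 3, rate_scale = 0.4,
                                 duration = 500, geometry, seed = 1,
                                 direction = c(0, 1), frame_dt = 1) {
  if (speed < 0) stop("speed must be >= 0")
  n <- geometry$n_soma_side
  direction <- direction / sqrt(sum(direction^2))
  g <- expand.grid(row = seq_len(n), col = seq_len(n))
  times <- seq(0, duration - frame_dt, by = frame_dt)
  center0 <- c(n / 2, n / 2)
  with_seed(seed, {
    out <- vector("list", length(times))
    truth <- matrix(0, length(times), 2)
    for (k in seq_along(times)) {
      ctr <- (center0 + speed * times[k] * direction - 1) %% n + 1
      truth[k, ] <- ctr
      dr <- abs(g$row - ctr[1]); dr <- pmin(dr, n - dr)
      dc <- abs(g$col - ctr[2]); dc <- pmin(dc, n - dc)
      lambda <- rate_scale * frame_dt * exp(-(dr^2 + dc^2) /
                                              (2 * profile_sigma^2))
      cnt <- stats::rpois(length(lambda), lambda)
      hit <- which(cnt > 0)
      if (length(hit))
        out[[k]] <- data.frame(
          time_ms = times[k] + stats::runif(sum(cnt[hit]), 0, frame_dt),
          soma_row = rep(g$row[hit], cnt[hit]),
          soma_col = rep(g$col[hit], cnt[hit]))
    }
    spikes <- do.call(rbind, Filter(Negate(is.null), out))
    if (is.null(spikes)) spikes <- empty_raster()[c("time_ms", "soma_row",
                                                    "soma_col")]
    spikes <- spikes[order(spikes$time_ms), ]
    spikes$unit <- rowcol_to_unit(spikes$soma_row, spikes$soma_col, n)
    list(spikes = spikes,
         truth = data.frame(t = times, row = truth[, 1], col = truth[, 2]))
  })
}
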