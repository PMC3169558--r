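#' Spatial regions on a lattice
#'
#' Regions address subsets of one field's units. `region_all()` is the whole
#' field; `region_disk()` is a periodic disk of given radius (lattice units)
#' around a center `(row, col)`; `region_line()` is a thin line of constant
#' row or column index with a given width; `region_mask()` takes an explicit
#' logical matrix.
#'
#' @param center Numeric `(row, col)` in lattice units.
#' @param radius Disk radius in lattice units (> 0).
#' @param axis `"col"` for a vertical line (constant column) or `"row"` for a
#'   horizontal one.
#' @param offset First row/column index of the line.
#' @param width Line width in lattice units (> 0).
#' @param mask Logical matrix of lattice dimensions.
#' @return A `stim_region` object.
#' @export
region_all <- function() structure(list(type = "all"), class = "stim_region")

#' @rdname region_all
#' @export
region_disk <- function(center, radius) {
  if (radius <= 0) stop("radius must be > 0")
  structure(list(type = "disk", center = center, radius = radius),
            class = "stim_region")
}

#' @rdname region_all
#' @export
region_line <- function(axis = c("col", "row"), offset, width = 1) {
  if (width <= 0) stop("width must be > 0")
  structure(list(type = "line", axis = match.arg(axis), offset = offset,
                 width = width), class = "stim_region")
}

#' @rdname region_all
#' @export
region_mask <- function(mask) {
  if (!is.logical(mask) || !is.matrix(mask)) stop("mask must be a logical matrix")
  structure(list(type = "mask", mask = mask), class = "stim_region")
}

# region -> 1-based unit indices on an n x n lattice (periodic)
resolve_region <- function(region, n) {
  switch(region$type,
    all = seq_len(n * n),
    disk = {
      g <- expand.grid(row = seq_len(n), col = seq_len(n))
      dr <- abs(g$row - region$center[1]); dr <- pmin(dr, n - dr)
      dc <- abs(g$col - region$center[2]); dc <- pmin(dc, n - dc)
      which(sqrt(dr^2 + dc^2) <= region$radius)
    },
    line = {
      idx <- ((seq(region$offset, length.out = region$width) - 1) %% n) + 1
      g <- expand.grid(row = seq_len(n), col = seq_len(n))
      if (region$axis == "col") which(g$col %in% idx) else which(g$row %in% idx)
    },
    mask = {
      if (!all(dim(region$mask) == c(n, n)))
        stop("mask dimensions do not match the lattice")
      which(as.vector(region$mask))
    },
    stop("malformed region"))
}

#' One stimulus segment
#'
#' A segment injects current into one population over a time window.
#' Kinds: `"constant"` (fixed amplitude; a negative amplitude is a
#' hyperpolarizing, inhibitory current), `"white_noise"` (fresh i.i.d.
#' Gaussian samples per unit per integration step, zero mean, variance
#' scaled as `variance / dt` per sample so total injected noise power is
#' step-size invariant), `"inhibitory"` (alias for a constant hyperpolarizing
#' current of magnitude `amplitude`), and `"pulse_train"` (brief constant
#' pulses of width `pulse_width` at `pulse_times`).
#'
#' @param t_start,t_end Segment window, ms.
#' @param target `"soma"` or `"dendrite"`.
#' @param region A `stim_region`.
#' @param kind Segment kind (see above).
#' @param amplitude Current amplitude, pA.
#' @param variance Noise variance parameter (pA^2 ms); noise kind only.
#' @param pulse_times Pulse onset times, ms; pulse_train kind only.
#' @param pulse_width Pulse width, ms; pulse_train kind only.
#' @return A `stim_segment` object.
#' @export
stim_segment <- function(t_start, t_end, target = c("soma", "dendrite"),
                         region = region_all(),
                         kind = c("constant", "white_noise", "inhibitory",
                                  "pulse_train"),
                         amplitude = 0, variance = 0, pulse_times = NULL,
                         pulse_width = 5) {
  kind <- match.arg(kind)
  target <- match.arg(target)
  if (t_end < t_start) stop("t_end must be >= t_start")
  if (variance < 0) stop("variance must be >= 0")
  if (kind == "pulse_train" && is.null(pulse_times))
    stop("pulse_train requires pulse_times")
  structure(list(t_start = t_start, t_end = t_end, target = target,
                 region = region, kind = kind, amplitude = amplitude,
                 variance = variance, pulse_times = pulse_times,
                 pulse_width = pulse_width),
            class = "stim_segment")
}

#' External-current protocol
#'
#' An ordered schedule of [stim_segment()]s plus the seed of the noise
#' stream. Segments may overlap; their contributions sum.
#'
#' @param segments A list of `stim_segment`s (a bare segment is accepted).
#' @param rng_seed Integer seed governing every white-noise sample drawn when
#'   the protocol is simulated or rendered.
#' @return A `stim_protocol` object.
#' @export
stimulus_protocol <- function(segments = list(), rng_seed = 1L) {
  if (inherits(segments, "stim_segment")) segments <- list(segments)
  stopifnot(all(vapply(segments, inherits, TRUE, "stim_segment")))
  ord <- order(vapply(segments, `[[`, 0, "t_start"))
  structure(list(segments = segments[ord], rng_seed = as.integer(rng_seed)),
            class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("<stim_protocol> %d segment(s), noise seed %d\n",
              length(x$segments), x$rng_seed))
  for (s in x$segments)
    cat(sprintf("  [%g, %g) ms  %s  %s  %s  amp=%g var=%g\n",
                s$t_start, s$t_end, s$target, s$kind, s$region$type,
                s$amplitude, s$variance))
  invisible(x)
}

#' Concatenate protocol fragments
#'
#' @param ... `stim_protocol`s, `stim_segment`s or lists of segments.
#' @param rng_seed Seed of the combined protocol.
#' @return A `stim_protocol`.
#' @export
combine_protocols <- function(..., rng_seed = 1L) {
  parts <- list(...)
  segs <- list()
  for (p in parts) {
    if (inherits(p, "stim_protocol")) segs <- c(segs, p$segments)
    else if (inherits(p, "stim_segment")) segs <- c(segs, list(p))
    else segs <- c(segs, p)
  }
  stimulus_protocol(segs, rng_seed)
}

# flatten a protocol into the C++ segment tables (one list per target);
# pulse trains expand to constant mini-segments; inhibitory becomes a
# negative constant; noise sd per sample is sqrt(variance / dt)
compile_protocol <- function(protocol, geometry, dt) {
  out <- list(soma = list(), dendrite = list())
  for (s in protocol$segments) {
    n <- if (s$target == "soma") geometry$n_soma_side else geometry$n_dend_side
    idx <- resolve_region(s$region, n) - 1L
    add <- function(t0, t1, kind, amp, sd)
      list(t0 = t0, t1 = t1, kind = kind, amp = amp, sd_sample = sd, idx = idx)
    segs <- switch(s$kind,
      constant = list(add(s$t_start, s$t_end, 0, s$amplitude, 0)),
      inhibitory = list(add(s$t_start, s$t_end, 0, -abs(s$amplitude), 0)),
      white_noise = list(add(s$t_start, s$t_end, 1, 0, sqrt(s$variance / dt))),
      pulse_train = lapply(s$pulse_times, function(tk)
        add(s$t_start + tk, min(s$t_start + tk + s$pulse_width, s$t_end),
            0, s$amplitude, 0)))
    out[[s$target]] <- c(out[[s$target]], segs)
  }
  out
}

#' Evaluate the stimulus field at a time point
#'
#' Reference evaluation of a protocol: the summed current over all active
#' segments for each unit of the target population. White-noise samples are
#' drawn from a stream determined by `rng_seed` and the step index
#' `floor(t / dt)`, so repeated evaluation is reproducible.
#'
#' @param protocol A [stimulus_protocol()].
#' @param t Time, ms.
#' @param target `"soma"` or `"dendrite"`.
#' @param geometry A [field_geometry()].
#' @param dt Integration step the noise variance is scaled against, ms.
#' @return Numeric vector of currents over the target population's units.
#' @export
current_at <- function(protocol, t, target = c("soma", "dendrite"), geometry,
                       dt = 0.1) {
  target <- match.arg(target)
  n <- if (target == "soma") geometry$n_soma_side else geometry$n_dend_side
  segs <- compile_protocol(protocol, geometry, dt)[[target]]
  I <- numeric(n * n)
  step_index <- floor(t / dt)
  k_noise <- 0L
  for (s in segs) {
    if (t < s$t0 || t >= s$t1) next
    if (s$kind == 0) I[s$idx + 1L] <- I[s$idx + 1L] + s$amp
    else {
      k_noise <- k_noise + 1L
      draws <- with_seed(protocol$rng_seed + 1009L * k_noise + step_index,
                        stats::rnorm(length(s$idx), 0, s$sd_sample))
      I[s$idx + 1L] <- I[s$idx + 1L] + draws
    }
  }
  I
}

#' Mobile-to-immobile switching fragment
#'
#' The canonical protocol freezes a moving bump by inserting a transient
#' global somatic inhibition between a noiseless (constant-drive) phase and a
#' noisy phase. The inhibition duration is meant to match the somatic
#' adaptation decay time `1/a`: long enough for spiking (but not the bump's
#' adaptation footprint) to vanish, short enough that the dendritic plateaus
#' marking the bump's location survive. `duration = 0` degenerates to a
#' plain noise onset (the failing control); `duration >> tau_d` erases the
#' location information.
#'
#' @param t0 Inhibition onset, ms.
#' @param duration Inhibition duration, ms (>= 0).
#' @param inhib_amplitude Magnitude of the hyperpolarizing current, pA.
#' @param const_amplitude If non-`NULL`, a constant-drive segment over
#'   `[const_from, t0)` is prepended.
#' @param const_from Start of the constant phase, ms.
#' @param noise_variance If non-`NULL`, a global somatic white-noise segment
#'   over `[t0 + duration, noise_until)` is appended.
#' @param noise_until End of the noisy phase, ms.
#' @return A list of [stim_segment()]s, composable with
#'   [combine_protocols()].
#' @export
make_switch_to_immobile <- function(t0, duration, inhib_amplitude = 100,
                                    const_amplitude = NULL, const_from = 0,
                                    noise_variance = NULL,
                                    noise_until = NULL) {
  if (duration < 0) stop("duration must be >= 0")
  segs <- list()
  if (!is.null(const_amplitude))
    segs <- c(segs, list(stim_segment(const_from, t0, "soma", region_all(),
                                      "constant", amplitude = const_amplitude)))
  if (duration > 0)
    segs <- c(segs, list(stim_segment(t0, t0 + duration, "soma", region_all(),
                                      "inhibitory",
                                      amplitude = inhib_amplitude)))
  if (!is.null(noise_variance))
    segs <- c(segs, list(stim_segment(t0 + duration, noise_until, "soma",
                                      region_all(), "white_noise",
                                      variance = noise_variance)))
  segs
}

#' Immobile-to-mobile switching fragment
#'
#' Ignites motion of an immobile bump with two consecutive excitatory inputs
#' on thin vertical lines of somata: the first on the line through the bump
#' center, the second (briefer) on the strictly adjacent line, biasing the
#' adaptation field so the self-regenerative loop starts in that direction.
#'
#' @param t0 Onset of the first line input, ms.
#' @param bump_center `(row, col)` of the immobile bump, lattice units.
#' @param first_duration,second_duration Durations, ms; the second must be
#'   shorter than the first.
#' @param line_offset Column displacement of the second line; must equal the
#'   line width (strict adjacency).
#' @param amplitude Excitatory amplitude, pA.
#' @param width Line width, lattice units.
#' @return A list of two [stim_segment()]s.
#' @export
make_switch_to_mobile <- function(t0, bump_center, first_duration,
                                  second_duration, line_offset = 1,
                                  amplitude = 30, width = 1) {
  if (abs(line_offset) != width)
    stop("second line must be strictly adjacent: |line_offset| must equal width")
  if (second_duration >= first_duration)
    stop("second_duration must be shorter than first_duration")
  col0 <- round(bump_center[2])
  list(stim_segment(t0, t0 + first_duration, "soma",
                    region_line("col", col0, width), "constant",
                    amplitude = amplitude),
       stim_segment(t0 + first_duration,
                    t0 + first_duration + second_duration, "soma",
                    region_line("col", col0 + line_offset, width), "constant",
                    amplitude = amplitude))
}

#' Random dendritic pulse protocol
#'
#' `n_inputs` brief current pulses, each strong enough to evoke one dendritic
#' plateau, delivered to dendritic units drawn uniformly from a disk of
#' radius `input_radius` at the field center, at times drawn uniformly from
#' `[0, input_duration]`. Used to probe how the plateau duration extends the
#' temporal window over which scattered inputs integrate into a bump.
#'
#' @param input_radius Disk radius, lattice units (>= 0; 0 targets the
#'   central unit only).
#' @param input_duration Length of the input period, ms.
#' @param n_inputs Number of pulses (>= 1).
#' @param pulse_width Pulse width, ms.
#' @param amplitude Pulse amplitude, pA.
#' @param seed RNG seed for times and targets.
#' @param geometry A [field_geometry()].
#' @param t0 Input period onset, ms.
#' @param dend Optional [dendrite_params()]; if supplied, the amplitude is
#'   checked against the single-unit plateau threshold and a warning is
#'   issued when below it.
#' @return A `stim_protocol` with `n_inputs` pulse segments.
#' @export
make_dendritic_pulse_protocol <- function(input_radius, input_duration,
                                          n_inputs, pulse_width = 5,
                                          amplitude = 120, seed = 1L,
                                          geometry, t0 = 0, dend = NULL) {
  if (n_inputs < 1) stop("n_inputs must be >= 1")
  n <- geometry$n_dend_side
  center <- c(n / 2, n / 2)
  pool <- if (input_radius <= 0) {
    rowcol_to_unit(round(center[1]), round(center[2]), n)
  } else resolve_region(region_disk(center, input_radius), n)
  draws <- with_seed(seed, list(times = stats::runif(n_inputs, 0, input_duration),
                                units = pool[sample.int(length(pool), n_inputs,
                                                        replace = TRUE)]))
  if (!is.null(dend)) {
    thr <- plateau_threshold(dend, pulse_width = pulse_width)
    if (amplitude < thr)
      warning(sprintf("amplitude %.3g pA is below the single-unit plateau threshold (%.3g pA)",
                      amplitude, thr))
  }
  segs <- mapply(function(tk, unit) {
    m <- matrix(FALSE, n, n); m[unit] <- TRUE
    stim_segment(t0 + tk, t0 + tk + pulse_width, "dendrite", region_mask(m),
                 "constant", amplitude = amplitude)
  }, draws$times, draws$units, SIMPLIFY = FALSE)
  stimulus_protocol(segs, rng_seed = seed)
}

#' Strip confinement
#'
#' `strip_mask()` marks a periodic horizontal strip of rows centered on the
#' field; `strip_confinement_segment()` realizes the confinement as a strong
#' static hyperpolarizing current outside the strip, so bump motion reduces
#' to one coordinate without touching the model equations.
#'
#' @param geometry A [field_geometry()].
#' @param strip_height Strip height in lattice units, in `(0, n_soma_side]`.
#' @param amplitude Magnitude of the confining inhibitory current, pA.
#' @param t0,t1 Segment window, ms.
#' @return `strip_mask()`: a logical `n x n` matrix (`TRUE` inside the
#'   strip); `strip_confinement_segment()`: a [stim_segment()] (or `NULL`
#'   when the strip covers the whole field).
#' @export
strip_mask <- function(geometry, strip_height) {
  n <- geometry$n_soma_side
  if (strip_height <= 0 || strip_height > n)
    stop("strip_height must be in (0, n_soma_side]")
  r0 <- floor((n - strip_height) / 2) + 1
  rows <- seq(r0, length.out = strip_height)
  matrix(seq_len(n) %in% rows, n, n)
}

#' @rdname strip_mask
#' @export
strip_confinement_segment <- function(geometry, strip_height, amplitude = 200,
                                      t0 = 0, t1 = Inf) {
  m <- strip_mask(geometry, strip_height)
  if (all(m)) return(NULL)
  stim_segment(t0, t1, "soma", region_mask(!m), "inhibitory",
               amplitude = amplitude)
}
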