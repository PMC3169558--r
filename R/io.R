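#' Serialize a stimulus protocol to YAML
#'
#' @param protocol A [stimulus_protocol()].
#' @param path YAML file path.
#' @return `read_protocol()` returns a `stim_protocol`.
#' @export
write_protocol <- function(protocol, path) {
  segs <- lapply(protocol$segments, function(s) {
    r <- s$region
    reg <- switch(r$type,
      all = list(type = "all"),
      disk = list(type = "disk", center = r$center, radius = r$radius),
      line = list(type = "line", axis = r$axis, offset = r$offset,
                  width = r$width),
      mask = list(type = "mask", n = nrow(r$mask), which = which(r$mask)))
    list(t_start = s$t_start, t_end = s$t_end, target = s$target,
         kind = s$kind, amplitude = s$amplitude, variance = s$variance,
         pulse_times = s$pulse_times, pulse_width = s$pulse_width,
         region = reg)
  })
  yaml::write_yaml(list(rng_seed = protocol$rng_seed, segments = segs), path)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  spec <- yaml::read_yaml(path)
  segs <- lapply(spec$segments, function(s) {
    r <- s$region
    region <- switch(r$type,
      all = region_all(),
      disk = region_disk(unlist(r$center), r$radius),
      line = region_line(r$axis, r$offset, r$width),
      mask = { m <- matrix(FALSE, r$n, r$n); m[unlist(r$which)] <- TRUE
               region_mask(m) },
      stop("malformed region in protocol file"))
    stim_segment(s$t_start, s$t_end, s$target, region, s$kind,
                 amplitude = s$amplitude %||% 0,
                 variance = s$variance %||% 0,
                 pulse_times = unlist(s$pulse_times),
                 pulse_width = s$pulse_width %||% 5)
  })
  stimulus_protocol(segs, rng_seed = spec$rng_seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read recorded state snapshots as CSV
#'
#' Long-format portable container for the per-variable field snapshots a
#' simulation records: one row per (time, variable, row, col).
#'
#' @param snapshots The `snapshots` element of a [simulate_network()] result.
#' @param path CSV path.
#' @return `read_snapshots()` returns the snapshots list (`t` plus one 3-D
#'   array per variable).
#' @export
write_snapshots <- function(snapshots, path) {
  rows <- lapply(c("u", "V", "w"), function(var) {
    a <- snapshots[[var]]
    if (is.null(a) || length(a) == 0) return(NULL)
    d <- dim(a)
    data.frame(t = rep(snapshots$t, each = d[1] * d[2]),
               variable = var,
               row = rep(seq_len(d[1]), times = d[2] * d[3]),
               col = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
               value = as.vector(a))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_snapshots
#' @export
read_snapshots <- function(path) {
  x <- utils::read.csv(path)
  ts <- sort(unique(x$t))
  out <- list(t = ts)
  for (var in unique(x$variable)) {
    xs <- x[x$variable == var, ]
    n1 <- max(xs$row); n2 <- max(xs$col)
    a <- array(0, dim = c(n1, n2, length(ts)))
    for (k in seq_along(ts)) {
      xk <- xs[xs$t == ts[k], ]
      a[cbind(xk$row, xk$col, k)] <- xk$value
    }
    out[[var]] <- a
  }
  out
}
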