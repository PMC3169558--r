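#' Gaussian connection kernel
#'
#' Connection probabilities between the two fields fall off as a Gaussian of
#' distance, mimicking the measured connectivity of layer 2/3 pyramidal
#' neurons: `p(d) = amplitude * exp(-d^2 / (2 sigma^2))`.
#'
#' @param sigma Kernel width in mm (> 0).
#' @param amplitude Probability at zero distance, in (0, 1].
#' @return An object of class `gaussian_kernel`.
#' @export
gaussian_kernel <- function(sigma, amplitude) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (amplitude <= 0 || amplitude > 1) stop("amplitude must be in (0, 1]")
  structure(list(sigma = sigma, amplitude = amplitude),
            class = "gaussian_kernel")
}

#' Connection probability at a given distance
#'
#' @param d Distance(s) in mm, >= 0.
#' @param kernel A [gaussian_kernel()].
#' @return Probability in `[0, amplitude]`, monotone non-increasing in `d`.
#' @examples
#' k <- gaussian_kernel(0.5, 0.2)
#' connection_probability(0, k)          # 0.2
#' connection_probability(0.5, k)        # 0.2 * exp(-1/2)
#' @export
connection_probability <- function(d, kernel) {
  if (any(d < 0)) stop("distance must be >= 0")
  kernel$amplitude * exp(-d^2 / (2 * kernel$sigma^2))
}

#' Sample the fixed random soma-dendrite coupling
#'
#' Every soma--dendrite pair is connected independently: soma `i` innervates
#' dendritic unit `j` ("axon" edge) with probability given by the axon kernel
#' at their wrapped distance, and dendritic unit `j` is a branch of soma `k`
#' ("branch" edge) with probability given by the branch kernel. The map is
#' sampled once, before any simulation, and is immutable; soma-to-soma
#' coupling is the composition of the two samples through a shared dendritic
#' unit.
#'
#' @param geometry A [field_geometry()].
#' @param axon_kernel,branch_kernel [gaussian_kernel()]s for soma-to-dendrite
#'   and dendrite-to-soma sampling.
#' @param seed Integer RNG seed; the map is a deterministic function of
#'   (geometry, kernels, seed).
#' @return An object of class `connectivity_map` with `axon_targets` (list:
#'   per soma, integer vector of innervated dendritic units),
#'   `branch_owners` (list: per dendritic unit, integer vector of somata
#'   owning it as a branch), `soma_branches` (transpose of `branch_owners`,
#'   used by the dendro-somatic current), plus `geometry`, `kernels`, `seed`.
#' @export
build_connectivity <- function(geometry, axon_kernel, branch_kernel, seed) {
  stopifnot(inherits(geometry, "field_geometry"),
            inherits(axon_kernel, "gaussian_kernel"),
            inherits(branch_kernel, "gaussian_kernel"))
  xs <- unit_positions(geometry, "soma")
  yd <- unit_positions(geometry, "dendrite")
  ns <- nrow(xs); nd <- nrow(yd)

  sample_edges <- function(from_pos, to_pos, kernel) {
    # per source unit, Bernoulli over all targets at wrapped distance
    L <- geometry$extent
    out <- vector("list", nrow(from_pos))
    for (i in seq_len(nrow(from_pos))) {
      dx <- abs(to_pos[, 1] - from_pos[i, 1]); dx <- pmin(dx, L - dx)
      dy <- abs(to_pos[, 2] - from_pos[i, 2]); dy <- pmin(dy, L - dy)
      p <- connection_probability(sqrt(dx^2 + dy^2), kernel)
      out[[i]] <- which(stats::runif(nrow(to_pos)) < p)
    }
    out
  }

  res <- with_seed(seed, {
    list(axon = sample_edges(xs, yd, axon_kernel),
         branch = sample_edges(yd, xs, branch_kernel))
  })

  # transpose branch_owners (dendrite -> owning somata) into soma -> branches
  from <- rep.int(seq_len(nd), lengths(res$branch))
  to <- unlist(res$branch, use.names = FALSE)
  soma_branches <- unname(split(from, factor(to, levels = seq_len(ns))))

  structure(list(axon_targets = res$axon,
                 branch_owners = res$branch,
                 soma_branches = soma_branches,
                 geometry = geometry,
                 kernels = list(axon = axon_kernel, branch = branch_kernel),
                 seed = as.integer(seed)),
            class = "connectivity_map")
}

#' @export
print.connectivity_map <- function(x, ...) {
  cat(sprintf("<connectivity_map> seed %d: %d axon edges (mean out-degree %.1f), %d branch edges (mean branches/soma %.1f)\n",
              x$seed, sum(lengths(x$axon_targets)),
              mean(lengths(x$axon_targets)),
              sum(lengths(x$branch_owners)),
              mean(lengths(x$soma_branches))))
  invisible(x)
}

# CSR (0-based) adjacency for the C++ stepper
conn_csr <- function(lists) {
  lens <- lengths(lists)
  list(ptr = as.integer(c(0L, cumsum(lens))),
       idx = as.integer(unlist(lists, use.names = FALSE) - 1L))
}

#' Persist / load a connectivity map
#'
#' The adjacency is written in coordinate-list form as a plain CSV
#' (`edge_type`, `from`, `to`) next to a JSON sidecar recording the geometry,
#' kernels and seed, so a map can be rebuilt or audited without the package.
#'
#' @param conn A [build_connectivity()] result.
#' @param path Base path; `<path>.csv` and `<path>.json` are written.
#' @return `write_connectivity()` returns `path` invisibly;
#'   `read_connectivity()` returns a `connectivity_map`.
#' @export
write_connectivity <- function(conn, path) {
  ax <- data.frame(edge_type = "axon",
                   from = rep.int(seq_along(conn$axon_targets),
                                  lengths(conn$axon_targets)),
                   to = unlist(conn$axon_targets, use.names = FALSE))
  br <- data.frame(edge_type = "branch",
                   from = rep.int(seq_along(conn$branch_owners),
                                  lengths(conn$branch_owners)),
                   to = unlist(conn$branch_owners, use.names = FALSE))
  utils::write.csv(rbind(ax, br), paste0(path, ".csv"), row.names = FALSE)
  side <- list(geometry = unclass(conn$geometry),
               kernels = lapply(conn$kernels, unclass),
               seed = conn$seed)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  geom <- field_geometry(side$geometry$n_soma_side, side$geometry$n_dend_side,
                         extent = side$geometry$extent)
  edges <- utils::read.csv(paste0(path, ".csv"))
  ns <- geom$n_soma_side^2; nd <- geom$n_dend_side^2
  ax <- edges[edges$edge_type == "axon", ]
  br <- edges[edges$edge_type == "branch", ]
  axon <- unname(split(ax$to, factor(ax$from, levels = seq_len(ns))))
  branch <- unname(split(br$to, factor(br$from, levels = seq_len(nd))))
  soma_branches <- unname(split(br$from, factor(br$to, levels = seq_len(ns))))
  structure(list(axon_targets = axon, branch_owners = branch,
                 soma_branches = soma_branches, geometry = geom,
                 kernels = list(axon = do.call(gaussian_kernel, as.list(side$kernels$axon)),
                                branch = do.call(gaussian_kernel, as.list(side$kernels$branch))),
                 seed = as.integer(side$seed)),
            class = "connectivity_map")
}

# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
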