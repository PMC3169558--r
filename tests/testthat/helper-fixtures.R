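# shared small fixtures, built once per test run
fx <- local({
  cache <- new.env(parent = emptyenv())
  function(name, build) {
    if (!exists(name, envir = cache)) assign(name, build(), envir = cache)
    get(name, envir = cache)
  }
})

geom16 <- function() fx("geom16", function() field_geometry(16, extent = 5))
conn16 <- function() fx("conn16", function()
  build_connectivity(geom16(), gaussian_kernel(0.9, 0.3),
                     gaussian_kernel(0.9, 0.3), seed = 7))
dend_fast <- function() fx("dend_fast", function() dendrite_params(tau_d = 25))
dend_slow <- function() fx("dend_slow", function() dendrite_params(tau_d = 200))

# deterministic Gaussian-blob snapshot series (rate fields, no sampling noise)
blob_series <- function(n, centers, sigma = 2, hop = 10) {
  g <- expand.grid(row = seq_len(n), col = seq_len(n))
  arr <- array(0, dim = c(n, n, nrow(centers)))
  for (k in seq_len(nrow(centers))) {
    dr <- abs(g$row - centers[k, 1]); dr <- pmin(dr, n - dr)
    dc <- abs(g$col - centers[k, 2]); dc <- pmin(dc, n - dc)
    arr[, , k] <- matrix(exp(-(dr^2 + dc^2) / (2 * sigma^2)), n, n)
  }
  structure(arr, t = seq(0, by = hop, length.out = nrow(centers)), hop = hop,
            window = 10, filter_sigma = sigma, class = "snapshot_series")
}
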