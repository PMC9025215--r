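# Shared fixtures, built once per test session (everything is generated in
# code; nothing is read from disk).

.world_cache <- new.env(parent = emptyenv())

# a small but complete synthetic world
test_world <- function(seed = 7, grid = c(40, 40), n_raw = 300) {
  key <- paste(seed, paste(grid, collapse = "x"), n_raw, sep = "_")
  if (is.null(.world_cache[[key]]))
    .world_cache[[key]] <- synth_world(seed, grid, n_raw)
  .world_cache[[key]]
}

# a raster from a matrix on a unit-degree grid
mk_raster <- function(m, xmin = 0, ymin = 0) {
  m <- as.matrix(m)
  grid_raster(m, xmin = xmin, xmax = xmin + ncol(m),
              ymin = ymin, ymax = ymin + nrow(m))
}

# random occurrence records
mk_records <- function(n, seed = 1, lon = c(0, 10), lat = c(40, 50)) {
  set.seed(seed)
  data.frame(
    lon = runif(n, lon[1], lon[2]),
    lat = runif(n, lat[1], lat[2]),
    year = sample(1990:2020, n, replace = TRUE),
    coord_uncertainty_m = runif(n, 100, 5000)
  )
}

# presence/background toy modelling problem with a known monotone driver
mk_pb <- function(n1 = 150, n0 = 600, p = 3, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm((n1 + n0) * p), n1 + n0, p,
              dimnames = list(NULL, paste0("v", seq_len(p))))
  prob <- plogis(2.5 * x[, 1])
  y <- rbinom(n1 + n0, 1, prob)
  # enforce requested class sizes approximately by resampling labels
  list(x = x, y = y)
}
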