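#' Great-circle distance (haversine)
#'
#' Spherical Earth, radius 6371 km. Vectorized over the longer argument pair.
#' @param lon1,lat1,lon2,lat2 decimal degrees
#' @return distance in km
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  r <- 6371
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Full pairwise great-circle distance matrix
#' @param lon,lat coordinate vectors
#' @return symmetric n x n matrix of km
#' @export
haversine_matrix <- function(lon, lat) {
  n <- length(lon)
  m <- matrix(0, n, n)
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    d <- haversine_km(lon[i], lat[i], lon[j], lat[j])
    m[i, j] <- d
    m[j, i] <- d
  }
  m
}

# population standard deviation (divides by n, not n-1)
sd_pop <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

# half-up rounding to `digits` decimals, used only at serialization time
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# draw an integer sub-seed stream from one explicit seed without touching
# the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
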