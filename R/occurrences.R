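#' Filter occurrence records by year, coordinate uncertainty and validity
#'
#' Keeps records with \code{year >= min_year}, coordinate uncertainty
#' missing or at most \code{max_uncertainty_km} (strictly greater values
#' are removed), and valid coordinates (non-missing, lat in [-90, 90], lon
#' in [-180, 180]). Input order is preserved; an empty result is allowed.
#'
#' @param records data.frame with lon, lat, year, coord_uncertainty_m
#' @param min_year earliest year retained (default 1970, matching the
#'   baseline climatology period)
#' @param max_uncertainty_km uncertainty cutoff in km (default 9.25, one
#'   half of a 5-arc-minute-scale cell diagonal)
#' @return filtered data.frame
#' @export
filter_records <- function(records, min_year = 1970,
                           max_uncertainty_km = 9.25) {
  ok_coord <- !is.na(records$lon) & !is.na(records$lat) &
    records$lat >= -90 & records$lat <= 90 &
    records$lon >= -180 & records$lon <= 180
  ok_year <- !is.na(records$year) & records$year >= min_year
  unc <- records$coord_uncertainty_m
  ok_unc <- is.na(unc) | unc <= max_uncertainty_km * 1000
  out <- records[ok_coord & ok_year & ok_unc, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove duplicate records per raster cell
#'
#' At most one record per cell of the analysis grid; the first record in
#' input order wins. Records outside the grid extent are dropped with a
#' warning.
#'
#' @param records data.frame with lon, lat
#' @param grid \code{grid_raster} defining the analysis resolution
#' @return deduplicated data.frame
#' @export
dedupe_by_cell <- function(records, grid) {
  cell <- rst_cell(grid, records$lon, records$lat)
  if (anyNA(cell)) {
    warning(sum(is.na(cell)), " record(s) outside grid extent dropped")
  }
  keep <- !is.na(cell) & !duplicated(cell, incomparables = NA)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

tri_circumradius <- function(x, y) {
  a <- sqrt((x[2] - x[3])^2 + (y[2] - y[3])^2)
  b <- sqrt((x[1] - x[3])^2 + (y[1] - y[3])^2)
  cc <- sqrt((x[1] - x[2])^2 + (y[1] - y[2])^2)
  area2 <- abs((x[2] - x[1]) * (y[3] - y[1]) - (x[3] - x[1]) * (y[2] - y[1]))
  if (area2 <= 0) return(Inf)
  a * b * cc / (2 * area2)
}

#' Buffered alpha-hull extent of occurrence
#'
#' The alpha complex of the occurrence points: Delaunay triangles (via
#' \pkg{deldir}) whose circumradius is at most \code{alpha} (in degrees),
#' buffered by \code{buffer_km}. As alpha grows the hull converges to the
#' convex hull. The returned study area supports containment queries and
#' (planar, degree^2) area computation; every input point is contained.
#'
#' @param points data.frame with lon, lat (>= 3 non-collinear points)
#' @param alpha alpha parameter in degrees (default 2)
#' @param buffer_km buffer width in km (default 50)
#' @return object of class \code{study_area}
#' @export
alpha_hull_eoo <- function(points, alpha = 2, buffer_km = 50) {
  pts <- unique(data.frame(lon = points$lon, lat = points$lat))
  if (nrow(pts) < 3) stop("need at least 3 distinct points for an alpha hull")
  rng <- function(v) diff(range(v))
  # collinearity check via the triangulation failing to produce triangles
  tl <- tryCatch({
    dd <- deldir::deldir(pts$lon, pts$lat, suppressMsge = TRUE)
    deldir::triang.list(dd)
  }, error = function(e) NULL)
  if (is.null(tl) || length(tl) == 0)
    stop("insufficient data: points are collinear or too few for a hull")
  keep <- Filter(function(tr) tri_circumradius(tr$x, tr$y) <= alpha, tl)
  if (length(keep) == 0)
    stop("alpha too small: no triangle passes the circumradius filter")
  tris <- lapply(keep, function(tr) cbind(x = tr$x, y = tr$y))
  structure(list(triangles = tris, alpha = alpha, buffer_km = buffer_km,
                 points = pts),
            class = "study_area")
}

#' @export
print.study_area <- function(x, ...) {
  cat(sprintf("study_area: %d alpha-complex triangles (alpha=%g deg), buffer %g km\n",
              length(x$triangles), x$alpha, x$buffer_km))
  invisible(x)
}

point_in_tri <- function(px, py, tx, ty) {
  d1 <- (px - tx[2]) * (ty[1] - ty[2]) - (tx[1] - tx[2]) * (py - ty[2])
  d2 <- (px - tx[3]) * (ty[2] - ty[3]) - (tx[2] - tx[3]) * (py - ty[3])
  d3 <- (px - tx[1]) * (ty[3] - ty[1]) - (tx[3] - tx[1]) * (py - ty[1])
  neg <- (d1 < 0) | (d2 < 0) | (d3 < 0)
  pos <- (d1 > 0) | (d2 > 0) | (d3 > 0)
  !(neg & pos)
}

# km distance from points to a segment, planar local approximation
dist_to_segment_km <- function(px, py, x1, y1, x2, y2) {
  latref <- (y1 + y2) / 2
  kx <- 111.32 * cos(latref * pi / 180)
  ky <- 110.54
  ax <- (px - x1) * kx; ay <- (py - y1) * ky
  bx <- (x2 - x1) * kx; by <- (y2 - y1) * ky
  len2 <- bx^2 + by^2
  t <- if (len2 > 0) pmin(1, pmax(0, (ax * bx + ay * by) / len2)) else 0
  sqrt((ax - t * bx)^2 + (ay - t * by)^2)
}

#' Test whether points fall inside a (buffered) study area
#' @param sa a \code{study_area}
#' @param lon,lat coordinates
#' @return logical vector
#' @export
sa_contains <- function(sa, lon, lat) {
  inside <- rep(FALSE, length(lon))
  for (tr in sa$triangles) {
    todo <- !inside
    if (!any(todo)) break
    inside[todo] <- point_in_tri(lon[todo], lat[todo], tr[, "x"], tr[, "y"])
  }
  if (sa$buffer_km > 0) {
    todo <- which(!inside)
    if (length(todo)) {
      mind <- rep(Inf, length(todo))
      for (tr in sa$triangles) {
        for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
          d <- dist_to_segment_km(lon[todo], lat[todo],
                                  tr[e[1], "x"], tr[e[1], "y"],
                                  tr[e[2], "x"], tr[e[2], "y"])
          mind <- pmin(mind, d)
        }
      }
      inside[todo] <- mind <= sa$buffer_km
    }
  }
  inside
}

#' Planar area of the (unbuffered) alpha complex, degree^2
#' @param sa a \code{study_area}
#' @return numeric area in squared degrees
#' @export
sa_area <- function(sa) {
  sum(vapply(sa$triangles, function(tr) {
    abs((tr[2, "x"] - tr[1, "x"]) * (tr[3, "y"] - tr[1, "y"]) -
          (tr[3, "x"] - tr[1, "x"]) * (tr[2, "y"] - tr[1, "y"])) / 2
  }, numeric(1)))
}

#' Export the study area as a GeoJSON MultiPolygon
#'
#' Writes the alpha-complex triangles as an (undissolved) MultiPolygon in
#' WGS84. The buffer is metadata (a \code{buffer_km} property), not
#' geometry.
#' @param sa a \code{study_area}
#' @param path output .geojson path
#' @export
sa_write_geojson <- function(sa, path) {
  polys <- lapply(sa$triangles, function(tr) {
    ring <- rbind(tr, tr[1, , drop = FALSE])
    list(lapply(seq_len(nrow(ring)), function(i) c(ring[i, "x"], ring[i, "y"])))
  })
  gj <- list(
    type = "Feature",
    properties = list(alpha = sa$alpha, buffer_km = sa$buffer_km),
    geometry = list(type = "MultiPolygon", coordinates = polys)
  )
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Spatial thinning by great-circle distance
#'
#' Greedy randomized thinning: while any two retained records are within
#' \code{thin_dist_km} (haversine), remove a record with the most
#' conflicting neighbors (random tie-break). \code{n_reps} randomized runs
#' are performed and a run retaining the most records is returned (ties:
#' first attaining run). Deterministic given \code{seed}. Applying the
#' result to itself returns it unchanged.
#'
#' @param records data.frame with lon, lat
#' @param thin_dist_km minimum allowed pairwise distance (km), > 0
#' @param n_reps number of randomized runs (default 10)
#' @param seed explicit integer seed
#' @return thinned data.frame (subset of input rows, input order)
#' @export
spatial_thin <- function(records, thin_dist_km, n_reps = 10, seed = 1) {
  stopifnot(thin_dist_km > 0)
  n <- nrow(records)
  if (n <= 1) return(records)
  d <- haversine_matrix(records$lon, records$lat)
  conflict <- d < thin_dist_km & upper.tri(d) # strict: == thin_dist ok
  conflict <- conflict | t(conflict)
  if (!any(conflict)) return(records)

  with_seed(seed, {
    best <- NULL
    for (rep in seq_len(n_reps)) {
      alive <- rep(TRUE, n)
      deg <- rowSums(conflict)
      while (any(deg[alive] > 0)) {
        cand <- which(alive & deg == max(deg[alive]))
        drop <- if (length(cand) > 1) sample(cand, 1) else cand
        alive[drop] <- FALSE
        nb <- which(conflict[drop, ] & alive)
        deg[nb] <- deg[nb] - 1
        deg[drop] <- 0
      }
      if (is.null(best) || sum(alive) > sum(best)) best <- alive
    }
    out <- records[best, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Environmental thinning (regular bins in niche space)
#'
#' Partitions the environmental space of the supplied variables into
#' \code{n_bins_per_var} equal-width bins per axis (over each variable's
#' observed range) and keeps exactly one seeded-random record per occupied
#' multidimensional bin. Constant variables collapse to a single bin (a
#' message is logged). Re-applying with the same parameters and seed is the
#' identity.
#'
#' @param records data.frame of occurrence records
#' @param env_values data.frame/matrix, one row per record: the retained
#'   uncorrelated predictor values at that record
#' @param n_bins_per_var bins per variable (>= 2, default 25)
#' @param seed explicit integer seed
#' @param ranges optional named list of c(min, max) fixing the binning
#'   domain per variable (default: the observed range). Idempotence —
#'   re-thinning the output returns it unchanged — holds for a fixed
#'   partition, i.e. when the first call's ranges are reused.
#' @return thinned data.frame (subset of input rows, input order), with the
#'   partition used attached as the \code{"ranges"} attribute
#' @export
env_thin <- function(records, env_values, n_bins_per_var = 25, seed = 1,
                     ranges = NULL) {
  stopifnot(n_bins_per_var >= 2)
  env_values <- as.data.frame(env_values)
  if (nrow(env_values) != nrow(records))
    stop("env_values must have one row per record")
  used_ranges <- lapply(stats::setNames(names(env_values),
                                        names(env_values)), function(nm) {
    if (!is.null(ranges) && !is.null(ranges[[nm]])) ranges[[nm]]
    else range(env_values[[nm]], na.rm = TRUE)
  })
  bins <- lapply(names(env_values), function(nm) {
    v <- env_values[[nm]]
    rng <- used_ranges[[nm]]
    if (diff(rng) == 0) {
      message("constant environmental variable: axis collapses to one bin")
      return(rep(1L, length(v)))
    }
    b <- floor((v - rng[1]) / diff(rng) * n_bins_per_var) + 1L
    pmin(pmax(b, 1L), n_bins_per_var) # extremes belong to the edge bins
  })
  key <- do.call(paste, c(bins, sep = "|"))
  with_seed(seed, {
    keep <- unlist(lapply(split(seq_len(nrow(records)), key), function(idx) {
      if (length(idx) == 1) idx else sample(idx, 1)
    }), use.names = FALSE)
    out <- records[sort(keep), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "ranges") <- used_ranges
    out
  })
}

#' Read/write occurrence CSV (lon,lat,year,coord_uncertainty_m)
#' @param records data.frame of records
#' @param path file path
#' @export
write_occurrences <- function(records, path) {
  cols <- c("lon", "lat", "year", "coord_uncertainty_m")
  utils::write.csv(records[intersect(c(cols, "flag"), names(records))],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(path) {
  utils::read.csv(path)
}
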