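#' Binarize a suitability map
#'
#' 1 where suitability >= threshold, 0 below, missing propagates.
#' @param suitability \code{grid_raster}
#' @param threshold numeric threshold (from the evaluation module)
#' @return \code{grid_raster} of 0/1/NA, with the threshold attached
#' @export
binarize <- function(suitability, threshold) {
  v <- as.vector(suitability$values)
  out <- rst_like(suitability, as.numeric(v >= threshold))
  attr(out, "threshold") <- threshold
  out
}

#' Range change between two binary maps (unlimited dispersal)
#'
#' With C = number of current-presence cells: loss = 100 x (cells 1 -> 0)
#' / C, gain = 100 x (cells 0 -> 1) / C (all newly suitable cells count —
#' the unlimited-dispersal convention), overall change = gain - loss.
#' Cells missing in either map are excluded from every count.
#'
#' @param current,future co-registered binary \code{grid_raster} maps
#' @return list with loss_pct, gain_pct, overall_change_pct and the
#'   underlying counts (lost, gained, stable, absent, current_cells)
#' @export
range_change <- function(current, future) {
  stopifnot(same_grid(current, future))
  a <- as.vector(current$values)
  b <- as.vector(future$values)
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  cc <- sum(a == 1)
  if (cc == 0) stop("current map has no presence cells")
  lost <- sum(a == 1 & b == 0)
  gained <- sum(a == 0 & b == 1)
  stable <- sum(a == 1 & b == 1)
  absent <- sum(a == 0 & b == 0)
  loss <- 100 * lost / cc
  gain <- 100 * gained / cc
  list(loss_pct = loss, gain_pct = gain,
       overall_change_pct = gain - loss,
       counts = c(lost = lost, gained = gained, stable = stable,
                  absent = absent, current_cells = cc))
}

#' Transition map (absent/lost/stable/gained)
#'
#' Integer codes: 0 = absent in both, 1 = lost (1 -> 0), 2 = stable,
#' 3 = gained (0 -> 1); missing propagates.
#' @inheritParams range_change
#' @return \code{grid_raster} of codes
#' @export
transition_map <- function(current, future) {
  stopifnot(same_grid(current, future))
  a <- as.vector(current$values); b <- as.vector(future$values)
  code <- rep(NA_real_, length(a))
  ok <- !is.na(a) & !is.na(b)
  code[ok] <- 0
  code[ok & a == 1 & b == 0] <- 1
  code[ok & a == 1 & b == 1] <- 2
  code[ok & a == 0 & b == 1] <- 3
  rst_like(current, code)
}

#' Percentage of current occurrences falling in future-unsuitable cells
#'
#' 100 x (records whose cell is 0 or missing in the future map) / (records
#' in data cells of the current map).
#'
#' @param occurrences data.frame with lon, lat (post-cleaning records)
#' @param future binary \code{grid_raster}
#' @param current optional binary \code{grid_raster}; when given, only
#'   records in its data cells enter the denominator
#' @return percentage in [0, 100]
#' @export
occurrences_lost <- function(occurrences, future, current = NULL) {
  fut <- rst_extract(future, occurrences$lon, occurrences$lat)
  usable <- rep(TRUE, nrow(occurrences))
  if (!is.null(current)) {
    cur <- rst_extract(current, occurrences$lon, occurrences$lat)
    usable <- !is.na(cur)
  } else {
    usable <- !is.na(rst_cell(future, occurrences$lon, occurrences$lat))
  }
  if (!sum(usable)) stop("no usable occurrence records on the grid")
  lost <- is.na(fut[usable]) | fut[usable] == 0
  100 * mean(lost)
}

#' Aggregate range-change reports across GCMs
#'
#' Unweighted arithmetic mean of each percentage across the members of a
#' scenario group (e.g. the GCMs of one SSP x time slice); values are
#' rounded to 2 decimals (half-up) for reporting.
#'
#' @param reports data.frame with columns group, loss_pct, gain_pct,
#'   overall_change_pct, occ_lost_pct
#' @param digits reporting decimals (default 2)
#' @return data.frame with one row per group of mean percentages
#' @export
aggregate_scenarios <- function(reports, digits = 2) {
  stopifnot(nrow(reports) >= 1)
  cols <- intersect(c("loss_pct", "gain_pct", "overall_change_pct",
                      "occ_lost_pct"), names(reports))
  agg <- stats::aggregate(reports[cols], by = list(group = reports$group),
                          FUN = mean)
  agg[cols] <- lapply(agg[cols], round_half_up, digits = digits)
  agg[order(agg$group), , drop = FALSE]
}

#' Median centroid of a binary range map
#'
#' Component-wise median of the coordinates of presence-cell centers (the
#' robust reading of a "median centroid"); the geometric mean-coordinate
#' centroid is available via \code{method = "centroid"}.
#'
#' @param map binary \code{grid_raster}
#' @param method "median" (default) or "centroid"
#' @return named numeric c(lon, lat)
#' @export
median_centroid <- function(map, method = c("median", "centroid")) {
  method <- match.arg(method)
  v <- as.vector(map$values)
  pres <- which(!is.na(v) & v == 1)
  if (!length(pres)) stop("empty range map: no presence cells")
  xy <- rst_coords(map)
  f <- if (method == "median") stats::median else mean
  c(lon = f(xy$lon[pres]), lat = f(xy$lat[pres]))
}

#' Great-circle distance between two centroids (km)
#' @param a,b named numeric c(lon, lat)
#' @return km
#' @export
centroid_distance <- function(a, b) {
  haversine_km(a[["lon"]], a[["lat"]], b[["lon"]], b[["lat"]])
}

#' Pairwise centroid distance matrix across scenarios
#' @param centroids named list of c(lon, lat)
#' @return symmetric matrix of km
#' @export
centroid_matrix <- function(centroids) {
  n <- length(centroids)
  m <- matrix(0, n, n, dimnames = list(names(centroids), names(centroids)))
  for (i in seq_len(n)) for (j in seq_len(n))
    m[i, j] <- centroid_distance(centroids[[i]], centroids[[j]])
  m
}

#' Mean altitude over the presence cells of a binary map
#' @param map binary \code{grid_raster}
#' @param elevation co-registered elevation \code{grid_raster} (m)
#' @return meters
#' @export
mean_altitude <- function(map, elevation) {
  stopifnot(same_grid(map, elevation))
  v <- as.vector(map$values)
  pres <- !is.na(v) & v == 1
  if (!any(pres)) stop("empty range map: no presence cells")
  mean(as.vector(elevation$values)[pres], na.rm = TRUE)
}

#' Altitude samples of a binary map (one value per presence cell)
#' @inheritParams mean_altitude
#' @return numeric vector of elevations
#' @export
altitude_samples <- function(map, elevation) {
  v <- as.vector(map$values)
  pres <- !is.na(v) & v == 1
  if (!any(pres)) stop("empty range map: no presence cells")
  as.vector(elevation$values)[pres]
}

#' Nonparametric altitude-shift tests across scenario groups
#'
#' Kruskal-Wallis rank test (with tie correction) across all groups, plus
#' pairwise two-sided Wilcoxon rank-sum tests with Holm adjustment.
#'
#' @param altitude_samples_by_group named list of numeric vectors
#'   (per-presence-cell elevations per scenario)
#' @return list with kw_stat, kw_df, kw_p and the pairwise_p matrix
#' @export
shift_tests <- function(altitude_samples_by_group) {
  if (length(altitude_samples_by_group) < 2)
    stop("need at least 2 groups")
  sizes <- vapply(altitude_samples_by_group, length, integer(1))
  if (any(sizes == 0))
    stop("empty group(s): ",
         paste(names(altitude_samples_by_group)[sizes == 0], collapse = ", "))
  values <- unlist(altitude_samples_by_group, use.names = FALSE)
  grp <- factor(rep(names(altitude_samples_by_group), sizes),
                levels = names(altitude_samples_by_group))
  kw <- stats::kruskal.test(values, grp)
  pw <- suppressWarnings(
    stats::pairwise.wilcox.test(values, grp, p.adjust.method = "holm",
                                exact = FALSE))
  list(kw_stat = unname(kw$statistic), kw_df = unname(kw$parameter),
       kw_p = kw$p.value, pairwise_p = pw$p.value,
       adjust = "holm")
}

#' Serialize range-change reports as a CSV
#'
#' Mirrors the published table layout: one row per scenario with loss,
#' gain, overall change and occurrences-lost percentages plus the raw
#' counts; percentages rounded half-up to 2 decimals at serialization
#' only.
#'
#' @param reports data.frame with scenario metadata and report columns
#' @param path output CSV path
#' @export
write_range_reports <- function(reports, path) {
  num <- vapply(reports, is.numeric, logical(1)) &
    grepl("_pct$", names(reports))
  reports[num] <- lapply(reports[num], round_half_up, digits = 2)
  utils::write.csv(reports, path, row.names = FALSE)
  invisible(path)
}
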