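#' @useDynLib rangeshift, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# coerce a 12-layer monthly input (list of grid_raster or cells x 12 matrix)
# to a cells x 12 matrix; returns the template raster as an attribute
monthly_matrix <- function(x, what = "monthly input") {
  if (is.matrix(x)) {
    if (ncol(x) != 12) stop(what, " must have 12 columns")
    return(x)
  }
  if (length(x) != 12) stop(what, " must have 12 layers")
  tmpl <- x[[1]]
  for (l in x[-1]) if (!same_grid(tmpl, l)) stop(what, ": layers not co-registered")
  m <- vapply(x, function(l) as.vector(l$values), numeric(length(tmpl$values)))
  attr(m, "template") <- tmpl
  m
}

row_minmax <- function(m, fun) do.call(fun, as.data.frame(m))

#' The 19 bioclimatic variables
#'
#' Derives bio1-bio19 from 12 monthly layers each of minimum, maximum and
#' average temperature (degrees C) and precipitation (mm), following the
#' WorldClim/ANUCLIM conventions. Quarters are calendar-contiguous 3-month
#' windows with December-January wraparound; the wettest/driest/warmest/
#' coldest quarter is the first window attaining the extreme (ties broken by
#' earliest start month). Temperature seasonality (bio4) is 100 x the
#' population standard deviation of the 12 monthly means, and precipitation
#' seasonality (bio15) is the population coefficient of variation with the
#' +1 mm offset: 100 * sd(p) / (1 + mean(p)).
#'
#' @param monthly_tmin,monthly_tmax,monthly_tavg,monthly_prec lists of 12
#'   co-registered \code{grid_raster} layers (or cells x 12 matrices).
#' @return a \code{raster_stack} (or named matrix if matrix input) of 19
#'   layers named bio1..bio19.
#' @export
bioclim <- function(monthly_tmin, monthly_tmax, monthly_tavg, monthly_prec) {
  tn <- monthly_matrix(monthly_tmin, "tmin")
  tx <- monthly_matrix(monthly_tmax, "tmax")
  ta <- monthly_matrix(monthly_tavg, "tavg")
  pr <- monthly_matrix(monthly_prec, "prec")
  tmpl <- attr(ta, "template")
  if (!is.null(tmpl)) {
    for (m in list(tn, tx, pr)) {
      t2 <- attr(m, "template")
      if (!is.null(t2) && !same_grid(tmpl, t2)) stop("inputs not co-registered")
    }
  }
  n <- nrow(ta)
  if (nrow(tn) != n || nrow(tx) != n || nrow(pr) != n)
    stop("inputs not co-registered (cell counts differ)")

  qsum <- function(m) { # 12 wraparound 3-month window sums, cells x 12
    idx <- cbind(1:12, c(2:12, 1), c(3:12, 1, 2))
    vapply(1:12, function(q) rowSums(m[, idx[q, ], drop = FALSE]),
           numeric(n))
  }
  qt <- qsum(ta) / 3   # quarterly mean temperature
  qp <- qsum(pr)       # quarterly precipitation total

  pick <- function(values, by, decreasing) {
    idx <- apply(by, 1, if (decreasing) which.max else which.min)
    values[cbind(seq_len(n), idx)]
  }

  b <- list()
  b$bio1 <- rowMeans(ta)
  b$bio2 <- rowMeans(tx - tn)
  b$bio4 <- 100 * sqrt(pmax(0, rowMeans(ta^2) - rowMeans(ta)^2))
  b$bio5 <- row_minmax(tx, pmax)
  b$bio6 <- row_minmax(tn, pmin)
  b$bio7 <- b$bio5 - b$bio6
  b$bio3 <- ifelse(b$bio7 == 0, NA_real_, 100 * b$bio2 / b$bio7)
  b$bio8 <- pick(qt, qp, TRUE)    # mean temp of wettest quarter
  b$bio9 <- pick(qt, qp, FALSE)   # driest quarter
  b$bio10 <- row_minmax(qt, pmax) # warmest quarter
  b$bio11 <- row_minmax(qt, pmin) # coldest quarter
  b$bio12 <- rowSums(pr)
  b$bio13 <- row_minmax(pr, pmax)
  b$bio14 <- row_minmax(pr, pmin)
  b$bio15 <- 100 * sqrt(pmax(0, rowMeans(pr^2) - rowMeans(pr)^2)) /
    (1 + rowMeans(pr))
  b$bio16 <- row_minmax(qp, pmax)
  b$bio17 <- row_minmax(qp, pmin)
  b$bio18 <- pick(qp, qt, TRUE)   # precip of warmest quarter
  b$bio19 <- pick(qp, qt, FALSE)  # coldest quarter
  b <- b[paste0("bio", 1:19)]

  if (is.null(tmpl)) {
    out <- do.call(cbind, b)
    colnames(out) <- names(b)
    return(out)
  }
  raster_stack(lapply(b, function(v) rst_like(tmpl, v)))
}

mid_month_doy <- c(15, 46, 74, 105, 135, 166, 196, 227, 258, 288, 319, 349)
days_in_month <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)

solar_declination <- function(month) {
  0.409 * sin(2 * pi * mid_month_doy[month] / 365 - 1.39)
}

#' Mid-month day length (hours) from latitude
#' @param lat latitude, decimal degrees
#' @param month integer 1-12
#' @return hours of daylight
#' @export
day_length <- function(lat, month) {
  phi <- lat * pi / 180
  delta <- solar_declination(month)
  ws <- acos(pmin(1, pmax(-1, -tan(phi) * tan(delta))))
  24 * ws / pi
}

#' Extra-terrestrial solar radiation (closed form)
#'
#' Mid-month daily extra-terrestrial radiation (MJ m-2 day-1) from the
#' standard astronomical formula (solar constant 0.0820 MJ m-2 min-1).
#' @param lat latitude, decimal degrees
#' @param month integer 1-12
#' @return radiation, MJ m-2 day-1
#' @export
extraterrestrial_radiation <- function(lat, month) {
  phi <- lat * pi / 180
  j <- mid_month_doy[month]
  dr <- 1 + 0.033 * cos(2 * pi * j / 365)
  delta <- solar_declination(month)
  ws <- acos(pmin(1, pmax(-1, -tan(phi) * tan(delta))))
  (24 * 60 / pi) * 0.0820 * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
}

#' Thornthwaite monthly potential evapotranspiration
#'
#' Standard heat-index formulation with day-length/month-length correction;
#' the high-temperature branch (T >= 26.5 C) uses the usual quadratic.
#' @param tavg cells x 12 matrix of monthly mean temperature (C)
#' @param lat per-cell latitude (decimal degrees)
#' @return cells x 12 matrix of PET (mm/month)
#' @export
thornthwaite_pet <- function(tavg, lat) {
  tpos <- pmax(tavg, 0)
  heat <- rowSums((tpos / 5)^1.514)
  a <- 6.75e-7 * heat^3 - 7.71e-5 * heat^2 + 1.792e-2 * heat + 0.49239
  pet <- matrix(0, nrow(tavg), 12)
  for (m in 1:12) {
    tm <- tavg[, m]
    base <- ifelse(heat > 0 & tm > 0, 16 * (10 * pmax(tm, 0) / pmax(heat, 1e-12))^a, 0)
    hot <- !is.na(tm) & tm >= 26.5
    base[hot] <- -415.85 + 32.24 * tm[hot] - 0.43 * tm[hot]^2
    k <- (day_length(lat, m) / 12) * (days_in_month[m] / 30)
    pet[, m] <- pmax(0, base * k)
  }
  pet
}

#' Thornthwaite aridity index
#'
#' TAI = 100 * D / PET_annual where D sums the monthly water deficit
#' max(0, PET - precipitation). 0 = never water-limited, 100 = no effective
#' precipitation in any deficit month. Cells with zero annual PET get 0.
#'
#' @param monthly_tavg,monthly_prec lists of 12 co-registered
#'   \code{grid_raster} layers (or cells x 12 matrices, in which case
#'   \code{lat} must be supplied).
#' @param lat optional per-cell latitudes (taken from the grid otherwise)
#' @return \code{grid_raster} (or numeric vector for matrix input)
#' @export
thornthwaite_aridity <- function(monthly_tavg, monthly_prec, lat = NULL) {
  ta <- monthly_matrix(monthly_tavg, "tavg")
  pr <- monthly_matrix(monthly_prec, "prec")
  tmpl <- attr(ta, "template")
  if (is.null(lat)) {
    if (is.null(tmpl)) stop("lat required for matrix input")
    lat <- rst_coords(tmpl)$lat
  }
  pet <- thornthwaite_pet(ta, lat)
  annual <- rowSums(pet)
  deficit <- rowSums(pmax(pet - pr, 0))
  tai <- ifelse(annual > 0, 100 * deficit / annual, 0)
  if (is.null(tmpl)) tai else rst_like(tmpl, tai)
}

# shift a matrix by (dr, dc) with NA padding
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
  ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

#' Terrain variables from elevation
#'
#' Slope and aspect by Horn's 8-neighbor method (degrees; aspect clockwise
#' from north, 0 on flat cells), topographic position index
#' (cell - mean of 8 neighbors), terrain ruggedness index
#' (mean |cell - neighbor|), and the McCune-Keon heat load index from
#' slope, folded aspect and latitude. Edge cells use the neighbors that
#' exist. Cell sizes are converted to meters with a latitude-dependent
#' east-west scale.
#'
#' @param elevation \code{grid_raster} of elevation in meters (>= 3x3 cells)
#' @return \code{raster_stack} with layers slope, aspect, heat_load, tpi, tri
#' @export
terrain_vars <- function(elevation) {
  z <- elevation$values
  if (nrow(z) < 3 || ncol(z) < 3) stop("elevation raster must be at least 3x3")
  res <- rst_res(elevation)
  lat <- rst_axes(elevation)$lat
  xres_m <- res[1] * 111320 * cos(lat * pi / 180) # per row
  yres_m <- res[2] * 110540

  # replicate-padded neighbors for the Horn gradient
  pad <- rbind(z[1, , drop = FALSE], z, z[nrow(z), , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, ncol(pad), drop = FALSE])
  nb <- function(dr, dc) pad[seq_len(nrow(z)) + 1 + dr, seq_len(ncol(z)) + 1 + dc]
  a <- nb(-1, -1); bb <- nb(-1, 0); cc <- nb(-1, 1)
  d <- nb(0, -1);                   f <- nb(0, 1)
  g <- nb(1, -1);  h <- nb(1, 0);   i <- nb(1, 1)

  dzdx <- sweep((cc + 2 * f + i) - (a + 2 * d + g), 1, 8 * xres_m, "/")
  dzdy <- ((a + 2 * bb + cc) - (g + 2 * h + i)) / (8 * yres_m) # +y = north
  slope_rad <- atan(sqrt(dzdx^2 + dzdy^2))
  slope <- slope_rad * 180 / pi
  aspect <- (atan2(-dzdx, -dzdy) * 180 / pi) %% 360 # downslope bearing
  aspect[slope == 0] <- 0

  # TPI / TRI with NA-padded neighbors (edges use available neighbors)
  shifts <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                 c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  nsum <- matrix(0, nrow(z), ncol(z))
  asum <- matrix(0, nrow(z), ncol(z))
  cnt <- matrix(0, nrow(z), ncol(z))
  for (s in shifts) {
    sh <- shift_mat(z, s[1], s[2])
    ok <- !is.na(sh)
    nsum[ok] <- nsum[ok] + sh[ok]
    asum[ok] <- asum[ok] + abs(z[ok] - sh[ok])
    cnt[ok] <- cnt[ok] + 1
  }
  tpi <- z - nsum / cnt
  tri <- asum / cnt

  # McCune-Keon heat load (their eq. 2), folded aspect about SW (225 deg)
  phi <- matrix(lat * pi / 180, nrow(z), ncol(z))
  fold <- abs(180 - abs(aspect - 225)) * pi / 180
  hl <- exp(-1.467 + 1.582 * cos(phi) * cos(slope_rad) -
              1.500 * cos(fold) * sin(slope_rad) * sin(phi) -
              0.262 * sin(phi) * sin(slope_rad) +
              0.607 * sin(fold) * sin(slope_rad))

  mk <- function(v) grid_raster(v, elevation$xmin, elevation$xmax,
                                elevation$ymin, elevation$ymax)
  raster_stack(list(slope = mk(slope), aspect = mk(aspect),
                    heat_load = mk(hl), tpi = mk(tpi), tri = mk(tri)))
}

vif_values <- function(x) {
  r <- stats::cor(x)
  inv <- tryCatch(solve(r), error = function(e)
    solve(r + diag(1e-10, nrow(r))))
  stats::setNames(diag(inv), colnames(x))
}

#' Stepwise collinearity screening (pairwise Spearman + VIF)
#'
#' Iteratively finds the variable pair with the largest absolute Spearman
#' rank correlation; while it is at or above \code{corr_max}, the pair
#' member with the larger variance inflation factor is dropped (ties broken
#' by dropping the alphabetically later name). Once no pair exceeds
#' \code{corr_max}, variables with VIF at or above \code{vif_max} are
#' removed stepwise, largest first. Constant columns are dropped up front
#' with a warning.
#'
#' @param x data.frame/matrix of predictor values sampled at points, or a
#'   \code{raster_stack} together with \code{points} (data.frame lon/lat).
#' @param points optional data.frame with lon, lat used to sample a stack
#' @param corr_max pairwise absolute Spearman threshold (default 0.7)
#' @param vif_max VIF threshold (default 10)
#' @return character vector of retained layer names (input order)
#' @export
vifcor_select <- function(x, points = NULL, corr_max = 0.7, vif_max = 10) {
  if (inherits(x, "raster_stack") || (is.list(x) && !is.data.frame(x))) {
    if (is.null(points)) stop("points required when x is a raster stack")
    x <- stack_extract(x, points$lon, points$lat)
  }
  x <- as.data.frame(x)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  orig <- names(x)
  const <- vapply(x, function(v) stats::sd(v) == 0 || !is.finite(stats::sd(v)),
                  logical(1))
  if (any(const)) {
    warning("dropping constant layer(s): ", paste(names(x)[const], collapse = ", "))
    x <- x[!const]
  }

  drop_of_pair <- function(x, i, j) {
    nm <- names(x)
    v <- tryCatch(vif_values(x), error = function(e) NULL)
    if (is.null(v) || !all(is.finite(v[c(i, j)])) ||
        isTRUE(all.equal(v[[i]], v[[j]]))) {
      # undefined or tied VIF: drop the alphabetically later name
      return(if (nm[i] > nm[j]) i else j)
    }
    if (v[[i]] > v[[j]]) i else j
  }

  repeat {
    if (ncol(x) < 2) break
    s <- abs(stats::cor(x, method = "spearman"))
    diag(s) <- 0
    mx <- max(s)
    if (mx < corr_max) break
    ij <- which(s == mx, arr.ind = TRUE)[1, ]
    # deterministic pair orientation: i = earlier column
    i <- min(ij); j <- max(ij)
    x <- x[-drop_of_pair(x, i, j)]
  }
  repeat {
    if (ncol(x) < 2) break
    v <- vif_values(x)
    if (max(v) < vif_max) break
    worst <- which(v == max(v))
    worst <- worst[order(names(v)[worst], decreasing = TRUE)][1]
    x <- x[-worst]
  }
  orig[orig %in% names(x)]
}

#' Annual temperature-seasonality time series at a location
#'
#' One bio4 value (100 x population sd of the 12 monthly means) per year.
#' Input is either a years x 12 matrix of monthly mean temperatures already
#' extracted at the location, or a list (one element per year) of 12-layer
#' monthly rasters plus a lon/lat location resolved to the nearest grid
#' cell.
#'
#' @param tavg_by_year years x 12 matrix, or list of lists of 12 rasters
#' @param lon,lat location (required for raster input)
#' @param years optional names for the output
#' @return named numeric vector of bio4 values
#' @export
seasonality_series <- function(tavg_by_year, lon = NULL, lat = NULL,
                               years = NULL) {
  if (!is.matrix(tavg_by_year)) {
    if (is.null(lon) || is.null(lat)) stop("location required for raster input")
    tmpl <- tavg_by_year[[1]][[1]]
    cell <- rst_cell(tmpl, lon, lat)
    if (is.na(cell)) stop("location outside grid extent")
    tavg_by_year <- t(vapply(tavg_by_year, function(yr)
      vapply(yr, function(l) l$values[cell], numeric(1)), numeric(12)))
  }
  if (ncol(tavg_by_year) != 12) stop("need 12 monthly values per year")
  out <- apply(tavg_by_year, 1, function(v) 100 * sd_pop(v))
  if (!is.null(years)) names(out) <- years
  out
}
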