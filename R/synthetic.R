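#' Synthetic world generation
#'
#' The synthetic-data module generates every input the pipeline needs —
#' monthly climate, elevation, a latent "true" suitability surface, and
#' occurrence records with deliberate contamination — with known ground
#' truth, so all downstream stages are testable without any downloads.
#' Spatial autocorrelation comes from Gaussian-smoothed white noise; the
#' monthly temperature cycle is sinusoidal with an amplitude that grows
#' with latitude (strong spatial gradient in temperature seasonality), and
#' precipitation declines toward the equatorward edge (strong aridity
#' gradient). All randomness flows from one explicit seed per call.
#'
#' @name synthetic
NULL

default_extent <- c(xmin = -10, xmax = 30, ymin = 35, ymax = 70)

# separable Gaussian smoothing of a matrix; edge-renormalized
smooth_field <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  op <- function(n) {
    s <- matrix(0, n, n)
    for (d in seq(-half, half)) {
      idx <- seq_len(n) + d
      ok <- idx >= 1 & idx <= n
      s[cbind(which(ok), idx[ok])] <- s[cbind(which(ok), idx[ok])] + k[d + half + 1]
    }
    sweep(s, 1, rowSums(s), "/")
  }
  op(nrow(m)) %*% m %*% t(op(ncol(m)))
}

# smooth standardized noise field (mean ~0, sd ~1)
noise_field <- function(nr, nc, sigma) {
  f <- smooth_field(matrix(stats::rnorm(nr * nc), nr, nc), sigma)
  (f - mean(f)) / stats::sd(f)
}

check_grid_shape <- function(grid_shape) {
  if (length(grid_shape) != 2 || any(!is.finite(grid_shape)) ||
      any(grid_shape <= 0))
    stop("grid_shape must be two positive integers")
  if (any(grid_shape < 20))
    stop("grid_shape must be at least 20 x 20")
  as.integer(grid_shape)
}

#' Synthetic elevation field
#'
#' Nonnegative, spatially smooth, and (via the lapse rate applied by
#' \code{\link{gen_climate}} with the same seed) negatively correlated with
#' annual mean temperature.
#'
#' @param seed explicit integer seed
#' @param grid_shape c(nrow, ncol), at least 20 x 20
#' @param extent named vector xmin/xmax/ymin/ymax (decimal degrees)
#' @param base mean elevation (m)
#' @param amplitude relief amplitude (m); 0 gives a constant raster
#' @param sigma smoothing length (cells)
#' @return \code{grid_raster} of elevation in meters
#' @export
gen_elevation <- function(seed, grid_shape = c(100, 100),
                          extent = default_extent,
                          base = 500, amplitude = 450, sigma = 6) {
  grid_shape <- check_grid_shape(grid_shape)
  with_seed(seed, {
    f <- if (amplitude > 0) noise_field(grid_shape[1], grid_shape[2], sigma)
         else matrix(0, grid_shape[1], grid_shape[2])
    grid_raster(pmax(base + amplitude * f, 0),
                extent[["xmin"]], extent[["xmax"]],
                extent[["ymin"]], extent[["ymax"]])
  })
}

#' Parameters for a synthetic climate scenario
#'
#' @param name scenario label
#' @param delta_t additive temperature offset vs current (degrees C)
#' @param delta_seasonality multiplicative factor on the annual temperature
#'   cycle amplitude (1 = unchanged)
#' @param delta_prec multiplicative factor on precipitation at the
#'   equatorward edge (1 = unchanged); the applied factor is latitude-graded
#'   and exceeds 1 toward the poleward edge when \code{delta_prec < 1}
#' @return list of class \code{scenario_params}
#' @export
scenario_params <- function(name = "current", delta_t = 0,
                            delta_seasonality = 1, delta_prec = 1) {
  stopifnot(delta_seasonality > 0, delta_prec >= 0)
  structure(list(name = name, delta_t = delta_t,
                 delta_seasonality = delta_seasonality,
                 delta_prec = delta_prec),
            class = "scenario_params")
}

#' Synthetic monthly climate for one scenario
#'
#' Generates 12 monthly layers each of tmin/tavg/tmax (C) and precipitation
#' (mm) on a latitude-gradient temperature field with elevation lapse (the
#' elevation is the \code{\link{gen_elevation}} field for the same seed,
#' so the two are consistent). The annual cycle is sinusoidal (coldest in
#' January, warmest in July) with a spatially varying shape; its amplitude
#' increases with latitude and is multiplied by \code{delta_seasonality},
#' while \code{delta_t} shifts all temperatures and \code{delta_prec}
#' scales precipitation. Same seed and parameters give bit-identical
#' output.
#'
#' @inheritParams gen_elevation
#' @param params a \code{\link{scenario_params}} object
#' @return object of class \code{climate_scenario}: lists \code{tmin},
#'   \code{tmax}, \code{tavg}, \code{prec} of 12 \code{grid_raster} layers
#'   plus the scenario parameters and the shared grid template
#' @export
gen_climate <- function(seed, grid_shape = c(100, 100),
                        params = scenario_params(),
                        extent = default_extent) {
  grid_shape <- check_grid_shape(grid_shape)
  elev <- gen_elevation(seed, grid_shape, extent)
  tmpl <- elev
  lat <- matrix(rst_axes(tmpl)$lat, grid_shape[1], grid_shape[2])

  with_seed(seed + 1L, {
    nr <- grid_shape[1]; nc <- grid_shape[2]
    n_t <- noise_field(nr, nc, 6)
    n_a <- noise_field(nr, nc, 6)
    n_d <- noise_field(nr, nc, 6)
    n_p <- noise_field(nr, nc, 6)
    eta <- lapply(1:12, function(m) 0.12 * noise_field(nr, nc, 8))

    lat01 <- (lat - extent[["ymin"]]) / (extent[["ymax"]] - extent[["ymin"]])
    t_ann <- 24 - 22 * lat01 - 6.5 * elev$values / 1000 + 1.2 * n_t +
      params$delta_t
    # the seasonality increase is latitude-graded: full strength at the
    # equatorward edge, tapering to one sixth at the poleward edge (southern
    # Europe is projected to see much larger seasonality increases than the
    # north); still strictly > 1 everywhere when delta_seasonality > 1
    seas_grad <- 1 + (params$delta_seasonality - 1) * (1.2 - lat01) / 1.2
    amp <- pmax(6 + 3 * lat01 + 3 * n_a, 1) * seas_grad
    dtr <- pmax(8 + 1.5 * n_d, 2)
    # precipitation: wet poleward edge, arid equatorward edge, with strong
    # mesoscale structure (fragmented, realistic ranges); the change factor
    # is latitude-graded (delta_prec applies fully in the south and flips
    # to a modest increase in the north, the usual GCM consensus)
    prec_grad <- params$delta_prec + (1 - params$delta_prec) * 1.5 * lat01
    p_ann <- pmax(40 + 1800 * lat01^1.3 + 600 * n_p, 30) * prec_grad

    s <- -cos(2 * pi * ((1:12) - 0.5) / 12)  # -1 in Jan, +1 in Jul
    w <- -s                                  # winter-wet precipitation cycle
    tavg <- lapply(1:12, function(m) t_ann + amp * (s[m] + eta[[m]]))
    tmin <- lapply(1:12, function(m) tavg[[m]] - dtr / 2)
    tmax <- lapply(1:12, function(m) tavg[[m]] + dtr / 2)
    prec <- lapply(1:12, function(m) pmax(p_ann / 12 * (1 + 0.15 * w[m]), 0))

    as_layers <- function(l) lapply(l, function(v)
      grid_raster(v, extent[["xmin"]], extent[["xmax"]],
                  extent[["ymin"]], extent[["ymax"]]))
    structure(list(name = params$name,
                   tmin = as_layers(tmin), tmax = as_layers(tmax),
                   tavg = as_layers(tavg), prec = as_layers(prec),
                   params = params, template = tmpl, seed = seed),
              class = "climate_scenario")
  })
}

#' @export
print.climate_scenario <- function(x, ...) {
  cat(sprintf(
    "climate_scenario '%s' (%d x %d; delta_t=%g, delta_seasonality=%g, delta_prec=%g)\n",
    x$name, nrow(x$template$values), ncol(x$template$values),
    x$params$delta_t, x$params$delta_seasonality, x$params$delta_prec))
  invisible(x)
}

#' Latent true suitability from a scenario
#'
#' The generative truth is a logistic function of two predictors only —
#' temperature seasonality (bio4) and the Thornthwaite aridity index —
#' standardized against the reference (current) scenario. This encodes the
#' target pattern the pipeline must recover: seasonality is the dominant
#' driver, aridity second, everything else nuisance.
#'
#' @param reference a \code{climate_scenario} used to fix the
#'   standardization (training-domain means/sds)
#' @param beta0 intercept
#' @param beta_seasonality,beta_aridity coefficients on the standardized
#'   predictors (negative = high seasonality/aridity unsuitable)
#' @return object of class \code{truth_params}
#' @export
make_truth <- function(reference, beta0 = -14, beta_seasonality = -12,
                       beta_aridity = -9) {
  b <- bioclim(reference$tmin, reference$tmax, reference$tavg, reference$prec)
  seas <- as.vector(b$bio4$values)
  arid <- as.vector(thornthwaite_aridity(reference$tavg, reference$prec)$values)
  structure(list(beta0 = beta0, beta_seasonality = beta_seasonality,
                 beta_aridity = beta_aridity,
                 center = c(seas = mean(seas), arid = mean(arid)),
                 scale = c(seas = stats::sd(seas), arid = stats::sd(arid))),
            class = "truth_params")
}

#' Evaluate the latent truth on a scenario
#' @param truth a \code{truth_params} object
#' @param scenario a \code{climate_scenario}
#' @return \code{grid_raster} of suitability in (0,1)
#' @export
truth_suitability <- function(truth, scenario) {
  b <- bioclim(scenario$tmin, scenario$tmax, scenario$tavg, scenario$prec)
  seas <- as.vector(b$bio4$values)
  arid <- as.vector(thornthwaite_aridity(scenario$tavg, scenario$prec)$values)
  z1 <- (seas - truth$center[["seas"]]) / truth$scale[["seas"]]
  z2 <- (arid - truth$center[["arid"]]) / truth$scale[["arid"]]
  eta <- truth$beta0 + truth$beta_seasonality * z1 + truth$beta_aridity * z2
  rst_like(scenario$template, stats::plogis(eta))
}

#' Sample occurrence records from a true suitability surface
#'
#' Presences are drawn cell-wise with probability proportional to
#' suitability and jittered uniformly within the cell. Contaminated
#' records exercise every cleaning rule: \code{pre1970} records get years
#' before 1970, \code{high_uncertainty} records get coordinate uncertainty
#' above 9.25 km, and \code{duplicate} records are exact copies of clean
#' records (removed later by cell deduplication). The \code{flag} column
#' records the ground truth so cleaning tests know the expected survivor
#' count. Contamination counts are exact: \code{round(fraction * n_raw)}.
#'
#' @param true_suitability \code{grid_raster} of suitability
#' @param n_raw total number of records to emit (>= 50)
#' @param seed explicit integer seed
#' @param contamination named numeric: fractions \code{pre1970},
#'   \code{high_uncertainty}, \code{duplicate} (sum must be <= 1)
#' @return data.frame with lon, lat, year, coord_uncertainty_m, flag
#' @export
sample_occurrences <- function(true_suitability, n_raw = 1000, seed = 1,
                               contamination = c(pre1970 = 0.05,
                                                 high_uncertainty = 0.05,
                                                 duplicate = 0.05)) {
  if (n_raw < 50) stop("n_raw must be at least 50")
  frac <- c(pre1970 = 0, high_uncertainty = 0, duplicate = 0)
  frac[names(contamination)] <- contamination
  if (any(frac < 0) || sum(frac) > 1)
    stop("contamination fractions must be nonnegative and sum to <= 1")
  n_bad <- round(frac * n_raw)
  n_clean <- n_raw - sum(n_bad)

  r <- true_suitability
  res <- rst_res(r)
  prob <- as.vector(r$values)
  prob[is.na(prob)] <- 0
  ax <- rst_axes(r)
  nr <- nrow(r$values)

  with_seed(seed, {
    draw <- function(n) {
      cell <- sample.int(length(prob), n, replace = TRUE, prob = prob)
      col <- (cell - 1L) %/% nr + 1L
      row <- (cell - 1L) %% nr + 1L
      data.frame(
        lon = ax$lon[col] + stats::runif(n, -0.5, 0.5) * res[1],
        lat = ax$lat[row] + stats::runif(n, -0.5, 0.5) * res[2]
      )
    }
    clean <- draw(n_clean)
    clean$year <- sample(1990:2020, n_clean, replace = TRUE)
    unc <- stats::runif(n_clean, 100, 8000)
    unc[stats::runif(n_clean) < 0.2] <- NA # some records lack the field
    clean$coord_uncertainty_m <- unc
    clean$flag <- "clean"

    old <- draw(n_bad[["pre1970"]])
    if (nrow(old)) {
      old$year <- sample(1900:1969, nrow(old), replace = TRUE)
      old$coord_uncertainty_m <- stats::runif(nrow(old), 100, 8000)
      old$flag <- "pre1970"
    }
    vague <- draw(n_bad[["high_uncertainty"]])
    if (nrow(vague)) {
      vague$year <- sample(1990:2020, nrow(vague), replace = TRUE)
      vague$coord_uncertainty_m <- stats::runif(nrow(vague), 10000, 30000)
      vague$flag <- "high_uncertainty"
    }
    dup <- clean[sample.int(max(1, n_clean), n_bad[["duplicate"]],
                            replace = TRUE), , drop = FALSE]
    if (nrow(dup)) dup$flag <- "duplicate"

    out <- rbind(clean, if (nrow(old)) old, if (nrow(vague)) vague,
                 if (nrow(dup)) dup)
    out <- out[sample.int(nrow(out)), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Generate a complete synthetic world
#'
#' Convenience wrapper producing the current scenario, a set of future
#' scenarios, elevation, the generative truth and raw occurrences. The
#' default future scenarios pair a warming offset with a seasonality
#' increase and a precipitation decrease, constructed so the truth-suitable
#' area moves poleward.
#'
#' @inheritParams gen_climate
#' @param n_raw raw occurrence count
#' @param contamination passed to \code{\link{sample_occurrences}}
#' @param futures named list of \code{\link{scenario_params}}
#' @return list with elements current, futures, elevation, truth,
#'   truth_map, occurrences
#' @export
synth_world <- function(seed = 1, grid_shape = c(100, 100), n_raw = 1000,
                        contamination = c(pre1970 = 0.05,
                                          high_uncertainty = 0.05,
                                          duplicate = 0.05),
                        futures = default_futures(),
                        extent = default_extent) {
  current <- gen_climate(seed, grid_shape, scenario_params("current"),
                         extent = extent)
  fut <- lapply(futures, function(p) gen_climate(seed, grid_shape, p,
                                                 extent = extent))
  elevation <- gen_elevation(seed, grid_shape, extent)
  truth <- make_truth(current)
  truth_map <- truth_suitability(truth, current)
  occ <- sample_occurrences(truth_map, n_raw, seed + 2L, contamination)
  list(current = current, futures = fut, elevation = elevation,
       truth = truth, truth_map = truth_map, occurrences = occ)
}

#' Default future scenario set (GCM x SSP x time analogue)
#'
#' Two emissions levels at two time slices: mild (delta_t +1.5/+2,
#' seasonality x1.05/x1.08) and severe (delta_t +3/+4.5, seasonality
#' x1.10/x1.15, precipitation x0.9/x0.85).
#' @return named list of \code{\link{scenario_params}}
#' @export
default_futures <- function() {
  list(
    mild_2070   = scenario_params("mild_2070",   1.5, 1.05, 0.95),
    mild_2090   = scenario_params("mild_2090",   2.0, 1.08, 0.92),
    severe_2070 = scenario_params("severe_2070", 3.0, 1.10, 0.85),
    severe_2090 = scenario_params("severe_2090", 4.5, 1.15, 0.80)
  )
}

#' Write a scenario's layers and a manifest to disk
#'
#' One ESRI ASCII grid per layer plus a YAML manifest listing scenario
#' names and files.
#' @param scenario a \code{climate_scenario}
#' @param dir output directory (created if needed)
#' @return invisibly, the manifest list
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (var in c("tmin", "tmax", "tavg", "prec")) {
    for (m in 1:12) {
      f <- file.path(dir, sprintf("%s_%s_%02d.asc", scenario$name, var, m))
      write_ascii_grid(scenario[[var]][[m]], f)
      files <- c(files, basename(f))
    }
  }
  manifest <- list(scenario = scenario$name,
                   delta_t = scenario$params$delta_t,
                   delta_seasonality = scenario$params$delta_seasonality,
                   delta_prec = scenario$params$delta_prec,
                   files = files)
  yaml::write_yaml(manifest, file.path(dir, paste0(scenario$name, ".yaml")))
  invisible(manifest)
}
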