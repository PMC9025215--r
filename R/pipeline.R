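#' Build the full predictor stack for a scenario
#'
#' 19 bioclimatic layers, the Thornthwaite aridity index, elevation and
#' the 5 terrain variables — the synthetic-mode analogue of the full
#' predictor menu (soil layers have no synthetic counterpart; the
#' generated nuisance layers play their role in collinearity screening).
#'
#' @param scenario a \code{climate_scenario}
#' @param elevation \code{grid_raster} of elevation (m)
#' @return \code{raster_stack} of 26 named layers
#' @export
predictor_stack <- function(scenario, elevation) {
  b <- bioclim(scenario$tmin, scenario$tmax, scenario$tavg, scenario$prec)
  tai <- thornthwaite_aridity(scenario$tavg, scenario$prec)
  terr <- terrain_vars(elevation)
  raster_stack(c(b, list(aridity = tai, elevation = elevation), terr))
}

#' Default pipeline configuration
#'
#' A fully serializable description of one synthetic-mode run; a run is a
#' pure function of the configuration. Sizes default to a scaled-down but
#' complete analysis that runs in minutes on one CPU.
#'
#' @param ... overrides of any default entry
#' @return named list of class \code{run_config}
#' @export
default_config <- function(...) {
  cfg <- list(
    mode = "synthetic",
    seed = 1,
    grid_shape = c(80, 80),
    n_raw = 900,
    contamination = c(pre1970 = 0.05, high_uncertainty = 0.05,
                      duplicate = 0.05),
    alpha = 3,
    buffer_km = 650,
    thin_dist_km = NULL,      # default: one cell diagonal
    thin_reps = 5,
    n_bins_per_var = 8,
    background_n = 3000,
    algorithms = c("maxent", "rf"),
    maxent = list(feature_classes = c("L", "Q", "H"), reg_mult = 1,
                  nknots = 6, tune = FALSE),
    rf = list(num_trees = 300, mtry = 4, min_node = 2),
    brt = list(n_trees = 200, learning_rate = 0.05, depth = 3),
    bagged = list(n_boot = 20),
    tss_min = 0.6,
    ensemble_methods = c("median", "mean", "weighted_mean",
                         "committee_average", "pca"),
    threshold_rule = "maxSSS",
    uncertainty_quantile = 0.90,
    vif_corr_max = 0.7,
    vif_max = 10,
    branches = c("geo", "env"),
    out_dir = NULL
  )
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

fit_algorithm <- function(alg, px, bx, folds, cfg) {
  x <- rbind(px, bx)
  y <- c(rep(1, nrow(px)), rep(0, nrow(bx)))
  fold_id <- c(folds$presence, folds$background)
  if (alg == "maxent") {
    settings <- cfg$maxent
    if (isTRUE(settings$tune)) {
      tuned <- tune_maxent(px, bx, folds, nknots = settings$nknots)
      settings$feature_classes <- tuned$best$feature_classes
      settings$reg_mult <- tuned$best$reg_mult
    }
    fit_fun <- function(x, y)
      fit_maxent(x[y == 1, , drop = FALSE], x[y == 0, , drop = FALSE],
                 feature_classes = settings$feature_classes,
                 reg_mult = settings$reg_mult, nknots = settings$nknots)
    cv <- cv_evaluate(fit_fun, x, y, fold_id)
    model <- fit_fun(x, y)
  } else if (alg == "rf") {
    fit_fun <- function(x, y) fit_rf(x, y, num_trees = cfg$rf$num_trees,
                                     mtry = cfg$rf$mtry,
                                     min_node = cfg$rf$min_node)
    cv <- with_seed(cfg$seed, cv_evaluate(fit_fun, x, y, fold_id))
    model <- with_seed(cfg$seed + 11L, fit_fun(x, y))
  } else if (alg == "brt") {
    fit_fun <- function(x, y) fit_brt(x, y, n_trees = cfg$brt$n_trees,
                                      learning_rate = cfg$brt$learning_rate,
                                      depth = cfg$brt$depth)
    cv <- with_seed(cfg$seed, cv_evaluate(fit_fun, x, y, fold_id))
    model <- with_seed(cfg$seed + 12L, fit_fun(x, y))
  } else if (alg == "bagged") {
    fit_fun <- function(x, y) fit_bagged(x, y, n_boot = cfg$bagged$n_boot)
    cv <- with_seed(cfg$seed, cv_evaluate(fit_fun, x, y, fold_id))
    model <- with_seed(cfg$seed + 13L, fit_fun(x, y))
  } else stop("unknown algorithm: ", alg)
  imp <- permutation_importance(model, x, y, nperm = 10, seed = cfg$seed)
  list(algorithm = alg, model = model, eval = cv$pooled, oof = cv$scores,
       importance = imp)
}

run_branch <- function(branch, world, cfg, out_dir) {
  grid <- world$current$template
  occ <- world$occurrences

  counts <- c(raw = nrow(occ))
  occ <- with_stage("filter", filter_records(occ))
  counts["filtered"] <- nrow(occ)
  occ <- with_stage("dedupe", dedupe_by_cell(occ, grid))
  counts["deduped"] <- nrow(occ)

  res <- rst_res(grid)
  thin_km <- cfg$thin_dist_km
  if (is.null(thin_km)) {
    lat0 <- mean(rst_axes(grid)$lat)
    thin_km <- sqrt((res[1] * 111.32 * cos(lat0 * pi / 180))^2 +
                      (res[2] * 110.54)^2)
  }
  occ <- with_stage("spatial_thin",
                    spatial_thin(occ, thin_km, cfg$thin_reps, cfg$seed))
  counts["geothin"] <- nrow(occ)

  sa <- with_stage("eoo", alpha_hull_eoo(occ, cfg$alpha, cfg$buffer_km))
  cur_stack <- with_stage("predictors",
                          predictor_stack(world$current, world$elevation))
  bg <- with_stage("background",
                   make_background(sa, grid, cfg$background_n, cfg$seed))
  vars <- with_stage("vifcor",
                     vifcor_select(cur_stack, bg, cfg$vif_corr_max,
                                   cfg$vif_max))

  if (branch == "env") {
    envv <- stack_extract(cur_stack[vars], occ$lon, occ$lat)
    occ <- with_stage("env_thin",
                      env_thin(occ, envv, cfg$n_bins_per_var, cfg$seed))
  }
  counts["final"] <- nrow(occ)

  px <- as.matrix(stack_extract(cur_stack[vars], occ$lon, occ$lat))
  bx <- as.matrix(stack_extract(cur_stack[vars], bg$lon, bg$lat))
  ok_p <- stats::complete.cases(px); ok_b <- stats::complete.cases(bx)
  px <- px[ok_p, , drop = FALSE]; bx <- bx[ok_b, , drop = FALSE]
  occ <- occ[ok_p, , drop = FALSE]

  folds <- with_stage("blocks",
                      spatial_blocks(occ, bg[ok_b, , drop = FALSE]))

  members <- with_stage("fit", lapply(cfg$algorithms, fit_algorithm,
                                      px = px, bx = bx, folds = folds,
                                      cfg = cfg))
  names(members) <- cfg$algorithms

  gated <- with_stage("gate", {
    g <- gate_members(members, cfg$tss_min)
    if (!length(g))
      stop("no member model passed the TSS >= ", cfg$tss_min, " gate (TSS: ",
           paste(sprintf("%s=%.3f", names(members),
                         vapply(members, function(m) m$eval$tss,
                                numeric(1))), collapse = ", "), ")")
    g
  })

  y <- c(rep(1, nrow(px)), rep(0, nrow(bx)))
  tss_w <- vapply(gated, function(m) m$eval$tss, numeric(1))
  thr_members <- vapply(gated, function(m) m$eval$thresholds$maxSSS,
                        numeric(1))
  oof <- lapply(gated, function(m) m$oof)

  cands <- with_stage("ensemble", {
    out <- list()
    for (meth in cfg$ensemble_methods) {
      sc <- combine_members(oof, meth, weights = tss_w,
                            thresholds = thr_members)
      out[[meth]] <- list(method = meth, scores = sc,
                          eval = evaluate_scores(y, sc))
    }
    out
  })
  best <- choose_best_ensemble(cands)

  # full-grid member and ensemble maps for the current scenario
  cells <- stack_values(cur_stack[vars])
  member_maps <- lapply(gated, function(m)
    rst_like(grid, predict_suitability(m$model, cells)))
  point_scores <- lapply(gated, function(m)
    c(predict_suitability(m$model, px), predict_suitability(m$model, bx)))
  member_thr_full <- vapply(seq_along(gated), function(i)
    threshold_maxSSS(y, point_scores[[i]]), numeric(1))
  ens_current <- combine_members(member_maps, best, weights = tss_w,
                                 thresholds = member_thr_full)
  ens_scores <- combine_members(point_scores, best, weights = tss_w,
                                thresholds = member_thr_full)
  thr <- if (cfg$threshold_rule == "maxSorensen")
    threshold_maxSorensen(y, ens_scores) else threshold_maxSSS(y, ens_scores)

  if ("bagged" %in% names(gated)) {
    unc <- rst_like(grid, predict_uncertainty(gated$bagged$model, cells))
    ens_current <- apply_mask(ens_current,
                              uncertainty_mask(unc, cfg$uncertainty_quantile))
  }
  bin_current <- binarize(ens_current, thr)
  tr_range <- training_range(cur_stack[vars])

  reports <- list(); centroids <- list(); alts <- list()
  centroids$current <- median_centroid(bin_current)
  alts$current <- altitude_samples(bin_current, world$elevation)
  transition_maps <- list()
  for (nm in names(world$futures)) {
    fut_stack <- predictor_stack(world$futures[[nm]], world$elevation)
    cmask <- clamping_mask(fut_stack[vars], tr_range)
    fcells <- stack_values(fut_stack[vars])
    fmaps <- lapply(gated, function(m)
      rst_like(grid, predict_suitability(m$model, fcells)))
    ens_fut <- combine_members(fmaps, best, weights = tss_w,
                               thresholds = member_thr_full)
    ens_fut <- apply_mask(ens_fut, cmask)
    if ("bagged" %in% names(gated)) {
      uncf <- rst_like(grid, predict_uncertainty(gated$bagged$model, fcells))
      ens_fut <- apply_mask(ens_fut,
                            uncertainty_mask(uncf, cfg$uncertainty_quantile))
    }
    bin_fut <- binarize(ens_fut, thr)
    rc <- range_change(bin_current, bin_fut)
    reports[[nm]] <- data.frame(
      scenario = nm, group = nm,
      loss_pct = rc$loss_pct, gain_pct = rc$gain_pct,
      overall_change_pct = rc$overall_change_pct,
      occ_lost_pct = occurrences_lost(occ, bin_fut, bin_current),
      t(rc$counts))
    centroids[[nm]] <- tryCatch(median_centroid(bin_fut),
                                error = function(e) c(lon = NA, lat = NA))
    alts[[nm]] <- tryCatch(altitude_samples(bin_fut, world$elevation),
                           error = function(e) numeric(0))
    transition_maps[[nm]] <- transition_map(bin_current, bin_fut)
  }
  reports <- do.call(rbind, reports)
  alts <- alts[vapply(alts, length, integer(1)) > 0]
  tests <- if (length(alts) >= 2) shift_tests(alts) else NULL

  # artifacts
  bdir <- file.path(out_dir, branch)
  dir.create(bdir, recursive = TRUE, showWarnings = FALSE)
  write_occurrences(occ, file.path(bdir, "occurrences_final.csv"))
  yaml::write_yaml(list(retained = vars), file.path(bdir, "predictors.yaml"))
  sa_write_geojson(sa, file.path(bdir, "study_area.geojson"))
  write_range_reports(reports, file.path(bdir, "range_change.csv"))
  cm <- centroid_matrix(centroids)
  utils::write.csv(cm, file.path(bdir, "centroid_distance_km.csv"))
  write_ascii_grid(ens_current, file.path(bdir, "ensemble_current.asc"))
  for (nm in names(transition_maps))
    write_ascii_grid(transition_maps[[nm]],
                     file.path(bdir, sprintf("transition_%s.asc", nm)))

  list(branch = branch, counts = counts, retained_vars = vars,
       members = lapply(members, function(m)
         list(algorithm = m$algorithm, tss = m$eval$tss,
              auc = m$eval$auc, importance = m$importance)),
       best_ensemble = best,
       ensemble_eval = cands[[best]]$eval,
       threshold = thr,
       reports = reports, centroids = centroids,
       centroid_km = cm[1, , drop = TRUE],
       mean_altitude = vapply(alts, mean, numeric(1)),
       shift_tests = tests,
       bin_current = bin_current)
}

#' Run the full pipeline from a configuration
#'
#' Synthetic-mode orchestration of the complete workflow: generate inputs,
#' clean and thin occurrences (geographic branch, plus environmental
#' thinning branch), derive and screen predictors, sample background,
#' spatial-block fit and evaluate each algorithm, gate, ensemble, project
#' every future scenario with clamping (and uncertainty) masks, and
#' produce range-change, centroid and altitude statistics. Writes all
#' artifacts plus a JSON manifest under \code{config$out_dir}.
#'
#' @param config a \code{\link{default_config}} list
#' @return invisibly, the manifest list (with per-branch results attached
#'   as the \code{results} attribute)
#' @export
run_pipeline <- function(config = default_config()) {
  if (config$tss_min > 1)
    stop("pipeline stage 'gate' failed: tss_min = ", config$tss_min,
         " can never be met (TSS is at most 1)")
  out_dir <- config$out_dir
  if (is.null(out_dir)) out_dir <- tempfile("rangeshift_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  world <- with_stage("synthetic_data",
    synth_world(config$seed, config$grid_shape, config$n_raw,
                config$contamination))

  results <- lapply(intersect(c("geo", "env"), config$branches),
                    function(b) run_branch(b, world, config, out_dir))
  names(results) <- vapply(results, `[[`, "", "branch")

  cfg_hashable <- unclass(config)
  cfg_hashable$out_dir <- NULL # the hash identifies the analysis, not paths
  cfg_json <- jsonlite::toJSON(cfg_hashable, auto_unbox = TRUE,
                               digits = NA, null = "null")
  tf <- tempfile(); writeLines(cfg_json, tf)
  manifest <- list(
    package_version = as.character(utils::packageVersion("rangeshift")),
    r_version = R.version.string,
    config = unclass(config),
    config_md5 = unname(tools::md5sum(tf)),
    timestamp = format(Sys.time(), tz = "UTC"),
    branches = lapply(results, function(r) list(
      counts = as.list(r$counts),
      retained_vars = r$retained_vars,
      member_tss = lapply(r$members, `[[`, "tss"),
      best_ensemble = r$best_ensemble,
      ensemble_tss = r$ensemble_eval$tss,
      threshold = r$threshold,
      artifacts = list.files(file.path(out_dir, r$branch))))
  )
  unlink(tf)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"),
             file.path(out_dir, "manifest.json"))
  attr(manifest, "results") <- results
  attr(manifest, "out_dir") <- out_dir
  invisible(manifest)
}
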