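#' Ground-truth recovery experiment on one synthetic world
#'
#' The end-to-end calibration experiment behind the package's synthetic
#' validation: generate a world, clean the occurrences, screen predictors,
#' fit the MaxEnt-style and random-forest members under spatial-block
#' cross-validation, ensemble them by TSS-weighted mean, and measure
#' (i) member and ensemble cross-validated TSS against the 0.6 gate,
#' (ii) whether the top permutation-importance variable is the retained
#' temperature-seasonality representative (bio4 itself, or — when the
#' collinearity screen eliminates bio4 in favor of a near-duplicate — the
#' retained variable most rank-correlated with bio4), (iii) the Spearman
#' correlation between the ensemble map and the generative truth, and
#' (iv) the latitudinal direction of the median-centroid shift under the
#' severe warming scenario.
#'
#' @param seed explicit integer seed (one world per seed)
#' @param grid_shape synthetic grid (default 100 x 100)
#' @param n_raw raw occurrences (default 900, about 800 clean)
#' @param background_n background points (default 3000)
#' @param buffer_km study-area buffer (default 650)
#' @param alpha alpha-hull parameter (default 3)
#' @param nperm permutations for the importance ranking (default 5;
#'   kept small because the ranking, not the variance, is assessed)
#' @return named list: tss_maxent, tss_rf, tss_ensemble, rho_truth,
#'   top_var, seasonality_rep, top_is_seasonality, dlat_severe
#' @export
recovery_run <- function(seed, grid_shape = c(100, 100), n_raw = 900,
                         background_n = 3000, buffer_km = 650, alpha = 3,
                         nperm = 5) {
  w <- synth_world(seed, grid_shape, n_raw)
  grd <- w$current$template
  occ <- dedupe_by_cell(filter_records(w$occurrences), grd)
  sa <- alpha_hull_eoo(occ, alpha = alpha, buffer_km = buffer_km)
  stack <- predictor_stack(w$current, w$elevation)
  bg <- make_background(sa, grd, background_n, seed)
  vars <- vifcor_select(stack, bg)
  px <- as.matrix(stack_extract(stack[vars], occ$lon, occ$lat))
  bx <- as.matrix(stack_extract(stack[vars], bg$lon, bg$lat))
  ok <- stats::complete.cases(px)
  px <- px[ok, , drop = FALSE]; occ <- occ[ok, , drop = FALSE]
  folds <- spatial_blocks(occ, bg)
  y <- c(rep(1, nrow(px)), rep(0, nrow(bx)))
  x <- rbind(px, bx)
  fid <- c(folds$presence, folds$background)

  fit_mx <- function(x, y)
    fit_maxent(x[y == 1, , drop = FALSE], x[y == 0, , drop = FALSE],
               feature_classes = c("L", "Q", "H"), reg_mult = 1, nknots = 6)
  cv_mx <- cv_evaluate(fit_mx, x, y, fid)
  m_mx <- fit_mx(x, y)
  fit_rf_ <- function(x, y) fit_rf(x, y, num_trees = 300, mtry = 4,
                                   min_node = 2)
  cv_rf <- with_seed(seed, cv_evaluate(fit_rf_, x, y, fid))
  m_rf <- with_seed(seed + 7L, fit_rf_(x, y))

  tss <- c(maxent = cv_mx$pooled$tss, rf = cv_rf$pooled$tss)
  wts <- pmax(tss, 0.01)
  ens_oof <- combine_members(list(cv_mx$scores, cv_rf$scores),
                             "weighted_mean", weights = wts)
  ens_tss <- evaluate_scores(y, ens_oof)$tss

  imp <- (permutation_importance(m_mx, x, y, nperm = nperm, seed = seed) +
            permutation_importance(m_rf, x, y, nperm = nperm, seed = seed)) / 2
  top <- names(imp)[which.max(imp)]
  b4 <- stack_extract(stack["bio4"], bg$lon, bg$lat)$bio4
  rep4 <- if ("bio4" %in% vars) "bio4" else
    vars[which.max(abs(vapply(as.data.frame(bx), stats::cor, numeric(1),
                              y = b4, method = "spearman")))]

  cells <- stack_values(stack[vars])
  ens_map <- (wts[1] * predict_suitability(m_mx, cells) +
                wts[2] * predict_suitability(m_rf, cells)) / sum(wts)
  rho <- stats::cor(ens_map, as.vector(w$truth_map$values),
                    method = "spearman")
  pt_scores <- (wts[1] * c(predict_suitability(m_mx, px),
                           predict_suitability(m_mx, bx)) +
                  wts[2] * c(predict_suitability(m_rf, px),
                             predict_suitability(m_rf, bx))) / sum(wts)
  thr <- threshold_maxSSS(y, pt_scores)
  cur_bin <- rst_like(grd, as.numeric(ens_map >= thr))
  fcells <- stack_values(predictor_stack(w$futures$severe_2090,
                                         w$elevation)[vars])
  fmap <- (wts[1] * predict_suitability(m_mx, fcells) +
             wts[2] * predict_suitability(m_rf, fcells)) / sum(wts)
  fut_bin <- rst_like(grd, as.numeric(fmap >= thr))
  dlat <- median_centroid(fut_bin)[["lat"]] - median_centroid(cur_bin)[["lat"]]

  list(tss_maxent = unname(tss[1]), tss_rf = unname(tss[2]),
       tss_ensemble = ens_tss, rho_truth = rho, top_var = top,
       seasonality_rep = rep4,
       top_is_seasonality = (top == rep4 || top == "bio4"),
       dlat_severe = dlat)
}
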