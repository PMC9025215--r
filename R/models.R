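#' Sample background (pseudo-absence) points within the study area
#'
#' Uniform over the grid cells that carry data and whose centers fall in
#' the buffered study area; points are jittered uniformly within their
#' cell. Deterministic given the seed.
#'
#' @param study_area a \code{study_area} (from \code{\link{alpha_hull_eoo}})
#' @param grid \code{grid_raster} carrying the analysis grid (NA = no data)
#' @param n number of points (default 30000)
#' @param seed explicit integer seed
#' @return data.frame with lon, lat
#' @export
make_background <- function(study_area, grid, n = 30000, seed = 1) {
  xy <- rst_coords(grid)
  ok <- !is.na(as.vector(grid$values)) & sa_contains(study_area, xy$lon, xy$lat)
  cells <- which(ok)
  if (!length(cells)) stop("degenerate study area: no grid cells inside")
  res <- rst_res(grid)
  with_seed(seed, {
    pick <- cells[sample.int(length(cells), n, replace = TRUE)]
    data.frame(
      lon = xy$lon[pick] + stats::runif(n, -0.5, 0.5) * res[1],
      lat = xy$lat[pick] + stats::runif(n, -0.5, 0.5) * res[2]
    )
  })
}

#' Four spatial blocks by presence coordinate medians
#'
#' The 2x2 checkerboard-free blocking rule: split at the median presence
#' longitude, then within each half at that half's median presence
#' latitude; background points are assigned by the same boundaries.
#' Blocks: 1 = SW, 2 = NW, 3 = SE, 4 = NE.
#'
#' @param presences,background data.frames with lon, lat
#' @return list with integer vectors \code{presence} and \code{background}
#'   of block ids in 1..4
#' @export
spatial_blocks <- function(presences, background) {
  if (nrow(unique(presences[c("lon", "lat")])) < 4)
    stop("need at least 4 non-collocated presences for spatial blocks")
  med_lon <- stats::median(presences$lon)
  west_p <- presences$lon <= med_lon
  med_lat_w <- stats::median(presences$lat[west_p])
  med_lat_e <- stats::median(presences$lat[!west_p])
  assign_block <- function(lon, lat) {
    west <- lon <= med_lon
    ifelse(west,
           ifelse(lat <= med_lat_w, 1L, 2L),
           ifelse(lat <= med_lat_e, 3L, 4L))
  }
  out <- list(presence = assign_block(presences$lon, presences$lat),
              background = assign_block(background$lon, background$lat))
  if (length(unique(out$presence)) < 4)
    warning("not all 4 blocks contain presences")
  out
}

# ---- MaxEnt-style learner ---------------------------------------------------

# per-variable min-max scaling meta from reference data
feature_meta <- function(ref, feature_classes, nknots) {
  vars <- colnames(ref)
  lapply(stats::setNames(vars, vars), function(v) {
    x <- ref[, v]
    rng <- range(x, na.rm = TRUE)
    if (diff(rng) == 0) rng[2] <- rng[1] + 1
    knots <- if ("H" %in% feature_classes) {
      q <- stats::quantile(x, probs = seq(0, 1, length.out = nknots + 2),
                           names = FALSE)
      unique(q[-c(1, nknots + 2)])
    } else numeric(0)
    list(min = rng[1], max = rng[2], knots = knots)
  })
}

# design matrix for the configured feature classes; returns matrix with a
# "penalty_class" attribute (L/Q/H per column)
build_features <- function(x, meta, feature_classes) {
  x <- as.matrix(x)
  cols <- list(); classes <- character(0)
  for (v in names(meta)) {
    m <- meta[[v]]
    z <- (x[, v] - m$min) / (m$max - m$min)
    if ("L" %in% feature_classes) {
      cols[[paste0("L_", v)]] <- z; classes <- c(classes, "L")
    }
    if ("Q" %in% feature_classes) {
      cols[[paste0("Q_", v)]] <- z^2; classes <- c(classes, "Q")
    }
    if ("H" %in% feature_classes && length(m$knots)) {
      for (ki in seq_along(m$knots)) {
        zk <- (m$knots[ki] - m$min) / (m$max - m$min)
        if (zk < 1) {
          cols[[sprintf("Hu_%s_%02d", v, ki)]] <- pmax(0, (z - zk) / (1 - zk))
          classes <- c(classes, "H")
        }
        if (zk > 0) {
          cols[[sprintf("Hd_%s_%02d", v, ki)]] <- pmax(0, (zk - z) / zk)
          classes <- c(classes, "H")
        }
      }
    }
  }
  out <- do.call(cbind, cols)
  attr(out, "penalty_class") <- classes
  out
}

#' MaxEnt-style penalized presence-background model
#'
#' The maxnet-equivalent formulation: an infinitely-weighted logistic
#' regression (presences weight 1, background \code{bg_weight}) on
#' linear/quadratic/hinge features of the min-max scaled predictors,
#' fitted with an L1 penalty by \pkg{glmnet}. Per-feature penalties scale
#' with the feature's standard deviation and class-specific base
#' regularization, all multiplied by \code{reg_mult}. Predictions use the
#' complementary log-log transform of the exponential-model linear
#' predictor normalized over the background (the "cloglog" output).
#'
#' @param presences_x,background_x predictor matrices (same columns)
#' @param feature_classes subset of c("L","Q","H"), nonempty
#' @param reg_mult regularization multiplier (> 0, default 1)
#' @param nknots hinge knots per variable (default 8)
#' @param bg_weight background observation weight (default 100)
#' @return object of class \code{sdm_maxent}
#' @export
fit_maxent <- function(presences_x, background_x,
                       feature_classes = c("L", "Q", "H"), reg_mult = 1,
                       nknots = 8, bg_weight = 100) {
  stopifnot(reg_mult > 0)
  feature_classes <- match.arg(feature_classes, c("L", "Q", "H"),
                               several.ok = TRUE)
  presences_x <- as.matrix(presences_x)
  background_x <- as.matrix(background_x)
  if (nrow(presences_x) < 2) stop("need at least 2 presences")

  meta <- feature_meta(rbind(presences_x, background_x), feature_classes,
                       nknots)
  xall <- rbind(presences_x, background_x)
  mm <- build_features(xall, meta, feature_classes)
  y <- c(rep(1, nrow(presences_x)), rep(0, nrow(background_x)))
  w <- ifelse(y == 1, 1, bg_weight)

  cls <- attr(mm, "penalty_class")
  np <- sum(y == 1)
  base <- c(L = 0.05, Q = 0.05, H = 0.5 / sqrt(np))[cls]
  sds <- apply(mm, 2, stats::sd)
  reg <- base * pmax(sds, 1e-6) * reg_mult
  lambda_final <- mean(reg) * sum(y) / sum(w)
  lambdas <- lambda_final * 10^seq(3, 0, length.out = 100)

  # glmnet requires >= 2 columns; pad single-feature designs with a zero
  # column (coefficient is always 0, dropped below)
  padded <- ncol(mm) == 1
  mm_fit <- if (padded) cbind(mm, `..pad` = 0) else mm
  pf <- reg / mean(reg)
  if (padded) pf <- c(pf, 1)
  fit <- glmnet::glmnet(mm_fit, y, family = "binomial", weights = w,
                        standardize = FALSE, lambda = lambdas,
                        penalty.factor = pf)
  k <- length(fit$lambda)
  beta <- as.numeric(fit$beta[, k])
  names(beta) <- rownames(fit$beta)
  if (padded) beta <- beta[colnames(mm), drop = FALSE]

  eta_bg <- as.numeric(build_features(background_x, meta, feature_classes)
                       %*% beta)
  # normalize the exponential model to sum to 1 over the background, then
  # take the entropy of that distribution (the cloglog offset)
  alpha <- -log(sum(exp(eta_bg - max(eta_bg)))) - max(eta_bg)
  pr <- exp(eta_bg + alpha)
  entropy <- -sum(ifelse(pr > 0, pr * log(pr), 0))

  structure(list(algorithm = "MaxEnt", beta = beta, alpha = alpha,
                 entropy = entropy, meta = meta,
                 feature_classes = feature_classes,
                 reg_mult = reg_mult, lambda = lambda_final,
                 penalty = reg, bg_weight = bg_weight,
                 vars = colnames(presences_x)),
            class = c("sdm_maxent", "sdm_model"))
}

#' Linear predictor of a MaxEnt-style model (feature scale)
#' @param model an \code{sdm_maxent} model
#' @param x predictor matrix
#' @return numeric linear predictor
#' @export
maxent_link <- function(model, x) {
  x <- align_columns(model, x)
  mm <- build_features(x, model$meta, model$feature_classes)
  as.numeric(mm %*% model$beta)
}

#' @export
predict_suitability.sdm_maxent <- function(model, x) {
  eta <- maxent_link(model, x)
  p <- 1 - exp(-exp(eta + model$alpha + model$entropy))
  pmin(1, pmax(0, p))
}

#' Tune MaxEnt feature classes and regularization by omission rate
#'
#' Exhaustive grid over feature-class combinations and regularization
#' multipliers. Each candidate is scored by the mean cross-validated
#' omission rate of test presences at the training maxSSS threshold; ties
#' are broken by higher mean test TSS, then by smaller multiplier, then by
#' grid order. Returns the winner and the full leaderboard.
#'
#' @param presences_x,background_x predictor matrices
#' @param folds a \code{\link{spatial_blocks}} result
#' @param feature_grid list of feature-class combinations (default all 7
#'   nonempty subsets of L, Q, H)
#' @param reg_grid regularization multipliers (default seq(1, 10, 0.1),
#'   91 values; 7 x 91 = 637 candidates)
#' @param ... passed to \code{\link{fit_maxent}}
#' @return list with \code{best} (feature_classes, reg_mult) and
#'   \code{leaderboard} data.frame
#' @export
tune_maxent <- function(presences_x, background_x, folds,
                        feature_grid = list("L", "Q", "H", c("L", "Q"),
                                            c("L", "H"), c("Q", "H"),
                                            c("L", "Q", "H")),
                        reg_grid = seq(1, 10, by = 0.1), ...) {
  presences_x <- as.matrix(presences_x)
  background_x <- as.matrix(background_x)
  blocks <- sort(unique(folds$presence))
  grid <- expand.grid(fc = seq_along(feature_grid), rm = reg_grid)
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    fc <- feature_grid[[grid$fc[g]]]
    rmult <- grid$rm[g]
    om <- tss <- numeric(0)
    for (b in blocks) {
      ptr <- folds$presence != b; btr <- folds$background != b
      if (sum(!ptr) == 0 || sum(ptr) < 2) next
      m <- tryCatch(
        fit_maxent(presences_x[ptr, , drop = FALSE],
                   background_x[btr, , drop = FALSE],
                   feature_classes = fc, reg_mult = rmult, ...),
        error = function(e) NULL)
      if (is.null(m)) next
      tr_scores <- c(predict_suitability(m, presences_x[ptr, , drop = FALSE]),
                     predict_suitability(m, background_x[btr, , drop = FALSE]))
      tr_obs <- c(rep(1, sum(ptr)), rep(0, sum(btr)))
      thr <- threshold_maxSSS(tr_obs, tr_scores)
      te_p <- predict_suitability(m, presences_x[!ptr, , drop = FALSE])
      te_b <- predict_suitability(m, background_x[!btr, , drop = FALSE])
      om <- c(om, omission_rate(te_p, thr))
      cm <- confusion_metrics(c(rep(1, length(te_p)), rep(0, length(te_b))),
                              as.numeric(c(te_p, te_b) >= thr))
      tss <- c(tss, cm$tss)
    }
    rows[[g]] <- data.frame(
      feature_classes = paste(fc, collapse = ""), reg_mult = rmult,
      mean_omission = if (length(om)) mean(om) else NA_real_,
      mean_tss = if (length(tss)) mean(tss) else NA_real_)
  }
  lb <- do.call(rbind, rows)
  ord <- order(lb$mean_omission, -lb$mean_tss, lb$reg_mult,
               seq_len(nrow(lb)))
  best_row <- ord[1]
  list(best = list(feature_classes = feature_grid[[grid$fc[best_row]]],
                   reg_mult = grid$rm[best_row]),
       leaderboard = lb)
}

#' Permutation importance of predictors
#'
#' For each variable, the mean drop in AUC (over background-vs-presence
#' scoring) when that variable's values are permuted, averaged over
#' \code{nperm} shuffles and rescaled to sum to 100. Deterministic given
#' \code{seed}.
#'
#' @param model fitted model with a \code{predict_suitability} method
#' @param x predictor matrix
#' @param y 0/1 response
#' @param nperm permutations per variable (default 100; larger for final
#'   reporting)
#' @param seed explicit integer seed
#' @return named numeric vector of percentages summing to 100
#' @export
permutation_importance <- function(model, x, y, nperm = 100, seed = 1) {
  x <- align_columns(model, x)
  base_auc <- rank_metrics(y, predict_suitability(model, x))$auc
  with_seed(seed, {
    drops <- vapply(colnames(x), function(v) {
      d <- numeric(nperm)
      for (k in seq_len(nperm)) {
        xp <- x
        perm <- sample.int(nrow(x))
        xp[, v] <- xp[perm, v]
        d[k] <- base_auc - rank_metrics(y, predict_suitability(model, xp))$auc
      }
      mean(d)
    }, numeric(1))
    drops <- pmax(drops, 0)
    if (sum(drops) <= 0) {
      rep(100 / length(drops), length(drops))
    } else {
      100 * drops / sum(drops)
    }
  })
}

#' Fit a tuned tree-based model with variable reduction
#'
#' The sequential variable-reduction loop: fit, compute permutation
#' importance, and while the weakest variable's importance is below
#' \code{importance_min} percent, drop it provided the cross-validated
#' test TSS does not degrade (beyond \code{tss_tol}); then search the
#' hyperparameter grid for the best mean test TSS. If every variable ends
#' up below the cutoff the single best variable is kept with a warning.
#'
#' @param algorithm "RF" or "BRT"
#' @param presences_x,background_x predictor matrices
#' @param folds a \code{\link{spatial_blocks}} result
#' @param nperm permutations for importance during reduction (default 100)
#' @param importance_min percent importance below which a variable is a
#'   removal candidate (default 5)
#' @param tss_tol allowed CV TSS decrease when dropping (default 0.02)
#' @param param_grid data.frame of hyperparameter candidates (defaults per
#'   algorithm)
#' @param seed explicit integer seed
#' @return object of class \code{sdm_tuned}: the final model plus
#'   \code{cv} report, \code{importance} and the tuning table
#' @export
fit_tree_model <- function(algorithm = c("RF", "BRT"), presences_x,
                           background_x, folds, nperm = 100,
                           importance_min = 5, tss_tol = 0.02,
                           param_grid = NULL, seed = 1) {
  algorithm <- match.arg(algorithm)
  presences_x <- as.matrix(presences_x)
  background_x <- as.matrix(background_x)
  if (ncol(presences_x) < 1) stop("need at least one predictor")
  x <- rbind(presences_x, background_x)
  y <- c(rep(1, nrow(presences_x)), rep(0, nrow(background_x)))
  fold_id <- c(folds$presence, folds$background)

  fitter <- function(params) {
    if (algorithm == "RF") {
      function(x, y) fit_rf(x, y, num_trees = params$num_trees,
                            min_node = params$min_node)
    } else {
      function(x, y) fit_brt(x, y, n_trees = params$n_trees,
                             learning_rate = params$learning_rate,
                             depth = params$depth)
    }
  }
  if (is.null(param_grid)) {
    param_grid <- if (algorithm == "RF") {
      expand.grid(num_trees = c(150, 300), min_node = c(2, 10))
    } else {
      expand.grid(n_trees = c(150, 400), learning_rate = c(0.05, 0.1),
                  depth = 3)
    }
  }
  default_params <- as.list(param_grid[1, , drop = FALSE])

  cv_tss <- function(vars, params) {
    with_seed(seed, {
      cv <- cv_evaluate(fitter(params), x[, vars, drop = FALSE], y, fold_id)
      cv$pooled$tss
    })
  }

  # sequential variable reduction
  vars <- colnames(x)
  current_tss <- cv_tss(vars, default_params)
  repeat {
    if (length(vars) == 1) break
    m <- with_seed(seed, fitter(default_params)(x[, vars, drop = FALSE], y))
    imp <- permutation_importance(m, x[, vars, drop = FALSE], y,
                                  nperm = nperm, seed = seed)
    weakest <- names(imp)[which.min(imp)]
    if (imp[weakest] >= importance_min) break
    cand <- setdiff(vars, weakest)
    cand_tss <- cv_tss(cand, default_params)
    if (cand_tss >= current_tss - tss_tol) {
      vars <- cand
      current_tss <- cand_tss
    } else break
  }
  if (length(vars) == 1 && ncol(x) > 1)
    warning("all variables below importance cutoff; keeping the single best")

  # hyperparameter search on the reduced variable set
  scores <- vapply(seq_len(nrow(param_grid)), function(i)
    cv_tss(vars, as.list(param_grid[i, , drop = FALSE])), numeric(1))
  best <- which.max(scores)
  best_params <- as.list(param_grid[best, , drop = FALSE])

  final_cv <- with_seed(seed,
    cv_evaluate(fitter(best_params), x[, vars, drop = FALSE], y, fold_id))
  model <- with_seed(seed + 1L,
    fitter(best_params)(x[, vars, drop = FALSE], y))
  importance <- permutation_importance(model, x[, vars, drop = FALSE], y,
                                       nperm = nperm, seed = seed)
  structure(list(algorithm = algorithm, model = model, vars = vars,
                 params = best_params, cv = final_cv$pooled,
                 per_fold = final_cv$per_fold,
                 tuning = cbind(param_grid, tss = scores),
                 importance = importance),
            class = c("sdm_tuned", "sdm_model"))
}

#' @export
predict_suitability.sdm_tuned <- function(model, x) {
  x <- align_columns(model, x)
  predict_suitability(model$model, x)
}
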