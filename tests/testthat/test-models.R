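test_that("background sampling is contained, uniform and deterministic", {
  pts <- data.frame(lon = c(0, 0, 8, 8), lat = c(40, 48, 40, 48))
  sa <- alpha_hull_eoo(pts, alpha = 100, buffer_km = 0)
  g <- mk_raster(matrix(0, 40, 40), ymin = 38) # extent [0,40]x[38,78]
  bg <- make_background(sa, g, 4000, seed = 3)
  expect_true(all(sa_contains(sa, bg$lon, bg$lat)))
  expect_identical(bg, make_background(sa, g, 4000, seed = 3))
  expect_false(identical(bg, make_background(sa, g, 4000, seed = 4)))
  # uniformity: chi-square over a 4x4 grid of equal-area quadrats strictly
  # inside the hull
  inner <- bg[bg$lon > 0.5 & bg$lon < 7.5 & bg$lat > 40.5 & bg$lat < 47.5, ]
  tab <- table(cut(inner$lon, seq(0.5, 7.5, length.out = 5)),
               cut(inner$lat, seq(40.5, 47.5, length.out = 5)))
  expect_gt(chisq.test(as.vector(tab))$p.value, 0.01)
  # degenerate study area
  tiny <- alpha_hull_eoo(data.frame(lon = c(0, 0.001, 0.002),
                                    lat = c(40, 40.001, 40.0005)),
                         alpha = 10, buffer_km = 0)
  g2 <- mk_raster(matrix(0, 20, 20), xmin = 30, ymin = 60)
  expect_error(make_background(tiny, g2, 10, 1), "degenerate")
})

test_that("spatial blocks follow the median-split rule", {
  corners <- data.frame(lon = c(0, 0, 10, 10), lat = c(40, 50, 40, 50))
  bg <- data.frame(lon = c(1, 9), lat = c(41, 49))
  fa <- spatial_blocks(corners, bg)
  expect_setequal(fa$presence, 1:4)
  expect_equal(fa$background, c(1L, 4L))
  # balance: counts differ by <= 1 for n divisible by 4 without ties
  for (seed in 1:5) {
    set.seed(seed)
    p <- data.frame(lon = runif(40), lat = runif(40))
    f <- spatial_blocks(p, bg)
    expect_lte(diff(range(table(f$presence))), 1)
  }
  # translation equivariance: shifting everything leaves assignments fixed
  set.seed(9)
  p <- data.frame(lon = runif(20), lat = runif(20))
  f1 <- spatial_blocks(p, bg)
  p2 <- data.frame(lon = p$lon + 3, lat = p$lat - 2)
  bg2 <- data.frame(lon = bg$lon + 3, lat = bg$lat - 2)
  expect_equal(spatial_blocks(p2, bg2)$presence, f1$presence)
  expect_error(spatial_blocks(corners[c(1, 1, 1, 1), ], bg), "non-collocated")
})

test_that("maxent collapses to a constant under extreme regularization", {
  set.seed(2)
  px <- matrix(rnorm(60, 1), 60, 1, dimnames = list(NULL, "v"))
  bx <- matrix(rnorm(400, 0), 400, 1, dimnames = list(NULL, "v"))
  m <- fit_maxent(px, bx, feature_classes = "L", reg_mult = 1e4)
  expect_equal(unname(m$beta), 0)
  p <- predict_suitability(m, rbind(px, bx))
  expect_lt(diff(range(p)), 1e-10)
  expect_error(fit_maxent(px[1, , drop = FALSE], bx), "2 presences")
})

test_that("L-only maxent matches direct optimization of its objective", {
  set.seed(1)
  px <- matrix(rnorm(160, 1), 80, 2, dimnames = list(NULL, c("a", "b")))
  bx <- matrix(rnorm(800, 0), 400, 2, dimnames = list(NULL, c("a", "b")))
  m <- fit_maxent(px, bx, feature_classes = "L", reg_mult = 1,
                  bg_weight = 100)
  mm <- rangeshift:::build_features(rbind(px, bx), m$meta, "L")
  y <- c(rep(1, 80), rep(0, 400))
  w <- ifelse(y == 1, 1, 100)
  wt <- w / mean(w) # the solver's weight convention
  n <- length(y)
  lam <- m$lambda
  pf <- m$penalty / mean(m$penalty)
  # FISTA on F = -(1/n) sum wt_i loglik_i + lam * sum pf_j |beta_j|
  b0 <- 0; beta <- rep(0, ncol(mm)); zb0 <- b0; zbeta <- beta; tk <- 1
  step <- 1 / (max(colSums(mm^2 * wt)) / n + sum(wt) / n)
  for (it in 1:30000) {
    p <- plogis(zb0 + mm %*% zbeta)
    g0 <- -sum(wt * (y - p)) / n
    g <- -as.numeric(crossprod(mm, wt * (y - p))) / n
    nb0 <- zb0 - step * g0
    nb <- zbeta - step * g
    nb <- sign(nb) * pmax(abs(nb) - step * lam * pf, 0)
    tk1 <- (1 + sqrt(1 + 4 * tk^2)) / 2
    zb0 <- nb0 + (tk - 1) / tk1 * (nb0 - b0)
    zbeta <- nb + (tk - 1) / tk1 * (nb - beta)
    b0 <- nb0; beta <- nb; tk <- tk1
  }
  expect_equal(unname(m$beta), unname(beta), tolerance = 1e-3)
})

test_that("L-only maxent responds monotonically to a monotone driver", {
  set.seed(3)
  bx <- matrix(runif(600, 0, 1), 600, 1, dimnames = list(NULL, "v"))
  keep <- runif(600) < plogis(6 * (bx - 0.5))
  px <- bx[keep, , drop = FALSE][1:120, , drop = FALSE]
  m <- fit_maxent(px, bx, feature_classes = "L", reg_mult = 1)
  grid <- matrix(seq(0, 1, length.out = 50), ncol = 1,
                 dimnames = list(NULL, "v"))
  p <- predict_suitability(m, grid)
  expect_true(all(diff(p) >= -1e-12))
})

test_that("maxent tuning scans the grid and returns the omission winner", {
  w <- test_world()
  grd <- w$current$template
  occ <- dedupe_by_cell(filter_records(w$occurrences), grd)
  sa <- alpha_hull_eoo(occ, alpha = 5, buffer_km = 300)
  stack <- raster_stack(list(
    bio4 = bioclim(w$current$tmin, w$current$tmax, w$current$tavg,
                   w$current$prec)$bio4,
    aridity = thornthwaite_aridity(w$current$tavg, w$current$prec)))
  bg <- make_background(sa, grd, 500, 1)
  px <- as.matrix(stack_extract(stack, occ$lon, occ$lat))
  bx <- as.matrix(stack_extract(stack, bg$lon, bg$lat))
  folds <- spatial_blocks(occ, bg)
  # single candidate -> returned as-is
  one <- tune_maxent(px, bx, folds, feature_grid = list("L"), reg_grid = 2)
  expect_equal(one$best$reg_mult, 2)
  expect_equal(one$best$feature_classes, "L")
  # leaderboard covers the full cartesian grid
  tn <- tune_maxent(px, bx, folds,
                    feature_grid = list("L", c("L", "Q")),
                    reg_grid = c(1, 2, 5))
  expect_equal(nrow(tn$leaderboard), 6)
  # the winner attains the minimal mean omission (exhaustive re-scan)
  lb <- tn$leaderboard
  expect_equal(min(lb$mean_omission),
               lb$mean_omission[lb$feature_classes ==
                                  paste(tn$best$feature_classes,
                                        collapse = "") &
                                  lb$reg_mult == tn$best$reg_mult])
})

test_that("the full candidate grid has the documented 7 x 91 shape", {
  grid <- expand.grid(fc = 1:7, rm = seq(1, 10, by = 0.1))
  expect_equal(nrow(grid), 637)
})

test_that("tree models stay in [0, 1] and find monotone structure", {
  pb <- mk_pb(seed = 5)
  set.seed(5)
  for (m in list(fit_rf(pb$x, pb$y, num_trees = 60),
                 fit_brt(pb$x, pb$y, n_trees = 80, learning_rate = 0.1))) {
    p <- predict_suitability(m, pb$x)
    expect_true(all(p >= 0 & p <= 1))
    expect_gt(rank_metrics(pb$y, p)$auc, 0.75)
  }
})

test_that("permutation importance isolates informative variables", {
  set.seed(8)
  n <- 800
  x <- cbind(v1 = rnorm(n), v2 = rnorm(n), junk = rnorm(n))
  y <- rbinom(n, 1, plogis(2 * x[, "v1"]))
  m <- fit_maxent(x[y == 1, , drop = FALSE], x[y == 0, , drop = FALSE],
                  feature_classes = "L", reg_mult = 1)
  imp <- permutation_importance(m, x, y, nperm = 20, seed = 1)
  expect_equal(sum(imp), 100, tolerance = 0.5)
  expect_equal(names(which.max(imp)), "v1")
  expect_lt(imp[["junk"]], 5)
  # duplicated informative variables share importance in expectation: a
  # single randomized fit splits credit arbitrarily (sd ~19 points), so
  # the symmetry check averages over seeded refits
  set.seed(9)
  x2 <- cbind(a = rnorm(n))
  x2 <- cbind(x2, b = x2[, "a"]) # exact duplicate
  y2 <- rbinom(n, 1, plogis(3 * x2[, "a"]))
  imps <- vapply(1:40, function(i) {
    set.seed(500 + i)
    m2 <- fit_rf(x2, y2, num_trees = 60, mtry = 1)
    permutation_importance(m2, x2, y2, nperm = 5, seed = i)
  }, numeric(2))
  expect_lt(abs(diff(rowMeans(imps))), 10)
  # nperm = 1 is reproducible under the same seed
  i1 <- permutation_importance(m, x, y, nperm = 1, seed = 42)
  i2 <- permutation_importance(m, x, y, nperm = 1, seed = 42)
  expect_identical(i1, i2)
})

test_that("variable reduction removes pure-noise predictors", {
  # four strong signals plus one pure-noise column; the normalized
  # importance of noise must fall under the 5 percent cutoff and be
  # removed without degrading CV TSS, in >= 9/10 seeds
  drops <- vapply(1:10, function(seed) {
    set.seed(seed)
    n1 <- 150; n0 <- 500
    mk <- function(n, mus) sapply(mus, function(m) rnorm(n, m))
    mus <- c(1.8, -1.6, 1.5, -1.4)
    px <- cbind(mk(n1, mus), noise = rnorm(n1))
    bx <- cbind(mk(n0, rep(0, 4)), noise = rnorm(n0))
    colnames(px) <- colnames(bx) <- c(paste0("sig", 1:4), "noise")
    folds <- list(presence = rep(1:4, length.out = n1),
                  background = rep(1:4, length.out = n0))
    fit <- fit_tree_model("RF", px, bx, folds, nperm = 30,
                          param_grid = data.frame(num_trees = 60,
                                                  min_node = 25),
                          seed = seed)
    !("noise" %in% fit$vars) && all(paste0("sig", 1:4) %in% fit$vars)
  }, logical(1))
  expect_gte(sum(drops), 9)
})

test_that("single-predictor tree models survive and normalize importance", {
  set.seed(4)
  px <- matrix(rnorm(80, 1.5), 80, 1, dimnames = list(NULL, "only"))
  bx <- matrix(rnorm(300, 0), 300, 1, dimnames = list(NULL, "only"))
  folds <- list(presence = rep(1:4, 20), background = rep(1:4, 75))
  fit <- fit_tree_model("BRT", px, bx, folds, nperm = 3,
                        param_grid = data.frame(n_trees = 60,
                                                learning_rate = 0.1,
                                                depth = 2),
                        seed = 1)
  expect_equal(fit$vars, "only")
  expect_equal(sum(fit$importance), 100, tolerance = 0.5)
  p <- predict_suitability(fit, rbind(px, bx))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("the bagged wrapper exposes meaningful per-cell uncertainty", {
  pb <- mk_pb(seed = 6)
  set.seed(6)
  m <- fit_bagged(pb$x, pb$y,
                  fit_fun = function(x, y) fit_rf(x, y, num_trees = 30),
                  n_boot = 10)
  p <- predict_suitability(m, pb$x)
  u <- predict_uncertainty(m, pb$x)
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(u >= 0))
  expect_gt(sd(u), 0)
  mx <- fit_maxent(pb$x[pb$y == 1, , drop = FALSE],
                   pb$x[pb$y == 0, , drop = FALSE], "L")
  expect_error(predict_uncertainty(mx, pb$x), "uncertainty")
})
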