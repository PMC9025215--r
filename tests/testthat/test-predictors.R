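mk_monthly <- function(values_by_month, nr = 4, nc = 4) {
  lapply(values_by_month, function(v) mk_raster(matrix(v, nr, nc), ymin = 40))
}

test_that("bioclim reproduces hand-computed seasonality and sums", {
  tavg <- mk_monthly(c(rep(5, 6), rep(15, 6)))
  tmin <- mk_monthly(c(rep(0, 6), rep(10, 6)))
  tmax <- mk_monthly(c(rep(10, 6), rep(20, 6)))
  prec <- mk_monthly(rep(50, 12))
  b <- bioclim(tmin, tmax, tavg, prec)
  # population sd of six 5s and six 15s is exactly 5 -> bio4 = 500
  expect_equal(as.vector(b$bio4$values), rep(500, 16))
  expect_equal(as.vector(b$bio1$values), rep(10, 16))
  expect_equal(as.vector(b$bio5$values), rep(20, 16))
  expect_equal(as.vector(b$bio6$values), rep(0, 16))
  expect_equal(as.vector(b$bio7$values), rep(20, 16))
  expect_equal(as.vector(b$bio12$values), rep(600, 16))
  expect_equal(as.vector(b$bio15$values), rep(0, 16))
  # constant temperature -> bio4 = 0
  b0 <- bioclim(mk_monthly(rep(3, 12)), mk_monthly(rep(13, 12)),
                mk_monthly(rep(8, 12)), prec)
  expect_equal(as.vector(b0$bio4$values), rep(0, 16))
})

test_that("bioclim agrees with a direct per-cell oracle on random fields", {
  set.seed(21)
  ta <- matrix(rnorm(30 * 12, 10, 8), 30, 12)
  tn <- ta - runif(30, 2, 6); tx <- ta + runif(30, 2, 6)
  pr <- matrix(rexp(30 * 12, 1 / 60), 30, 12)
  b <- bioclim(tn, tx, ta, pr)
  sd_pop <- function(v) sqrt(mean((v - mean(v))^2))
  expect_equal(unname(b[, "bio4"]), apply(ta, 1, function(v) 100 * sd_pop(v)))
  expect_equal(unname(b[, "bio12"]), rowSums(pr))
  expect_equal(unname(b[, "bio13"]), apply(pr, 1, max))
  expect_equal(unname(b[, "bio15"]),
               apply(pr, 1, function(v) 100 * sd_pop(v) / (1 + mean(v))))
  # wettest-quarter temperature by explicit wraparound enumeration
  oracle_bio8 <- sapply(1:30, function(i) {
    qs <- sapply(1:12, function(q) sum(pr[i, ((q - 1):(q + 1)) %% 12 + 1]))
    qt <- sapply(1:12, function(q) mean(ta[i, ((q - 1):(q + 1)) %% 12 + 1]))
    qt[which.max(qs)]
  })
  expect_equal(unname(b[, "bio8"]), oracle_bio8)
  expect_error(bioclim(tn[1:10, ], tx, ta, pr), "co-registered")
})

test_that("aridity index hits its closed-form extremes and is monotone", {
  lat <- rep(45, 8)
  ta <- matrix(rep(c(0, 2, 8, 14, 18, 22, 21, 16, 11, 6, 2, 0), each = 8),
               8, 12)
  wet <- matrix(500, 8, 12)
  expect_equal(thornthwaite_aridity(ta, wet, lat = lat), rep(0, 8))
  dry <- matrix(0, 8, 12)
  expect_equal(thornthwaite_aridity(ta, dry, lat = lat), rep(100, 8))
  # reducing precipitation never decreases aridity
  set.seed(2)
  pr <- matrix(runif(8 * 12, 0, 120), 8, 12)
  t1 <- thornthwaite_aridity(ta, pr, lat = lat)
  t2 <- thornthwaite_aridity(ta, pr * 0.5, lat = lat)
  expect_true(all(t2 >= t1))
  # PET is zero in an all-freezing year
  expect_equal(thornthwaite_aridity(matrix(-5, 8, 12), dry, lat = lat),
               rep(0, 8))
})

test_that("day length and solar radiation behave astronomically", {
  # equator: ~12 h all year
  expect_equal(day_length(0, 1), 12, tolerance = 0.1)
  expect_equal(day_length(0, 7), 12, tolerance = 0.1)
  # far north: longer days in July than January
  expect_gt(day_length(65, 7), day_length(65, 1))
  # radiation nonnegative and higher in summer at mid-latitudes
  expect_gt(extraterrestrial_radiation(50, 7),
            extraterrestrial_radiation(50, 1))
  expect_gte(extraterrestrial_radiation(80, 1), 0)
})

test_that("terrain variables are exact on flat and planar surfaces", {
  flat <- mk_raster(matrix(100, 6, 6), ymin = 45)
  tv <- terrain_vars(flat)
  expect_equal(as.vector(tv$slope$values), rep(0, 36))
  expect_equal(as.vector(tv$tpi$values), rep(0, 36))
  expect_equal(as.vector(tv$tri$values), rep(0, 36))
  # inclined plane: constant slope, zero TPI in the interior
  z <- outer(rep(1, 8), 1:8) * 500 # rises east
  plane <- mk_raster(z, ymin = 45)
  tv2 <- terrain_vars(plane)
  # the east-west meter scale varies with latitude, so slope is constant
  # within rows of the interior (and TPI identically zero)
  interior <- tv2$slope$values[3:6, 3:6]
  for (i in 1:4)
    expect_equal(max(interior[i, ]) - min(interior[i, ]), 0,
                 tolerance = 1e-9)
  expect_equal(as.vector(tv2$tpi$values[3:6, 3:6]), rep(0, 16))
  # east-rising plane drains west: aspect 270
  expect_equal(tv2$aspect$values[4, 4], 270)
  # TPI antisymmetry and TRI nonnegativity on a random surface
  set.seed(4)
  z3 <- matrix(rnorm(49, 500, 60), 7, 7)
  up <- terrain_vars(mk_raster(z3, ymin = 45))
  dn <- terrain_vars(mk_raster(-z3, ymin = 45))
  expect_equal(dn$tpi$values, -up$tpi$values)
  expect_true(all(up$tri$values >= 0))
  expect_error(terrain_vars(mk_raster(matrix(1, 2, 2))), "3x3")
})

test_that("collinearity screening drops twins and verifies against brute force", {
  set.seed(6)
  n <- 400
  base <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  # identical twin of a plus an independent variable
  x <- cbind(base, a2 = base$a)
  keep <- vifcor_select(x)
  expect_length(keep, 3)
  expect_true(xor("a" %in% keep, "a2" %in% keep))
  # nothing correlated -> identity
  expect_equal(vifcor_select(base), names(base))
  # brute-force recheck of the returned set on a hard case
  y <- data.frame(a = rnorm(n))
  y$b <- y$a * 0.95 + rnorm(n, 0, 0.3)
  y$c <- y$a * -0.9 + rnorm(n, 0, 0.4)
  y$d <- rnorm(n)
  y$e <- y$d * 0.85 + rnorm(n, 0, 0.5)
  kept <- vifcor_select(y, corr_max = 0.7, vif_max = 10)
  s <- abs(cor(y[kept], method = "spearman")); diag(s) <- 0
  expect_lt(max(s), 0.7)
  vif <- diag(solve(cor(y[kept])))
  expect_lt(max(vif), 10)
  # constant layer dropped with a warning
  y$f <- 1
  expect_warning(k2 <- vifcor_select(y), "constant")
  expect_false("f" %in% k2)
})

test_that("seasonality time series track amplitude exactly", {
  base <- 10 + 8 * -cos(2 * pi * ((1:12) - 0.5) / 12)
  years <- rbind(base, base, base)
  s <- seasonality_series(years)
  expect_equal(s, rep(s[1], 3), ignore_attr = TRUE)
  # doubling the cycle amplitude doubles bio4 (sd linearity)
  doubled <- rbind(base, 10 + 2 * (base - 10))
  s2 <- seasonality_series(doubled)
  expect_equal(s2[2], 2 * s2[1], ignore_attr = TRUE)
  # a south location with a growing amplitude trend outpaces a stable north
  amp_s <- seq(6, 10, length.out = 20); amp_n <- rep(8, 20)
  south <- t(sapply(amp_s, function(a) 15 + a * -cos(2 * pi * ((1:12) - 0.5) / 12)))
  north <- t(sapply(amp_n, function(a) 5 + a * -cos(2 * pi * ((1:12) - 0.5) / 12)))
  trend <- function(v) unname(coef(lm(v ~ seq_along(v)))[2])
  expect_gt(trend(seasonality_series(south)), trend(seasonality_series(north)))
  # raster input: nearest-cell lookup, error outside the grid
  w <- test_world()
  yearly <- list(w$current$tavg, w$current$tavg)
  s3 <- seasonality_series(yearly, lon = 5, lat = 50)
  expect_length(s3, 2)
  expect_equal(s3[1], s3[2])
  expect_error(seasonality_series(yearly, lon = 100, lat = 0), "outside")
})
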