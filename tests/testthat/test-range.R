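test_that("binarization thresholds correctly and propagates missing cells", {
  s <- mk_raster(matrix(c(0.1, 0.5, 0.9, NA, 0.4, 0.6, 0.2, 0.8, 0.5), 3, 3))
  b <- binarize(s, 0.5)
  expect_equal(as.vector(b$values),
               c(0, 1, 1, NA, 0, 1, 0, 1, 1)) # >= threshold is presence
  expect_true(all(binarize(s, 0)$values[!is.na(s$values)] == 1))
  expect_true(all(binarize(s, 2)$values[!is.na(s$values)] == 0))
})

test_that("range change reproduces hand counts and the paper identity", {
  # current 10 cells; future keeps 6, adds 3
  cur <- mk_raster(matrix(c(rep(1, 10), rep(0, 15)), 5, 5))
  fut_v <- c(rep(1, 6), rep(0, 4), rep(1, 3), rep(0, 12))
  fut <- mk_raster(matrix(fut_v, 5, 5))
  rc <- range_change(cur, fut)
  expect_equal(rc$loss_pct, 40)
  expect_equal(rc$gain_pct, 30)
  expect_equal(rc$overall_change_pct, -10)
  expect_equal(unname(rc$counts["stable"]), 6)
  # identical maps
  rc0 <- range_change(cur, cur)
  expect_equal(rc0$loss_pct, 0)
  expect_equal(rc0$gain_pct, 0)
  expect_equal(rc0$overall_change_pct, 0)
  # published per-GCM row: gain 14.36 - loss 38.29 = overall -23.93
  expect_equal(14.36 - 38.29, -23.93)
  expect_error(range_change(mk_raster(matrix(0, 2, 2)),
                            mk_raster(matrix(1, 2, 2))), "no presence")
})

test_that("overall = gain - loss and masked cells never count", {
  set.seed(12)
  for (rep in 1:5) {
    cur <- mk_raster(matrix(rbinom(64, 1, 0.5), 8, 8))
    fut <- mk_raster(matrix(rbinom(64, 1, 0.4), 8, 8))
    fut$values[1, 1] <- NA
    rc <- range_change(cur, fut)
    expect_equal(rc$overall_change_pct, rc$gain_pct - rc$loss_pct,
                 tolerance = 1e-9)
    # the masked cell contributes to no bucket
    expect_equal(sum(rc$counts[c("lost", "gained", "stable", "absent")]),
                 63 - sum(is.na(cur$values[-1])))
  }
})

test_that("transition maps encode absent/lost/stable/gained", {
  cur <- mk_raster(matrix(c(1, 1, 0, 0), 2, 2))
  fut <- mk_raster(matrix(c(1, 0, 1, 0), 2, 2))
  tm <- transition_map(cur, fut)
  expect_equal(as.vector(tm$values), c(2, 1, 3, 0))
})

test_that("occurrence loss percentages match hand counts", {
  fut <- mk_raster(matrix(c(rep(0, 10), rep(1, 15)), 5, 5))
  # 20 records: 8 in the first 10 (future-0) cells, 12 in future-1 cells
  xy <- rst_coords(fut)
  occ <- data.frame(lon = xy$lon[c(1:8, 11:22)], lat = xy$lat[c(1:8, 11:22)])
  expect_equal(occurrences_lost(occ, fut), 40)
  all1 <- mk_raster(matrix(1, 5, 5))
  all0 <- mk_raster(matrix(0, 5, 5))
  expect_equal(occurrences_lost(occ, all1), 0)
  expect_equal(occurrences_lost(occ, all0), 100)
  expect_error(occurrences_lost(data.frame(lon = 99, lat = 99), fut),
               "usable")
})

test_that("scenario aggregation reproduces the published means", {
  tab <- read.csv(system.file("extdata", "published_range_change_envthin.csv",
                              package = "rangeshift"))
  tab$group <- paste(tab$time_slice, tab$ssp)
  agg <- aggregate_scenarios(tab)
  ref <- read.csv(system.file("extdata", "published_reference_means.csv",
                              package = "rangeshift"))
  ref$group <- paste(ref$time_slice, ref$ssp)
  ref <- ref[order(ref$group), ]
  expect_equal(agg$loss_pct, ref$loss_pct, tolerance = 0.011)
  expect_equal(agg$gain_pct, ref$gain_pct, tolerance = 0.011)
  expect_equal(agg$occ_lost_pct, ref$occ_lost_pct, tolerance = 0.011)
  # single-report group is the identity
  one <- data.frame(group = "g", loss_pct = 12.345, gain_pct = 1,
                    overall_change_pct = -11.345, occ_lost_pct = 3)
  expect_equal(aggregate_scenarios(one)$loss_pct, 12.35) # half-up at 2 dp
})

test_that("median centroids sit at symmetry centers and match brute force", {
  single <- mk_raster(matrix(c(0, 0, 0, 1), 2, 2))
  expect_equal(median_centroid(single), c(lon = 1.5, lat = 0.5))
  # symmetric cross
  v <- matrix(0, 5, 5); v[3, ] <- 1; v[, 3] <- 1
  cross <- mk_raster(v)
  expect_equal(median_centroid(cross), c(lon = 2.5, lat = 2.5))
  set.seed(3)
  for (rep in 1:5) {
    m <- mk_raster(matrix(rbinom(49, 1, 0.3), 7, 7))
    if (!any(m$values == 1)) next
    cen <- median_centroid(m)
    xy <- rst_coords(m)
    pres <- which(as.vector(m$values) == 1)
    expect_equal(cen[["lon"]], median(xy$lon[pres]))
    expect_equal(cen[["lat"]], median(xy$lat[pres]))
    # the geometric variant equals the coordinate means
    cg <- median_centroid(m, method = "centroid")
    expect_equal(cg[["lon"]], mean(xy$lon[pres]))
  }
  expect_error(median_centroid(mk_raster(matrix(0, 3, 3))), "empty")
})

test_that("centroid distances use the haversine closed form", {
  expect_equal(centroid_distance(c(lon = 3, lat = 45), c(lon = 3, lat = 45)),
               0)
  d <- centroid_distance(c(lon = 0, lat = 0), c(lon = 0, lat = 1))
  expect_equal(d, 6371 * pi / 180, tolerance = 1e-6) # 111.19 km
  a <- c(lon = -3, lat = 52); b <- c(lon = 21, lat = 41)
  expect_equal(centroid_distance(a, b), centroid_distance(b, a))
  m <- centroid_matrix(list(x = a, y = b))
  expect_equal(m["x", "y"], m["y", "x"])
  expect_equal(diag(m), c(x = 0, y = 0))
})

test_that("mean altitude averages presence cells only", {
  elev <- mk_raster(matrix(c(0, 1000, 400, 800), 2, 2))
  map2 <- mk_raster(matrix(c(1, 1, 0, 0), 2, 2))
  expect_equal(mean_altitude(map2, elev), 500)
  const <- mk_raster(matrix(100, 2, 2))
  expect_equal(mean_altitude(map2, const), 100)
  set.seed(6)
  e <- mk_raster(matrix(runif(36, 0, 2000), 6, 6))
  b <- mk_raster(matrix(rbinom(36, 1, 0.4), 6, 6))
  if (any(b$values == 1)) {
    expect_equal(mean_altitude(b, e),
                 mean(e$values[b$values == 1]))
  }
  expect_error(mean_altitude(mk_raster(matrix(0, 2, 2)), const), "empty")
})

test_that("altitude shift tests give the expected df and detect separation", {
  groups7 <- lapply(1:7, function(i) rnorm(60, 500 + 10 * i, 50))
  names(groups7) <- paste0("g", 1:7)
  st <- shift_tests(groups7)
  expect_equal(st$kw_df, 6) # 7 groups -> df = 6
  # identically distributed groups: tiny statistic, large p
  same <- list(a = rep(1:30, 2), b = rep(1:30, 2), c = rep(1:30, 2))
  st0 <- shift_tests(same)
  expect_lt(st0$kw_stat, 1e-6)
  expect_gt(st0$kw_p, 0.99)
  # well-separated groups: decisive rejection
  sep <- list(low = rnorm(100, 200, 20), high = rnorm(100, 800, 20))
  expect_lt(shift_tests(sep)$kw_p, 0.001)
  expect_error(shift_tests(list(a = 1:5)), "2 groups")
  expect_error(shift_tests(list(a = 1:5, b = numeric(0))), "empty")
})
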