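test_that("record filtering applies the year, uncertainty and coordinate rules", {
  rec <- data.frame(
    lon = c(5, 6, 7, NA, 8, 9),
    lat = c(45, 46, 47, 48, 49, 95),
    year = c(1969, 1970, 2000, 2000, 2000, 2000),
    coord_uncertainty_m = c(500, 9250, 9251, 500, NA, 500)
  )
  out <- filter_records(rec)
  # 1969 removed; exactly 9.25 km kept (strict > removal); 9251 m removed;
  # non-georeferenced removed; missing uncertainty kept; lat 95 invalid
  expect_equal(out$lon, c(6, 8))
  # order preservation on a clean set
  clean <- mk_records(20)
  expect_equal(filter_records(clean), clean)
})

test_that("cell deduplication keeps the first record per cell", {
  g <- mk_raster(matrix(0, 10, 10))
  rec <- data.frame(lon = c(1.2, 1.8, 5.5, 1.4), lat = c(3.2, 3.3, 5.5, 3.6),
                    year = 2000, coord_uncertainty_m = 100)
  # records 1, 2 and 4 share cell (lon in [1,2), lat in [3,4))
  out <- dedupe_by_cell(rec, g)
  expect_equal(nrow(out), 2)
  expect_equal(out$lon[1], 1.2)
  # distinct cells -> identity
  rec2 <- data.frame(lon = seq(0.5, 8.5, 1), lat = seq(0.5, 8.5, 1))
  expect_equal(nrow(dedupe_by_cell(rec2, g)), 9)
  # outside the grid -> dropped with a warning
  rec3 <- data.frame(lon = c(1, 99), lat = c(1, 1))
  expect_warning(out3 <- dedupe_by_cell(rec3, g), "outside")
  expect_equal(nrow(out3), 1)
})

test_that("dedupe survivor count is invariant to input order", {
  g <- mk_raster(matrix(0, 20, 20))
  set.seed(3)
  rec <- data.frame(lon = runif(80, 0, 20), lat = runif(80, 0, 20))
  n0 <- nrow(dedupe_by_cell(rec, g))
  for (k in 1:5) {
    perm <- sample.int(80)
    expect_equal(nrow(dedupe_by_cell(rec[perm, ], g)), n0)
  }
})

test_that("alpha hull contains its points and matches the convex hull limit", {
  sq <- data.frame(lon = c(0, 0, 4, 4), lat = c(40, 44, 40, 44))
  sa <- alpha_hull_eoo(sq, alpha = 100, buffer_km = 10)
  expect_true(all(sa_contains(sa, sq$lon, sq$lat)))
  # containment of 200 random points used to build the hull
  set.seed(8)
  pts <- data.frame(lon = runif(200, 0, 6), lat = runif(200, 40, 45))
  sa2 <- alpha_hull_eoo(pts, alpha = 2, buffer_km = 50)
  expect_true(all(sa_contains(sa2, pts$lon, pts$lat)))
  # alpha -> Inf, buffer 0: area equals the convex hull area (chull oracle)
  sa3 <- alpha_hull_eoo(pts, alpha = 1e6, buffer_km = 0)
  ch <- chull(pts$lon, pts$lat)
  xs <- pts$lon[ch]; ys <- pts$lat[ch]
  area_ch <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
  expect_equal(sa_area(sa3), area_ch, tolerance = 1e-6)
  expect_error(alpha_hull_eoo(sq[1:2, ]), "3")
  col <- data.frame(lon = c(1, 2, 3), lat = c(1, 2, 3))
  expect_error(alpha_hull_eoo(col), "collinear|insufficient")
})

test_that("spatial thinning enforces the distance and is idempotent", {
  # all pairwise distances above the threshold -> identity
  far <- data.frame(lon = c(0, 2, 4), lat = c(45, 45, 45))
  expect_equal(spatial_thin(far, thin_dist_km = 50, seed = 1), far)
  # 3 collinear points 5 km apart, thinning at 6 km -> the two ends
  # (enumeration: {1,3} is the only 2-subset with min distance > 6 km)
  lat5km <- 5 / 110.574
  three <- data.frame(lon = c(0, 0, 0), lat = 45 + c(0, lat5km, 2 * lat5km))
  out <- spatial_thin(three, thin_dist_km = 6, n_reps = 10, seed = 2)
  expect_equal(nrow(out), 2)
  expect_equal(out$lat, three$lat[c(1, 3)])
  # property: output minimum pairwise distance exceeds the threshold
  set.seed(5)
  rnd <- data.frame(lon = runif(60, 0, 3), lat = runif(60, 44, 47))
  th <- spatial_thin(rnd, thin_dist_km = 25, n_reps = 5, seed = 5)
  d <- haversine_matrix(th$lon, th$lat)
  expect_gt(min(d[upper.tri(d)]), 25)
  # idempotence
  expect_equal(spatial_thin(th, thin_dist_km = 25, n_reps = 5, seed = 5), th)
  # determinism
  expect_equal(spatial_thin(rnd, 25, 5, seed = 9),
               spatial_thin(rnd, 25, 5, seed = 9))
})

test_that("environmental thinning keeps one record per occupied bin", {
  rec <- mk_records(9, seed = 2)
  lattice <- expand.grid(a = c(0.1, 0.5, 0.9), b = c(0.1, 0.5, 0.9))
  out <- env_thin(rec, lattice, n_bins_per_var = 3, seed = 1)
  expect_equal(nrow(out), 9) # one record per bin, 9 occupied bins
  one_bin <- data.frame(a = rep(0.5, 9), b = rep(0.5, 9))
  expect_message(out1 <- env_thin(rec, one_bin, 3, seed = 1), "constant")
  expect_equal(nrow(out1), 1)
  # survivor count equals the independently computed occupied-bin count
  set.seed(11)
  rec2 <- mk_records(200, seed = 11)
  env <- data.frame(a = runif(200), b = rnorm(200))
  out2 <- env_thin(rec2, env, n_bins_per_var = 5, seed = 3)
  bin <- function(v, k) pmin(floor((v - min(v)) / diff(range(v)) * k) + 1, k)
  occupied <- nrow(unique(data.frame(bin(env$a, 5), bin(env$b, 5))))
  expect_equal(nrow(out2), occupied)
  expect_lte(nrow(out2), nrow(rec2))
  # idempotence under the same partition (the first call's bin ranges)
  keep_idx <- match(interaction(out2$lon, out2$lat),
                    interaction(rec2$lon, rec2$lat))
  out3 <- env_thin(out2, env[keep_idx, ], n_bins_per_var = 5, seed = 3,
                   ranges = attr(out2, "ranges"))
  expect_equal(nrow(out3), nrow(out2))
  expect_equal(out3$lon, out2$lon)
})

test_that("cleaning pipeline counts are monotone non-increasing", {
  w <- test_world()
  g <- w$current$template
  occ0 <- w$occurrences
  occ1 <- filter_records(occ0)
  occ2 <- dedupe_by_cell(occ1, g)
  occ3 <- spatial_thin(occ2, 40, n_reps = 2, seed = 1)
  env <- stack_extract(raster_stack(list(t = w$truth_map)), occ3$lon, occ3$lat)
  occ4 <- env_thin(occ3, env, n_bins_per_var = 10, seed = 1)
  counts <- c(nrow(occ0), nrow(occ1), nrow(occ2), nrow(occ3), nrow(occ4))
  expect_true(all(diff(counts) <= 0))
})
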