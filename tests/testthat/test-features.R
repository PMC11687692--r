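test_that("SIC buffers hit the trivial extremes and the half-ice oracle", {
  all_ice <- one_floe_scene(ice_fun = function(x, y) TRUE)
  expect_equal(sic_at_radius(all_ice$rasters, all_ice$floe, 500), 1.0)

  water <- one_floe_scene(ice_fun = function(x, y) FALSE)
  expect_equal(sic_at_radius(water$rasters, water$floe, 500), 0.0)

  half <- one_floe_scene(ice_fun = function(x, y) x < 1500)
  expect_equal(sic_at_radius(half$rasters, half$floe, 500), 0.5,
               tolerance = 0.02)

  # the focal floe's own pixels are excluded from the fraction
  expect_equal(sic_at_radius(water$rasters, water$floe, 100), 0.0)

  expect_error(sic_at_radius(water$rasters, water$floe, 5000),
               "edge_filter")
})

test_that("ice area inside nested SIC buffers is non-decreasing in radius", {
  sc <- one_floe_scene(ice_fun = function(x, y) (x + y) %% 400 < 180)
  radii <- c(150, 250, 500, 750)
  # independent pixel-count oracle on the same mask
  n <- nrow(sc$rasters$ice)
  cx <- (seq_len(n) - 0.5) * sc$px
  X <- matrix(cx, n, n, byrow = TRUE); Y <- matrix(cx, n, n)
  d <- sqrt((X - sc$floe$x)^2 + (Y - sc$floe$y)^2)
  areas <- vapply(radii, function(r)
    sum(sc$rasters$ice[d > sc$r0 & d <= sc$r0 + r &
                         sc$rasters$labels != 1L]), numeric(1))
  expect_true(all(diff(areas) >= 0))
  sic <- vapply(radii, function(r)
    sic_at_radius(sc$rasters, sc$floe, r), numeric(1))
  counts <- vapply(radii, function(r)
    sum(d > sc$r0 & d <= sc$r0 + r & !(sc$rasters$labels == 1L)),
    numeric(1))
  expect_equal(sic * counts, areas, tolerance = 1e-9)
})

test_that("terrain metrics recover closed forms on flat and tilted seabeds", {
  px <- 10
  n <- 100
  flat <- scene_rasters(ice = matrix(0L, n, n),
                        bathy = matrix(-300, n, n), pixel_size = px)
  m <- bathy_metrics(flat, c(500, 500), 200)
  expect_equal(unname(unlist(m)), c(0, 0, 0))

  # plane z = 0.01 x: slope 0.01 m/m, roughness 2*0.01*px, TRI 6/8*0.01*px
  X <- matrix((seq_len(n) - 0.5) * px, n, n, byrow = TRUE)
  plane <- scene_rasters(ice = matrix(0L, n, n), bathy = 0.01 * X,
                         pixel_size = px)
  mp <- bathy_metrics(plane, c(500, 500), 200)
  expect_equal(mp$slope, 0.01, tolerance = 1e-10)
  expect_equal(mp$rough, 0.02 * px, tolerance = 1e-10)
  expect_equal(mp$tri, 0.01 * px * 6 / 8, tolerance = 1e-10)

  # shift invariance
  shift <- scene_rasters(ice = matrix(0L, n, n), bathy = 0.01 * X + 123,
                         pixel_size = px)
  ms <- bathy_metrics(shift, c(500, 500), 200)
  expect_equal(ms, mp, tolerance = 1e-12)

  expect_error(bathy_metrics(flat, c(500, 500), 2), "one pixel")
})

test_that("colony distance matches the brute-force minimum", {
  expect_equal(colony_distance(c(200, 0),
                               data.frame(x = c(0, 1000), y = c(0, 0))), 200)
  expect_equal(colony_distance(c(5, 5), data.frame(x = 5, y = 5)), 0)
  expect_error(colony_distance(c(0, 0), data.frame(x = numeric(0),
                                                   y = numeric(0))),
               "empty")
  set.seed(31)
  cols <- data.frame(x = runif(100, -1e4, 1e4), y = runif(100, -1e4, 1e4))
  pts <- cbind(runif(20, 0, 5000), runif(20, 0, 5000))
  got <- colony_distance(pts, cols)
  oracle <- apply(pts, 1, function(p)
    min(sqrt((p[1] - cols$x)^2 + (p[2] - cols$y)^2)))
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("edge filtering matches a brute-force inset test and reports seals", {
  set.seed(5)
  n <- 400
  fl <- data.frame(floe_id = seq_len(n),
                   x = runif(n, 0, 10000), y = runif(n, 0, 10000),
                   area = runif(n, 1, 2000),
                   seal_count = rpois(n, 0.3))
  ef <- edge_filter(fl, c(10000, 10000), buffer = 1000)
  r0 <- sqrt(fl$area / pi)
  oracle_keep <- fl$x - r0 >= 1000 & fl$y - r0 >= 1000 &
    10000 - fl$x - r0 >= 1000 & 10000 - fl$y - r0 >= 1000
  expect_identical(ef$retained$floe_id, fl$floe_id[oracle_keep])
  expect_equal(ef$excluded_seals, sum(fl$seal_count[!oracle_keep]))

  # a small floe near the corner is excluded, a central one retained
  toy <- data.frame(floe_id = 1:2, x = c(500, 5000), y = c(500, 5000),
                    area = pi * 10^2)
  ef2 <- edge_filter(toy, c(10000, 10000))
  expect_identical(ef2$retained$floe_id, 2L)
  expect_error(edge_filter(toy, c(1500, 1500), buffer = 1000), "interior")
})

test_that("stratified size-bin sampling obeys quotas and is uniform in-bin", {
  set.seed(8)
  n <- 1e5
  fl <- data.frame(floe_id = seq_len(n),
                   area = exp(runif(n, 0, log(5000))))
  out <- stratified_sample(fl, n_bins = 20, per_bin = 3000, seed = 2)
  expect_lte(nrow(out), 20 * 3000)
  # bins smaller than the quota are kept whole
  la <- log(fl$area)
  breaks <- seq(min(la), max(la), length.out = 21)
  bin <- findInterval(la, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  tab_in <- table(bin)
  tab_out <- table(findInterval(log(out$area), breaks,
                                rightmost.closed = TRUE, all.inside = TRUE))
  for (b in names(tab_in))
    expect_equal(unname(tab_out[b]),
                 min(unname(tab_in[b]), 3000), ignore_attr = TRUE)
  # within one bin the draw is uniform: quarter-counts pass chi-square
  b10 <- out$area[findInterval(log(out$area), breaks,
                               rightmost.closed = TRUE,
                               all.inside = TRUE) == 10]
  qcut <- cut(b10, quantile(fl$area[bin == 10], seq(0, 1, 0.25)),
              include.lowest = TRUE)
  expect_gt(chisq.test(table(qcut))$p.value, 0.01)
  # determinism
  expect_identical(out, stratified_sample(fl, 20, 3000, seed = 2))
  expect_error(stratified_sample(fl[0, ], 20, 3000), "no floes")
})

test_that("the assembled feature table is complete and order-invariant", {
  sp <- scene_spec(width = 4200, height = 4200, pixel_size = 15,
                   n_floes = 40, depth_corr_length = 500)
  f <- gen_floe_field(sp, seed = 21)
  ef <- edge_filter(f$floes, c(sp$width, sp$height))
  ft <- build_feature_table(ef$retained, f$rasters, f$colonies)
  want <- c("sic_150", "sic_250", "sic_500", "sic_750", "sic_1000",
            "slope_1000", "tri_1000", "rough_1000", "colony_dist",
            "edge_dist")
  expect_true(all(want %in% names(ft)))
  expect_equal(nrow(ft), nrow(ef$retained))
  expect_true(all(ft$sic_750 >= 0 & ft$sic_750 <= 1))

  perm <- sample(nrow(ef$retained))
  ft2 <- build_feature_table(ef$retained[perm, ], f$rasters, f$colonies)
  expect_equal(ft2[order(ft2$floe_id), want],
               ft[order(ft$floe_id), want], ignore_attr = TRUE)

  empty <- build_feature_table(ef$retained[0, ], f$rasters, f$colonies)
  expect_true(all(want %in% names(empty)))
  expect_equal(nrow(empty), 0)
})
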