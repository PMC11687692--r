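test_that("model predictions: trivial cases and hand arithmetic", {
  m <- seal_model()
  z <- data.frame(area = 0, rough_1000 = 0, sic_750 = 0, colony_dist = 0)
  expect_equal(predict(m, z), exp(-7.53), tolerance = 1e-12)
  # area 100 m^2 under the increment parameterization
  d <- data.frame(area = 100, rough_1000 = 0, sic_750 = 0, colony_dist = 0)
  want <- exp(-7.53 + 0.139 * 49.84 + (0.139 - 0.136) * (100 - 49.84))
  expect_equal(predict(m, d), want, tolerance = 1e-12)
  expect_error(predict(m, z[, -2, drop = FALSE]), "rough_1000")
})

test_that("mean curve is continuous, piecewise log-linear, non-decreasing", {
  m <- seal_model()
  a <- seq(1, 2000, by = 0.25)
  nd <- data.frame(area = a, rough_1000 = 0, sic_750 = 0, colony_dist = 0)
  eta <- predict(m, nd, type = "link")
  expect_true(all(diff(eta) >= -1e-12))
  sl <- diff(eta) / diff(a)
  seg1 <- a[-1] < m$psi[1]
  seg2 <- a[-1] > m$psi[1] + 1 & a[-1] < m$psi[2]
  expect_equal(unique(round(sl[seg1], 6)), 0.139)
  expect_equal(unique(round(sl[seg2], 6)), 0.003)
  # no jump at either breakpoint
  for (p in m$psi)
    expect_lt(abs(diff(predict(m, data.frame(
      area = p + c(-1e-9, 1e-9), rough_1000 = 0, sic_750 = 0,
      colony_dist = 0), type = "link"))), 1e-7)
})

test_that("NB prediction-interval width grows with floe area", {
  m <- seal_model()
  a <- seq(1, 2000, length.out = 200)
  mu <- predict(m, data.frame(area = a, rough_1000 = 10, sic_750 = 0.7,
                              colony_dist = 1e5))
  w <- qnbinom(0.975, size = m$theta, mu = mu) -
    qnbinom(0.025, size = m$theta, mu = mu)
  expect_true(all(diff(w) >= 0))
})

test_that("error metrics match hand computations", {
  em <- error_metrics(c(1, 2, 0), c(1, 2, 0), area = c(1, 10, 100))
  expect_equal(em$rmse, 0)
  expect_equal(em$mape, 0)
  expect_equal(error_metrics(c(0, 0, 3), c(0, 0, 0),
                             scheme = "per_floe_rmse")$rmse, sqrt(3))
  # 3-bin toy: bins by area decade; zero-observation bins dropped
  obs <- c(10, 0, 4, 0)
  pred <- c(8, 1, 5, 2)
  area <- c(2, 3, 40, 600)      # bins: [1], [2], [3] with bin 1 = {2,3}
  em2 <- error_metrics(obs, pred, scheme = "binned_mape", area = area,
                       n_bins = 3)
  hand <- 100 * mean(c(abs(10 - 9) / 10, abs(4 - 5) / 4))
  expect_equal(em2$mape, hand)
  expect_error(error_metrics(c(0, 0), c(1, 1), scheme = "binned_mape",
                             area = c(1, 2)), "zero")
})

test_that("White's LM test and residual diagnostics behave at the edges", {
  set.seed(2)
  mu <- runif(200, 1, 5)
  r <- rnorm(200)
  wt <- white_lm_test(r, mu)
  expect_equal(wt$df, 2)
  expect_true(wt$p_value >= 0 && wt$p_value <= 1)
  expect_error(white_lm_test(r, rep(3, 200)), "constant")

  d <- sim_floe_table(800, seed = 9)
  f <- segnb(seal_count ~ area + rough_1000 + sic_750, d, npsi = 1)
  dg <- residual_diagnostics(f)
  expect_length(dg$pearson$ci, 2)
  expect_true(dg$pearson$ci[1] < dg$pearson$estimate &&
                dg$pearson$estimate < dg$pearson$ci[2])

  # perfectly fitted data: residuals identically zero -> undefined
  fake <- structure(list(family = "gaussian"), class = "segnb")
  fake$y <- rep(2, 50); fake$fitted.values <- rep(2, 50)
  fake2 <- list(fitted.values = 1:50)
  expect_error(residual_diagnostics(
    structure(list(family = "gaussian", y = seq(1, 2, length.out = 50),
                   fitted.values = seq(1, 2, length.out = 50)),
              class = "segnb")), "constant")
})

test_that("bootstrap intervals: degeneracy, support, and conservation", {
  d <- sim_floe_table(300, seed = 12)
  # degenerate fitting function ignores the resample: zero-width CI
  fixed <- segnb(seal_count ~ area + rough_1000, d, npsi = 0)
  bt0 <- bootstrap_intervals(d, function(dd) fixed, n_boot = 100, seed = 1)
  expect_true(all(bt0$point$ci_hi - bt0$point$ci_lo < 1e-12))
  # real refits: PI bounds are non-negative integers containing the CI
  fml <- seal_count ~ area + rough_1000 + sic_750
  bt <- bootstrap_intervals(
    d, function(dd) segnb(fml, dd, npsi = 0), n_boot = 150, seed = 2)
  expect_true(all(bt$point$pi_lo >= 0))
  expect_true(all(bt$point$ci_lo >= bt$point$pi_lo - 1e-9))
  expect_true(all(bt$point$ci_hi <= bt$point$pi_hi + 1e-9))
  # conservation: scene prediction equals the sum of floe-level predictions
  expect_equal(bt$scene$predicted, sum(bt$point$mu), tolerance = 1e-12)
})

test_that("held-out RMSE of the true mean approaches the NB noise floor", {
  # a predictor equal to the generating mean cannot beat process noise:
  # RMSE -> sqrt(E[mu + mu^2/theta]) on large samples
  m <- seal_model()
  d <- sim_floe_table(20000, seed = 19)
  mu <- predict(m, d)
  floor_ <- sqrt(mean(mu + mu^2 / m$theta))
  got <- error_metrics(d$seal_count, mu, scheme = "per_floe_rmse")$rmse
  expect_lt(abs(got - floor_) / floor_, 0.10)
})

test_that("scene report aggregates per scene with an overall row", {
  d <- sim_floe_table(600, seed = 14)
  d$scene_id <- rep(1:3, each = 200)
  mu <- predict(seal_model(), d)
  rp <- scene_report(d, mu)
  expect_equal(nrow(rp), 4)
  expect_equal(rp$observed[4], sum(d$seal_count))
  expect_equal(rp$predicted[4], sum(mu), tolerance = 1e-12)
  expect_equal(rp$rmse[4], mean(rp$rmse[1:3]), tolerance = 1e-12)
})
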