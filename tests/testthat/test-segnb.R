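test_that("NB GLM mean-matching, rank checks, and the Poisson limit", {
  f <- fit_nb_glm(matrix(1, 30, 1), rep(2L, 30))
  expect_equal(unname(f$coefficients), log(2), tolerance = 1e-8)
  expect_equal(unname(f$fitted.values[1]), 2, tolerance = 1e-8)

  expect_error(fit_nb_glm(cbind(1, x = 1:10, x2 = 2 * (1:10)),
                          rpois(10, 2)),
               "collinear")
  expect_error(fit_nb_glm(matrix(1, 5, 1), c(1, 2, -1, 0, 0)),
               "non-negative")

  set.seed(1)
  y <- rpois(5000, 3)
  f2 <- fit_nb_glm(matrix(1, 5000, 1), y)
  expect_gt(as.numeric(f2$theta), 10)
})

test_that("NB GLM recovers known parameters within sampling error", {
  set.seed(42)
  hits <- 0
  for (r in 1:5) {
    n <- 1e4
    x <- runif(n, 0, 2)
    mu <- exp(0.3 + 0.8 * x)
    y <- rnbinom(n, size = 1.5, mu = mu)
    f <- fit_nb_glm(cbind(1, x = x), y)
    ok <- abs(f$coefficients - c(0.3, 0.8)) < 3.5 * f$se
    if (all(ok)) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("hinge basis arithmetic and guards", {
  expect_equal(unname(hinge(49.84, 49.84)[1, 1]), 0)
  expect_equal(unname(hinge(100, 49.84)[1, 1]), 50.16)
  expect_error(hinge(1:10, c(5, 3)), "strictly increasing")
  expect_error(hinge(1:10, 99), "outside")
  # continuity of the hinge predictor across the breakpoint
  x <- seq(49, 51, by = 1e-4)
  h <- hinge(x, 50)
  expect_lt(max(abs(diff(h[, 1]))), 2e-4)
})

test_that("npsi = 0 reproduces the plain NB GLM exactly", {
  d <- sim_floe_table(1500, seed = 4)
  s0 <- segnb(seal_count ~ area + sic_750, d, npsi = 0)
  g <- fit_nb_glm(cbind(1, area = d$area, sic = d$sic_750), d$seal_count)
  expect_equal(unname(s0$coefficients), unname(g$coefficients),
               tolerance = 1e-10)
  expect_equal(s0$loglik, g$loglik, tolerance = 1e-10)
  expect_equal(s0$theta, as.numeric(g$theta), tolerance = 1e-8)
})

test_that("a noiseless Gaussian kink is recovered essentially exactly", {
  x <- seq(0, 100, by = 0.5)
  y <- 1 + 0.5 * x - 0.3 * pmax(0, x - 50)
  d <- data.frame(x = x, y = y)
  f <- segnb(y ~ x, d, seg = "x", npsi = 1, family = "gaussian")
  expect_lt(abs(f$psi - 50), 1e-4)
  expect_equal(unname(f$slopes), c(0.5, 0.2), tolerance = 1e-6)
})

test_that("iterative breakpoint estimate matches the profile-grid oracle", {
  for (s in 1:3) {
    d <- sim_kinked_counts(300, seed = s)
    f <- segnb(y ~ x, d, seg = "x", npsi = 1)
    o <- profile_psi_grid(d)
    step <- max(diff(o$grid))
    expect_lt(abs(f$psi - o$psi), step + 1e-9)
  }
})

test_that("profile log-likelihood is non-decreasing over accepted iterations", {
  d <- sim_kinked_counts(2000, seed = 9, theta = 0.8)
  f <- segnb(y ~ x, d, seg = "x", npsi = 1)
  ll <- f$trace[, "loglik"]
  expect_true(all(diff(ll) >= -1e-7 * (abs(ll[-1]) + 1)))
  expect_true(f$converged)
})

test_that("coefficients rescale exactly and breakpoints are equivariant", {
  d <- sim_floe_table(3000, seed = 6)
  f1 <- segnb(seal_count ~ area + rough_1000 + sic_750, d, npsi = 1)
  d2 <- d
  d2$rough_1000 <- d2$rough_1000 * 10
  f2 <- segnb(seal_count ~ area + rough_1000 + sic_750, d2, npsi = 1,
              psi = f1$psi)
  expect_equal(unname(f2$coefficients["rough_1000"]),
               unname(f1$coefficients["rough_1000"]) / 10,
               tolerance = 1e-4)
  # scaling the segmented covariate scales the breakpoint
  d3 <- d
  d3$area <- d3$area * 2
  f3 <- segnb(seal_count ~ area + rough_1000 + sic_750, d3, npsi = 1,
              psi = f1$psi * 2)
  expect_equal(f3$psi, f1$psi * 2, tolerance = 1e-3)
  expect_equal(unname(f3$slopes), unname(f1$slopes) / 2, tolerance = 1e-3)
})

test_that("the segmented model beats the unsegmented one on kinked data", {
  d <- sim_kinked_counts(4000, seed = 13, theta = 1)
  f1 <- segnb(y ~ x, d, seg = "x", npsi = 1)
  f0 <- segnb(y ~ x, d, seg = "x", npsi = 0)
  expect_lt(f1$aic, f0$aic)
})

test_that("fit accessors, summary and serialization are coherent", {
  d <- sim_floe_table(2500, seed = 10)
  f <- segnb(seal_count ~ area + rough_1000 + sic_750 + colony_dist, d,
             npsi = 2)
  expect_equal(f$aic, 2 * f$df - 2 * f$loglik)
  expect_true(all(is.finite(f$se_psi)) && all(f$se_psi > 0))
  qs <- quantile(d$area, f$control$quantiles)
  expect_true(all(f$psi > qs[1] & f$psi < qs[2]))
  expect_lt(f$psi[1], f$psi[2])

  s <- summary(f)
  expect_true(all(is.na(s$coefficients[grep("^U", rownames(s$coefficients)),
                                       "Pr(>|z|)"])))
  expect_false(anyNA(s$coefficients[c("(Intercept)", "area"), "Pr(>|z|)"]))

  # residuals and simulate are on the right scale
  r <- residuals(f, "pearson")
  expect_equal(length(r), nrow(d))
  sim <- simulate(f, nsim = 2, seed = 1)
  expect_true(all(sim >= 0) && all(sim == round(sim)))

  tmp <- tempfile(fileext = ".json")
  write_model_json(f, tmp)
  f2 <- read_model_json(tmp)
  nd <- d[1:50, ]
  expect_equal(predict(f2, nd), predict(f, nd), tolerance = 1e-10)

  expect_error(predict(f, nd[, setdiff(names(nd), "sic_750")]), "sic_750")
})

test_that("degenerate inputs are rejected with useful errors", {
  d <- sim_kinked_counts(100, seed = 2)
  d$x <- round(d$x / 10)  # too few distinct values for 2 breakpoints
  expect_error(segnb(y ~ x, d, seg = "x", npsi = 2), "distinct values")
  expect_error(segnb(y ~ x, sim_kinked_counts(100, seed = 2), seg = "x",
                     npsi = 3), "npsi")
})
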