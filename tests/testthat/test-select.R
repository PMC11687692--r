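# Step-function response: one informative predictor among noise.
sim_step <- function(n, seed, noise = 0.1) {
  set.seed(seed)
  x <- data.frame(x1 = runif(n), x2 = runif(n), x3 = runif(n))
  y <- 3 * (x$x1 > 0.5) + rnorm(n, 0, noise)
  list(x = x, y = y)
}

test_that("the forest learns a step signal and is seed-deterministic", {
  d <- sim_step(300, seed = 1)
  f <- fit_forest(d$x, d$y, ntree = 150, seed = 5)
  expect_gt(f$oob["r2"], 0.9)
  f2 <- fit_forest(d$x, d$y, ntree = 150, seed = 5)
  expect_identical(f$oob_pred, f2$oob_pred)
  expect_error(fit_forest(d$x[1:5, ], d$y[1:5]), "at least 10")
})

test_that("grid search is exhaustive with deterministic tie-breaking", {
  d <- sim_step(200, seed = 2)
  g1 <- forest_grid_search(d$x, d$y, ntree_grid = 50, mtry_grid = 2,
                           seed = 1)
  expect_equal(g1$best_ntree, 50)
  expect_equal(g1$best_mtry, 2)
  g <- forest_grid_search(d$x, d$y, ntree_grid = c(50, 100),
                          mtry_grid = c(1, 2, 3), seed = 1)
  expect_equal(nrow(g$table), 6)
  expect_error(forest_grid_search(d$x, d$y, integer(0), 1), "empty")
})

test_that("CPFI: informative predictor dominates; null predictor is null", {
  d <- sim_step(300, seed = 3)
  f <- fit_forest(d$x, d$y, ntree = 150, seed = 7)
  imp <- cpfi(f, n_perm = 10, seed = 11)
  expect_equal(imp$predictor[1], "x1")
  # noise predictors: importance within Monte-Carlo error of zero
  for (j in which(imp$predictor != "x1")) {
    mc_se <- imp$sd[j] / sqrt(attr(imp, "n_perm"))
    # forests exploit noise in deep splits, so null importance carries a
    # small positive bias; bound by MC error or a sliver of the signal
    expect_lt(abs(imp$importance[j]),
              max(4 * mc_se, 0.005 * imp$importance[1]))
  }
  # cond_threshold above 1 disables conditioning entirely
  imp2 <- cpfi(f, cond_threshold = 1.01, n_perm = 5, seed = 11)
  expect_true(all(imp2$n_conditioners == 0))
  expect_identical(cpfi(f, n_perm = 5, seed = 13),
                   cpfi(f, n_perm = 5, seed = 13))
})

test_that("conditioning shrinks the importance of a correlated duplicate", {
  hits <- 0
  for (r in 1:10) {
    set.seed(100 + r)
    n <- 300
    x1 <- runif(n)
    x <- data.frame(x1 = x1, x2 = x1 + rnorm(n, 0, 0.05),
                    x3 = runif(n))
    y <- 2 * x1 + rnorm(n, 0, 0.1)
    f <- fit_forest(x, y, ntree = 100, seed = r)
    cond <- cpfi(f, cond_threshold = 0.2, n_perm = 5, seed = r)
    marg <- cpfi(f, cond_threshold = 1.01, n_perm = 5, seed = r)
    ci <- cond$importance[cond$predictor == "x2"]
    mi <- marg$importance[marg$predictor == "x2"]
    if (ci < mi) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("all-subsets AIC ranking is exhaustive and correctly ordered", {
  d <- sim_floe_table(2500, seed = 21)
  tb <- dredge_aic(d, optional_terms = c("rough_1000", "sic_750",
                                         "colony_dist"),
                   npsi = 1)
  expect_equal(nrow(tb), 8)
  expect_true(all(grepl("^area", tb$terms)))
  ok <- tb$converged
  expect_equal(tb$delta_aic[ok][1], 0)
  expect_true(all(diff(tb$aic[ok]) >= 0))
  expect_equal(tb$rank[ok][1], 1L)
})

test_that("the near-best AIC set contains the generating covariates", {
  # selection consistency, scaled down: among active (rough, sic) and inert
  # (perimeter, slope) candidates, the generating pair must appear in the
  # delta-AIC < 2 set in a majority of replicates
  hits <- 0
  for (r in 1:5) {
    d <- sim_floe_table(2500, seed = 40 + r)
    full <- segnb(seal_count ~ area + rough_1000 + sic_750, d, npsi = 1)
    tb <- dredge_aic(d, optional_terms = c("rough_1000", "sic_750",
                                           "perimeter", "slope_1000"),
                     npsi = 1, psi_init = full$psi)
    near <- tb$terms[tb$converged & tb$delta_aic < 2]
    if (any(grepl("rough_1000", near) & grepl("sic_750", near)))
      hits <- hits + 1
  }
  expect_gte(hits, 3)
})

test_that("cross-validation folds are balanced, seeded, and scene-aware", {
  d <- sim_floe_table(1001, seed = 30)
  cv <- cross_validate(list(c("rough_1000"), c("rough_1000", "sic_750")),
                       d, scheme = "kfold", k = 5, npsi = 1, seed = 3)
  expect_equal(sort(as.integer(table(cv$folds))), c(200, 200, 200, 200, 201))
  cv2 <- cross_validate(list(c("rough_1000")), d, scheme = "kfold", k = 5,
                        npsi = 1, seed = 3)
  expect_identical(cv$folds, cv2$folds)
  expect_true(cv$best %in% seq_len(2))
  # leave-one-scene-out: every scene held out exactly once
  d$scene_id <- rep(1:3, length.out = nrow(d))
  cvs <- cross_validate(list(c("rough_1000")), d, scheme = "loso", npsi = 1)
  expect_equal(cvs$k, 3)
  expect_setequal(unique(cvs$folds), 1:3)
  d$scene_id <- 1L
  expect_error(cross_validate(list("rough_1000"), d, scheme = "loso"),
               "one scene")
})
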