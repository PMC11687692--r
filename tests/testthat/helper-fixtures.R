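# Shared fixture builders (everything generated in code; no stored data).

# Tiny raster bundle with a single centred circular floe and configurable
# surrounding ice. `ice_fun(x, y)` decides ice for non-floe pixels.
one_floe_scene <- function(extent = 3000, px = 5, floe_area = 400,
                           ice_fun = function(x, y) FALSE) {
  n <- extent / px
  cx <- (seq_len(n) - 0.5) * px
  cy <- (seq_len(n) - 0.5) * px
  X <- matrix(cx, n, n, byrow = TRUE)
  Y <- matrix(cy, n, n)
  r0 <- sqrt(floe_area / pi)
  d2 <- (X - extent / 2)^2 + (Y - extent / 2)^2
  labels <- matrix(0L, n, n)
  labels[d2 <= r0^2] <- 1L
  ice <- matrix(as.integer(ice_fun(X, Y)), n, n)
  ice[labels == 1L] <- 1L
  rast <- scene_rasters(ice = ice, labels = labels,
                        bathy = matrix(-400, n, n), pixel_size = px)
  floe <- data.frame(floe_id = 1L, x = extent / 2, y = extent / 2,
                     area = floe_area)
  list(rasters = rast, floe = floe, extent = extent, px = px, r0 = r0)
}

# NB2 data from a log-linear model with an optional single kink; used by the
# segmented-fit tests.
sim_kinked_counts <- function(n, b0 = 0.5, b1 = 0.08, dslope = -0.07,
                              psi = 50, theta = 1, xmax = 100, seed = 1) {
  set.seed(seed)
  x <- runif(n, 0, xmax)
  eta <- b0 + b1 * x + if (!is.null(psi)) dslope * pmax(0, x - psi) else 0
  y <- rnbinom(n, size = theta, mu = exp(eta))
  data.frame(x = x, y = y)
}

# Brute-force profile-likelihood grid search for one breakpoint: the
# independent oracle for the iterative estimator.
profile_psi_grid <- function(d, window = c(0.05, 0.95)) {
  xs <- sort(unique(d$x))
  mids <- (xs[-1] + xs[-length(xs)]) / 2
  qs <- quantile(d$x, window)
  mids <- mids[mids >= qs[1] & mids <= qs[2]]
  th <- NULL
  ll <- vapply(mids, function(p) {
    f <- tryCatch(fit_nb_glm(cbind(1, x = d$x, u = pmax(0, d$x - p)), d$y,
                             theta = th),
                  error = function(e) NULL)
    if (is.null(f)) return(-Inf)
    th <<- f$theta
    f$loglik
  }, numeric(1))
  list(psi = mids[which.max(ll)], grid = mids, loglik = ll)
}
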