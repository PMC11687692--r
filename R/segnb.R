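#' Hinge (broken-stick) basis
#'
#' Builds the hinge columns \eqn{h(x, \psi) = \max(0, x - \psi)} used to encode
#' slope changes at breakpoints while keeping the predictor continuous.
#'
#' @param x numeric vector (the segmented covariate).
#' @param psi numeric vector of strictly increasing breakpoints; each must lie
#'   within \code{range(x)}.
#' @return numeric matrix with one column per breakpoint, named
#'   \code{U1, U2, ...}.
#' @export
hinge <- function(x, psi) {
  if (length(psi) == 0L) return(matrix(numeric(0), nrow = length(x), ncol = 0))
  if (is.unsorted(psi, strictly = TRUE))
    stop("breakpoints must be strictly increasing")
  r <- range(x)
  if (length(x) > 1 && any(psi < r[1] | psi > r[2]))
    stop("breakpoint(s) outside the observed range of x: ",
         paste(format(psi[psi < r[1] | psi > r[2]]), collapse = ", "))
  m <- matrix(vapply(psi, function(p) pmax(0, x - p), numeric(length(x))),
              nrow = length(x))
  colnames(m) <- paste0("U", seq_along(psi))
  m
}

#' Control parameters for segmented model fitting
#'
#' @param tol convergence tolerance on the breakpoint update, relative to the
#'   range of the segmented covariate.
#' @param maxit maximum outer (breakpoint) iterations.
#' @param quantiles two probabilities bounding the breakpoint search window;
#'   estimates are constrained to these quantiles of the segmented covariate.
#' @param n_starts number of quantile-grid starting points screened when no
#'   initial breakpoints are supplied.
#' @param n_keep number of screened starts from which the full iteration is
#'   run (best final log-likelihood wins).
#' @param min_sep minimum separation between adjacent breakpoints, as a
#'   fraction of the search window; estimates closer than this trigger an
#'   error suggesting fewer breakpoints.
#' @param max_halving maximum number of step-halvings per iteration when the
#'   working log-likelihood decreases.
#' @param polish after convergence, re-evaluate the profile log-likelihood at
#'   candidate midpoints near each breakpoint and keep the best (guards
#'   against settling one discrete basin short on small samples); skipped
#'   when the segmented covariate has more than 5000 distinct values.
#' @param polish_window how many candidate midpoints on each side of an
#'   estimate the polish examines.
#' @param screen_n above this sample size, start screening runs on a
#'   deterministic x-stratified subsample of this many rows.
#' @return A list of class \code{"segnb_control"}.
#' @export
segnb_control <- function(tol = 1e-6, maxit = 30, quantiles = c(0.05, 0.95),
                          n_starts = 9, n_keep = 2, min_sep = 0.02,
                          max_halving = 5, polish = TRUE,
                          polish_window = 10L, screen_n = 10000L) {
  stopifnot(tol > 0, maxit >= 1, length(quantiles) == 2,
            quantiles[1] < quantiles[2], n_keep >= 1, min_sep >= 0,
            screen_n >= 100)
  structure(list(tol = tol, maxit = maxit, quantiles = quantiles,
                 n_starts = n_starts, n_keep = n_keep, min_sep = min_sep,
                 max_halving = max_halving, polish = polish,
                 polish_window = as.integer(polish_window),
                 screen_n = screen_n),
            class = "segnb_control")
}

#' Segmented negative binomial regression for floe-level seal counts
#'
#' Fits a count GLM whose log-mean is piecewise linear in one covariate
#' (typically ice-floe area), with the breakpoint locations estimated from the
#' data. The mean model is
#' \deqn{\log \mu = X\beta + \beta_x x + \sum_k \delta_k \max(0, x - \psi_k),}
#' so \eqn{\delta_k} are slope \emph{increments}: the slope in segment
#' \eqn{k+1} is \eqn{\beta_x + \delta_1 + \dots + \delta_k}. Counts are NB2
#' (\code{family = "nb2"}, \eqn{\mathrm{Var} = \mu + \mu^2/\theta}); a Gaussian
#' identity-link family is available for diagnostics and exact-recovery
#' checks on continuous responses.
#'
#' Breakpoints are estimated by iterative linearization: at the current
#' \eqn{\psi} the model is refit with the hinge columns
#' \eqn{U_k = \max(0, x-\psi_k)} plus the auxiliary columns
#' \eqn{V_k = -1\{x > \psi_k\}}, and each breakpoint is updated by
#' \eqn{\psi_k \leftarrow \psi_k + \hat\gamma_k/\hat\delta_k} where
#' \eqn{\hat\gamma_k} is the \eqn{V_k} coefficient, with step-halving if the
#' working log-likelihood decreases, until the relative change in \eqn{\psi}
#' falls below \code{control$tol}. Breakpoint standard errors use the delta
#' method on the \eqn{\gamma/\delta} ratio at convergence. Estimates are
#' constrained to the quantile window in \code{control}; with no starting
#' values a quantile grid of candidates is screened by profile log-likelihood
#' and the iteration is run from the best few.
#'
#' @param formula model formula for the linear (unsegmented) part, e.g.
#'   \code{seal_count ~ area + rough_1000 + sic_750 + colony_dist}. The
#'   segmented covariate must appear as a main effect.
#' @param data data frame containing all model variables.
#' @param seg name of the covariate receiving breakpoints (default
#'   \code{"area"}).
#' @param npsi number of breakpoints, 0, 1 or 2. \code{npsi = 0} reduces to an
#'   ordinary NB2 GLM.
#' @param psi optional numeric vector of starting breakpoints (length
#'   \code{npsi}); default is quantile-grid multi-start.
#' @param family \code{"nb2"} (default) or \code{"gaussian"}.
#' @param control a \code{\link{segnb_control}} list.
#'
#' @return An object of class \code{"segnb"} with methods \code{print},
#'   \code{summary}, \code{coef}, \code{predict}, \code{simulate},
#'   \code{residuals}, \code{fitted}, \code{logLik} and \code{plot}. Key
#'   fields: \code{coefficients} (base terms then hinge increments
#'   \code{U1.<seg>}, ...), \code{psi} and \code{se_psi}, \code{slopes}
#'   (derived per-segment slopes), \code{theta}, \code{loglik}, \code{aic}
#'   (with \eqn{k} counting \eqn{\theta} and the breakpoints), \code{trace}
#'   (breakpoint path), \code{converged}.
#'
#' @examples
#' d <- sim_floe_table(2000, seed = 1)
#' fit <- segnb(seal_count ~ area + rough_1000 + sic_750 + colony_dist,
#'              data = d, seg = "area", npsi = 2)
#' summary(fit)
#' @export
segnb <- function(formula, data, seg = "area", npsi = 2, psi = NULL,
                  family = c("nb2", "gaussian"),
                  control = segnb_control()) {
  family <- match.arg(family)
  if (!npsi %in% 0:2) stop("npsi must be 0, 1 or 2")
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (npsi > 0 && !seg %in% colnames(X))
    stop("segmented covariate '", seg, "' must be a main effect in the formula")
  xseg <- if (npsi > 0) X[, seg] else NULL

  if (npsi > 0) {
    nd <- length(unique(xseg))
    if (nd < 20 * (npsi + 1))
      stop("need at least ", 20 * (npsi + 1), " distinct values of '", seg,
           "' for ", npsi, " breakpoint(s); have ", nd)
    if (!is.null(psi)) {
      if (length(psi) != npsi) stop("psi must have length npsi = ", npsi)
      if (is.unsorted(psi, strictly = TRUE))
        stop("starting breakpoints must be strictly increasing")
    }
  }

  base_fit_fun <- if (family == "nb2") {
    function(M, th, eta, tol = 1e-8) fit_nb_glm(M, y, theta = th,
                                                etastart = eta, tol = tol)
  } else {
    function(M, th, eta, tol = 1e-8) .gaussian_fit(M, y)
  }

  if (npsi == 0L) {
    f <- base_fit_fun(X, NULL, NULL)
    return(.as_segnb(f, X = X, psi = numeric(0), se_psi = numeric(0),
                     seg = seg, formula = formula, mf = mf, family = family,
                     trace = NULL, iter = f$iter, converged = f$converged,
                     call = match.call(), control = control))
  }

  qs <- stats::quantile(xseg, control$quantiles, names = FALSE)
  starts <- if (!is.null(psi)) list(.clip_psi(psi, qs)) else
    .screen_starts(X, y, xseg, npsi, qs, control, base_fit_fun)

  best <- NULL
  errors <- character(0)
  for (p0 in starts) {
    res <- tryCatch(
      .muggeo(X, y, xseg, p0, qs, control, base_fit_fun),
      error = function(e) conditionMessage(e))
    if (is.character(res)) { errors <- c(errors, res); next }
    if (is.null(best) || res$loglik > best$loglik) best <- res
  }
  if (is.null(best))
    stop("segmented fit failed from all starting values:\n  ",
         paste(unique(errors), collapse = "\n  "))

  sep_tol <- control$min_sep * diff(qs)
  if (npsi > 1 && any(diff(best$psi) < sep_tol))
    stop("breakpoints collapsed (", paste(format(best$psi), collapse = ", "),
         "); try fewer breakpoints")

  .as_segnb(best$fit, X = X, psi = best$psi, se_psi = best$se_psi,
            seg = seg, formula = formula, mf = mf, family = family,
            trace = best$trace, iter = best$iter, converged = best$converged,
            call = match.call(), control = control)
}

## --- internals ---------------------------------------------------------

.clip_psi <- function(psi, qs) pmin(pmax(psi, qs[1]), qs[2])

## Screen quantile-grid candidate breakpoints by one profile (hinge-only) fit
## each; return the n_keep best as Muggeo starting points. On large data the
## screening fits run on a deterministic x-stratified subsample: start
## selection needs only the coarse shape of the profile.
.screen_starts <- function(X, y, xseg, npsi, qs, control, fit_fun) {
  n <- length(y)
  if (n > control$screen_n) {
    idx <- order(xseg)[round(seq(1, n, length.out = control$screen_n))]
    Xs <- X[idx, , drop = FALSE]
    ys <- y[idx]
    xs <- xseg[idx]
    sub_fit <- if (identical(environment(fit_fun)$family, "gaussian"))
      function(M, th, eta, tol = 1e-8) .gaussian_fit(M, ys)
    else
      function(M, th, eta, tol = 1e-8) fit_nb_glm(M, ys, theta = th,
                                                  etastart = eta, tol = tol)
    return(.screen_starts_impl(Xs, ys, xs, npsi, qs, control, sub_fit))
  }
  .screen_starts_impl(X, y, xseg, npsi, qs, control, fit_fun)
}

.screen_starts_impl <- function(X, y, xseg, npsi, qs, control, fit_fun) {
  if (npsi == 1L) {
    probs <- seq(0.1, 0.9, length.out = max(3, control$n_starts %/% 2 + 1))
    cand <- lapply(stats::quantile(xseg, probs, names = FALSE), function(p)
      .clip_psi(p, qs))
  } else {
    k <- max(3, ceiling(sqrt(control$n_starts)))
    g <- stats::quantile(xseg, seq(0.15, 0.93, length.out = k + 1),
                         names = FALSE)
    cand <- list()
    for (i in seq_len(length(g) - 1)) for (j in seq(i + 1, length(g)))
      cand[[length(cand) + 1L]] <- .clip_psi(c(g[i], g[j]), qs)
  }
  ll <- vapply(cand, function(p) {
    f <- tryCatch(fit_fun(cbind(X, hinge(xseg, p)), NULL, NULL, tol = 1e-4),
                  error = function(e) NULL)
    if (is.null(f)) -Inf else f$loglik
  }, numeric(1))
  keep <- order(ll, decreasing = TRUE)[seq_len(min(control$n_keep,
                                                   sum(is.finite(ll))))]
  if (length(keep) == 0L) stop("no feasible starting breakpoints found")
  cand[keep]
}

.muggeo <- function(X, y, xseg, psi, qs, control, fit_fun) {
  K <- length(psi)
  p0 <- ncol(X)
  th <- NULL; eta <- NULL
  rng <- diff(range(xseg))
  ## intermediate fits run at a looser likelihood tolerance: the breakpoint
  ## path only needs fit accuracy comparable to its own step size
  prof <- function(p, tol = 1e-6)
    fit_fun(cbind(X, hinge(xseg, p)), th, eta, tol = tol)
  f0 <- prof(psi)
  ll_prof <- f0$loglik
  th <- f0$theta; eta <- f0$linear.predictors
  trace <- matrix(c(psi, ll_prof), nrow = 1,
                  dimnames = list(NULL, c(paste0("psi", seq_len(K)), "loglik")))
  converged <- FALSE
  it <- 0L
  for (it in seq_len(control$maxit)) {
    ## working fit with the linearization columns V_k = -1{x > psi_k}
    U <- hinge(xseg, psi)
    V <- vapply(psi, function(p) -as.numeric(xseg > p), numeric(length(xseg)))
    colnames(V) <- paste0("V", seq_len(K))
    f <- fit_fun(cbind(X, U, V), th, eta, tol = 1e-6)
    th <- f$theta; eta <- f$linear.predictors
    bU <- f$coefficients[p0 + seq_len(K)]
    gV <- f$coefficients[p0 + K + seq_len(K)]
    step <- gV / bU
    step[!is.finite(step)] <- 0

    ## backtracking: accept the proposal only if the profile log-likelihood
    ## does not decrease, halving the step otherwise
    accepted <- FALSE
    for (h in 0:control$max_halving) {
      psi_new <- sort(.clip_psi(psi + step, qs))
      fp <- tryCatch(prof(psi_new), error = function(e) NULL)
      if (!is.null(fp) && fp$loglik >= ll_prof - 1e-10 * (abs(ll_prof) + 1)) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) { converged <- TRUE; break }  # no uphill move left
    dpsi <- max(abs(psi_new - psi)) / rng
    dll <- fp$loglik - ll_prof
    psi <- psi_new
    ll_prof <- fp$loglik
    th <- fp$theta; eta <- fp$linear.predictors
    trace <- rbind(trace, c(psi, ll_prof))
    if (dpsi < control$tol ||
        (it >= 3L && dll < 1e-9 * (abs(ll_prof) + 1))) {
      converged <- TRUE
      break
    }
  }

  ## discrete local polish: the profile log-likelihood is jagged at the
  ## granularity of the observed covariate, and the linearization can settle
  ## one basin short on small samples; re-evaluate the profile at candidate
  ## midpoints near each estimate and keep the best. Skipped when the
  ## covariate is dense enough that the profile is effectively smooth.
  xs_u <- sort(unique(xseg))
  if (control$polish && length(xs_u) <= 5000) {
    mids <- (xs_u[-1] + xs_u[-length(xs_u)]) / 2
    mids <- mids[mids >= qs[1] & mids <= qs[2]]
    for (pass in 1:3) {
      improved <- FALSE
      for (k in seq_len(K)) {
        near <- order(abs(mids - psi[k]))[
          seq_len(min(2 * control$polish_window + 1, length(mids)))]
        for (cand in mids[near]) {
          p_try <- psi; p_try[k] <- cand
          if (K > 1 && is.unsorted(p_try, strictly = TRUE)) next
          fp <- tryCatch(prof(p_try), error = function(e) NULL)
          if (!is.null(fp) && fp$loglik > ll_prof + 1e-10) {
            psi <- p_try
            ll_prof <- fp$loglik
            th <- fp$theta; eta <- fp$linear.predictors
            improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
  }

  ## SE(psi_k) = SE(gamma_k)/|delta_k| from the V-augmented fit at convergence
  U <- hinge(xseg, psi)
  V <- vapply(psi, function(p) -as.numeric(xseg > p), numeric(length(xseg)))
  colnames(V) <- paste0("V", seq_len(K))
  faux <- fit_fun(cbind(X, U, V), th, eta)
  se_psi <- faux$se[p0 + K + seq_len(K)] /
    abs(faux$coefficients[p0 + seq_len(K)])
  names(se_psi) <- paste0("psi", seq_len(K))

  fit <- fit_fun(cbind(X, U), th, eta)
  if (!fit$converged) stop("inner GLM did not converge at final breakpoints")
  list(psi = psi, se_psi = se_psi, fit = fit, loglik = fit$loglik,
       trace = trace, iter = it, converged = converged)
}

## Gaussian identity-link fit with the same return contract as fit_nb_glm.
.gaussian_fit <- function(X, y) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("design matrix is rank deficient")
  f <- stats::lm.fit(X, y)
  n <- length(y)
  res <- f$residuals
  s2 <- sum(res^2) / n  # ML variance
  ll <- sum(stats::dnorm(y, y - res, sqrt(max(s2, 1e-300)), log = TRUE))
  R <- qr.R(qr(X))
  vc <- tryCatch(chol2inv(R) * s2 * n / max(1, n - ncol(X)),
                 error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  dimnames(vc) <- list(colnames(X), colnames(X))
  k <- ncol(X) + 1L
  structure(list(
    coefficients = structure(f$coefficients, names = colnames(X)),
    se = sqrt(diag(vc)), vcov = vc,
    theta = NA_real_, se_theta = NA_real_,
    loglik = ll, aic = 2 * k - 2 * ll, df = k,
    fitted.values = y - res, linear.predictors = y - res,
    weights = rep(1, n), iter = 1L, converged = TRUE, nobs = n
  ), class = "nb_glm_fit")
}

.as_segnb <- function(fit, X, psi, se_psi, seg, formula, mf, family,
                      trace, iter, converged, call, control) {
  K <- length(psi)
  co <- fit$coefficients
  if (K > 0)
    names(co)[ncol(X) + seq_len(K)] <- paste0("U", seq_len(K), ".", seg)
  names(fit$se) <- names(co)
  slopes <- if (K > 0) {
    s <- cumsum(c(co[seg], co[ncol(X) + seq_len(K)]))
    names(s) <- paste0("segment", seq_len(K + 1))
    s
  } else NULL
  k <- fit$df + K  # breakpoints count as parameters
  structure(list(
    call = call, formula = formula, seg = seg, family = family,
    coefficients = co, se = fit$se, vcov = fit$vcov,
    theta = as.numeric(fit$theta), se_theta = as.numeric(fit$se_theta),
    psi = unname(psi), se_psi = unname(se_psi), slopes = slopes,
    loglik = fit$loglik, aic = 2 * k - 2 * fit$loglik, df = k,
    fitted.values = fit$fitted.values,
    linear.predictors = fit$linear.predictors,
    model = mf, y = stats::model.response(mf), nobs = fit$nobs,
    iter = iter, converged = converged, trace = trace, control = control
  ), class = "segnb")
}
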