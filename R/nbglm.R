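#' Negative binomial (NB2) GLM on a design matrix
#'
#' Maximum-likelihood fit of a log-link NB2 regression, \eqn{\mathrm{Var}(y) =
#' \mu + \mu^2/\theta}, by alternating iteratively reweighted least squares for
#' the regression coefficients with Newton maximum-likelihood updates for the
#' dispersion \eqn{\theta} (the same alternation \code{MASS::glm.nb} uses, on a
#' bare design matrix so it can sit inside the breakpoint-estimation loop
#' without formula overhead).
#'
#' @param x numeric design matrix (include the intercept column yourself).
#' @param y non-negative integer response vector, \code{length(y) == nrow(x)}.
#' @param theta optional starting value for the dispersion.
#' @param etastart optional starting linear predictor (warm start).
#' @param tol relative log-likelihood convergence tolerance for the outer
#'   beta/theta alternation.
#' @param maxit maximum outer alternations.
#'
#' @return An object of class \code{"nb_glm_fit"}: a list with
#'   \code{coefficients}, \code{se}, \code{vcov}, \code{theta},
#'   \code{se_theta}, \code{loglik}, \code{aic} (with \eqn{k} counting
#'   \eqn{\theta}), \code{fitted.values}, \code{linear.predictors},
#'   \code{weights} (final IRLS weights), \code{iter}, \code{converged},
#'   \code{df} and \code{nobs}.
#'
#' @details Coefficient standard errors come from the inverse Fisher
#'   information \eqn{(X^T W X)^{-1}} at the MLE; the dispersion standard error
#'   from the observed information of the profile theta likelihood (as returned
#'   by \code{MASS::theta.ml}). The two blocks are orthogonal for NB2, so the
#'   joint observed information is block-diagonal at the MLE.
#'
#' @export
fit_nb_glm <- function(x, y, theta = NULL, etastart = NULL,
                       tol = 1e-8, maxit = 25) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (nrow(x) != length(y))
    stop("nrow(x) [", nrow(x), "] != length(y) [", length(y), "]")
  if (any(y < 0) || any(y != round(y)))
    stop("y must be non-negative integers")
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[seq(qx$rank + 1L, ncol(x))]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }

  th <- theta
  if (is.null(th)) {
    mu0 <- rep(mean(y) + 0.1, length(y))
    th <- .safe_theta_ml(y, mu0, fallback = 1)
  }
  ll_old <- -Inf
  converged <- FALSE
  fit <- NULL
  it <- 0L
  for (it in seq_len(maxit)) {
    fit <- suppressWarnings(stats::glm.fit(
      x, y, family = MASS::negative.binomial(th), etastart = etastart,
      control = stats::glm.control(epsilon = 1e-8, maxit = 50)))
    mu <- fit$fitted.values
    th <- .safe_theta_ml(y, mu, fallback = th,
                         warm = if (it > 1 || !is.null(theta)) th)
    ll <- .nb_loglik(y, mu, th)
    etastart <- fit$linear.predictors
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  mu <- fit$fitted.values
  ll <- .nb_loglik(y, mu, th)
  w <- fit$weights
  xw <- x * sqrt(w)
  vc <- tryCatch(chol2inv(chol(crossprod(xw))),
                 error = function(e) matrix(NA_real_, ncol(x), ncol(x)))
  dimnames(vc) <- list(colnames(x), colnames(x))
  beta <- fit$coefficients
  names(beta) <- colnames(x)
  k <- ncol(x) + 1L  # + theta
  structure(list(
    coefficients = beta,
    se = sqrt(diag(vc)),
    vcov = vc,
    theta = th,
    se_theta = attr(th, "SE") %||% NA_real_,
    loglik = ll,
    aic = 2 * k - 2 * ll,
    df = k,
    fitted.values = mu,
    linear.predictors = fit$linear.predictors,
    weights = w,
    iter = it,
    converged = converged && fit$converged,
    nobs = length(y)
  ), class = "nb_glm_fit")
}

#' @export
print.nb_glm_fit <- function(x, digits = 4, ...) {
  cat("Negative binomial (NB2) GLM, log link\n")
  print(round(rbind(estimate = x$coefficients, se = x$se), digits))
  cat("theta:", format(as.numeric(x$theta), digits = digits),
      "  logLik:", format(x$loglik, digits = digits + 2),
      "  AIC:", format(x$aic, digits = digits + 2), "\n")
  if (!x$converged) cat("WARNING: fit did not converge\n")
  invisible(x)
}

#' @export
logLik.nb_glm_fit <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$nobs,
            class = "logLik")
}

.nb_loglik <- function(y, mu, theta) {
  sum(stats::dnbinom(y, size = as.numeric(theta), mu = mu, log = TRUE))
}

## Newton ML update for the NB2 dispersion with a warm start; the same score
## and observed information as MASS::theta.ml, but starting from the previous
## alternation's estimate instead of a moment estimator, which cuts the
## digamma/trigamma sweeps to one or two per alternation.
.theta_newton <- function(y, mu, t0, limit = 15, eps = 1e-8) {
  n <- length(y)
  th <- max(t0, 1e-4)
  for (i in seq_len(limit)) {
    th <- abs(th)
    sc <- sum(digamma(th + y) - digamma(th) + log(th) + 1 -
                log(th + mu) - (y + th) / (mu + th))
    info <- sum(-trigamma(th + y) + trigamma(th) - 1 / th +
                  2 / (mu + th) - (y + th) / (mu + th)^2)
    del <- sc / info
    th_new <- th + del
    if (th_new <= 0) th_new <- th / 2
    if (abs(del) <= eps * (abs(th) + eps)) {
      th <- th_new
      break
    }
    th <- th_new
  }
  structure(th, SE = sqrt(1 / max(info, 1e-300)))
}

## Dispersion update with divergence guards: Newton from a warm start where
## available, falling back to MASS::theta.ml from cold. The Newton iteration
## diverges when counts are under-dispersed (Poisson or tighter); cap at 1e8,
## numerically the Poisson limit.
.safe_theta_ml <- function(y, mu, fallback, warm = NULL) {
  th <- if (!is.null(warm) && is.finite(warm) && warm > 0 && warm < 1e7) {
    tryCatch(suppressWarnings(.theta_newton(y, mu, as.numeric(warm))),
             error = function(e) NULL)
  } else {
    tryCatch(suppressWarnings(MASS::theta.ml(y, mu, limit = 25)),
             error = function(e) NULL)
  }
  if (is.null(th) || !is.finite(th) || th <= 0) {
    th <- if (stats::var(y) <= mean(y)) 1e8 else as.numeric(fallback)
  }
  if (th > 1e8) th <- structure(1e8, SE = attr(th, "SE"))
  th
}

`%||%` <- function(a, b) if (is.null(a)) b else a
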