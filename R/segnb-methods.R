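#' @export
print.segnb <- function(x, digits = 4, ...) {
  cat("Segmented", if (x$family == "nb2") "negative binomial (NB2)" else
    "Gaussian", "regression\n")
  cat("Call: "); print(x$call)
  if (length(x$psi)) {
    cat("Breakpoints in", x$seg, ":",
        paste(format(x$psi, digits = digits + 1), collapse = ", "), "\n")
    cat("Per-segment slopes:",
        paste(format(x$slopes, digits = digits), collapse = ", "), "\n")
  }
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  if (x$family == "nb2")
    cat("theta:", format(x$theta, digits = digits), "\n")
  cat("logLik:", format(x$loglik, digits = digits + 3),
      "  AIC:", format(x$aic, digits = digits + 3), "\n")
  if (!x$converged) cat("WARNING: breakpoint iteration did not converge\n")
  invisible(x)
}

#' Summary of a segmented count model
#'
#' Wald z tests for the unsegmented terms. Tests for the hinge (slope-change)
#' terms are reported as \code{NA}: under the null of no breakpoint the
#' breakpoint location is unidentified, so their Wald p-values are unreliable
#' without a Davies-type correction, which this package deliberately does not
#' perform.
#'
#' @param object a \code{\link{segnb}} fit.
#' @param ... unused.
#' @export
summary.segnb <- function(object, ...) {
  est <- object$coefficients
  se <- object$se
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  hingeterms <- grepl("^U[0-9]+\\.", names(est))
  p[hingeterms] <- NA_real_
  ct <- cbind(Estimate = est, `Std. Error` = se, `z value` = z,
              `Pr(>|z|)` = p)
  psi_tab <- if (length(object$psi))
    cbind(Estimate = object$psi, `Std. Error` = object$se_psi) else NULL
  structure(list(call = object$call, coefficients = ct, psi = psi_tab,
                 slopes = object$slopes, theta = object$theta,
                 se_theta = object$se_theta, family = object$family,
                 loglik = object$loglik, aic = object$aic,
                 nobs = object$nobs, converged = object$converged,
                 iter = object$iter),
            class = "summary.segnb")
}

#' @export
print.summary.segnb <- function(x, digits = 4, ...) {
  cat("Call: "); print(x$call)
  cat("\nCoefficients:\n")
  stats::printCoefmat(x$coefficients, digits = digits, na.print = "NA",
                      has.Pvalue = TRUE)
  if (!is.null(x$psi)) {
    cat("\nBreakpoints:\n")
    rownames(x$psi) <- paste0("psi", seq_len(nrow(x$psi)))
    print(round(x$psi, digits))
    cat("\nDerived per-segment slopes:\n")
    print(round(x$slopes, digits))
  }
  if (x$family == "nb2")
    cat("\ntheta (NB2 dispersion):", format(x$theta, digits = digits),
        if (is.finite(x$se_theta)) paste0(" (SE ", format(x$se_theta,
          digits = digits), ")") else "", "\n")
  cat("logLik:", format(x$loglik, digits = digits + 3),
      "  AIC:", format(x$aic, digits = digits + 3),
      "  n:", x$nobs, "\n")
  if (!x$converged) cat("WARNING: breakpoint iteration did not converge\n")
  invisible(x)
}

#' @export
coef.segnb <- function(object, ...) object$coefficients

#' @export
logLik.segnb <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$nobs,
            class = "logLik")
}

#' @export
fitted.segnb <- function(object, ...) object$fitted.values

#' Predict expected seal counts from a segmented fit
#'
#' @param object a \code{\link{segnb}} fit.
#' @param newdata data frame with all model covariates; default the training
#'   data.
#' @param type \code{"response"} (expected count, default) or \code{"link"}.
#' @param ... unused.
#' @export
predict.segnb <- function(object, newdata = NULL,
                          type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- object$linear.predictors
  } else {
    tt <- stats::delete.response(stats::terms(object$formula))
    need <- all.vars(tt)
    miss <- setdiff(need, names(newdata))
    if (length(miss))
      stop("newdata is missing model covariate(s): ",
           paste(miss, collapse = ", "))
    X <- stats::model.matrix(tt, stats::model.frame(tt, newdata,
                                                    na.action = stats::na.fail))
    if (length(object$psi)) {
      U <- vapply(object$psi, function(p) pmax(0, newdata[[object$seg]] - p),
                  numeric(nrow(newdata)))
      colnames(U) <- paste0("U", seq_along(object$psi), ".", object$seg)
      X <- cbind(X, U)
    }
    eta <- drop(X[, names(object$coefficients), drop = FALSE] %*%
                  object$coefficients)
  }
  if (type == "link") eta else
    if (object$family == "nb2") exp(eta) else eta
}

#' @export
residuals.segnb <- function(object,
                            type = c("pearson", "deviance", "response"),
                            ...) {
  type <- match.arg(type)
  y <- object$y
  mu <- object$fitted.values
  if (object$family == "gaussian") return(y - mu)
  switch(type,
    response = y - mu,
    pearson = (y - mu) / sqrt(mu + mu^2 / object$theta),
    deviance = {
      th <- object$theta
      d <- 2 * (ifelse(y > 0, y * log(y / mu), 0) -
                  (y + th) * log((y + th) / (mu + th)))
      sign(y - mu) * sqrt(pmax(d, 0))
    })
}

#' Simulate counts from a fitted segmented NB model
#'
#' Draws NB2 counts at the fitted means and dispersion.
#'
#' @param object a \code{\link{segnb}} fit with \code{family = "nb2"}.
#' @param nsim number of response vectors.
#' @param seed optional integer seed.
#' @param newdata optional data frame of covariates to simulate at.
#' @param ... unused.
#' @export
simulate.segnb <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                           ...) {
  if (object$family != "nb2") stop("simulate is defined for NB2 fits")
  if (!is.null(seed)) set.seed(seed)
  mu <- if (is.null(newdata)) object$fitted.values else
    predict(object, newdata)
  out <- as.data.frame(replicate(
    nsim, stats::rnbinom(length(mu), size = object$theta, mu = mu)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a segmented count-model fit
#'
#' Observed counts against the segmented covariate with the fitted mean curve
#' (all other covariates held at their training means) and the estimated
#' breakpoints.
#'
#' @param x a \code{\link{segnb}} fit.
#' @param n_grid grid resolution of the mean curve.
#' @param ... passed to \code{plot}.
#' @export
plot.segnb <- function(x, n_grid = 400, ...) {
  d <- x$model
  xs <- d[[x$seg]]
  grid <- data.frame(seq(min(xs), max(xs), length.out = n_grid))
  names(grid) <- x$seg
  for (v in setdiff(all.vars(stats::delete.response(stats::terms(x$formula))),
                    x$seg))
    grid[[v]] <- mean(d[[v]])
  mu <- predict(x, grid)
  graphics::plot(xs, x$y, pch = 16, cex = 0.4,
                 col = grDevices::grey(0.4, 0.5),
                 xlab = x$seg, ylab = "count", ...)
  graphics::lines(grid[[x$seg]], mu, col = "red3", lwd = 2)
  if (length(x$psi))
    graphics::abline(v = x$psi, lty = 2, col = "blue3")
  invisible(x)
}
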