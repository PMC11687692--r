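#' White's heteroscedasticity test (LM form) on model residuals
#'
#' Regresses squared residuals on the fitted values and their squares and
#' compares \eqn{n R^2} with \eqn{\chi^2_2}. This is the Lagrange-multiplier
#' form of White's test specialised to the question "does residual variance
#' change with the predicted count?" (the auxiliary regressors are
#' \eqn{\hat\mu} and \eqn{\hat\mu^2} rather than all model regressors and
#' cross-products).
#'
#' @param residuals residual vector (Pearson residuals for a count fit).
#' @param mu fitted values, same length.
#' @return list with \code{statistic}, \code{df} (= 2), \code{p_value}.
#' @export
white_lm_test <- function(residuals, mu) {
  if (length(residuals) != length(mu)) stop("length mismatch")
  if (stats::sd(mu) == 0) stop("fitted values are constant; test undefined")
  r2 <- residuals^2
  aux <- stats::lm(r2 ~ mu + I(mu^2))
  R2 <- summary(aux)$r.squared
  stat <- length(r2) * R2
  list(statistic = stat, df = 2,
       p_value = stats::pchisq(stat, df = 2, lower.tail = FALSE))
}

#' Residual diagnostics for a fitted count model
#'
#' Two checks of the mean-variance fit: (i) Pearson's correlation between the
#' Pearson residuals and the fitted counts, with a Fisher-z confidence
#' interval (a strong correlation indicates systematic misfit across the
#' predicted range); (ii) White's LM test for heteroscedasticity of the
#' residuals across predicted values (\code{\link{white_lm_test}}).
#'
#' @param fit a \code{\link{segnb}} fit (or any object with
#'   \code{residuals(fit, "pearson")} and \code{fitted(fit)}).
#' @param level confidence level for the correlation CI.
#' @return list of class \code{"segnb_diag"}: \code{pearson}
#'   (\code{estimate}, \code{ci}, \code{p_value}) and \code{white}
#'   (\code{statistic}, \code{df}, \code{p_value}), plus \code{n}.
#' @export
residual_diagnostics <- function(fit, level = 0.95) {
  r <- stats::residuals(fit, type = "pearson")
  mu <- stats::fitted(fit)
  if (length(r) < 30) stop("need at least 30 observations")
  if (stats::sd(mu) == 0)
    stop("fitted values are constant; correlation undefined")
  if (stats::sd(r) == 0)
    stop("residuals are constant; correlation undefined")
  ct <- stats::cor.test(r, mu, conf.level = level)
  wt <- white_lm_test(r, mu)
  structure(list(
    pearson = list(estimate = unname(ct$estimate),
                   ci = as.numeric(ct$conf.int),
                   p_value = ct$p.value),
    white = wt, n = length(r), level = level
  ), class = "segnb_diag")
}

#' @export
print.segnb_diag <- function(x, digits = 3, ...) {
  cat("Residual diagnostics (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  Pearson r(resid, mu) = %.3f  %.0f%% CI [%.3f, %.3f]  p = %.3g\n",
              x$pearson$estimate, 100 * x$level, x$pearson$ci[1],
              x$pearson$ci[2], x$pearson$p_value))
  cat(sprintf("  White LM = %.2f on %d df  p = %.3g\n",
              x$white$statistic, x$white$df, x$white$p_value))
  invisible(x)
}
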