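#' Error metrics for floe-level count predictions
#'
#' Two schemes. \code{"per_floe_rmse"}: root mean squared error of predicted
#' versus observed counts per floe. \code{"binned_mape"}: because most floes
#' hold zero seals, per-floe percentage error is undefined; observed and
#' predicted counts are aggregated into log-spaced floe-size bins and MAPE is
#' the mean of |obs - pred|/obs over bins with non-zero observed totals.
#'
#' @param observed,predicted equal-length numeric vectors.
#' @param scheme \code{"per_floe_rmse"}, \code{"binned_mape"}, or
#'   \code{"both"}.
#' @param area floe areas, required for the binned MAPE.
#' @param n_bins number of log-spaced size bins (default 20).
#' @return named list with \code{rmse} and/or \code{mape} (MAPE in percent).
#' @export
error_metrics <- function(observed, predicted,
                          scheme = c("both", "per_floe_rmse", "binned_mape"),
                          area = NULL, n_bins = 20) {
  scheme <- match.arg(scheme)
  if (length(observed) != length(predicted))
    stop("observed and predicted lengths differ")
  out <- list()
  if (scheme %in% c("both", "per_floe_rmse"))
    out$rmse <- sqrt(mean((observed - predicted)^2))
  if (scheme %in% c("both", "binned_mape")) {
    if (is.null(area)) stop("binned MAPE needs floe areas")
    la <- log(area)
    breaks <- seq(min(la), max(la), length.out = n_bins + 1)
    bin <- findInterval(la, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    obs_b <- tapply(observed, bin, sum)
    pred_b <- tapply(predicted, bin, sum)
    keep <- obs_b > 0
    if (!any(keep)) stop("all size bins have zero observed counts; ",
                         "MAPE undefined")
    out$mape <- 100 * mean(abs(obs_b[keep] - pred_b[keep]) / obs_b[keep])
  }
  out
}

#' Bootstrap confidence and prediction intervals for seal abundance
#'
#' Nonparametric case resampling of floes: each replicate refits the model on
#' a resample (via \code{fit_fun}) and predicts every original floe. The CI
#' for the expected count \eqn{\mu_i} is the percentile interval of the
#' replicate \eqn{\hat\mu_i^b}; the PI for a new count additionally draws
#' \eqn{y_i^b \sim \mathrm{NB2}(\hat\mu_i^b, \hat\theta^b)} per replicate and
#' takes percentile bounds of the draws (parameter and sampling uncertainty
#' combined). Scene-level intervals use the replicate totals
#' \eqn{\sum_i \hat\mu_i^b} (CI) and \eqn{\sum_i y_i^b} (PI).
#'
#' @param data floe feature table (rows are the resampling unit).
#' @param fit_fun function(data) returning a fitted model with a
#'   \code{predict} method and a \code{theta} field (e.g. a
#'   \code{\link{segnb}} wrapper).
#' @param n_boot bootstrap replicates (>= 100; the reference analysis used
#'   1000).
#' @param level interval level (default 0.95).
#' @param seed integer seed.
#' @param max_fail_rate abort if more than this fraction of replicates fails
#'   to converge (default 0.05).
#' @return list of class \code{"floe_boot"}: \code{point} (data frame with
#'   per-floe \code{mu}, CI and PI bounds), \code{scene} (totals with CI and
#'   PI), \code{n_boot}, \code{n_failed}, \code{level}.
#' @export
bootstrap_intervals <- function(data, fit_fun, n_boot = 1000, level = 0.95,
                                seed = 1, max_fail_rate = 0.05) {
  if (n_boot < 100) stop("n_boot must be at least 100")
  set.seed(.sub_seed(seed, 9))
  n <- nrow(data)
  fit0 <- fit_fun(data)
  mu0 <- predict(fit0, data)
  mu_b <- matrix(NA_real_, n_boot, n)
  y_b <- matrix(NA_real_, n_boot, n)
  failed <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    fb <- tryCatch(fit_fun(data[idx, , drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(fb) || isFALSE(fb$converged)) { failed <- failed + 1L; next }
    mu <- tryCatch(predict(fb, data), error = function(e) NULL)
    if (is.null(mu)) { failed <- failed + 1L; next }
    mu_b[b, ] <- mu
    th <- fb$theta %||% Inf
    y_b[b, ] <- if (is.finite(th))
      stats::rnbinom(n, size = th, mu = mu) else stats::rpois(n, mu)
  }
  if (failed / n_boot > max_fail_rate)
    stop(failed, "/", n_boot, " bootstrap replicates failed to converge ",
         "(limit ", 100 * max_fail_rate, "%)")
  a <- (1 - level) / 2
  qs <- function(m) apply(m, 2, stats::quantile, probs = c(a, 1 - a),
                          na.rm = TRUE)
  ci <- qs(mu_b); pi_ <- qs(y_b)
  ## a count PI must cover the plausible range of the mean itself; enveloping
  ## the CI keeps CI within PI even where the integer draws degenerate to 0
  point <- data.frame(mu = mu0, ci_lo = ci[1, ], ci_hi = ci[2, ],
                      pi_lo = pmin(pi_[1, ], ci[1, ]),
                      pi_hi = pmax(pi_[2, ], ci[2, ]))
  tot_mu <- rowSums(mu_b); tot_y <- rowSums(y_b)
  scene <- data.frame(
    observed = if ("seal_count" %in% names(data))
      sum(data$seal_count) else NA_real_,
    predicted = sum(mu0),
    ci_lo = stats::quantile(tot_mu, a, na.rm = TRUE),
    ci_hi = stats::quantile(tot_mu, 1 - a, na.rm = TRUE),
    pi_lo = stats::quantile(tot_y, a, na.rm = TRUE),
    pi_hi = stats::quantile(tot_y, 1 - a, na.rm = TRUE),
    row.names = NULL)
  structure(list(point = point, scene = scene, n_boot = n_boot,
                 n_failed = failed, level = level),
            class = "floe_boot")
}

#' @export
print.floe_boot <- function(x, ...) {
  cat("Bootstrap intervals (", x$n_boot, " replicates, ",
      100 * x$level, "% level, ", x$n_failed, " failed)\n", sep = "")
  cat("Scene totals:\n")
  print(round(x$scene, 2))
  invisible(x)
}

#' Per-scene prediction report
#'
#' Aggregates per-floe predictions into the scene-level table used to judge
#' model transfer: observed and predicted totals, per-floe RMSE and
#' size-binned MAPE per scene.
#'
#' @param data floe table with \code{scene_id}, \code{seal_count},
#'   \code{area}.
#' @param predicted per-floe expected counts.
#' @return data frame with one row per scene plus an \code{"overall"} row
#'   (metrics averaged across scenes, totals summed).
#' @export
scene_report <- function(data, predicted) {
  sc <- split(seq_len(nrow(data)), data$scene_id)
  rows <- lapply(names(sc), function(s) {
    ii <- sc[[s]]
    em <- error_metrics(data$seal_count[ii], predicted[ii],
                        area = data$area[ii])
    data.frame(scene = s, rmse = em$rmse, mape = em$mape,
               observed = sum(data$seal_count[ii]),
               predicted = sum(predicted[ii]))
  })
  out <- do.call(rbind, rows)
  rbind(out, data.frame(scene = "overall", rmse = mean(out$rmse),
                        mape = mean(out$mape),
                        observed = sum(out$observed),
                        predicted = sum(out$predicted)))
}
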