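#' Regression forest with out-of-bag metrics
#'
#' Bootstrap-aggregated regression trees (variance-reduction splits, `mtry`
#' candidate predictors per split) via the \pkg{randomForest} engine, with
#' the out-of-bag (OOB) performance summary used for screening covariates:
#' RMSE, R-squared, MAE, and -- for a count response -- "accuracy", the
#' fraction of OOB predictions that round to the observed count (reported,
#' never used for selection).
#'
#' @param x data frame of predictors.
#' @param y numeric response.
#' @param ntree number of trees (>= 1).
#' @param mtry predictors tried per split (1..ncol(x)); default
#'   \code{max(1, floor(ncol(x)/3))}.
#' @param seed integer seed (forest growth is seeded and reproducible).
#' @return list of class \code{"floe_forest"}: \code{forest} (the
#'   randomForest object, with inbag counts kept), \code{oob} (named metric
#'   vector), \code{oob_pred}, \code{ntree}, \code{mtry}, \code{seed}.
#' @export
fit_forest <- function(x, y, ntree = 500, mtry = NULL, seed = 1) {
  if (nrow(x) < 10) stop("need at least 10 observations")
  if (is.null(mtry)) mtry <- max(1, floor(ncol(x) / 3))
  stopifnot(ntree >= 1, mtry >= 1, mtry <= ncol(x))
  set.seed(.sub_seed(seed, 6))
  rf <- randomForest::randomForest(x = x, y = y, ntree = ntree, mtry = mtry,
                                   keep.inbag = TRUE, keep.forest = TRUE)
  pred <- rf$predicted  # OOB predictions
  ok <- !is.na(pred)
  rmse <- sqrt(mean((pred[ok] - y[ok])^2))
  oob <- c(rmse = rmse,
           r2 = 1 - sum((pred[ok] - y[ok])^2) / sum((y[ok] - mean(y[ok]))^2),
           mae = mean(abs(pred[ok] - y[ok])),
           accuracy = mean(round(pred[ok]) == y[ok]))
  structure(list(forest = rf, oob = oob, oob_pred = pred, ntree = ntree,
                 mtry = mtry, seed = seed, x = x, y = y),
            class = "floe_forest")
}

#' @export
print.floe_forest <- function(x, ...) {
  cat("Regression forest: ntree =", x$ntree, ", mtry =", x$mtry, "\n")
  print(round(x$oob, 4))
  invisible(x)
}

#' Grid search over forest hyperparameters
#'
#' Exhaustive evaluation of (ntree, mtry) combinations by OOB RMSE; ties are
#' broken toward smaller ntree, then smaller mtry.
#'
#' @param x predictors; @param y response.
#' @param ntree_grid,mtry_grid non-empty integer vectors.
#' @param seed integer seed (one sub-seed per cell).
#' @return list with \code{best} (the winning \code{\link{fit_forest}}),
#'   \code{best_ntree}, \code{best_mtry} and \code{table} (one row per cell
#'   with the OOB metrics).
#' @export
forest_grid_search <- function(x, y, ntree_grid, mtry_grid, seed = 1) {
  if (!length(ntree_grid) || !length(mtry_grid)) stop("empty grid")
  cells <- expand.grid(ntree = sort(ntree_grid), mtry = sort(mtry_grid))
  cells <- cells[order(cells$ntree, cells$mtry), ]
  fits <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells)))
    fits[[i]] <- fit_forest(x, y, ntree = cells$ntree[i],
                            mtry = cells$mtry[i], seed = seed + i)
  tab <- cbind(cells, t(vapply(fits, function(f) f$oob, numeric(4))))
  best_i <- which.min(tab$rmse)  # first minimum = smallest ntree then mtry
  list(best = fits[[best_i]], best_ntree = cells$ntree[best_i],
       best_mtry = cells$mtry[best_i], table = tab)
}

## OOB predictions of a kept forest on (possibly permuted) feature values
.oob_predict <- function(ff, xnew) {
  rf <- ff$forest
  all_pred <- stats::predict(rf, xnew, predict.all = TRUE)$individual
  inbag <- rf$inbag
  oob <- inbag == 0
  rs <- rowSums(all_pred * oob)
  n_oob <- rowSums(oob)
  out <- rs / n_oob
  out[n_oob == 0] <- NA_real_
  out
}

#' Conditional permutation feature importance (CPFI)
#'
#' Permutation importance corrected for correlated predictors: for each
#' predictor, observations are first stratified into cells defined by the
#' quantile grid of every other predictor whose absolute Spearman correlation
#' with it exceeds \code{cond_threshold}; the predictor is then permuted
#' \emph{within} cells, so the permutation preserves its dependence structure
#' with its conditioners and measures only its own contribution. Importance
#' is the mean increase in OOB mean-squared error over \code{n_perm}
#' permutations. With no conditioners (or \code{cond_threshold} > 1) this
#' reduces exactly to classical permutation importance.
#'
#' @param ff a \code{\link{fit_forest}} result.
#' @param cond_threshold absolute Spearman correlation above which a
#'   predictor joins the conditioning set (default 0.2).
#' @param n_bins quantile bins per conditioning predictor (default 4), capped
#'   so that cells keep at least 2 observations.
#' @param n_perm permutation repeats (default 10).
#' @param seed integer seed.
#' @return data frame of class \code{"cpfi_table"}: one row per predictor
#'   with \code{importance} (mean OOB MSE increase), \code{sd} over repeats,
#'   \code{n_conditioners}, and \code{conditioners} (comma-joined names).
#' @export
cpfi <- function(ff, cond_threshold = 0.2, n_bins = 4, n_perm = 10,
                 seed = 1) {
  stopifnot(inherits(ff, "floe_forest"), n_perm >= 1)
  x <- ff$x; y <- ff$y
  set.seed(.sub_seed(seed, 7))
  base_pred <- .oob_predict(ff, x)
  ok0 <- !is.na(base_pred)
  base_err <- mean((base_pred[ok0] - y[ok0])^2)
  p <- ncol(x)
  rho <- suppressWarnings(stats::cor(x, method = "spearman"))
  out <- data.frame(predictor = colnames(x), importance = NA_real_,
                    sd = NA_real_, n_conditioners = 0L,
                    conditioners = "", stringsAsFactors = FALSE)
  for (j in seq_len(p)) {
    if (length(unique(x[[j]])) == 1L) {
      warning("predictor '", colnames(x)[j], "' is constant; importance 0")
      out$importance[j] <- 0; out$sd[j] <- 0
      next
    }
    cond <- setdiff(which(abs(rho[j, ]) > cond_threshold), j)
    cond <- cond[!is.na(cond)]
    cells <- .cond_cells(x, cond, n_bins)
    out$n_conditioners[j] <- length(cond)
    out$conditioners[j] <- paste(colnames(x)[cond], collapse = ",")
    incr <- numeric(n_perm)
    for (r in seq_len(n_perm)) {
      xp <- x
      xp[[j]] <- .permute_within(x[[j]], cells)
      pp <- .oob_predict(ff, xp)
      ok <- !is.na(pp)
      incr[r] <- mean((pp[ok] - y[ok])^2) - base_err
    }
    out$importance[j] <- mean(incr)
    out$sd[j] <- stats::sd(incr)
  }
  attr(out, "n_perm") <- n_perm
  class(out) <- c("cpfi_table", "data.frame")
  out[order(-out$importance), ]
}

## cell labels from the quantile grid of the conditioning predictors,
## shrinking the grid until every non-empty cell holds >= 2 rows
.cond_cells <- function(x, cond, n_bins) {
  n <- nrow(x)
  if (!length(cond)) return(rep(1L, n))
  b <- n_bins
  repeat {
    labs <- rep("", n)
    for (k in cond) {
      qs <- unique(stats::quantile(x[[k]], seq(0, 1, length.out = b + 1)))
      cuts <- if (length(qs) > 2)
        cut(x[[k]], qs, include.lowest = TRUE, labels = FALSE)
      else rep(1L, n)
      labs <- paste(labs, cuts, sep = ".")
    }
    f <- factor(labs)
    if (b == 1L || min(table(f)) >= 2) return(as.integer(f))
    b <- b - 1L
  }
}

.permute_within <- function(v, cells) {
  for (cl in unique(cells)) {
    ii <- which(cells == cl)
    if (length(ii) > 1) v[ii] <- v[sample(ii)]
  }
  v
}

#' All-subsets AIC ranking of candidate covariates
#'
#' Fits every subset of \code{optional_terms} on top of the fixed segmented
#' area term (2^p fits) with \code{\link{segnb}} and ranks the converged fits
#' by AIC.
#'
#' @param data floe feature table with the response and all candidate
#'   columns.
#' @param response response column name (default \code{"seal_count"}).
#' @param optional_terms character vector of candidate covariate names
#'   (p <= 12).
#' @param seg segmented covariate (always included; default \code{"area"}).
#' @param npsi breakpoints for every fit (default 2).
#' @param psi_init optional starting breakpoints passed to each fit (speeds
#'   up the sweep; default quantile multi-start per subset).
#' @param control a \code{\link{segnb_control}}.
#' @return data frame of class \code{"model_rank_table"}: one row per subset
#'   with \code{terms}, \code{k}, \code{loglik}, \code{aic},
#'   \code{delta_aic}, \code{rank}, \code{converged}. Non-converged fits are
#'   flagged and excluded from the ranking.
#' @export
dredge_aic <- function(data, response = "seal_count", optional_terms,
                       seg = "area", npsi = 2, psi_init = NULL,
                       control = segnb_control()) {
  p <- length(optional_terms)
  if (p > 12) stop("at most 12 optional terms (2^p fits)")
  subsets <- lapply(0:(2^p - 1), function(m)
    optional_terms[bitwAnd(m, 2^(seq_len(p) - 1)) > 0])
  rows <- lapply(subsets, function(terms) {
    rhs <- paste(c(seg, terms), collapse = " + ")
    fml <- stats::as.formula(paste(response, "~", rhs))
    fit <- tryCatch(segnb(fml, data, seg = seg, npsi = npsi, psi = psi_init,
                          control = control),
                    error = function(e) NULL)
    data.frame(
      terms = paste(c(seg, terms), collapse = "+"),
      k = if (is.null(fit)) NA_real_ else fit$df,
      loglik = if (is.null(fit)) NA_real_ else fit$loglik,
      aic = if (is.null(fit)) NA_real_ else fit$aic,
      converged = !is.null(fit) && fit$converged,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ok <- out$converged & is.finite(out$aic)
  out$delta_aic <- out$aic - min(out$aic[ok])
  out$rank <- NA_integer_
  out$rank[ok] <- rank(out$aic[ok], ties.method = "first")
  out <- out[order(!ok, out$aic), ]
  rownames(out) <- NULL
  class(out) <- c("model_rank_table", "data.frame")
  out
}

#' Cross-validated comparison of candidate models
#'
#' Evaluates candidate covariate sets by held-out error under k-fold or
#' leave-one-scene-out splitting. The final-model rule is lowest mean
#' held-out MAPE (size-bin aggregated, see \code{\link{error_metrics}}), ties
#' broken by lowest RMSE.
#'
#' @param models list of character vectors of covariate names (each fitted on
#'   top of the segmented \code{seg} term).
#' @param data floe feature table.
#' @param scheme \code{"kfold"} (default) or \code{"loso"}
#'   (leave-one-scene-out, requires a \code{scene_id} column with > 1 scene).
#' @param k folds for \code{"kfold"} (default 5); fold sizes differ by at
#'   most one.
#' @param response,seg,npsi,control as in \code{\link{dredge_aic}}.
#' @param seed integer seed for the fold assignment.
#' @return list of class \code{"cv_report"}: \code{table} (per-model mean
#'   MAPE/RMSE), \code{folds} (the assignment), \code{best} (index of the
#'   selected model), \code{scheme}, \code{seed}.
#' @export
cross_validate <- function(models, data, scheme = c("kfold", "loso"), k = 5,
                           response = "seal_count", seg = "area", npsi = 2,
                           control = segnb_control(), seed = 1) {
  scheme <- match.arg(scheme)
  n <- nrow(data)
  if (scheme == "kfold") {
    set.seed(.sub_seed(seed, 8))
    fold <- sample(rep(seq_len(k), length.out = n))
  } else {
    if (length(unique(data$scene_id)) < 2)
      stop("leave-one-scene-out requires more than one scene")
    fold <- as.integer(factor(data$scene_id))
    k <- max(fold)
  }
  tab <- data.frame(model = vapply(models, function(m)
    paste(c(seg, m), collapse = "+"), character(1)),
    mape = NA_real_, rmse = NA_real_)
  for (mi in seq_along(models)) {
    fml <- stats::as.formula(paste(response, "~",
                                   paste(c(seg, models[[mi]]),
                                         collapse = " + ")))
    mape_f <- rmse_f <- numeric(k)
    for (f in seq_len(k)) {
      tr <- data[fold != f, , drop = FALSE]
      te <- data[fold == f, , drop = FALSE]
      fit <- segnb(fml, tr, seg = seg, npsi = npsi, control = control)
      mu <- predict(fit, te)
      rmse_f[f] <- error_metrics(te[[response]], mu,
                                 scheme = "per_floe_rmse")$rmse
      mape_f[f] <- error_metrics(te[[response]], mu, scheme = "binned_mape",
                                 area = te[[seg]])$mape
    }
    tab$mape[mi] <- mean(mape_f)
    tab$rmse[mi] <- mean(rmse_f)
  }
  best <- order(tab$mape, tab$rmse)[1]
  structure(list(table = tab, folds = fold, best = best, scheme = scheme,
                 k = k, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Cross-validation (", x$scheme, ", k = ", x$k, ")\n", sep = "")
  print(transform(x$table, mape = round(mape, 3), rmse = round(rmse, 3)))
  cat("selected model:", x$table$model[x$best], "\n")
  invisible(x)
}
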