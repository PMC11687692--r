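#' Write floes to GeoJSON
#'
#' Writes a FeatureCollection of Polygon features in planar scene meters
#' (no CRS member; coordinates are scene-local). Circular floes are written
#' as 64-gons; coordinates are rounded to 3 decimals (mm at scene scale).
#' Properties: \code{floe_id}, \code{scene_id}, \code{area_m2},
#' \code{perimeter_m}, \code{seal_count} and any covariate columns present.
#'
#' @param floes floe data frame (x, y and area, or precomputed vertices).
#' @param path output path.
#' @param n_vertices polygon vertices per floe (default 64).
#' @export
write_floes <- function(floes, path, n_vertices = 64) {
  covs <- setdiff(names(floes),
                  c("floe_id", "scene_id", "area", "perimeter", "x", "y",
                    "radius", "seal_count"))
  feats <- lapply(seq_len(nrow(floes)), function(i) {
    r0 <- sqrt(floes$area[i] / pi)
    th <- seq(0, 2 * pi, length.out = n_vertices + 1)
    ring <- cbind(round(floes$x[i] + r0 * cos(th), 3),
                  round(floes$y[i] + r0 * sin(th), 3))
    ring[n_vertices + 1, ] <- ring[1, ]  # closed ring
    props <- c(list(floe_id = floes$floe_id[i],
                    scene_id = floes$scene_id[i] %||% 1L,
                    area_m2 = floes$area[i],
                    perimeter_m = floes$perimeter[i] %||% (2 * pi * r0),
                    seal_count = floes$seal_count[i] %||% NA),
               lapply(covs, function(cl) floes[[cl]][i]))
    names(props)[-(1:5)] <- covs
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(ring)),
         properties = props)
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats), path,
    auto_unbox = TRUE, digits = NA, na = "null", pretty = FALSE)
  invisible(path)
}

.shoelace <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

.ring_perimeter <- function(xy) {
  d <- diff(rbind(xy, xy[1, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

#' Read floes from GeoJSON or CSV
#'
#' GeoJSON: a FeatureCollection of Polygon features; area and perimeter are
#' recomputed from the exterior ring (shoelace formula) when absent from the
#' properties; centroids are the ring vertex means. CSV: the flat schema
#' written by \code{\link{write_feature_csv}} (requires at least
#' \code{floe_id}, \code{area}; an informative error lists anything
#' missing). Mixed geometry types are rejected.
#'
#' @param path input file (.geojson/.json or .csv).
#' @return floe data frame.
#' @export
read_floes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    d <- utils::read.csv(path)
    req <- c("floe_id", "area")
    miss <- setdiff(req, names(d))
    if (length(miss))
      stop("CSV is missing required column(s): ", paste(miss, collapse = ", "))
    return(d)
  }
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(g$type, "FeatureCollection"))
    stop("not a GeoJSON FeatureCollection")
  types <- unique(vapply(g$features, function(f) f$geometry$type,
                         character(1)))
  if (length(types) > 1)
    stop("mixed geometry types: ", paste(types, collapse = ", "))
  if (length(types) && types != "Polygon")
    stop("unsupported geometry type: ", types)
  rows <- lapply(seq_along(g$features), function(i) {
    f <- g$features[[i]]
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) unlist(p)))
    ring <- ring[-nrow(ring), , drop = FALSE]  # drop closing vertex
    pr <- f$properties
    num <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
    base <- data.frame(
      floe_id = if (is.null(pr$floe_id)) i - 1L else pr$floe_id,
      scene_id = if (is.null(pr$scene_id)) 1L else pr$scene_id,
      area = if (is.null(pr$area_m2)) .shoelace(ring) else num(pr$area_m2),
      perimeter = if (is.null(pr$perimeter_m)) .ring_perimeter(ring)
        else num(pr$perimeter_m),
      x = mean(ring[, 1]), y = mean(ring[, 2]),
      seal_count = if (is.null(pr$seal_count)) NA_integer_
        else as.integer(pr$seal_count))
    extra <- setdiff(names(pr), c("floe_id", "scene_id", "area_m2",
                                  "perimeter_m", "seal_count"))
    for (cl in extra) base[[cl]] <- num(pr[[cl]])
    base
  })
  do.call(rbind, rows)
}

#' Write a grid as an ESRI ASCII raster
#'
#' Plain-text single-band raster (.asc): header
#' \code{ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value} followed by
#' rows from the top of the scene down, matching the matrix layout.
#'
#' @param m numeric matrix (row 1 = top of scene).
#' @param path output path.
#' @param pixel_size cell size in m.
#' @param xll,yll lower-left corner coordinates (default 0).
#' @export
write_ascii_grid <- function(m, path, pixel_size, xll = 0, yll = 0) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(m)),
               paste("nrows", nrow(m)),
               paste("xllcorner", format(xll, scientific = FALSE)),
               paste("yllcorner", format(yll, scientific = FALSE)),
               paste("cellsize", format(pixel_size, scientific = FALSE)),
               "NODATA_value -9999"), con)
  utils::write.table(format(m, trim = TRUE, digits = 6,
                            scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII raster
#' @param path .asc file.
#' @return list with \code{grid} (matrix, row 1 = top), \code{pixel_size},
#'   \code{xll}, \code{yll}.
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  m <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(m) <- NULL
  if (nrow(m) != h["nrows"] || ncol(m) != h["ncols"])
    stop("grid dimensions do not match header")
  m[m == h["nodata_value"]] <- NA
  list(grid = m, pixel_size = unname(h["cellsize"]),
       xll = unname(h["xllcorner"]), yll = unname(h["yllcorner"]))
}

#' Write the floe feature table as CSV
#'
#' Numeric columns are written at 6 significant digits with fixed key order,
#' so identical inputs produce byte-identical files.
#'
#' @param floes feature table.
#' @param path output path.
#' @export
write_feature_csv <- function(floes, path) {
  out <- floes
  for (cl in names(out))
    if (is.double(out[[cl]])) out[[cl]] <- signif(out[[cl]], 6)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a fitted segmented model to JSON
#'
#' Documented schema: \code{family}, \code{seg}, \code{formula},
#' \code{coefficients} (named), \code{se}, \code{psi}, \code{se_psi},
#' \code{slopes}, \code{theta}, \code{se_theta}, \code{loglik}, \code{aic},
#' \code{df}, \code{nobs}, \code{converged}, \code{iter}.
#'
#' @param fit a \code{\link{segnb}} fit.
#' @param path output path.
#' @export
write_model_json <- function(fit, path) {
  stopifnot(inherits(fit, "segnb"))
  obj <- list(
    family = fit$family, seg = fit$seg,
    formula = deparse(fit$formula),
    coefficients = as.list(fit$coefficients),
    se = as.list(fit$se),
    psi = fit$psi, se_psi = fit$se_psi,
    slopes = as.list(fit$slopes %||% numeric(0)),
    theta = fit$theta, se_theta = fit$se_theta,
    loglik = fit$loglik, aic = fit$aic, df = fit$df, nobs = fit$nobs,
    converged = fit$converged, iter = fit$iter)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Load a serialized segmented model
#'
#' Returns a lightweight \code{"segnb"} object sufficient for
#' \code{predict(fit, newdata)} and \code{simulate}; fields tied to the
#' training data (fitted values, model frame, trace) are absent.
#'
#' @param path model JSON written by \code{\link{write_model_json}}.
#' @export
read_model_json <- function(path) {
  o <- jsonlite::fromJSON(path)
  num <- function(v) {
    v[vapply(v, is.null, logical(1))] <- NA_real_
    vapply(v, as.numeric, numeric(1))
  }
  structure(list(
    family = o$family, seg = o$seg,
    formula = stats::as.formula(paste(o$formula, collapse = " ")),
    coefficients = num(as.list(o$coefficients)),
    se = num(as.list(o$se)),
    psi = num(as.list(o$psi)), se_psi = num(as.list(o$se_psi)),
    slopes = num(as.list(o$slopes)),
    theta = o$theta, se_theta = o$se_theta,
    loglik = o$loglik, aic = o$aic, df = o$df, nobs = o$nobs,
    converged = o$converged, iter = o$iter
  ), class = "segnb")
}
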