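#' Scene raster bundle
#'
#' Binds the co-registered grids of one scene: binary ice mask, integer floe
#' labels, and bathymetry, all at the same resolution in planar scene meters
#' (origin at the top-left pixel corner, y increasing downward; pixel (r, c)
#' has center ((c-0.5) px, (r-0.5) px)).
#'
#' @param ice binary matrix (1 = ice).
#' @param labels integer matrix of floe ids (0 = open water); optional.
#' @param bathy numeric matrix of depths (m); optional.
#' @param pixel_size m/pixel, > 0.
#' @return A list of class \code{"scene_rasters"} with fields \code{ice},
#'   \code{labels}, \code{bathy}, \code{pixel_size}, \code{width},
#'   \code{height}.
#' @export
scene_rasters <- function(ice, labels = NULL, bathy = NULL, pixel_size) {
  if (pixel_size <= 0) stop("pixel_size must be positive")
  ice <- as.matrix(ice)
  for (m in list(labels, bathy))
    if (!is.null(m) && !identical(dim(as.matrix(m)), dim(ice)))
      stop("all rasters must share the same grid dimensions")
  structure(list(ice = ice, labels = labels, bathy = bathy,
                 pixel_size = pixel_size,
                 width = ncol(ice) * pixel_size,
                 height = nrow(ice) * pixel_size),
            class = "scene_rasters")
}

#' Sea-ice concentration in a metric buffer around a floe
#'
#' Fraction of ice-covered pixels whose centers fall within \code{radius}
#' meters of the floe's boundary, excluding the focal floe's own pixels
#' (the covariate measures the \emph{surrounding} ice). Floes are circles of
#' equivalent radius \eqn{r_0 = \sqrt{area/\pi}}, so the buffer is the annulus
#' \eqn{r_0 < d \le r_0 + radius} around the centroid.
#'
#' @param rasters a \code{\link{scene_rasters}}.
#' @param floe one floe record (list/row with \code{x}, \code{y}, \code{area}
#'   and optionally \code{floe_id}).
#' @param radius buffer width in m, > 0.
#' @return fraction in [0, 1].
#' @export
sic_at_radius <- function(rasters, floe, radius) {
  if (radius <= 0) stop("radius must be positive")
  r0 <- sqrt(floe$area / pi)
  rout <- r0 + radius
  if (floe$x - rout < 0 || floe$y - rout < 0 ||
      floe$x + rout > rasters$width || floe$y + rout > rasters$height)
    stop("buffer extends past scene bounds; apply edge_filter first ",
         "(floe ", floe$floe_id %||% "?", ", radius ", radius, ")")
  px <- rasters$pixel_size
  jc <- which(abs((seq_len(ncol(rasters$ice)) - 0.5) * px - floe$x) <= rout)
  jr <- which(abs((seq_len(nrow(rasters$ice)) - 0.5) * px - floe$y) <= rout)
  dx2 <- ((jc - 0.5) * px - floe$x)^2
  dy2 <- ((jr - 0.5) * px - floe$y)^2
  d2 <- outer(dy2, dx2, "+")
  ann <- d2 > r0^2 & d2 <= rout^2
  if (!is.null(rasters$labels) && !is.null(floe$floe_id)) {
    own <- rasters$labels[jr, jc, drop = FALSE] == floe$floe_id
    ann <- ann & !own
  }
  if (!any(ann)) return(0)
  mean(rasters$ice[jr, jc, drop = FALSE][ann])
}

## 3x3 focal terrain metrics; edge ring is NA
.focal_metrics <- function(z, pixel_size) {
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3 || nc < 3) stop("raster too small for 3x3 focal metrics")
  sh <- function(dr, dc) {
    out <- matrix(NA_real_, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    out[ok_r, ok_c] <- z[rs[ok_r], cs[ok_c]]
    out
  }
  n <- sh(-1, 0); s <- sh(1, 0); e <- sh(0, 1); w <- sh(0, -1)
  ne <- sh(-1, 1); nw <- sh(-1, -1); se <- sh(1, 1); sw <- sh(1, -1)
  gx <- (e - w) / (2 * pixel_size)
  gy <- (s - n) / (2 * pixel_size)
  slope <- sqrt(gx^2 + gy^2)
  tri <- (abs(n - z) + abs(s - z) + abs(e - z) + abs(w - z) +
            abs(ne - z) + abs(nw - z) + abs(se - z) + abs(sw - z)) / 8
  stack <- function(f) {
    m <- z
    for (q in list(n, s, e, w, ne, nw, se, sw)) m <- f(m, q)
    m
  }
  rough <- stack(pmax) - stack(pmin)
  edge <- matrix(FALSE, nr, nc)
  edge[c(1, nr), ] <- TRUE; edge[, c(1, nc)] <- TRUE
  slope[edge] <- NA; tri[edge] <- NA; rough[edge] <- NA
  list(slope = slope, tri = tri, rough = rough)
}

#' Bathymetric terrain metrics averaged in a circle
#'
#' Per-pixel 3x3 focal metrics -- slope (central-difference gradient
#' magnitude, m/m), TRI (mean absolute difference from the center cell, m)
#' and roughness (window max minus min, m) -- averaged over pixels whose
#' centers fall within \code{radius} of \code{center}.
#'
#' @param rasters a \code{\link{scene_rasters}} with \code{bathy}.
#' @param center c(x, y) in scene meters.
#' @param radius circle radius in m; must be at least one pixel.
#' @return named list \code{slope}, \code{tri}, \code{rough}.
#' @export
bathy_metrics <- function(rasters, center, radius) {
  if (is.null(rasters$bathy)) stop("rasters carry no bathymetry grid")
  px <- rasters$pixel_size
  if (radius < px) stop("radius must be at least one pixel (", px, " m)")
  fm <- .focal_metrics(rasters$bathy, px)
  jc <- which(abs((seq_len(ncol(rasters$bathy)) - 0.5) * px - center[1]) <= radius)
  jr <- which(abs((seq_len(nrow(rasters$bathy)) - 0.5) * px - center[2]) <= radius)
  if (!length(jc) || !length(jr)) stop("circle lies outside the raster")
  d2 <- outer(((jr - 0.5) * px - center[2])^2,
              ((jc - 0.5) * px - center[1])^2, "+")
  inside <- d2 <= radius^2
  avg <- function(m) mean(m[jr, jc, drop = FALSE][inside], na.rm = TRUE)
  list(slope = avg(fm$slope), tri = avg(fm$tri), rough = avg(fm$rough))
}

#' Distance to the nearest penguin colony
#'
#' @param centroid c(x, y) in scene meters (or a matrix of centroids).
#' @param colonies data frame or matrix with columns x, y; must be non-empty.
#' @return Euclidean distance(s) in m.
#' @export
colony_distance <- function(centroid, colonies) {
  colonies <- as.matrix(as.data.frame(colonies)[, c("x", "y")])
  if (nrow(colonies) == 0) stop("colony set is empty")
  pts <- if (is.null(dim(centroid))) matrix(centroid, ncol = 2) else
    as.matrix(centroid)
  apply(pts, 1, function(p)
    sqrt(min((p[1] - colonies[, 1])^2 + (p[2] - colonies[, 2])^2)))
}

#' Edge-buffer filtering of floes
#'
#' Drops floes whose geometry comes within \code{buffer} meters of the scene
#' boundary, so that covariates computed in buffers up to that radius never
#' read outside the rasters. For circular floes the criterion is
#' \eqn{\min(x - r_0,\ y - r_0,\ W - x - r_0,\ H - y - r_0) \ge buffer}.
#'
#' @param floes floe data frame (x, y, area, optionally seal_count).
#' @param bounds c(width, height) in m.
#' @param buffer buffer width in m (default 1000).
#' @return list with \code{retained} (data frame), \code{excluded} (data
#'   frame) and \code{excluded_seals} (total seal count removed, NA-safe).
#' @export
edge_filter <- function(floes, bounds, buffer = 1000) {
  w <- bounds[1]; h <- bounds[2]
  if (buffer >= min(w, h) / 2)
    stop("buffer (", buffer, " m) leaves no scene interior")
  r0 <- sqrt(floes$area / pi)
  keep <- (floes$x - r0 >= buffer) & (floes$y - r0 >= buffer) &
    (w - floes$x - r0 >= buffer) & (h - floes$y - r0 >= buffer)
  excl <- floes[!keep, , drop = FALSE]
  list(retained = floes[keep, , drop = FALSE],
       excluded = excl,
       excluded_seals = if ("seal_count" %in% names(excl))
         sum(excl$seal_count, na.rm = TRUE) else 0L)
}

#' Stratified sampling of floes by size bin
#'
#' Partitions floe areas into \code{n_bins} log-spaced bins spanning the
#' observed range and draws up to \code{per_bin} floes uniformly without
#' replacement within each bin, ensuring all floe-size regimes are
#' represented in a training sample.
#'
#' @param floes floe data frame with \code{area}.
#' @param n_bins number of size bins (default 20).
#' @param per_bin sampling quota per bin (default 3000).
#' @param seed integer seed.
#' @return sampled floe data frame (original row order within bins not
#'   preserved; rows are a subset of the input).
#' @export
stratified_sample <- function(floes, n_bins = 20, per_bin = 3000, seed = 1) {
  if (nrow(floes) == 0) stop("no floes to sample")
  stopifnot(n_bins >= 1, per_bin >= 1)
  set.seed(.sub_seed(seed, 5))
  la <- log(floes$area)
  breaks <- seq(min(la), max(la), length.out = n_bins + 1)
  bin <- findInterval(la, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  idx <- unlist(lapply(split(seq_len(nrow(floes)), bin), function(ii) {
    if (length(ii) <= per_bin) ii else sample(ii, per_bin)
  }), use.names = FALSE)
  floes[sort(idx), , drop = FALSE]
}

#' Assemble the per-floe covariate table
#'
#' Computes, for every (already edge-filtered) floe: SIC in buffers at the
#' requested radii, bathymetric slope/TRI/roughness in a 1000 m circle,
#' distance to the nearest penguin colony, and distance to the scene edge.
#' Purely deterministic.
#'
#' @param floes edge-filtered floe data frame (floe_id, x, y, area, ...).
#' @param rasters a \code{\link{scene_rasters}} with ice and bathymetry.
#' @param colonies data frame of colony points (x, y).
#' @param radii SIC buffer radii in m.
#' @return the input data frame with columns \code{sic_<r>},
#'   \code{slope_1000}, \code{tri_1000}, \code{rough_1000},
#'   \code{colony_dist}, \code{edge_dist} appended.
#' @export
build_feature_table <- function(floes, rasters, colonies,
                                radii = c(150, 250, 500, 750, 1000)) {
  sic_cols <- paste0("sic_", radii)
  if (nrow(floes) == 0) {
    for (cl in c(sic_cols, "slope_1000", "tri_1000", "rough_1000",
                 "colony_dist", "edge_dist"))
      floes[[cl]] <- numeric(0)
    return(floes)
  }
  fm <- .focal_metrics(rasters$bathy, rasters$pixel_size)
  px <- rasters$pixel_size
  nr <- nrow(rasters$bathy); nc <- ncol(rasters$bathy)
  for (i in seq_len(nrow(floes))) {
    fl <- floes[i, ]
    for (k in seq_along(radii)) {
      v <- tryCatch(sic_at_radius(rasters, fl, radii[k]),
                    error = function(e)
                      stop("floe ", fl$floe_id, ": ", conditionMessage(e)))
      floes[i, sic_cols[k]] <- v
    }
    jc <- which(abs((seq_len(nc) - 0.5) * px - fl$x) <= 1000)
    jr <- which(abs((seq_len(nr) - 0.5) * px - fl$y) <= 1000)
    d2 <- outer(((jr - 0.5) * px - fl$y)^2, ((jc - 0.5) * px - fl$x)^2, "+")
    inside <- d2 <= 1000^2
    floes[i, "slope_1000"] <- mean(fm$slope[jr, jc, drop = FALSE][inside],
                                   na.rm = TRUE)
    floes[i, "tri_1000"] <- mean(fm$tri[jr, jc, drop = FALSE][inside],
                                 na.rm = TRUE)
    floes[i, "rough_1000"] <- mean(fm$rough[jr, jc, drop = FALSE][inside],
                                   na.rm = TRUE)
    floes[i, "colony_dist"] <- colony_distance(c(fl$x, fl$y), colonies)
    r0 <- sqrt(fl$area / pi)
    floes[i, "edge_dist"] <- min(fl$x, fl$y, rasters$width - fl$x,
                                 rasters$height - fl$y) - r0
  }
  floes
}
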