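#' Validate a pipeline run configuration
#'
#' A run configuration mirrors the generator and model specifications plus
#' per-stage options. Unknown keys anywhere are rejected before any stage
#' runs, and a configuration round-trips losslessly through its YAML file.
#'
#' Sections (all optional, defaults apply): \code{scene} (arguments of
#' \code{\link{scene_spec}}), \code{model} (arguments of
#' \code{\link{seal_model}}), \code{features} (\code{edge_buffer},
#' \code{radii}, \code{stratify}, \code{n_bins}, \code{per_bin}), \code{fit}
#' (\code{covariates}, \code{npsi}), \code{predict} (\code{n_boot},
#' \code{level}), and top-level \code{seed}.
#'
#' @param config list, or path to a YAML file.
#' @return validated config list of class \code{"run_config"}.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  allowed <- list(
    scene = names(formals(scene_spec)),
    model = names(formals(seal_model)),
    features = c("edge_buffer", "radii", "stratify", "n_bins", "per_bin"),
    fit = c("covariates", "npsi"),
    predict = c("n_boot", "level"),
    seed = NULL)
  bad <- setdiff(names(config), names(allowed))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (sec in intersect(names(config), c("scene", "model", "features",
                                         "fit", "predict"))) {
    bad <- setdiff(names(config[[sec]]), allowed[[sec]])
    if (length(bad))
      stop("unknown key(s) in '", sec, "': ", paste(bad, collapse = ", "))
  }
  defaults <- list(scene = list(), model = list(),
                   features = list(edge_buffer = 1000,
                                   radii = c(150, 250, 500, 750, 1000),
                                   stratify = FALSE, n_bins = 20,
                                   per_bin = 3000),
                   fit = list(covariates = c("rough_1000", "sic_750",
                                             "colony_dist"), npsi = 2),
                   predict = list(n_boot = 0, level = 0.95),
                   seed = 1)
  out <- utils::modifyList(defaults, config)
  class(out) <- "run_config"
  out
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full synthetic-scene analysis pipeline
#'
#' Executes simulate -> features -> fit -> predict on one synthetic scene and
#' writes all artifacts plus a manifest with file digests: floes.geojson,
#' ice.asc, bathy.asc, colonies.csv, features.csv, model.json, preds.csv,
#' report.csv, manifest.json. A stage failure halts with the stage name;
#' artifacts of completed stages persist. Reruns with the same configuration
#' and seed produce identical digests.
#'
#' @param config a \code{\link{run_config}} (or list / YAML path coercible to
#'   one).
#' @param out_dir output directory (created if needed).
#' @param seed optional override of the config seed.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = run_config(), out_dir, seed = NULL) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  if (!is.null(seed)) config$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)

  spec <- .stage("config", do.call(scene_spec, config$scene))
  gen <- .stage("config", do.call(seal_model, config$model))

  field <- .stage("simulate", {
    f <- gen_floe_field(spec, seed = config$seed)
    write_ascii_grid(f$rasters$ice, pth("ice.asc"), spec$pixel_size)
    write_ascii_grid(f$rasters$bathy, pth("bathy.asc"), spec$pixel_size)
    utils::write.csv(f$colonies, pth("colonies.csv"), row.names = FALSE)
    f
  })

  feats <- .stage("features", {
    ef <- edge_filter(field$floes, c(spec$width, spec$height),
                      buffer = config$features$edge_buffer)
    ft <- build_feature_table(ef$retained, field$rasters, field$colonies,
                              radii = config$features$radii)
    ft <- sample_counts(ft, gen, seed = config$seed)
    if (isTRUE(config$features$stratify))
      ft <- stratified_sample(ft, config$features$n_bins,
                              config$features$per_bin, seed = config$seed)
    write_floes(ft, pth("floes.geojson"))
    write_feature_csv(ft, pth("features.csv"))
    ft
  })

  fit <- .stage("fit", {
    fml <- stats::as.formula(paste(
      "seal_count ~ area +", paste(config$fit$covariates, collapse = " + ")))
    m <- segnb(fml, feats, seg = "area", npsi = config$fit$npsi)
    write_model_json(m, pth("model.json"))
    m
  })

  preds <- .stage("predict", {
    mu <- predict(fit, feats)
    pd <- data.frame(floe_id = feats$floe_id, scene_id = feats$scene_id,
                     observed = feats$seal_count, mu = mu)
    if (config$predict$n_boot >= 100) {
      fml <- fit$formula
      bt <- bootstrap_intervals(
        feats, function(d) segnb(fml, d, seg = "area",
                                 npsi = config$fit$npsi,
                                 psi = fit$psi),
        n_boot = config$predict$n_boot, level = config$predict$level,
        seed = config$seed)
      pd <- cbind(pd, bt$point[, -1])
    }
    write_feature_csv(pd, pth("preds.csv"))
    rep <- scene_report(feats, mu)
    write_feature_csv(rep, pth("report.csv"))
    pd
  })

  arts <- c("ice.asc", "bathy.asc", "colonies.csv", "floes.geojson",
            "features.csv", "model.json", "preds.csv", "report.csv")
  manifest <- list(
    package = "floeseal",
    version = as.character(utils::packageVersion("floeseal")),
    seed = config$seed,
    n_floes_simulated = nrow(field$floes),
    n_floes_analyzed = nrow(feats),
    files = lapply(stats::setNames(arts, arts), function(f)
      list(md5 = unname(tools::md5sum(pth(f))))))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
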