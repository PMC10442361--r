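#' Write the trap-survey table as long-format CSV
#'
#' One row per site-year: `site_id, x, y, year, count`.
#'
#' @param sites a `site_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sites_csv <- function(sites, path) {
  long <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i) {
    ct <- sites$counts[[i]]
    data.frame(site_id = sites$site_id[i], x = sites$x[i], y = sites$y[i],
               year = as.integer(names(ct)), count = as.integer(ct))
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

# rectangles (row runs of cells) covering one unit of a cell-assignment grid,
# each as a GeoJSON polygon ring
unit_polygons <- function(assignment, unit) {
  v <- assignment$values
  cell <- assignment$cell
  polys <- list()
  for (i in seq_len(nrow(v))) {
    in_row <- which(v[i, ] == unit)
    if (!length(in_row)) next
    runs <- split(in_row, cumsum(c(1L, diff(in_row) != 1L)))
    for (run in runs) {
      x0 <- assignment$xmin + (min(run) - 1L) * cell
      x1 <- assignment$xmin + max(run) * cell
      y0 <- assignment$ymin + (i - 1L) * cell
      y1 <- assignment$ymin + i * cell
      polys[[length(polys) + 1L]] <- list(list(
        c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0)))
    }
  }
  polys
}

#' Write administrative units as GeoJSON
#'
#' Each unit becomes a Feature with a MultiPolygon geometry built from its
#' grid cells (horizontal runs merged into rectangles) and all table columns
#' as properties.
#'
#' @param admin an `admin_table` (with its `"assignment"` grid attribute).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_admin_geojson <- function(admin, path) {
  assignment <- attr(admin, "assignment")
  if (is.null(assignment)) stop("admin table lacks an assignment grid")
  props <- as.data.frame(admin)
  features <- lapply(seq_len(nrow(admin)), function(u) {
    list(
      type = "Feature",
      properties = as.list(props[u, , drop = FALSE]),
      geometry = list(type = "MultiPolygon",
                      coordinates = unit_polygons(assignment, u))
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the full abundance-to-risk pipeline on a synthetic landscape
#'
#' End to end: simulate the landscape and survey; build site covariates
#' (climate at the site cell, land composition in the foraging buffer) and
#' apply the collinearity filter; run the replicated stratified evaluation of
#' the four abundance-model variants and both occurrence-model variants;
#' select the best of each by rank sums (abundance models) and mean AUC
#' (occurrence models); refit the selected variants on the full survey;
#' compare their site predictions across observed abundance categories with
#' Kruskal-Wallis/Dunn; project the final abundance model over the coarse
#' grid; aggregate to administrative units, validate against synthetic
#' nest-report and apiary data, and compute both risk indices. With `out_dir`
#' set, all tables and rasters are written as CSV / ASCII grid / GeoJSON; the
#' run is a pure function of `(config, process, seed, sizes)`, so outputs are
#' byte-identical across repeated runs.
#'
#' @param config a [landscape_config()]; its seed is overridden by `seed`.
#' @param process an [abundance_process()].
#' @param seed master integer seed.
#' @param n_sites trap locations to simulate.
#' @param n_units administrative units to simulate.
#' @param n_rep evaluation replicates.
#' @param radius foraging-buffer radius, km.
#' @param cor_threshold collinearity threshold.
#' @param out_dir optional output directory (created if needed).
#' @return List with `sites`, `covariates` (retained names), `evaluation`,
#'   `sam_variant`, `sdm_variant`, `comparison` (Kruskal-Dunn for SAM and
#'   SDM), `prediction` ([grid_layer()]), `units` (risk table), `validation`.
#' @export
run_pipeline <- function(config = landscape_config(),
                         process = abundance_process(),
                         seed = 1L, n_sites = 248, n_units = 159,
                         n_rep = 100, radius = 1, cor_threshold = 0.8,
                         out_dir = NULL) {
  config$seed <- as.integer(seed)
  env <- generate_environment(config)
  composition <- align_to_coarse(env$landcover, env$climate[[1L]],
                                 radius = radius,
                                 class_names = config$land_classes)
  surface <- generate_abundance_surface(env$climate, composition, process, config)
  sites <- sample_sites(surface, n_sites, config, process)
  sites_cov <- site_covariates(sites, env, radius = radius,
                               class_names = config$land_classes)
  candidates <- c(names(env$climate), names(composition))
  retained <- collinearity_filter(sites_cov[, candidates, drop = FALSE],
                                  threshold = cor_threshold,
                                  priority = candidates)
  evaluation <- replicate_evaluation(sites_cov, retained, n_rep = n_rep,
                                     base_seed = as.integer(seed) * 1000L)
  summ <- evaluation$summary
  sam_summ <- summ[summ$task == "SAM", , drop = FALSE]
  sdm_summ <- summ[summ$task == "SDM", , drop = FALSE]
  names(sam_summ) <- sub("_mean$", "", names(sam_summ))
  names(sdm_summ) <- sub("_mean$", "", names(sdm_summ))
  sam_variant <- rank_select(sam_summ)
  sdm_variant <- rank_select(sdm_summ, metrics = c(auc = "max"))

  final_seed <- as.integer(seed) * 1000L
  sam_final <- fit_sam(sites_cov, retained,
                       algorithm = sub("SAM_([A-Z]+)_.*", "\\1", sam_variant),
                       transform = sub("SAM_[A-Z]+_", "", sam_variant),
                       seed = final_seed)
  sdm_final <- fit_sdm(sites_cov, retained,
                       algorithm = sub("SDM_", "", sdm_variant),
                       seed = final_seed)
  sam_pred_sites <- predict_abundance(sam_final, sites_cov)
  sdm_prob_sites <- predict_presence(sdm_final, sites_cov)
  comparison <- list(
    sam = kruskal_dunn(sam_pred_sites, sites_cov$category),
    sdm = kruskal_dunn(sdm_prob_sites, sites_cov$category))

  # project the final abundance model over the coarse grid
  grid_cov <- c(lapply(env$climate, function(g) as.vector(g$values)),
                lapply(composition, function(g) as.vector(g$values)))
  grid_df <- as.data.frame(grid_cov)
  pred_vec <- predict_abundance(sam_final, grid_df)
  prediction <- grid_layer(
    matrix(pred_vec, nrow(surface$values), ncol(surface$values)),
    cell = surface$cell, xmin = surface$xmin, ymin = surface$ymin)

  admin <- generate_admin_data(surface, n_units, config)
  units <- unit_risk(aggregate_admin(prediction, admin))
  validation <- validate_abundance(units)

  result <- list(sites = sites_cov, covariates = retained,
                 evaluation = evaluation, sam_variant = sam_variant,
                 sdm_variant = sdm_variant, comparison = comparison,
                 prediction = prediction, units = units,
                 validation = validation)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_sites_csv(sites, file.path(out_dir, "sites.csv"))
    cov_tab <- sites_cov[, c("site_id", "mean_count", "category", candidates)]
    cov_tab$category <- as.character(cov_tab$category)
    utils::write.csv(cov_tab, file.path(out_dir, "covariates.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(candidates = candidates, retained = retained,
           threshold = cor_threshold),
      file.path(out_dir, "retained_covariates.json"), auto_unbox = TRUE)
    utils::write.csv(evaluation$replicates,
                     file.path(out_dir, "evaluation_replicates.csv"),
                     row.names = FALSE)
    utils::write.csv(evaluation$summary,
                     file.path(out_dir, "evaluation_summary.csv"),
                     row.names = FALSE)
    write_ascii_grid(prediction, file.path(out_dir, "predicted_abundance.asc"))
    unit_out <- as.data.frame(units)
    utils::write.csv(unit_out, file.path(out_dir, "unit_risk.csv"),
                     row.names = FALSE)
    write_admin_geojson(units, file.path(out_dir, "admin_risk.geojson"))
    sel <- data.frame(
      task = c("SAM", "SDM"), selected = c(sam_variant, sdm_variant))
    utils::write.csv(sel, file.path(out_dir, "selected_variants.csv"),
                     row.names = FALSE)
  }
  result
}

#' Read a pipeline configuration from YAML
#'
#' Maps a YAML file with optional `landscape`, `process` and `run` sections
#' onto [landscape_config()], [abundance_process()] and the [run_pipeline()]
#' arguments.
#'
#' @param path YAML file.
#' @return List with `config`, `process` and `run` (a named list of
#'   run_pipeline arguments).
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs")
  raw <- yaml::read_yaml(path)
  config <- do.call(landscape_config, raw$landscape %||% list())
  process <- do.call(abundance_process, raw$process %||% list())
  list(config = config, process = process, run = raw$run %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
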