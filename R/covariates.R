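#' Land-cover composition within a foraging-radius buffer
#'
#' For each query point, computes the area (km2) of every land-cover class
#' inside a circular buffer, the scale over which worker hornets forage from
#' the nest (1 km by default). A fine cell contributes its full area to the
#' class it carries iff its centre lies within `radius` of the query point.
#' Buffers that extend beyond the raster use only the covered cells and are
#' flagged as partial; a point outside the raster extent is flagged as an
#' error rather than silently reported as zeros.
#'
#' @param landcover fine integer [grid_layer()] with classes `1..K`.
#' @param centers data frame with columns `x`, `y` (km).
#' @param radius buffer radius in km.
#' @param class_names optional class names for the output columns (prefixed
#'   `area_`); defaults to `class1..classK`.
#' @return A data frame with one row per centre: `area_<class>` columns in
#'   km2, plus logicals `partial` (buffer clipped by the raster edge) and
#'   `outside` (centre not on the raster; all areas `NA`).
#' @export
land_composition_buffer <- function(landcover, centers, radius = 1,
                                    class_names = NULL) {
  stopifnot(inherits(landcover, "grid_layer"))
  if (radius <= 0) stop("radius must be positive")
  v <- landcover$values
  n_class <- max(v, na.rm = TRUE)
  if (is.null(class_names)) class_names <- paste0("class", seq_len(n_class))
  if (length(class_names) < n_class)
    stop("fewer class_names than classes present in the raster")
  n_class <- length(class_names)
  cell <- landcover$cell
  cell_area <- cell^2
  nr <- nrow(v); nc <- ncol(v)
  half <- ceiling(radius / cell) + 1L
  n_pts <- nrow(centers)
  areas <- matrix(0, n_pts, n_class)
  partial <- logical(n_pts)
  outside <- logical(n_pts)
  xmax <- landcover$xmin + nc * cell
  ymax <- landcover$ymin + nr * cell
  for (i in seq_len(n_pts)) {
    px <- centers$x[i]; py <- centers$y[i]
    if (px < landcover$xmin || px > xmax || py < landcover$ymin || py > ymax) {
      outside[i] <- TRUE
      areas[i, ] <- NA_real_
      next
    }
    c0 <- floor((px - landcover$xmin) / cell - half) + 1L
    r0 <- floor((py - landcover$ymin) / cell - half) + 1L
    cols <- max(1L, c0):min(nc, c0 + 2L * half)
    rows <- max(1L, r0):min(nr, r0 + 2L * half)
    partial[i] <- px - radius < landcover$xmin || px + radius > xmax ||
      py - radius < landcover$ymin || py + radius > ymax
    cx <- landcover$xmin + (cols - 0.5) * cell
    cy <- landcover$ymin + (rows - 0.5) * cell
    inside <- outer(cy - py, cx - px, function(dy, dx) dx^2 + dy^2) <= radius^2
    cls <- v[rows, cols, drop = FALSE][inside]
    areas[i, ] <- tabulate(cls, n_class) * cell_area
  }
  out <- as.data.frame(areas)
  names(out) <- paste0("area_", class_names)
  out$partial <- partial
  out$outside <- outside
  out
}

#' Resample buffer composition onto the coarse grid
#'
#' Evaluates [land_composition_buffer()] at every coarse cell centre so the
#' land-composition covariates live on the same grid as the climate stack.
#'
#' @param landcover fine integer [grid_layer()].
#' @param coarse a coarse [grid_layer()] defining the target grid (e.g. one
#'   climate layer).
#' @param radius buffer radius in km.
#' @param class_names class names for the output layers.
#' @return A named list of coarse [grid_layer()]s, one per class
#'   (`area_<class>`), bitwise-aligned with `coarse`.
#' @export
align_to_coarse <- function(landcover, coarse, radius = 1, class_names = NULL) {
  stopifnot(inherits(landcover, "grid_layer"), inherits(coarse, "grid_layer"))
  if (abs(landcover$xmin - coarse$xmin) > 1e-9 ||
      abs(landcover$ymin - coarse$ymin) > 1e-9)
    stop("alignment error: fine and coarse grids have different origins")
  ctr <- grid_centers(coarse)
  comp <- land_composition_buffer(landcover, ctr, radius = radius,
                                  class_names = class_names)
  area_cols <- grep("^area_", names(comp), value = TRUE)
  stats::setNames(lapply(area_cols, function(cn) {
    grid_layer(matrix(comp[[cn]], nrow(coarse$values), ncol(coarse$values)),
               cell = coarse$cell, xmin = coarse$xmin, ymin = coarse$ymin)
  }), area_cols)
}

#' Greedy collinearity filter on a covariate table
#'
#' Removes variables so that no retained pair has `|Pearson r|` above the
#' threshold. Variables are visited in priority order (e.g. frequency of use
#' in the habitat-modelling literature) and retained iff their absolute
#' correlation with every already-retained variable stays at or below the
#' threshold, so within any violating pair the higher-priority variable
#' survives. Constant columns have undefined correlations and are treated as
#' uncorrelated, with a warning.
#'
#' @param table data frame of candidate covariates (rows = sites).
#' @param threshold correlation magnitude above which a pair is collinear.
#' @param priority character vector ordering all candidate variables, highest
#'   priority first; defaults to column order.
#' @return Character vector of retained variable names (in priority order).
#' @export
collinearity_filter <- function(table, threshold = 0.8, priority = NULL) {
  if (ncol(table) < 2) stop("need at least 2 candidate variables")
  if (nrow(table) < 3) stop("need at least 3 rows to estimate correlations")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (is.null(priority)) priority <- names(table)
  if (!setequal(priority, names(table)))
    stop("priority must cover exactly the candidate variables")
  constant <- vapply(table, function(x) stats::sd(x) == 0, TRUE)
  if (any(constant))
    warning(sprintf("constant column(s) treated as uncorrelated: %s",
                    paste(names(table)[constant], collapse = ", ")))
  cm <- suppressWarnings(stats::cor(table))
  cm[is.na(cm)] <- 0
  retained <- character(0)
  for (var in priority) {
    if (length(retained) == 0 ||
        all(abs(cm[var, retained]) <= threshold))
      retained <- c(retained, var)
  }
  retained
}

#' Per-site mean abundance from yearly trap counts
#'
#' Averages each site's yearly capture counts into the single mean-abundance
#' response `x` used by the abundance models.
#'
#' @param sites a `site_table` (with list-column `counts`) or a long data
#'   frame with columns `site_id` and `count`.
#' @return Data frame `site_id`, `mean_count`.
#' @export
site_mean_abundance <- function(sites) {
  if (!is.null(sites$counts)) {
    n <- lengths(sites$counts)
    if (any(n == 0)) stop("every site needs at least one yearly count")
    data.frame(site_id = sites$site_id,
               mean_count = vapply(sites$counts, mean, 0))
  } else {
    if (is.null(sites$site_id) || is.null(sites$count))
      stop("expected a site table with `counts` or long columns site_id/count")
    agg <- stats::aggregate(count ~ site_id, data = sites, FUN = mean)
    names(agg)[2L] <- "mean_count"
    agg
  }
}

#' Assemble the model covariate table for survey sites
#'
#' Climate values are read from the coarse cell containing each site;
#' land-composition areas come from a foraging-radius buffer around the exact
#' site coordinates.
#'
#' @param sites a `site_table` (columns `x`, `y`).
#' @param env environment list from [generate_environment()], or any list with
#'   `climate` and `landcover`.
#' @param radius buffer radius in km.
#' @param class_names land-class names; defaults to `class1..K`.
#' @return `sites` with one numeric column per covariate appended.
#' @export
site_covariates <- function(sites, env, radius = 1, class_names = NULL) {
  loc <- grid_locate(env$climate[[1L]], sites$x, sites$y)
  if (any(!loc$inside)) stop("site(s) outside the climate grid")
  clim <- lapply(env$climate, function(g) g$values[cbind(loc$row, loc$col)])
  comp <- land_composition_buffer(env$landcover, sites, radius = radius,
                                  class_names = class_names)
  cbind(sites, as.data.frame(clim),
        comp[, grep("^area_", names(comp)), drop = FALSE])
}
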