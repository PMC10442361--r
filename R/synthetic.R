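#' Configuration of a synthetic study landscape
#'
#' Describes the geometry and environmental structure of a simulated study
#' region: a coarse grid carrying smooth bioclimatic fields (1-km cells by
#' default, emulating interpolated climate layers) and a fine categorical
#' land-cover grid (25-m cells, seven classes). Climate variables are rescaled
#' into realistic Korean ranges (annual mean temperature, isothermality,
#' annual/wettest-month/driest-month precipitation, precipitation
#' seasonality); land-class prevalence defaults to a forest-dominated mix.
#'
#' @param extent_km edge length of the square study region in km.
#' @param coarse_cell coarse (climate/model) cell size in km; must be an
#'   integer multiple of `fine_cell`.
#' @param fine_cell fine (land-cover) cell size in km.
#' @param climate_ranges named list of `c(min, max)` per climate variable, in
#'   native units.
#' @param land_classes character vector of land-class names.
#' @param land_prevalence expected areal share of each class; recycled names
#'   from `land_classes`; normalised to sum to 1.
#' @param climate_smooth_km Gaussian smoothing length (sd, km) of the climate
#'   fields.
#' @param land_patch_km resolution (km) of the latent patch grid on which the
#'   land-cover class scores are generated before resampling to the fine grid;
#'   controls the typical patch size.
#' @param seed integer seed; together with the config it fully determines all
#'   generated outputs.
#' @return An object of class `landscape_config`.
#' @export
landscape_config <- function(extent_km = 40,
                             coarse_cell = 1,
                             fine_cell = 0.025,
                             climate_ranges = list(
                               bio1  = c(2.75, 17.41),
                               bio3  = c(17.60, 33.41),
                               bio12 = c(1073, 1928),
                               bio13 = c(209, 486),
                               bio14 = c(14, 77),
                               bio15 = c(35.66, 116.07)
                             ),
                             land_classes = c("agri", "barren", "forest",
                                              "grass", "urban", "water", "wet"),
                             land_prevalence = c(agri = 0.188, barren = 0.013,
                                                 forest = 0.687, grass = 0.029,
                                                 urban = 0.054, water = 0.016,
                                                 wet = 0.007),
                             climate_smooth_km = 10,
                             land_patch_km = 1.5,
                             seed = 1L) {
  if (extent_km <= 0 || coarse_cell <= 0 || fine_cell <= 0)
    stop("configuration error: extent and cell sizes must be positive")
  ratio <- coarse_cell / fine_cell
  if (abs(ratio - round(ratio)) > 1e-8)
    stop("configuration error: coarse_cell must be an integer multiple of fine_cell")
  if (abs(extent_km / coarse_cell - round(extent_km / coarse_cell)) > 1e-8)
    stop("configuration error: extent_km must be a whole number of coarse cells")
  bad <- vapply(climate_ranges, function(r) r[1] >= r[2], TRUE)
  if (any(bad))
    stop("configuration error: climate_ranges must have min < max")
  if (length(land_prevalence) != length(land_classes))
    stop("configuration error: one prevalence per land class")
  structure(list(
    extent_km = extent_km, coarse_cell = coarse_cell, fine_cell = fine_cell,
    climate_ranges = climate_ranges, land_classes = land_classes,
    land_prevalence = land_prevalence / sum(land_prevalence),
    climate_smooth_km = climate_smooth_km, land_patch_km = land_patch_km,
    seed = as.integer(seed)
  ), class = "landscape_config")
}

# Gaussian smoothing of a matrix field by separable 1-D kernels, with
# truncated-and-renormalised edges.
gaussian_smooth <- function(m, sd_cells) {
  if (sd_cells <= 0) return(m)
  half <- max(1L, ceiling(3 * sd_cells))
  k <- stats::dnorm(seq(-half, half), sd = sd_cells)
  smooth_1d <- function(mat) {
    n <- nrow(mat)
    h <- min(half, n - 1L)
    # banded smoothing matrix, rows renormalised at the edges
    S <- matrix(0, n, n)
    for (d in seq(-h, h)) {
      idx <- seq_len(n - abs(d))
      if (d >= 0) S[cbind(idx, idx + d)] <- k[d + half + 1]
      else S[cbind(idx - d, idx)] <- k[d + half + 1]
    }
    (S / rowSums(S)) %*% mat
  }
  t(smooth_1d(t(smooth_1d(m))))
}

rescale_range <- function(m, lo, hi) {
  rng <- range(m)
  if (rng[1] == rng[2]) return(matrix((lo + hi) / 2, nrow(m), ncol(m)))
  lo + (m - rng[1]) / (rng[2] - rng[1]) * (hi - lo)
}

#' Generate synthetic climate and land-cover rasters
#'
#' Climate layers are spatially autocorrelated Gaussian fields (white noise
#' smoothed over `climate_smooth_km`) min-max rescaled into each variable's
#' configured range, on the coarse grid. Land cover is a categorical field on
#' the fine grid: per-class latent scores (smoothed noise plus a
#' prevalence-dependent offset) are generated on a patch-resolution grid,
#' resampled to the fine grid by nearest neighbour, and the class with the
#' highest score wins each cell.
#'
#' @param config a [landscape_config()].
#' @return A list with `climate` (named list of coarse [grid_layer()]s) and
#'   `landcover` (fine integer [grid_layer()]; levels follow
#'   `config$land_classes`).
#' @export
generate_environment <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  withr::with_seed(config$seed, {
    n_co <- round(config$extent_km / config$coarse_cell)
    climate <- lapply(config$climate_ranges, function(rng) {
      z <- matrix(stats::rnorm(n_co * n_co), n_co, n_co)
      z <- gaussian_smooth(z, config$climate_smooth_km / config$coarse_cell)
      # histogram-equalise: smooth field, exactly uniform marginal over the
      # configured range (the whole climatic gradient is represented in every
      # realisation, as it is across a national study area)
      u <- (rank(z, ties.method = "first") - 0.5) / length(z)
      z <- matrix(rng[1] + u * (rng[2] - rng[1]), n_co, n_co)
      grid_layer(z, cell = config$coarse_cell)
    })

    # latent class scores on a patch grid, upsampled to the fine grid
    n_fine <- round(config$extent_km / config$fine_cell)
    n_patch <- max(8L, round(config$extent_km / (config$land_patch_km / 4)))
    n_patch <- min(n_patch, n_fine)
    prev <- config$land_prevalence
    scores <- lapply(seq_along(prev), function(k) {
      z <- matrix(stats::rnorm(n_patch * n_patch), n_patch, n_patch)
      z <- gaussian_smooth(z, config$land_patch_km / (config$extent_km / n_patch))
      z / stats::sd(z) + log(prev[k]) * 0.45
    })
    cls_patch <- matrix(1L, n_patch, n_patch)
    best <- scores[[1L]]
    for (k in seq_along(scores)[-1L]) {
      better <- scores[[k]] > best
      cls_patch[better] <- k
      best[better] <- scores[[k]][better]
    }
    idx <- pmin.int(ceiling(seq_len(n_fine) / n_fine * n_patch), n_patch)
    landcover <- grid_layer(cls_patch[idx, idx, drop = FALSE],
                            cell = config$fine_cell)
    list(climate = climate, landcover = landcover)
  })
}

#' Abundance-generating process
#'
#' Defines the latent expected-abundance surface and the observation model of
#' the simulator. The log expected count in a cell is an intercept plus a sum
#' of covariate effects; each effect acts on the covariate rescaled to `[0, 1]`
#' over its plausible range and can be `"linear"`, `"threshold"` (step at
#' `at`), or `"saturating"` (Michaelis-Menten with half-saturation `half`).
#' Observed yearly trap counts are negative binomial (size `dispersion`)
#' around the cell expectation, thinned by a site-level occupancy envelope.
#'
#' The envelope is the occurrence process of the simulation: the probability
#' that a site is occupied at all is a logistic function of an environmental
#' driver - by default a climate axis (annual mean temperature), not the
#' expected abundance itself. Establishment is thereby partially decoupled
#' from abundance magnitude: within the suitable envelope, occupancy
#' saturates while expected abundance still varies over orders of magnitude
#' through the remaining covariates. This is the data structure in which
#' occurrence models can tell presence from absence yet carry little
#' information about how abundant the species is where it occurs. Setting
#' `var = "mu"` makes the envelope a function of log1p expected abundance
#' instead, coupling occurrence fully to abundance.
#'
#' @param intercept intercept of the log-scale linear predictor.
#' @param terms list of effect terms; each a list with `var`, `shape`
#'   (`"linear"`, `"threshold"`, `"saturating"`), `coef`, optional `at`/`half`
#'   and an optional `range = c(lo, hi)` used to standardise the covariate
#'   (climate variables default to their configured range, land-composition
#'   areas to `[0, pi]` km2).
#' @param dispersion negative-binomial size parameter of yearly counts
#'   (smaller = more overdispersed).
#' @param occupancy list defining the logistic occupancy envelope: `var`
#'   (covariate name, or `"mu"` for log1p expected abundance), `midpoint` and
#'   `steepness` on the standardised driver scale (`[0, 1]` for covariates,
#'   log1p counts for `"mu"`). `steepness = Inf` gives a hard threshold;
#'   `midpoint = -Inf` makes every site occupied.
#' @return An object of class `abundance_process`.
#' @export
abundance_process <- function(intercept = 1.2,
                              terms = list(
                                list(var = "bio1", shape = "linear", coef = 3.51),
                                list(var = "bio15", shape = "linear", coef = -2.30),
                                list(var = "area_forest", shape = "saturating",
                                     coef = 3.24, half = 0.35),
                                list(var = "area_urban", shape = "linear", coef = 1.22)
                              ),
                              dispersion = 2.5,
                              occupancy = list(var = "bio3", midpoint = 0.22,
                                               steepness = 8)) {
  if (dispersion <= 0) stop("dispersion must be positive")
  if (is.numeric(occupancy) && length(occupancy) == 2)
    occupancy <- list(var = "mu", midpoint = occupancy[[1L]],
                      steepness = occupancy[[2L]])
  stopifnot(is.list(occupancy),
            all(c("var", "midpoint", "steepness") %in% names(occupancy)))
  structure(list(intercept = intercept, terms = terms,
                 dispersion = dispersion, occupancy = occupancy),
            class = "abundance_process")
}

# evaluate one effect term on a numeric vector/matrix of covariate values
eval_term <- function(term, x, config) {
  rng <- term$range
  if (is.null(rng)) {
    rng <- if (term$var %in% names(config$climate_ranges))
      config$climate_ranges[[term$var]] else c(0, pi)
  }
  u <- pmin(pmax((x - rng[1]) / (rng[2] - rng[1]), 0), 1)
  switch(term$shape,
    linear = term$coef * u,
    threshold = term$coef * (u > (if (is.null(term$at)) 0.5 else term$at)),
    saturating = {
      h <- if (is.null(term$half)) 0.3 else term$half
      term$coef * u / (u + h)
    },
    stop(sprintf("unknown effect shape '%s'", term$shape))
  )
}

#' Latent expected-abundance surface
#'
#' Computes the per-cell expected yearly trap count
#' `mu = exp(intercept + sum of effects)` on the coarse grid from the climate
#' stack and the land-composition stack (per-class buffer areas, as produced
#' by [align_to_coarse()]).
#'
#' @param climate named list of coarse climate [grid_layer()]s.
#' @param composition named list of coarse land-composition [grid_layer()]s
#'   (km2 per class, names like `area_forest`).
#' @param process an [abundance_process()].
#' @param config the [landscape_config()] (supplies standardisation ranges).
#' @return A [grid_layer()] of expected counts, with the process attached as
#'   attribute `"process"`.
#' @export
generate_abundance_surface <- function(climate, composition, process, config) {
  stopifnot(inherits(process, "abundance_process"))
  layers <- c(climate, composition)
  ref <- layers[[1L]]
  for (nm in names(layers)) stop_if_grid_mismatch(ref, layers[[nm]], nm)
  eta <- matrix(process$intercept, nrow(ref$values), ncol(ref$values))
  for (term in process$terms) {
    if (!term$var %in% names(layers))
      stop(sprintf("alignment error: covariate '%s' not in the stacks", term$var))
    eta <- eta + eval_term(term, layers[[term$var]]$values, config)
  }
  out <- grid_layer(exp(eta), cell = ref$cell, xmin = ref$xmin, ymin = ref$ymin)
  occ <- process$occupancy
  driver <- if (identical(occ$var, "mu")) {
    log1p(out$values)
  } else {
    if (!occ$var %in% names(layers))
      stop(sprintf("alignment error: occupancy driver '%s' not in the stacks",
                   occ$var))
    rng <- if (occ$var %in% names(config$climate_ranges))
      config$climate_ranges[[occ$var]] else c(0, pi)
    pmin(pmax((layers[[occ$var]]$values - rng[1]) / (rng[2] - rng[1]), 0), 1)
  }
  p_occ <- occupancy_prob(driver, occ)
  attr(out, "occupancy") <- grid_layer(
    matrix(p_occ, nrow(ref$values), ncol(ref$values)),
    cell = ref$cell, xmin = ref$xmin, ymin = ref$ymin)
  attr(out, "process") <- process
  out
}

# logistic occupancy probability given the (already standardised) driver
occupancy_prob <- function(driver, occupancy) {
  mid <- occupancy$midpoint; steep <- occupancy$steepness
  if (!is.finite(mid) && mid < 0) return(rep(1, length(driver)))
  if (!is.finite(steep)) return(as.numeric(driver > mid))
  stats::plogis(steep * (driver - mid))
}

#' Simulate a trap survey over the abundance surface
#'
#' Places `n_sites` traps at distinct coarse cells (uniformly at random, at
#' cell centres), assigns each site 1-4 survey years, and draws yearly counts:
#' a site is first declared occupied or not from the process's occupancy
#' envelope; occupied sites draw negative-binomial counts around the cell's
#' expected abundance, unoccupied sites record zeros. The default process and
#' survey size are calibrated so that the four abundance categories
#' (Absence / Low / Mid / High) occur in proportions close to 61/50/110/27
#' out of 248 and the count distribution is strongly right-skewed.
#'
#' @param surface expected-abundance [grid_layer()] from
#'   [generate_abundance_surface()].
#' @param n_sites number of trap locations.
#' @param config the [landscape_config()].
#' @param process the [abundance_process()]; defaults to the one attached to
#'   `surface`.
#' @param years candidate survey years (a site samples the first k of them,
#'   k uniform on 1..4).
#' @return A data frame of class `site_table`: `site_id`, `x`, `y`, `row`,
#'   `col`, list-column `counts` (named yearly counts), `n_years`,
#'   `mean_count`, `category`.
#' @export
sample_sites <- function(surface, n_sites = 248, config,
                         process = attr(surface, "process"),
                         years = 2018:2021) {
  stopifnot(inherits(surface, "grid_layer"), inherits(process, "abundance_process"))
  n_cells <- length(surface$values)
  if (n_sites < 1) stop("n_sites must be at least 1")
  if (n_sites > n_cells)
    stop(sprintf("n_sites (%d) exceeds the number of coarse cells (%d)",
                 n_sites, n_cells))
  withr::with_seed(config$seed + 1L, {
    cells <- sample.int(n_cells, n_sites)
    centers <- grid_centers(surface)[cells, , drop = FALSE]
    mu <- as.vector(surface$values)[cells]
    occ_grid <- attr(surface, "occupancy")
    p_occ <- if (!is.null(occ_grid)) as.vector(occ_grid$values)[cells]
             else occupancy_prob(log1p(mu), process$occupancy)
    occ <- stats::rbinom(n_sites, 1L, p_occ)
    n_years <- sample(4L, n_sites, replace = TRUE)
    counts <- lapply(seq_len(n_sites), function(i) {
      yrs <- years[seq_len(n_years[i])]
      ct <- if (occ[i] == 1L && mu[i] > 0)
        stats::rnbinom(n_years[i], size = process$dispersion, mu = mu[i])
      else rep(0L, n_years[i])
      stats::setNames(as.integer(ct), yrs)
    })
    mean_count <- vapply(counts, function(ct) mean(ct), 0)
    out <- data.frame(
      site_id = sprintf("S%03d", seq_len(n_sites)),
      x = centers$x, y = centers$y, row = centers$row, col = centers$col,
      n_years = n_years, mean_count = mean_count,
      category = categorize(mean_count)
    )
    out$counts <- counts
    class(out) <- c("site_table", "data.frame")
    out
  })
}

#' Simulate administrative units with population, apiary and report data
#'
#' Tessellates the coarse grid into `n_units` contiguous units by discrete
#' Voronoi assignment (each coarse cell joins its nearest of `n_units` random
#' unit seeds), then draws per-unit sensitivity and validation data:
#' residential population and honeybee-colony counts from right-skewed
#' log-normal distributions, nest-removal report counts from a Poisson whose
#' expectation is proportional to (mean unit abundance x population) with
#' multiplicative log-normal heterogeneity, and an apiary damage rate
#' increasing with unit abundance on the log scale. The report process injects
#' the positive abundance-report correlation that the validation step is meant
#' to detect.
#'
#' @param surface expected-abundance [grid_layer()] on the coarse grid.
#' @param n_units number of administrative units (default 159).
#' @param config the [landscape_config()].
#' @param report_rate proportionality constant of expected reports per
#'   (abundance x resident); `0` yields all-zero report counts.
#' @param report_noise_sd sd of the log-normal heterogeneity multiplier on
#'   the report expectation.
#' @return A data frame of class `admin_table` (`unit_id`, `population`,
#'   `colonies`, `report_count`, `apiary_rate`, `n_cells`, `mean_abundance`)
#'   with the unit-assignment [grid_layer()] attached as attribute
#'   `"assignment"`.
#' @export
generate_admin_data <- function(surface, n_units = 159, config,
                                report_rate = 4e-5, report_noise_sd = 0.6) {
  stopifnot(inherits(surface, "grid_layer"))
  n_cells <- length(surface$values)
  if (n_units < 2) stop("n_units must be at least 2")
  if (n_units > n_cells)
    stop(sprintf("n_units (%d) exceeds the number of coarse cells (%d)",
                 n_units, n_cells))
  withr::with_seed(config$seed + 2L, {
    ctr <- grid_centers(surface)
    seeds <- sample.int(n_cells, n_units)
    # nearest-seed assignment of every coarse cell
    d2 <- outer(ctr$x, ctr$x[seeds], "-")^2 + outer(ctr$y, ctr$y[seeds], "-")^2
    unit <- max.col(-d2, ties.method = "first")
    assignment <- grid_layer(
      matrix(unit, nrow(surface$values), ncol(surface$values)),
      cell = surface$cell, xmin = surface$xmin, ymin = surface$ymin)
    mu <- as.vector(surface$values)
    mean_ab <- vapply(seq_len(n_units),
                      function(u) mean(mu[unit == u]), 0)
    n_in <- tabulate(unit, n_units)
    population <- pmax(1, round(stats::rlnorm(n_units, meanlog = 10.5, sdlog = 0.9)))
    colonies <- pmax(1, round(stats::rlnorm(n_units, meanlog = 6.2, sdlog = 0.8)))
    lambda <- report_rate * mean_ab * population *
      exp(stats::rnorm(n_units, 0, report_noise_sd))
    report_count <- stats::rpois(n_units, lambda)
    la <- log1p(mean_ab)
    apiary_rate <- stats::plogis(
      -2 + 1.2 * (la - mean(la)) / max(stats::sd(la), 1e-9) +
        stats::rnorm(n_units, 0, 0.5))
    out <- data.frame(
      unit_id = sprintf("U%03d", seq_len(n_units)),
      population = population, colonies = colonies,
      report_count = report_count, apiary_rate = apiary_rate,
      n_cells = n_in, mean_abundance = mean_ab
    )
    attr(out, "assignment") <- assignment
    class(out) <- c("admin_table", "data.frame")
    out
  })
}
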