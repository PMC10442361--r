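#' Aggregate a prediction raster over administrative units
#'
#' Unit-level hazard: the mean of `log(x + 1)`-transformed cell predictions
#' over the cells whose centres fall inside each unit. Units containing no
#' cell centres are reported as missing.
#'
#' @param prediction coarse [grid_layer()] of predicted abundance (original
#'   count scale).
#' @param admin an `admin_table` from [generate_admin_data()], or any object
#'   with an `"assignment"` [grid_layer()] attribute on the same grid.
#' @param log_scale aggregate on the `log1p` scale (default) or on the raw
#'   scale.
#' @return `admin` with a `mean_log_abundance` column appended (named
#'   `mean_pred` when `log_scale = FALSE`).
#' @export
aggregate_admin <- function(prediction, admin, log_scale = TRUE) {
  assignment <- attr(admin, "assignment")
  if (is.null(assignment)) stop("admin table lacks an assignment grid")
  stop_if_grid_mismatch(prediction, assignment, "prediction and admin grids")
  vals <- if (log_scale) log1p(as.vector(prediction$values))
          else as.vector(prediction$values)
  unit <- as.vector(assignment$values)
  m <- tapply(vals, factor(unit, levels = seq_len(nrow(admin))), mean)
  out <- as.data.frame(admin)
  col <- if (log_scale) "mean_log_abundance" else "mean_pred"
  out[[col]] <- as.numeric(m)
  attr(out, "assignment") <- assignment
  class(out) <- class(admin)
  out
}

#' Reports per capita
#'
#' Standardizes nest-removal report counts by the residential population of
#' each unit so units of different size are comparable. Units with zero
#' population get `NA` with a warning (they cannot be standardized and are
#' excluded from validation correlations).
#'
#' @param report_count nonnegative counts.
#' @param population resident counts.
#' @return Numeric vector of reports per resident.
#' @export
standardize_reports <- function(report_count, population) {
  if (any(report_count < 0, na.rm = TRUE) || any(population < 0, na.rm = TRUE))
    stop("report_count and population must be nonnegative")
  zero <- !is.na(population) & population == 0
  if (any(zero))
    warning(sprintf("%d unit(s) with zero population set to NA", sum(zero)))
  out <- report_count / population
  out[zero] <- NA_real_
  out
}

#' Validate aggregated abundance against independent report data
#'
#' Correlates unit-level abundance (the `mean_log_abundance` hazard) with
#' (i) nest-removal reports per capita and (ii) the apiary damage rate, via
#' [correlation_test()]. Both correlations are expected positive when the
#' abundance map is informative.
#'
#' @param units an aggregated `admin_table` (after [aggregate_admin()]).
#' @return List with `reports` and `apiary` [correlation_test()] results.
#' @export
validate_abundance <- function(units) {
  if (is.null(units$mean_log_abundance))
    stop("units must carry mean_log_abundance (run aggregate_admin first)")
  rpc <- standardize_reports(units$report_count, units$population)
  out <- list(reports = correlation_test(units$mean_log_abundance, rpc))
  if (!is.null(units$apiary_rate))
    out$apiary <- correlation_test(units$mean_log_abundance, units$apiary_rate)
  out
}

#' Hazard x sensitivity risk index
#'
#' Risk is the product of the hazard (predicted hornet abundance) and a
#' sensitivity factor (residential population for human-health risk, number
#' of honeybee colonies for apicultural risk).
#'
#' @param hazard nonnegative hazard values.
#' @param sensitivity nonnegative sensitivity values.
#' @return `hazard * sensitivity`.
#' @export
risk_index <- function(hazard, sensitivity) {
  if (any(hazard < 0, na.rm = TRUE) || any(sensitivity < 0, na.rm = TRUE))
    stop("hazard and sensitivity must be nonnegative")
  hazard * sensitivity
}

#' Classify values into ordinal levels by quantile breaks
#'
#' Five-level classification (for mapping) with breaks at the
#' 20/40/60/80th percentiles; class 1 is the lowest fifth. Classification is
#' monotone: a larger value never receives a smaller class. When ties leave
#' fewer distinct breaks than classes the classing is coarser, with a
#' warning.
#'
#' @param values numeric vector.
#' @param n_classes number of levels.
#' @return Integer vector of class labels in `1..n_classes`.
#' @export
classify_levels <- function(values, n_classes = 5) {
  qs <- stats::quantile(values, probs = seq_len(n_classes - 1) / n_classes,
                        na.rm = TRUE, names = FALSE)
  breaks <- unique(qs)
  if (length(breaks) < n_classes - 1)
    warning("tied quantiles: fewer than ", n_classes, " distinct classes")
  findInterval(values, breaks, left.open = TRUE) + 1L
}

#' Build the unit-level risk table
#'
#' Combines the aggregated hazard with both sensitivity factors into the two
#' risk indices and their five-level classes.
#'
#' @param units an aggregated `admin_table` with `mean_log_abundance`.
#' @param n_classes number of risk levels.
#' @return `units` with columns `risk_health`, `risk_honeybee`,
#'   `class_health`, `class_honeybee`, `class_abundance` appended.
#' @export
unit_risk <- function(units, n_classes = 5) {
  if (is.null(units$mean_log_abundance))
    stop("units must carry mean_log_abundance (run aggregate_admin first)")
  units$risk_health <- risk_index(units$mean_log_abundance, units$population)
  units$risk_honeybee <- risk_index(units$mean_log_abundance, units$colonies)
  units$class_abundance <- classify_levels(units$mean_log_abundance, n_classes)
  units$class_health <- classify_levels(units$risk_health, n_classes)
  units$class_honeybee <- classify_levels(units$risk_honeybee, n_classes)
  units
}
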