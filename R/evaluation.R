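#' Standardized mean absolute error
#'
#' Mean absolute error between predictions and observations, scaled by the
#' mean observed value so models on different abundance scales are directly
#' comparable. An ideal model scores 0.
#'
#' @param pred,obs numeric vectors of equal length.
#' @return A single nonnegative number.
#' @export
standardized_mae <- function(pred, obs) {
  if (length(pred) != length(obs) || length(obs) < 1)
    stop("pred and obs must have equal positive length")
  m <- mean(obs)
  if (m == 0) stop("mean observed value is 0: scaled MAE undefined")
  mean(abs(pred - obs)) / m
}

#' Discrimination statistics: Pearson r and calibration slope
#'
#' Pearson correlation between predictions and observations, and the
#' least-squares slope of the linear model `obs ~ pred` (the calibration
#' convention: a perfectly calibrated model has slope 1; slopes below 1
#' indicate over-dispersion of the predictions). `slope_obs_on_pred = FALSE`
#' regresses predictions on observations instead.
#'
#' @param pred,obs numeric vectors of equal length >= 3.
#' @param slope_obs_on_pred regress observations on predictions (default)?
#' @return List with `pearson_r` and `slope`.
#' @export
discrimination <- function(pred, obs, slope_obs_on_pred = TRUE) {
  if (length(pred) != length(obs) || length(obs) < 3)
    stop("need equal-length vectors of at least 3 values")
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0)
    stop("constant input: correlation undefined")
  r <- stats::cor(pred, obs)
  slope <- if (slope_obs_on_pred)
    stats::cov(pred, obs) / stats::var(pred)
  else
    stats::cov(pred, obs) / stats::var(obs)
  list(pearson_r = r, slope = slope)
}

#' Area under the ROC curve
#'
#' Rank-sum (Mann-Whitney) formulation: the probability that a random
#' presence scores above a random absence, counting ties as one half.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1, logical, or a 2-level factor).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  y <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' t statistic of a Pearson correlation
#'
#' `t = r * sqrt(df) / sqrt(1 - r^2)` with `df = n - 2`.
#'
#' @param r Pearson correlation.
#' @param df degrees of freedom (n - 2).
#' @return The t statistic (`Inf` with sign of r when `|r| = 1`).
#' @export
t_from_r <- function(r, df) {
  if (abs(r) >= 1) return(sign(r) * Inf)
  r * sqrt(df) / sqrt(1 - r^2)
}

#' Pearson correlation test
#'
#' Correlation between two vectors with the two-sided t test of the null
#' `r = 0` (`df = n - 2`).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return List of class `correlation_test`: `r`, `t`, `df`, `p`, `n`.
#' @export
correlation_test <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  r <- stats::cor(x, y)
  df <- n - 2
  t <- t_from_r(r, df)
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df)
  structure(list(r = r, t = t, df = df, p = p, n = n),
            class = "correlation_test")
}

#' @export
print.correlation_test <- function(x, ...) {
  cat(sprintf("Pearson's r = %.3f; t = %.3f; df = %d; p = %.3g\n",
              x$r, x$t, x$df, x$p))
  invisible(x)
}

#' Kruskal-Wallis test with Dunn's post-hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis rank-sum test across groups, followed by
#' Dunn's pairwise z tests with Bonferroni correction and a compact letter
#' display: groups sharing a letter are not significantly different at
#' adjusted p < `alpha`.
#'
#' @param values numeric vector.
#' @param groups grouping factor (or coercible).
#' @param alpha significance level for the letter display.
#' @return List of class `kruskal_dunn`: `H`, `df`, `p`, data frame
#'   `pairwise` (`group1`, `group2`, `z`, `p_adj`), and named character
#'   `letters`.
#' @export
kruskal_dunn <- function(values, groups, alpha = 0.05) {
  g <- droplevels(factor(groups))
  k <- nlevels(g)
  if (k < 2) stop("need at least 2 groups")
  n <- length(values)
  if (length(unique(values)) == 1L) {
    # no variation at all: H = 0 by convention, nothing separates
    pairs <- utils::combn(levels(g), 2)
    pairwise <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                           z = 0, p_adj = 1)
    return(structure(
      list(H = 0, df = k - 1, p = 1, pairwise = pairwise,
           letters = stats::setNames(rep("a", k), levels(g))),
      class = "kruskal_dunn"))
  }
  kw <- stats::kruskal.test(values, g)
  rk <- rank(values)
  mean_rank <- tapply(rk, g, mean)
  n_g <- tapply(rk, g, length)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- utils::combn(levels(g), 2)
  n_pairs <- ncol(pairs)
  z <- p_adj <- numeric(n_pairs)
  for (j in seq_len(n_pairs)) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / n_g[[a]] + 1 / n_g[[b]]))
    z[j] <- (mean_rank[[a]] - mean_rank[[b]]) / se
    p_adj[j] <- min(1, 2 * stats::pnorm(-abs(z[j])) * n_pairs)
  }
  pairwise <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                         z = z, p_adj = p_adj)
  letters_out <- compact_letters(levels(g), pairwise, alpha)
  structure(list(H = unname(kw$statistic), df = unname(kw$parameter),
                 p = kw$p.value, pairwise = pairwise, letters = letters_out),
            class = "kruskal_dunn")
}

# insert-and-absorb compact letter display: start from one block holding all
# groups; every significant pair splits the blocks containing both; blocks
# that become subsets of others are absorbed.
compact_letters <- function(groups, pairwise, alpha = 0.05) {
  blocks <- list(groups)
  sig <- pairwise[pairwise$p_adj < alpha, , drop = FALSE]
  for (j in seq_len(nrow(sig))) {
    a <- sig$group1[j]; b <- sig$group2[j]
    new_blocks <- list()
    for (bl in blocks) {
      if (a %in% bl && b %in% bl)
        new_blocks <- c(new_blocks, list(setdiff(bl, a)), list(setdiff(bl, b)))
      else new_blocks <- c(new_blocks, list(bl))
    }
    # absorb subsets
    keep <- rep(TRUE, length(new_blocks))
    for (i in seq_along(new_blocks)) {
      for (l in seq_along(new_blocks)) {
        if (i != l && keep[i] && keep[l] &&
            all(new_blocks[[i]] %in% new_blocks[[l]]) &&
            !(all(new_blocks[[l]] %in% new_blocks[[i]]) && i < l))
          keep[i] <- FALSE
      }
    }
    blocks <- new_blocks[keep]
  }
  out <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(blocks)) {
    for (gname in blocks[[i]])
      out[gname] <- paste0(out[gname], letters[i])
  }
  out
}

#' Replicated stratified evaluation of model variants
#'
#' Runs `n_rep` independent stratified 70/30 splits. In each replicate every
#' abundance-model variant (RF/GBM x raw/log1p) is fitted on the training set
#' and scored on the test set with [standardized_mae()] and
#' [discrimination()] on the abundance scale; every occurrence-model variant
#' (RF/GBM) is additionally scored with [auc_score()] against the binary test
#' labels, and its abundance metrics are computed by comparing predicted
#' probability with observed relative abundance (observations scaled by the
#' maximum observed mean abundance of the full data set).
#'
#' @param sites data frame with `mean_count`, `category` and covariates.
#' @param covariates character vector of covariate names.
#' @param n_rep number of replicates.
#' @param base_seed integer; replicate i uses seed `base_seed + i`.
#' @param train_fraction training fraction of each stratified split.
#' @param sam_variants,sdm_variants data frames of variants to run (defaults:
#'   all four SAMs, both SDMs); set `sdm_variants = NULL` to skip SDMs.
#' @return List of class `evaluation`: `replicates` (long data frame with
#'   columns replicate, variant, task, algorithm, transform, accuracy,
#'   pearson_r, slope, auc) and `summary` (mean and sd per variant and
#'   metric).
#' @export
replicate_evaluation <- function(sites, covariates, n_rep = 100,
                                 base_seed = 1L, train_fraction = 0.7,
                                 sam_variants = expand.grid(
                                   algorithm = c("RF", "GBM"),
                                   transform = c("raw", "log1p"),
                                   stringsAsFactors = FALSE),
                                 sdm_variants = data.frame(
                                   algorithm = c("RF", "GBM"))) {
  if (n_rep < 1) stop("n_rep must be at least 1")
  max_obs <- max(sites$mean_count)
  rows <- list()
  all_variants <- rbind(
    data.frame(variant = paste0("SAM_", sam_variants$algorithm, "_",
                                sam_variants$transform),
               task = "SAM", algorithm = sam_variants$algorithm,
               transform = sam_variants$transform),
    if (!is.null(sdm_variants))
      data.frame(variant = paste0("SDM_", sdm_variants$algorithm),
                 task = "SDM", algorithm = sdm_variants$algorithm,
                 transform = "binary"))
  for (i in seq_len(n_rep)) {
    seed_i <- as.integer(base_seed) + i
    split <- tryCatch(stratified_split(sites, train_fraction, seed = seed_i),
                      error = function(e) e)
    if (inherits(split, "error")) {
      # a failed partition is recorded for every variant, not fatal
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = i, all_variants,
        accuracy = NA_real_, pearson_r = NA_real_, slope = NA_real_,
        auc = NA_real_, error = conditionMessage(split))
      next
    }
    obs <- split$test$mean_count
    for (v in seq_len(nrow(sam_variants))) {
      alg <- sam_variants$algorithm[v]; tr <- sam_variants$transform[v]
      row <- tryCatch({
        fit <- fit_sam(split$train, covariates, alg, tr, seed = seed_i)
        pred <- predict_abundance(fit, split$test)
        disc <- discrimination(pred, obs)
        data.frame(replicate = i, variant = paste0("SAM_", alg, "_", tr),
                   task = "SAM", algorithm = alg, transform = tr,
                   accuracy = standardized_mae(pred, obs),
                   pearson_r = disc$pearson_r, slope = disc$slope,
                   auc = NA_real_, error = NA_character_)
      }, error = function(e)
        data.frame(replicate = i, variant = paste0("SAM_", alg, "_", tr),
                   task = "SAM", algorithm = alg, transform = tr,
                   accuracy = NA_real_, pearson_r = NA_real_,
                   slope = NA_real_, auc = NA_real_,
                   error = conditionMessage(e)))
      rows[[length(rows) + 1L]] <- row
    }
    if (!is.null(sdm_variants)) for (v in seq_len(nrow(sdm_variants))) {
      alg <- sdm_variants$algorithm[v]
      row <- tryCatch({
        fit <- fit_sdm(split$train, covariates, alg, seed = seed_i)
        prob <- predict_presence(fit, split$test)
        obs_rel <- obs / max_obs
        disc <- discrimination(prob, obs_rel)
        data.frame(replicate = i, variant = paste0("SDM_", alg),
                   task = "SDM", algorithm = alg, transform = "binary",
                   accuracy = standardized_mae(prob, obs_rel),
                   pearson_r = disc$pearson_r, slope = disc$slope,
                   auc = auc_score(prob, obs > 0), error = NA_character_)
      }, error = function(e)
        data.frame(replicate = i, variant = paste0("SDM_", alg),
                   task = "SDM", algorithm = alg, transform = "binary",
                   accuracy = NA_real_, pearson_r = NA_real_,
                   slope = NA_real_, auc = NA_real_,
                   error = conditionMessage(e)))
      rows[[length(rows) + 1L]] <- row
    }
  }
  replicates <- do.call(rbind, rows)
  metrics <- c("accuracy", "pearson_r", "slope", "auc")
  summ <- do.call(rbind, lapply(split(replicates, replicates$variant), function(d) {
    out <- data.frame(variant = d$variant[1L], task = d$task[1L],
                      algorithm = d$algorithm[1L], transform = d$transform[1L],
                      n_ok = sum(is.na(d$error)))
    for (m in metrics) {
      out[[paste0(m, "_mean")]] <- mean(d[[m]], na.rm = TRUE)
      out[[paste0(m, "_sd")]] <- stats::sd(d[[m]], na.rm = TRUE)
    }
    out
  }))
  rownames(summ) <- NULL
  structure(list(replicates = replicates, summary = summ),
            class = "evaluation")
}

#' Select the best variant by rank sums
#'
#' Ranks each variant on every metric (direction per metric: `"min"` = lower
#' is better, `"max"` = higher is better, `"one"` = closer to 1 is better)
#' and selects the variant with the smallest rank sum. Ties are broken by the
#' rank on the first metric, then by input order.
#'
#' @param summary data frame with a `variant` column and one column per
#'   metric (e.g. the `summary` element of [replicate_evaluation()], using
#'   the `_mean` columns).
#' @param metrics named character vector mapping metric column to direction,
#'   e.g. `c(accuracy = "min", pearson_r = "max", slope = "one")`.
#' @return The selected variant id, with the ranked table as attribute
#'   `"ranks"`.
#' @export
rank_select <- function(summary,
                        metrics = c(accuracy = "min", pearson_r = "max",
                                    slope = "one")) {
  if (nrow(summary) == 0) stop("empty summary table")
  missing <- setdiff(names(metrics), names(summary))
  if (length(missing))
    stop("missing metric column(s): ", paste(missing, collapse = ", "))
  if (any(is.na(summary[, names(metrics)])))
    stop("missing metric values")
  ranks <- vapply(names(metrics), function(m) {
    v <- summary[[m]]
    key <- switch(metrics[[m]],
                  min = v, max = -v, one = abs(v - 1),
                  stop("direction must be 'min', 'max' or 'one'"))
    rank(key, ties.method = "average")
  }, numeric(nrow(summary)))
  ranks <- matrix(ranks, nrow = nrow(summary),
                  dimnames = list(NULL, names(metrics)))
  total <- rowSums(ranks)
  ord <- order(total, ranks[, 1L], seq_len(nrow(summary)))
  tab <- data.frame(variant = summary$variant, ranks, rank_sum = total)
  structure(summary$variant[ord[1L]], ranks = tab[ord, , drop = FALSE])
}
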