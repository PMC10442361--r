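#' Abundance categories
#'
#' Classifies mean trap captures into the four survey abundance levels:
#' Absence (exactly 0), Low (0 < x < 10), Mid (10 <= x < 100), High
#' (x >= 100). The integer category labels of the survey (1-9, 10-99) are
#' generalised to half-open intervals so fractional multi-year means (e.g.
#' 9.5) are always classifiable.
#'
#' @param mean_count nonnegative numeric vector of mean capture counts.
#' @return Factor with levels `Absence`, `Low`, `Mid`, `High`.
#' @export
categorize <- function(mean_count) {
  if (any(mean_count < 0, na.rm = TRUE)) stop("mean_count must be nonnegative")
  lab <- ifelse(mean_count == 0, "Absence",
         ifelse(mean_count < 10, "Low",
         ifelse(mean_count < 100, "Mid", "High")))
  factor(lab, levels = c("Absence", "Low", "Mid", "High"))
}

#' Stratified train/test split
#'
#' Splits site rows into training and test sets at random while preserving
#' the compositional proportion of abundance categories: within each category
#' `round(train_fraction * n)` rows go to training.
#'
#' @param sites data frame with a `category` column.
#' @param train_fraction fraction of each category assigned to training.
#' @param seed integer seed.
#' @return List with data frames `train` and `test`.
#' @export
stratified_split <- function(sites, train_fraction = 0.7, seed = 1L) {
  cat_ <- droplevels(factor(sites$category))
  sizes <- table(cat_)
  if (train_fraction < 1 && any(sizes < 2))
    stop(sprintf("category with fewer than 2 members: %s",
                 paste(names(sizes)[sizes < 2], collapse = ", ")))
  withr::with_seed(as.integer(seed), {
    train_idx <- unlist(lapply(levels(cat_), function(lv) {
      idx <- which(cat_ == lv)
      n_train <- min(length(idx), round(train_fraction * length(idx)))
      sample(idx, n_train)
    }), use.names = FALSE)
  })
  list(train = sites[sort(train_idx), , drop = FALSE],
       test = sites[setdiff(seq_len(nrow(sites)), train_idx), , drop = FALSE])
}

#' Fit a species abundance model (SAM)
#'
#' Regression of mean trap abundance on the environmental covariates, with
#' either a random forest (1000 trees, reference regression defaults:
#' node size 5, p/3 candidate variables per split) or gradient-boosted
#' stumps (100 trees, depth 1, learning rate 0.1, bag fraction 0.5,
#' squared-error loss). The response enters either raw or as `log(x + 1)`.
#'
#' @param train training data frame containing `mean_count` and the
#'   covariates.
#' @param covariates character vector of covariate column names.
#' @param algorithm `"RF"` or `"GBM"`.
#' @param transform `"raw"` or `"log1p"`.
#' @param seed integer seed; fitting is deterministic given (data, seed).
#' @return An object of class `sam_fit`.
#' @export
fit_sam <- function(train, covariates, algorithm = c("RF", "GBM"),
                    transform = c("raw", "log1p"), seed = 1L) {
  algorithm <- match.arg(algorithm)
  transform <- match.arg(transform)
  x <- as.matrix(train[, covariates, drop = FALSE])
  if (!is.numeric(x)) stop("non-numeric covariate among: ",
                           paste(covariates, collapse = ", "))
  y <- train$mean_count
  if (transform == "log1p") y <- log1p(y)
  model <- withr::with_seed(as.integer(seed), {
    if (algorithm == "RF") {
      randomForest::randomForest(
        x, y, ntree = 1000, nodesize = 5,
        mtry = max(1L, floor(length(covariates) / 3)),
        importance = FALSE)
    } else {
      xgboost::xgb.train(
        params = list(max_depth = 1, learning_rate = 0.1, subsample = 0.5,
                      objective = "reg:squarederror", nthread = 1,
                      seed = as.integer(seed)),
        data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
        nrounds = 100, verbose = 0)
    }
  })
  structure(list(task = "SAM", algorithm = algorithm, transform = transform,
                 covariates = covariates, model = model, seed = seed,
                 train = train[, c("mean_count", covariates), drop = FALSE]),
            class = "sam_fit")
}

#' Fit a species distribution model (SDM)
#'
#' Occurrence model on binary-encoded abundance (presence = mean count > 0):
#' a probability random forest (1000 trees, classification defaults) or
#' gradient-boosted stumps with Bernoulli loss. Predictions are establishment
#' probabilities in `[0, 1]` (fraction of trees voting presence for the
#' forest; inverse-logit score for the boosted model).
#'
#' @inheritParams fit_sam
#' @return An object of class `sdm_fit`.
#' @export
fit_sdm <- function(train, covariates, algorithm = c("RF", "GBM"), seed = 1L) {
  algorithm <- match.arg(algorithm)
  x <- as.matrix(train[, covariates, drop = FALSE])
  presence <- as.integer(train$mean_count > 0)
  if (length(unique(presence)) < 2)
    stop("training set has a single occurrence class")
  model <- withr::with_seed(as.integer(seed), {
    if (algorithm == "RF") {
      randomForest::randomForest(
        x, factor(presence, levels = c(0, 1)), ntree = 1000,
        mtry = max(1L, floor(sqrt(length(covariates)))))
    } else {
      xgboost::xgb.train(
        params = list(max_depth = 1, learning_rate = 0.1, subsample = 0.5,
                      objective = "binary:logistic", nthread = 1,
                      seed = as.integer(seed)),
        data = xgboost::xgb.DMatrix(x, label = presence, nthread = 1),
        nrounds = 100, verbose = 0)
    }
  })
  structure(list(task = "SDM", algorithm = algorithm, transform = "binary",
                 covariates = covariates, model = model, seed = seed,
                 train = train[, c("mean_count", covariates), drop = FALSE]),
            class = "sdm_fit")
}

check_newdata <- function(fit, newdata) {
  missing <- setdiff(fit$covariates, names(newdata))
  if (length(missing))
    stop("missing covariate column(s): ", paste(missing, collapse = ", "))
  as.matrix(as.data.frame(newdata)[, fit$covariates, drop = FALSE])
}

raw_predict <- function(fit, x) {
  if (inherits(fit$model, "randomForest")) {
    if (fit$task == "SDM")
      stats::predict(fit$model, x, type = "prob")[, "1"]
    else
      stats::predict(fit$model, x)
  } else {
    stats::predict(fit$model, x)
  }
}

#' Predict abundance on the original count scale
#'
#' log1p-variant predictions are back-transformed with `expm1`; predictions
#' on either scale are clipped at zero (boosted ensembles can extrapolate
#' slightly below the smallest training response).
#'
#' @param fit a `sam_fit`.
#' @param newdata data frame with the model covariates.
#' @return Numeric vector of nonnegative predicted mean counts.
#' @export
predict_abundance <- function(fit, newdata) {
  stopifnot(inherits(fit, "sam_fit"))
  p <- raw_predict(fit, check_newdata(fit, newdata))
  if (fit$transform == "log1p") pmax(expm1(p), 0) else pmax(p, 0)
}

#' Predict establishment probability
#'
#' @param fit an `sdm_fit`.
#' @param newdata data frame with the model covariates.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_presence <- function(fit, newdata) {
  stopifnot(inherits(fit, "sdm_fit"))
  raw_predict(fit, check_newdata(fit, newdata))
}

#' Node-purity variable importance
#'
#' Per-covariate contribution to the improvement of node purity summed over
#' the ensemble: residual-sum-of-squares decrease for the random forest
#' (Gini decrease for classification), split gain for the boosted model.
#'
#' @param fit a fitted `sam_fit` or `sdm_fit`.
#' @return Data frame `variable`, `importance`, sorted decreasing.
#' @export
variable_importance <- function(fit) {
  if (!inherits(fit, c("sam_fit", "sdm_fit")))
    stop("unsupported operation: importance needs a fitted tree ensemble")
  if (inherits(fit$model, "randomForest")) {
    imp <- randomForest::importance(fit$model, type = 2)
    out <- data.frame(variable = rownames(imp), importance = imp[, 1L])
  } else {
    tab <- xgboost::xgb.importance(model = fit$model)
    sc <- stats::setNames(rep(0, length(fit$covariates)), fit$covariates)
    sc[tab$Feature] <- tab$Gain
    out <- data.frame(variable = names(sc), importance = unname(sc))
  }
  rownames(out) <- NULL
  out[order(-out$importance), , drop = FALSE]
}

#' Partial dependence of a fitted model on one covariate
#'
#' For each of `n_grid` values spanning the covariate's observed training
#' range, every training row has the covariate overwritten by the grid value
#' and the model predictions are averaged - the marginal effect of the
#' variable with all others held at their observed joint distribution.
#' Predictions are on the fitted model's response scale (abundance for SAMs,
#' probability for SDMs).
#'
#' @param fit a fitted `sam_fit` or `sdm_fit`.
#' @param variable covariate name.
#' @param n_grid number of grid points (endpoints included).
#' @return Data frame of class `partial_dependence`: `variable`, `value`,
#'   `yhat`.
#' @export
partial_dependence <- function(fit, variable, n_grid = 50) {
  if (!variable %in% fit$covariates)
    stop(sprintf("unknown variable '%s'", variable))
  train <- fit$train
  rng <- range(train[[variable]])
  grid <- seq(rng[1], rng[2], length.out = n_grid)
  pred_fun <- if (fit$task == "SAM") predict_abundance else predict_presence
  yhat <- vapply(grid, function(g) {
    d <- train
    d[[variable]] <- g
    mean(pred_fun(fit, d))
  }, 0)
  structure(data.frame(variable = variable, value = grid, yhat = yhat),
            class = c("partial_dependence", "data.frame"))
}
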