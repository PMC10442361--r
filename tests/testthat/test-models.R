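test_that("abundance categorization follows the interval rule", {
  expect_equal(as.character(categorize(c(0, 0.5, 9.5, 10, 99.9, 100, 338.5))),
               c("Absence", "Low", "Low", "Mid", "Mid", "High", "High"))
  # exactly one category fires for any nonnegative value
  withr::with_seed(1, x <- c(0, 10, 100, runif(200, 0, 500)))
  expect_false(any(is.na(categorize(x))))
  expect_error(categorize(-1), "nonnegative")
})

test_that("stratified split preserves category composition", {
  withr::with_seed(2, {
    sites <- data.frame(mean_count = c(rep(0, 61), runif(50, 1, 9),
                                       runif(110, 10, 99), runif(27, 100, 400)))
    sites$category <- categorize(sites$mean_count)
    sites <- sites[sample(nrow(sites)), ]
  })
  sp <- stratified_split(sites, 0.7, seed = 5)
  train_by_cat <- table(sp$train$category)
  expect_true(all(abs(train_by_cat - round(0.7 * c(61, 50, 110, 27))) <= 1))
  expect_equal(nrow(sp$train) + nrow(sp$test), 248)
  expect_equal(sort(c(rownames(sp$train), rownames(sp$test))),
               sort(rownames(sites)))
  # seeded reproducibility, distinct seeds differ
  expect_identical(sp, stratified_split(sites, 0.7, seed = 5))
  expect_false(identical(sp$train, stratified_split(sites, 0.7, seed = 6)$train))
  # degenerate fraction: everything trains
  sp1 <- stratified_split(sites, 1.0, seed = 1)
  expect_equal(nrow(sp1$test), 0)
  # undersized category errors by name
  tiny <- sites[c(which(sites$category == "Absence"),
                  which(sites$category == "Low")[1]), ]
  expect_error(stratified_split(tiny, 0.7, seed = 1), "Low")
})

test_that("abundance models learn a separable response and are deterministic", {
  d <- separable_sites()
  covs <- fixture_covariates(d)
  for (alg in c("RF", "GBM")) {
    fit <- fit_sam(d, covs, algorithm = alg, transform = "log1p", seed = 3)
    pred <- predict_abundance(fit, d)
    expect_true(all(is.finite(pred)) && all(pred >= 0))
    expect_gt(cor(pred, d$mean_count), 0.95)
    expect_gt(cor(pred, d$mean_count, method = "spearman"), 0.9)
    # determinism under identical (data, seed)
    fit2 <- fit_sam(d, covs, algorithm = alg, transform = "log1p", seed = 3)
    expect_identical(pred, predict_abundance(fit2, d))
  }
  # raw transform clips negative extrapolations at zero
  fit_raw <- fit_sam(d, covs, algorithm = "GBM", transform = "raw", seed = 3)
  expect_true(all(predict_abundance(fit_raw, d) >= 0))
  # missing covariate column named in the error
  expect_error(predict_abundance(fit_raw, d[, setdiff(names(d), "driver")]),
               "driver")
})

test_that("occurrence models binarize correctly and separate separable data", {
  d <- separable_sites()
  d$mean_count <- ifelse(d$driver > 5, 50, 0)  # linearly separable presence
  d$category <- categorize(d$mean_count)
  covs <- fixture_covariates(d)
  for (alg in c("RF", "GBM")) {
    fit <- fit_sdm(d, covs, algorithm = alg, seed = 4)
    prob <- predict_presence(fit, d)
    expect_true(all(prob >= 0 & prob <= 1))
    expect_equal(auc_score(prob, d$mean_count > 0), 1.0)
    expect_identical(prob,
                     predict_presence(fit_sdm(d, covs, algorithm = alg, seed = 4), d))
  }
  d$mean_count <- 0
  expect_error(fit_sdm(d, covs, seed = 1), "single occurrence class")
})

test_that("node-purity importance ranks a true driver over pure noise", {
  hits <- vapply(1:10, function(s) {
    withr::with_seed(s, {
      d <- as.data.frame(matrix(rnorm(400 * 6), 400,
                                dimnames = list(NULL, paste0("n", 1:6))))
      d$driver <- rnorm(400)
      d$mean_count <- exp(1 + 1.2 * d$driver)
    })
    fit <- fit_sam(d, c(paste0("n", 1:6), "driver"), "RF", "log1p", seed = s)
    variable_importance(fit)$variable[1L] == "driver"
  }, TRUE)
  expect_gte(sum(hits), 8)
})

test_that("importance splits across duplicated covariates without crashing", {
  d <- separable_sites()
  d$driver2 <- d$driver
  fit_dup <- fit_sam(d, c(fixture_covariates(d)), "RF", "log1p", seed = 5)
  imp <- variable_importance(fit_dup)
  expect_true(all(imp$importance >= 0))
  combined <- sum(imp$importance[imp$variable %in% c("driver", "driver2")])
  fit_single <- fit_sam(d, setdiff(fixture_covariates(d), "driver2"),
                        "RF", "log1p", seed = 5)
  imp_s <- variable_importance(fit_single)
  single <- imp_s$importance[imp_s$variable == "driver"]
  expect_gt(combined, 0.5 * single)
  expect_lt(combined, 2 * single)
})

test_that("null importance shows no runaway scores", {
  ok <- vapply(1:10, function(s) {
    withr::with_seed(s, {
      d <- as.data.frame(matrix(rnorm(200 * 8), 200,
                                dimnames = list(NULL, paste0("n", 1:8))))
      d$mean_count <- exp(rnorm(200))
    })
    fit <- fit_sam(d, paste0("n", 1:8), "RF", "log1p", seed = s)
    imp <- variable_importance(fit)$importance
    max(imp) <= 3 * median(imp)
  }, TRUE)
  expect_gte(sum(ok), 7)
})

test_that("partial dependence recovers marginal effects", {
  d <- separable_sites()
  covs <- fixture_covariates(d)
  fit <- fit_sam(d, covs, "RF", "log1p", seed = 6)
  # additive single-variable model: curve tracks the generating effect
  pd <- partial_dependence(fit, "driver", n_grid = 30)
  expect_equal(nrow(pd), 30)
  # the generating effect is linear on the log scale; the curve should track
  # it up to a constant (ensembles flatten at the extremes of the range)
  expect_gt(cor(log1p(pd$yhat), 0.5 * pd$value), 0.95)
  expect_true(!is.unsorted(pd$value))
  # grid contract: two points sit at the observed min and max
  pd2 <- partial_dependence(fit, "driver", n_grid = 2)
  expect_equal(pd2$value, range(d$driver))
  # a model that ignores the variable entirely gives a flat curve
  registerS3method("predict", "vb_const_mod",
                   function(object, newdata, ...) rep(1.5, nrow(newdata)),
                   envir = asNamespace("stats"))
  fit_const <- structure(
    list(task = "SAM", transform = "log1p", covariates = covs,
         model = structure(list(), class = "vb_const_mod"),
         train = d[, c("mean_count", covs)]),
    class = "sam_fit")
  pd0 <- partial_dependence(fit_const, "driver", n_grid = 10)
  expect_lt(max(pd0$yhat) - min(pd0$yhat), 1e-9)
  expect_error(partial_dependence(fit, "nope"), "unknown variable")
})

test_that("back-transform round trip is exact over the count range", {
  x <- c(0, 1, 9.5, 10, 100, 338.5, 1e6)
  expect_equal(expm1(log1p(x)), x, tolerance = 1e-12)
})
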