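test_that("standardized MAE matches hand computation and is scale-invariant", {
  expect_equal(standardized_mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(standardized_mae(c(2, 3, 4), c(1, 2, 3)), 0.5)
  withr::with_seed(1, {
    pred <- runif(30, 0, 50); obs <- runif(30, 1, 50)
    for (c_ in c(0.1, 3, 250)) {
      expect_equal(standardized_mae(c_ * pred, c_ * obs),
                   standardized_mae(pred, obs))
    }
  })
  expect_error(standardized_mae(1, c(1, 2)), "equal")
  expect_error(standardized_mae(c(1, 2), c(0, 0)), "undefined")
})

test_that("discrimination equals the closed-form least-squares oracle", {
  expect_equal(discrimination(c(1, 2, 3), c(1, 2, 3)),
               list(pearson_r = 1, slope = 1))
  d <- discrimination(c(1, 2, 3), c(2, 4, 6))
  expect_equal(d$pearson_r, 1)
  expect_equal(d$slope, 2)
  for (s in 1:20) {
    withr::with_seed(s, {
      pred <- rnorm(20); obs <- 2 * pred + rnorm(20)
    })
    got <- discrimination(pred, obs)
    # brute-force formulas
    r_oracle <- sum((pred - mean(pred)) * (obs - mean(obs))) /
      sqrt(sum((pred - mean(pred))^2) * sum((obs - mean(obs))^2))
    slope_oracle <- sum((pred - mean(pred)) * (obs - mean(obs))) /
      sum((pred - mean(pred))^2)
    expect_equal(got$pearson_r, r_oracle)
    expect_equal(got$slope, slope_oracle)
    expect_equal(got$slope, unname(coef(lm(obs ~ pred))[2]))
    # reversed convention
    expect_equal(discrimination(pred, obs, slope_obs_on_pred = FALSE)$slope,
                 unname(coef(lm(pred ~ obs))[2]))
  }
  expect_error(discrimination(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("AUC equals the pairwise oracle and is rank-invariant", {
  # perfect separation and all-ties
  expect_equal(auc_score(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1.0)
  expect_equal(auc_score(rep(0.4, 6), c(0, 1, 0, 1, 1, 0)), 0.5)
  pair_auc <- function(scores, labels) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  # 12-point tied case
  s <- c(0.1, 0.4, 0.4, 0.35, 0.8, 0.8, 0.8, 0.2, 0.6, 0.7, 0.35, 0.9)
  y <- c(0, 0, 1, 0, 1, 0, 1, 0, 1, 1, 1, 1)
  expect_equal(auc_score(s, y), pair_auc(s, y))
  for (i in 1:20) {
    withr::with_seed(i, {
      sc <- sample(seq(0, 1, 0.05), 15, replace = TRUE)
      lb <- rbinom(15, 1, 0.5)
    })
    if (length(unique(lb)) < 2) next
    expect_equal(auc_score(sc, lb), pair_auc(sc, lb))
    # invariance under strictly increasing transforms
    expect_equal(auc_score(exp(3 * sc) - 2, lb), auc_score(sc, lb))
    expect_equal(auc_score(rank(sc, ties.method = "average"), lb),
                 auc_score(sc, lb))
  }
  expect_error(auc_score(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("correlation t statistics match the analytic formula and cor.test", {
  expect_equal(t_from_r(0.322, 157), 4.268, tolerance = 0.01 / 4.268)
  expect_equal(t_from_r(0.629, 157), 10.134, tolerance = 0.01 / 10.134)
  expect_equal(t_from_r(0, 50), 0)
  expect_equal(t_from_r(1, 10), Inf)
  withr::with_seed(3, {
    x <- rnorm(40); y <- 0.5 * x + rnorm(40)
  })
  got <- correlation_test(x, y)
  ref <- cor.test(x, y)
  expect_equal(got$r, unname(ref$estimate))
  expect_equal(got$t, unname(ref$statistic))
  expect_equal(got$df, unname(ref$parameter))
  expect_equal(got$p, ref$p.value)
  expect_equal(correlation_test(x, 2 * x)$p, 0)
})

test_that("Kruskal-Wallis H matches a hand-rank oracle; Dunn letters behave", {
  vals <- c(1, 2, 3, 11, 12, 13)
  grp <- rep(c("a", "b"), each = 3)
  got <- kruskal_dunn(vals, grp)
  # hand computation: ranks 1..6, no ties
  Ra <- sum(1:3); n <- 6
  H_oracle <- 12 / (n * (n + 1)) * (Ra^2 / 3 + sum(4:6)^2 / 3) - 3 * (n + 1)
  expect_equal(got$H, H_oracle)
  expect_equal(got$df, 1)
  expect_equal(unname(got$H), unname(kruskal.test(vals, factor(grp))$statistic))
  # all values equal: H = 0
  expect_equal(kruskal_dunn(rep(5, 9), rep(c("a", "b", "c"), 3))$H, 0)
  # tie-corrected H agrees with stats::kruskal.test on tied data
  withr::with_seed(4, {
    v <- sample(1:5, 40, replace = TRUE)
    g <- sample(c("a", "b", "c"), 40, replace = TRUE)
  })
  expect_equal(kruskal_dunn(v, g)$H, unname(kruskal.test(v, factor(g))$statistic))
  # clearly separated groups get distinct letters; identical groups share
  sep <- kruskal_dunn(c(1:10, 101:110, 1001:1010), rep(c("a", "b", "c"), each = 10))
  expect_equal(length(unique(sep$letters)), 3)
  same <- kruskal_dunn(rep(1:10, 3), rep(c("a", "b", "c"), each = 10))
  expect_equal(length(unique(same$letters)), 1)
  expect_error(kruskal_dunn(1:5, rep("a", 5)), "at least 2 groups")
})

test_that("null Kruskal-Wallis rejects at close to the nominal rate", {
  rejections <- vapply(1:20, function(s) {
    withr::with_seed(100 + s, {
      v <- rnorm(60)
      g <- rep(c("a", "b", "c"), each = 20)
    })
    kruskal_dunn(v, g)$p < 0.05
  }, TRUE)
  expect_lte(sum(rejections), 3)
})

test_that("rank-sum selection reproduces the reference comparison table", {
  # printed mean metrics of the four abundance-model variants; the
  # log-response random forest must win the rank sum
  tab <- data.frame(
    variant = c("SAM_RF_raw", "SAM_RF_log1p", "SAM_GBM_raw", "SAM_GBM_log1p"),
    accuracy = c(0.956, 0.537, 1.114, 0.599),
    pearson_r = c(0.271, 0.470, 0.158, 0.344),
    slope = c(0.557, 0.867, 0.234, 0.477))
  sel <- rank_select(tab)
  expect_equal(as.character(sel), "SAM_RF_log1p")
  # occurrence models compared on AUC alone
  sdm <- data.frame(variant = c("SDM_RF", "SDM_GBM"), auc = c(0.732, 0.649))
  expect_equal(as.character(rank_select(sdm, metrics = c(auc = "max"))), "SDM_RF")
  # a dominating variant wins regardless of tie rules
  dom <- data.frame(variant = c("v1", "v2", "v3"),
                    accuracy = c(0.2, 0.5, 0.9),
                    pearson_r = c(0.9, 0.5, 0.2),
                    slope = c(1.0, 0.7, 0.3))
  expect_equal(as.character(rank_select(dom)), "v1")
  # invariance to row order
  perm <- tab[c(3, 1, 4, 2), ]
  expect_equal(as.character(rank_select(perm)), "SAM_RF_log1p")
  expect_error(rank_select(tab[0, ]), "empty")
})

test_that("replicated evaluation aggregates per-replicate metrics faithfully", {
  d <- separable_sites(n = 120)
  covs <- fixture_covariates(d)
  ev <- replicate_evaluation(d, covs, n_rep = 3, base_seed = 7,
                             sam_variants = data.frame(algorithm = "GBM",
                                                       transform = "log1p"),
                             sdm_variants = NULL)
  expect_equal(nrow(ev$replicates), 3)
  expect_true(all(is.na(ev$replicates$error)))
  expect_equal(ev$summary$accuracy_mean, mean(ev$replicates$accuracy))
  expect_equal(ev$summary$pearson_r_mean, mean(ev$replicates$pearson_r))
  # n_rep = 1 reduces to a single split evaluation
  ev1 <- replicate_evaluation(d, covs, n_rep = 1, base_seed = 7,
                              sam_variants = data.frame(algorithm = "GBM",
                                                        transform = "log1p"),
                              sdm_variants = NULL)
  sp <- stratified_split(d, 0.7, seed = 8L)
  fit <- fit_sam(sp$train, covs, "GBM", "log1p", seed = 8L)
  pred <- predict_abundance(fit, sp$test)
  expect_equal(ev1$replicates$accuracy,
               standardized_mae(pred, sp$test$mean_count))
  # reproducible end to end
  ev2 <- replicate_evaluation(d, covs, n_rep = 3, base_seed = 7,
                              sam_variants = data.frame(algorithm = "GBM",
                                                        transform = "log1p"),
                              sdm_variants = NULL)
  expect_identical(ev$replicates, ev2$replicates)
})
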