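test_that("feature building one-hot encodes and median-imputes", {
  feats <- data.frame(conservation = c(1, NA, 3),
                      sasa = c(10, 20, 30),
                      aa = c("A", "W", "C"))
  fb <- buildFeatures(feats, target = c(0, 1, 2))
  expect_equal(fb$y, c(0, 1, 2))
  aa_cols <- grep("^aa_", colnames(fb$X))
  expect_length(aa_cols, 20)
  expect_equal(unname(rowSums(fb$X[, aa_cols])), c(1, 1, 1))
  expect_equal(fb$X[, "aa_W"], c(0, 1, 0))
  # imputed value is the column median, with an indicator
  expect_equal(unname(fb$X[2, "conservation"]), 2)
  expect_equal(fb$X[, "conservation_missing"], c(0, 1, 0))
  expect_equal(unname(fb$medians["conservation"]), 2)
  expect_warning(buildFeatures(data.frame(x = c(NA_real_, NA_real_),
                                          y = c(1, 2))),
                 "all-missing")
})

test_that("median imputation matches brute force at 30% missingness", {
  set.seed(13)
  df <- data.frame(a = rnorm(10), b = rnorm(10))
  df$a[sample(10, 3)] <- NA
  fb <- buildFeatures(df)
  manual <- df$a
  manual[is.na(manual)] <- median(sort(df$a[!is.na(df$a)]))
  expect_equal(unname(fb$X[, "a"]), manual)
})

test_that("out-of-fold fit learns a noiseless linear target", {
  set.seed(14)
  X <- cbind(x1 = runif(240, -2, 2), x2 = rnorm(240))
  y <- 3 * X[, "x1"]
  fit <- fitOOF(X, y, n_folds = 8, seed = 2, nrounds = 300)
  expect_lt(sqrt(mean(fit$residuals^2)), 0.05 * sd(y))
  # permuted targets carry no signal
  fitp <- fitOOF(X, sample(y), n_folds = 8, seed = 2, nrounds = 50)
  expect_lt(abs(cor(fitp$oof, sample(y))), 2 / sqrt(240))
})

test_that("fold bookkeeping is disjoint, exhaustive and seeded", {
  set.seed(15)
  X <- matrix(rnorm(200), 100, 2)
  y <- rnorm(100)
  fit <- fitOOF(X, y, n_folds = 8, seed = 3, nrounds = 10)
  expect_setequal(unique(fit$fold_id), 1:8)
  expect_length(fit$oof, 100)
  expect_true(max(table(fit$fold_id)) - min(table(fit$fold_id)) <= 1)
  fit2 <- fitOOF(X, y, n_folds = 8, seed = 3, nrounds = 10)
  expect_identical(fit$fold_id, fit2$fold_id)
  expect_identical(fit$oof, fit2$oof)
  expect_error(fitOOF(X[1:10, ], y[1:10], n_folds = 11), "exceed")
  expect_error(fitOOF(X[1:10, ], y[1:10], n_folds = 8), "2 rows per fold")
})

test_that("median replacement is idempotent and collapses guide-feature-only differences", {
  set.seed(16)
  X <- cbind(pos = 1:60, guide_score = rnorm(60))
  y <- sin(1:60 / 8) + 0.5 * X[, "guide_score"]
  fit <- fitOOF(X, y, n_folds = 6, seed = 4, nrounds = 80)
  c1 <- correctScores(fit, X, "guide_score")
  Xc <- X; Xc[, "guide_score"] <- median(X[, "guide_score"])
  c2 <- correctScores(fit, Xc, "guide_score")
  expect_equal(c1, c2)  # idempotent: replacing twice = once
  # rows identical except guide-dependent features get equal corrections
  Xpair <- rbind(c(10, -1.5), c(10, 1.5))
  colnames(Xpair) <- colnames(X)
  expect_equal(diff(correctScores(fit, Xpair, "guide_score")), 0)
  # a constant guide column makes correction a no-op
  X0 <- X; X0[, "guide_score"] <- 0.7
  fit0 <- fitOOF(X0, sin(1:60 / 8), n_folds = 6, seed = 4, nrounds = 80)
  expect_equal(correctScores(fit0, X0, "guide_score"),
               as.numeric(stats::predict(
                 fit0$final_model,
                 xgboost::xgb.DMatrix(X0, nthread = 1))))
  expect_error(correctScores(fit, X, character(0)), "at least one")
  expect_error(correctScores(fit, X, "nope"), "not in X")
})

test_that("ensemble-mean correction is available and close to the final model", {
  set.seed(17)
  X <- cbind(pos = 1:80, gs = rnorm(80))
  y <- cos(1:80 / 10) + 0.3 * X[, "gs"] + rnorm(80, 0, 0.05)
  fit <- fitOOF(X, y, n_folds = 8, seed = 5, nrounds = 60)
  cf <- correctScores(fit, X, "gs")
  ce <- correctScores(fit, X, "gs", use_ensemble = TRUE)
  expect_length(ce, 80)
  expect_gt(cor(cf, ce), 0.95)
})

test_that("bias correction recovers the true landscape better than raw scores", {
  fx <- biased_screen_fixture(seed = 21, g = 600L, n_res = 200L,
                              cells = 30000L, depth = 300000L)
  cp <- correctProfile(fx$profile, fx$features,
                       guide_cols = "efficiency_score",
                       n_folds = 8, seed = 22, nrounds = 120)
  d <- profileData(cp)
  expect_lt(rmse(d$functional_corrected, fx$truth_score),
            rmse(d$functional_raw, fx$truth_score))
  expect_gt(cor(d$functional_corrected, fx$truth_score,
                method = "spearman"),
            cor(d$functional_raw, fx$truth_score, method = "spearman"))
  # interval columns bracket the corrected score
  expect_true(all(d$functional_pi_low <= d$functional_corrected &
                  d$functional_corrected <= d$functional_pi_high))
})

test_that("prediction intervals collapse, widen monotonically and cover", {
  set.seed(18)
  n <- 400
  X <- cbind(x = runif(n, -3, 3), gs = rnorm(n))
  y <- X[, "x"]^2 + rnorm(n, 0, 0.3)
  fit <- fitOOF(X, y, n_folds = 8, seed = 6, nrounds = 150)
  corr <- correctScores(fit, X, "gs")
  pi50 <- predictionInterval(corr, fit$residuals, 0.5)
  pi95 <- predictionInterval(corr, fit$residuals, 0.95)
  pi_tiny <- predictionInterval(corr, fit$residuals, 1e-4)
  expect_true(all(pi95$high - pi95$low >= pi50$high - pi50$low))
  expect_lt(max(pi_tiny$high - pi_tiny$low), 0.02)
  # empirical coverage of fresh data within +/- 5 points of nominal
  Xn <- cbind(x = runif(n, -3, 3), gs = rnorm(n))
  yn <- Xn[, "x"]^2 + rnorm(n, 0, 0.3)
  pred <- correctScores(fit, Xn, "gs")
  pin <- predictionInterval(pred, fit$residuals, 0.95)
  cover <- mean(yn >= pin$low & yn <= pin$high)
  expect_gt(cover, 0.90)
  expect_error(predictionInterval(corr, fit$residuals, 1.2), "level")
})

test_that("benchmark metrics match hand computation and bootstrap sanely", {
  p <- c(1, 2, 3, 4, 6)
  a <- c(1.5, 2, 2.5, 5, 5)
  bm <- benchmarkPredictions(p, a, n_boot = 500, seed = 1)
  expect_equal(bm$rmse, sqrt(mean(c(-0.5, 0, 0.5, -1, 1)^2)))
  expect_equal(bm$pearson, cor(p, a))
  ident <- benchmarkPredictions(a, a, n_boot = 100, seed = 1)
  expect_equal(ident$rmse, 0)
  expect_equal(ident$pearson, 1)
  neg <- benchmarkPredictions(-a, a, n_boot = 100, seed = 1)
  expect_equal(neg$pearson, -1)
  const <- benchmarkPredictions(rep(1, 5), a, n_boot = 100, seed = 1)
  expect_true(is.na(const$pearson))
  expect_true(all(bm$bootstrap$ci_low <= bm$bootstrap$median))
})
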