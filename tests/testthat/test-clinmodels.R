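test_that("univariate screening returns Pearson r with its t-test p", {
  # hand-computed on 5-point toy data
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 6)
  scr <- univariate_screen(cbind(f = x), y)
  ct <- stats::cor.test(x, y)
  expect_equal(scr$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(scr$p, ct$p.value, tolerance = 1e-12)
  # feature identical to the outcome
  scr2 <- univariate_screen(cbind(self = y), y)
  expect_equal(scr2$r, 1)
  expect_equal(scr2$p, 0)
  # null features pass at roughly the nominal rate
  set.seed(71)
  hits <- replicate(400, {
    s <- univariate_screen(matrix(stats::rnorm(100), ncol = 1), stats::rnorm(100))
    s$p < 0.05
  })
  expect_lt(abs(mean(hits) - 0.05), 0.03)
})

test_that("regression reports match closed-form and lm oracles", {
  set.seed(72)
  n <- 80
  X <- matrix(stats::rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 1 + 0.5 * X[, 1] - 0.3 * X[, 2] + stats::rnorm(n)
  rep_ <- regression_report(y, X)
  lm_fit <- stats::lm(y ~ X)
  sm <- summary(lm_fit)
  expect_equal(rep_$r2, sm$r.squared, tolerance = 1e-12)
  expect_equal(rep_$adjusted_r2, sm$adj.r.squared, tolerance = 1e-12)
  expect_equal(rep_$F, unname(sm$fstatistic[1]), tolerance = 1e-10)
  expect_equal(rep_$rmse, sqrt(sum(stats::residuals(lm_fit)^2) / n),
               tolerance = 1e-12)
  expect_equal(rep_$aic, unname(stats::extractAIC(lm_fit)[2]),
               tolerance = 1e-10)
  # adjusted R2 identity
  k <- 3
  expect_equal(rep_$adjusted_r2,
               1 - (1 - rep_$r2) * (n - 1) / (n - k - 1), tolerance = 1e-12)
})

test_that("standardized coefficients are invariant to feature rescaling", {
  set.seed(73)
  n <- 100
  X <- matrix(stats::rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- 0.4 * X[, 1] + stats::rnorm(n)
  r1 <- regression_report(y, X)
  X2 <- X; X2[, 1] <- X2[, 1] * 1000
  r2 <- regression_report(y, X2)
  expect_equal(r1$predictors$beta_std, r2$predictors$beta_std, tolerance = 1e-10)
  expect_equal(r1$r2, r2$r2, tolerance = 1e-12)
  expect_equal(r1$aic, r2$aic, tolerance = 1e-9)
  expect_equal(predict_report <- fixelstats:::predict_report(r1, X),
               fixelstats:::predict_report(r2, X2), tolerance = 1e-9)
})

test_that("stepwise AIC selects true predictors and traces decreasing AIC", {
  # AIC's add/drop threshold corresponds to |t| > sqrt(2), so a pure-noise
  # covariate survives in about 16% of runs; the true predictor must always
  # be kept and the noise one dropped at the AIC-implied rate.
  set.seed(74)
  hits <- 0
  for (r in 1:50) {
    X <- matrix(stats::rnorm(50 * 2), 50, 2, dimnames = list(NULL, c("x1", "x2")))
    y <- 2 * X[, 1] + stats::rnorm(50)
    st <- stepwise_aic(y, X)
    expect_true("x1" %in% st$features)
    if (identical(st$features, "x1")) hits <- hits + 1
    if (nrow(st$trace) > 1)
      expect_true(all(diff(st$trace$aic) < 0))
  }
  expect_gte(hits, 35)
})

test_that("stepwise AIC handles edge cases deterministically", {
  set.seed(75)
  y <- stats::rnorm(30)
  # no candidates: intercept-only model, empty trace
  st0 <- stepwise_aic(y, matrix(nrow = 30, ncol = 0))
  expect_equal(length(st0$features), 0)
  expect_equal(nrow(st0$trace), 0)
  expect_equal(st0$report$rmse, sqrt(mean((y - mean(y))^2)), tolerance = 1e-12)
  # perfect fit -> AIC undefined
  x <- stats::rnorm(30)
  expect_error(stepwise_aic(2 * x, cbind(x1 = x)), "perfect fit")
  # determinism
  X <- matrix(stats::rnorm(60 * 4), 60, 4, dimnames = list(NULL, paste0("f", 1:4)))
  yy <- X[, 2] + stats::rnorm(60)
  expect_identical(stepwise_aic(yy, X)$features, stepwise_aic(yy, X)$features)
})

test_that("stepwise AIC final models are locally optimal and match MASS::stepAIC", {
  set.seed(76)
  for (r in 1:20) {
    p <- 5
    X <- matrix(stats::rnorm(60 * p), 60, p,
                dimnames = list(NULL, paste0("f", seq_len(p))))
    beta <- c(1, 0.8, 0, 0, 0) * sample(c(-1, 1), p, replace = TRUE)
    y <- drop(X %*% beta) + stats::rnorm(60)
    st <- stepwise_aic(y, X)
    # single-neighbor local optimality
    final_aic <- st$aic
    feats <- st$features
    for (f in colnames(X)) {
      alt <- if (f %in% feats) setdiff(feats, f) else c(feats, f)
      fit <- stats::lm(y ~ ., data = data.frame(y = y, X[, alt, drop = FALSE]))
      expect_gte(unname(stats::extractAIC(fit)[2]), final_aic - 1e-8)
    }
    # cross-check against MASS::stepAIC from the full model
    d <- data.frame(y = y, X)
    ms <- MASS::stepAIC(stats::lm(y ~ ., data = d), trace = 0)
    ms_feats <- sort(setdiff(names(stats::coef(ms)), "(Intercept)"))
    expect_identical(st$features, ms_feats)
  }
})

test_that("hierarchical regression screens, prunes and reports block gains", {
  set.seed(77)
  n <- 300
  dat <- data.frame(age = stats::rnorm(n, 48, 10), sex = stats::rbinom(n, 1, 0.5),
                    education_high = stats::rbinom(n, 1, 0.5),
                    duration = stats::rnorm(n, 14, 8),
                    NBV = stats::rnorm(n), lesion_load = stats::rnorm(n),
                    fA = stats::rnorm(n), fB = stats::rnorm(n), fC = stats::rnorm(n))
  dat$out <- 0.02 * dat$age + 0.5 * dat$fA + stats::rnorm(n)
  h <- hierarchical_regression(dat, "out",
                               c("age", "sex", "education_high", "duration"),
                               c("NBV", "lesion_load"), c("fA", "fB", "fC"))
  expect_true("fA" %in% h$selected_block3)
  bfA <- h$block3$predictors
  expect_gt(bfA$b[bfA$predictor == "fA"], 0)
  expect_equal(unname(h$delta_r2["block1"]), h$block1$r2)
  expect_equal(sum(h$delta_r2), h$block3$r2, tolerance = 1e-12)
  expect_gt(h$delta_r2["block3"], 0.1)
})

test_that("hierarchical regression flags an empty block 3 under the null", {
  set.seed(78)
  hits <- 0
  for (r in 1:30) {
    n <- 150
    dat <- data.frame(a = stats::rnorm(n), b = stats::rnorm(n),
                      v = stats::rnorm(n),
                      f1 = stats::rnorm(n), f2 = stats::rnorm(n))
    dat$out <- 0.5 * dat$a + stats::rnorm(n)
    h <- hierarchical_regression(dat, "out", c("a", "b"), "v", c("f1", "f2"))
    if (h$block3_empty || length(h$selected_block3) == 0) hits <- hits + 1
  }
  expect_gte(hits, 24)
})

test_that("perfectly collinear features are rejected with their names", {
  set.seed(79)
  n <- 60
  dat <- data.frame(a = stats::rnorm(n), v = stats::rnorm(n), f1 = stats::rnorm(n))
  dat$f2 <- dat$f1           # exact duplicate
  dat$out <- dat$a + dat$f1 * 0.5 + stats::rnorm(n, 0, 0.5)
  expect_error(
    hierarchical_regression(dat, "out", "a", "v", c("f1", "f2")),
    "collinear.*f2")
})

test_that("nested CV is deterministic and leak-free by construction", {
  set.seed(80)
  X <- matrix(stats::rnorm(200 * 8), 200, 8,
              dimnames = list(NULL, paste0("f", 1:8)))
  y <- 0.7 * X[, 1] + stats::rnorm(200, 0, 0.8)
  r1 <- nested_cv_predict(X, y, seed = 5)
  r2 <- nested_cv_predict(X, y, seed = 5)
  expect_identical(r1$test_idx, r2$test_idx)
  expect_identical(r1$consistent_features, r2$consistent_features)
  expect_identical(r1$test_rmse, r2$test_rmse)
  expect_identical(r1$test_r, r2$test_r)
  # test and training indices partition the sample
  expect_equal(sort(c(r1$test_idx, r1$train_idx)), seq_len(200))
  expect_equal(length(r1$test_idx), 40)
})

test_that("nested CV recovers a strong feature and nulls out pure noise", {
  set.seed(81)
  X <- matrix(stats::rnorm(320 * 5), 320, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  y <- 0.8 * X[, 1] + stats::rnorm(320, 0, 0.6)
  r <- nested_cv_predict(X, y, seed = 3)
  expect_true("f1" %in% r$consistent_features)
  expect_false(r$null_model)
  expect_gt(r$test_r, 0.5)
  # pure noise: empty consistent set -> flagged null model
  y0 <- stats::rnorm(320)
  r0 <- nested_cv_predict(X, y0, seed = 3)
  if (r0$null_model) {
    expect_equal(length(r0$consistent_features), 0)
    expect_true(is.na(r0$test_r))
  }
})
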