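# Baseline association models (hierarchical regression with backward
# selection) and the nested cross-validated prediction framework with
# stepwise AIC feature selection.

#' Univariate screening of candidate features
#'
#' Pearson correlation of each feature with the outcome and its t-test
#' p-value; used as a data-reduction step before multivariate modelling.
#'
#' @param features Data frame / matrix of candidate features.
#' @param outcome Numeric outcome vector.
#' @return Data frame: `feature`, `r`, `p`, `n`.
#' @export
univariate_screen <- function(features, outcome) {
  X <- as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(outcome)
  r <- drop(stats::cor(X, outcome))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  data.frame(feature = colnames(X), r = r, p = p, n = n,
             row.names = NULL, stringsAsFactors = FALSE)
}

# AIC with additive constants dropped: n*log(RSS/n) + 2k, k = number of
# coefficients including the intercept. Matches stats::extractAIC for lm.
# tss supplies the outcome scale used to detect an (effectively) perfect fit.
aic_rss <- function(rss, n, k, tss = 1) {
  if (rss <= 1e-12 * max(tss, .Machine$double.eps))
    stop_invalid("AIC undefined: perfect fit (RSS = 0)")
  n * log(rss / n) + 2 * k
}

fit_ols <- function(y, X) {
  X1 <- cbind(`(Intercept)` = 1, X)
  qrx <- qr(X1)
  if (qrx$rank < ncol(X1)) {
    piv <- qrx$pivot[(qrx$rank + 1):ncol(X1)]
    stop_invalid("collinear predictors: %s",
                 paste(colnames(X1)[piv], collapse = ", "))
  }
  coef <- qr.coef(qrx, y)
  fitted <- drop(X1 %*% coef)
  rss <- sum((y - fitted)^2)
  list(coef = coef, fitted = fitted, rss = rss, qr = qrx,
       n = length(y), k = ncol(X1))
}

#' Regression fit report
#'
#' Summary of an OLS fit: unstandardized and standardized coefficients,
#' univariate correlations, adjusted R-squared
#' `1 - (1 - R2)(n - 1)/(n - k - 1)`, the overall F, AIC
#' (`n log(RSS/n) + 2k`) and `RMSE = sqrt(RSS/n)`.
#'
#' @param outcome Numeric outcome.
#' @param features Data frame / matrix of predictors (may have 0 columns for
#'   the intercept-only model).
#' @param outcome_name Label carried into the report.
#' @return Object of class `regression_report`.
#' @export
regression_report <- function(outcome, features, outcome_name = "outcome") {
  X <- as.matrix(features)
  if (is.null(colnames(X)) && ncol(X) > 0)
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  f <- fit_ols(outcome, X)
  n <- f$n; k_pred <- ncol(X)
  tss <- sum((outcome - mean(outcome))^2)
  r2 <- 1 - f$rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - k_pred - 1)
  Fstat <- if (k_pred > 0)
    (r2 / k_pred) / ((1 - r2) / (n - k_pred - 1)) else NA_real_
  model_p <- if (k_pred > 0)
    stats::pf(Fstat, k_pred, n - k_pred - 1, lower.tail = FALSE) else NA_real_
  sigma2 <- f$rss / (n - k_pred - 1)
  XtXi <- chol2inv(chol(crossprod(cbind(1, X))))
  se <- sqrt(sigma2 * diag(XtXi))
  tstat <- f$coef / se
  p_coef <- 2 * stats::pt(abs(tstat), n - k_pred - 1, lower.tail = FALSE)
  beta_std <- if (k_pred > 0)
    f$coef[-1] * apply(X, 2, stats::sd) / stats::sd(outcome) else numeric(0)
  r_uni <- if (k_pred > 0) drop(stats::cor(X, outcome)) else numeric(0)
  predictors <- data.frame(
    predictor = names(f$coef), b = unname(f$coef), se = se, t = tstat,
    p = p_coef,
    beta_std = c(NA_real_, unname(beta_std)),
    r_univariate = c(NA_real_, unname(r_uni)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(outcome = outcome_name, predictors = predictors,
                 r2 = r2, adjusted_r2 = adj_r2, F = Fstat, p = model_p,
                 aic = aic_rss(f$rss, n, k_pred + 1, tss),
                 rmse = sqrt(f$rss / n), rss = f$rss, n = n,
                 coef = f$coef),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("<regression_report> %s: adj R2 = %.3f, F = %.2f, p = %.3g, RMSE = %.3f, AIC = %.2f\n",
              x$outcome, x$adjusted_r2, x$F, x$p, x$rmse, x$aic))
  invisible(x)
}

predict_report <- function(report, features) {
  X <- cbind(1, as.matrix(features)[, names(report$coef)[-1], drop = FALSE])
  drop(X %*% report$coef)
}

#' Bidirectional stepwise selection by AIC
#'
#' Greedy bidirectional search over single-feature additions and removals,
#' starting (by default) from the full candidate set: at each step the
#' single move with the largest AIC decrease is applied; the search stops
#' when no move decreases the AIC. `AIC = n log(RSS/n) + 2k` with `k` the
#' coefficient count including the intercept. Ties are broken
#' deterministically: drops are preferred over adds, then lexicographic
#' feature order.
#'
#' @param outcome Numeric outcome.
#' @param candidates Data frame / matrix of candidate features.
#' @param start `"full"` (default) or `"empty"`, or a character vector of
#'   feature names.
#' @return List of class `stepwise_trace`: `trace` (action, feature, AIC
#'   after each move), `features` (final set, sorted), `report` (final
#'   [regression_report()]), `aic`.
#' @export
stepwise_aic <- function(outcome, candidates, start = "full") {
  X <- as.matrix(candidates)
  if (ncol(X) > 0 && is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  all_feats <- colnames(X)
  n <- length(outcome)
  if (n <= length(all_feats) + 1)
    stop_invalid("need n > number of candidates + 1")
  current <- if (identical(start, "full")) all_feats
             else if (identical(start, "empty")) character(0)
             else intersect(start, all_feats)
  tss <- sum((outcome - mean(outcome))^2)
  aic_of <- function(feats) {
    f <- fit_ols(outcome, X[, feats, drop = FALSE])
    aic_rss(f$rss, n, length(feats) + 1, tss)
  }
  cur_aic <- aic_of(current)
  trace <- data.frame(action = character(0), feature = character(0),
                      aic = numeric(0), stringsAsFactors = FALSE)
  repeat {
    # candidate moves: all drops, then all adds, lexicographic within type
    moves <- rbind(
      if (length(current))
        data.frame(action = "drop", feature = sort(current),
                   stringsAsFactors = FALSE),
      if (length(setdiff(all_feats, current)))
        data.frame(action = "add", feature = sort(setdiff(all_feats, current)),
                   stringsAsFactors = FALSE))
    if (is.null(moves) || nrow(moves) == 0) break
    aics <- vapply(seq_len(nrow(moves)), function(i) {
      feats <- if (moves$action[i] == "drop")
        setdiff(current, moves$feature[i]) else c(current, moves$feature[i])
      aic_of(feats)
    }, 0)
    best <- which.min(aics)   # ties: first row wins = drop, then lexicographic
    if (aics[best] >= cur_aic - 1e-10) break
    current <- if (moves$action[best] == "drop")
      setdiff(current, moves$feature[best])
    else c(current, moves$feature[best])
    cur_aic <- aics[best]
    trace <- rbind(trace, data.frame(action = moves$action[best],
                                     feature = moves$feature[best],
                                     aic = cur_aic, stringsAsFactors = FALSE))
  }
  report <- regression_report(outcome, X[, sort(current), drop = FALSE])
  structure(list(trace = trace, features = sort(current),
                 report = report, aic = cur_aic),
            class = "stepwise_trace")
}

#' @export
print.stepwise_trace <- function(x, ...) {
  cat("<stepwise_trace>", nrow(x$trace), "moves; final AIC",
      sprintf("%.2f", x$aic), "\n  features:",
      if (length(x$features)) paste(x$features, collapse = ", ") else "(none)",
      "\n")
  invisible(x)
}

#' Three-block hierarchical regression with backward selection
#'
#' Block 1 (demographics / clinical covariates) is forced; block 2
#' (conventional MRI: volumes, lesion load) is added on top; block 3
#' candidate fixel metrics first pass a univariate screen
#' (`p < screen_alpha`) and the surviving set is then pruned by backward
#' elimination (drop the least significant while its p-value exceeds
#' `p_remove`), always keeping blocks 1-2 in the model. The report gives
#' the added explained variance of each block.
#'
#' @param data Data frame holding all variables.
#' @param outcome Outcome column name.
#' @param block1,block2,block3 Character vectors of column names (disjoint).
#' @param screen_alpha Univariate inclusion threshold (default 0.05).
#' @param p_remove Backward-elimination p-to-remove (default 0.10).
#' @return List of class `hierarchical_regression`: per-block
#'   [regression_report()]s (`block1`, `block2`, `block3`), `delta_r2`,
#'   `screen` (univariate table), `selected_block3`, and
#'   `block3_empty` flag.
#' @export
hierarchical_regression <- function(data, outcome, block1, block2, block3,
                                    screen_alpha = 0.05, p_remove = 0.10) {
  blocks <- list(block1, block2, block3)
  if (anyDuplicated(unlist(blocks)))
    stop_invalid("blocks must be disjoint")
  y <- data[[outcome]]
  n <- length(y)
  if (n <= length(unlist(blocks)))
    stop_invalid("need n greater than the total number of predictors")
  X <- as.matrix(data[, unlist(blocks), drop = FALSE])
  r1 <- regression_report(y, X[, block1, drop = FALSE], outcome)
  r2 <- regression_report(y, X[, c(block1, block2), drop = FALSE], outcome)
  scr <- univariate_screen(X[, block3, drop = FALSE], y)
  keep <- scr$feature[scr$p < screen_alpha]
  flagged_empty <- length(keep) == 0
  # backward elimination among block-3 features only
  while (length(keep)) {
    rep3 <- regression_report(y, X[, c(block1, block2, keep), drop = FALSE],
                              outcome)
    pr <- rep3$predictors
    p3 <- pr$p[match(keep, pr$predictor)]
    if (max(p3) <= p_remove) break
    keep <- keep[-which.max(p3)]
  }
  r3 <- regression_report(y, X[, c(block1, block2, keep), drop = FALSE],
                          outcome)
  structure(list(
    block1 = r1, block2 = r2, block3 = r3,
    delta_r2 = c(block1 = r1$r2, block2 = r2$r2 - r1$r2,
                 block3 = r3$r2 - r2$r2),
    screen = scr, selected_block3 = keep,
    block3_empty = flagged_empty),
    class = "hierarchical_regression")
}

#' @export
print.hierarchical_regression <- function(x, ...) {
  cat("<hierarchical_regression>\n  delta R2:",
      sprintf("%s=%.3f", names(x$delta_r2), x$delta_r2), "\n  block 3:",
      if (length(x$selected_block3)) paste(x$selected_block3, collapse = ", ")
      else "(none retained)", "\n")
  invisible(x)
}

make_folds <- function(n, k) {
  # balanced fold sizes, random assignment (caller controls the RNG state)
  unname(split(seq_len(n), sample(rep_len(seq_len(k), n))))
}

#' Nested cross-validated prediction with consistency-based feature selection
#'
#' (1) The data are split into a training set (80%) and an isolated test set
#' (20%) by a seeded shuffle. (2) A 10-fold outer loop runs on the training
#' set; within each outer training set, an inner 5-fold loop retains a
#' feature only if its univariate regression on the outcome is significant
#' (`p < alpha`) in all inner training folds. (3) Features retained in all
#' outer loops (100% consistency; or a majority with
#' `consistency = "outer_majority"`) form the consistent set. (4) A stepwise
#' AIC model over the consistent set is fitted on the full training set.
#' (5) The frozen model is applied to the untouched test set, reporting test
#' RMSE and the Pearson correlation of observed and predicted values. A
#' fingerprint of the test rows taken before training is verified at
#' evaluation time to guard against leakage.
#'
#' @param features Data frame / matrix of candidate features.
#' @param outcome Numeric outcome.
#' @param outer_k,inner_k Fold counts (default 10 and 5).
#' @param test_fraction Held-out fraction (default 0.2).
#' @param alpha Univariate significance threshold (default 0.05).
#' @param seed Integer seed controlling the split and folds.
#' @param consistency `"strict"` (all outer loops, default) or
#'   `"outer_majority"` (more than half).
#' @return List of class `nested_cv_result`: `consistent_features`,
#'   `fold_features` (per outer loop), `final` ([regression_report()]),
#'   `train_rmse`, `test_rmse`, `test_r`, `null_model` flag, fold
#'   assignments and seed.
#' @export
nested_cv_predict <- function(features, outcome, outer_k = 10L, inner_k = 5L,
                              test_fraction = 0.2, alpha = 0.05, seed = 1L,
                              consistency = c("strict", "outer_majority")) {
  consistency <- match.arg(consistency)
  X <- as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- outcome
  n <- nrow(X)
  n_test <- max(1L, round(test_fraction * n))
  sets <- with_seed(seed, {
    test_idx <- sort(sample.int(n, n_test))
    train_idx <- setdiff(seq_len(n), test_idx)
    outer <- make_folds(length(train_idx), outer_k)
    inner <- lapply(seq_len(outer_k), function(o)
      make_folds(length(train_idx) - length(outer[[o]]), inner_k))
    list(test_idx = test_idx, train_idx = train_idx,
         outer = outer, inner = inner)
  })
  test_idx <- sets$test_idx
  train_idx <- sets$train_idx
  if (min(lengths(sets$inner[[1]])) * (inner_k - 1) < 10)
    stop_invalid("too few subjects per inner training fold (need >= 10)")
  fingerprint <- fnv1a_hash(paste(
    format(X[test_idx, , drop = FALSE], digits = 15),
    format(y[test_idx], digits = 15), collapse = "|"))

  Xtr <- X[train_idx, , drop = FALSE]
  ytr <- y[train_idx]
  fold_features <- vector("list", outer_k)
  for (o in seq_len(outer_k)) {
    o_train <- setdiff(seq_along(ytr), sets$outer[[o]])
    inner_folds <- sets$inner[[o]]
    keep <- rep(TRUE, ncol(X))
    for (i in seq_len(inner_k)) {
      i_train <- o_train[-inner_folds[[i]]]
      scr <- univariate_screen(Xtr[i_train, , drop = FALSE], ytr[i_train])
      keep <- keep & (scr$p < alpha)
    }
    fold_features[[o]] <- colnames(X)[keep]
  }
  counts <- table(unlist(fold_features))
  consistent <- if (consistency == "strict")
    names(counts)[counts == outer_k] else names(counts)[counts > outer_k / 2]
  consistent <- intersect(colnames(X), consistent)

  if (length(consistent) == 0) {
    final <- regression_report(ytr, Xtr[, character(0), drop = FALSE])
    null_model <- TRUE
    pred_test <- rep(mean(ytr), length(test_idx))
  } else {
    st <- stepwise_aic(ytr, Xtr[, consistent, drop = FALSE], start = "full")
    final <- st$report
    null_model <- FALSE
    pred_test <- predict_report(final, X[test_idx, , drop = FALSE])
  }

  check <- fnv1a_hash(paste(
    format(X[test_idx, , drop = FALSE], digits = 15),
    format(y[test_idx], digits = 15), collapse = "|"))
  if (!identical(check, fingerprint))
    stop("internal error: test set was modified during training")

  ytest <- y[test_idx]
  test_rmse <- sqrt(mean((ytest - pred_test)^2))
  test_r <- if (stats::sd(pred_test) > 0) stats::cor(ytest, pred_test)
            else NA_real_
  structure(list(
    consistent_features = consistent, fold_features = fold_features,
    final = final, train_rmse = final$rmse, test_rmse = test_rmse,
    test_r = test_r, null_model = null_model,
    test_idx = test_idx, train_idx = train_idx, seed = seed),
    class = "nested_cv_result")
}

#' @export
print.nested_cv_result <- function(x, ...) {
  cat("<nested_cv_result>\n  consistent features:",
      if (length(x$consistent_features))
        paste(x$consistent_features, collapse = ", ") else "(none)",
      sprintf("\n  train RMSE %.3f | test RMSE %.3f | test r %.3f\n",
              x$train_rmse, x$test_rmse, x$test_r))
  invisible(x)
}
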