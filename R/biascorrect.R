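#' @importFrom xgboost xgb.train xgb.DMatrix
NULL

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
           "P", "Q", "R", "S", "T", "V", "W", "Y")

## default deterministic booster settings; single thread for
## bit-reproducibility across machines
.xgb_params <- function(objective) {
  list(objective = objective, eta = 0.1, max_depth = 4, subsample = 1,
       colsample_bytree = 1, nthread = 1)
}

.xgb_fit <- function(X, y, objective = "reg:squarederror", nrounds = 200) {
  xgb.train(params = .xgb_params(objective),
            data = xgb.DMatrix(as.matrix(X), label = y, nthread = 1),
            nrounds = nrounds)
}

.xgb_predict <- function(model, X) {
  stats::predict(model, xgb.DMatrix(as.matrix(X), nthread = 1))
}

#' Build a numeric feature matrix from a residue feature table
#'
#' One-hot encodes amino-acid identity over the 20 canonical residues,
#' median-imputes missing numeric features (adding a 0/1 missingness
#' indicator column per imputed feature) and returns the design matrix
#' aligned with the target vector.
#'
#' @param features data.frame of per-residue features; the column named
#'   by \code{aa_col} (if present) is treated as categorical amino-acid
#'   identity, everything else as numeric.
#' @param target numeric target vector (same row order), or NULL.
#' @param aa_col name of the amino-acid identity column.
#' @return list(X = numeric matrix, y = target, medians = named numeric
#'   of imputation medians).
#' @export
buildFeatures <- function(features, target = NULL, aa_col = "aa") {
  stopifnot(is.data.frame(features))
  num_cols <- setdiff(names(features), aa_col)
  X <- list()
  medians <- numeric(0)
  for (nm in num_cols) {
    v <- as.numeric(features[[nm]])
    if (all(is.na(v))) {
      warning("dropping all-missing feature column: ", nm)
      next
    }
    if (anyNA(v)) {
      med <- median(v, na.rm = TRUE)
      X[[paste0(nm, "_missing")]] <- as.numeric(is.na(v))
      v[is.na(v)] <- med
      medians[nm] <- med
    }
    X[[nm]] <- v
  }
  if (aa_col %in% names(features)) {
    aa <- as.character(features[[aa_col]])
    for (a in .AA20) X[[paste0("aa_", a)]] <- as.numeric(aa == a)
  }
  X <- do.call(cbind, X)
  rownames(X) <- NULL
  list(X = X, y = target, medians = medians)
}

#' Fit an out-of-fold regression ensemble
#'
#' Rows are shuffled into \code{n_folds} disjoint folds (seeded); for
#' each fold a gradient-boosted regressor trained on the complement
#' predicts that fold, so every row receives exactly one prediction from
#' a model blind to it. A final model trained on all rows is retained
#' for downstream bias correction.
#'
#' @param X numeric feature matrix.
#' @param y numeric target.
#' @param n_folds folds (>= 2); default 8.
#' @param seed integer seed for the fold shuffle.
#' @param nrounds boosting rounds.
#' @return list(oof = OOF predictions, fold_id, models = per-fold
#'   models, final_model, residuals = y - oof).
#' @export
fitOOF <- function(X, y, n_folds = 8L, seed = 1L, nrounds = 200L) {
  n <- nrow(X)
  if (n_folds < 2) stop("n_folds must be >= 2")
  if (n_folds > n) stop("n_folds must not exceed the number of rows")
  if (n < 2 * n_folds) stop("need at least 2 rows per fold")
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(n_folds), n))
  oof <- numeric(n)
  models <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    hold <- fold_id == f
    models[[f]] <- .xgb_fit(X[!hold, , drop = FALSE], y[!hold],
                            nrounds = nrounds)
    oof[hold] <- .xgb_predict(models[[f]], X[hold, , drop = FALSE])
  }
  final <- .xgb_fit(X, y, nrounds = nrounds)
  list(oof = oof, fold_id = fold_id, models = models, final_model = final,
       residuals = y - oof)
}

#' Bias-corrected scores by median-replacing guide-dependent features
#'
#' Sets every guide-dependent feature column to its global median over
#' the supplied matrix (leaving residue-context features untouched) and
#' returns the model prediction on the modified matrix: the landscape a
#' screen would have produced had every guide carried median efficiency.
#'
#' @param fit result of \code{\link{fitOOF}} (or any object with
#'   \code{final_model} and, when \code{use_ensemble}, \code{models}).
#' @param X feature matrix used for training.
#' @param guide_cols names of the guide-dependent feature columns; never
#'   inferred.
#' @param use_ensemble average the per-fold models instead of the final
#'   all-data model.
#' @return Numeric vector of corrected scores, one per row of \code{X}.
#' @export
correctScores <- function(fit, X, guide_cols, use_ensemble = FALSE) {
  if (length(guide_cols) == 0)
    stop("guide_cols must name at least one guide-dependent column")
  missing_cols <- setdiff(guide_cols, colnames(X))
  if (length(missing_cols))
    stop("guide-dependent columns not in X: ",
         paste(missing_cols, collapse = ", "))
  Xc <- X
  for (nm in guide_cols) Xc[, nm] <- median(X[, nm])
  if (use_ensemble) {
    preds <- vapply(fit$models, function(m) .xgb_predict(m, Xc),
                    numeric(nrow(Xc)))
    rowMeans(preds)
  } else {
    .xgb_predict(fit$final_model, Xc)
  }
}

#' Prediction interval from out-of-fold residuals
#'
#' Global residual-quantile interval: corrected score plus/minus the
#' \code{level} quantile of the absolute OOF residuals.
#'
#' @param corrected corrected scores.
#' @param residuals OOF residuals from \code{\link{fitOOF}}.
#' @param level two-sided coverage in (0, 1); 0.95 for a 95\% interval.
#' @return data.frame(low, high).
#' @export
predictionInterval <- function(corrected, residuals, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  h <- unname(quantile(abs(residuals), level))
  data.frame(low = corrected - h, high = corrected + h)
}

#' Benchmark predictions against actual scores
#'
#' Point RMSE, Pearson r and Spearman rho plus a seeded percentile
#' bootstrap (median and 95\% CI) of each metric.
#'
#' @param predictions,actuals equal-length numeric vectors (n >= 3).
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @return list(rmse, pearson, spearman, bootstrap = data.frame with one
#'   row per metric: median, ci_low, ci_high). Correlations on a
#'   constant vector are reported as NA.
#' @export
benchmarkPredictions <- function(predictions, actuals, n_boot = 10000L,
                                 seed = 1L) {
  stopifnot(length(predictions) == length(actuals))
  n <- length(actuals)
  if (n < 3) stop("need at least 3 pairs")
  metric <- function(p, a) {
    c(rmse = sqrt(mean((p - a)^2)),
      pearson = if (stats::sd(p) == 0 || stats::sd(a) == 0) NA_real_
                else stats::cor(p, a),
      spearman = if (stats::sd(p) == 0 || stats::sd(a) == 0) NA_real_
                 else stats::cor(p, a, method = "spearman"))
  }
  pt <- metric(predictions, actuals)
  set.seed(seed)
  bs <- matrix(NA_real_, n_boot, 3)
  for (b in seq_len(n_boot)) {
    i <- sample.int(n, n, replace = TRUE)
    bs[b, ] <- metric(predictions[i], actuals[i])
  }
  boot <- data.frame(
    metric = names(pt),
    median = apply(bs, 2, median, na.rm = TRUE),
    ci_low = apply(bs, 2, quantile, 0.025, na.rm = TRUE),
    ci_high = apply(bs, 2, quantile, 0.975, na.rm = TRUE))
  list(rmse = unname(pt["rmse"]), pearson = unname(pt["pearson"]),
       spearman = unname(pt["spearman"]), bootstrap = boot)
}

#' Bias-correct a residue profile end to end
#'
#' Convenience wrapper: builds the feature matrix, fits the out-of-fold
#' model on the raw residue scores, median-replaces the guide-dependent
#' features and attaches \code{oof}, \code{corrected} and prediction
#' interval columns to the profile, per score type.
#'
#' @param profile a \linkS4class{ResidueProfile} with \code{<score>_raw}
#'   columns.
#' @param features per-residue feature data.frame (rows aligned with the
#'   profile).
#' @param guide_cols names of guide-dependent feature columns.
#' @param score_types score column stems to correct.
#' @param n_folds,seed,nrounds passed to \code{\link{fitOOF}}.
#' @param level prediction-interval coverage.
#' @param aa_col amino-acid identity column in \code{features}.
#' @return The profile with added columns \code{<score>_oof},
#'   \code{<score>_corrected}, \code{<score>_pi_low},
#'   \code{<score>_pi_high}; fitted objects in the \code{fits} attribute.
#' @export
correctProfile <- function(profile, features, guide_cols,
                           score_types = c("dropout", "functional"),
                           n_folds = 8L, seed = 1L, nrounds = 200L,
                           level = 0.95, aa_col = "aa") {
  d <- profileData(profile)
  stopifnot(nrow(features) == nrow(d))
  fits <- list()
  for (st in score_types) {
    raw_col <- paste0(st, "_raw")
    if (!raw_col %in% names(d)) next
    fb <- buildFeatures(features, d[[raw_col]], aa_col = aa_col)
    fit <- fitOOF(fb$X, fb$y, n_folds = n_folds, seed = seed,
                  nrounds = nrounds)
    corr <- correctScores(fit, fb$X, guide_cols)
    pi <- predictionInterval(corr, fit$residuals, level)
    d[[paste0(st, "_oof")]] <- fit$oof
    d[[paste0(st, "_corrected")]] <- corr
    d[[paste0(st, "_pi_low")]] <- pi$low
    d[[paste0(st, "_pi_high")]] <- pi$high
    fits[[st]] <- fit
  }
  out <- ResidueProfile(d)
  attr(out, "fits") <- fits
  out
}
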