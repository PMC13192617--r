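## Stage-2 regressor: a boosted linear model plus a tree boost on its
## residuals. A deterministic stand-in for an AutoML ensemble: the linear
## stage captures the (often near-linear) descriptor->logBB relation that
## pure tree boosting approximates poorly, the tree stage the remainder.
.hybrid_fit <- function(X, y, nrounds = 200L) {
  X <- as.matrix(X)
  lin <- xgb.train(params = list(booster = "gblinear",
                                 objective = "reg:squarederror",
                                 nthread = 1),
                   data = xgb.DMatrix(X, label = y, nthread = 1),
                   nrounds = nrounds)
  resid <- y - .xgb_predict(lin, X)
  tree <- xgb.train(params = list(objective = "reg:squarederror",
                                  eta = 0.05, max_depth = 3, nthread = 1),
                    data = xgb.DMatrix(X, label = resid, nthread = 1),
                    nrounds = nrounds %/% 2L)
  structure(list(linear = lin, tree = tree), class = "hybrid_booster")
}

.hybrid_predict <- function(model, X) {
  X <- as.matrix(X)
  .xgb_predict(model$linear, X) + .xgb_predict(model$tree, X)
}

#' Remove test compounds seen during training (leakage control)
#'
#' Drops every test-set row whose compound key appears in the training
#' set. Keys are compared as exact strings after an optional
#' canonicalisation function (e.g. a canonical-SMILES backend); when no
#' canonicaliser is supplied, exact-string matching is used with a
#' message. Rows whose key fails to canonicalise are excluded with a
#' warning.
#'
#' @param train_keys character keys of the training compounds.
#' @param test data.frame with a key column.
#' @param key_col name of the key column in \code{test}.
#' @param canonicalize optional \code{function(keys) -> keys}.
#' @return \code{test} filtered; removal counts in attributes
#'   \code{n_removed} (overlap) and \code{n_failed} (canonicalisation).
#' @export
deduplicateCompounds <- function(train_keys, test, key_col = "compound_key",
                                 canonicalize = NULL) {
  stopifnot(key_col %in% names(test))
  keys <- as.character(test[[key_col]])
  if (is.null(canonicalize)) {
    message("no canonicaliser supplied; matching compound keys exactly")
    canon_test <- keys
    canon_train <- as.character(train_keys)
    failed <- rep(FALSE, length(keys))
  } else {
    canon_test <- tryCatch(canonicalize(keys), error = function(e) NULL)
    canon_train <- canonicalize(as.character(train_keys))
    if (is.null(canon_test)) stop("canonicalisation of test keys failed")
    failed <- is.na(canon_test)
    if (any(failed))
      warning(sum(failed), " test keys failed to canonicalise; excluded")
  }
  overlap <- !failed & canon_test %in% canon_train
  out <- test[!failed & !overlap, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(overlap)
  attr(out, "n_failed") <- sum(failed)
  out
}

#' Fit the stacked blood-brain-barrier model
#'
#' Stage 1: a gradient-boosted binary penetrance classifier trained on
#' the classification dataset with seeded n-fold out-of-fold
#' predictions (OOF AUC retained as an internal diagnostic), then refit
#' on all classification rows. Stage 2: the refit classifier's
#' probability on the regression compounds is appended to their
#' descriptors and a gradient-boosted regressor is fit on descriptors +
#' probability to predict logBB. The regression set is assumed disjoint
#' from the classification set (enforce with
#' \code{\link{deduplicateCompounds}}), so the full-data refit
#' probability leaks nothing.
#'
#' @param class_data list/data.frame pair: \code{descriptors}
#'   (data.frame) and \code{bbb_class} (0/1).
#' @param reg_data list with \code{descriptors} and \code{logbb}.
#' @param n_folds stage-1 folds (default 8).
#' @param seed integer seed.
#' @param nrounds boosting rounds for both stages.
#' @return A \linkS4class{StackedBBBModel}.
#' @export
fitStacked <- function(class_data, reg_data, n_folds = 8L, seed = 1L,
                       nrounds = 200L) {
  Xc <- as.matrix(class_data$descriptors)
  yc <- as.numeric(class_data$bbb_class)
  Xr <- as.matrix(reg_data$descriptors)
  yr <- as.numeric(reg_data$logbb)
  if (!identical(colnames(Xc), colnames(Xr)))
    stop("classification and regression descriptor schemas differ")
  n <- nrow(Xc)
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(n_folds), n))
  oof <- numeric(n)
  for (f in seq_len(n_folds)) {
    hold <- fold_id == f
    m <- .xgb_fit(Xc[!hold, , drop = FALSE], yc[!hold],
                  objective = "binary:logistic", nrounds = nrounds)
    oof[hold] <- .xgb_predict(m, Xc[hold, , drop = FALSE])
  }
  oof_auc <- .mw_auc(oof, yc)
  stage1 <- .xgb_fit(Xc, yc, objective = "binary:logistic",
                     nrounds = nrounds)
  prob_r <- .xgb_predict(stage1, Xr)
  X2 <- cbind(Xr, bbb_prob = prob_r)
  stage2 <- .hybrid_fit(X2, yr, nrounds = nrounds)
  meds <- apply(Xr, 2, median)
  new("StackedBBBModel", stage1 = stage1, stage2 = stage2,
      descriptors = colnames(Xr), fold_id = fold_id, oof_auc = oof_auc,
      medians = meds, seed = as.integer(seed))
}

#' Predict logBB with a stacked model
#'
#' Missing descriptors are imputed with the training medians (with a
#' warning); \code{class_score} is the logBB prediction itself, the
#' ranking score used for ROC evaluation against penetrance labels.
#'
#' @param model a \linkS4class{StackedBBBModel}.
#' @param descriptors data.frame/matrix of descriptors.
#' @return data.frame(logbb_pred, class_score).
#' @export
predictBBB <- function(model, descriptors) {
  X <- as.data.frame(descriptors)
  miss <- setdiff(model@descriptors, names(X))
  if (length(miss)) {
    warning("imputing missing descriptors with training medians: ",
            paste(miss, collapse = ", "))
    for (nm in miss) X[[nm]] <- model@medians[[nm]]
  }
  X <- as.matrix(X[, model@descriptors, drop = FALSE])
  if (anyNA(X)) {
    for (nm in colnames(X)) {
      j <- is.na(X[, nm])
      if (any(j)) {
        warning("imputing NA values in '", nm, "' with training median")
        X[j, nm] <- model@medians[[nm]]
      }
    }
  }
  prob <- .xgb_predict(model@stage1, X)
  pred <- .hybrid_predict(model@stage2, cbind(X, bbb_prob = prob))
  data.frame(logbb_pred = pred, class_score = pred)
}

## Mann-Whitney formulation of the AUC, with tie handling via midranks
.mw_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC AUC with compound-level bootstrap
#'
#' AUC by the Mann-Whitney rank statistic, plus a seeded bootstrap over
#' compounds: mean AUC and a 95 percent percentile interval.
#'
#' @param scores numeric ranking scores.
#' @param labels binary labels (0/1 or logical).
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @return list(auc, boot_mean, ci_low, ci_high).
#' @export
evaluateAUC <- function(scores, labels, n_boot = 10000L, seed = 1L) {
  labels <- as.numeric(labels)
  if (length(scores) < 10) stop("need at least 10 observations")
  auc <- .mw_auc(scores, labels)
  set.seed(seed)
  n <- length(scores)
  bs <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    i <- sample.int(n, n, replace = TRUE)
    bs[b] <- if (length(unique(labels[i])) < 2) NA_real_
             else .mw_auc(scores[i], labels[i])
  }
  list(auc = auc, boot_mean = mean(bs, na.rm = TRUE),
       ci_low = unname(quantile(bs, 0.025, na.rm = TRUE)),
       ci_high = unname(quantile(bs, 0.975, na.rm = TRUE)))
}
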