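#' Fit a FACS gating classifier
#'
#' Trains a gradient-boosted binary classifier (default parameters) on
#' labelled reference events, holding out a calibration split whose
#' posteriors are later used to turn a target false-discovery rate into
#' per-class probability cutoffs.
#'
#' @param reference data.frame of events with channel columns and a
#'   condition label column (exactly two conditions, >= 50 events each).
#' @param channels channel column names; default: all numeric columns
#'   except \code{event_id}.
#' @param label_col name of the condition label column.
#' @param calibration_frac fraction of events held out for calibration.
#' @param cofactor optional arcsinh cofactor applied to channels
#'   (\code{asinh(x / cofactor)}); NA = no transform.
#' @param seed integer seed for the split.
#' @param nrounds boosting rounds.
#' @return A \linkS4class{GateModel}.
#' @export
fitGate <- function(reference, channels = NULL, label_col = "label",
                    calibration_frac = 0.25, cofactor = NA_real_,
                    seed = 1L, nrounds = 50L) {
  stopifnot(is.data.frame(reference), label_col %in% names(reference))
  lab <- as.character(reference[[label_col]])
  classes <- sort(unique(lab))
  if (length(classes) != 2)
    stop("reference must contain exactly 2 condition labels, got ",
         length(classes))
  if (any(table(lab) < 50))
    stop("need >= 50 events per condition")
  if (is.null(channels))
    channels <- names(reference)[vapply(reference, is.numeric, TRUE) &
                                 names(reference) != "event_id"]
  X <- as.matrix(reference[, channels, drop = FALSE])
  if (!is.na(cofactor)) X <- asinh(X / cofactor)
  y <- as.numeric(lab == classes[2])
  set.seed(seed)
  n <- nrow(X)
  cal_idx <- sample.int(n, max(1L, round(calibration_frac * n)))
  train <- setdiff(seq_len(n), cal_idx)
  booster <- .xgb_fit(X[train, , drop = FALSE], y[train],
                      objective = "binary:logistic", nrounds = nrounds)
  post <- .xgb_predict(booster, X[cal_idx, , drop = FALSE])
  new("GateModel", booster = booster, channels = channels,
      classes = classes,
      calibration = data.frame(posterior = post, label = lab[cal_idx]),
      cofactor = cofactor, seed = as.integer(seed))
}

## smallest posterior threshold >= 0.5 whose estimated FDR on the
## calibration split is <= fdr; estimated FDR at t = fraction of
## opposite-condition events among calibration events with posterior >= t
.class_cutoff <- function(post, is_class, fdr) {
  cand <- sort(unique(c(0.5, post[post >= 0.5])))
  for (t in cand) {
    called <- post >= t
    if (!any(called)) next
    if (mean(!is_class[called]) <= fdr) return(t)
  }
  Inf  # no threshold achieves the FDR: class never called
}

#' Classify events at a target false-discovery rate
#'
#' Scores events with a fitted \linkS4class{GateModel} and assigns each
#' to one of the two gated classes or to \code{"unspecific"}. Each
#' class's posterior cutoff is the smallest threshold (at or above 0.5)
#' whose estimated false-discovery rate on the held-out calibration
#' split does not exceed \code{fdr}; ties at the cutoff are included.
#' Events clearing neither cutoff are unspecific. At \code{fdr = 1} the
#' cutoffs sit at 0.5 and no event is unspecific.
#'
#' @param events data.frame carrying the model's channel columns.
#' @param model a \linkS4class{GateModel}.
#' @param fdr target false-discovery rate in (0, 1].
#' @return \code{events} with added columns \code{posterior} (probability
#'   of the second class) and \code{class}; per-class fractions and the
#'   cutoffs are attached as attributes \code{fractions} and
#'   \code{cutoffs}.
#' @export
classifyEvents <- function(events, model, fdr = 0.05) {
  stopifnot(is(model, "GateModel"))
  if (fdr <= 0 || fdr > 1) stop("fdr must be in (0, 1]")
  miss <- setdiff(model@channels, names(events))
  if (length(miss))
    stop("events are missing channels: ", paste(miss, collapse = ", "))
  X <- as.matrix(events[, model@channels, drop = FALSE])
  if (!is.na(model@cofactor)) X <- asinh(X / model@cofactor)
  p2 <- .xgb_predict(model@booster, X)   # posterior of classes[2]
  cal <- model@calibration
  cut2 <- .class_cutoff(cal$posterior, cal$label == model@classes[2], fdr)
  cut1 <- .class_cutoff(1 - cal$posterior, cal$label == model@classes[1], fdr)
  cls <- rep("unspecific", nrow(events))
  cls[p2 >= cut2] <- model@classes[2]
  cls[(1 - p2) >= cut1] <- model@classes[1]
  both <- (p2 >= cut2) & ((1 - p2) >= cut1)  # only possible at cutoffs = 0.5
  cls[both] <- ifelse(p2[both] >= 0.5, model@classes[2], model@classes[1])
  out <- events
  out$posterior <- p2
  out$class <- cls
  frac <- table(factor(cls, levels = c(model@classes, "unspecific")))
  attr(out, "fractions") <- as.numeric(frac) / max(nrow(events), 1L)
  names(attr(out, "fractions")) <- names(frac)
  attr(out, "cutoffs") <- c(setNames(cut1, model@classes[1]),
                            setNames(cut2, model@classes[2]))
  out
}
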