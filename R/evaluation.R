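#' Confusion counts at a score cutoff
#'
#' A score strictly greater than the cutoff is a predicted positive; all
#' scores equal to the cutoff are predicted negative.
#'
#' @param labels 0/1 vector.
#' @param scores numeric vector, same length.
#' @param cutoff numeric cutoff (default 0.5).
#' @return named integer vector (tp, fp, tn, fn).
#' @export
confusionCounts <- function(labels, scores, cutoff = 0.5) {
  if (length(labels) != length(scores)) stop("length mismatch")
  if (length(labels) && !all(labels %in% c(0, 1))) stop("labels must be 0/1")
  pred <- scores > cutoff
  c(tp = sum(pred & labels == 1), fp = sum(pred & labels == 0),
    tn = sum(!pred & labels == 0), fn = sum(!pred & labels == 1))
}

#' Sensitivity, specificity, MCC and F1 from confusion counts
#'
#' Sn = TP/(TP+FN); Sp = TN/(TN+FP);
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN));
#' F1 = 2*TP / (2*TP + FP + FN). A metric whose denominator is zero is
#' returned as 0 and listed in the \code{degenerate} attribute instead of
#' raising, so degenerate confusion tables never abort a batch run.
#'
#' @param counts named vector with tp, fp, tn, fn.
#' @return named numeric (sn, sp, mcc, f1) with attribute
#'   \code{"degenerate"} naming zero-denominator metrics.
#' @export
computeMetrics <- function(counts) {
  tp <- as.numeric(counts[["tp"]]); fp <- as.numeric(counts[["fp"]])
  tn <- as.numeric(counts[["tn"]]); fn <- as.numeric(counts[["fn"]])
  if (any(c(tp, fp, tn, fn) < 0)) stop("counts must be non-negative")
  degenerate <- character()
  ratio <- function(num, den, name) {
    if (den == 0) {
      degenerate <<- c(degenerate, name)
      0
    } else num / den
  }
  sn <- ratio(tp, tp + fn, "sn")
  sp <- ratio(tn, tn + fp, "sp")
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- ratio(tp * tn - fp * fn, mcc_den, "mcc")
  f1 <- ratio(2 * tp, 2 * tp + fp + fn, "f1")
  out <- c(sn = sn, sp = sp, mcc = mcc, f1 = f1)
  attr(out, "degenerate") <- degenerate
  out
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic through mid-ranks:
#' P(score of a positive > score of a negative) with ties counted 1/2.
#' Equals exhaustive pairwise enumeration and is invariant under any
#' strictly increasing transform of the scores.
#'
#' @param labels 0/1 vector with both classes present.
#' @param scores numeric vector.
#' @return AUC in [0, 1].
#' @export
computeAuc <- function(labels, scores) {
  if (length(labels) != length(scores)) stop("length mismatch")
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Normalized per-feature importance of a trained model
#'
#' Mean decrease in Gini impurity for random forests, total gain for
#' XGBoost; normalized to sum to 1 and named by feature. Features a boosted
#' model never split on get importance 0.
#'
#' @param model an \code{\linkS4class{ErnaModel}}.
#' @return named numeric vector summing to 1.
#' @export
featureImportance <- function(model) {
  if (!is(model, "ErnaModel")) stop("'model' must be an ErnaModel")
  if (model@algorithm == "random_forest") {
    imp <- randomForest::importance(model@fit, type = 2)[, 1L]
  } else {
    bst <- xgboost::xgb.load.raw(model@fit)
    tab <- xgboost::xgb.importance(feature_names = model@featureNames,
                                   model = bst)
    imp <- setNames(rep(0, length(model@featureNames)), model@featureNames)
    imp[tab$Feature] <- tab$Gain
  }
  tot <- sum(imp)
  if (tot <= 0) stop("model carries no importance information (unfitted?)")
  imp / tot
}

#' Assemble an evaluation report from labels and scores
#'
#' @param labels 0/1 vector.
#' @param scores numeric score vector.
#' @param cutoff score cutoff for the hard-call metrics (default 0.5).
#' @param importance optional named numeric importance vector to embed.
#' @return an \code{\linkS4class{ErnaEvalReport}}.
#' @export
evaluateScores <- function(labels, scores, cutoff = 0.5, importance = numeric()) {
  counts <- confusionCounts(labels, scores, cutoff)
  m <- computeMetrics(counts)
  degenerate <- attr(m, "degenerate")
  auc <- if (sum(labels == 1) > 0 && sum(labels == 0) > 0) {
    computeAuc(labels, scores)
  } else {
    degenerate <- c(degenerate, "auc")
    NA_real_
  }
  new("ErnaEvalReport", sn = m[["sn"]], sp = m[["sp"]], auc = auc,
      mcc = m[["mcc"]], f1 = m[["f1"]],
      counts = setNames(as.integer(counts), names(counts)),
      cutoff = cutoff, degenerate = degenerate,
      featureImportance = importance)
}

#' Evaluate a trained model on a feature matrix
#'
#' Scores the regions, computes all hard-call metrics at the cutoff plus
#' AUC, and embeds the model's normalized feature importance.
#'
#' @param model an \code{\linkS4class{ErnaModel}}.
#' @param features a \code{\linkS4class{FeatureMatrix}} or matrix.
#' @param labels 0/1 vector aligned with the rows.
#' @param cutoff score cutoff (default 0.5).
#' @return an \code{\linkS4class{ErnaEvalReport}}.
#' @export
evaluateModel <- function(model, features, labels, cutoff = 0.5) {
  scores <- predictScores(model, features)
  evaluateScores(labels, scores, cutoff = cutoff,
                 importance = featureImportance(model))
}
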