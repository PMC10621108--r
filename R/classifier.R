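#' Stratified train/test split of labeled regions
#'
#' Splits the positive (PR) and negative (NR) regions into training and test
#' sets, preserving the class proportions; fuzzy regions are excluded from
#' supervised fitting. Deterministic given the seed.
#'
#' @param labeled a labeled \code{GRanges} from \code{\link{assignLabels}}.
#' @param fraction training fraction (default 0.8).
#' @param seed integer seed.
#' @return list with integer index vectors \code{train} and \code{test}
#'   (indices into \code{labeled}), plus \code{fraction}, \code{stratified},
#'   \code{seed}.
#' @export
makeSplit <- function(labeled, fraction = 0.8, seed = 1L) {
  lab <- mcols(labeled)$label
  pos <- which(lab == "PR")
  neg <- which(lab == "NR")
  if (!length(pos)) stop("no positive (PR) regions")
  if (!length(neg)) stop("no negative (NR) regions")
  withSeed(seed, {
    tr_pos <- sort(sample(pos, round(fraction * length(pos))))
    tr_neg <- sort(sample(neg, round(fraction * length(neg))))
  })
  train <- sort(c(tr_pos, tr_neg))
  test <- sort(setdiff(c(pos, neg), train))
  list(train = train, test = test, fraction = fraction,
       stratified = TRUE, seed = as.integer(seed))
}

#' Binary labels (1 = positive) for the supervised subset
#'
#' @param labeled a labeled \code{GRanges}.
#' @param idx indices (e.g. from \code{\link{makeSplit}}).
#' @return integer vector of 0/1 labels.
#' @export
binaryLabels <- function(labeled, idx = seq_along(labeled)) {
  lab <- mcols(labeled)$label[idx]
  if (any(lab == "FR")) stop("fuzzy regions carry no supervised label")
  as.integer(lab == "PR")
}

defaultRfGrid <- function(n_features) {
  s <- max(1L, floor(sqrt(n_features)))
  list(mtry = unique(pmin(n_features, c(max(1L, floor(s / 2)), s, 2L * s))),
       ntree = c(250L, 500L, 1000L))
}

defaultXgbGrid <- function() {
  list(nrounds = c(50L, 100L, 200L), max_depth = c(3L, 4L, 6L),
       eta = c(0.05, 0.1, 0.3))
}

#' Tune a random forest by out-of-bag error, one hyperparameter at a time
#'
#' Coordinate-wise search: \code{mtry} is scanned with \code{ntree} fixed at
#' the middle grid value, then \code{ntree} is scanned at the best
#' \code{mtry}; each candidate is scored by its out-of-bag error. Ties are
#' broken toward smaller \code{ntree}, then smaller \code{mtry}.
#'
#' @param x numeric feature matrix (rows = regions).
#' @param y 0/1 labels.
#' @param grid list with integer vectors \code{mtry} and \code{ntree};
#'   default per \code{floor(sqrt(F))}-scaled standard ranges.
#' @param seed integer seed.
#' @return list with \code{mtry}, \code{ntree}, \code{oob} (the selected
#'   point's error) and \code{trace} (per-candidate errors).
#' @export
tuneRandomForest <- function(x, y, grid = NULL, seed = 1L) {
  if (length(unique(y)) < 2L) stop("labels are degenerate (one class)")
  if (is.null(grid)) grid <- defaultRfGrid(ncol(x))
  if (!length(grid$mtry) || !length(grid$ntree)) stop("empty grid")
  yf <- factor(y, levels = c(0, 1))
  oobAt <- function(mtry, ntree) {
    withSeed(seed, {
      rf <- randomForest::randomForest(x, yf, mtry = mtry, ntree = ntree)
    })
    unname(rf$err.rate[ntree, "OOB"])
  }
  trace <- data.frame(mtry = integer(), ntree = integer(), oob = numeric())
  ntree_mid <- sort(grid$ntree)[ceiling(length(grid$ntree) / 2)]
  mtrys <- sort(unique(grid$mtry))
  e1 <- vapply(mtrys, oobAt, numeric(1), ntree = ntree_mid)
  trace <- rbind(trace, data.frame(mtry = mtrys, ntree = ntree_mid, oob = e1))
  best_mtry <- mtrys[which.min(e1)]            # ties -> smaller mtry
  ntrees <- sort(unique(grid$ntree))
  e2 <- vapply(ntrees, function(nt) oobAt(best_mtry, nt), numeric(1))
  trace <- rbind(trace, data.frame(mtry = best_mtry, ntree = ntrees, oob = e2))
  best_ntree <- ntrees[which.min(e2)]          # ties -> smaller ntree
  list(mtry = best_mtry, ntree = best_ntree, oob = min(e2), trace = trace)
}

#' Tune XGBoost by stratified five-fold cross-validation
#'
#' Scores every grid point (nrounds, max_depth, eta) by its mean
#' misclassification error over 5 stratified folds. Ties are broken toward
#' smaller \code{nrounds}, then smaller \code{max_depth}, then larger
#' \code{eta}.
#'
#' @param x numeric feature matrix.
#' @param y 0/1 labels (>= \code{folds} examples per class).
#' @param grid list with vectors \code{nrounds}, \code{max_depth},
#'   \code{eta}.
#' @param folds number of CV folds (default 5).
#' @param seed integer seed.
#' @return list with the selected \code{nrounds}, \code{max_depth},
#'   \code{eta}, \code{cv_error} and \code{trace}.
#' @export
tuneXgboost <- function(x, y, grid = NULL, folds = 5L, seed = 1L) {
  if (is.null(grid)) grid <- defaultXgbGrid()
  if (!length(grid$nrounds) || !length(grid$max_depth) || !length(grid$eta))
    stop("empty grid")
  if (min(table(y)) < folds) stop("need >= folds examples per class")
  fold_id <- withSeed(seed, stratifiedFolds(y, folds))
  # grid ordered so that which.min's first hit honors the tie-break order
  g <- expand.grid(eta = sort(grid$eta, decreasing = TRUE),
                   max_depth = sort(grid$max_depth),
                   nrounds = sort(grid$nrounds))
  g <- g[order(g$nrounds, g$max_depth, -g$eta), , drop = FALSE]
  errs <- numeric(nrow(g))
  for (i in seq_len(nrow(g))) {
    fold_err <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      withSeed(seed + f, {
        bst <- xgbFit(x[tr, , drop = FALSE], y[tr], nrounds = g$nrounds[i],
                      max_depth = g$max_depth[i], eta = g$eta[i])
      })
      pred <- xgbPredict(bst, x[!tr, , drop = FALSE])
      fold_err[f] <- mean((pred > 0.5) != (y[!tr] == 1))
    }
    errs[i] <- mean(fold_err)
  }
  best <- which.min(errs)
  list(nrounds = g$nrounds[best], max_depth = g$max_depth[best],
       eta = g$eta[best], cv_error = errs[best],
       trace = cbind(g, cv_error = errs))
}

stratifiedFolds <- function(y, folds) {
  id <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  id
}

#' Train an eRNA classifier
#'
#' Fits a random forest or XGBoost model on the positive/negative feature
#' matrix. Class imbalance is left to the learner (no resampling); both
#' algorithms tolerate it. Deterministic given the seed.
#'
#' @param features a \code{\linkS4class{FeatureMatrix}} or plain numeric
#'   matrix.
#' @param y 0/1 labels, one per row.
#' @param algorithm \code{"random_forest"} or \code{"xgboost"}.
#' @param hyperparameters named list (RF: \code{mtry}, \code{ntree}; XGB:
#'   \code{nrounds}, \code{max_depth}, \code{eta}); defaults are the middle
#'   of the standard grids when omitted.
#' @param combination feature-combination index recorded with the model
#'   (taken from \code{features} when it is a \code{FeatureMatrix}).
#' @param seed integer seed.
#' @param tuningTrace optional data.frame recorded from tuning.
#' @return an \code{\linkS4class{ErnaModel}}.
#' @export
trainModel <- function(features, y, algorithm = c("random_forest", "xgboost"),
                       hyperparameters = NULL, combination = NULL, seed = 1L,
                       tuningTrace = data.frame()) {
  algorithm <- match.arg(algorithm)
  x <- if (is(features, "FeatureMatrix")) featureValues(features) else features
  if (is.null(combination))
    combination <- if (is(features, "FeatureMatrix")) combinationIndex(features) else 1L
  if (nrow(x) != length(y)) stop("feature/label length mismatch")
  if (length(unique(y)) < 2L) stop("labels must contain both classes")
  if (algorithm == "random_forest") {
    if (is.null(hyperparameters))
      hyperparameters <- list(mtry = max(1L, floor(sqrt(ncol(x)))), ntree = 500L)
    withSeed(seed, {
      fit <- randomForest::randomForest(
        x, factor(y, levels = c(0, 1)),
        mtry = hyperparameters$mtry, ntree = hyperparameters$ntree,
        importance = TRUE
      )
    })
  } else {
    if (is.null(hyperparameters))
      hyperparameters <- list(nrounds = 100L, max_depth = 4L, eta = 0.1)
    withSeed(seed, {
      bst <- xgbFit(x, y, nrounds = hyperparameters$nrounds,
                    max_depth = hyperparameters$max_depth,
                    eta = hyperparameters$eta)
    })
    fit <- xgboost::xgb.save.raw(bst)
  }
  new("ErnaModel", algorithm = algorithm, hyperparameters = hyperparameters,
      combination = as.integer(combination), seed = as.integer(seed),
      featureNames = colnames(x), fit = fit, tuningTrace = tuningTrace)
}

#' Predict eRNA scores for regions
#'
#' Scores in [0, 1], one per region, in input order. The feature columns
#' must match the model's feature names exactly, including order; a
#' mismatch is an error, never a silent mis-prediction.
#'
#' @param model an \code{\linkS4class{ErnaModel}}.
#' @param features a \code{\linkS4class{FeatureMatrix}} or numeric matrix.
#' @return numeric score vector.
#' @export
predictScores <- function(model, features) {
  x <- if (is(features, "FeatureMatrix")) featureValues(features) else features
  if (!identical(colnames(x), model@featureNames))
    stop("feature columns do not match the model's feature names/order")
  if (nrow(x) == 0L) return(numeric(0))
  if (model@algorithm == "random_forest") {
    unname(predict(model@fit, x, type = "prob")[, "1"])
  } else {
    bst <- xgboost::xgb.load.raw(model@fit)
    xgbPredict(bst, x)
  }
}

# single-threaded binary-logistic boosting through the stable low-level API
xgbFit <- function(x, y, nrounds, max_depth, eta) {
  dm <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = eta, nthread = 1),
    data = dm, nrounds = nrounds, verbose = 0
  )
}

xgbPredict <- function(bst, x) {
  predict(bst, xgboost::xgb.DMatrix(x, nthread = 1))
}

#' Apply a model trained in one cell to another cell
#'
#' Cross-cell validation: the model is applied without refitting to the
#' other cell's feature matrix (which must use the same feature
#' combination), and evaluated against that cell's labels.
#'
#' @param model an \code{\linkS4class{ErnaModel}} trained on cell A.
#' @param features cell B's \code{\linkS4class{FeatureMatrix}}.
#' @param y cell B's 0/1 labels.
#' @param cutoff score cutoff for hard calls (default 0.5).
#' @return list with \code{scores} and \code{report}
#'   (\code{\linkS4class{ErnaEvalReport}}).
#' @export
crossCellApply <- function(model, features, y, cutoff = 0.5) {
  if (is(features, "FeatureMatrix") &&
      combinationIndex(features) != model@combination)
    stop("feature-combination mismatch between model and features")
  scores <- predictScores(model, features)
  list(scores = scores,
       report = evaluateScores(y, scores, cutoff = cutoff))
}

#' Save a trained model as a self-describing archive
#'
#' The archive embeds the algorithm, hyperparameters, feature names,
#' package version and an md5 checksum of the serialized payload;
#' \code{\link{loadModel}} verifies the checksum before deserializing.
#'
#' @param model an \code{\linkS4class{ErnaModel}}.
#' @param path output file.
#' @export
saveModel <- function(model, path) {
  payload <- serialize(list(
    algorithm = model@algorithm, hyperparameters = model@hyperparameters,
    combination = model@combination, seed = model@seed,
    featureNames = model@featureNames, fit = model@fit,
    tuningTrace = model@tuningTrace,
    version = as.character(utils::packageVersion("eRNAtools"))
  ), connection = NULL)
  saveRDS(list(payload = payload, md5 = md5OfBytes(payload)), path)
  invisible(path)
}

#' Load a model archive, verifying its checksum
#' @param path file written by \code{\link{saveModel}}.
#' @return an \code{\linkS4class{ErnaModel}}.
#' @export
loadModel <- function(path) {
  arch <- readRDS(path)
  if (!identical(md5OfBytes(arch$payload), arch$md5))
    stop("model archive checksum mismatch; file corrupted")
  obj <- unserialize(arch$payload)
  new("ErnaModel", algorithm = obj$algorithm,
      hyperparameters = obj$hyperparameters, combination = obj$combination,
      seed = obj$seed, featureNames = obj$featureNames, fit = obj$fit,
      tuningTrace = obj$tuningTrace)
}

md5OfBytes <- function(bytes) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(bytes, tmp)
  unname(tools::md5sum(tmp))
}

# evaluate under a temporary seed without disturbing the caller's RNG state
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}
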