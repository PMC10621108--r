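# small labeled dataset shared by the classifier tests: clear class signal
# in the methylation block, built once at a fixed seed
mkTrainingCell <- function(n = 600L, seed = 13L, uninformative = FALSE) {
  cfg <- if (uninformative) {
    simConfig(n_regions = n, seed = seed, h3k27ac_enrichment = 1,
              h3k9ac_enrichment = 1, methyl_means = c(0.5, 0.5),
              gene_expression_boost = 1)
  } else {
    simConfig(n_regions = n, seed = seed)
  }
  cell <- simulateCell(cfg)
  calls <- ifelse(cell$truth$class == "positive", "true_eRNA", "noise")
  lab <- assignLabels(cell$regions, calls, cell$dnase)
  fm <- buildFeatureMatrix(cell$regions, methyl = cell$methyl,
                           h3k27ac = cell$h3k27ac,
                           sequences = cell$sequences, combination = 2L)
  list(cell = cell, lab = lab, fm = fm)
}

test_that("stratified split keeps class proportions, excludes fuzzy regions", {
  n <- 500L
  regions <- toyRegions((0:(n - 1)) * 400, rep(200, n))
  calls <- c(rep("true_eRNA", 100), rep("noise", 400))
  peaks <- regions[1:100]                       # all expressed ones open
  lab <- assignLabels(regions, calls, peaks)    # 100 PR, 400 NR
  sp <- makeSplit(lab, fraction = 0.8, seed = 2L)
  lab_train <- mcols(lab)$label[sp$train]
  expect_equal(sum(lab_train == "PR"), 80L)
  expect_equal(sum(lab_train == "NR"), 320L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), 1:500)
  # determinism
  sp2 <- makeSplit(lab, fraction = 0.8, seed = 2L)
  expect_identical(sp, sp2)
  # class-empty error
  lab_nopos <- assignLabels(regions, rep("noise", n), GRanges())
  expect_error(makeSplit(lab_nopos), "no positive")
})

test_that("RF tuning searches coordinate-wise, stays in the grid, is deterministic", {
  d <- mkTrainingCell()
  sp <- makeSplit(d$lab, seed = 3L)
  x <- featureValues(d$fm)[sp$train, ]
  y <- binaryLabels(d$lab, sp$train)
  grid <- list(mtry = c(1L, 3L), ntree = c(60L, 120L))
  tuned <- tuneRandomForest(x, y, grid = grid, seed = 3L)
  expect_true(tuned$mtry %in% grid$mtry)
  expect_true(tuned$ntree %in% grid$ntree)
  expect_lt(tuned$oob, 0.5)                       # informative features
  tuned2 <- tuneRandomForest(x, y, grid = grid, seed = 3L)
  expect_identical(tuned[c("mtry", "ntree", "oob")],
                   tuned2[c("mtry", "ntree", "oob")])
  # one-point grid returns that point
  one <- tuneRandomForest(x, y, grid = list(mtry = 2L, ntree = 50L), seed = 3L)
  expect_equal(one$mtry, 2L)
  expect_equal(one$ntree, 50L)
  expect_error(tuneRandomForest(x, rep(1, nrow(x))), "degenerate")
})

test_that("XGBoost tuning with five folds stays in the grid and separates easy data", {
  d <- mkTrainingCell()
  sp <- makeSplit(d$lab, seed = 5L)
  x <- featureValues(d$fm)[sp$train, ]
  y <- binaryLabels(d$lab, sp$train)
  grid <- list(nrounds = c(20L, 40L), max_depth = 3L, eta = 0.3)
  tuned <- tuneXgboost(x, y, grid = grid, seed = 5L)
  expect_true(tuned$nrounds %in% grid$nrounds)
  expect_lt(tuned$cv_error, 0.1)                  # separable synthetic data
  tuned2 <- tuneXgboost(x, y, grid = grid, seed = 5L)
  expect_identical(tuned[c("nrounds", "max_depth", "eta", "cv_error")],
                   tuned2[c("nrounds", "max_depth", "eta", "cv_error")])
  one <- tuneXgboost(x, y, grid = list(nrounds = 10L, max_depth = 2L, eta = 0.5),
                     seed = 5L)
  expect_equal(one$nrounds, 10L)
  expect_error(tuneXgboost(x[1:6, ], y[1:6], grid = grid), "folds")
})

test_that("training is deterministic and perfectly fits a separating feature", {
  x <- cbind(sep = c(rnorm(50, -3), rnorm(50, 3)), noise = rnorm(100))
  y <- rep(c(0L, 1L), each = 50)
  for (algo in c("random_forest", "xgboost")) {
    m1 <- trainModel(x, y, algorithm = algo, seed = 7L)
    m2 <- trainModel(x, y, algorithm = algo, seed = 7L)
    expect_identical(predictScores(m1, x), predictScores(m2, x))
    expect_equal(computeAuc(y, predictScores(m1, x)), 1.0)
  }
  expect_error(trainModel(x, y[-1]), "mismatch")
})

test_that("prediction refuses mismatched or reordered feature columns", {
  d <- mkTrainingCell(n = 300L)
  sp <- makeSplit(d$lab, seed = 1L)
  x <- featureValues(d$fm)
  model <- trainModel(x[sp$train, ], binaryLabels(d$lab, sp$train),
                      combination = 2L, seed = 1L)
  expect_error(predictScores(model, x[, rev(colnames(x))]), "match")
  expect_error(predictScores(model, x[, -1]), "match")
  expect_length(predictScores(model, x[0, , drop = FALSE]), 0L)
  s <- predictScores(model, x[sp$test, ])
  expect_length(s, length(sp$test))
  expect_true(all(s >= 0 & s <= 1))
  y_test <- binaryLabels(d$lab, sp$test)
  expect_gt(mean(s[y_test == 1]), mean(s[y_test == 0]))
})

test_that("cross-cell application shares signal structure without refitting", {
  cfgs <- list(simConfig(n_regions = 600L, seed = 31L),
               simConfig(n_regions = 600L, seed = 32L))
  cells <- simulateMultiCell(cfgs, shared_positive_fraction = 0.05, seed = 31L)
  prep <- lapply(cells, function(cell) {
    calls <- ifelse(cell$truth$class == "positive", "true_eRNA", "noise")
    lab <- assignLabels(cell$regions, calls, cell$dnase)
    fm <- buildFeatureMatrix(cell$regions, methyl = cell$methyl,
                             h3k27ac = cell$h3k27ac,
                             sequences = cell$sequences, combination = 2L)
    keep <- which(mcols(lab)$label %in% c("PR", "NR"))
    list(x = featureValues(fm)[keep, ], y = binaryLabels(lab, keep), fm = fm)
  })
  model <- trainModel(prep[[1]]$x, prep[[1]]$y, combination = 2L, seed = 31L)
  res <- crossCellApply(model, prep[[2]]$x, prep[[2]]$y)
  expect_s4_class(res$report, "ErnaEvalReport")
  expect_gte(res$report@auc, 0.85)
  # permuted labels give chance-level AUC
  set.seed(99)
  yp <- sample(prep[[2]]$y)
  null <- crossCellApply(model, prep[[2]]$x, yp)
  expect_lt(abs(null$report@auc - 0.5), 0.07)
  # combination mismatch is refused
  fm1 <- buildFeatureMatrix(cells[[2]]$regions, methyl = cells[[2]]$methyl,
                            sequences = cells[[2]]$sequences, combination = 1L)
  expect_error(crossCellApply(model, fm1, prep[[2]]$y), "mismatch")
})

test_that("model archives round-trip and detect corruption", {
  x <- cbind(a = rnorm(80), b = rnorm(80))
  y <- rep(c(0L, 1L), 40)
  for (algo in c("random_forest", "xgboost")) {
    model <- trainModel(x, y, algorithm = algo, seed = 3L)
    path <- tempfile(fileext = ".bin")
    saveModel(model, path)
    back <- loadModel(path)
    expect_identical(predictScores(back, x), predictScores(model, x))
    expect_identical(modelHyperparameters(back), modelHyperparameters(model))
    # corrupt one payload byte
    arch <- readRDS(path)
    arch$payload[100] <- as.raw(bitwXor(as.integer(arch$payload[100]), 255L))
    saveRDS(arch, path)
    expect_error(loadModel(path), "checksum")
  }
})

test_that("H3K27ac-informed combination is not worse than methylation alone", {
  aucs <- vapply(1:5, function(s) {
    cfg <- simConfig(n_regions = 500L, seed = 40L + s)
    cell <- simulateCell(cfg)
    calls <- ifelse(cell$truth$class == "positive", "true_eRNA", "noise")
    lab <- assignLabels(cell$regions, calls, cell$dnase)
    sp <- makeSplit(lab, seed = s)
    out <- vapply(c(1L, 2L), function(k) {
      fm <- buildFeatureMatrix(cell$regions, methyl = cell$methyl,
                               h3k27ac = cell$h3k27ac,
                               sequences = cell$sequences, combination = k)
      x <- featureValues(fm)
      m <- trainModel(x[sp$train, ], binaryLabels(lab, sp$train),
                      combination = k, seed = s)
      computeAuc(binaryLabels(lab, sp$test),
                 predictScores(m, x[sp$test, ]))
    }, numeric(1))
    out[2] - out[1]
  }, numeric(1))
  expect_true(all(aucs >= -0.02))
})
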