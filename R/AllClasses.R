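#' @import methods
#' @importFrom S4Vectors metadata metadata<- mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges granges seqnames start end width
#'   findOverlaps countOverlaps pintersect
#' @importFrom IRanges IRanges overlapsAny isDisjoint
#' @importFrom GenomeInfoDb seqlevels
#' @importFrom stats dpois dnbinom qpois qnbinom rpois rnbinom rbinom runif
#'   rbeta rexp optim pchisq median setNames quantile cor sd
NULL

#' Fitted Poisson + negative-binomial mixture
#'
#' Holds the maximum-likelihood fit of the two-component model used to
#' separate stochastic-transcription noise (Poisson, mean \code{u}) from true
#' eRNA expression (negative binomial, size \code{r}, probability \code{p}) in
#' discretized log-TPM counts, together with the mixing weight \code{a} (the
#' probability that a measurement originates from noise), the derived count
#' threshold at the interface of the two components, and split diagnostics
#' (kurtosis/skewness per side, Poisson goodness-of-fit p-value on the noise
#' side).
#'
#' @slot a numeric, noise mixing weight in (0, 1).
#' @slot u numeric, Poisson mean (> 0).
#' @slot r numeric, negative-binomial size (> 0).
#' @slot p numeric, negative-binomial probability in (0, 1).
#' @slot loglik numeric, maximized log-likelihood.
#' @slot threshold integer, smallest count at/above the noise mode where the
#'   signal component dominates; \code{NA} when no crossing exists.
#' @slot converged logical, whether at least one optimizer start converged.
#' @slot diagnostics list with elements \code{kurtosis_noise},
#'   \code{skewness_noise}, \code{kurtosis_signal}, \code{skewness_signal},
#'   \code{poisson_gof_pvalue}.
#' @slot trace data.frame, one row per optimizer start (start index,
#'   converged, loglik).
#' @exportClass MixtureFit
setClass("MixtureFit",
  slots = c(
    a = "numeric", u = "numeric", r = "numeric", p = "numeric",
    loglik = "numeric", threshold = "integer", converged = "logical",
    diagnostics = "list", trace = "data.frame"
  ),
  prototype = prototype(
    a = NA_real_, u = NA_real_, r = NA_real_, p = NA_real_,
    loglik = NA_real_, threshold = NA_integer_, converged = FALSE,
    diagnostics = list(), trace = data.frame()
  )
)

setValidity("MixtureFit", function(object) {
  msg <- character()
  if (isTRUE(object@converged)) {
    if (!(object@a > 0 && object@a < 1)) msg <- c(msg, "'a' must lie in (0, 1)")
    if (!(object@u > 0)) msg <- c(msg, "'u' must be positive")
    if (!(object@r > 0)) msg <- c(msg, "'r' must be positive")
    if (!(object@p > 0 && object@p < 1)) msg <- c(msg, "'p' must lie in (0, 1)")
    if (!is.finite(object@loglik)) msg <- c(msg, "'loglik' must be finite when converged")
  }
  if (!is.na(object@threshold) && object@threshold < 0L)
    msg <- c(msg, "'threshold' must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Region-by-feature matrix for eRNA prediction
#'
#' A rectangular region x feature table restricted to one of the seven
#' feature combinations (methylation, H3K27ac, H3K9ac, flanking-gene
#' expression, GC percent). Missing signal is imputed as 0 and flagged in
#' \code{missingMask}; the values matrix itself never contains \code{NA}.
#'
#' @slot values numeric matrix, regions in rows, features in columns.
#' @slot combination integer in 1..7, the feature-combination index.
#' @slot missingMask logical matrix, same shape as \code{values}; TRUE where
#'   the value was imputed because no underlying signal was available.
#' @exportClass FeatureMatrix
setClass("FeatureMatrix",
  slots = c(values = "matrix", combination = "integer", missingMask = "matrix")
)

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (!is.numeric(v)) msg <- c(msg, "'values' must be numeric")
  if (anyNA(v) || any(!is.finite(v))) msg <- c(msg, "'values' must be finite (imputation policy applies before construction)")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    msg <- c(msg, "'values' must have unique column names")
  if (!(object@combination %in% 1:7)) msg <- c(msg, "'combination' must be in 1..7")
  if (!identical(dim(object@missingMask), dim(v)))
    msg <- c(msg, "'missingMask' must match the shape of 'values'")
  if (length(msg)) msg else TRUE
})

#' Trained eRNA classifier
#'
#' A fitted random-forest or XGBoost model with the hyperparameters it was
#' trained under, the feature-combination index, the exact feature ordering
#' prediction requires, and the tuning trace (one row per grid point with its
#' out-of-bag or cross-validated error).
#'
#' @slot algorithm character, \code{"random_forest"} or \code{"xgboost"}.
#' @slot hyperparameters named list (RF: mtry, ntree; XGB: nrounds,
#'   max_depth, eta).
#' @slot combination integer in 1..7.
#' @slot seed integer seed the fit was made under.
#' @slot featureNames character, ordered feature names.
#' @slot fit the fitted estimator (randomForest object, or raw bytes from
#'   \code{xgb.save.raw}).
#' @slot tuningTrace data.frame, per-grid-point error from tuning (empty when
#'   hyperparameters were supplied directly).
#' @exportClass ErnaModel
setClass("ErnaModel",
  slots = c(
    algorithm = "character", hyperparameters = "list",
    combination = "integer", seed = "integer",
    featureNames = "character", fit = "ANY", tuningTrace = "data.frame"
  )
)

setValidity("ErnaModel", function(object) {
  msg <- character()
  if (!object@algorithm %in% c("random_forest", "xgboost"))
    msg <- c(msg, "'algorithm' must be 'random_forest' or 'xgboost'")
  if (!(object@combination %in% 1:7)) msg <- c(msg, "'combination' must be in 1..7")
  if (!length(object@featureNames)) msg <- c(msg, "'featureNames' must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Classifier evaluation report
#'
#' Sensitivity, specificity, AUC, Matthews correlation coefficient and
#' F1-score at a fixed score cutoff, with the confusion counts behind them.
#' Metrics whose denominator is zero are reported as 0 and flagged in
#' \code{degenerate} rather than raised as errors, so that batch cross-cell
#' runs on skewed inputs never abort.
#'
#' @slot sn,sp,auc,mcc,f1 numeric metrics (sn, sp, f1, auc in [0,1]; mcc in
#'   [-1,1]).
#' @slot counts named integer vector with elements tp, fp, tn, fn.
#' @slot cutoff numeric, the score cutoff used for hard calls.
#' @slot degenerate character, names of metrics that hit a zero denominator.
#' @slot featureImportance named numeric, normalized per-feature importance
#'   (empty when not requested).
#' @exportClass ErnaEvalReport
setClass("ErnaEvalReport",
  slots = c(
    sn = "numeric", sp = "numeric", auc = "numeric", mcc = "numeric",
    f1 = "numeric", counts = "integer", cutoff = "numeric",
    degenerate = "character", featureImportance = "numeric"
  )
)

setValidity("ErnaEvalReport", function(object) {
  msg <- character()
  rng01 <- function(x) is.na(x) || (x >= 0 && x <= 1)
  if (!rng01(object@sn)) msg <- c(msg, "'sn' must lie in [0,1]")
  if (!rng01(object@sp)) msg <- c(msg, "'sp' must lie in [0,1]")
  if (!rng01(object@auc)) msg <- c(msg, "'auc' must lie in [0,1]")
  if (!rng01(object@f1)) msg <- c(msg, "'f1' must lie in [0,1]")
  if (!(is.na(object@mcc) || (object@mcc >= -1 && object@mcc <= 1)))
    msg <- c(msg, "'mcc' must lie in [-1,1]")
  if (!all(c("tp", "fp", "tn", "fn") %in% names(object@counts)))
    msg <- c(msg, "'counts' must carry tp, fp, tn, fn")
  if (length(msg)) msg else TRUE
})

#' Synthetic-cell generator configuration
#'
#' Parameters of the synthetic multi-omics cell: the planted count mixture,
#' the positive-class fraction, class-conditional methylation means and
#' histone enrichment folds, DNase open-chromatin probabilities per class,
#' flanking-gene layout and GC range. Defaults emulate the statistical
#' structure of labeled enhancer sets in lymphoblastoid cells: positives are
#' a 14\% minority, hypomethylated, H3K27ac-enriched at the region center and
#' mostly DNase-open.
#'
#' @slot n_regions integer, number of enhancer regions.
#' @slot region_length integer, bp per region.
#' @slot mixture named numeric (a, u, r, p): noise weight, Poisson mean, NB
#'   size, NB probability for the discretized log-TPM counts.
#' @slot class_balance numeric, fraction of regions whose latent class is
#'   positive (true eRNA source).
#' @slot methyl_means numeric length-2, mean CpG methylation for (positive,
#'   negative) regions.
#' @slot cpg_density numeric, expected CpG sites per bp.
#' @slot h3k27ac_enrichment,h3k9ac_enrichment numeric fold of the positive
#'   central coverage bump over background (1 = uninformative).
#' @slot dnase_open_prob numeric length-2, P(open | positive), P(open |
#'   negative).
#' @slot n_genes_per_side integer, genes placed on each side of the region
#'   block.
#' @slot gene_expression_boost numeric fold applied to genes nearest positive
#'   regions.
#' @slot gc_range numeric length-2, uniform GC-content range for simulated
#'   sequences.
#' @slot zero_tpm_prob numeric, probability a noise-class region yields TPM 0
#'   (masked by the log-transform cutoff).
#' @slot seed integer random seed.
#' @exportClass SimConfig
setClass("SimConfig",
  slots = c(
    n_regions = "integer", region_length = "integer", mixture = "numeric",
    class_balance = "numeric", methyl_means = "numeric", cpg_density = "numeric",
    h3k27ac_enrichment = "numeric", h3k9ac_enrichment = "numeric",
    dnase_open_prob = "numeric", n_genes_per_side = "integer",
    gene_expression_boost = "numeric", gc_range = "numeric",
    zero_tpm_prob = "numeric", seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  m <- object@mixture
  if (!all(c("a", "u", "r", "p") %in% names(m)))
    msg <- c(msg, "'mixture' must be named (a, u, r, p)")
  else {
    if (!(m[["a"]] > 0 && m[["a"]] < 1)) msg <- c(msg, "mixture 'a' in (0,1)")
    if (!(m[["u"]] > 0)) msg <- c(msg, "mixture 'u' > 0")
    if (!(m[["r"]] > 0)) msg <- c(msg, "mixture 'r' > 0")
    if (!(m[["p"]] > 0 && m[["p"]] < 1)) msg <- c(msg, "mixture 'p' in (0,1)")
  }
  if (object@n_regions < 1L) msg <- c(msg, "'n_regions' must be >= 1")
  if (object@region_length < 3L) msg <- c(msg, "'region_length' must be >= 3")
  if (!(object@class_balance > 0 && object@class_balance < 1))
    msg <- c(msg, "'class_balance' must lie in (0,1)")
  if (any(object@methyl_means < 0 | object@methyl_means > 1))
    msg <- c(msg, "'methyl_means' must lie in [0,1]")
  if (any(object@dnase_open_prob < 0 | object@dnase_open_prob > 1))
    msg <- c(msg, "'dnase_open_prob' must lie in [0,1]")
  if (object@h3k27ac_enrichment < 1 || object@h3k9ac_enrichment < 1)
    msg <- c(msg, "enrichment folds must be >= 1")
  if (object@zero_tpm_prob < 0 || object@zero_tpm_prob > 1)
    msg <- c(msg, "'zero_tpm_prob' must lie in [0,1]")
  if (length(msg)) msg else TRUE
})
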