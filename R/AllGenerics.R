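#' @rdname MixtureFit-class
#' @param object a \code{MixtureFit}, \code{FeatureMatrix}, \code{ErnaModel}
#'   or \code{ErnaEvalReport}.
#' @export
setGeneric("mixtureParams", function(object) standardGeneric("mixtureParams"))

#' @rdname MixtureFit-class
#' @export
setGeneric("noiseThreshold", function(object) standardGeneric("noiseThreshold"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("combinationIndex", function(object) standardGeneric("combinationIndex"))

#' @rdname ErnaModel-class
#' @export
setGeneric("modelAlgorithm", function(object) standardGeneric("modelAlgorithm"))

#' @rdname ErnaModel-class
#' @export
setGeneric("modelFeatureNames", function(object) standardGeneric("modelFeatureNames"))

#' @rdname ErnaModel-class
#' @export
setGeneric("modelHyperparameters", function(object) standardGeneric("modelHyperparameters"))

#' @rdname ErnaEvalReport-class
#' @export
setGeneric("evalMetrics", function(object) standardGeneric("evalMetrics"))

# ---- accessors ----

#' @rdname MixtureFit-class
#' @export
setMethod("mixtureParams", "MixtureFit", function(object) {
  c(a = object@a, u = object@u, r = object@r, p = object@p)
})

#' @rdname MixtureFit-class
#' @export
setMethod("noiseThreshold", "MixtureFit", function(object) object@threshold)

#' @rdname FeatureMatrix-class
#' @export
setMethod("featureValues", "FeatureMatrix", function(object) object@values)

#' @rdname FeatureMatrix-class
#' @export
setMethod("combinationIndex", "FeatureMatrix", function(object) object@combination)

#' @rdname ErnaModel-class
#' @export
setMethod("modelAlgorithm", "ErnaModel", function(object) object@algorithm)

#' @rdname ErnaModel-class
#' @export
setMethod("modelFeatureNames", "ErnaModel", function(object) object@featureNames)

#' @rdname ErnaModel-class
#' @export
setMethod("modelHyperparameters", "ErnaModel", function(object) object@hyperparameters)

#' @rdname ErnaEvalReport-class
#' @export
setMethod("evalMetrics", "ErnaEvalReport", function(object) {
  c(sn = object@sn, sp = object@sp, auc = object@auc,
    mcc = object@mcc, f1 = object@f1)
})

# ---- show methods ----

setMethod("show", "MixtureFit", function(object) {
  cat("MixtureFit (Poisson noise + negative-binomial signal)\n")
  cat(sprintf("  a = %.4f  u = %.4f  r = %.4f  p = %.4f\n",
              object@a, object@u, object@r, object@p))
  cat(sprintf("  loglik = %.3f  threshold = %s  converged = %s\n",
              object@loglik,
              ifelse(is.na(object@threshold), "NA", object@threshold),
              object@converged))
  d <- object@diagnostics
  if (length(d)) {
    cat(sprintf("  noise side : kurtosis %.3f, skewness %.3f\n",
                d$kurtosis_noise, d$skewness_noise))
    cat(sprintf("  signal side: kurtosis %.3f, skewness %.3f\n",
                d$kurtosis_signal, d$skewness_signal))
    cat(sprintf("  Poisson GOF p-value (noise side): %.4g\n",
                d$poisson_gof_pvalue))
  }
  invisible(NULL)
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d regions x %d features (combination %d)\n",
              nrow(object@values), ncol(object@values), object@combination))
  cat("  features:", paste(utils::head(colnames(object@values), 6), collapse = ", "),
      if (ncol(object@values) > 6) "..." else "", "\n")
  cat(sprintf("  imputed cells: %d\n", sum(object@missingMask)))
  invisible(NULL)
})

setMethod("show", "ErnaModel", function(object) {
  cat(sprintf("ErnaModel: %s (combination %d, seed %d)\n",
              object@algorithm, object@combination, object@seed))
  hp <- object@hyperparameters
  cat("  hyperparameters:",
      paste(sprintf("%s=%s", names(hp), unlist(hp)), collapse = ", "), "\n")
  cat(sprintf("  %d features\n", length(object@featureNames)))
  invisible(NULL)
})

setMethod("show", "ErnaEvalReport", function(object) {
  cat("ErnaEvalReport\n")
  cat(sprintf("  Sn = %.4f  Sp = %.4f  AUC = %.4f  MCC = %.4f  F1 = %.4f\n",
              object@sn, object@sp, object@auc, object@mcc, object@f1))
  cat(sprintf("  counts: tp=%d fp=%d tn=%d fn=%d (cutoff %.3g)\n",
              object@counts[["tp"]], object@counts[["fp"]],
              object@counts[["tn"]], object@counts[["fn"]], object@cutoff))
  if (length(object@degenerate))
    cat("  degenerate metrics (zero denominator):",
        paste(object@degenerate, collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d regions x %d bp, positive fraction %.3f, seed %d\n",
              object@n_regions, object@region_length, object@class_balance,
              object@seed))
  m <- object@mixture
  cat(sprintf("  mixture: a=%.3f u=%.3f r=%.3f p=%.3f\n",
              m[["a"]], m[["u"]], m[["r"]], m[["p"]]))
  invisible(NULL)
})
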