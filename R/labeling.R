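#' Test overlap of two interval sets with a minimum width
#'
#' @param a,b \code{GRanges}.
#' @param min_bp minimum overlap in bp (>= 1).
#' @return logical vector along \code{a}: TRUE where the interval overlaps
#'   any interval of \code{b} by at least \code{min_bp} bases on the same
#'   chromosome.
#' @export
intervalOverlaps <- function(a, b, min_bp = 1L) {
  if (min_bp < 1L) stop("'min_bp' must be >= 1")
  suppressWarnings(overlapsAny(a, b, minoverlap = min_bp))
}

#' Partition regions into positive, fuzzy and negative sets
#'
#' Combines the expression call with the chromatin state: a region called
#' \code{true_eRNA} that lies in open chromatin (overlaps a DNase peak) is a
#' positive region (PR); a region called \code{noise} or \code{masked} that
#' does not overlap any peak is a negative region (NR); every other region
#' is fuzzy (FR) — its evidence is contradictory, so it is excluded from
#' supervised fitting and later re-predicted. Masked regions (TPM at or
#' below the transform cutoff) are the lowest expression stratum and are
#' treated as below-threshold.
#'
#' @param regions a \code{GRanges} of enhancer regions.
#' @param calls character vector aligned with \code{regions}; each element
#'   one of \code{"noise"}, \code{"true_eRNA"}, \code{"masked"}.
#' @param dnase_peaks a \code{GRanges} of DNase open-chromatin peaks.
#' @param min_bp minimum overlap (bp) for a region to count as open.
#' @return the input \code{GRanges} with metadata columns \code{call} and
#'   \code{label} (factor PR/FR/NR); the three labels partition the input.
#' @export
assignLabels <- function(regions, calls, dnase_peaks, min_bp = 1L) {
  if (length(calls) != length(regions))
    stop("every region must carry a call")
  if (anyNA(calls) || !all(calls %in% c("noise", "true_eRNA", "masked")))
    stop("calls must be one of 'noise', 'true_eRNA', 'masked'")
  open <- intervalOverlaps(regions, dnase_peaks, min_bp = min_bp)
  expressed <- calls == "true_eRNA"
  label <- ifelse(expressed & open, "PR",
                  ifelse(!expressed & !open, "NR", "FR"))
  out <- regions
  mcols(out)$call <- calls
  mcols(out)$label <- factor(label, levels = c("PR", "FR", "NR"))
  out
}

#' Extract one label class from a labeled region set
#'
#' @param labeled a \code{GRanges} with a \code{label} column as produced by
#'   \code{\link{assignLabels}}.
#' @param which \code{"PR"}, \code{"FR"} or \code{"NR"}.
#' @return the subset \code{GRanges}.
#' @export
labeledSubset <- function(labeled, which = c("PR", "FR", "NR")) {
  which <- match.arg(which)
  labeled[mcols(labeled)$label == which]
}

#' Fraction of query intervals overlapping a reference set
#'
#' The overlap ratio used to validate called regions against orthogonal
#' marks (e.g. EP300 binding sites or an enhancer-state annotation): the
#' fraction of query intervals that overlap at least one reference interval
#' by >= 1 bp.
#'
#' @param query,reference non-empty \code{GRanges}.
#' @return a real in [0, 1].
#' @export
overlapRatio <- function(query, reference) {
  if (!length(query)) stop("empty query")
  if (!length(reference)) stop("empty reference")
  mean(suppressWarnings(overlapsAny(query, reference, minoverlap = 1L)))
}

#' Regions sharing a label across all cells
#'
#' @param labelings list of labeled \code{GRanges} (one per cell), all over
#'   the same region universe (same coordinates in the same order).
#' @param which \code{"PR"} or \code{"NR"}.
#' @return the subset of the universe carrying the requested label in every
#'   cell.
#' @export
sharedRegions <- function(labelings, which = c("PR", "NR")) {
  which <- match.arg(which)
  if (length(labelings) < 2L) stop("need >= 2 cells")
  ref <- granges(labelings[[1L]])
  for (l in labelings[-1L]) {
    if (length(l) != length(ref) || !all(granges(l) == ref))
      stop("labelings must share one region universe")
  }
  hit <- Reduce(`&`, lapply(labelings, function(l) mcols(l)$label == which))
  labelings[[1L]][hit]
}
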