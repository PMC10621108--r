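#' Whole-region and three-segment signal averages
#'
#' Each region is cut into three contiguous near-equal segments (cut points
#' at floor(L/3) and floor(2L/3); the remainder goes to the last segment)
#' and the track signal is averaged over the whole region and over each
#' segment, weighting every track interval by the number of bases it
#' contributes.
#'
#' @param regions a \code{GRanges} (every region at least \code{3} bp).
#' @param track a signal \code{GRanges} with a \code{score} column
#'   (disjoint intervals, as from \code{\link{readBedGraph}}).
#' @param mode \code{"coverage"}: bases not covered by the track count as
#'   signal 0 and the denominator is the full segment width (read-coverage
#'   semantics). \code{"sparse"}: only covered bases (e.g. CpG sites) enter
#'   the average and the denominator is the covered-base count; a segment
#'   with no covered base yields the imputation value 0 and a missing flag.
#' @return numeric matrix, one row per region, columns \code{whole},
#'   \code{seg1}, \code{seg2}, \code{seg3}; attribute \code{"missing"} is a
#'   logical matrix of the same shape flagging imputed cells.
#' @export
segmentSignal <- function(regions, track, mode = c("coverage", "sparse")) {
  mode <- match.arg(mode)
  n <- length(regions)
  if (any(width(regions) < 3L)) stop("every region must be >= 3 bp (3 segments)")
  segs <- regionSegments(regions)      # GRanges of length 4n, grouped by part
  sums <- rep(0, 4L * n)
  covered <- rep(0, 4L * n)
  if (length(track)) {
    hits <- findOverlaps(segs, track)
    if (length(hits)) {
      qi <- S4Vectors::queryHits(hits)
      ti <- S4Vectors::subjectHits(hits)
      ov <- width(pintersect(segs[qi], track[ti]))
      val <- mcols(track)$score[ti]
      sums <- sums + as.numeric(rowsumAt(ov * val, qi, 4L * n))
      covered <- covered + as.numeric(rowsumAt(ov, qi, 4L * n))
    }
  }
  denom <- if (mode == "coverage") as.numeric(width(segs)) else covered
  vals <- ifelse(denom > 0, sums / pmax(denom, 1), 0)
  miss <- denom == 0
  out <- matrix(vals, nrow = n, ncol = 4L,
                dimnames = list(names(regions), c("whole", "seg1", "seg2", "seg3")))
  attr(out, "missing") <- matrix(miss, nrow = n, ncol = 4L,
                                 dimnames = dimnames(out))
  out
}

# whole region plus its three segments, as one GRanges ordered so that
# element (part-1)*n + i is part 'part' of region i
regionSegments <- function(regions) {
  n <- length(regions)
  L <- width(regions)
  c1 <- floor(L / 3)
  c2 <- floor(2 * L / 3)
  s <- start(regions)
  chrom <- rep(seqnames(regions), 4L)
  starts <- c(s, s, s + c1, s + c2)
  ends <- c(end(regions), s + c1 - 1L, s + c2 - 1L, end(regions))
  GRanges(chrom, IRanges(start = starts, end = ends))
}

rowsumAt <- function(x, index, n) {
  out <- numeric(n)
  agg <- rowsum(x, index)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' DNA methylation features for enhancer regions
#'
#' Average methylated fraction over the whole region and over its three
#' segments, computed over CpG-bearing positions only (the track's
#' intervals), each weighted by the number of CpGs it represents. Segments
#' without any CpG are imputed as 0 and flagged.
#'
#' @param regions a \code{GRanges}.
#' @param methyl_track methylation \code{GRanges} with \code{score} in [0, 1].
#' @return matrix with columns \code{methyl_whole}, \code{methyl_seg1..3};
#'   attribute \code{"missing"} flags imputed cells.
#' @export
methylationFeatures <- function(regions, methyl_track) {
  sc <- mcols(methyl_track)$score
  if (length(methyl_track) && (is.null(sc) || any(sc < 0 | sc > 1)))
    stop("methylation values must lie in [0, 1]")
  out <- segmentSignal(regions, methyl_track, mode = "sparse")
  renameSignalCols(out, "methyl")
}

#' Histone modification coverage features for enhancer regions
#'
#' Average sequencing-read coverage over the whole region and its three
#' segments; bases without reads contribute coverage 0.
#'
#' @param regions a \code{GRanges}.
#' @param coverage_track coverage \code{GRanges} with non-negative
#'   \code{score}.
#' @param mark feature-name prefix, e.g. \code{"h3k27ac"}.
#' @return matrix with columns \code{<mark>_whole}, \code{<mark>_seg1..3}.
#' @export
histoneFeatures <- function(regions, coverage_track, mark = "h3k27ac") {
  sc <- mcols(coverage_track)$score
  if (length(coverage_track) && (is.null(sc) || any(sc < 0)))
    stop("coverage values must be non-negative")
  out <- segmentSignal(regions, coverage_track, mode = "coverage")
  renameSignalCols(out, mark)
}

renameSignalCols <- function(m, prefix) {
  cn <- paste0(prefix, "_", colnames(m))
  colnames(m) <- cn
  colnames(attr(m, "missing")) <- cn
  m
}

#' Flanking-gene expression features
#'
#' For each region, the \code{n_each} nearest genes by |TSS - region center|
#' on each side (upstream: TSS left of the center; downstream: TSS at or
#' right of the center, nearest first) contribute their TPM; slots without a
#' gene are padded with 0. The final feature is the maximum expression over
#' the selected genes.
#'
#' @param regions a \code{GRanges}.
#' @param genes width-1 TSS \code{GRanges} with \code{expression}
#'   (see \code{\link{readGeneTable}}).
#' @param n_each genes per side (default 10).
#' @return matrix with \code{2 * n_each + 1} columns: \code{gene_up1..},
#'   \code{gene_down1..}, \code{gene_max}.
#' @export
geneExpressionFeatures <- function(regions, genes, n_each = 10L) {
  n <- length(regions)
  cn <- c(paste0("gene_up", seq_len(n_each)),
          paste0("gene_down", seq_len(n_each)), "gene_max")
  out <- matrix(0, nrow = n, ncol = 2L * n_each + 1L,
                dimnames = list(names(regions), cn))
  if (!length(genes) || !n) return(out)
  gchrom <- as.character(seqnames(genes))
  gtss <- start(genes) - 1L          # 0-based TSS
  gexp <- mcols(genes)$expression
  rchrom <- as.character(seqnames(regions))
  center <- (start(regions) - 1L + end(regions)) / 2
  for (i in seq_len(n)) {
    on_chr <- which(gchrom == rchrom[i])
    if (!length(on_chr)) next
    d <- gtss[on_chr] - center[i]
    up <- on_chr[d < 0][order(abs(d[d < 0]))]
    down <- on_chr[d >= 0][order(d[d >= 0])]
    up <- utils::head(up, n_each)
    down <- utils::head(down, n_each)
    if (length(up)) out[i, seq_along(up)] <- gexp[up]
    if (length(down)) out[i, n_each + seq_along(down)] <- gexp[down]
    sel <- c(up, down)
    out[i, 2L * n_each + 1L] <- if (length(sel)) max(gexp[sel]) else 0
  }
  out
}

#' GC content of a nucleotide sequence
#'
#' (#G + #C) / (#A + #C + #G + #T); N bases are excluded from the
#' denominator. An all-N (or empty-after-exclusion) sequence yields the
#' imputation value 0 with a missing flag.
#'
#' @param sequences a \code{DNAStringSet} or character vector over
#'   \{A, C, G, T, N\}.
#' @return numeric vector in [0, 1]; attribute \code{"missing"} flags all-N
#'   sequences.
#' @export
gcPercent <- function(sequences) {
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
  if (any(Biostrings::width(sequences) == 0L)) stop("empty sequence")
  freq <- Biostrings::letterFrequency(sequences, letters = c("A", "C", "G", "T"))
  denom <- rowSums(freq)
  gc <- ifelse(denom > 0, (freq[, "G"] + freq[, "C"]) / pmax(denom, 1), 0)
  attr(gc, "missing") <- denom == 0
  gc
}

featureCombinations <- list(
  `1` = c("methyl", "gc"),
  `2` = c("methyl", "h3k27ac", "gc"),
  `3` = c("methyl", "h3k9ac", "gc"),
  `4` = c("methyl", "h3k27ac", "h3k9ac", "gc"),
  `5` = c("gene", "methyl", "h3k27ac", "gc"),
  `6` = c("gene", "methyl", "h3k9ac", "gc"),
  `7` = c("gene", "methyl", "h3k27ac", "h3k9ac", "gc")
)

#' Assemble the region-by-feature matrix for one feature combination
#'
#' The seven combinations index increasingly rich inputs: (1) methylation +
#' GC; (2) + H3K27ac; (3) methylation + H3K9ac + GC; (4) methylation + both
#' histone marks + GC; (5-7) are (2-4) plus flanking-gene expression.
#' Blocks appear in the order gene expression (21 columns, when included),
#' methylation (4), H3K27ac (4), H3K9ac (4), GC (1), with stable column
#' names, so matrices from different cells align exactly.
#'
#' @param regions a \code{GRanges} of enhancer regions.
#' @param methyl methylation track (\code{GRanges}, score in [0, 1]).
#' @param h3k27ac,h3k9ac coverage tracks; required only by combinations that
#'   use them.
#' @param genes TSS \code{GRanges} with \code{expression}; required by
#'   combinations 5-7.
#' @param sequences \code{DNAStringSet} (or character) of the region
#'   sequences, one per region, for the GC feature.
#' @param combination integer 1..7.
#' @return a \code{\linkS4class{FeatureMatrix}}.
#' @export
buildFeatureMatrix <- function(regions, methyl = NULL, h3k27ac = NULL,
                               h3k9ac = NULL, genes = NULL, sequences = NULL,
                               combination = 2L) {
  combination <- as.integer(combination)
  if (!combination %in% 1:7) stop("'combination' must be in 1..7")
  blocks <- featureCombinations[[as.character(combination)]]
  need <- function(x, what) {
    if (is.null(x)) stop(sprintf("combination %d requires %s", combination, what))
    x
  }
  vals <- list(); miss <- list()
  addBlock <- function(m) {
    mm <- attr(m, "missing")
    if (is.null(mm)) mm <- matrix(FALSE, nrow(m), ncol(m), dimnames = dimnames(m))
    attr(m, "missing") <- NULL
    vals[[length(vals) + 1L]] <<- m
    miss[[length(miss) + 1L]] <<- mm
  }
  for (b in blocks) {
    switch(b,
      gene = addBlock(geneExpressionFeatures(
        regions, need(genes, "a gene table"))),
      methyl = addBlock(methylationFeatures(
        regions, need(methyl, "a methylation track"))),
      h3k27ac = addBlock(histoneFeatures(
        regions, need(h3k27ac, "an H3K27ac track"), "h3k27ac")),
      h3k9ac = addBlock(histoneFeatures(
        regions, need(h3k9ac, "an H3K9ac track"), "h3k9ac")),
      gc = {
        g <- gcPercent(need(sequences, "region sequences"))
        if (length(g) != length(regions))
          stop("'sequences' must supply one sequence per region")
        m <- matrix(as.numeric(g), ncol = 1L,
                    dimnames = list(names(regions), "gc_percent"))
        mm <- matrix(attr(g, "missing"), ncol = 1L, dimnames = dimnames(m))
        vals[[length(vals) + 1L]] <- m
        miss[[length(miss) + 1L]] <- mm
      }
    )
  }
  values <- do.call(cbind, vals)
  missing <- do.call(cbind, miss)
  if (is.null(rownames(values)) && !is.null(names(regions)))
    rownames(values) <- names(regions)
  new("FeatureMatrix", values = values, combination = combination,
      missingMask = missing)
}
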