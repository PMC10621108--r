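#' Read a BED file of genomic intervals
#'
#' Parses 3-6 column BED (tab-separated, 0-based half-open on disk) into a
#' \code{GRanges} (1-based closed in memory; the shift happens exactly once,
#' here). Order is preserved. Malformed lines are reported with their line
#' numbers. Plain and gzip-compressed files are both accepted.
#'
#' @param path file path.
#' @param one_based set to TRUE when the file uses 1-based inclusive
#'   coordinates instead of the BED convention; starts are then shifted by -1
#'   exactly once on read.
#' @return a \code{GRanges}; columns 4 and 5, when present, become the
#'   \code{name} and \code{score} metadata columns.
#' @export
readBed <- function(path, one_based = FALSE) {
  lines <- readBedLines(path, min_fields = 3L)
  if (nrow(lines$fields) == 0L)
    return(GRanges())
  f <- lines$fields
  start0 <- suppressWarnings(as.numeric(f[, 2L]))
  end0 <- suppressWarnings(as.numeric(f[, 3L]))
  bad <- which(is.na(start0) | is.na(end0) | start0 != floor(start0) |
                 end0 != floor(end0))
  if (length(bad))
    stop("non-integer coordinates at line(s): ",
         paste(lines$lineno[bad], collapse = ", "))
  if (one_based) start0 <- start0 - 1
  bad <- which(end0 <= start0 | start0 < 0)
  if (length(bad))
    stop("invalid interval (end <= start, or negative start) at line(s): ",
         paste(lines$lineno[bad], collapse = ", "))
  gr <- GRanges(f[, 1L], IRanges(start = start0 + 1, end = end0))
  if (ncol(f) >= 4L) mcols(gr)$name <- f[, 4L]
  if (ncol(f) >= 5L) {
    sc <- suppressWarnings(as.numeric(f[, 5L]))
    mcols(gr)$score <- sc
  }
  gr
}

#' Read a bedGraph signal track
#'
#' Parses 4-column chrom/start/end/value lines into a \code{GRanges} with a
#' \code{score} metadata column. Intervals are sorted per chromosome;
#' overlapping intervals on one chromosome are rejected because a piecewise
#' signal must be single-valued at every base.
#'
#' @param path file path (plain or gzipped).
#' @param mode \code{"coverage"} accepts any non-negative value (read
#'   coverage); \code{"methylation"} additionally requires values in [0, 1]
#'   (per-CpG methylated fraction).
#' @return a \code{GRanges} sorted by (chrom, start) with numeric
#'   \code{score}; \code{metadata(x)$mode} records the track semantics.
#' @export
readBedGraph <- function(path, mode = c("coverage", "methylation")) {
  mode <- match.arg(mode)
  lines <- readBedLines(path, min_fields = 4L)
  if (nrow(lines$fields) == 0L) {
    gr <- GRanges()
    metadata(gr)$mode <- mode
    return(gr)
  }
  f <- lines$fields
  start0 <- suppressWarnings(as.numeric(f[, 2L]))
  end0 <- suppressWarnings(as.numeric(f[, 3L]))
  val <- suppressWarnings(as.numeric(f[, 4L]))
  bad <- which(is.na(val))
  if (length(bad))
    stop("non-numeric value column at line(s): ",
         paste(lines$lineno[bad], collapse = ", "))
  bad <- which(is.na(start0) | is.na(end0) | end0 <= start0 | start0 < 0)
  if (length(bad))
    stop("invalid interval at line(s): ",
         paste(lines$lineno[bad], collapse = ", "))
  if (any(!is.finite(val))) stop("signal values must be finite")
  if (mode == "methylation" && any(val < 0 | val > 1))
    stop("methylation values must lie in [0, 1]")
  if (mode == "coverage" && any(val < 0))
    stop("coverage values must be non-negative")
  gr <- GRanges(f[, 1L], IRanges(start = start0 + 1, end = end0), score = val)
  gr <- GenomicRanges::sort(gr)
  if (!isDisjoint(gr))
    stop("overlapping intervals on one chromosome; a signal track must be disjoint")
  metadata(gr)$mode <- mode
  gr
}

#' Read a CAGE TPM matrix
#'
#' Reads a tab-separated table whose header row names the samples and whose
#' first column is a region identifier encoding the coordinates, either
#' \code{chrom:start-end} (the FANTOM dialect) or \code{chrom_start_end}.
#' Coordinates in the identifier follow the BED convention (0-based
#' half-open).
#'
#' @param path file path (plain or gzipped).
#' @return a \code{RangedSummarizedExperiment} with assay \code{"tpm"}
#'   (regions x samples, non-negative) and row ranges recovered from the
#'   identifiers.
#' @export
readCageMatrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expected a region-id column plus >= 1 sample column")
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate region ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  tpm <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(tpm) <- "double"
  if (anyNA(tpm)) stop("non-numeric TPM entries")
  if (any(tpm < 0)) stop("negative TPM entries")
  if (anyDuplicated(colnames(tpm))) stop("duplicate sample names")
  rowRanges <- parseRegionIds(ids)
  names(rowRanges) <- ids
  rownames(tpm) <- ids
  SummarizedExperiment::SummarizedExperiment(
    assays = list(tpm = tpm), rowRanges = rowRanges
  )
}

# "chrom:start-end" (FANTOM) with "chrom_start_end" fallback; BED coords.
parseRegionIds <- function(ids) {
  m <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
  ok <- lengths(m) == 4L
  if (!all(ok)) {
    m2 <- regmatches(ids[!ok], regexec("^(.+)_([0-9]+)_([0-9]+)$", ids[!ok]))
    if (any(lengths(m2) != 4L))
      stop("unparseable region id(s): ",
           paste(utils::head(ids[!ok][lengths(m2) != 4L], 5), collapse = ", "))
    m[!ok] <- m2
  }
  chrom <- vapply(m, `[`, character(1), 2L)
  s0 <- as.numeric(vapply(m, `[`, character(1), 3L))
  e0 <- as.numeric(vapply(m, `[`, character(1), 4L))
  if (any(e0 <= s0)) stop("region id with end <= start")
  GRanges(chrom, IRanges(start = s0 + 1, end = e0))
}

#' Read a gene annotation + expression table
#'
#' TSV with columns \code{gene_id}, \code{chrom}, \code{tss} (0-based
#' position), \code{strand} (+/-), \code{tpm}.
#'
#' @param path file path (plain or gzipped).
#' @return a width-1 \code{GRanges} at each TSS with metadata columns
#'   \code{gene_id} and \code{expression}.
#' @export
readGeneTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) return(GRanges(gene_id = character(), expression = numeric()))
  need <- c("gene_id", "chrom", "tss", "strand", "tpm")
  if (!all(need %in% names(tab)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  if (!all(tab$strand %in% c("+", "-")))
    stop("unknown strand symbol(s): ",
         paste(unique(setdiff(tab$strand, c("+", "-"))), collapse = ", "))
  if (any(tab$tpm < 0)) stop("negative gene tpm")
  if (any(tab$tss < 0)) stop("negative tss")
  GRanges(tab$chrom, IRanges(start = tab$tss + 1, width = 1),
          strand = tab$strand, gene_id = tab$gene_id, expression = tab$tpm)
}

#' Write genomic intervals as BED
#'
#' Inverse of \code{\link{readBed}}: emits 0-based half-open coordinates, and
#' the \code{name}/\code{score} metadata columns when present (a \code{label}
#' or \code{call} column is written into the name field by the labeling CLI).
#'
#' @param gr a \code{GRanges}.
#' @param path output path.
#' @param name optional character vector overriding the name field.
#' @export
writeBed <- function(gr, path, name = NULL) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr))
  if (is.null(name) && !is.null(mcols(gr)$name)) name <- mcols(gr)$name
  if (!is.null(name)) {
    df$name <- name
    if (!is.null(mcols(gr)$score)) df$score <- mcols(gr)$score
  }
  writeTsv(df, path, col.names = FALSE)
}

#' Write a signal track as bedGraph
#' @param gr a \code{GRanges} with a numeric \code{score} column.
#' @param path output path.
#' @export
writeBedGraph <- function(gr, path) {
  stopifnot(!is.null(mcols(gr)$score))
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   value = mcols(gr)$score)
  writeTsv(df, path, col.names = FALSE)
}

#' Write a CAGE TPM matrix
#' @param se a \code{RangedSummarizedExperiment} with assay \code{"tpm"}.
#' @param path output path.
#' @export
writeCageMatrix <- function(se, path) {
  tpm <- SummarizedExperiment::assay(se, "tpm")
  ids <- rownames(tpm)
  if (is.null(ids)) {
    rr <- SummarizedExperiment::rowRanges(se)
    ids <- sprintf("%s:%d-%d", as.character(seqnames(rr)), start(rr) - 1L, end(rr))
  }
  df <- data.frame(region = ids, tpm, check.names = FALSE)
  writeTsv(df, path, col.names = TRUE)
}

#' Write a gene table
#' @param genes a width-1 \code{GRanges} as returned by
#'   \code{\link{readGeneTable}}.
#' @param path output path.
#' @export
writeGeneTable <- function(genes, path) {
  df <- data.frame(gene_id = mcols(genes)$gene_id,
                   chrom = as.character(seqnames(genes)),
                   tss = start(genes) - 1L,
                   strand = as.character(BiocGenerics::strand(genes)),
                   tpm = mcols(genes)$expression)
  writeTsv(df, path, col.names = TRUE)
}

# ---- internals ----

readBedLines <- function(path, min_fields) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path)
  keep <- !grepl("^(#|track|browser)", raw) & nzchar(trimws(raw))
  lineno <- which(keep)
  raw <- raw[keep]
  if (!length(raw))
    return(list(fields = matrix(character(), 0, min_fields), lineno = integer()))
  parts <- strsplit(raw, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < min_fields))
    stop(sprintf("expected >= %d tab-separated fields at line(s): %s",
                 min_fields,
                 paste(lineno[nf < min_fields], collapse = ", ")))
  width <- min(max(nf), 6L)
  fields <- t(vapply(parts, function(x) {
    length(x) <- width
    x
  }, character(width)))
  list(fields = fields, lineno = lineno)
}

writeTsv <- function(df, path, col.names) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = col.names)
}

#' @importFrom IRanges isDisjoint
#' @importFrom BiocGenerics strand
NULL
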