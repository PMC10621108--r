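#' Construct a synthetic-cell configuration
#'
#' Defaults plant a clearly separable two-component count mixture (Poisson
#' mean 2 noise vs negative-binomial mean 12 signal), a 14\% positive-class
#' minority, hypomethylated positives (mean 0.15) vs hypermethylated
#' negatives (mean 0.75, elevated toward the region center), an 8-fold
#' central H3K27ac bump over background for positives (4-fold for H3K9ac),
#' and mostly-open chromatin for positives (P = 0.9) vs mostly-closed for
#' negatives (P = 0.1).
#'
#' @param n_regions number of enhancer regions (default 2000).
#' @param region_length bp per region (default 300).
#' @param mixture named numeric (a, u, r, p).
#' @param class_balance positive fraction (default 0.14).
#' @param methyl_means c(positive, negative) mean CpG methylation.
#' @param cpg_density CpG sites per bp (default 1/50).
#' @param h3k27ac_enrichment,h3k9ac_enrichment central-bump fold over
#'   background for positive regions (1 = uninformative).
#' @param dnase_open_prob c(P(open|positive), P(open|negative)).
#' @param n_genes_per_side genes placed per inter-region boundary (default 1).
#' @param gene_expression_boost expression fold for genes flanking positive
#'   regions.
#' @param gc_range uniform GC-content range of simulated sequences.
#' @param zero_tpm_prob probability a noise region reports TPM 0 (masked).
#' @param seed integer seed.
#' @return a \code{\linkS4class{SimConfig}}.
#' @export
simConfig <- function(n_regions = 2000L, region_length = 300L,
                      mixture = c(a = 0.6, u = 2, r = 4, p = 0.25),
                      class_balance = 0.14,
                      methyl_means = c(0.15, 0.75), cpg_density = 1 / 50,
                      h3k27ac_enrichment = 8, h3k9ac_enrichment = 4,
                      dnase_open_prob = c(0.9, 0.1),
                      n_genes_per_side = 1L, gene_expression_boost = 3,
                      gc_range = c(0.35, 0.65), zero_tpm_prob = 0.05,
                      seed = 1L) {
  new("SimConfig", n_regions = as.integer(n_regions),
      region_length = as.integer(region_length), mixture = mixture,
      class_balance = class_balance, methyl_means = methyl_means,
      cpg_density = cpg_density, h3k27ac_enrichment = h3k27ac_enrichment,
      h3k9ac_enrichment = h3k9ac_enrichment,
      dnase_open_prob = dnase_open_prob,
      n_genes_per_side = as.integer(n_genes_per_side),
      gene_expression_boost = gene_expression_boost, gc_range = gc_range,
      zero_tpm_prob = zero_tpm_prob, seed = as.integer(seed))
}

#' Draw counts from the planted noise/signal mixture
#'
#' Each draw comes from Poisson(u) with probability \code{a} (noise) and
#' from NB(r, p) otherwise (signal); the component of every draw is
#' recorded.
#'
#' @param mixture named numeric (a, u, r, p).
#' @param n number of draws.
#' @param seed integer seed.
#' @return list with integer \code{counts} and character \code{component}
#'   ("noise"/"signal").
#' @export
simulateMixtureCounts <- function(mixture, n, seed = 1L) {
  a <- mixture[["a"]]; u <- mixture[["u"]]
  r <- mixture[["r"]]; p <- mixture[["p"]]
  if (!(a >= 0 && a <= 1) || !(u > 0) || !(r > 0) || !(p > 0 && p < 1))
    stop("invalid mixture parameters")
  if (n < 1) stop("n must be >= 1")
  withSeed(seed, {
    noise <- runif(n) < a
    counts <- integer(n)
    counts[noise] <- rpois(sum(noise), u)
    counts[!noise] <- rnbinom(sum(!noise), size = r, prob = p)
  })
  list(counts = counts, component = ifelse(noise, "noise", "signal"))
}

#' Simulate one synthetic cell
#'
#' Generates a complete single-cell dataset over \code{n_regions} enhancer
#' regions on one chromosome: CAGE TPM back-transformed from planted
#' mixture counts (positive regions draw from the negative-binomial signal
#' component, negative regions from the Poisson noise component), per-CpG
#' beta-distributed methylation (low in positives; elevated toward the
#' region center in negatives), binned histone coverage with a central
#' triangular bump in positives, DNase peaks drawn per class, boundary
#' genes whose expression is boosted next to positive regions, and random
#' sequences with uniform GC. All latent truth is recorded.
#'
#' @param config a \code{\linkS4class{SimConfig}}.
#' @param cell_name sample name used in the CAGE matrix (default "cell1").
#' @param positive_idx optional integer vector forcing which regions are
#'   latent positives (used by \code{\link{simulateMultiCell}}).
#' @return a list with elements \code{regions}, \code{cage},
#'   \code{methyl}, \code{h3k27ac}, \code{h3k9ac}, \code{dnase},
#'   \code{genes}, \code{sequences}, \code{truth}, \code{config}.
#' @export
simulateCell <- function(config, cell_name = "cell1", positive_idx = NULL) {
  validObject(config)
  n <- config@n_regions
  L <- config@region_length
  gap <- 700L
  m <- config@mixture
  withSeed(config@seed, {
    start0 <- (seq_len(n) - 1L) * (L + gap)
    ids <- sprintf("chr1:%d-%d", start0, start0 + L)   # FANTOM id dialect
    regions <- GRanges("chr1", IRanges(start = start0 + 1L, width = L))
    names(regions) <- ids
    mcols(regions)$name <- ids

    if (is.null(positive_idx)) {
      positive <- runif(n) < config@class_balance
    } else {
      positive <- seq_len(n) %in% positive_idx
    }
    component <- ifelse(positive, "signal", "noise")

    counts <- integer(n)
    counts[positive] <- rnbinom(sum(positive), size = m[["r"]], prob = m[["p"]])
    counts[!positive] <- rpois(sum(!positive), m[["u"]])
    tpm <- exp((counts - 4) / 10)        # inverse of the log-TPM transform
    drop0 <- !positive & runif(n) < config@zero_tpm_prob
    tpm[drop0] <- 0

    open <- runif(n) < ifelse(positive, config@dnase_open_prob[1L],
                              config@dnase_open_prob[2L])
    dnase <- regions[open]
    dnase <- GRanges(seqnames(dnase),
                     IRanges(start = start(dnase) + floor(L / 4),
                             end = end(dnase) - floor(L / 4)))

    methyl <- simulateMethylTrack(regions, positive, config)
    h3k27ac <- simulateHistoneTrack(regions, positive,
                                    config@h3k27ac_enrichment)
    h3k9ac <- simulateHistoneTrack(regions, positive,
                                   config@h3k9ac_enrichment)
    genes <- simulateGenes(regions, positive, config)
    sequences <- simulateSequences(regions, config)

    tpm_mat <- matrix(tpm, ncol = 1, dimnames = list(ids, cell_name))
    cage <- SummarizedExperiment::SummarizedExperiment(
      assays = list(tpm = tpm_mat), rowRanges = regions)

    truth <- data.frame(
      region = ids,
      class = ifelse(positive, "positive", "negative"),
      component = component, count = counts, tpm = tpm,
      dnase_open = open, stringsAsFactors = FALSE
    )
  })
  list(regions = regions, cage = cage, methyl = methyl, h3k27ac = h3k27ac,
       h3k9ac = h3k9ac, dnase = dnase, genes = genes, sequences = sequences,
       truth = truth, config = config)
}

# per-CpG methylation: sites on a regular grid inside each region, values
# Beta(mean * 10, (1 - mean) * 10); negative-region means rise linearly
# toward the region center
simulateMethylTrack <- function(regions, positive, config) {
  step <- max(1L, round(1 / config@cpg_density))
  L <- config@region_length
  offs <- seq(0L, L - 1L, by = step)
  n <- length(regions)
  pos_site <- rep(start(regions), each = length(offs)) +
    rep(offs, times = n)
  site_positive <- rep(positive, each = length(offs))
  tri <- 1 - abs(rep(offs, times = n) - (L - 1) / 2) / ((L - 1) / 2)
  mu <- ifelse(site_positive, config@methyl_means[1L],
               pmin(0.98, config@methyl_means[2L] +
                      0.15 * tri * (config@methyl_means[2L] !=
                                      config@methyl_means[1L])))
  mu <- pmin(pmax(mu, 0.02), 0.98)
  conc <- 10
  val <- rbeta(length(mu), mu * conc, (1 - mu) * conc)
  GRanges(rep(as.character(seqnames(regions)), each = length(offs)),
          IRanges(start = pos_site, width = 1L), score = val)
}

# binned read coverage: Poisson background (mean 2) everywhere, plus a
# triangular central bump of (fold - 1) * background in positive regions
simulateHistoneTrack <- function(regions, positive, fold, bin = 50L,
                                 lambda_bg = 2) {
  L <- unique(width(regions))[1L]
  nb <- max(1L, floor(L / bin))
  n <- length(regions)
  bin_start <- rep(start(regions), each = nb) +
    rep((seq_len(nb) - 1L) * bin, times = n)
  bin_end <- pmin(bin_start + bin - 1L, rep(end(regions), each = nb))
  mid <- (seq_len(nb) - 0.5) / nb
  tri <- 1 - abs(mid - 0.5) * 2
  bump <- rep(positive, each = nb) * (fold - 1) * lambda_bg * rep(tri, times = n)
  lam <- lambda_bg + bump
  val <- rpois(length(lam), lam)
  GRanges(rep(as.character(seqnames(regions)), each = nb),
          IRanges(start = bin_start, end = bin_end), score = as.numeric(val))
}

# genes at inter-region boundaries; log-normal base expression, boosted for
# genes adjacent to a positive region
simulateGenes <- function(regions, positive, config) {
  n <- length(regions)
  per_side <- max(1L, config@n_genes_per_side)
  bounds <- c(start(regions)[1L] - 350L,
              (end(regions)[-n] + start(regions)[-1L]) %/% 2L,
              end(regions)[n] + 350L)
  tss <- unlist(lapply(seq_len(per_side), function(j) bounds + (j - 1L) * 17L))
  tss <- pmax(tss, 1L)
  base <- stats::rlnorm(length(tss), meanlog = 1, sdlog = 0.6)
  near_pos <- logical(n + 1L)
  near_pos[seq_len(n)] <- near_pos[seq_len(n)] | positive
  near_pos[seq_len(n) + 1L] <- near_pos[seq_len(n) + 1L] | positive
  boost <- ifelse(rep(near_pos, times = per_side),
                  config@gene_expression_boost, 1)
  GRanges("chr1", IRanges(start = tss, width = 1L),
          strand = rep_len(c("+", "-"), length(tss)),
          gene_id = sprintf("G%05d", seq_along(tss)),
          expression = base * boost)
}

simulateSequences <- function(regions, config) {
  n <- length(regions)
  L <- config@region_length
  gc <- runif(n, config@gc_range[1L], config@gc_range[2L])
  # one uniform draw per base, mapped through each region's GC cut points
  u <- runif(n * L)
  g <- rep(gc, each = L)
  letter <- ifelse(u < (1 - g) / 2, "A",
            ifelse(u < (1 - g) / 2 + g / 2, "C",
            ifelse(u < (1 - g) / 2 + g, "G", "T")))
  seqs <- vapply(seq_len(n), function(i)
    paste(letter[((i - 1L) * L + 1L):(i * L)], collapse = ""), character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names(regions)
  out
}

#' Simulate several cells over one region universe
#'
#' All cells share the same region coordinates. A controllable fraction of
#' each cell's latent positives is shared by every cell; the remaining
#' positives are disjoint across cells. Negatives are consequently mostly
#' shared, mirroring real multi-cell labelings where negatives overlap
#' heavily and positives barely.
#'
#' @param configs list of \code{\linkS4class{SimConfig}} (>= 2), equal
#'   \code{n_regions} and \code{region_length}.
#' @param shared_positive_fraction fraction of each cell's positives present
#'   in every cell (0..1).
#' @param seed integer seed for the shared/exclusive assignment.
#' @return list of synthetic cells (see \code{\link{simulateCell}}), named
#'   cell1, cell2, ...
#' @export
simulateMultiCell <- function(configs, shared_positive_fraction = 0.05,
                              seed = 1L) {
  if (length(configs) < 2L) stop("need >= 2 cells")
  n <- configs[[1L]]@n_regions
  if (!all(vapply(configs, function(cfg) cfg@n_regions == n, logical(1))))
    stop("all cells must share one region universe (equal n_regions)")
  f <- shared_positive_fraction
  if (f < 0 || f > 1) stop("'shared_positive_fraction' must lie in [0, 1]")
  n_pos <- vapply(configs, function(cfg) round(cfg@class_balance * n),
                  numeric(1))
  n_shared <- round(f * min(n_pos))
  if (any(n_shared > n_pos))
    stop("shared fraction exceeds the smallest cell's positive fraction")
  n_excl <- n_pos - n_shared
  if (n_shared + sum(n_excl) > n)
    stop("universe too small for disjoint exclusive positive sets")
  withSeed(seed, {
    shared <- sample(n, n_shared)
    rest <- sample(setdiff(seq_len(n), shared))
    excl <- vector("list", length(configs))
    at <- 0L
    for (i in seq_along(configs)) {
      excl[[i]] <- rest[seq_len(n_excl[i]) + at]
      at <- at + n_excl[i]
    }
  })
  cells <- lapply(seq_along(configs), function(i) {
    simulateCell(configs[[i]], cell_name = paste0("cell", i),
                 positive_idx = sort(c(shared, excl[[i]])))
  })
  names(cells) <- paste0("cell", seq_along(configs))
  cells
}

#' Write a synthetic cell to disk
#'
#' Emits cage.tsv, regions.bed, methyl.bedgraph, h3k27ac.bedgraph,
#' h3k9ac.bedgraph, dnase.bed, genes.tsv, genome.fa and truth.tsv; every
#' file reads back losslessly through the package's readers.
#'
#' @param cell a list from \code{\link{simulateCell}}.
#' @param outdir output directory (created if absent).
#' @return invisibly, the named vector of written paths.
#' @export
writeSyntheticCell <- function(cell, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    cage = file.path(outdir, "cage.tsv"),
    regions = file.path(outdir, "regions.bed"),
    methyl = file.path(outdir, "methyl.bedgraph"),
    h3k27ac = file.path(outdir, "h3k27ac.bedgraph"),
    h3k9ac = file.path(outdir, "h3k9ac.bedgraph"),
    dnase = file.path(outdir, "dnase.bed"),
    genes = file.path(outdir, "genes.tsv"),
    genome = file.path(outdir, "genome.fa"),
    truth = file.path(outdir, "truth.tsv")
  )
  writeCageMatrix(cell$cage, paths[["cage"]])
  writeBed(cell$regions, paths[["regions"]])
  writeBedGraph(cell$methyl, paths[["methyl"]])
  writeBedGraph(cell$h3k27ac, paths[["h3k27ac"]])
  writeBedGraph(cell$h3k9ac, paths[["h3k9ac"]])
  writeBed(cell$dnase, paths[["dnase"]])
  writeGeneTable(cell$genes, paths[["genes"]])
  Biostrings::writeXStringSet(cell$sequences, paths[["genome"]])
  writeTsv(cell$truth, paths[["truth"]], col.names = TRUE)
  invisible(paths)
}
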