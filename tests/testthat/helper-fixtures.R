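suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
})

# in-code fixtures ------------------------------------------------------

toyRegions <- function(starts0, widths, chrom = "chr1") {
  GRanges(chrom, IRanges(start = starts0 + 1L, width = widths))
}

toyTrack <- function(starts0, ends0, values, chrom = "chr1") {
  GRanges(chrom, IRanges(start = starts0 + 1L, end = ends0), score = values)
}

writeLinesTmp <- function(lines) {
  path <- tempfile(fileext = ".txt")
  writeLines(lines, path)
  path
}

# independent oracles ---------------------------------------------------

# mixture log-likelihood by literal per-observation summation of the two
# closed-form pmfs (factorials through lgamma), no dpois/dnbinom
oracleMixtureLoglik <- function(a, u, r, p, counts) {
  total <- 0
  for (k in counts) {
    pois <- exp(k * log(u) - u - lgamma(k + 1))
    nb <- exp(lgamma(k + r) - lgamma(k + 1) - lgamma(r) +
                r * log(p) + k * log(1 - p))
    total <- total + log(a * pois + (1 - a) * nb)
  }
  total
}

# smallest k >= floor(u) where the weighted signal pmf beats the weighted
# noise pmf, by literal scan
oracleThreshold <- function(a, u, r, p) {
  # scan cap: 0.9999 quantile of the mixture, by literal cdf accumulation
  q <- 0
  acc <- a * dpois(0, u) + (1 - a) * dnbinom(0, size = r, prob = p)
  while (acc < 0.9999) {
    q <- q + 1
    acc <- acc + a * dpois(q, u) + (1 - a) * dnbinom(q, size = r, prob = p)
  }
  if (floor(u) > q) return(NA_integer_)
  for (k in floor(u):q) {
    if ((1 - a) * dnbinom(k, size = r, prob = p) > a * dpois(k, u))
      return(k)
  }
  NA_integer_
}

# per-base averaging over a region given a track, naive loop
oracleSegmentMeans <- function(region_start0, region_end0, track, mode) {
  bases <- region_start0:(region_end0 - 1L)
  val <- rep(NA_real_, length(bases))
  for (j in seq_along(track$start0)) {
    sel <- bases >= track$start0[j] & bases < track$end0[j]
    val[sel] <- track$value[j]
  }
  L <- length(bases)
  c1 <- floor(L / 3); c2 <- floor(2 * L / 3)
  parts <- list(seq_len(L), 1:c1, (c1 + 1):c2, (c2 + 1):L)
  vapply(parts, function(idx) {
    v <- val[idx]
    if (mode == "coverage") {
      v[is.na(v)] <- 0
      mean(v)
    } else {
      v <- v[!is.na(v)]
      if (!length(v)) 0 else mean(v)
    }
  }, numeric(1))
}

# O(n^2) pairwise AUC
oracleAuc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (sp in pos) for (sn in neg)
    tot <- tot + (sp > sn) + 0.5 * (sp == sn)
  tot / (length(pos) * length(neg))
}

# MCC as the Pearson correlation of the reconstructed binary vectors
oracleMccAsCor <- function(tp, fp, tn, fn) {
  truth <- c(rep(1, tp), rep(0, fp), rep(0, tn), rep(1, fn))
  pred <- c(rep(1, tp), rep(1, fp), rep(0, tn), rep(0, fn))
  suppressWarnings(cor(truth, pred))
}

# brute-force nearest-gene selection
oracleGeneFeatures <- function(center0, gene_tss0, gene_exp, n_each = 10L) {
  d <- gene_tss0 - center0
  up <- order(abs(d[d < 0]))
  down <- order(d[d >= 0])
  up_exp <- gene_exp[d < 0][up][seq_len(min(n_each, sum(d < 0)))]
  down_exp <- gene_exp[d >= 0][down][seq_len(min(n_each, sum(d >= 0)))]
  out <- numeric(2L * n_each + 1L)
  if (length(up_exp)) out[seq_along(up_exp)] <- up_exp
  if (length(down_exp)) out[n_each + seq_along(down_exp)] <- down_exp
  sel <- c(up_exp, down_exp)
  out[2L * n_each + 1L] <- if (length(sel)) max(sel) else 0
  out
}
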