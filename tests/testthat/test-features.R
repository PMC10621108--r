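test_that("segment averages match forced arithmetic on simple tracks", {
  region <- toyRegions(0, 300)
  uniform <- toyTrack(0, 300, 0.8)
  m <- segmentSignal(region, uniform, mode = "coverage")
  expect_equal(unname(m[1, ]), c(0.8, 0.8, 0.8, 0.8))
  # value 1 on first third, 0 elsewhere
  split_track <- toyTrack(c(0, 100), c(100, 300), c(1, 0))
  m <- segmentSignal(region, split_track, mode = "coverage")
  expect_equal(unname(m[1, ]), c(1 / 3, 1, 0, 0))
  # empty track in coverage mode: all zeros
  m <- segmentSignal(region, GRanges(), mode = "coverage")
  expect_equal(unname(m[1, ]), c(0, 0, 0, 0))
  expect_error(segmentSignal(toyRegions(0, 2), uniform), ">= 3 bp")
})

test_that("segment averages equal the per-base oracle on random tracks", {
  set.seed(11)
  for (i in 1:100) {
    L <- sample(9:400, 1)
    s0 <- sample(0:1000, 1)
    region <- toyRegions(s0, L)
    # random disjoint intervals across [s0 - 50, s0 + L + 50]
    cuts <- sort(sample(max(0, s0 - 50):(s0 + L + 50), sample(2:12, 1)))
    starts <- cuts[-length(cuts)]; ends <- cuts[-1]
    keep <- sample(c(TRUE, FALSE), length(starts), replace = TRUE)
    if (!any(keep)) keep[1] <- TRUE
    vals <- round(runif(sum(keep), 0, 10), 3)
    track <- toyTrack(starts[keep], ends[keep], vals)
    mode <- sample(c("coverage", "sparse"), 1)
    got <- segmentSignal(region, track, mode = mode)
    want <- oracleSegmentMeans(s0, s0 + L,
                               list(start0 = starts[keep], end0 = ends[keep],
                                    value = vals), mode)
    expect_equal(unname(got[1, ]), want, tolerance = 1e-10)
  }
})

test_that("whole mean equals the mean of segment means when length divides by 3", {
  set.seed(2)
  for (i in 1:20) {
    L <- 3 * sample(5:100, 1)
    region <- toyRegions(0, L)
    cuts <- sort(sample(0:L, 6))
    track <- toyTrack(cuts[c(1, 3, 5)], cuts[c(2, 4, 6)] + 1, runif(3, 0, 5))
    m <- segmentSignal(region, track, mode = "coverage")
    expect_equal(unname(m[1, "whole"]),
                 mean(m[1, c("seg1", "seg2", "seg3")]), tolerance = 1e-10)
  }
})

test_that("feature matrix is invariant to track interval storage order", {
  region <- toyRegions(c(0, 500), c(300, 300))
  track <- toyTrack(c(0, 120, 510, 700), c(100, 290, 600, 790),
                    c(0.2, 0.9, 0.5, 0.1))
  shuffled <- track[c(3, 1, 4, 2)]
  expect_equal(segmentSignal(region, track, "sparse"),
               segmentSignal(region, shuffled, "sparse"))
})

test_that("methylation features average per-CpG and flag empty segments", {
  region <- toyRegions(0, 300)
  # two CpGs at 0.2 and 0.8 inside the first segment
  track <- toyTrack(c(10, 20), c(11, 21), c(0.2, 0.8))
  m <- methylationFeatures(region, track)
  expect_equal(m[1, "methyl_seg1"], 0.5, ignore_attr = TRUE)
  expect_equal(m[1, "methyl_whole"], 0.5, ignore_attr = TRUE)
  # segments 2 and 3 carry no CpG: imputed 0 + missing flag
  expect_equal(m[1, "methyl_seg2"], 0, ignore_attr = TRUE)
  miss <- attr(m, "missing")
  expect_true(miss[1, "methyl_seg2"] && miss[1, "methyl_seg3"])
  expect_false(miss[1, "methyl_seg1"])
  expect_error(methylationFeatures(region, toyTrack(0, 1, 1.2)), "\\[0, 1\\]")
})

test_that("histone features count uncovered bases as zero coverage", {
  region <- toyRegions(0, 300)
  expect_equal(unname(histoneFeatures(region, GRanges())[1, ]), c(0, 0, 0, 0))
  expect_equal(unname(histoneFeatures(region, toyTrack(0, 300, 5))[1, ]),
               c(5, 5, 5, 5))
  expect_error(histoneFeatures(region, toyTrack(0, 1, -2)), "non-negative")
})

test_that("flanking-gene features match the brute-force oracle", {
  region <- toyRegions(1000, 200)     # center at 1100
  center0 <- 1100
  # exactly one upstream gene
  g1 <- GRanges("chr1", IRanges(start = 501, width = 1), strand = "+",
                gene_id = "G1", expression = 7)
  f <- geneExpressionFeatures(region, g1)
  expect_equal(unname(f[1, "gene_up1"]), 7)
  expect_equal(unname(f[1, "gene_max"]), 7)
  expect_equal(sum(f[1, ] != 0), 2L)
  # no genes on the chromosome: 21 zeros
  f0 <- geneExpressionFeatures(region, GRanges("chr2", IRanges(1, width = 1),
                                               gene_id = "X", expression = 3))
  expect_equal(unname(f0[1, ]), rep(0, 21))
  # random gene sets against the oracle
  set.seed(5)
  for (i in 1:30) {
    ng <- sample(1:40, 1)
    tss0 <- sample(0:5000, ng)
    expr <- round(runif(ng, 0, 50), 2)
    genes <- GRanges("chr1", IRanges(start = tss0 + 1, width = 1),
                     gene_id = paste0("G", seq_len(ng)), expression = expr)
    got <- geneExpressionFeatures(region, genes)
    want <- oracleGeneFeatures(center0, tss0, expr)
    expect_equal(unname(got[1, ]), want)
  }
})

test_that("GC percent counts G+C over non-N bases", {
  expect_equal(as.numeric(gcPercent("ACGT")), 0.5)
  expect_equal(as.numeric(gcPercent("AAAA")), 0)
  expect_equal(as.numeric(gcPercent("GCGC")), 1)
  expect_equal(as.numeric(gcPercent("GCNN")), 1)   # N excluded from denominator
  gN <- gcPercent("NNNN")
  expect_equal(as.numeric(gN), 0)
  expect_true(attr(gN, "missing")[1])
  expect_error(gcPercent(""), "empty")
  # gc + at = 1 for N-free sequences
  set.seed(6)
  seqs <- vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = ""),
    character(1))
  at <- vapply(strsplit(seqs, ""), function(s) mean(s %in% c("A", "T")),
               numeric(1))
  expect_equal(as.numeric(gcPercent(seqs)) + at, rep(1, 20))
})

test_that("feature combinations declare the right columns and required inputs", {
  cfg <- simConfig(n_regions = 40L, seed = 8L)
  cell <- simulateCell(cfg)
  args <- list(regions = cell$regions, methyl = cell$methyl,
               h3k27ac = cell$h3k27ac, h3k9ac = cell$h3k9ac,
               genes = cell$genes, sequences = cell$sequences)
  ncols <- c(5, 9, 9, 13, 30, 30, 34)
  for (k in 1:7) {
    fm <- do.call(buildFeatureMatrix, c(args, combination = k))
    expect_equal(ncol(featureValues(fm)), ncols[k])
    expect_equal(combinationIndex(fm), k)
    expect_false(anyNA(featureValues(fm)))
  }
  expect_true(all(c("methyl_whole", "gc_percent") %in%
                    colnames(featureValues(
                      do.call(buildFeatureMatrix, c(args, combination = 1))))))
  expect_error(buildFeatureMatrix(cell$regions, methyl = cell$methyl,
                                  sequences = cell$sequences, combination = 2),
               "H3K27ac")
  expect_error(do.call(buildFeatureMatrix, c(args, combination = 9)), "1..7")
})
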