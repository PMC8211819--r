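test_that("flanked windows add 2 kb each side and clamp at contig edges", {
  g <- toy_genes(5001L, 8000L)                      # [5000, 8000) in bed terms
  w <- flank_window(g)
  expect_equal(GenomicRanges::start(w), 3001L)
  expect_equal(GenomicRanges::end(w), 10000L)
  expect_false(S4Vectors::mcols(w)$truncated)

  edge <- toy_genes(501L, 1500L)
  w2 <- flank_window(edge)
  expect_equal(GenomicRanges::start(w2), 1L)
  expect_equal(GenomicRanges::end(w2), 3500L)
  expect_true(S4Vectors::mcols(w2)$truncated)

  expect_identical(IRanges::ranges(flank_window(g, flank = 0L)),
                   IRanges::ranges(g))
  no_len <- GenomicRanges::GRanges("chrZ", IRanges::IRanges(10L, 20L))
  expect_error(flank_window(no_len), "chromosome")
})

test_that("density metrics follow the count and coverage arithmetic", {
  g <- toy_genes(10001L, 16000L)                    # window = 10 kb after flanks
  merged <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(9000L, 12000L, 14000L), width = 500L),
    strand = "+", seqlengths = c(chr1 = 100000L))
  d <- rlfs_density(g, merged)
  expect_equal(d$window_length_bp, 10000L)
  expect_equal(d$rlfs_count, 3L)
  expect_equal(d$rlfs_per_kb, 0.3)
  expect_equal(d$pct_coverage, 15)

  far <- GenomicRanges::shift(merged, 50000L)
  d0 <- rlfs_density(g, far)
  expect_equal(d0$rlfs_count, 0L)
  expect_equal(d0$pct_coverage, 0)

  # an interval straddling the window edge counts fully but covers partially
  straddle <- GenomicRanges::GRanges("chr1", IRanges::IRanges(7501L, 8500L),
                                     strand = "+",
                                     seqlengths = c(chr1 = 100000L))
  ds <- rlfs_density(g, straddle)
  expect_equal(ds$rlfs_count, 1L)
  expect_equal(ds$pct_coverage, 100 * 500 / 10000)
})

test_that("density metrics agree with a per-base bitmap oracle on random inputs", {
  set.seed(5)
  L <- 50000L
  for (i in 1:10) {
    n_genes <- 20L
    gstart <- sample.int(L - 3000L, n_genes)
    genes <- toy_genes(gstart, gstart + sample.int(2000L, n_genes), L = L)
    merged <- merge_hits(random_intervals(200L, L), ignore_strand = TRUE)
    d <- rlfs_density(genes, merged, co_transcriptional = FALSE)
    w <- flank_window(genes)
    bm <- bitmap_of_gr(merged, L)
    for (j in seq_len(n_genes)) {
      ws <- GenomicRanges::start(w)[j]; we <- GenomicRanges::end(w)[j]
      cnt <- sum(GenomicRanges::start(merged) <= we &
                   GenomicRanges::end(merged) >= ws)
      expect_identical(d$rlfs_count[j], cnt)
      expect_equal(d$pct_coverage[j], 100 * sum(bm[ws:we]) / (we - ws + 1L))
    }
  }
})

test_that("gene features report GC percent and canonical G4 motifs on both strands", {
  seqs <- Biostrings::DNAStringSet(c(
    chr1 = paste0(paste(rep("AT", 20), collapse = ""),       # 40 nt AT
                  "GGGTGGGTGGGTGGG",                         # one plus-strand G4
                  paste(rep("GC", 20), collapse = ""),       # 40 nt GC
                  "CCCTCCCTCCCTCCC",                         # one minus-strand G4
                  paste(rep("A", 10), collapse = ""))))
  g_at <- toy_genes(1L, 40L, L = Biostrings::width(seqs))
  f <- gene_features(g_at, seqs)
  expect_equal(f$gc_pct, 0)
  expect_equal(f$g4_count, 0L)
  g_g4 <- toy_genes(41L, 55L, L = Biostrings::width(seqs))
  expect_equal(gene_features(g_g4, seqs)$g4_count, 1L)
  g_gc <- toy_genes(56L, 95L, L = Biostrings::width(seqs))
  expect_equal(gene_features(g_gc, seqs)$gc_pct, 100)
  g_c4 <- toy_genes(96L, 110L, L = Biostrings::width(seqs))
  expect_equal(gene_features(g_c4, seqs)$g4_count, 1L)

  too_long <- suppressWarnings(toy_genes(100L, 9999L, L = Biostrings::width(seqs)))
  expect_error(gene_features(too_long, seqs), "shorter")
})

test_that("doubling merged interval lengths doubles coverage but not counts", {
  g <- toy_genes(10001L, 16000L)
  merged <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(11000L, 13000L), width = 200L), strand = "+",
    seqlengths = c(chr1 = 100000L))
  doubled <- GenomicRanges::resize(merged, 400L, fix = "center")
  d1 <- rlfs_density(g, merged)
  d2 <- rlfs_density(g, doubled)
  expect_equal(d2$pct_coverage, 2 * d1$pct_coverage)
  expect_equal(d2$rlfs_count, d1$rlfs_count)
})

test_that("metrics are invariant to gene order and density denominator is switchable", {
  set.seed(3)
  L <- 50000L
  gstart <- sample.int(L - 3000L, 10L)
  genes <- toy_genes(gstart, gstart + 1000L, L = L)
  merged <- merge_hits(random_intervals(100L, L), ignore_strand = TRUE)
  d <- rlfs_density(genes, merged, co_transcriptional = FALSE)
  perm <- sample(length(genes))
  dp <- rlfs_density(genes[perm], merged, co_transcriptional = FALSE)
  expect_equal(dp[order(dp$gene_id), ], d[order(d$gene_id), ],
               ignore_attr = TRUE)
  dg <- rlfs_density(genes, merged, co_transcriptional = FALSE,
                     denominator = "gene")
  expect_equal(dg$rlfs_per_kb,
               d$rlfs_count / (GenomicRanges::width(genes) / 1000))
})
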