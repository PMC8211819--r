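small_cfg <- function(...) {
  args <- list(seed = 17L, chrom_length_bp = 100000L, n_genes = 120L,
               n_responders = 30L, planted_rlfs_rate = 5)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

test_that("identical config and seed give byte-identical genomes", {
  cfg <- small_cfg()
  s1 <- simulate_genome(cfg)
  s2 <- simulate_genome(cfg)
  expect_identical(as.character(s1$sequences), as.character(s2$sequences))
  expect_identical(as.data.frame(s1$truth$planted_rlfs),
                   as.data.frame(s2$truth$planted_rlfs))
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_genome_fasta(s1$sequences, f1)
  write_genome_fasta(s2$sequences, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  unlink(c(f1, f2))
})

test_that("zero planting rate gives background sequence only", {
  sim <- simulate_genome(small_cfg(planted_rlfs_rate = 0))
  expect_length(sim$truth$planted_rlfs, 0L)
  expect_equal(Biostrings::width(sim$sequences), 100000L)
})

test_that("a chromosome too short for a cassette is an explicit error", {
  expect_error(simulate_genome(sim_config(seed = 1L, chrom_length_bp = 300L,
                                          n_genes = 1L, n_responders = 0L)),
               "too short")
})

test_that("planted loci lie in bounds, are disjoint and match the cassette pattern", {
  cfg <- small_cfg(planted_rlfs_rate = 10)
  sim <- simulate_genome(cfg)
  pl <- sim$truth$planted_rlfs
  expect_gt(length(pl), 0L)
  expect_true(all(GenomicRanges::start(pl) >= 1L))
  expect_true(all(GenomicRanges::end(pl) <= 100000L))
  hits_self <- GenomicRanges::countOverlaps(pl, pl)
  expect_true(all(hits_self == 1L))
  for (i in seq_along(pl)) {
    frag <- Biostrings::subseq(sim$sequences[[as.character(GenomicRanges::seqnames(pl)[i])]],
                               GenomicRanges::start(pl)[i],
                               GenomicRanges::end(pl)[i])
    if (as.character(GenomicRanges::strand(pl)[i]) == "-")
      frag <- Biostrings::reverseComplement(frag)
    expect_true(cassette_matches_pattern(as.character(frag)))
  }
})

test_that("responder selection is neutral without an enrichment effect", {
  cfg <- small_cfg(rlfs_enrichment_effect = 1, n_genes = 200L,
                   n_responders = 50L)
  sim <- simulate_genome(cfg)
  ann <- simulate_annotation(cfg, sim$sequences, sim$truth)
  w <- flank_window(ann$genes)
  ov <- GenomicRanges::countOverlaps(w, sim$truth$planted_rlfs) > 0
  is_resp <- names(ann$genes) %in% ann$responders$gene_id
  # same overlap rate up to binomial noise (3 sd)
  p_hat <- mean(ov)
  se <- sqrt(p_hat * (1 - p_hat) * (1 / sum(is_resp) + 1 / sum(!is_resp)))
  expect_lt(abs(mean(ov[is_resp]) - mean(ov[!is_resp])), 3 * se + 1e-9)
})

test_that("with a strong effect, responders are RLFS-dense and genes stay disjoint", {
  cfg <- small_cfg(rlfs_enrichment_effect = 10, planted_rlfs_rate = 20)
  sim <- simulate_genome(cfg)
  ann <- simulate_annotation(cfg, sim$sequences, sim$truth)
  expect_length(ann$genes, cfg$n_genes)
  expect_true(all(GenomicRanges::countOverlaps(ann$genes, ann$genes,
                                               ignore.strand = TRUE) == 1L))
  merged <- merge_hits(find_rlfs(sim$sequences))
  m <- rlfs_density(ann$genes, merged)
  is_resp <- m$gene_id %in% ann$responders$gene_id
  expect_gt(mean(m$rlfs_per_kb[is_resp]), mean(m$rlfs_per_kb[!is_resp]))
})

test_that("gene annotation round-trips through the BED6 writer and reader", {
  cfg <- small_cfg()
  sim <- simulate_genome(cfg)
  ann <- simulate_annotation(cfg, sim$sequences, sim$truth)
  bed <- tempfile(fileext = ".bed")
  write_bed6(ann$genes, bed)
  back <- read_bed6(bed)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(ann$genes))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(ann$genes))
  expect_equal(as.character(GenomicRanges::strand(back)),
               as.character(GenomicRanges::strand(ann$genes)))
  expect_equal(S4Vectors::mcols(back)$gene_id,
               S4Vectors::mcols(ann$genes)$gene_id)
  expect_true(all(S4Vectors::mcols(back)$score == 0))
  unlink(bed)
})

test_that("annotation fails loudly when genes cannot be placed without overlap", {
  cfg <- sim_config(seed = 2L, chrom_length_bp = 10000L, n_genes = 100L,
                    mean_gene_length_bp = 2000, n_responders = 0L,
                    planted_rlfs_rate = 0)
  sim <- simulate_genome(cfg)
  expect_error(simulate_annotation(cfg, sim$sequences, sim$truth),
               "non-overlapping")
})

test_that("count matrix has the planted group structure and stable library sizes", {
  cfg <- small_cfg()
  sim <- simulate_genome(cfg)
  ann <- simulate_annotation(cfg, sim$sequences, sim$truth)
  expr <- simulate_expression(cfg, ann$genes, ann$responders)
  expect_equal(dim(expr$counts), c(120L, 12L))
  expect_equal(sort(unique(expr$design$group)),
               sort(c("siCTRL_norm", "siSETX_norm", "siCTRL_hyp", "siSETX_hyp")))
  cs <- colSums(expr$counts)
  expect_lt(max(cs) / min(cs), 3)
  expect_identical(simulate_expression(cfg, ann$genes, ann$responders)$counts,
                   expr$counts)

  # responders shift only in the knockdown-hypoxia group
  up <- ann$responders$gene_id[ann$responders$direction == "up"]
  kd_hyp <- expr$design$sample[expr$design$group == "siSETX_hyp"]
  ctrl_hyp <- expr$design$sample[expr$design$group == "siCTRL_hyp"]
  lfc <- log2(rowMeans(expr$counts[up, kd_hyp, drop = FALSE]) + 0.5) -
    log2(rowMeans(expr$counts[up, ctrl_hyp, drop = FALSE]) + 0.5)
  expect_gt(median(lfc), 1.5)
  ctrl_norm <- expr$design$sample[expr$design$group == "siCTRL_norm"]
  kd_norm <- expr$design$sample[expr$design$group == "siSETX_norm"]
  lfc_norm <- log2(rowMeans(expr$counts[up, kd_norm, drop = FALSE]) + 0.5) -
    log2(rowMeans(expr$counts[up, ctrl_norm, drop = FALSE]) + 0.5)
  expect_lt(abs(median(lfc_norm)), 0.5)
})

test_that("a null expression simulation leaves responders unremarkable", {
  cfg <- small_cfg(de_log2fc = 0)
  sim <- simulate_genome(cfg)
  ann <- simulate_annotation(cfg, sim$sequences, sim$truth)
  expr <- simulate_expression(cfg, ann$genes, ann$responders)
  de <- rank_product(expr$counts, expr$design, "siCTRL_hyp", "siSETX_hyp",
                     n_permutations = 100L, seed = 3L, mode = "paired")
  sets <- extract_gene_sets(de, 0.05)
  hits <- length(intersect(c(sets$up, sets$down), ann$responders$gene_id))
  expect_lte(hits, 3L)
})

test_that("assay tables carry their planted effects", {
  cfg <- small_cfg(ct_noise_sd = 0, ct_fold_change = 2)
  at <- simulate_assay_tables(cfg)
  # zero-noise Ct table recovers the fold change exactly
  expect_equal(ddct_fold_change(at$ct)$fold_change, 2)
  # noisy recovery stays close
  atn <- simulate_assay_tables(small_cfg(ct_noise_sd = 0.15))
  expect_equal(ddct_fold_change(atn$ct)$fold_change, 2, tolerance = 0.25)
  # foci fraction within the binomial 99% envelope
  treated <- atn$foci$foci_count[atn$foci$condition == "treated"]
  p_hat <- foci_positive_fraction(treated) / 100
  se <- sqrt(0.4 * 0.6 / length(treated))
  expect_lt(abs(p_hat - 0.4), 3 * se)
  # fibre condition means near the planted rates
  rates <- tapply(fibre_rate(atn$fibre$x_pixels, atn$fibre$t_minutes),
                  atn$fibre$condition, mean)
  truth <- atn$truth$fibre_rates
  for (cond in names(truth))
    expect_equal(unname(rates[cond]), unname(truth[cond]),
                 tolerance = 0.12)
  expect_identical(simulate_assay_tables(cfg)$ct, at$ct)
})
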