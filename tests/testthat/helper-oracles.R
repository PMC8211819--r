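# Brute-force oracles and fixture builders shared across tests.
# All oracles are deliberately naive (per-base bitmaps, enumeration),
# independent of the package's interval/statistics code paths.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(Biostrings)
})

# per-base boolean coverage of 1-based closed intervals
bitmap_of <- function(starts, ends, L) {
  v <- logical(L)
  for (i in seq_along(starts)) v[starts[i]:ends[i]] <- TRUE
  v
}

bitmap_of_gr <- function(gr, L)
  bitmap_of(GenomicRanges::start(gr), GenomicRanges::end(gr), L)

# random unstranded interval set on one chromosome
random_intervals <- function(n, L, max_width = 200L) {
  w <- sample.int(max_width, n, replace = TRUE)
  s <- sapply(w, function(wi) sample.int(L - wi + 1L, 1L))
  GenomicRanges::GRanges("chr1", IRanges::IRanges(start = s, width = w),
          seqlengths = c(chr1 = L))
}

# random DNA with elevated G and C so that RLFS hits occur on both strands
random_g_rich_seq <- function(L, gc_each = 0.35) {
  at <- (1 - 2 * gc_each) / 2
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
               prob = c(at, gc_each, gc_each, at)),
        collapse = "")
}

# mirror of hit coordinates through a sequence of length L (for the
# strand-symmetry contract)
mirror_hit_frame <- function(gr, L) {
  mc <- S4Vectors::mcols(gr)
  d <- data.frame(start = L - GenomicRanges::end(gr) + 1L,
                  end = L - GenomicRanges::start(gr) + 1L,
                  riz_start = L - mc$riz_end + 1L,
                  riz_end = L - mc$riz_start + 1L,
                  rez_start = L - mc$rez_end + 1L,
                  rez_end = L - mc$rez_start + 1L,
                  g_tract_count = mc$g_tract_count,
                  rez_g_fraction = mc$rez_g_fraction)
  d[order(d$start, d$end), , drop = FALSE]
}

hit_frame <- function(gr) {
  mc <- S4Vectors::mcols(gr)
  d <- data.frame(start = GenomicRanges::start(gr),
                  end = GenomicRanges::end(gr),
                  riz_start = mc$riz_start, riz_end = mc$riz_end,
                  rez_start = mc$rez_start, rez_end = mc$rez_end,
                  g_tract_count = mc$g_tract_count,
                  rez_g_fraction = mc$rez_g_fraction)
  d[order(d$start, d$end), , drop = FALSE]
}

# naive pattern oracle for a planted cassette: RIZ seed of three G3 tracts
# with short non-G spacers, then (after a linker) a G-rich extension
cassette_matches_pattern <- function(seq_char) {
  grepl("^GGG[ACT]{1,5}GGG[ACT]{1,5}GGG", seq_char) &&
    {
      ext <- substr(seq_char, nchar(seq_char) - 299L, nchar(seq_char))
      counts <- table(strsplit(ext, "")[[1]])
      (counts[["G"]] / 300) >= 0.4
    }
}

# exact expected pfp for the rank-product statistic on tiny instances:
# marginal rank of a gene in each of k comparisons is uniform on 1..G,
# independent across comparisons under the permutation null
exact_expected_count <- function(rp_value, G, k) {
  grid <- as.matrix(do.call(expand.grid, rep(list(seq_len(G)), k)))
  null_rp <- exp(rowMeans(log(grid)))
  G * mean(null_rp <= rp_value + 1e-12)
}

# independent Spearman rho for ties-free vectors
brute_spearman <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# small deterministic gene set on one chromosome with seqlengths
toy_genes <- function(starts, ends, strand = "+", L = 100000L) {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(starts, ends), strand = strand,
                seqlengths = c(chr1 = L))
  S4Vectors::mcols(gr)$gene_id <- sprintf("g%03d", seq_along(gr))
  S4Vectors::mcols(gr)$exon_count <- rep(1L, length(gr))
  gr
}

# all permutations of 1..n (recursive; used only for tiny n)
combinat_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1L))
    for (i in 0:(n - 1L)) out[[length(out) + 1L]] <- append(p, n, after = i)
  out
}
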