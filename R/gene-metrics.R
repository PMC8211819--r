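#' Flanked analysis window of a gene
#'
#' Adds `flank` bp at the transcription start and termination sites so that
#' promoter and terminator regions are included in downstream RLFS metrics,
#' truncating at contig edges. Truncation is recorded in the `truncated`
#' metadata column.
#'
#' @param genes a [GenomicRanges::GRanges] of gene spans. Chromosome
#'   lengths must be available, either as `seqlengths(genes)` or through
#'   `chrom_lengths`.
#' @param flank bp added to each side (default 2000).
#' @param chrom_lengths optional named vector of chromosome lengths.
#'
#' @return A [GenomicRanges::GRanges] of windows, same order and metadata
#'   as `genes`, plus a `truncated` logical column.
#' @export
flank_window <- function(genes, flank = 2000L, chrom_lengths = NULL) {
  stopifnot(methods::is(genes, "GRanges"))
  assert_count(flank, "flank", min = 0L)
  if (!is.null(chrom_lengths)) {
    missing <- setdiff(as.character(GenomeInfoDb::seqnames(GenomeInfoDb::seqinfo(genes))),
                       names(chrom_lengths))
    if (length(missing))
      stop("unknown chromosome(s): ", paste(missing, collapse = ", "))
    GenomeInfoDb::seqlengths(genes) <- chrom_lengths[GenomeInfoDb::seqlevels(genes)]
  }
  sl <- GenomeInfoDb::seqlengths(genes)
  if (any(is.na(sl[as.character(GenomicRanges::seqnames(genes))])))
    stop("unknown chromosome length; supply `chrom_lengths` or set seqlengths")
  lens <- sl[as.character(GenomicRanges::seqnames(genes))]
  new_start <- pmax(1L, GenomicRanges::start(genes) - flank)
  new_end <- pmin(as.integer(lens), GenomicRanges::end(genes) + flank)
  truncated <- new_start > GenomicRanges::start(genes) - flank |
    new_end < GenomicRanges::end(genes) + flank
  out <- genes
  GenomicRanges::ranges(out) <- IRanges::IRanges(start = new_start, end = new_end)
  S4Vectors::mcols(out)$truncated <- truncated
  out
}

gene_ids_of <- function(genes) {
  ids <- S4Vectors::mcols(genes)$gene_id
  if (is.null(ids)) ids <- names(genes)
  if (is.null(ids)) ids <- sprintf("gene_%04d", seq_along(genes))
  as.character(ids)
}

#' Per-gene RLFS density metrics
#'
#' For each gene, counts merged RLFS intervals overlapping its flanked
#' window by at least 1 bp (`rlfs_count`; an interval overlapping two genes
#' counts for both) and the percentage of the window covered by RLFS
#' (`pct_coverage`, clipped to the window). `rlfs_per_kb` divides the count
#' by the window length in kb; set `denominator = "gene"` to use the
#' unflanked gene length instead.
#'
#' @param genes [GenomicRanges::GRanges] of gene spans (stranded).
#' @param merged disjoint merged RLFS intervals from [merge_hits()]. They
#'   are assumed to be on the same assembly.
#' @param flank flank added to each gene side, bp.
#' @param co_transcriptional if `TRUE` (default), only RLFS on the gene's
#'   strand are counted (strand-aware overlap); `merged` should then be the
#'   strand-aware merge.
#' @param denominator `"window"` (default; flanks included, matching the
#'   order of operations in which flanks are added before density is
#'   measured) or `"gene"`.
#' @param chrom_lengths optional named chromosome lengths (see
#'   [flank_window()]).
#'
#' @return A data.frame with one row per gene: `gene_id`,
#'   `window_length_bp`, `rlfs_count`, `rlfs_per_kb`, `pct_coverage`,
#'   `truncated`.
#' @export
rlfs_density <- function(genes, merged, flank = 2000L,
                         co_transcriptional = TRUE,
                         denominator = c("window", "gene"),
                         chrom_lengths = NULL) {
  denominator <- match.arg(denominator)
  stopifnot(methods::is(merged, "GRanges"))
  windows <- flank_window(genes, flank = flank, chrom_lengths = chrom_lengths)
  ignore <- !co_transcriptional
  n <- GenomicRanges::countOverlaps(windows, merged, ignore.strand = ignore)
  ov <- GenomicRanges::findOverlaps(windows, merged, ignore.strand = ignore)
  q <- S4Vectors::queryHits(ov)
  s <- S4Vectors::subjectHits(ov)
  covered_w <- pmin(GenomicRanges::end(windows)[q], GenomicRanges::end(merged)[s]) -
    pmax(GenomicRanges::start(windows)[q], GenomicRanges::start(merged)[s]) + 1L
  covered <- rep(0, length(windows))
  if (length(q)) {
    agg <- tapply(covered_w, q, sum)
    covered[as.integer(names(agg))] <- as.numeric(agg)
  }
  wlen <- GenomicRanges::width(windows)
  denom <- if (denominator == "window") wlen else GenomicRanges::width(genes)
  data.frame(gene_id = gene_ids_of(genes),
             window_length_bp = as.integer(wlen),
             rlfs_count = as.integer(n),
             rlfs_per_kb = n / (denom / 1000),
             pct_coverage = 100 * covered / wlen,
             truncated = S4Vectors::mcols(windows)$truncated,
             stringsAsFactors = FALSE)
}

g4_regex <- function(min_tract = 3L, max_loop = 7L, min_tracts = 4L) {
  sprintf("G{%d,}(?:[ACGT]{1,%d}G{%d,}){%d,}",
          min_tract, max_loop, min_tract, min_tracts - 1L)
}

count_matches <- function(seq_char, pattern) {
  m <- gregexpr(pattern, seq_char, perl = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

#' Gene features: length, exon count, GC percent, G4 motifs
#'
#' GC percent is computed on the unflanked gene body (G+C over A+C+G+T,
#' ambiguous bases excluded from the denominator). `g4_count` is the number
#' of non-overlapping matches of the canonical G-quadruplex motif
#' `G{3,}(N{1,7}G{3,}){3,}` on both strands of the gene body (the minus
#' strand is scanned as the equivalent C-motif on the reference).
#'
#' @param genes [GenomicRanges::GRanges] of gene spans.
#' @param seqs [Biostrings::DNAStringSet] covering the gene spans.
#' @param g4_min_tract,g4_max_loop,g4_min_tracts motif parameters.
#'
#' @return A data.frame: `gene_id`, `gene_length_bp`, `exon_count`,
#'   `gc_pct`, `g4_count`.
#' @export
gene_features <- function(genes, seqs, g4_min_tract = 3L, g4_max_loop = 7L,
                          g4_min_tracts = 4L) {
  stopifnot(methods::is(genes, "GRanges"), methods::is(seqs, "DNAStringSet"))
  chroms <- as.character(GenomicRanges::seqnames(genes))
  if (!all(chroms %in% names(seqs)))
    stop("sequence missing for chromosome(s): ",
         paste(setdiff(chroms, names(seqs)), collapse = ", "))
  if (any(GenomicRanges::end(genes) > Biostrings::width(seqs)[match(chroms, names(seqs))]))
    stop("sequence shorter than gene span")
  body <- Biostrings::subseq(seqs[match(chroms, names(seqs))],
                             start = GenomicRanges::start(genes),
                             end = GenomicRanges::end(genes))
  freq <- Biostrings::alphabetFrequency(body, baseOnly = TRUE)
  acgt <- rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
  gc <- rowSums(freq[, c("C", "G"), drop = FALSE])
  gc_pct <- ifelse(acgt > 0, 100 * gc / acgt, 0)
  pat_g <- g4_regex(g4_min_tract, g4_max_loop, g4_min_tracts)
  pat_c <- gsub("G", "C", pat_g, fixed = TRUE)
  chars <- as.character(body)
  g4 <- vapply(chars, function(s)
    count_matches(s, pat_g) + count_matches(s, pat_c), integer(1),
    USE.NAMES = FALSE)
  ec <- S4Vectors::mcols(genes)$exon_count
  if (is.null(ec)) ec <- NA_integer_
  data.frame(gene_id = gene_ids_of(genes),
             gene_length_bp = GenomicRanges::width(genes),
             exon_count = as.integer(ec),
             gc_pct = gc_pct,
             g4_count = g4,
             stringsAsFactors = FALSE)
}

#' All per-gene RLFS metrics and features in one table
#'
#' Convenience wrapper joining [rlfs_density()] and [gene_features()].
#'
#' @inheritParams rlfs_density
#' @inheritParams gene_features
#' @return A data.frame with one row per gene and all metric/feature
#'   columns.
#' @export
compute_gene_metrics <- function(genes, merged, seqs, flank = 2000L,
                                 co_transcriptional = TRUE,
                                 denominator = c("window", "gene")) {
  dens <- rlfs_density(genes, merged, flank = flank,
                       co_transcriptional = co_transcriptional,
                       denominator = denominator,
                       chrom_lengths = stats::setNames(Biostrings::width(seqs),
                                                       names(seqs)))
  feat <- gene_features(genes, seqs)
  merge(dens, feat, by = "gene_id", sort = FALSE)
}
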