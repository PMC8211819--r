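#' Merge RLFS hits that overlap by at least one base pair
#'
#' Collapses overlapping hits into disjoint intervals while preserving the
#' union of the input coverage exactly. Intervals that merely touch
#' (adjacent on half-open coordinates, zero bases shared) are *not* merged:
#' the merge rule is "at least 1 bp of overlap", read literally.
#'
#' @param hits a [GenomicRanges::GRanges] of RLFS hits (e.g. from
#'   [find_rlfs()]).
#' @param ignore_strand if `FALSE` (default) hits are merged within each
#'   strand (strand-aware view); if `TRUE`, strand is dropped first
#'   (strand-collapsed view).
#'
#' @return A sorted [GenomicRanges::GRanges] of pairwise-disjoint intervals
#'   (per strand when `ignore_strand = FALSE`).
#' @export
merge_hits <- function(hits, ignore_strand = FALSE) {
  stopifnot(methods::is(hits, "GRanges"))
  if (length(hits) && any(GenomicRanges::width(hits) < 1L))
    stop("hits contain an empty (width < 1) interval")
  if (ignore_strand) GenomicRanges::strand(hits) <- "*"
  # min.gapwidth = 0: merge overlapping ranges only, keep adjacent ones apart
  merged <- GenomicRanges::reduce(hits, min.gapwidth = 0L,
                                  ignore.strand = FALSE)
  GenomicRanges::sort(merged, ignore.strand = TRUE)
}

#' Keep only co-transcriptional RLFS for a gene
#'
#' An RLFS is co-transcriptional for a gene when its predicted strand
#' equals the gene's transcribed strand, so the nascent RNA can hybridise
#' with the template; only such hits are retained, and only if they overlap
#' the gene's flanked analysis window.
#'
#' @param hits [GenomicRanges::GRanges] of RLFS hits.
#' @param gene a length-1 stranded [GenomicRanges::GRanges]; strand `"*"`
#'   is an error.
#' @param flank flank added to each side of the gene before the overlap
#'   test, bp (default 2000, covering promoter and terminator regions).
#'
#' @return The retained subset of `hits`.
#' @export
co_transcriptional_filter <- function(hits, gene, flank = 2000L) {
  stopifnot(methods::is(hits, "GRanges"), methods::is(gene, "GRanges"),
            length(gene) == 1L)
  gstrand <- as.character(GenomicRanges::strand(gene))
  if (gstrand == "*") stop("gene has no strand; co-transcriptional filtering needs one")
  window <- flank_window(gene, flank = flank)
  same <- as.character(GenomicRanges::strand(hits)) == gstrand
  hits <- hits[same]
  IRanges::subsetByOverlaps(hits, window, ignore.strand = TRUE)
}
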