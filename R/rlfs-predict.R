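#' RLFS scanning model parameters
#'
#' The scanner models an R-loop forming sequence as an R-loop initiation
#' zone (RIZ) of clustered G-tracts followed, after a short linker, by an
#' R-loop elongation zone (REZ) of sustained G-richness on the same strand.
#' All thresholds are surfaced here so the model can be matched to other
#' parameterisations.
#'
#' @param min_gtract_len minimum length of a G-tract (consecutive G), nt.
#' @param min_gtracts minimum number of G-tracts in a RIZ.
#' @param max_tract_gap maximum N-free gap between consecutive G-tracts of a
#'   RIZ, nt.
#' @param max_linker maximum distance between the RIZ 3' end and the REZ
#'   start, nt.
#' @param rez_min_len minimum accepted REZ length, nt.
#' @param rez_max_len maximum REZ extension, nt.
#' @param rez_g_min_frac minimum G fraction that must be sustained over
#'   every `rez_window`-nt sub-window of the REZ (and over the whole REZ
#'   when it is shorter than one sub-window).
#' @param rez_window sub-window width for the sustained G-fraction rule, nt.
#'
#' @return A named list of class `"rlfs_params"`.
#' @export
rlfs_params <- function(min_gtract_len = 3L, min_gtracts = 3L,
                        max_tract_gap = 10L, max_linker = 50L,
                        rez_min_len = 50L, rez_max_len = 2000L,
                        rez_g_min_frac = 0.4, rez_window = 100L) {
  assert_count(min_gtract_len, "min_gtract_len")
  assert_count(min_gtracts, "min_gtracts")
  assert_count(max_tract_gap, "max_tract_gap", min = 0L)
  assert_count(max_linker, "max_linker", min = 0L)
  assert_count(rez_min_len, "rez_min_len")
  assert_count(rez_max_len, "rez_max_len")
  assert_count(rez_window, "rez_window")
  if (rez_g_min_frac <= 0 || rez_g_min_frac > 1)
    stop("`rez_g_min_frac` must be in (0, 1]")
  if (rez_min_len > rez_max_len) stop("`rez_min_len` exceeds `rez_max_len`")
  structure(list(min_gtract_len = as.integer(min_gtract_len),
                 min_gtracts = as.integer(min_gtracts),
                 max_tract_gap = as.integer(max_tract_gap),
                 max_linker = as.integer(max_linker),
                 rez_min_len = as.integer(rez_min_len),
                 rez_max_len = as.integer(rez_max_len),
                 rez_g_min_frac = rez_g_min_frac,
                 rez_window = as.integer(rez_window)),
            class = "rlfs_params")
}

# cumulative-sum lookup with implicit zero at index 0
cs0 <- function(v, i) if (i >= 1L) v[i] else 0L

# Scan the plus strand of one sequence (character scalar, upper case).
# Returns a data.frame of hits in 1-based closed coordinates.
scan_plus_strand <- function(s, p) {
  empty <- data.frame(start = integer(), end = integer(),
                      riz_start = integer(), riz_end = integer(),
                      rez_start = integer(), rez_end = integer(),
                      g_tract_count = integer(), rez_g_fraction = double())
  L <- nchar(s)
  if (L == 0L) return(empty)
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- !(x %in% c("A", "C", "G", "T", "N"))
  if (any(bad))
    stop("non-IUPAC character in sequence: ",
         paste(unique(x[bad]), collapse = ", "))
  isG <- x == "G"
  cumG <- cumsum(isG)
  cumN <- cumsum(x == "N")

  # G-tracts
  r <- rle(isG)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= p$min_gtract_len
  gs <- starts[keep]
  ge <- ends[keep]
  k <- length(gs)
  if (k < p$min_gtracts) return(empty)

  # chain tracts into candidate RIZs: maximal runs of tracts whose N-free
  # gaps are <= max_tract_gap
  if (k > 1L) {
    gap <- gs[-1L] - ge[-k] - 1L
    gapN <- cumN[gs[-1L] - 1L] - cumN[ge[-k]]
    link <- gap <= p$max_tract_gap & gapN == 0L
    grp <- cumsum(c(TRUE, !link))
  } else grp <- 1L
  cnt <- tabulate(grp)
  riz_ids <- which(cnt >= p$min_gtracts)
  if (length(riz_ids) == 0L) return(empty)
  first_idx <- match(riz_ids, grp)
  last_idx <- length(grp) - match(riz_ids, rev(grp)) + 1L
  riz_start <- gs[first_idx]
  riz_end <- ge[last_idx]
  riz_tracts <- cnt[riz_ids]

  # sustained-G-fraction window validity for REZ extension
  W <- p$rez_window
  n_starts <- L - W + 1L
  if (n_starts >= 1L) {
    idx <- seq_len(n_starts)
    gw <- cumG[idx + W - 1L] - c(0L, cumG)[idx]
    nw <- cumN[idx + W - 1L] - c(0L, cumN)[idx]
    valid <- gw >= p$rez_g_min_frac * W & nw == 0L
    next_false <- c(which(!valid), n_starts + 1L)
  } else {
    valid <- logical(0)
    next_false <- 1L
  }

  rez_extent <- function(s0) {
    # longest REZ [s0, e] satisfying the sustained-fraction rule, or NA
    if (s0 > L - p$rez_min_len + 1L) return(NA_integer_)
    if (s0 <= n_starts && valid[s0]) {
      j <- next_false[findInterval(s0 - 1L, next_false) + 1L]
      return(min(j - 1L + W - 1L, s0 + p$rez_max_len - 1L, L))
    }
    emax <- min(s0 + W - 2L, L, s0 + p$rez_max_len - 1L)
    emin <- s0 + p$rez_min_len - 1L
    if (emin > emax) return(NA_integer_)
    es <- emin:emax
    g <- cumG[es] - cs0(cumG, s0 - 1L)
    n <- cumN[es] - cs0(cumN, s0 - 1L)
    ok <- g >= p$rez_g_min_frac * (es - s0 + 1L) & n == 0L
    if (!any(ok)) return(NA_integer_)
    max(es[ok])
  }

  out <- vector("list", length(riz_ids))
  for (i in seq_along(riz_ids)) {
    cand <- (riz_end[i] + 1L):min(riz_end[i] + 1L + p$max_linker, L)
    best_s <- NA_integer_; best_e <- NA_integer_; best_len <- -1L
    for (s0 in cand) {
      e <- rez_extent(s0)
      if (!is.na(e) && (e - s0 + 1L) > best_len) {
        best_len <- e - s0 + 1L; best_s <- s0; best_e <- e
      }
    }
    if (is.na(best_s) || best_len < p$rez_min_len) next
    gfrac <- (cumG[best_e] - cs0(cumG, best_s - 1L)) / best_len
    out[[i]] <- data.frame(start = riz_start[i], end = best_e,
                           riz_start = riz_start[i], riz_end = riz_end[i],
                           rez_start = best_s, rez_end = best_e,
                           g_tract_count = riz_tracts[i],
                           rez_g_fraction = gfrac)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

# Map hits found on the reverse complement back to original coordinates.
mirror_hits <- function(hits, L) {
  if (nrow(hits) == 0L) return(hits)
  data.frame(start = L - hits$end + 1L, end = L - hits$start + 1L,
             riz_start = L - hits$riz_end + 1L, riz_end = L - hits$riz_start + 1L,
             rez_start = L - hits$rez_end + 1L, rez_end = L - hits$rez_start + 1L,
             g_tract_count = hits$g_tract_count,
             rez_g_fraction = hits$rez_g_fraction)
}

#' Predict R-loop forming sequences
#'
#' Scans nucleotide sequence for RLFS under the RIZ/REZ model described in
#' [rlfs_params()]. A hit consists of a RIZ (>= `min_gtracts` G-tracts of
#' >= `min_gtract_len` G separated by N-free gaps of <= `max_tract_gap` nt)
#' followed within `max_linker` nt by the longest REZ whose G fraction stays
#' at or above `rez_g_min_frac` over every `rez_window`-nt sub-window.
#' Minus-strand hits are found on the reverse complement and mapped back,
#' so a hit's strand is the strand whose nascent transcript would form the
#' RNA/DNA hybrid. N bases break both G-tracts and REZ windows; any other
#' non-ACGTN character is an error. An empty sequence yields no hits.
#'
#' @param seqs a [Biostrings::DNAStringSet], [Biostrings::DNAString], or
#'   (named) character vector of sequences.
#' @param strand `"both"` (default), `"+"`, or `"-"`.
#' @param params an [rlfs_params()] object.
#'
#' @return A [GenomicRanges::GRanges] of hits (1-based closed, as usual for
#'   GRanges; BED export converts to 0-based half-open) with metadata
#'   columns `riz_start`, `riz_end`, `rez_start`, `rez_end` (sub-span
#'   coordinates on the reference), `g_tract_count` and `rez_g_fraction`.
#' @seealso [merge_hits()], [co_transcriptional_filter()]
#' @export
find_rlfs <- function(seqs, strand = c("both", "+", "-"),
                      params = rlfs_params()) {
  strand <- match.arg(strand)
  stopifnot(inherits(params, "rlfs_params"))
  if (methods::is(seqs, "DNAString"))
    seqs <- Biostrings::DNAStringSet(list(seq1 = seqs))
  if (is.character(seqs)) {
    if (is.null(names(seqs)))
      names(seqs) <- paste0("seq", seq_along(seqs))
    seqs <- toupper(seqs)
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad))
      stop("non-IUPAC character in sequence(s): ",
           paste(names(seqs)[bad], collapse = ", "))
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  stopifnot(methods::is(seqs, "DNAStringSet"))
  if (is.null(names(seqs)))
    names(seqs) <- paste0("seq", seq_along(seqs))

  per_chrom <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    L <- Biostrings::width(seqs)[i]
    chrom <- names(seqs)[i]
    s_fwd <- as.character(seqs[[i]])
    res <- list()
    if (strand %in% c("both", "+")) {
      h <- scan_plus_strand(s_fwd, params)
      if (nrow(h)) { h$strand <- "+"; res[[length(res) + 1L]] <- h }
    }
    if (strand %in% c("both", "-")) {
      s_rev <- as.character(Biostrings::reverseComplement(seqs[[i]]))
      h <- mirror_hits(scan_plus_strand(s_rev, params), L)
      if (nrow(h)) { h$strand <- "-"; res[[length(res) + 1L]] <- h }
    }
    if (length(res)) {
      h <- do.call(rbind, res)
      h$chrom <- chrom
      per_chrom[[i]] <- h
    }
  }
  per_chrom <- per_chrom[!vapply(per_chrom, is.null, logical(1))]
  sl <- stats::setNames(Biostrings::width(seqs), names(seqs))
  if (length(per_chrom) == 0L) {
    gr <- GenomicRanges::GRanges(seqlengths = sl)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      riz_start = integer(), riz_end = integer(),
      rez_start = integer(), rez_end = integer(),
      g_tract_count = integer(), rez_g_fraction = double())
    return(gr)
  }
  h <- do.call(rbind, per_chrom)
  gr <- GenomicRanges::GRanges(
    seqnames = factor(h$chrom, levels = names(seqs)),
    ranges = IRanges::IRanges(start = h$start, end = h$end),
    strand = h$strand,
    riz_start = h$riz_start, riz_end = h$riz_end,
    rez_start = h$rez_start, rez_end = h$rez_end,
    g_tract_count = h$g_tract_count,
    rez_g_fraction = h$rez_g_fraction,
    seqlengths = sl)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  names(gr) <- sprintf("RLFS_%04d", seq_along(gr))
  gr
}
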