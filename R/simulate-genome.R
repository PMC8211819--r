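# Build one RLFS cassette (character vector of bases) with the structure
# the scanner model detects: RIZ seed of three G3 tracts with 1-5 nt
# G-free spacers, a 10-40 nt G-free linker, then a 300 nt extension whose
# G content is spread evenly at 45% so that every 100-nt sub-window holds
# exactly 45 G. Returns list(seq = chars, riz_len, linker_len, ext_len).
make_rlfs_cassette <- function(ext_len = 300L) {
  nonG <- c("A", "C", "T")
  sp1 <- sample(nonG, sample.int(5L, 1L), replace = TRUE)
  sp2 <- sample(nonG, sample.int(5L, 1L), replace = TRUE)
  riz <- c(rep("G", 3), sp1, rep("G", 3), sp2, rep("G", 3))
  linker <- sample(nonG, sample(10:40, 1L), replace = TRUE)
  ipos <- seq_len(ext_len)
  is_g <- floor(ipos * 0.45) > floor((ipos - 1) * 0.45)
  ext <- character(ext_len)
  ext[is_g] <- "G"
  ext[!is_g] <- sample(nonG, sum(!is_g), replace = TRUE)
  list(seq = c(riz, linker, ext),
       riz_len = length(riz), linker_len = length(linker), ext_len = ext_len)
}

#' Simulate a genome with planted RLFS cassettes
#'
#' Generates chromosomes of uniform base composition (25% each base) and
#' plants G-tract cassettes — an initiation-zone seed of three G3 tracts,
#' a short linker, and a 300 nt 45%-G elongation extension — at
#' Poisson-distributed positions (expected `planted_rlfs_rate` per 100 kb
#' per chromosome), on random strands, rejecting overlaps. Minus-strand
#' cassettes are inserted as their reverse complement. Every planted locus
#' is recorded in the truth table.
#'
#' @param config a [sim_config()].
#' @return A list: `sequences` ([Biostrings::DNAStringSet]) and `truth`
#'   (list with `planted_rlfs`, a stranded [GenomicRanges::GRanges] of the
#'   planted spans).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_(derive_seed(config$seed, 1L), {
    L <- config$chrom_length_bp
    max_cassette <- 19L + 40L + 300L
    seqs <- vector("list", config$n_chromosomes)
    planted <- list()
    for (ci in seq_len(config$n_chromosomes)) {
      chrom <- sprintf("chr%d", ci)
      x <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      n_plant <- stats::rpois(1L, config$planted_rlfs_rate * L / 1e5)
      if (config$planted_rlfs_rate > 0 && L < max_cassette)
        stop("chromosome too short (", L, " bp) to host any planted RLFS cassette (",
             max_cassette, " bp)")
      placed <- matrix(numeric(0), ncol = 2)
      kept <- 0L
      for (j in seq_len(n_plant)) {
        cas <- make_rlfs_cassette()
        clen <- length(cas$seq)
        strand <- sample(c("+", "-"), 1L)
        for (try in seq_len(200L)) {
          pos <- sample.int(L - clen + 1L, 1L)
          pend <- pos + clen - 1L
          if (nrow(placed) == 0L ||
              !any(pos <= placed[, 2] & pend >= placed[, 1])) {
            ins <- if (strand == "+") cas$seq else
              rev(chartr("ACGT", "TGCA", cas$seq))
            x[pos:pend] <- ins
            placed <- rbind(placed, c(pos, pend))
            kept <- kept + 1L
            planted[[length(planted) + 1L]] <-
              data.frame(chrom = chrom, start = pos, end = pend,
                         strand = strand, stringsAsFactors = FALSE)
            break
          }
        }
      }
      seqs[[ci]] <- paste(x, collapse = "")
      names(seqs)[ci] <- chrom
    }
    sequences <- Biostrings::DNAStringSet(unlist(seqs))
    names(sequences) <- names(seqs)
    sl <- stats::setNames(rep(L, config$n_chromosomes),
                          names(sequences))
    if (length(planted)) {
      pd <- do.call(rbind, planted)
      gr <- GenomicRanges::GRanges(
        seqnames = factor(pd$chrom, levels = names(sequences)),
        ranges = IRanges::IRanges(pd$start, pd$end),
        strand = pd$strand, seqlengths = sl)
      gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
      names(gr) <- sprintf("planted_%03d", seq_along(gr))
    } else {
      gr <- GenomicRanges::GRanges(seqlengths = sl)
    }
    list(sequences = sequences,
         truth = list(planted_rlfs = gr))
  })
}
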