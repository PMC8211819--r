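#' Simulate a stranded gene annotation over a synthetic genome
#'
#' Places `n_genes` non-overlapping stranded genes (exponential lengths
#' with mean `mean_gene_length_bp`, floored at 150 bp) across the
#' chromosomes, with uniformly random inter-gene gaps. Each gene gets an
#' exon count (1 + Poisson(7)) and a biotype (90% protein_coding).
#' Responder genes — the truly differentially expressed set — are then
#' drawn from the protein-coding genes with selection odds multiplied by
#' `rlfs_enrichment_effect` when the gene's 2 kb-flanked window overlaps a
#' planted same-strand RLFS cassette, which concentrates knockdown effects
#' in RLFS-dense genes. Responder directions are split
#' `responder_up_fraction` up / rest down.
#'
#' @param config a [sim_config()].
#' @param sequences genome [Biostrings::DNAStringSet] from
#'   [simulate_genome()].
#' @param truth the matching truth list (for `planted_rlfs`).
#' @return A list: `genes` (stranded [GenomicRanges::GRanges] with
#'   `gene_id`, `exon_count`, `biotype`) and `responders` (data.frame
#'   `gene_id`, `direction`).
#' @export
simulate_annotation <- function(config, sequences, truth) {
  stopifnot(inherits(config, "sim_config"),
            methods::is(sequences, "DNAStringSet"))
  with_seed_(derive_seed(config$seed, 2L), {
    chroms <- names(sequences)
    lens <- stats::setNames(Biostrings::width(sequences), chroms)
    n <- config$n_genes
    glen <- pmax(150L, as.integer(round(stats::rexp(n, 1 / config$mean_gene_length_bp))))
    chr_of <- sample(chroms, n, replace = TRUE, prob = lens)
    starts <- integer(n)
    for (chrom in chroms) {
      idx <- which(chr_of == chrom)
      if (length(idx) == 0L) next
      total <- sum(glen[idx])
      slack <- lens[[chrom]] - total
      if (slack < length(idx))
        stop("cannot place ", length(idx), " non-overlapping genes totalling ",
             total, " bp on ", chrom, " (", lens[[chrom]], " bp)")
      cuts <- floor(sort(stats::runif(length(idx))) * slack)
      ord <- sample(idx)  # random gene order along the chromosome
      offsets <- cumsum(c(0L, glen[ord][-length(ord)]))
      starts[ord] <- as.integer(cuts + offsets + 1L)
    }
    genes <- GenomicRanges::GRanges(
      seqnames = factor(chr_of, levels = chroms),
      ranges = IRanges::IRanges(start = starts, width = glen),
      strand = sample(c("+", "-"), n, replace = TRUE),
      seqlengths = lens)
    genes <- GenomicRanges::sort(genes, ignore.strand = TRUE)
    S4Vectors::mcols(genes)$gene_id <- sprintf("gene_%04d", seq_len(n))
    S4Vectors::mcols(genes)$exon_count <- 1L + stats::rpois(n, 7)
    S4Vectors::mcols(genes)$biotype <- sample(
      c("protein_coding", "other"), n, replace = TRUE, prob = c(0.9, 0.1))
    names(genes) <- S4Vectors::mcols(genes)$gene_id

    planted <- truth$planted_rlfs
    windows <- flank_window(genes, flank = 2000L)
    overlaps_planted <- GenomicRanges::countOverlaps(
      windows, planted, ignore.strand = FALSE) > 0
    pc <- S4Vectors::mcols(genes)$biotype == "protein_coding"
    weight <- ifelse(overlaps_planted, config$rlfs_enrichment_effect, 1)
    weight[!pc] <- 0
    if (config$n_responders > sum(pc))
      stop("more responders requested than protein-coding genes available")
    resp_idx <- sample.int(n, config$n_responders, prob = weight)
    n_up <- round(config$n_responders * config$responder_up_fraction)
    direction <- rep("down", config$n_responders)
    if (n_up > 0) direction[seq_len(n_up)] <- "up"
    responders <- data.frame(
      gene_id = S4Vectors::mcols(genes)$gene_id[resp_idx],
      direction = sample(direction),
      stringsAsFactors = FALSE)
    list(genes = genes, responders = responders)
  })
}
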