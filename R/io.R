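#' Write sequences to FASTA
#' @param seqs a [Biostrings::DNAStringSet].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(seqs, path) {
  stopifnot(methods::is(seqs, "DNAStringSet"))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read sequences from FASTA
#' @param path FASTA file. Names are truncated at the first whitespace.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write a stranded interval set as BED6
#'
#' Names come from `mcols(gr)$gene_id`, then `names(gr)`; the score column
#' is `mcols(gr)$score` if present, otherwise 0. BED is 0-based half-open
#' on disk; the conversion is handled by rtracklayer.
#'
#' @param gr a [GenomicRanges::GRanges].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(gr, path) {
  stopifnot(methods::is(gr, "GRanges"))
  out <- GenomicRanges::granges(gr)
  nm <- S4Vectors::mcols(gr)$gene_id
  if (is.null(nm)) nm <- names(gr)
  if (is.null(nm)) nm <- sprintf("feature_%04d", seq_along(gr))
  names(out) <- nm
  sc <- S4Vectors::mcols(gr)$score
  S4Vectors::mcols(out)$score <- if (is.null(sc)) rep(0L, length(gr)) else sc
  rtracklayer::export.bed(out, path)
  invisible(path)
}

#' Read a BED6 file as GRanges
#' @param path BED file.
#' @return A [GenomicRanges::GRanges] with `name` copied into a `gene_id`
#'   metadata column.
#' @export
read_bed6 <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(S4Vectors::mcols(gr)$name)) {
    S4Vectors::mcols(gr)$gene_id <- S4Vectors::mcols(gr)$name
    names(gr) <- S4Vectors::mcols(gr)$name
  }
  gr
}

# md5 of an R object via its canonical JSON serialisation
object_checksum <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}

file_checksums <- function(paths) {
  cs <- tools::md5sum(paths)
  stats::setNames(unname(cs), basename(paths))
}
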