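#' Simulate a four-group negative-binomial count matrix
#'
#' Draws per-gene baseline means from a log-normal distribution and
#' negative-binomial counts (variance `mu + dispersion * mu^2`) for four
#' groups — control/knockdown siRNA crossed with normoxia/hypoxia, with
#' `n_samples_per_group` replicates each. Responder genes have their mean
#' multiplied by `2^(+/- de_log2fc)` (sign per the truth table) in the
#' knockdown-hypoxia group only. Size factors are fixed at 1: the
#' differential-expression stage, not normalisation, is under test.
#'
#' @param config a [sim_config()].
#' @param genes gene [GenomicRanges::GRanges] from [simulate_annotation()].
#' @param responders responder truth data.frame (`gene_id`, `direction`).
#' @return A list: `counts` (genes x samples integer matrix) and `design`
#'   (data.frame `sample`, `sirna`, `oxygen`, `group`).
#' @export
simulate_expression <- function(config, genes, responders) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_(derive_seed(config$seed, 3L), {
    ids <- gene_ids_of(genes)
    G <- length(ids)
    nrep <- config$n_samples_per_group
    groups <- c("siCTRL_norm", "siSETX_norm", "siCTRL_hyp", "siSETX_hyp")
    design <- data.frame(
      sample = paste0(rep(groups, each = nrep), "_", seq_len(nrep)),
      sirna = rep(c("siCTRL", "siSETX", "siCTRL", "siSETX"), each = nrep),
      oxygen = rep(c("norm", "norm", "hyp", "hyp"), each = nrep),
      group = rep(groups, each = nrep),
      stringsAsFactors = FALSE)
    mu0 <- stats::rlnorm(G, config$baseline_meanlog, config$baseline_sdlog)
    shift <- rep(0, G)
    ridx <- match(responders$gene_id, ids)
    shift[ridx] <- ifelse(responders$direction == "up",
                          config$de_log2fc, -config$de_log2fc)
    size <- 1 / config$nb_dispersion
    counts <- matrix(0L, nrow = G, ncol = nrow(design),
                     dimnames = list(ids, design$sample))
    for (j in seq_len(nrow(design))) {
      mu <- if (design$group[j] == "siSETX_hyp") mu0 * 2^shift else mu0
      counts[, j] <- stats::rnbinom(G, mu = mu, size = size)
    }
    list(counts = counts, design = design)
  })
}
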