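#' Simulation configuration
#'
#' Builds the configuration object consumed by the synthetic-data generators
#' ([simulate_genome()], [simulate_annotation()], [simulate_expression()],
#' [simulate_cohort()], [simulate_assay_tables()]). The defaults define a
#' desk-scale study: one 200 kb chromosome with planted R-loop-forming
#' cassettes, 300 non-overlapping stranded genes of which 60 "responder"
#' genes preferentially overlap planted cassettes, a four-group
#' (control/knockdown x normoxia/hypoxia) negative-binomial count matrix in
#' which responders shift only in the knockdown-hypoxia group, a tumour
#' cohort expression table with a tunable query-vs-panel Spearman
#' correlation, and small bench-assay tables with known effect sizes.
#'
#' @param seed integer; master seed. Every generator derives its own
#'   sub-stream from it, so identical config + seed gives byte-identical
#'   outputs.
#' @param n_chromosomes,chrom_length_bp genome shape.
#' @param planted_rlfs_rate expected planted RLFS cassettes per 100 kb per
#'   strand-pair (Poisson).
#' @param n_genes,mean_gene_length_bp gene annotation shape. Gene length is
#'   exponential with this mean, floored at 150 bp.
#' @param rlfs_enrichment_effect odds multiplier (>= 1) applied to the
#'   probability that a responder gene overlaps a planted same-strand
#'   cassette.
#' @param n_responders number of responder (truly differentially expressed)
#'   genes.
#' @param responder_up_fraction fraction of responders that go up under
#'   knockdown in hypoxia (default 0.571, i.e. ~341:256).
#' @param n_samples_per_group replicates per group (4 groups).
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param de_log2fc absolute log2 fold change planted in responder genes in
#'   the knockdown-hypoxia group.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of per-gene
#'   baseline expression means.
#' @param cohort_n,cohort_rho cohort size and target Spearman correlation
#'   (in \[-1, 1\]) between the query gene and the panel score.
#' @param cohort_n_background number of unrelated background genes included
#'   in the cohort table.
#' @param fibre_n_tracks fibre tracks per condition.
#' @param ct_fold_change,ct_noise_sd,ct_replicates planted qPCR fold change,
#'   Ct noise (sd, cycles) and replicate count.
#' @param foci_positive_fraction,foci_n_cells planted fraction of
#'   focus-positive cells (at the default threshold of >5 foci) and number
#'   of cells scored per condition.
#'
#' @return A named list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 1L,
                       chrom_length_bp = 200000L,
                       planted_rlfs_rate = 20,
                       n_genes = 300L,
                       mean_gene_length_bp = 400,
                       rlfs_enrichment_effect = 10,
                       n_responders = 60L,
                       responder_up_fraction = 0.571,
                       n_samples_per_group = 3L,
                       nb_dispersion = 0.05,
                       de_log2fc = 2,
                       baseline_meanlog = log(200),
                       baseline_sdlog = 1,
                       cohort_n = 400L,
                       cohort_rho = 0.6,
                       cohort_n_background = 20L,
                       fibre_n_tracks = 150L,
                       ct_fold_change = 2,
                       ct_noise_sd = 0.15,
                       ct_replicates = 3L,
                       foci_positive_fraction = 0.4,
                       foci_n_cells = 200L) {
  assert_count(seed, "seed", min = 0L)
  assert_count(n_chromosomes, "n_chromosomes")
  assert_count(chrom_length_bp, "chrom_length_bp")
  assert_count(n_genes, "n_genes")
  assert_count(n_responders, "n_responders", min = 0L)
  assert_count(n_samples_per_group, "n_samples_per_group")
  assert_count(cohort_n, "cohort_n")
  assert_positive(mean_gene_length_bp, "mean_gene_length_bp")
  assert_positive(nb_dispersion, "nb_dispersion")
  if (!is.numeric(planted_rlfs_rate) || planted_rlfs_rate < 0)
    stop("`planted_rlfs_rate` must be >= 0")
  if (!is.numeric(rlfs_enrichment_effect) || rlfs_enrichment_effect < 1)
    stop("`rlfs_enrichment_effect` must be >= 1")
  if (abs(cohort_rho) > 1) stop("`cohort_rho` must lie in [-1, 1]")
  if (n_responders > n_genes) stop("`n_responders` cannot exceed `n_genes`")
  cfg <- list(
    seed = as.integer(seed),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.integer(chrom_length_bp),
    planted_rlfs_rate = planted_rlfs_rate,
    n_genes = as.integer(n_genes),
    mean_gene_length_bp = mean_gene_length_bp,
    rlfs_enrichment_effect = rlfs_enrichment_effect,
    n_responders = as.integer(n_responders),
    responder_up_fraction = responder_up_fraction,
    n_samples_per_group = as.integer(n_samples_per_group),
    nb_dispersion = nb_dispersion,
    de_log2fc = de_log2fc,
    baseline_meanlog = baseline_meanlog,
    baseline_sdlog = baseline_sdlog,
    cohort_n = as.integer(cohort_n),
    cohort_rho = cohort_rho,
    cohort_n_background = as.integer(cohort_n_background),
    fibre_n_tracks = as.integer(fibre_n_tracks),
    ct_fold_change = ct_fold_change,
    ct_noise_sd = ct_noise_sd,
    ct_replicates = as.integer(ct_replicates),
    foci_positive_fraction = foci_positive_fraction,
    foci_n_cells = as.integer(foci_n_cells)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_chromosomes, "chromosome(s) x", x$chrom_length_bp,
      "bp;", x$n_genes, "genes (", x$n_responders, "responders );",
      "seed", x$seed, "\n")
  invisible(x)
}
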