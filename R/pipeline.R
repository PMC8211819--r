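#' Run the end-to-end RLFS enrichment analysis
#'
#' Orchestrates the full pipeline on synthetic data: simulate a genome
#' with planted RLFS cassettes, a gene annotation and a count matrix;
#' predict and merge RLFS; compute per-gene metrics; call differential
#' expression by rank product; test the up- and down-regulated sets for
#' RLFS enrichment against the protein-coding background; and run the
#' cohort signature and bench-assay quantifications. All stage outputs are
#' written under `outdir` and hashed into `manifest.json`. Re-running with
#' an identical config and seed reproduces byte-identical stage outputs;
#' with `resume = TRUE`, stages whose outputs already exist (and whose
#' config checksum matches) are skipped.
#'
#' @param outdir run directory (created if needed).
#' @param config a [sim_config()]; its `seed` drives every stage.
#' @param enrichment_iterations resampling iterations for the enrichment
#'   stage (default 1000, a fast setting; the full-scale analysis uses
#'   100000).
#' @param draw_fraction fraction of the test-set size drawn per iteration.
#' @param genome_display_n size of the display sample of the background.
#' @param n_permutations rank-product permutations.
#' @param pfp_cutoff pfp threshold for the up/down gene sets.
#' @param flank flank added to genes for RLFS metrics, bp.
#' @param rlfs scanner parameters ([rlfs_params()]).
#' @param resume skip stages whose outputs are present and current.
#' @param quiet suppress per-stage log lines.
#'
#' @return Invisibly, a list with the in-memory stage results
#'   (`sequences`, `genes`, `truth`, `counts`, `metrics`, `de`,
#'   `gene_sets`, `enrichment`, `signature`, `assays`) and the `manifest`.
#' @export
run_pipeline <- function(outdir, config = sim_config(),
                         enrichment_iterations = 1000L,
                         draw_fraction = 0.2, genome_display_n = 500L,
                         n_permutations = 100L, pfp_cutoff = 0.05,
                         flank = 2000L, rlfs = rlfs_params(),
                         resume = TRUE, quiet = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_sum <- object_checksum(list(config = unclass(config),
                                  enrichment_iterations = enrichment_iterations,
                                  draw_fraction = draw_fraction,
                                  genome_display_n = genome_display_n,
                                  n_permutations = n_permutations,
                                  pfp_cutoff = pfp_cutoff, flank = flank,
                                  rlfs = unclass(rlfs)))
  manifest_path <- file.path(outdir, "manifest.json")
  old_manifest <- if (file.exists(manifest_path))
    tryCatch(jsonlite::read_json(manifest_path), error = function(e) NULL)
  can_resume <- resume && !is.null(old_manifest) &&
    identical(old_manifest$config_checksum, as.character(cfg_sum))
  stages <- list()
  log_stage <- function(name, skipped, t0, outputs) {
    if (!quiet)
      message(sprintf("[%s] %s (%.2fs) seed=%d outputs=%s", name,
                      if (skipped) "resumed" else "done",
                      as.numeric(Sys.time()) - t0, config$seed,
                      paste(basename(outputs), collapse = ",")))
  }
  run_stage <- function(name, outputs, fn) {
    t0 <- as.numeric(Sys.time())
    paths <- file.path(outdir, outputs)
    skipped <- can_resume && all(file.exists(paths))
    if (!skipped) fn(paths)
    stages[[name]] <<- list(outputs = as.list(file_checksums(paths)))
    log_stage(name, skipped, t0, paths)
    invisible(NULL)
  }

  # stage 1: synthetic data --------------------------------------------
  sim <- simulate_genome(config)
  ann <- simulate_annotation(config, sim$sequences, sim$truth)
  expr <- simulate_expression(config, ann$genes, ann$responders)
  run_stage("simulate",
            c("genome.fa", "planted.bed", "genes.bed", "genes.tsv",
              "responders.tsv", "counts.tsv", "design.tsv"),
            function(paths) {
              write_genome_fasta(sim$sequences, paths[1])
              write_bed6(sim$truth$planted_rlfs, paths[2])
              write_bed6(ann$genes, paths[3])
              write_tsv_(data.frame(
                gene_id = S4Vectors::mcols(ann$genes)$gene_id,
                exon_count = S4Vectors::mcols(ann$genes)$exon_count,
                biotype = S4Vectors::mcols(ann$genes)$biotype), paths[4])
              write_tsv_(ann$responders, paths[5])
              write_tsv_(data.frame(gene_id = rownames(expr$counts),
                                    expr$counts, check.names = FALSE), paths[6])
              write_tsv_(expr$design, paths[7])
            })

  # stage 2: RLFS prediction and merge ---------------------------------
  hits <- find_rlfs(sim$sequences, params = rlfs)
  merged <- merge_hits(hits)
  run_stage("rlfs", c("rlfs_hits.bed", "rlfs_merged.bed"),
            function(paths) {
              h <- hits
              S4Vectors::mcols(h)$score <-
                pmin(1000L, as.integer(round(1000 * S4Vectors::mcols(h)$rez_g_fraction)))
              write_bed6(h, paths[1])
              write_bed6(merged, paths[2])
            })

  # stage 3: per-gene metrics ------------------------------------------
  metrics <- compute_gene_metrics(ann$genes, merged, sim$sequences,
                                  flank = flank)
  metrics$biotype <- S4Vectors::mcols(ann$genes)$biotype[
    match(metrics$gene_id, S4Vectors::mcols(ann$genes)$gene_id)]
  run_stage("metrics", "metrics.tsv",
            function(paths) write_tsv_(metrics, paths[1]))

  # stage 4: differential expression -----------------------------------
  de <- rank_product(expr$counts, expr$design, "siCTRL_hyp", "siSETX_hyp",
                     n_permutations = n_permutations,
                     seed = derive_seed(config$seed, 7L))
  sets <- extract_gene_sets(de, pfp_cutoff = pfp_cutoff)
  run_stage("de", c("de.tsv", "genes_up.txt", "genes_down.txt"),
            function(paths) {
              write_tsv_(de, paths[1])
              writeLines(sets$up, paths[2])
              writeLines(sets$down, paths[3])
            })

  # stage 5: enrichment -------------------------------------------------
  pc_metrics <- metrics[metrics$biotype == "protein_coding", ]
  genome_vals <- stats::setNames(pc_metrics$rlfs_per_kb, pc_metrics$gene_id)
  enr <- list()
  for (set_name in c("up", "down")) {
    ids <- intersect(sets[[set_name]], pc_metrics$gene_id)
    if (length(ids) < 5L) {
      enr[[set_name]] <- list(note = "fewer than 5 genes; test skipped",
                              n = length(ids))
      next
    }
    for (metric in c("rlfs_per_kb", "pct_coverage")) {
      vals <- stats::setNames(pc_metrics[[metric]], pc_metrics$gene_id)
      res <- enrichment_test(vals[ids], vals,
                             metric = metric,
                             n_iterations = enrichment_iterations,
                             draw_fraction = draw_fraction,
                             seed = derive_seed(config$seed,
                                                6L + match(set_name, c("up", "down"))))
      enr[[set_name]][[metric]] <- res
    }
  }
  disp <- genome_display_sample(genome_vals,
                                n = min(genome_display_n, length(genome_vals)),
                                seed = derive_seed(config$seed, 9L))
  run_stage("enrich", "enrichment.json",
            function(paths) {
              slim <- lapply(enr, function(e) lapply(e, function(r) {
                if (!inherits(r, "enrichment_result")) return(r)
                r[c("metric", "mean_of_test_means", "mean_of_genome_means",
                    "delta_means", "cohen_d", "t_statistic", "p_two_tailed",
                    "p_resampled", "p_raw", "p_floored", "config")]
              }))
              jsonlite::write_json(slim, paths[1], auto_unbox = TRUE,
                                   digits = NA, pretty = TRUE)
            })

  # stage 6: cohort signature -------------------------------------------
  cohort <- simulate_cohort(config)
  sig <- signature_analysis(cohort$expr, cohort$panel, cohort$query_gene)
  run_stage("signature", c("cohort.tsv", "signature.json"),
            function(paths) {
              write_tsv_(data.frame(gene_id = rownames(cohort$expr),
                                    cohort$expr, check.names = FALSE), paths[1])
              jsonlite::write_json(
                list(rho = sig$rho, p_two_tailed = sig$p_two_tailed,
                     n_samples = sig$n_samples, method = sig$method,
                     true_rho = cohort$true_rho),
                paths[2], auto_unbox = TRUE, digits = NA, pretty = TRUE)
            })

  # stage 7: bench assays ------------------------------------------------
  assays <- simulate_assay_tables(config)
  assay_summary <- list(
    fibre_rate_kb_min = tapply(
      fibre_rate(assays$fibre$x_pixels, assays$fibre$t_minutes),
      assays$fibre$condition, mean),
    ddct = ddct_fold_change(assays$ct)[c("fold_change", "ddct")],
    foci_positive_pct = tapply(assays$foci$foci_count, assays$foci$condition,
                               foci_positive_fraction))
  run_stage("assays", c("fibre.tsv", "ct.tsv", "foci.tsv", "assays.json"),
            function(paths) {
              write_tsv_(assays$fibre, paths[1])
              write_tsv_(assays$ct, paths[2])
              write_tsv_(assays$foci, paths[3])
              jsonlite::write_json(assay_summary, paths[4], auto_unbox = TRUE,
                                   digits = NA, pretty = TRUE)
            })

  manifest <- list(
    package_version = as.character(utils::packageVersion("rloopenrich")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config_checksum = as.character(cfg_sum),
    stages = stages)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(sequences = sim$sequences, truth = sim$truth,
                 genes = ann$genes, responders = ann$responders,
                 counts = expr$counts, design = expr$design,
                 hits = hits, merged = merged, metrics = metrics,
                 de = de, gene_sets = sets, enrichment = enr,
                 genome_display = disp, cohort = cohort, signature = sig,
                 assays = assays, assay_summary = assay_summary,
                 manifest = manifest, outdir = outdir))
}

#' Run the pipeline from a YAML configuration file
#'
#' The YAML file may contain a `sim:` block (fields of [sim_config()]) and
#' top-level pipeline options (`enrichment_iterations`, `draw_fraction`,
#' `genome_display_n`, `n_permutations`, `pfp_cutoff`, `flank`, and an
#' `rlfs:` block of [rlfs_params()] fields).
#'
#' @param yaml_path path to the YAML config.
#' @param outdir run directory.
#' @param ... overrides passed on to [run_pipeline()].
#' @return See [run_pipeline()].
#' @export
run_pipeline_yaml <- function(yaml_path, outdir, ...) {
  if (!file.exists(yaml_path)) stop("config file not found: ", yaml_path)
  y <- yaml::read_yaml(yaml_path)
  config <- do.call(sim_config, if (is.null(y$sim)) list() else y$sim)
  rlfs <- do.call(rlfs_params, if (is.null(y$rlfs)) list() else y$rlfs)
  opts <- y[setdiff(names(y), c("sim", "rlfs"))]
  args <- c(list(outdir = outdir, config = config, rlfs = rlfs), opts,
            list(...))
  do.call(run_pipeline, args[!duplicated(names(args))])
}
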