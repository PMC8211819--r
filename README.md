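# rloopenrich

R-loops are three-stranded nucleic-acid structures — an RNA/DNA hybrid
plus a displaced single strand — that form co-transcriptionally and can
both regulate gene expression and threaten genome stability. A recurring
question in studies of R-loop biology (for example, of stress-responsive
helicases that resolve R-loops under tumour hypoxia) is whether the genes
whose expression changes in an experiment are unusually rich in **R-loop
forming sequences (RLFS)**. `rloopenrich` implements that analysis and
its satellite quantifications as a tested, reproducible R package for
computational biologists:

* **RLFS prediction** (`find_rlfs`): scans both strands of a genome with
  an explicit RIZ/REZ model — an initiation zone of ≥ 3 G-tracts (≥ 3 G,
  gaps ≤ 10 nt) followed within ≤ 50 nt by an elongation zone of 50–2000
  nt whose G fraction stays ≥ 0.4 over every 100-nt sub-window. Hits
  overlapping by ≥ 1 bp are merged (`merge_hits`), and only
  co-transcriptional hits (same strand as the gene) are assessed.
* **Per-gene metrics** (`compute_gene_metrics`): RLFS per kb and percent
  coverage on 2 kb-flanked gene windows, plus gene length, exon count,
  GC% and canonical G4-motif counts.
* **Resampling enrichment** (`enrichment_test`): both a gene set and the
  protein-coding background are subsampled (20% of the set size per
  draw, 100,000 iterations at full scale) and the mean distributions
  compared by a two-tailed t-test, with effect sizes and a calibrated
  raw-metric p-value reported alongside.
* **Rank-product differential expression** (`rank_product`):
  RP = (∏ fold-change ranks)^(1/k) with permutation-based
  false-prediction proportions (pfp), plus FPKM for reporting.
* **Metagene signatures** (`signature_analysis`): median-rescaled cohort
  expression, median panel scores, Spearman correlation with exact
  small-sample p-values.
* **Bench assays** (`fibre_rate`, `ddct_fold_change`,
  `foci_positive_fraction`): V = (x · 0.132 µm · 2.59 kb/µm)/t for DNA
  fibre tracks, 2^−ΔΔCt fold changes, and strict ">n foci" positive
  fractions.
* **Synthetic data with truth tables** (`simulate_genome`,
  `simulate_annotation`, `simulate_expression`, `simulate_cohort`,
  `simulate_assay_tables`) and a one-call pipeline (`run_pipeline`) that
  writes FASTA/BED/TSV/JSON outputs and a checksum manifest.

## Worked example

Simulate a 200 kb genome with planted RLFS cassettes, call RLFS, compute
per-gene metrics, find the genes that respond to a knockdown in
"hypoxia", and test both response sets for RLFS enrichment:

```r
library(rloopenrich)

cfg  <- sim_config(seed = 1)
sim  <- simulate_genome(cfg)                       # 43 planted cassettes
ann  <- simulate_annotation(cfg, sim$sequences, sim$truth)
hits <- find_rlfs(sim$sequences)                   # 44 hits, both strands
merged  <- merge_hits(hits)
metrics <- compute_gene_metrics(ann$genes, merged, sim$sequences)
head(metrics[, c("gene_id", "rlfs_count", "rlfs_per_kb", "pct_coverage")], 3)
#>     gene_id rlfs_count rlfs_per_kb pct_coverage
#> 1 gene_0001          1   0.3235199    11.549660
#> 2 gene_0002          1   0.2719608    10.035355
#> 3 gene_0003          1   0.2413710     8.906589

expr <- simulate_expression(cfg, ann$genes, ann$responders)
de   <- rank_product(expr$counts, expr$design, "siCTRL_hyp", "siSETX_hyp",
                     n_permutations = 100, seed = 2)
sets <- extract_gene_sets(de, pfp_cutoff = 0.05)   # 34 up, 27 down

vals <- setNames(metrics$rlfs_per_kb, metrics$gene_id)
enrichment_test(vals[sets$up], vals, metric = "rlfs_per_kb",
                n_iterations = 10000, seed = 3)
#> Resampling enrichment test (rlfs_per_kb)
#>   test set n = 34, background n = 300, 10000 iterations of 7 draws
#>   mean of test means   = 0.2127
#>   mean of genome means = 0.1264
#>   delta = 0.0863, Cohen's d (raw) = 0.544
#>   p (resampled distributions) = 2.23e-308 [at numerical floor]
#>   p (raw per-gene metrics)    = 0.000494
```

The up-regulated set carries roughly 0.09 more RLFS per kb than the
genome background. The floored distribution-comparison p-value signals a
non-zero location difference (it shrinks with the iteration count — see
the methods vignette); the calibrated raw-metric p (5 × 10⁻⁴) and the
effect sizes carry the inference. The cohort arm recovers a planted
query-vs-panel association:

```r
coh <- simulate_cohort(cfg)                        # target Spearman rho 0.6
signature_analysis(coh$expr, coh$panel, coh$query_gene)
#> Spearman rho = 0.6052 (n = 400, two-tailed p = 2.46e-41, t-approximation)

fibre_rate(x = 100, t = 20)                        # pixels, minutes
#> [1] 1.7094                                       # kb/min
```

The whole analysis, with all files and a checksum manifest, is one call:

```r
run_pipeline("my_run", sim_config(seed = 1))
```

or from a shell, `Rscript inst/scripts/rloop-pipeline.R --outdir my_run
--seed 1` (optionally with a YAML config; see `?run_pipeline_yaml`).

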