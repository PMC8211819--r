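---
title: "Methods: RLFS prediction, density metrics and enrichment analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RLFS prediction, density metrics and enrichment analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rloopenrich)
```

# Scope

`rloopenrich` implements the computational core of a common analysis in
R-loop biology: given a genome, a gene annotation and a differential
expression experiment, decide whether the differentially expressed genes
carry more R-loop forming sequences (RLFS) than the protein-coding
background. The package also provides the satellite quantifications such
studies report — rank-product differential expression, metagene signature
correlations in tumour cohorts, DNA-fibre replication rates, ΔΔCt fold
changes and focus-positive cell fractions — and a synthetic-data generator
with recorded ground truth so that every stage can be validated end to end
without external downloads.

# The RLFS scanning model

An R-loop forms co-transcriptionally when the nascent RNA re-anneals to
the template strand. Sequence models of R-loop formation describe two
zones on the non-template strand: an **R-loop initiation zone (RIZ)** of
clustered G-tracts, which nucleates the RNA/DNA hybrid, and a downstream
**R-loop elongation zone (REZ)** of sustained G-richness that lets the
hybrid extend. `find_rlfs()` fixes a concrete, fully documented
parameterisation of this structure:

* **RIZ** — at least 3 G-tracts of ≥ 3 consecutive G, separated by N-free
  gaps of ≤ 10 nt. Maximal tract chains are used, so overlapping
  candidates resolve to the longest cluster.
* **Linker** — the REZ may start at most 50 nt after the RIZ 3' end.
* **REZ** — the longest window (50–2000 nt) whose G fraction stays at or
  above 0.40 over every 100-nt sub-window; windows shorter than 100 nt
  must meet the threshold overall. The longest attainable REZ across
  admissible start positions is chosen; ties go to the earliest start.
* `N` bases break both tracts and windows (conservative); any other
  non-ACGTN character is an error. Minus-strand hits are computed on the
  reverse complement and mapped back, so a hit's strand is the strand
  whose transcript would form the hybrid.

Every threshold is a parameter of `rlfs_params()`, because published
RLFS tools differ in their exact settings and users may want to match a
particular one. The defaults above are a desk-scale approximation of the
RIZ/linker/REZ architecture of quantitative RLFS models, not a
re-implementation of any specific tool. The minimum REZ length (50 nt)
is the one setting with no published analogue; it is the shortest
elongation zone we accept as evidence of sustained G-richness rather
than a chance G excess.

Merging (`merge_hits()`) collapses hits that share **at least one base
pair**; intervals that merely touch are kept apart. Coverage of the
union is preserved exactly, which the tests verify against a per-base
bitmap oracle. `co_transcriptional_filter()` retains only hits on a
gene's transcribed strand that overlap its flanked window.

# Per-gene metrics

Genes are extended by 2 kb on each side (`flank_window()`) so that
promoter and terminator regions — where R-loops concentrate — are
included. Two density metrics are computed per gene on the merged,
co-transcriptional RLFS set:

* `rlfs_per_kb` — the number of merged RLFS intervals overlapping the
  window by ≥ 1 bp, divided by the window length in kb. An interval
  overlapping two gene windows counts for both: the count is an event
  count, while coverage is a length measure.
* `pct_coverage` — the percentage of window bases covered by RLFS,
  clipped to the window.

The density denominator includes the flanks by default, following the
order of operations in which flanks are added before density is
measured; `denominator = "gene"` switches to the unflanked length, since
descriptions of "RLFS per kb of gene length" are ambiguous on this
point. Gene features used for set comparisons — length, exon count, GC%,
and G-quadruplex motifs — come from `gene_features()`. The G4 motif is
the canonical `G{3,}(N{1,7}G{3,}){3,}` pattern counted non-overlapping
on both strands; this community default is used because studies name the
feature without restating a formula.

# The resampling enrichment test

To compare an RLFS metric between a differentially expressed gene set
and the protein-coding genome, both populations are subsampled — 20% of
the test-set size per draw, without replacement, 100,000 iterations at
full scale — and the per-draw means form two distributions that are
compared with a two-tailed t-test (Welch by default; a pooled-variance
option exists because "Student's t-test" descriptions leave this open).
`genome_display_sample()` provides the n = 500 background sample used
for display alongside the test sets.

An important statistical caveat is built into the reporting. The
resampled-mean distributions tighten as the iteration count grows, so
the p-value of their comparison (`p_resampled`) shrinks with the number
of iterations and is anticonservative with respect to gene-set
selection noise: under a null in which the "test set" is just a random
subset of the genome, the subset's sampling error (sd ≈ S·√(1/m − 1/N))
dwarfs the resampling standard error and `p_resampled` rejects almost
always. Reported values at the numerical floor (flagged `p_floored`)
should be read as "a non-zero location difference", not as an
astronomical significance. `enrichment_test()` therefore also reports
`p_raw`, a Welch t-test on the raw per-gene metrics, which *is*
calibrated: when a random gene set is compared against the rest of the
genome, `p_raw` is uniform (the suite verifies ≈ 5% rejections at
α = 0.05 and a Kolmogorov–Smirnov statistic < 0.1 over 200 replicate
runs). Effect sizes — the difference of mean-of-means and Cohen's d on
the raw metrics — are reported alongside both p-values and should carry
the interpretation. Note that the calibrated comparison is set versus
*complement*; including the test genes in the background makes `p_raw`
conservative when the set is a sizeable fraction of the genome.

# Rank-product differential expression

Differential expression between two groups uses the rank product: for
each of k pairwise A-vs-B comparisons, genes are ranked by log2 fold
change (pseudocount 0.5; average ranks on ties) and
RP = (∏ ranks)^(1/k). Significance is the false-prediction proportion
(pfp): the expected number of null rank products at or below a gene's
RP — estimated from independent uniform rank permutations per
comparison — divided by the gene's observed rank. One permutation null
is shared by the up and down analyses, which makes swapping the group
labels an exact symmetry under a fixed seed. Up/down gene sets are
extracted at pfp < 0.05 by default; the cutoff is configurable because
source analyses often leave it unstated.

Two comparison modes exist. The default **all-pairs** mode (k = nA·nB)
maximises power and recovers planted responders (|log2FC| = 2, NB
dispersion 0.05, n = 3/group) with recall ≥ 0.9 and precision ≥ 0.8. Its
comparisons reuse samples, however, and are therefore positively
correlated, while the permutation null assumes independent ranks — so
its pfp is anticonservative under the global null. **Paired** mode
(k = n independent comparisons, each replicate used once) matches the
null's independence assumption exactly: the suite measures a 5%
top-gene pfp < 0.05 rate over 200 null runs. Calibration statements
about the pfp refer to paired mode; at n = 3 paired mode is
underpowered (recall ≈ 0.35 at the conditions above), which is why
all-pairs remains the default for discovery. Ranks are computed on
pseudocounted counts, making the statistic invariant to power-law
rescalings of expression; FPKM (`fpkm()`) is provided as a reporting
transformation.

# Metagene signatures

Cohort tables are rescaled so every gene's median is exactly 1
(`median_rescale()`; genes with non-positive medians cannot be rescaled
and are dropped with a warning). A panel score is the per-sample median
of the rescaled panel genes, and `correlate_signature()` computes
Spearman's rho on average ranks with a two-tailed p — exact permutation
p for n ≤ 9 without ties, otherwise the t approximation
t = ρ·√((n−2)/(1−ρ²)). Panels are user-supplied gene lists; nothing is
hard-coded, and the simulated cohort's 6-gene panel uses the
hypoxia-associated p53 target names purely as labels.

# The synthetic-data generator

The generator exists so that every downstream stage can be scored
against recorded truth. Its defaults define the study conditions used
throughout the tests and the acceptance script:

* **Genome** — one 200 kb chromosome of uniform base composition (25%
  each), which isolates the planted signal for sensitivity tests.
  Cassettes are planted at Poisson positions (20 per 100 kb by default —
  a deliberately RLFS-dense genome, so that enough gene windows overlap
  a cassette for set-level contrasts at desk scale), on random strands,
  rejecting overlaps. A cassette is a RIZ seed
  (`GGG N1–5 GGG N1–5 GGG`, G-free spacers), a 10–40 nt G-free linker,
  and a 300 nt extension whose 45% G content is spread evenly so every
  100-nt sub-window holds exactly 45 G. The even spread matters: an
  i.i.d. 45% G extension would fail a sustained 40% sub-window rule in
  a nontrivial fraction of windows, making planted "true" loci
  undetectable by construction. With this cassette the scanner's
  measured sensitivity is ≥ 95% (in practice 100%).
* **Annotation** — 300 non-overlapping stranded genes, exponential
  lengths (mean 400 bp at demo scale, floored at 150 bp), exon counts
  1 + Poisson(7), 90% protein-coding. 60 responder genes are drawn with
  odds multiplied by `rlfs_enrichment_effect` (default 10) when the
  gene's flanked window overlaps a planted same-strand cassette; their
  directions split 57% up / 43% down, echoing the asymmetry typical of
  knockdown experiments.
* **Counts** — log-normal baseline means (meanlog log 200, sdlog 1) and
  negative-binomial counts with dispersion 0.05 at n = 3 per group,
  four groups (control/knockdown × normoxia/hypoxia); responders shift
  by ±2 log2 units only in the knockdown–hypoxia group. Size factors
  are fixed at 1 because the DE stage, not normalisation, is under
  test. Dispersion and library sizes of real experiments vary; these
  defaults are stand-ins chosen as typical of a clean cell-line
  RNA-seq, and they are parameters, not constants.
* **Cohort** — a Gaussian copula induces the query-vs-panel rank
  correlation: two latent normals with Pearson r = 2·sin(π·ρS/6) are
  pushed through strictly monotone log-normal marginals, hitting the
  target Spearman ρS analytically. All six panel genes are monotone
  transforms of one latent factor — a simplification that makes the
  panel median an exact monotone image of the factor (and ρS = 1
  recover exactly 1). Real panels have gene-specific noise that would
  attenuate the correlation; parameter-recovery results here therefore
  speak to the estimator, not to between-gene heterogeneity.
* **Assays** — fibre tracks with log-normal length noise around
  condition means corresponding to 1.5/1.3/0.8/0.5 kb/min
  (knockdown slows forks, more in hypoxia), with pulse presets of
  20 min (normoxia) and 60 min (hypoxia) stored as named constants to
  prevent unit errors; Ct tables with a planted fold change and 0.15
  cycle noise; foci tables with a binomial draw of positive cells.

Every generator derives an independent RNG sub-stream from the single
config seed, so identical config + seed yields byte-identical files; the
pipeline's manifest records md5 checksums to make this checkable. What
the generator does **not** emulate: read-level sequencing noise,
alignment artefacts, batch effects, isoform structure, gene-correlated
GC biases, or realistic chromatin context. Passing tests demonstrate
that the implementations compute their statistics correctly and recover
planted structure — not that real genomes behave like the simulation.

# Numerical choices and degenerate inputs

* Coordinates are 1-based closed in R (GRanges convention) and 0-based
  half-open on disk (BED, via rtracklayer).
* Merging requires ≥ 1 shared base; adjacency is not overlap.
* Enrichment draws are without replacement within an iteration;
  iterations are independent; `draw_size = round(0.2·|test set|)` with
  a floor of 1; test sets of fewer than 5 genes are an error.
* Rank-product pfp uses the "number of genes with RP ≤ RP_g" rank
  convention, so tied genes share their pfp; p-values of 0 from the
  resampled t comparison are floored at the smallest positive double
  and flagged.
* Spearman's rho is undefined for constant inputs (error); fewer than 5
  pairs is an error; ties force the t approximation.
* The fibre-rate calibration constants (0.132 µm/pixel, 2.59 kb/µm) are
  arguments, and ΔΔCt averages replicate Cts before differencing
  (standard Livak usage).

# Problem sizes

The test suite and the acceptance script run everything at desk scale:
200 kb genomes, 300 genes, 1,000–10,000 enrichment iterations, 100
rank-product permutations, 200-replicate calibration loops, and a
400-sample cohort over 100 seeds. These sizes were chosen so that the
statistical properties under test (calibration bands, recovery rates)
are measurable with comfortable margins while the whole suite completes
in about a minute; full-scale settings (100,000 iterations) remain the
documented defaults of the corresponding functions.

# Known limitations

* The scanner is a structural model; it does not compute hybridisation
  thermodynamics and will not match any external RLFS tool byte for
  byte.
* All-pairs rank product trades pfp calibration for power (see above);
  use paired mode when calibrated error control matters.
* The resampled-distribution p-value is reported for fidelity to common
  practice, but `p_raw` with effect sizes is the defensible inference.
* Cohort simulation induces perfect rank-dependence within the panel.
* The pipeline's resume logic is checksum-gated at the config level and
  file-existence at the stage level; it does not hash intermediate
  inputs per stage.
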