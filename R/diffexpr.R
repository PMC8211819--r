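#' FPKM normalisation
#'
#' Fragments per kilobase of transcript per million mapped fragments:
#' `fpkm[g, s] = counts[g, s] / ((length_g / 1000) * (total_s / 1e6))`.
#'
#' @param counts non-negative genes x samples matrix.
#' @param gene_length_bp positive per-gene lengths, recycled along rows.
#' @return Matrix of FPKM values with the dimnames of `counts`.
#' @export
fpkm <- function(counts, gene_length_bp) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (length(gene_length_bp) != nrow(counts))
    gene_length_bp <- rep_len(gene_length_bp, nrow(counts))
  if (any(gene_length_bp <= 0)) stop("gene lengths must be positive")
  totals <- colSums(counts)
  if (any(totals == 0)) stop("sample with zero total count")
  sweep(counts / (gene_length_bp / 1000), 2, totals / 1e6, "/")
}

rp_geomean <- function(rank_mat) exp(rowMeans(log(rank_mat)))

#' Rank-product differential expression
#'
#' Nonparametric differential-expression statistic: for each of the `k`
#' pairwise A-vs-B sample comparisons, genes are ranked by log2 fold change
#' (rank 1 = most up-regulated for the up analysis, most down-regulated for
#' the down analysis; ties get average ranks) and the rank product is the
#' geometric mean of a gene's ranks, `RP_g = (prod ranks)^(1/k)`.
#' Significance is the false-prediction proportion (pfp): the null
#' distribution of RP is built from `n_permutations` independent random
#' rank assignments per comparison, and
#' `pfp_g = (expected number of null RP values <= RP_g) / rank of g`,
#' where the rank of g counts genes with RP at or below RP_g. The same
#' permutation null serves the up and the down analysis, so swapping group
#' labels swaps the two results exactly under a fixed seed.
#'
#' Ranks are computed on `counts + pseudocount`, which makes the statistic
#' invariant to gene length within a sample; FPKM is a reporting
#' transformation, not an input requirement.
#'
#' @param counts non-negative genes x samples matrix with dimnames.
#' @param groups named character vector mapping sample name to group, or a
#'   data.frame with columns `sample` and `group`.
#' @param group_a,group_b the two groups to contrast (fold changes are B
#'   over A, so "up" means higher in `group_b`).
#' @param n_permutations permutations for the pfp null (default 100).
#' @param pseudocount added before log fold change (default 0.5).
#' @param mode `"all-pairs"` (default: every A replicate against every B
#'   replicate, k = nA * nB) or `"paired"` (positional pairing, requires
#'   nA == nB).
#' @param seed optional integer seed for the permutation null.
#'
#' @return A data.frame (one row per gene): `gene_id`, `rp_up`, `rp_down`,
#'   `pfp_up`, `pfp_down`, `mean_log2fc`, with attributes `n_permutations`
#'   and `n_comparisons`.
#' @export
rank_product <- function(counts, groups, group_a, group_b,
                         n_permutations = 100L, pseudocount = 0.5,
                         mode = c("all-pairs", "paired"), seed = NULL) {
  mode <- match.arg(mode)
  assert_count(n_permutations, "n_permutations")
  counts <- as.matrix(counts)
  if (is.data.frame(groups))
    groups <- stats::setNames(as.character(groups$group), groups$sample)
  if (is.null(colnames(counts)) || !all(colnames(counts) %in% names(groups)))
    stop("`groups` must cover every sample (column) in `counts`")
  grp <- groups[colnames(counts)]
  a_samples <- colnames(counts)[grp == group_a]
  b_samples <- colnames(counts)[grp == group_b]
  if (length(a_samples) == 0L) stop("group not found in design: ", group_a)
  if (length(b_samples) == 0L) stop("group not found in design: ", group_b)
  expr <- counts + pseudocount
  if (any(expr <= 0)) stop("expression must be strictly positive after pseudocount")

  if (mode == "all-pairs") {
    pairs <- expand.grid(a = a_samples, b = b_samples,
                         stringsAsFactors = FALSE)
  } else {
    if (length(a_samples) != length(b_samples))
      stop("paired mode needs equal group sizes")
    pairs <- data.frame(a = a_samples, b = b_samples,
                        stringsAsFactors = FALSE)
  }
  k <- nrow(pairs)
  G <- nrow(expr)
  fc <- log2(expr[, pairs$b, drop = FALSE]) - log2(expr[, pairs$a, drop = FALSE])
  rank_up <- apply(fc, 2, function(v) rank(-v, ties.method = "average"))
  rank_down <- apply(fc, 2, function(v) rank(v, ties.method = "average"))
  rank_up <- matrix(rank_up, nrow = G)
  rank_down <- matrix(rank_down, nrow = G)
  rp_up <- rp_geomean(rank_up)
  rp_down <- rp_geomean(rank_down)

  null_rp <- with_seed_(seed, {
    vapply(seq_len(n_permutations), function(p) {
      rmat <- vapply(seq_len(k), function(j) sample.int(G), integer(G))
      rp_geomean(matrix(rmat, nrow = G))
    }, numeric(G))
  })
  null_sorted <- sort(as.numeric(null_rp))
  exp_up <- findInterval(rp_up, null_sorted) / n_permutations
  exp_down <- findInterval(rp_down, null_sorted) / n_permutations
  obs_rank_up <- rank(rp_up, ties.method = "max")
  obs_rank_down <- rank(rp_down, ties.method = "max")

  ids <- rownames(counts)
  if (is.null(ids)) ids <- sprintf("gene_%04d", seq_len(G))
  out <- data.frame(gene_id = ids,
                    rp_up = rp_up, rp_down = rp_down,
                    pfp_up = exp_up / obs_rank_up,
                    pfp_down = exp_down / obs_rank_down,
                    mean_log2fc = rowMeans(fc),
                    stringsAsFactors = FALSE)
  attr(out, "n_permutations") <- as.integer(n_permutations)
  attr(out, "n_comparisons") <- k
  out
}

#' Extract up/down gene sets from a rank-product result
#'
#' Each gene is first assigned to its better direction (the smaller rank
#' product; exact ties resolved by the sign of the mean log2 fold change),
#' then kept if its pfp in that direction is below `pfp_cutoff`. The two
#' sets are therefore always disjoint.
#'
#' @param de result of [rank_product()].
#' @param pfp_cutoff pfp threshold (default 0.05); `Inf` assigns every gene
#'   to its better direction, `0` returns empty sets.
#' @return `list(up = <ids>, down = <ids>)`.
#' @export
extract_gene_sets <- function(de, pfp_cutoff = 0.05) {
  stopifnot(is.data.frame(de), pfp_cutoff >= 0)
  up_dir <- de$rp_up < de$rp_down |
    (de$rp_up == de$rp_down & de$mean_log2fc >= 0)
  list(up = de$gene_id[up_dir & de$pfp_up < pfp_cutoff],
       down = de$gene_id[!up_dir & de$pfp_down < pfp_cutoff])
}
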