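#' Rescale each gene to median 1
#'
#' Divides every gene (row) of a cohort expression table by its median so
#' that the per-gene median is exactly 1. Genes whose median is not
#' positive cannot be rescaled and are dropped with a warning.
#'
#' @param expr numeric genes x samples matrix (rownames = gene ids).
#' @return The rescaled matrix, possibly with fewer rows.
#' @export
median_rescale <- function(expr) {
  expr <- as.matrix(expr)
  med <- apply(expr, 1, stats::median)
  bad <- !(med > 0)
  if (any(bad)) {
    warning(sum(bad), " gene(s) with non-positive median excluded from rescaling: ",
            paste(utils::head(rownames(expr)[bad], 5), collapse = ", "))
    expr <- expr[!bad, , drop = FALSE]
    med <- med[!bad]
  }
  expr / med
}

#' Metagene panel score
#'
#' The per-sample score of a gene panel: the median, across panel genes, of
#' the median-rescaled expression in that sample.
#'
#' @param expr rescaled genes x samples matrix (see [median_rescale()]).
#' @param panel character vector of panel gene ids (unique, non-empty).
#' @return Named numeric vector of per-sample scores.
#' @export
panel_score <- function(expr, panel) {
  expr <- as.matrix(expr)
  if (length(panel) == 0L) stop("panel is empty")
  if (anyDuplicated(panel)) stop("panel gene ids must be unique")
  present <- intersect(panel, rownames(expr))
  if (length(present) == 0L) stop("no panel gene present in the expression table")
  if (length(present) < length(panel))
    warning("panel gene(s) missing from the table: ",
            paste(setdiff(panel, present), collapse = ", "))
  apply(expr[present, , drop = FALSE], 2, stats::median)
}

#' Spearman correlation of a query gene with a metagene score
#'
#' Computes Spearman's rho on average ranks and a two-tailed p-value: exact
#' permutation p for n <= 9 without ties (via [stats::cor.test()]'s exact
#' method), otherwise the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom.
#'
#' @param query per-sample expression of the query gene.
#' @param scores per-sample panel scores, same length/order.
#' @return A list of class `"signature_result"`: `rho`, `p_two_tailed`,
#'   `n_samples`, `method`.
#' @export
correlate_signature <- function(query, scores) {
  if (length(query) != length(scores))
    stop("`query` and `scores` must have equal length")
  ok <- is.finite(query) & is.finite(scores)
  query <- query[ok]; scores <- scores[ok]
  n <- length(query)
  if (n < 5L) stop("need at least 5 paired samples")
  if (stats::sd(query) == 0 || stats::sd(scores) == 0)
    stop("constant input: Spearman's rho is undefined")
  rq <- rank(query); rs <- rank(scores)
  rho <- stats::cor(rq, rs)
  ties <- anyDuplicated(query) > 0L || anyDuplicated(scores) > 0L
  if (n <= 9L && !ties) {
    p <- stats::cor.test(query, scores, method = "spearman",
                         exact = TRUE)$p.value
    method <- "exact"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    method <- "t-approximation"
  }
  structure(list(rho = rho, p_two_tailed = p, n_samples = n, method = method),
            class = "signature_result")
}

#' @export
print.signature_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4f (n = %d, two-tailed p = %.3g, %s)\n",
              x$rho, x$n_samples, x$p_two_tailed, x$method))
  invisible(x)
}

#' Full metagene signature analysis of a cohort table
#'
#' Rescales the cohort (per-gene median to 1), scores the panel per sample,
#' and correlates the query gene's rescaled expression with the score.
#'
#' @param expr raw genes x samples cohort matrix.
#' @param panel panel gene ids.
#' @param query_gene id of the query gene (must be in `expr`).
#' @return A `"signature_result"` with the per-sample `scores` attached.
#' @export
signature_analysis <- function(expr, panel, query_gene) {
  expr <- as.matrix(expr)
  if (!query_gene %in% rownames(expr))
    stop("query gene not in the expression table: ", query_gene)
  resc <- median_rescale(expr)
  if (!query_gene %in% rownames(resc))
    stop("query gene was excluded by median rescaling: ", query_gene)
  scores <- panel_score(resc, setdiff(panel, query_gene))
  res <- correlate_signature(resc[query_gene, ], scores)
  res$scores <- scores
  res
}
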