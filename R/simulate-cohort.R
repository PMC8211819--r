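#' Simulate a cohort expression table with a target query-panel correlation
#'
#' Emulates a tumour-cohort RNA-seq table containing a query gene (named
#' `SETX`), a 6-gene panel (named after the hypoxia-associated p53 target
#' panel: BTG2, CYFIP2, INPP5D, KANK3, PHLDA3, SULF2) and unrelated
#' background genes. The query-vs-panel association is induced through a
#' Gaussian copula: two latent normals with Pearson correlation
#' `r = 2 * sin(pi * rho_S / 6)` (the inverse of
#' `rho_S = (6 / pi) * asin(r / 2)`), transformed through strictly
#' monotone log-normal marginals, so the Spearman correlation between the
#' query gene and the panel median hits `cohort_rho` analytically. All six
#' panel genes are driven by the same latent factor with gene-specific
#' marginals; `cohort_rho = 1` therefore recovers rho = 1 exactly after
#' rank transformation.
#'
#' @param config a [sim_config()] (`cohort_n`, `cohort_rho`,
#'   `cohort_n_background`).
#' @return A list: `expr` (genes x samples matrix), `panel` (panel gene
#'   ids), `query_gene`, `true_rho`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  panel <- c("BTG2", "CYFIP2", "INPP5D", "KANK3", "PHLDA3", "SULF2")
  with_seed_(derive_seed(config$seed, 4L), {
    n <- config$cohort_n
    r <- 2 * sin(pi * config$cohort_rho / 6)
    z1 <- stats::rnorm(n)
    z2 <- r * z1 + sqrt(max(0, 1 - r^2)) * stats::rnorm(n)
    query <- stats::qlnorm(stats::pnorm(z1), meanlog = log(10), sdlog = 0.8)
    meanlogs <- log(stats::runif(length(panel), 5, 50))
    sdlogs <- stats::runif(length(panel), 0.5, 1.2)
    panel_expr <- t(vapply(seq_along(panel), function(j)
      stats::qlnorm(stats::pnorm(z2), meanlog = meanlogs[j], sdlog = sdlogs[j]),
      numeric(n)))
    nb <- config$cohort_n_background
    bg <- matrix(stats::rlnorm(nb * n, meanlog = log(20), sdlog = 1), nrow = nb)
    expr <- rbind(matrix(query, nrow = 1), panel_expr, bg)
    rownames(expr) <- c("SETX", panel, sprintf("BG%03d", seq_len(nb)))
    colnames(expr) <- sprintf("sample_%03d", seq_len(n))
    list(expr = expr, panel = panel, query_gene = "SETX",
         true_rho = config$cohort_rho)
  })
}
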