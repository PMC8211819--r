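#' Simulate bench-assay tables with known effect sizes
#'
#' Produces three small tables emulating the quantified wet-lab readouts:
#'
#' * `fibre`: per-track IdU lengths (pixels) and pulse durations for four
#'   conditions (control/knockdown x normoxia/hypoxia) with log-normal
#'   track-length noise around condition means corresponding to true rates
#'   of 1.5 / 1.3 / 0.8 / 0.5 kb/min (knockdown slows forks, more so in
#'   hypoxia). Pulse durations follow [fibre_pulse_minutes()].
#' * `ct`: qPCR Ct values (target vs 18S reference) for control and
#'   treated conditions with a planted `ct_fold_change` and Gaussian Ct
#'   noise `ct_noise_sd`.
#' * `foci`: per-cell focus counts for control and treated conditions; the
#'   number of positive cells (count > 5) in the treated condition is a
#'   binomial draw at `foci_positive_fraction` (control at 0.05).
#'
#' @param config a [sim_config()].
#' @return A list of data.frames `fibre`, `ct`, `foci`, plus `truth`
#'   (planted rates, fold change and foci fractions).
#' @export
simulate_assay_tables <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_(derive_seed(config$seed, 5L), {
    rates <- c(siCTRL_norm = 1.5, siSETX_norm = 1.3,
               siCTRL_hyp = 0.8, siSETX_hyp = 0.5)
    pulse <- c(siCTRL_norm = fibre_pulse_minutes("normoxia"),
               siSETX_norm = fibre_pulse_minutes("normoxia"),
               siCTRL_hyp = fibre_pulse_minutes("hypoxia"),
               siSETX_hyp = fibre_pulse_minutes("hypoxia"))
    nt <- config$fibre_n_tracks
    fibre <- do.call(rbind, lapply(names(rates), function(cond) {
      x_mean <- rates[[cond]] * pulse[[cond]] / (0.132 * 2.59)
      data.frame(track_id = paste0(cond, "_t", seq_len(nt)),
                 condition = cond,
                 x_pixels = stats::rlnorm(nt, log(x_mean), 0.3),
                 t_minutes = pulse[[cond]],
                 stringsAsFactors = FALSE)
    }))

    nr <- config$ct_replicates
    base_target <- 24; base_ref <- 12
    ct <- data.frame(
      sample = c(paste0("control_", seq_len(nr)), paste0("treated_", seq_len(nr))),
      condition = rep(c("control", "treated"), each = nr),
      target_gene = "TARGET1", ref_gene = "18S",
      ct_target = c(base_target + stats::rnorm(nr, 0, config$ct_noise_sd),
                    base_target - log2(config$ct_fold_change) +
                      stats::rnorm(nr, 0, config$ct_noise_sd)),
      ct_ref = base_ref + stats::rnorm(2 * nr, 0, config$ct_noise_sd),
      stringsAsFactors = FALSE)

    nc <- config$foci_n_cells
    foci_fracs <- c(control = 0.05, treated = config$foci_positive_fraction)
    foci <- do.call(rbind, lapply(names(foci_fracs), function(cond) {
      n_pos <- stats::rbinom(1L, nc, foci_fracs[[cond]])
      cnt <- c(6L + stats::rpois(n_pos, 3),
               sample(0:5, nc - n_pos, replace = TRUE,
                      prob = c(0.35, 0.25, 0.16, 0.1, 0.08, 0.06)))
      data.frame(cell_id = paste0(cond, "_c", seq_len(nc)),
                 condition = cond, marker = "53BP1",
                 foci_count = sample(cnt),
                 stringsAsFactors = FALSE)
    }))
    list(fibre = fibre, ct = ct, foci = foci,
         truth = list(fibre_rates = rates,
                      ct_fold_change = config$ct_fold_change,
                      foci_fractions = foci_fracs))
  })
}
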