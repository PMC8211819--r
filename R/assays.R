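#' DNA fibre replication rate
#'
#' Converts an IdU tract length in pixels to a replication rate:
#' `V (kb/min) = (x * um_per_pixel * kb_per_um) / t`, with the default
#' microscope calibration of 0.132 um per pixel and 2.59 kb per um.
#'
#' @param x IdU segment length(s), pixels (>= 0).
#' @param t IdU pulse duration(s), minutes (> 0). See
#'   [fibre_pulse_minutes()] for the standard pulse schemes.
#' @param um_per_pixel,kb_per_um calibration constants.
#' @return Replication rate(s), kb/min.
#' @export
fibre_rate <- function(x, t, um_per_pixel = 0.132, kb_per_um = 2.59) {
  if (any(!is.finite(x)) || any(x < 0)) stop("`x` must be non-negative and finite")
  if (any(!is.finite(t)) || any(t <= 0)) stop("pulse duration `t` must be positive")
  (x * um_per_pixel * kb_per_um) / t
}

#' Standard fibre-labelling pulse durations
#'
#' Named presets for the second (IdU) pulse length: 20 min under normoxia,
#' 60 min under hypoxia (where labelling is slowed and pulses lengthened).
#' Storing these as presets prevents silent unit errors between conditions.
#'
#' @param condition `"normoxia"` or `"hypoxia"`.
#' @return Pulse duration in minutes.
#' @export
fibre_pulse_minutes <- function(condition = c("normoxia", "hypoxia")) {
  condition <- match.arg(condition)
  c(normoxia = 20, hypoxia = 60)[[condition]]
}

#' Delta-delta-Ct relative fold change
#'
#' Livak quantification of qPCR data: replicate Ct values are averaged per
#' condition, `dCt = Ct_target - Ct_reference` within each condition,
#' `ddCt = dCt_treated - dCt_control`, and the relative mRNA fold change is
#' `2^-ddCt`.
#'
#' @param ct a data.frame with columns `condition` (values `"control"` and
#'   `"treated"`), `ct_target`, `ct_ref`, and optionally `target_gene` /
#'   `ref_gene` (which must then each be a single gene).
#' @return A list: `fold_change`, `ddct`, and the per-condition mean dCt.
#' @export
ddct_fold_change <- function(ct) {
  stopifnot(is.data.frame(ct),
            all(c("condition", "ct_target", "ct_ref") %in% names(ct)))
  if (!all(c("control", "treated") %in% ct$condition))
    stop("`ct` must contain both a 'control' and a 'treated' condition")
  for (col in c("target_gene", "ref_gene"))
    if (col %in% names(ct) && length(unique(ct[[col]])) > 1L)
      stop("mismatched genes in column `", col, "`; ddCt needs one target and one reference")
  dct <- tapply(ct$ct_target - ct$ct_ref, ct$condition, mean)
  ddct <- unname(dct[["treated"]] - dct[["control"]])
  list(fold_change = 2^(-ddct), ddct = ddct, dct = dct)
}

#' Fraction of focus-positive cells
#'
#' Percentage of cells whose focus count exceeds a threshold, e.g. cells
#' displaying more than 5 53BP1 foci per nucleus. The default is a strict
#' inequality: a cell with exactly `threshold` foci is not positive.
#'
#' @param counts integer per-cell focus counts (>= 0), at least one cell.
#' @param threshold focus-count threshold (default 5).
#' @param strict use `count > threshold` (default) rather than `>=`.
#' @return Percentage of positive cells in \[0, 100\].
#' @export
foci_positive_fraction <- function(counts, threshold = 5, strict = TRUE) {
  if (length(counts) == 0L) stop("empty foci table")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("foci counts must be non-negative integers")
  pos <- if (strict) counts > threshold else counts >= threshold
  100 * mean(pos)
}
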