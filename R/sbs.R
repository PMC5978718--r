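## Bleaching-score summaries: the Standardized Bleach Score and the
## population-level proportion bleached.

#' Standardized Bleach Score
#'
#' `SBS = BS_treatment - BS_control`, the per-thallus change in ordinal
#' Bleaching Score (1 = none, 2 = partial, 3 = full) at one treatment level
#' relative to its control apex. Ranges over -2..2; positive values mean the
#' treatment bleached the thallus beyond its control.
#'
#' @param bs_trt,bs_ctrl Integer scores in `{1, 2, 3}` (vectorised).
#' @return Integer vector in `[-2, 2]`.
#' @export
compute_sbs <- function(bs_trt, bs_ctrl) {
  if (any(!bs_trt %in% 1:3) || any(!bs_ctrl %in% 1:3)) {
    stop("Bleaching Scores must be 1, 2 or 3")
  }
  as.integer(bs_trt) - as.integer(bs_ctrl)
}

#' Proportion of thalli bleached
#'
#' The fraction of Standardized Bleach Scores greater than zero — the
#' population-level summary plotted against treatments and used as the
#' trait value for evolutionary-rate estimates.
#'
#' @param sbs Numeric vector of SBS values (nonempty).
#' @return Fraction in `[0, 1]`.
#' @export
proportion_bleached <- function(sbs) {
  if (length(sbs) == 0) stop("no SBS values")
  mean(sbs > 0)
}
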