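# Small self-contained assay calculators: double point-mutation rate
# bound, GCR frequency, qPCR cut efficiency (delta-delta-Ct) and DSB
# survival rate.

#' Double point-mutation rate bound for the two-marker cassette
#'
#' The GCR assay selects for simultaneous loss of two markers; its
#' specificity rests on simultaneous point mutation of both being
#' vanishingly rare. From the total spontaneous 5-FOA-resistance rate
#' and the ura5/ura4 mutation ratio, the inactivating rate of the first
#' marker is `total / (ratio + 1)`; scaling by ORF length gives the
#' second marker's rate, and their product bounds the double-mutation
#' rate (an order-of-magnitude bound, ~1e-14 per cell division at the
#' defaults).
#'
#' @param total_foa_resistance_rate Total spontaneous 5-FOA-resistance
#'   mutation rate per cell division (default 1.3e-7).
#' @param ura5_over_ura4_ratio Ratio of ura5 to ura4 mutations among
#'   5-FOA-resistant clones (default 1.85).
#' @param orf_len_ura4,orf_len_tk ORF lengths in bp (defaults 800 and
#'   1100).
#' @return A list with `rate_ura4`, `rate_tk` and `joint_rate` (the
#'   order-of-magnitude bound on simultaneous mutation).
#' @examples
#' signif(double_mutation_rates()$rate_ura4, 2)  # 4.6e-8
#' @export
double_mutation_rates <- function(total_foa_resistance_rate = 1.3e-7,
                                  ura5_over_ura4_ratio = 1.85,
                                  orf_len_ura4 = 800,
                                  orf_len_tk = 1100) {
  stopifnot(total_foa_resistance_rate > 0, ura5_over_ura4_ratio > 0,
            orf_len_ura4 > 0, orf_len_tk > 0)
  rate_ura4 <- total_foa_resistance_rate / (ura5_over_ura4_ratio + 1)
  rate_tk <- rate_ura4 * (orf_len_tk / orf_len_ura4)
  list(rate_ura4 = rate_ura4, rate_tk = rate_tk,
       joint_rate = rate_ura4 * rate_tk)
}

#' GCR frequency from plated colony counts
#'
#' Frequency of GCR-carrying (doubly resistant) cells among plated
#' cells, optionally corrected for plating viability measured on
#' non-selective plates.
#'
#' @param selective_count Colonies on the selective plate (>= 0).
#' @param cells_plated_selective Cells plated on the selective plate
#'   (> 0).
#' @param nonselective_count,cells_plated_nonselective Optional paired
#'   non-selective plating for a viability correction.
#' @return Dimensionless frequency.
#' @examples
#' gcr_frequency(50, 1e7)  # 5e-6
#' @export
gcr_frequency <- function(selective_count, cells_plated_selective,
                          nonselective_count = NULL,
                          cells_plated_nonselective = NULL) {
  if (any(cells_plated_selective <= 0))
    stop("'cells_plated_selective' must be > 0")
  freq <- selective_count / cells_plated_selective
  if (!is.null(nonselective_count)) {
    if (is.null(cells_plated_nonselective) ||
        any(cells_plated_nonselective <= 0))
      stop("'cells_plated_nonselective' must be > 0")
    if (any(nonselective_count <= 0))
      stop("'nonselective_count' must be > 0 for a viability correction")
    freq <- freq / (nonselective_count / cells_plated_nonselective)
  }
  freq
}

#' qPCR cut efficiency from delta-delta-Ct
#'
#' Fraction of template cut at an endonuclease site, from quantitative
#' PCR across the site relative to an uncut control amplicon:
#' `relative_intact = efficiency^-ddCt` with
#' `ddCt = (Ct_target - Ct_control)_treated -
#'         (Ct_target - Ct_control)_untreated`,
#' and `cut_fraction = 1 - relative_intact` clamped to `[0, 1]`.
#' The control amplicon is any reference locus not subject to cutting;
#' the amplification efficiency defaults to perfect doubling (2 per
#' cycle).
#'
#' @param ct_target_treated,ct_control_treated Ct values after
#'   induction.
#' @param ct_target_untreated,ct_control_untreated Ct values without
#'   induction.
#' @param efficiency Fold amplification per cycle, in (1, 2].
#' @return A list with `relative_intact_fraction`, `cut_fraction` and
#'   `delta_delta_ct`.
#' @examples
#' cut_efficiency(21.15, 20, 20, 20)$cut_fraction  # ~0.55
#' @export
cut_efficiency <- function(ct_target_treated, ct_control_treated,
                           ct_target_untreated, ct_control_untreated,
                           efficiency = 2) {
  cts <- c(ct_target_treated, ct_control_treated,
           ct_target_untreated, ct_control_untreated)
  if (any(cts <= 0)) stop("Ct values must be positive")
  if (efficiency <= 1 || efficiency > 2)
    stop("'efficiency' must be in (1, 2]")
  ddct <- (ct_target_treated - ct_control_treated) -
    (ct_target_untreated - ct_control_untreated)
  intact <- efficiency^(-ddct)
  list(relative_intact_fraction = intact,
       cut_fraction = min(max(1 - intact, 0), 1),
       delta_delta_ct = ddct)
}

#' Survival rate after DSB induction
#'
#' Percentage of colony-forming cells after treatment relative to the
#' untreated control, with an optional dilution correction.
#'
#' @param colonies_treated Colony count after treatment (>= 0).
#' @param colonies_untreated Colony count without treatment (> 0).
#' @param dilution_correction Multiplicative correction for unequal
#'   platings (default 1).
#' @return Survival in percent.
#' @examples
#' survival_rate(62, 100)  # 62
#' @export
survival_rate <- function(colonies_treated, colonies_untreated,
                          dilution_correction = 1) {
  if (any(colonies_untreated <= 0))
    stop("'colonies_untreated' must be > 0")
  100 * (colonies_treated / colonies_untreated) * dilution_correction
}
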