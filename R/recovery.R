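# Parameter recovery on synthetic arrays: the headline effect sizes
# re-estimated from a fresh simulation by the full analysis path.

#' Re-estimate the headline binding effects from simulated arrays
#'
#' Runs the array analysis end to end on freshly simulated data under
#' the study conditions (full design, 40-replicate SNP panels, four
#' sectors, two replicate arrays per condition, 30% spot noise):
#' simulate GABPa-only and GABPa+CREB1 scans, normalise on
#' CRE-disrupted core probes, estimate the background, summarise the
#' SNP panels and compute the recovered effect sizes.
#'
#' @param seed Integer seed for the simulated scans.
#' @param config [sim_config()] describing the generative model.
#' @param design [design_params()] for the array; genomic blocks are
#'   not needed.
#' @param sectors,arrays Sectors and replicate arrays per condition.
#' @return One-row tibble: `consensus_coop` (CREB1 enhancement of the
#'   canonical motif), `max_snp_coop` (largest cooperativity ratio over
#'   the 48 CC-panel SNPs), `cc_gc_ratio` (strong/weak consensus
#'   ratio), `max_core_fold` (largest consensus/SNP fold reduction over
#'   the nine GGA-core SNPs), `core_coop` (mean cooperativity ratio of
#'   the GGA-core SNPs), and `n_spots` (spots simulated per condition).
#' @export
estimate_panel_effects <- function(seed = 1L, config = sim_config(),
                                   design = design_params(),
                                   sectors = 1:4, arrays = 2L) {
  design <- build_design(design)
  seeds <- derive_seeds(seed, 2L)
  spots <- dplyr::bind_rows(
    simulate_array(design, "8:0", config, sectors = sectors,
                   arrays = arrays, seed = seeds[1]),
    simulate_array(design, "8:8", config, sectors = sectors,
                   arrays = arrays, seed = seeds[2])
  )
  norm <- normalize_conditions(spots)
  bg <- estimate_background(norm)
  bg_of <- function(cond) bg$background[bg$condition == cond]

  p_cc_minus <- summarize_snp_panel(filter(norm, .data$condition == "8:0"),
                                    ETS_CRE_CC)
  p_cc_plus <- summarize_snp_panel(filter(norm, .data$condition == "8:8"),
                                   ETS_CRE_CC)
  p_gc_minus <- summarize_snp_panel(filter(norm, .data$condition == "8:0"),
                                    ETS_CRE_GC)

  fc <- snp_fold_change(p_cc_minus, background = bg_of("8:0"))
  cr <- cooperativity_ratio(p_cc_plus, p_cc_minus,
                            background_plus = bg_of("8:8"),
                            background_minus = bg_of("8:0"))
  cc_gc <- (p_cc_minus$median[p_cc_minus$role == "consensus"] - bg_of("8:0")) /
    (p_gc_minus$median[p_gc_minus$role == "consensus"] - bg_of("8:0"))

  tibble(
    consensus_coop = cr$coop_ratio[cr$role == "consensus"],
    max_snp_coop = max(cr$coop_ratio[cr$role == "snp"]),
    cc_gc_ratio = cc_gc,
    max_core_fold = max(fc$fold_change[fc$position %in% 3:5]),
    core_coop = mean(cr$coop_ratio[!is.na(cr$position) &
                                     cr$position %in% 3:5]),
    n_spots = nrow(spots) / 2
  )
}
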