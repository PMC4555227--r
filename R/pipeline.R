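# End-to-end pipeline: design -> simulate -> analyse -> models ->
# toy genome -> enrichment -> cooperative calls.

#' Extract region sequences from a genome
#'
#' @param genome Genome (see [read_genome()]).
#' @param regions Region tibble (`contig`, `start`, `end`, optional
#'   `name`), 1-based closed.
#' @return Named character vector of region sequences.
#' @export
region_sequences <- function(genome, regions) {
  gen <- read_genome(genome)
  bad <- !regions$contig %in% names(gen)
  if (any(bad)) abort("regions reference contigs absent from the genome")
  seqs <- substring(gen[regions$contig], regions$start, regions$end)
  names(seqs) <- regions$name %||%
    sprintf("%s:%d-%d", regions$contig, regions$start, regions$end)
  seqs
}

#' Pipeline configuration
#'
#' Collects every stage parameter of [run_pipeline()] under one seeded
#' configuration. Defaults reproduce the published study conditions:
#' the full array design (40-replicate SNP panels), four sectors and two
#' replicate arrays per condition, 30% spot noise, and the GABPa-only
#' (`"8:0"`) vs GABPa+CREB1 (`"8:8"`) condition pair.
#'
#' @param seed Global seed; per-stage seeds are derived from it.
#' @param design [design_params()] for the array.
#' @param sim [sim_config()] for the intensity model.
#' @param condition_minus,condition_plus Condition labels without / with
#'   CREB1.
#' @param sectors,arrays Sectors and replicate arrays per condition.
#' @param genome Named list of arguments for [simulate_genome_peaks()].
#' @param fdr_coop,fdr_single Caller thresholds.
#' @return A list of class `etscre_pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            design = design_params(),
                            sim = sim_config(),
                            condition_minus = "8:0",
                            condition_plus = "8:8",
                            sectors = 1:4,
                            arrays = 2L,
                            genome = list(),
                            fdr_coop = 0.05,
                            fdr_single = 0.15) {
  structure(list(seed = as.integer(seed), design = design, sim = sim,
                 condition_minus = condition_minus,
                 condition_plus = condition_plus,
                 sectors = sectors, arrays = as.integer(arrays),
                 genome = genome, fdr_coop = fdr_coop,
                 fdr_single = fdr_single),
            class = "etscre_pipeline_config")
}

#' Run the full analysis pipeline on synthetic data
#'
#' Chains the stages end to end: build the array design; simulate
#' GABPa-only and GABPa+CREB1 arrays; normalise conditions on
#' CRE-disrupted core probes and estimate the background; summarise the
#' CC and GC SNP panels per condition; compute SNP fold changes,
#' cooperativity ratios and the consensus enhancement test; build
#' cooperative (+CREB1) and single-protein (-CREB1) energy models from
#' the panels; simulate a toy genome with planted sites; profile motif
#' enrichment in the peak groups; and call cooperative regions in the
#' co-bound peak set. Identical configurations (including the seed)
#' give identical outputs.
#'
#' @param config An [pipeline_config()].
#' @param out_dir Optional directory; key tables, model matrices, FASTA
#'   and BED files, the resolved configuration and an md5 manifest are
#'   written there.
#' @return Named list of stage outputs.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "etscre_pipeline_config"))
  seeds <- derive_seeds(config$seed, 5L)
  design <- build_design(config$design)

  spots <- dplyr::bind_rows(
    simulate_array(design, config$condition_minus, config$sim,
                   sectors = config$sectors, arrays = config$arrays,
                   seed = seeds[1]),
    simulate_array(design, config$condition_plus, config$sim,
                   sectors = config$sectors, arrays = config$arrays,
                   seed = seeds[2])
  )
  norm <- normalize_conditions(spots)
  background <- estimate_background(norm)
  bg_of <- function(cond) {
    background$background[background$condition == cond]
  }

  conds <- c(minus = config$condition_minus, plus = config$condition_plus)
  motifs <- c(CC = ETS_CRE_CC, GC = ETS_CRE_GC)
  panels <- purrr::map(conds, function(cond) {
    purrr::map(motifs, function(m) {
      summarize_snp_panel(filter(norm, .data$condition == cond), m)
    })
  })

  fold_changes <- purrr::imap(panels$minus, function(p, nm) {
    snp_fold_change(p, background = bg_of(config$condition_minus))
  })
  coop_ratios <- purrr::imap(panels$plus, function(p, nm) {
    cooperativity_ratio(p, panels$minus[[nm]],
                        background_plus = bg_of(config$condition_plus),
                        background_minus = bg_of(config$condition_minus))
  })
  enhancement <- consensus_enhancement_test(panels$plus$CC, panels$minus$CC)
  strong_weak <- strong_weak_ratio(panels$minus$CC, panels$minus$GC,
                                   background = bg_of(config$condition_minus),
                                   n_boot = 1000L, seed = seeds[5])

  # caller models come from the canonical (CC) composite panel of each
  # condition; the weak-motif panel feeds the strong/weak comparison,
  # not the caller (its S_max is the position-1 variant, which makes
  # the derived matrix too sharp to rank a decoy continuum)
  models <- list(
    coop = list(CC_plus_creb1 = build_pwm_from_panel(
      panels$plus$CC, name = "CC_plus_creb1")),
    single = list(CC_gabpa_only = build_pwm_from_panel(
      panels$minus$CC, name = "CC_gabpa_only"))
  )

  genome_sim <- do.call(simulate_genome_peaks,
                        c(config$genome, list(seed = seeds[3])))
  enrichment <- snp_enrichment_profile(genome_sim$genome,
                                       genome_sim$gabpa_peaks,
                                       genome_sim$creb1_peaks)
  groups <- split_peak_groups(genome_sim$gabpa_peaks,
                              genome_sim$creb1_peaks)
  cobound_seqs <- region_sequences(genome_sim$genome, groups$plus)
  calls <- call_cooperative(cobound_seqs, models$coop, models$single,
                            fdr_coop = config$fdr_coop,
                            fdr_single = config$fdr_single,
                            seed = seeds[4])

  res <- list(design = design, spots = norm, background = background,
              panels = panels, fold_changes = fold_changes,
              coop_ratios = coop_ratios, enhancement = enhancement,
              strong_weak = strong_weak,
              models = models, genome_sim = genome_sim,
              enrichment = enrichment, peak_groups = groups, calls = calls,
              config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

drop_list_cols <- function(x) x[, !vapply(x, is.list, logical(1))]

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_design(res$design, p("design.tsv"))
  readr::write_tsv(res$background, p("background.tsv"))
  for (side in names(res$panels)) {
    for (nm in names(res$panels[[side]])) {
      readr::write_tsv(drop_list_cols(res$panels[[side]][[nm]]),
                       p(sprintf("panel_%s_%s.tsv", nm, side)))
    }
  }
  for (nm in names(res$fold_changes)) {
    readr::write_tsv(res$fold_changes[[nm]], p(sprintf("fold_%s.tsv", nm)))
  }
  for (nm in names(res$coop_ratios)) {
    readr::write_tsv(res$coop_ratios[[nm]], p(sprintf("coop_ratio_%s.tsv", nm)))
  }
  for (side in names(res$models)) {
    for (nm in names(res$models[[side]])) {
      write_motif_matrix(res$models[[side]][[nm]],
                         p(sprintf("model_%s_%s.txt", side, nm)))
    }
  }
  write_genome_fasta(res$genome_sim$genome, p("genome.fa"))
  write_bed(res$genome_sim$gabpa_peaks, p("gabpa_peaks.bed"))
  write_bed(res$genome_sim$creb1_peaks, p("creb1_peaks.bed"))
  readr::write_tsv(res$genome_sim$truth, p("truth.tsv"))
  readr::write_tsv(res$strong_weak, p("strong_weak.tsv"))
  readr::write_tsv(res$enrichment, p("enrichment.tsv"))
  readr::write_tsv(as_tibble(res$calls), p("calls.tsv"))
  cfg <- res$config
  yaml::write_yaml(list(
    seed = cfg$seed,
    condition_minus = cfg$condition_minus,
    condition_plus = cfg$condition_plus,
    sectors = cfg$sectors, arrays = cfg$arrays,
    fdr_coop = cfg$fdr_coop, fdr_single = cfg$fdr_single,
    noise_cv = cfg$sim$noise_cv, background = cfg$sim$background,
    scale = cfg$sim$scale, flag_rate = cfg$sim$flag_rate,
    gamma_table = as.list(cfg$sim$gamma_table),
    genome = cfg$genome
  ), p("config.yaml"))
  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   p("manifest.tsv"))
  manifest <- tibble(file = basename(files),
                     md5 = unname(tools::md5sum(files)))
  readr::write_tsv(manifest, p("manifest.tsv"))
  invisible(out_dir)
}
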