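# Shared fixtures, built lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

cache_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# full published design (134,992 probes; genomic blocks omitted)
full_design <- function() {
  cache_fixture("full_design", function() build_design(design_params()))
}

# SNP-panel probes only (3,920 probes) — enough for panel analytics
snp_design <- function() {
  cache_fixture("snp_design", function() {
    dplyr::filter(full_design(), grepl("^snp", category))
  })
}

# noise-free, flag-free model configuration
noiseless_config <- function(...) {
  sim_config(noise_cv = 0, flag_rate = 0, ...)
}

# spot tables for the two conditions at study settings (4 sectors x 2
# arrays, 30% CV), SNP probes only
snp_spots <- function() {
  cache_fixture("snp_spots", function() {
    cfg <- sim_config()
    dplyr::bind_rows(
      simulate_array(snp_design(), "8:0", cfg, sectors = 1:4, arrays = 2,
                     seed = 101),
      simulate_array(snp_design(), "8:8", cfg, sectors = 1:4, arrays = 2,
                     seed = 102)
    )
  })
}

# caller model pair built from the SNP spot tables
caller_models <- function() {
  cache_fixture("caller_models", function() {
    sp <- snp_spots()
    list(
      coop = list(CC_plus = build_pwm_from_panel(
        summarize_snp_panel(dplyr::filter(sp, condition == "8:8"),
                            ETS_CRE_CC), name = "CC_plus")),
      single = list(CC_minus = build_pwm_from_panel(
        summarize_snp_panel(dplyr::filter(sp, condition == "8:0"),
                            ETS_CRE_CC), name = "CC_minus"))
    )
  })
}

# brute-force dinucleotide counter (test oracle)
dinuc_counts <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  sort(table(paste0(head(ch, -1), tail(ch, -1))))
}

# brute-force forward-strand motif scan (test oracle)
brute_match_positions <- function(seq, motif) {
  L <- nchar(motif)
  n <- nchar(seq)
  if (n < L) return(integer())
  starts <- seq_len(n - L + 1L)
  starts[substring(seq, starts, starts + L - 1L) == motif]
}

# one shared recovery run of the caller on the default toy genome
recovery_calls <- function() {
  cache_fixture("recovery_calls", function() {
    models <- caller_models()
    gs <- simulate_genome_peaks(seed = 33)
    grp <- split_peak_groups(gs$gabpa_peaks, gs$creb1_peaks)
    seqs <- region_sequences(gs$genome, grp$plus)
    calls <- call_cooperative(seqs, models$coop, models$single, seed = 34)
    list(calls = calls,
         merged = dplyr::left_join(tibble::as_tibble(calls), gs$truth,
                                   by = c(region = "site_id")))
  })
}
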