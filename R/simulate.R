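# Synthetic PBM generator: spot intensities with programmed affinity and
# cooperativity effects, and toy genomes with planted binding sites.

# Per-position relative affinities of the ETS 8-mer for GABPa alone,
# consensus bases = 1. Columns are motif positions 1..8 (CCGGAAGT);
# position 1 also encodes the 4-fold weaker G variant, so the same table
# serves both composite contexts multiplicatively. The GGA core
# (positions 3-5) carries reductions down to 1/27; flank positions have
# the milder, variable effects seen on the arrays.
default_ets_affinity <- function() {
  m <- matrix(1, nrow = 4, ncol = 8, dimnames = list(BASES, NULL))
  m["G", 1] <- 1 / 4;  m["A", 1] <- 1 / 10; m["T", 1] <- 1 / 20
  m["A", 2] <- 1 / 10; m["G", 2] <- 1 / 16; m["T", 2] <- 1 / 7
  m["A", 3] <- 1 / 27; m["C", 3] <- 1 / 24; m["T", 3] <- 1 / 25
  m["A", 4] <- 1 / 20; m["C", 4] <- 1 / 22; m["T", 4] <- 1 / 18
  m["C", 5] <- 1 / 15; m["G", 5] <- 1 / 12; m["T", 5] <- 1 / 10
  m["C", 6] <- 1 / 25; m["G", 6] <- 1 / 5;  m["T", 6] <- 1 / 8
  m["A", 7] <- 1 / 6;  m["C", 7] <- 1 / 18; m["T", 7] <- 1 / 7
  m["C", 8] <- 1 / 3;  m["A", 8] <- 1 / 6;  m["G", 8] <- 1 / 8
  m
}

# Cooperativity factors gamma by ETS 8-mer for sequences with an intact
# CRE half-site: consensus enhancement is 2-fold; the strongly enhanced
# flank SNPs reach 23-fold; GGA-core SNPs are enhanced 3-fold.
default_gamma_table <- function() {
  c(CCGGAAGT = 2, GCGGAAGT = 2,
    # strong cooperative flank SNPs of the CC motif
    TCGGAAGT = 20, CGGGAAGT = 18, CCGGACGT = 23, CCGGAACT = 20,
    CAGGAAGT = 7,
    # context-dependent counterparts in the GC motif
    GGGGAAGT = 8, GAGGAAGT = 17, GCGGAACT = 8, GCGGAAAT = 16,
    GCGGACGT = 12)
}

#' Configuration of the synthetic PBM intensity model
#'
#' Defines the generative model used by [expected_intensity()] and
#' [simulate_array()]. A probe's mean intensity is
#' `background + scale * a(s) * g(s, condition)`, where the relative
#' affinity `a(s)` multiplies per-position ETS mismatch effects and a
#' mild penalty per CRE-half mismatch, and the cooperativity factor
#' `g(s)` equals `gamma(s)` when CREB1 is present and the CRE half-site
#' is intact, decays toward 1 for one CRE mismatch (`cre_damage`), and is
#' 1 for two or more CRE mismatches or when CREB1 is absent. Spot
#' intensities are the mean times multiplicative log-normal noise with
#' coefficient of variation `noise_cv` and a per-sector factor.
#'
#' Defaults encode the reported effect sizes: 2-fold consensus
#' enhancement by CREB1, up to 23-fold enhancement for flank SNPs,
#' 3-fold enhancement of GGA-core SNPs, GGA-core reductions up to
#' 27-fold, and a 4-fold weaker G-variant ETS motif.
#'
#' @param ets_affinity 4 x 8 matrix (rows `A,C,G,T`) of per-position
#'   relative affinities; consensus bases must be 1.
#' @param cre_alt_affinity Multiplier on `a(s)` per CRE-half mismatch.
#' @param gamma_table Named vector of cooperativity factors by ETS 8-mer.
#' @param gamma_default,gamma_core Factors for 8-mers absent from
#'   `gamma_table`: flank SNPs / other sequences, and GGA-core SNPs.
#' @param cre_damage Scaling of `gamma - 1` for a single CRE mismatch.
#' @param noise_cv Coefficient of variation of the log-normal spot noise.
#' @param sector_factors Multiplicative per-sector biases.
#' @param background Additive baseline intensity (arbitrary units).
#' @param scale Intensity of the consensus CC composite above background
#'   in the absence of CREB1.
#' @param saturation_cap Optional ceiling on expected intensity.
#' @param flag_rate Fraction of spots flagged bad.
#' @return A list of class `etscre_sim_config`.
#' @export
sim_config <- function(ets_affinity = default_ets_affinity(),
                       cre_alt_affinity = 0.9,
                       gamma_table = default_gamma_table(),
                       gamma_default = 2,
                       gamma_core = 3,
                       cre_damage = 0.75,
                       noise_cv = 0.3,
                       sector_factors = c(1, 1, 1, 1),
                       background = 100,
                       scale = 10000,
                       saturation_cap = NULL,
                       flag_rate = 0.01) {
  stopifnot(identical(rownames(ets_affinity), BASES), ncol(ets_affinity) == 8,
            all(ets_affinity > 0), all(gamma_table > 0),
            cre_alt_affinity > 0, noise_cv >= 0,
            all(sector_factors > 0), background >= 0, scale > 0,
            flag_rate >= 0, flag_rate < 1)
  cons <- strsplit(ETS_CONSENSUS, "")[[1]]
  if (any(ets_affinity[cbind(match(cons, BASES), 1:8)] != 1)) {
    abort("consensus bases must have affinity 1 (a(consensus CC) = 1)")
  }
  structure(list(ets_affinity = ets_affinity,
                 cre_alt_affinity = cre_alt_affinity,
                 gamma_table = gamma_table, gamma_default = gamma_default,
                 gamma_core = gamma_core, cre_damage = cre_damage,
                 noise_cv = noise_cv, sector_factors = sector_factors,
                 background = background, scale = scale,
                 saturation_cap = saturation_cap, flag_rate = flag_rate),
            class = "etscre_sim_config")
}

# Align a core sequence to the composite: returns the ETS 8-mer and the
# number of observed mismatches to the CRE half-site (positions 9-16).
# Cores of panel length (<= 16) are ETS-aligned at position 1 by
# construction; longer (genomic) cores are aligned at the first
# [ACGT]CGGA anchor, failing that at the offset minimising Hamming
# distance to either composite (nearest-class fallback, reported via a
# message).
classify_core <- function(core_seq) {
  L <- nchar(core_seq)
  off <- ifelse(L <= 16L | substr(core_seq, 2L, 5L) == "CGGA", 1L,
                regexpr("CGGA", core_seq, fixed = TRUE) - 1L)
  bad <- off < 1L | off + 7L > L
  if (any(bad)) {
    inform(sprintf("%d core(s) lack a CGGA anchor; using nearest alignment",
                   sum(bad)))
    off[bad] <- vapply(which(bad), function(i) {
      offs <- seq_len(max(L[i] - 15L, 1L))
      d <- vapply(offs, function(o) {
        w <- substr(core_seq[i], o, min(o + 15L, L[i]))
        min(hamming_to(w, substr(c(ETS_CRE_CC, ETS_CRE_GC), 1, nchar(w))))
      }, numeric(1))
      offs[which.min(d)]
    }, integer(1))
  }
  ets8 <- substr(core_seq, off, off + 7L)
  cre_obs <- substr(core_seq, off + 8L, pmin(off + 15L, L))
  cre_ref <- substring("GACGTCAC", 1L, nchar(cre_obs))
  cre_mm <- mapply(function(a, b) {
    if (!nzchar(a)) return(8L)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, cre_obs, cre_ref, USE.NAMES = FALSE)
  tibble(core_seq = core_seq, ets8 = ets8, cre_mm = as.integer(cre_mm))
}

# gamma for an ETS 8-mer before CRE damage: exact table entry, else 3 for
# single GGA-core (positions 3-5) mismatches, else the default.
gamma_for_ets8 <- function(ets8, config) {
  g <- unname(config$gamma_table[ets8])
  miss <- is.na(g)
  if (any(miss)) {
    cc <- strsplit(ETS_CONSENSUS, "")[[1]]
    chars <- seq_char_matrix(ets8[miss])
    mm <- sweep(chars, 2, cc, FUN = "!=")
    mm[, 1] <- mm[, 1] & chars[, 1] != "G"  # G at position 1 is the GC context
    n_mm <- rowSums(mm)
    core_hit <- rowSums(mm[, 3:5, drop = FALSE]) > 0
    g[miss] <- ifelse(n_mm == 1 & core_hit, config$gamma_core,
                      config$gamma_default)
  }
  g
}

#' Expected spot intensity under the synthetic binding model
#'
#' @param core_seq Character vector of probe core sequences.
#' @param condition Condition label `"<gabpa>:<creb1>"` (e.g. `"8:8"`,
#'   `"8:0"`); CREB1 is present when the second amount is positive.
#' @param config An [sim_config()].
#' @return Numeric vector of expected intensities (arbitrary units).
#' @export
#' @examples
#' cfg <- sim_config()
#' expected_intensity(ETS_CRE_CC, "8:8", cfg) /
#'   expected_intensity(ETS_CRE_CC, "8:0", cfg)  # ~2-fold enhancement
expected_intensity <- function(core_seq, condition, config = sim_config()) {
  assert_dna(core_seq, what = "core_seq")
  cls <- classify_core(core_seq)
  chars <- seq_char_matrix(cls$ets8)
  a <- rep(1, length(core_seq))
  for (j in 1:8) {
    a <- a * config$ets_affinity[cbind(match(chars[, j], BASES), j)]
  }
  a <- a * config$cre_alt_affinity^cls$cre_mm
  g <- rep(1, length(core_seq))
  if (creb1_present(condition)) {
    gam <- gamma_for_ets8(cls$ets8, config)
    g <- ifelse(cls$cre_mm == 0L, gam,
                ifelse(cls$cre_mm == 1L, 1 + (gam - 1) * config$cre_damage, 1))
  }
  mu <- config$background + config$scale * a * g
  if (!is.null(config$saturation_cap)) mu <- pmin(mu, config$saturation_cap)
  mu
}

creb1_present <- function(condition) {
  parts <- strsplit(as.character(condition), ":", fixed = TRUE)[[1]]
  length(parts) >= 2 && suppressWarnings(as.numeric(parts[2])) > 0
}

#' Simulate a scanned ETS-CRE array
#'
#' Draws one spot per probe per sector per replicate array. Spot
#' intensity is the model mean ([expected_intensity()]) times log-normal
#' noise (`meanlog = 0`, CV `noise_cv`) times the sector factor; spots
#' are flagged bad independently at `flag_rate`. Fully reproducible from
#' `seed`.
#'
#' @param design Probe manifest from [build_design()].
#' @param condition Condition label (see [expected_intensity()]).
#' @param config An [sim_config()].
#' @param sectors Sector indices to print (the published array has four
#'   identical sectors).
#' @param arrays Number of replicate arrays (each protein was assayed
#'   twice).
#' @param seed Integer seed.
#' @return Spot-level tibble: `probe_id`, `core_seq`, `category`,
#'   `sector`, `array`, `condition`, `intensity`, `flag`.
#' @export
simulate_array <- function(design, condition, config = sim_config(),
                           sectors = 1:4, arrays = 1L, seed = 1L) {
  stopifnot(nrow(design) > 0)
  cores <- unique(design$core_seq)
  mu_map <- setNames(expected_intensity(cores, condition, config), cores)
  n_rep <- length(sectors) * arrays
  spots <- tidyr::expand_grid(
    design[, c("probe_id", "core_seq", "category")],
    sector = sectors, array = seq_len(arrays)
  )
  sdlog <- sqrt(log(1 + config$noise_cv^2))
  with_seed_or_not(seed, {
    noise <- if (config$noise_cv > 0) {
      exp(rnorm(nrow(spots), 0, sdlog))
    } else rep(1, nrow(spots))
    sf <- config$sector_factors[match(spots$sector,
                                      seq_along(config$sector_factors))]
    sf[is.na(sf)] <- 1
    spots$condition <- as.character(condition)
    spots$intensity <- unname(mu_map[spots$core_seq]) * noise * sf
    spots$flag <- runif(nrow(spots)) < config$flag_rate
  })
  spots
}

# --- toy genome / peak generator ------------------------------------------

random_dna <- function(n, probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(BASES, n, replace = TRUE, prob = probs[BASES]), collapse = "")
}

# First-order transition matrix for peak backgrounds: a GC-rich base
# distribution mixed with the transition statistics of the ETS
# consensus 8-mer, so that peak sequence (and, by exchangeability, its
# dinucleotide-preserving shuffles) carries the degenerate ETS-like
# content of promoter-derived ChIP peaks. Columns = current base,
# rows = next base.
peak_transition_matrix <- function(gc_content, motif_bias) {
  p0 <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
          G = gc_content / 2, T = (1 - gc_content) / 2)
  M <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  chars <- strsplit(ETS_CONSENSUS, "")[[1]]
  for (i in seq_len(length(chars) - 1)) {
    M[chars[i + 1], chars[i]] <- M[chars[i + 1], chars[i]] + 1
  }
  cs <- colSums(M)
  for (j in seq_len(4)) {
    M[, j] <- if (cs[j] > 0) M[, j] / cs[j] else p0[BASES]
  }
  (1 - motif_bias) * matrix(p0[BASES], 4, 4, dimnames = list(BASES, BASES)) +
    motif_bias * M
}

# sample n_seqs Markov sequences of the given width, vectorised over
# sequences
random_markov_block <- function(n_seqs, width, trans, p0) {
  cum <- apply(trans, 2, cumsum)
  out <- matrix("", n_seqs, width)
  state <- sample(BASES, n_seqs, replace = TRUE, prob = p0[BASES])
  out[, 1] <- state
  for (i in seq_len(width - 1L)) {
    u <- runif(n_seqs)
    idx <- match(state, BASES)
    nxt <- 1L + (u > cum[1, idx]) + (u > cum[2, idx]) + (u > cum[3, idx])
    state <- BASES[nxt]
    out[, i + 1L] <- state
  }
  apply(out, 1, paste, collapse = "")
}

# write `insert` into `seq` at 1-based position `at`
splice_in <- function(seq, insert, at) {
  paste0(substr(seq, 1L, at - 1L), insert,
         substr(seq, at + nchar(insert), nchar(seq)))
}

#' Simulate a toy genome with planted GABPa/CREB1 binding sites
#'
#' Builds a random genome and plants four classes of sites inside
#' ChIP-like peaks: cooperative-only composites (flank-SNP ETS variants
#' fused to an intact CRE, e.g. `CCGGACGT`+`GACGTCAC`) in peaks bound by
#' both proteins; independently co-bound regions (a strong ETS site plus
#' a separated CRE) in peaks of both proteins; plain consensus ETS sites
#' in GABPa-only peaks; and lone CRE sites in CREB1-only peaks. Peak
#' backgrounds are GC-rich with degenerate ETS-like fragments so that
#' shuffled decoys score in the mid-range under single-protein models,
#' as real promoter-derived peak sequence does.
#'
#' @param genome_length Total genome length (bp).
#' @param n_coop,n_indep,n_single,n_decoy Numbers of planted sites per
#'   class.
#' @param peak_width Width of each peak (bp).
#' @param gc_content GC fraction of peak backgrounds.
#' @param motif_bias Weight of the composite-motif transition statistics
#'   in the peak-background Markov chain (0 = independent GC-rich
#'   bases).
#' @param seed Integer seed.
#' @return List with `genome` (named character), `gabpa_peaks` and
#'   `creb1_peaks` (tibbles `contig`, `start`, `end`, 1-based closed),
#'   and `truth` (per-site tibble with class and planted sequence).
#' @export
simulate_genome_peaks <- function(genome_length = 200000L,
                                  n_coop = 60L, n_indep = 120L,
                                  n_single = 40L, n_decoy = 40L,
                                  peak_width = 300L, gc_content = 0.6,
                                  motif_bias = 0.8, seed = 1L) {
  n_peaks <- n_coop + n_indep + n_single + n_decoy
  gap <- 20L
  if (genome_length < (peak_width + gap) * (n_peaks + 1L)) {
    abort("genome_length too small to place the requested peaks")
  }
  coop_composites <- paste0(c("CCGGACGT", "TCGGAAGT", "CGGGAAGT", "CCGGAACT"),
                            "GACGTCAC")
  trans <- peak_transition_matrix(gc_content, motif_bias)
  p0 <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
          G = gc_content / 2, T = (1 - gc_content) / 2)
  empty_peaks <- tibble(name = character(), contig = character(),
                        start = integer(), end = integer())[, c(2:4, 1)]
  with_seed_or_not(seed, {
    genome <- random_dna(genome_length)
    if (n_peaks == 0L) {
      return(list(genome = c(chr1 = genome), gabpa_peaks = empty_peaks,
                  creb1_peaks = empty_peaks,
                  truth = tibble(site_id = character(), class = character(),
                                 contig = character(), start = integer(),
                                 end = integer(), site_seq = character(),
                                 site_start = integer())))
    }
    # evenly spaced, shuffled peak slots
    slot_pitch <- genome_length %/% (n_peaks + 1L)
    starts <- slot_pitch * seq_len(n_peaks) -
      sample.int(slot_pitch - peak_width - 1L, n_peaks, replace = TRUE)
    starts <- starts[sample.int(n_peaks)]
    classes <- c(rep("coop", n_coop), rep("indep", n_indep),
                 rep("single", n_single), rep("decoy", n_decoy))
    backgrounds <- random_markov_block(n_peaks, peak_width, trans, p0)
    truth <- purrr::map_dfr(seq_len(n_peaks), function(i) {
      bg <- backgrounds[i]
      mid <- peak_width %/% 2L
      site <- switch(classes[i],
        coop = sample(coop_composites, 1L),
        indep = ETS_CONSENSUS,
        single = ETS_CONSENSUS,
        decoy = CRE_MOTIF)
      site_at <- mid - nchar(site) %/% 2L
      bg <- splice_in(bg, site, site_at)
      if (classes[i] == "indep") {
        bg <- splice_in(bg, CRE_MOTIF, site_at + 40L)
      }
      tibble(site_id = sprintf("site_%03d", i), class = classes[i],
             contig = "chr1", start = starts[i],
             end = starts[i] + peak_width - 1L,
             site_seq = site, site_start = starts[i] + site_at - 1L,
             peak_seq = bg)
    })
    for (i in seq_len(nrow(truth))) {
      genome <- splice_in(genome, truth$peak_seq[i], truth$start[i])
    }
    peaks <- function(keep) {
      truth[truth$class %in% keep, c("site_id", "contig", "start", "end")] |>
        rename(name = "site_id")
    }
    list(genome = c(chr1 = genome),
         gabpa_peaks = peaks(c("coop", "indep", "single")),
         creb1_peaks = peaks(c("coop", "indep", "decoy")),
         truth = select(truth, -"peak_seq"))
  })
}

#' Write a genome to FASTA / regions to BED
#'
#' `write_bed()` converts the in-memory 1-based closed intervals to
#' BED's 0-based half-open convention; `read_bed()` converts back.
#'
#' @param genome Named character vector of contigs.
#' @param regions Region tibble (`contig`, `start`, `end`, optional
#'   `name`).
#' @param path Output path.
#' @return The path, invisibly (readers return tibbles).
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
write_bed <- function(regions, path) {
  out <- tibble(contig = regions$contig, start = regions$start - 1L,
                end = regions$end)
  if (!is.null(regions$name)) out$name <- regions$name
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_bed <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols())
  out <- tibble(contig = as.character(raw[[1]]),
                start = as.integer(raw[[2]]) + 1L,
                end = as.integer(raw[[3]]))
  if (ncol(raw) >= 4) out$name <- as.character(raw[[4]])
  out
}
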