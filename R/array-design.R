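# Array design: enumerate the probe content of the ETS-CRE custom PBM and
# assemble full-length 60-mer probe sequences.

#' Sequence constants of the ETS-CRE array
#'
#' The composite ETS-CRE 16-mers (strong `C` and weak `G` 5' variants of
#' the ETS motif fused to the CRE half-site), the 15-mer core-variant
#' templates (`N` marks a variable position), the probe scaffold flanks
#' and the constant 24-base primer-complement region that terminates
#' every probe on the slide side.
#'
#' @format Character scalars.
#' @name ets_cre_constants
NULL

#' @rdname ets_cre_constants
#' @export
ETS_CRE_CC <- "CCGGAAGTGACGTCAC"

#' @rdname ets_cre_constants
#' @export
ETS_CRE_GC <- "GCGGAAGTGACGTCAC"

#' @rdname ets_cre_constants
#' @export
ETS_CONSENSUS <- "CCGGAAGT"

#' @rdname ets_cre_constants
#' @export
CRE_MOTIF <- "GTGACGTCAC"

#' @rdname ets_cre_constants
#' @export
CORE_PATTERN_CC <- "CCGGANNNNNCGNNN"

#' @rdname ets_cre_constants
#' @export
CORE_PATTERN_GC <- "GCGGANNNNNCGNNN"

#' @rdname ets_cre_constants
#' @export
PROBE_FLANK_5P <- "GTCCTCAAGA"

#' @rdname ets_cre_constants
#' @export
PROBE_FLANK_3P <- "GACTCAGGTG"

#' @rdname ets_cre_constants
#' @export
PROBE_PRIMER <- "GGACACACTTTAACACATGGAGAG"

#' Enumerate all core-variant sequences of a template pattern
#'
#' Expands a template with fixed bases and `N` wildcards into every
#' concrete DNA sequence, in lexicographic order (`A < C < G < T`) of the
#' variable positions. The ETS-CRE array's core-variant blocks use the
#' 15-mer templates [CORE_PATTERN_CC] and [CORE_PATTERN_GC], each with
#' eight variable positions (4^8 = 65,536 sequences).
#'
#' @param pattern Template string over `{A,C,G,T,N}`.
#' @return Character vector of `4^k` sequences, `k` the number of `N`s.
#' @export
#' @examples
#' enumerate_core_variants("CCNN")[1:4]
enumerate_core_variants <- function(pattern) {
  assert_dna(pattern, allow_n = TRUE, what = "pattern")
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  var_pos <- which(chars == "N")
  k <- length(var_pos)
  if (k == 0L) return(pattern)
  n <- 4L^k
  out <- matrix(chars, nrow = n, ncol = length(chars), byrow = TRUE)
  for (j in seq_len(k)) {
    # first variable position varies slowest => lexicographic order
    out[, var_pos[j]] <- rep(BASES, each = 4L^(k - j), times = 4L^(j - 1L))
  }
  do.call(paste0, asplit(out, 2))
}

#' Enumerate the SNP panel of a motif
#'
#' Returns the consensus motif plus all `3L` single-base substitutions
#' (the "SNPs"), each annotated with its descriptor (position, reference
#' base, alternative base). For the 16-mer composite this is the
#' 49-sequence panel printed 40x on the array.
#'
#' @param motif Consensus DNA string.
#' @return Tibble with columns `seq`, `role` (`"consensus"`/`"snp"`),
#'   `position`, `ref`, `alt` (`NA` for the consensus row).
#' @export
#' @examples
#' enumerate_snp_panel("ACG")
enumerate_snp_panel <- function(motif) {
  assert_dna(motif, what = "motif")
  chars <- strsplit(motif, "", fixed = TRUE)[[1]]
  L <- length(chars)
  rows <- purrr::map_dfr(seq_len(L), function(i) {
    alts <- setdiff(BASES, chars[i])
    seqs <- vapply(alts, function(b) {
      v <- chars; v[i] <- b; paste(v, collapse = "")
    }, character(1), USE.NAMES = FALSE)
    tibble(seq = seqs, position = i, ref = chars[i], alt = alts)
  })
  dplyr::bind_rows(
    tibble(seq = motif, role = "consensus",
           position = NA_integer_, ref = NA_character_, alt = NA_character_),
    dplyr::mutate(rows, role = "snp", .after = "seq")
  )
}

#' Assemble a full 60-mer probe sequence
#'
#' Embeds a core sequence (up to 36 bp) in the array scaffold:
#' `5'-[flank]-core-[flank]-primer-3'`, with the constant 24-base
#' primer-complement region ([PROBE_PRIMER]) at the slide-proximal end and
#' the ETS end of the core toward solution. 16-mer cores receive the
#' printed 10-bp flanks ([PROBE_FLANK_5P]/[PROBE_FLANK_3P]); 36-mer
#' genomic cores receive no variable flanks. For other core lengths the
#' 5' flank is truncated from, and the 3' flank recycled from, the same
#' scaffold strings so that every probe is exactly 60 bases.
#'
#' @param core_seq Character vector of DNA cores (each `<= 36` bp).
#' @return Character vector of 60-base probe sequences.
#' @export
#' @examples
#' assemble_probe(ETS_CRE_CC)
assemble_probe <- function(core_seq) {
  assert_dna(core_seq, what = "core_seq")
  L <- nchar(core_seq)
  if (any(L > 36L)) abort("core_seq longer than 36 bases cannot be assembled")
  up <- pmin(10L, 36L - L)
  down <- 36L - L - up
  f5 <- substr(rep(PROBE_FLANK_5P, length(L)), 10L - up + 1L, 10L)
  f3 <- substr(rep(strrep(PROBE_FLANK_3P, 3L), length(L)), 1L, down)
  out <- paste0(f5, core_seq, f3, PROBE_PRIMER)
  stopifnot(all(nchar(out) == 60L))
  out
}

#' Extract genomic occurrences of a core pattern as fixed-width sites
#'
#' Scans both strands of a genome for exact matches of a template pattern
#' (`N` = any base) and returns the unique `window`-length sequences
#' covering each match. Minus-strand matches are reverse-complemented so
#' the stored site always carries the pattern on the forward strand. The
#' pattern is placed `pattern_offset` bases into the window (default:
#' centred, 11 bp upstream for a 15-mer in a 36-mer). Matches too close
#' to a contig edge are skipped with a message.
#'
#' @param genome Named character vector of contig sequences, a
#'   `Biostrings::DNAStringSet`, or a path to a FASTA file.
#' @param pattern Template over `{A,C,G,T,N}`.
#' @param window Site width (>= pattern length).
#' @param max_sites Optional cap; sites are subsampled uniformly.
#' @param seed Seed for the subsampling draw.
#' @param pattern_offset Bases of flank upstream of the pattern within the
#'   window; default `ceiling((window - nchar(pattern)) / 2)`.
#' @return Character vector of unique window-length sites.
#' @export
extract_genomic_sites <- function(genome, pattern, window = 36L,
                                  max_sites = NULL, seed = NULL,
                                  pattern_offset = NULL) {
  assert_dna(pattern, allow_n = TRUE, what = "pattern")
  P <- nchar(pattern)
  if (window < P) abort("window must be at least the pattern length")
  pattern_offset <- pattern_offset %||% as.integer(ceiling((window - P) / 2))
  if (pattern_offset < 0L || pattern_offset > window - P) {
    abort("pattern_offset must lie in [0, window - pattern length]")
  }
  gen <- read_genome(genome)
  subj <- Biostrings::DNAStringSet(gen)
  collect <- function(pat, minus) {
    hits <- Biostrings::vmatchPattern(pat, subj, fixed = "subject")
    purrr::imap(as.list(hits), function(ir, contig) {
      if (length(ir) == 0L) return(character())
      s <- IRanges::start(ir)
      clen <- nchar(gen[[contig]])
      if (minus) {
        fe <- s + P - 1L + pattern_offset
        fs <- fe - window + 1L
      } else {
        fs <- s - pattern_offset
        fe <- fs + window - 1L
      }
      ok <- fs >= 1L & fe <= clen
      if (any(!ok)) {
        inform(sprintf("%d match(es) on %s too close to a contig edge; skipped",
                       sum(!ok), contig))
      }
      seqs <- substring(gen[[contig]], fs[ok], fe[ok])
      if (minus) revcomp(seqs) else seqs
    })
  }
  sites <- c(
    unlist(collect(pattern, minus = FALSE), use.names = FALSE),
    unlist(collect(revcomp(pattern), minus = TRUE), use.names = FALSE)
  )
  sites <- unique(sites[!grepl("N", sites, fixed = TRUE)])
  if (!is.null(max_sites) && length(sites) > max_sites) {
    sites <- with_seed_or_not(seed, sort(sample(sites, max_sites)))
  }
  sites
}

#' Design parameters for the ETS-CRE array
#'
#' Bundles the motifs, templates, replicate count and (optional) genomes
#' that [build_design()] expands into a probe manifest. Defaults encode
#' the published array: two 15-mer core-variant templates, the two
#' composite 16-mers with 40-fold replicated SNP panels, and genomic
#' 36-mer blocks when genomes are supplied.
#'
#' @param core_patterns Named character vector of core templates
#'   (`core_CC`, `core_GC`).
#' @param snp_motifs Named character vector of SNP-panel motifs
#'   (`CC`, `GC`).
#' @param n_replicates Replicate features per SNP-panel sequence.
#' @param genomes Optional named list (`mouse`, `human`) of genomes
#'   accepted by [extract_genomic_sites()].
#' @param genomic_max_sites Optional named list of per-genome site caps
#'   (the published human block is subsampled).
#' @param genomic_window Genomic site width.
#' @param seed Seed for genomic subsampling.
#' @return A list of class `etscre_design_params`.
#' @export
design_params <- function(core_patterns = c(core_CC = CORE_PATTERN_CC,
                                            core_GC = CORE_PATTERN_GC),
                          snp_motifs = c(CC = ETS_CRE_CC, GC = ETS_CRE_GC),
                          n_replicates = 40L,
                          genomes = NULL,
                          genomic_max_sites = NULL,
                          genomic_window = 36L,
                          seed = 1L) {
  stopifnot(n_replicates >= 1L)
  structure(list(core_patterns = core_patterns, snp_motifs = snp_motifs,
                 n_replicates = as.integer(n_replicates), genomes = genomes,
                 genomic_max_sites = genomic_max_sites,
                 genomic_window = as.integer(genomic_window),
                 seed = as.integer(seed)),
            class = "etscre_design_params")
}

#' Build the probe manifest of an ETS-CRE array design
#'
#' Expands [design_params()] into one row per array feature, in the
#' published category order: core variants (CC then GC), SNP panels
#' (consensus then variants, CC then GC, each sequence replicated
#' `n_replicates` times), then genomic blocks. Probe ids are assigned
#' sequentially; full 60-mer sequences come from [assemble_probe()].
#'
#' @param params An [design_params()] object.
#' @return Tibble with columns `probe_id`, `category`, `core_seq`,
#'   `full_seq`, `replicate_index`, `snp_position`, `snp_ref`, `snp_alt`.
#' @export
build_design <- function(params = design_params()) {
  stopifnot(inherits(params, "etscre_design_params"))
  blocks <- list()
  for (nm in names(params$core_patterns)) {
    seqs <- enumerate_core_variants(params$core_patterns[[nm]])
    blocks[[nm]] <- tibble(category = nm, core_seq = seqs,
                           replicate_index = 1L,
                           snp_position = NA_integer_,
                           snp_ref = NA_character_, snp_alt = NA_character_)
  }
  for (nm in names(params$snp_motifs)) {
    panel <- enumerate_snp_panel(params$snp_motifs[[nm]])
    rep_block <- function(rows, cat) {
      rows <- rows[rep(seq_len(nrow(rows)), each = params$n_replicates), ]
      tibble(category = cat, core_seq = rows$seq,
             replicate_index = rep(seq_len(params$n_replicates),
                                   times = nrow(rows) / params$n_replicates),
             snp_position = rows$position, snp_ref = rows$ref,
             snp_alt = rows$alt)
    }
    blocks[[paste0("snp_consensus_", nm)]] <-
      rep_block(panel[panel$role == "consensus", ], paste0("snp_consensus_", nm))
    blocks[[paste0("snp_variant_", nm)]] <-
      rep_block(panel[panel$role == "snp", ], paste0("snp_variant_", nm))
  }
  for (gnm in names(params$genomes %||% list())) {
    for (pnm in names(params$core_patterns)) {
      sites <- extract_genomic_sites(
        params$genomes[[gnm]], params$core_patterns[[pnm]],
        window = params$genomic_window,
        max_sites = (params$genomic_max_sites %||% list())[[gnm]],
        seed = params$seed
      )
      if (length(sites)) {
        blocks[[paste(gnm, pnm, sep = "_")]] <-
          tibble(category = paste0("genomic_", gnm), core_seq = sites,
                 replicate_index = 1L, snp_position = NA_integer_,
                 snp_ref = NA_character_, snp_alt = NA_character_)
      }
    }
  }
  design <- dplyr::bind_rows(blocks)
  design <- dplyr::mutate(design,
                          probe_id = dplyr::row_number(),
                          full_seq = assemble_probe(.data$core_seq),
                          .before = 1)
  if (anyDuplicated(design$probe_id)) abort("duplicate probe ids in design")
  design
}

#' Read or write a probe manifest as TSV
#'
#' @param design Probe manifest tibble from [build_design()].
#' @param path File path.
#' @return `write_design()` returns `path` invisibly; `read_design()`
#'   returns the manifest tibble.
#' @export
write_design <- function(design, path) {
  readr::write_tsv(design, path)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    probe_id = readr::col_integer(), category = readr::col_character(),
    core_seq = readr::col_character(), full_seq = readr::col_character(),
    replicate_index = readr::col_integer(),
    snp_position = readr::col_integer(), snp_ref = readr::col_character(),
    snp_alt = readr::col_character()
  ))
}
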