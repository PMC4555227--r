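# Genomic enrichment: motif occurrence counting, peak-group splitting by
# CREB1 co-binding, and the enrichment score E = OCC_obs / OCC_exp.

#' Read a genome into a named character vector
#'
#' Accepts a FASTA path, a `Biostrings::DNAStringSet` or an already
#' named character vector; sequences are upper-cased.
#'
#' @param genome Genome in any accepted form.
#' @return Named character vector of contig sequences.
#' @export
read_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    out <- as.character(genome)
  } else if (is.character(genome) && length(genome) == 1 &&
             !grepl("^[ACGTNacgtn]+$", genome) && file.exists(genome)) {
    ss <- Biostrings::readDNAStringSet(genome)
    out <- as.character(ss)
  } else if (is.character(genome)) {
    out <- genome
    if (is.null(names(out))) names(out) <- paste0("contig", seq_along(out))
  } else {
    abort("genome must be a FASTA path, DNAStringSet or character vector")
  }
  names(out) <- sub("\\s.*$", "", names(out))
  toupper(out) |> setNames(names(out))
}

# total non-N genome length (the default L_g)
genome_length_nonN <- function(genome) {
  gen <- read_genome(genome)
  sum(nchar(gen)) - sum(vapply(gen, function(s) {
    lengths(regmatches(s, gregexpr("N", s, fixed = TRUE)))
  }, integer(1)))
}

#' Count exact motif occurrences in a genome
#'
#' Exact string matching on the forward strand plus, optionally, the
#' reverse complement. Palindrome hits at identical (contig, start) are
#' counted once. `N`s in the genome never match.
#'
#' @param genome Genome (see [read_genome()]).
#' @param motif Unambiguous DNA string.
#' @param both_strands Also match the reverse complement.
#' @return Tibble `contig`, `start`, `end` (1-based closed), `strand`,
#'   with attributes `motif` and `N` (the total count).
#' @export
count_motif_occurrences <- function(genome, motif, both_strands = TRUE) {
  assert_dna(motif, what = "motif")
  gen <- read_genome(genome)
  subj <- Biostrings::DNAStringSet(gen)
  proto <- tibble(contig = character(), start = integer(),
                  end = integer(), strand = character())
  hit_tbl <- function(pat, strand) {
    hits <- Biostrings::vmatchPattern(pat, subj)
    rows <- purrr::imap_dfr(as.list(hits), function(ir, contig) {
      if (length(ir) == 0L) return(NULL)
      tibble(contig = contig, start = IRanges::start(ir),
             end = IRanges::end(ir), strand = strand)
    })
    dplyr::bind_rows(proto, rows)
  }
  occ <- hit_tbl(motif, "+")
  if (both_strands) {
    rc <- revcomp(motif)
    occ <- dplyr::bind_rows(occ, hit_tbl(rc, "-")) %>%
      dplyr::distinct(.data$contig, .data$start, .keep_all = TRUE)
  }
  occ <- arrange(occ, .data$contig, .data$start)
  attr(occ, "motif") <- motif
  attr(occ, "N") <- nrow(occ)
  occ
}

#' Merge overlapping intervals of a region set
#'
#' @param regions Region tibble (`contig`, `start`, `end`, 1-based
#'   closed).
#' @return Merged, non-overlapping region tibble.
#' @export
merge_regions <- function(regions) {
  if (nrow(regions) == 0) {
    return(tibble(contig = character(), start = integer(), end = integer()))
  }
  purrr::map_dfr(split(regions, regions$contig), function(d) {
    red <- IRanges::reduce(IRanges::IRanges(d$start, d$end))
    tibble(contig = d$contig[1], start = IRanges::start(red),
           end = IRanges::end(red))
  }) %>%
    arrange(.data$contig, .data$start)
}

#' @rdname merge_regions
#' @return `region_length()`: total bases covered after merging (the
#'   `L_r` of the enrichment score).
#' @export
region_length <- function(regions) {
  m <- merge_regions(regions)
  sum(m$end - m$start + 1L)
}

# logical: does each interval of `x` overlap >= 1 bp of `y`?
overlaps_any <- function(x, y) {
  if (nrow(x) == 0) return(logical(0))
  if (nrow(y) == 0) return(rep(FALSE, nrow(x)))
  out <- rep(FALSE, nrow(x))
  for (ctg in unique(x$contig)) {
    xi <- which(x$contig == ctg)
    yi <- y$contig == ctg
    if (!any(yi)) next
    out[xi] <- IRanges::overlapsAny(
      IRanges::IRanges(x$start[xi], x$end[xi]),
      IRanges::IRanges(y$start[yi], y$end[yi])
    )
  }
  out
}

#' Split GABPa peaks by CREB1 co-binding
#'
#' A GABPa peak joins the `plus` group iff it overlaps at least one base
#' of any CREB1 peak (intervals are 1-based closed in memory; BED input
#' is converted by [read_bed()], so abutting BED intervals do not
#' overlap). The two groups partition the GABPa peaks exactly.
#'
#' @param gabpa_peaks,creb1_peaks Region tibbles.
#' @return List with region tibbles `plus` (GABPa+CREB1) and `minus`
#'   (GABPa-CREB1).
#' @export
split_peak_groups <- function(gabpa_peaks, creb1_peaks) {
  hit <- overlaps_any(gabpa_peaks, creb1_peaks)
  list(plus = gabpa_peaks[hit, ], minus = gabpa_peaks[!hit, ])
}

#' Enrichment score of a motif in a region group
#'
#' `OCC_obs` is the number of motif occurrences overlapping (>= 1 bp)
#' the merged group regions; the expectation under uniform placement is
#' `OCC_exp = N * L_r / L_g`, with `N` the genome-wide occurrence count,
#' `L_r` the merged group length and `L_g` the genome length. The
#' enrichment score is `E = OCC_obs / OCC_exp`.
#'
#' @param occurrences Occurrence tibble from [count_motif_occurrences()].
#' @param group Region tibble.
#' @param genome_length Total genome length `L_g` (non-N by convention).
#' @return One-row tibble `motif`, `N`, `occ_obs`, `occ_exp`, `L_r`,
#'   `L_g`, `enrichment`.
#' @export
enrichment_score <- function(occurrences, group, genome_length) {
  grp <- merge_regions(group)
  L_r <- sum(grp$end - grp$start + 1L)
  if (genome_length < L_r || L_r <= 0) {
    abort("need genome_length >= L_r > 0")
  }
  N <- nrow(occurrences)
  occ_obs <- sum(overlaps_any(occurrences, grp))
  occ_exp <- N * L_r / genome_length
  tibble(motif = attr(occurrences, "motif") %||% NA_character_,
         N = N, occ_obs = occ_obs, occ_exp = occ_exp,
         L_r = L_r, L_g = genome_length,
         enrichment = ifelse(N > 0, occ_obs / occ_exp, NA_real_))
}

#' Enrichment arithmetic from printed counts
#'
#' Computes the enrichment score and the bound fraction directly from an
#' observed occurrence count, a genome-wide count and a group-to-genome
#' length ratio — the worked-example form of the statistic (e.g. 1645
#' bound of 8608 genomic occurrences in peaks covering 0.2% of the
#' genome gives a 96-fold enrichment with 19.1% of occurrences bound).
#'
#' @param occ_obs Observed occurrences in the group.
#' @param n Genome-wide occurrence count `N`.
#' @param lr_over_lg Group fraction of the genome, `L_r / L_g`.
#' @return One-row tibble `occ_obs`, `n`, `lr_over_lg`, `occ_exp`,
#'   `enrichment`, `pct_bound`.
#' @export
#' @examples
#' enrichment_from_counts(1645, 8608, 0.002)
enrichment_from_counts <- function(occ_obs, n, lr_over_lg) {
  stopifnot(n > 0, lr_over_lg > 0)
  occ_exp <- n * lr_over_lg
  tibble(occ_obs = occ_obs, n = n, lr_over_lg = lr_over_lg,
         occ_exp = occ_exp, enrichment = occ_obs / occ_exp,
         pct_bound = 100 * occ_obs / n)
}

#' Enrichment profile of a consensus motif and its 1-bp variants
#'
#' Computes the enrichment score of the consensus motif and each
#' single-base variant (25 motifs for an 8-mer) in the GABPa+CREB1 and
#' GABPa-CREB1 peak groups, the per-motif ratio of the two enrichments,
#' and a Fisher exact test on the 2 x 2 table of occurrences falling
#' inside vs outside each group.
#'
#' @param genome Genome (see [read_genome()]).
#' @param gabpa_peaks,creb1_peaks Region tibbles.
#' @param consensus Consensus motif (default the ETS 8-mer).
#' @param genome_length `L_g`; defaults to the non-N genome length.
#' @param both_strands Count on both strands.
#' @return Tibble of class `etscre_enrichment_profile`: `motif`,
#'   `position`, `ref`, `alt`, `N`, `occ_obs_plus`, `occ_obs_minus`,
#'   `E_plus`, `E_minus`, `ratio`, `p_fisher`.
#' @export
snp_enrichment_profile <- function(genome, gabpa_peaks, creb1_peaks,
                                   consensus = ETS_CONSENSUS,
                                   genome_length = NULL,
                                   both_strands = TRUE) {
  gen <- read_genome(genome)
  L_g <- genome_length %||% genome_length_nonN(gen)
  groups <- split_peak_groups(gabpa_peaks, creb1_peaks)
  plus <- merge_regions(groups$plus)
  minus <- merge_regions(groups$minus)
  panel <- enumerate_snp_panel(consensus)
  purrr::pmap_dfr(panel, function(seq, role, position, ref, alt) {
    occ <- count_motif_occurrences(gen, seq, both_strands = both_strands)
    N <- nrow(occ)
    if (N == 0) {
      return(tibble(motif = seq, position = position, ref = ref, alt = alt,
                    N = 0L, occ_obs_plus = NA_integer_,
                    occ_obs_minus = NA_integer_, E_plus = NA_real_,
                    E_minus = NA_real_, ratio = NA_real_,
                    p_fisher = NA_real_))
    }
    score_group <- function(grp) {
      if (nrow(grp) == 0) {
        return(tibble(occ_obs = NA_integer_, enrichment = NA_real_))
      }
      enrichment_score(occ, grp, L_g)
    }
    ep <- score_group(plus)
    em <- score_group(minus)
    p <- if (is.na(ep$occ_obs) || is.na(em$occ_obs)) NA_real_ else {
      stats::fisher.test(matrix(c(ep$occ_obs, N - ep$occ_obs,
                                  em$occ_obs, N - em$occ_obs), 2))$p.value
    }
    tibble(motif = seq, position = position, ref = ref, alt = alt, N = N,
           occ_obs_plus = ep$occ_obs, occ_obs_minus = em$occ_obs,
           E_plus = ep$enrichment, E_minus = em$enrichment,
           ratio = ep$enrichment / em$enrichment, p_fisher = p)
  }) %>%
    structure(class = c("etscre_enrichment_profile", class(tibble())))
}
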