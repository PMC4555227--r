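# Intensity analytics: replicate aggregation, cross-condition
# normalisation, SNP fold changes, cooperativity ratios and the
# strong/weak motif comparison.

#' Aggregate replicate spots to per-sequence summaries
#'
#' Computes the median, MAD and unflagged spot count per probe sequence
#' (per condition if several are present). Flagged spots are excluded;
#' sequences whose spots are all flagged are reported with `NA` medians
#' (missing, never zero) and a warning.
#'
#' @param spots Spot-level tibble as produced by [simulate_array()]
#'   (columns `core_seq`, `category`, `condition`, `intensity`, `flag`).
#' @return Tibble with one row per (`condition`, `category`, `core_seq`):
#'   `median`, `mad`, `n`.
#' @export
aggregate_replicates <- function(spots) {
  if (nrow(spots) == 0) abort("spots table is empty")
  keys <- intersect(c("condition", "category", "core_seq"), names(spots))
  all_seqs <- dplyr::distinct(spots, across(all_of(keys)))
  agg <- spots %>%
    filter(!.data$flag) %>%
    group_by(across(all_of(keys))) %>%
    summarise(median = stats::median(.data$intensity),
              mad = stats::mad(.data$intensity),
              n = dplyr::n(), .groups = "drop")
  out <- left_join(all_seqs, agg, by = keys) %>%
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
  if (any(out$n == 0L)) {
    warn(sprintf("%d sequence(s) have no unflagged spots; reported as missing",
                 sum(out$n == 0L)))
  }
  out
}

#' Number of mismatches to the CRE half-site of the composite
#'
#' Counts mismatches of a core sequence's CRE half (positions 9-16 after
#' alignment at the ETS anchor) to `GACGTCAC`. Core variants with two or
#' more CRE mismatches carry no CREB1 half-site and serve as the
#' GABPa-only normalisation reference.
#'
#' @param core_seq Character vector of core sequences.
#' @return Integer vector of mismatch counts.
#' @export
cre_mismatches <- function(core_seq) {
  classify_core(core_seq)$cre_mm
}

#' Rescale conditions onto a common intensity scale
#'
#' Rescales each condition so that the median intensity over a reference
#' probe set is identical across conditions (the geometric mean of the
#' per-condition reference medians). The reference defaults to core
#' variant probes whose CRE half-site is disrupted (>= 2 mismatches),
#' i.e. probes that contain only GABPa sites and therefore report the
#' GABPa-GST gain of each scan independently of CREB1.
#'
#' @param spots Spot tibble covering several conditions.
#' @param reference Logical vector (recycled per row of `spots`)
#'   selecting reference spots, or `NULL` for the default.
#' @return The spot tibble with rescaled intensities; scale factors are
#'   attached as attribute `"scale_factors"` (see [scale_factors()]).
#' @export
normalize_conditions <- function(spots, reference = NULL) {
  if (is.null(reference)) {
    is_core <- spots$category %in% c("core_CC", "core_GC")
    reference <- is_core
    cores <- unique(spots$core_seq[is_core])
    if (length(cores)) {
      broken <- cores[cre_mismatches(cores) >= 2L]
      reference <- is_core & spots$core_seq %in% broken
    }
  }
  ref <- spots[reference & !spots$flag, ]
  if (nrow(ref) == 0) abort("reference probe set is empty")
  med <- ref %>% group_by(.data$condition) %>%
    summarise(ref_median = stats::median(.data$intensity), .groups = "drop")
  missing <- setdiff(unique(spots$condition), med$condition)
  if (length(missing)) {
    abort(paste("no reference probes in condition(s):",
                paste(missing, collapse = ", ")))
  }
  target <- exp(mean(log(med$ref_median)))
  med$factor <- target / med$ref_median
  out <- spots %>%
    left_join(med[, c("condition", "factor")], by = "condition") %>%
    mutate(intensity = .data$intensity * .data$factor) %>%
    select(-"factor")
  attr(out, "scale_factors") <- med
  out
}

#' @rdname normalize_conditions
#' @param x A tibble returned by [normalize_conditions()].
#' @export
scale_factors <- function(x) attr(x, "scale_factors")

#' Estimate the array background intensity
#'
#' The background is taken as the median of the bottom decile of
#' per-sequence median intensities over the core-variant probes; the
#' censoring floor is that background plus twice the MAD of the bottom
#' decile. Returned per condition.
#'
#' @param spots Spot tibble.
#' @param decile Quantile defining the bottom fraction.
#' @return Tibble `condition`, `background`, `floor`.
#' @export
estimate_background <- function(spots, decile = 0.1) {
  core <- filter(spots, .data$category %in% c("core_CC", "core_GC"),
                 !.data$flag)
  if (nrow(core) == 0) abort("no core-variant probes to estimate background")
  core %>%
    group_by(.data$condition, .data$core_seq) %>%
    summarise(med = stats::median(.data$intensity), .groups = "drop_last") %>%
    summarise(background = {
      low <- .data$med[.data$med <= stats::quantile(.data$med, decile)]
      stats::median(low)
    },
    floor = {
      low <- .data$med[.data$med <= stats::quantile(.data$med, decile)]
      stats::median(low) + 2 * stats::mad(low)
    }, .groups = "drop")
}

#' Summarise a SNP panel from spot intensities
#'
#' Collects the consensus and all single-base variants of a composite
#' motif into a per-sequence summary (median, MAD, unflagged count and
#' the raw unflagged spot vector as a list column for resampling). The
#' sequence with the highest median is the panel's `S_max` (see
#' [s_max()]).
#'
#' @param spots Spot tibble for a single condition.
#' @param motif The panel's consensus 16-mer (e.g. [ETS_CRE_CC]).
#' @return Tibble `seq`, `role`, `position`, `ref`, `alt`, `median`,
#'   `mad`, `n`, `spots`.
#' @export
summarize_snp_panel <- function(spots, motif = ETS_CRE_CC) {
  if (length(unique(spots$condition)) > 1) {
    abort("spots span several conditions; filter to one before summarising")
  }
  panel <- enumerate_snp_panel(motif)
  dat <- filter(spots, .data$core_seq %in% panel$seq, !.data$flag)
  summ <- dat %>%
    group_by(seq = .data$core_seq) %>%
    summarise(median = stats::median(.data$intensity),
              mad = stats::mad(.data$intensity), n = dplyr::n(),
              spots = list(.data$intensity), .groups = "drop")
  out <- left_join(panel, summ, by = "seq")
  if (any(is.na(out$median))) {
    warn(sprintf("%d panel sequence(s) missing from the spot table",
                 sum(is.na(out$median))))
  }
  structure(out, class = c("etscre_snp_panel", class(out)))
}

#' @rdname summarize_snp_panel
#' @param panel A panel summary tibble.
#' @return `s_max()`: one-row tibble with the highest-median sequence.
#' @export
s_max <- function(panel) {
  panel[which.max(panel$median), c("seq", "role", "median")]
}

#' Pearson correlation between replicate scans
#'
#' Computes Pearson's R on log-transformed intensities of the spots
#' shared (by probe id and sector) between two scans, excluding spots
#' flagged in either.
#'
#' @param a,b Spot tibbles.
#' @return Correlation coefficient.
#' @export
replicate_correlation <- function(a, b) {
  keys <- intersect(intersect(c("probe_id", "sector"), names(a)), names(b))
  shared <- inner_join(filter(a, !.data$flag), filter(b, !.data$flag),
                       by = keys, suffix = c("_a", "_b"),
                       relationship = "one-to-one")
  if (nrow(shared) < 3) abort("fewer than 3 shared unflagged probes")
  stats::cor(log(shared$intensity_a), log(shared$intensity_b))
}

#' Fold change of each SNP relative to the consensus
#'
#' Ratio of background-subtracted medians, consensus over SNP, ordered by
#' position then alternative base. SNPs whose median falls at or below
#' the censoring floor are reported at the floor with `censored = TRUE`
#' (the true reduction is at least the reported fold).
#'
#' @param panel Panel summary from [summarize_snp_panel()].
#' @param background Background intensity (see [estimate_background()]).
#' @param floor Censoring floor; defaults to `background` (no censoring
#'   margin).
#' @return Tibble `seq`, `position`, `ref`, `alt`, `fold_change`,
#'   `censored`.
#' @export
snp_fold_change <- function(panel, background = 0, floor = NULL) {
  floor <- floor %||% background
  cons <- panel$median[panel$role == "consensus"]
  if (length(cons) != 1 || is.na(cons) || cons <= background) {
    abort("consensus median must be present and above background")
  }
  snps <- filter(panel, .data$role == "snp") %>%
    mutate(censored = .data$median <= floor,
           fold_change = ifelse(
             .data$censored,
             (cons - background) / pmax(floor - background, 1e-12),
             (cons - background) / (.data$median - background))) %>%
    arrange(.data$position, .data$alt)
  select(snps, "seq", "position", "ref", "alt", "fold_change", "censored")
}

#' Cooperativity ratio with vs without CREB1
#'
#' Per-sequence ratio of background-subtracted median intensities from
#' the +CREB1 panel over the -CREB1 panel. Both panels must come from
#' condition-normalised intensities ([normalize_conditions()]) so that
#' global gain differences cancel. The consensus row carries the
#' reference enhancement (the dashed-line value of the array figures).
#'
#' @param panel_plus,panel_minus Panel summaries for the +/- CREB1
#'   conditions.
#' @param background_plus,background_minus Background intensities.
#' @return Tibble `seq`, `role`, `position`, `ref`, `alt`, `coop_ratio`.
#' @export
cooperativity_ratio <- function(panel_plus, panel_minus,
                                background_plus = 0, background_minus = 0) {
  joined <- inner_join(
    panel_plus[, c("seq", "role", "position", "ref", "alt", "median")],
    panel_minus[, c("seq", "median")],
    by = "seq", suffix = c("_plus", "_minus")
  )
  dropped <- nrow(panel_plus) + nrow(panel_minus) - 2 * nrow(joined)
  if (dropped > 0) {
    warn(sprintf("%d sequence(s) missing from one panel; omitted", dropped))
  }
  joined %>%
    mutate(coop_ratio = (.data$median_plus - background_plus) /
             (.data$median_minus - background_minus)) %>%
    select("seq", "role", "position", "ref", "alt", "coop_ratio")
}

#' Ratio of binding in the strong (CC) vs weak (GC) motif context
#'
#' For each SNP descriptor present in both panels, the ratio of
#' background-subtracted CC-context to GC-context medians, compared with
#' the consensus ratio (4-fold for the published arrays) by a stratified
#' bootstrap over replicate spots: spots of the four groups (SNP and
#' consensus in each context) are resampled `n_boot` times and the
#' two-sided bootstrap p-value of `log(ratio_snp) - log(ratio_consensus)`
#' is reported, with significance flags at 0.05 and 0.01. SNPs whose
#' medians sit at the background floor in both contexts are marked
#' unevaluable.
#'
#' @param panel_cc,panel_gc Panel summaries for the two motif contexts
#'   (same condition).
#' @param background Background intensity.
#' @param floor Unevaluability floor; defaults to `background`.
#' @param n_boot Bootstrap resamples.
#' @param seed Integer seed for resampling.
#' @return Tibble `position`, `alt`, `ratio`, `consensus_ratio`,
#'   `p_value`, `sig_05`, `sig_01`, `unevaluable`.
#' @export
strong_weak_ratio <- function(panel_cc, panel_gc, background = 0,
                              floor = NULL, n_boot = 1000L, seed = 1L) {
  floor <- floor %||% background
  cons_cc <- panel_cc[panel_cc$role == "consensus", ]
  cons_gc <- panel_gc[panel_gc$role == "consensus", ]
  consensus_ratio <- (cons_cc$median - background) /
    (cons_gc$median - background)
  snps <- inner_join(
    filter(panel_cc, .data$role == "snp")[, c("position", "alt", "median",
                                              "spots")],
    filter(panel_gc, .data$role == "snp")[, c("position", "alt", "median",
                                              "spots")],
    by = c("position", "alt"), suffix = c("_cc", "_gc")
  )
  boot_median <- function(x, B) {
    m <- matrix(sample(x, length(x) * B, replace = TRUE), ncol = B)
    matrixStats::colMedians(m)
  }
  with_seed_or_not(seed, {
    bc_cons_cc <- boot_median(cons_cc$spots[[1]], n_boot)
    bc_cons_gc <- boot_median(cons_gc$spots[[1]], n_boot)
    res <- purrr::pmap_dfr(snps, function(position, alt, median_cc, median_gc,
                                          spots_cc, spots_gc) {
      uneval <- median_cc <= floor && median_gc <= floor
      ratio <- (median_cc - background) / (median_gc - background)
      if (uneval) {
        return(tibble(position = position, alt = alt, ratio = ratio,
                      consensus_ratio = consensus_ratio,
                      p_value = NA_real_, sig_05 = NA, sig_01 = NA,
                      unevaluable = TRUE))
      }
      d <- log(pmax(boot_median(spots_cc, n_boot) - background, 1e-9)) -
        log(pmax(boot_median(spots_gc, n_boot) - background, 1e-9)) -
        (log(pmax(bc_cons_cc - background, 1e-9)) -
           log(pmax(bc_cons_gc - background, 1e-9)))
      p <- 2 * min(mean(d <= 0), mean(d >= 0))
      p <- min(1, max(p, 1 / (n_boot + 1)))
      tibble(position = position, alt = alt, ratio = ratio,
             consensus_ratio = consensus_ratio, p_value = p,
             sig_05 = p < 0.05, sig_01 = p < 0.01, unevaluable = FALSE)
    })
  })
  arrange(res, .data$position, .data$alt)
}

#' Test for CREB1 enhancement of consensus binding
#'
#' Two-sample t-test on log intensities of the consensus replicate spots
#' with vs without CREB1 (the published arrays show an approximately
#' two-fold, P < 0.0001 enhancement). Identical replicate sets
#' short-circuit to P = 1.
#'
#' @param panel_plus,panel_minus Panel summaries of normalised
#'   intensities.
#' @return One-row tibble `ratio`, `statistic`, `p_value`, `n_plus`,
#'   `n_minus`.
#' @export
consensus_enhancement_test <- function(panel_plus, panel_minus) {
  xp <- panel_plus$spots[[which(panel_plus$role == "consensus")]]
  xm <- panel_minus$spots[[which(panel_minus$role == "consensus")]]
  if (length(xp) < 2 || length(xm) < 2) {
    abort("need at least 2 unflagged consensus replicates per condition")
  }
  ratio <- stats::median(xp) / stats::median(xm)
  if (length(xp) == length(xm) && all(sort(xp) == sort(xm))) {
    return(tibble(ratio = ratio, statistic = 0, p_value = 1,
                  n_plus = length(xp), n_minus = length(xm)))
  }
  if (stats::sd(log(xp)) == 0 && stats::sd(log(xm)) == 0) {
    # degenerate (noise-free) replicates that differ: separation is exact
    return(tibble(ratio = ratio, statistic = Inf, p_value = 0,
                  n_plus = length(xp), n_minus = length(xm)))
  }
  tt <- stats::t.test(log(xp), log(xm))
  tibble(ratio = ratio, statistic = unname(tt$statistic),
         p_value = tt$p.value, n_plus = length(xp), n_minus = length(xm))
}

#' Join panel medians with external universal-PBM Z-scores
#'
#' Keys both tables by 8-mer in a canonical forward orientation (the
#' lexicographic minimum of a k-mer and its reverse complement), takes
#' the median panel intensity per 8-mer (several 16-mer panel sequences
#' share one ETS 8-mer) and inner-joins the external scores. Pearson and
#' Spearman correlations are attached as attribute `"correlation"`.
#'
#' @param panel Panel summary tibble.
#' @param zscores Tibble with columns `kmer` and `z`.
#' @param k Length of the motif prefix to key on.
#' @return Tibble `kmer`, `median`, `z`.
#' @export
join_external_zscores <- function(panel, zscores, k = 8L) {
  canon <- function(x) pmin(x, revcomp(x))
  lhs <- panel %>%
    mutate(kmer = canon(substr(.data$seq, 1L, k))) %>%
    group_by(.data$kmer) %>%
    summarise(median = stats::median(.data$median, na.rm = TRUE),
              .groups = "drop")
  rhs <- zscores %>%
    mutate(kmer = canon(.data$kmer)) %>%
    group_by(.data$kmer) %>%
    summarise(z = stats::median(.data$z), .groups = "drop")
  out <- inner_join(lhs, rhs, by = "kmer")
  if (nrow(out) == 0) abort("no overlapping k-mers between panel and Z-scores")
  attr(out, "correlation") <- tibble(
    pearson = stats::cor(out$median, out$z),
    spearman = stats::cor(out$median, out$z, method = "spearman")
  )
  out
}
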