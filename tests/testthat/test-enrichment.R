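# Motif occurrence counting, peak-group splitting and the enrichment
# score E.

test_that("motif counting matches a brute-force two-strand scan", {
  motif <- "CCGGAAGT"
  # genome equal to the motif itself
  occ0 <- count_motif_occurrences(c(chr1 = motif), motif)
  expect_equal(nrow(occ0), 1L)

  # toy 1-kb genome with 7 planted copies on mixed strands
  set.seed(8)
  bg <- paste(sample(c("A", "T"), 1000, TRUE), collapse = "")
  pos <- c(50, 200, 350, 500)
  neg <- c(650, 800, 950)
  g <- bg
  for (p in pos) g <- paste0(substr(g, 1, p - 1), motif,
                             substr(g, p + 8, nchar(g)))
  for (p in neg) g <- paste0(substr(g, 1, p - 1), revcomp(motif),
                             substr(g, p + 8, nchar(g)))
  occ <- count_motif_occurrences(c(chr1 = g), motif)
  expect_equal(nrow(occ), 7L)
  # brute-force oracle on both strands
  brute <- sort(c(brute_match_positions(g, motif),
                  brute_match_positions(g, revcomp(motif))))
  expect_equal(sort(occ$start), brute)

  # palindromic motif: one count per position, not two
  pal <- "GTGACGTCAC"
  gp <- paste0(strrep("A", 50), pal, strrep("A", 50))
  occp <- count_motif_occurrences(c(chr1 = gp), pal)
  expect_equal(nrow(occp), 1L)

  # Ns never match
  gn <- paste0("CCGGAAGN", strrep("T", 20))
  expect_equal(nrow(count_motif_occurrences(c(chr1 = gn), motif)), 0L)
})

test_that("peak groups partition GABPa peaks by CREB1 overlap", {
  gab <- tibble::tibble(contig = "chr1", start = c(10L, 100L, 200L),
                        end = c(50L, 150L, 250L))
  # empty CREB1 set: everything in minus
  grp0 <- split_peak_groups(gab, gab[0, ])
  expect_equal(nrow(grp0$plus), 0L)
  expect_equal(nrow(grp0$minus), 3L)

  # abutting half-open BED intervals share no base: read_bed converts
  path_g <- withr::local_tempfile(fileext = ".bed")
  path_c <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t0\t50", path_g)
  writeLines("chr1\t50\t80", path_c)
  grp1 <- split_peak_groups(read_bed(path_g), read_bed(path_c))
  expect_equal(nrow(grp1$plus), 0L)
  expect_equal(nrow(grp1$minus), 1L)

  # random toy sets against an O(n^2) oracle
  withr::with_seed(21, {
    g <- tibble::tibble(contig = sample(c("chr1", "chr2"), 40, TRUE),
                        start = sample.int(1000, 40))
    g$end <- g$start + sample.int(50, 40)
    c2 <- tibble::tibble(contig = sample(c("chr1", "chr2"), 25, TRUE),
                         start = sample.int(1000, 25))
    c2$end <- c2$start + sample.int(50, 25)
  })
  grp <- split_peak_groups(g, c2)
  oracle <- vapply(seq_len(nrow(g)), function(i) {
    any(c2$contig == g$contig[i] & c2$start <= g$end[i] &
          c2$end >= g$start[i])
  }, logical(1))
  expect_equal(nrow(grp$plus), sum(oracle))
  expect_equal(sort(c(grp$plus$start, grp$minus$start)), sort(g$start))
})

test_that("enrichment scores follow OCC_obs / (N * Lr / Lg)", {
  motif <- "ACGTAC"
  set.seed(3)
  g <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
  occ <- count_motif_occurrences(c(chr1 = g), motif)
  N <- nrow(occ)
  expect_gt(N, 0)
  # whole-genome group: E = 1 exactly
  whole <- tibble::tibble(contig = "chr1", start = 1L, end = 10000L)
  es <- enrichment_score(occ, whole, genome_length = 10000)
  expect_equal(es$enrichment, 1)
  expect_equal(es$occ_obs, N)

  # interval-tree counting equals per-position brute force on a split group
  grp <- tibble::tibble(contig = "chr1", start = c(1L, 4001L, 7500L),
                        end = c(2000L, 5000L, 9000L))
  es2 <- enrichment_score(occ, grp, genome_length = 10000)
  brute_obs <- sum(vapply(seq_len(N), function(i) {
    any(grp$start <= occ$end[i] & grp$end >= occ$start[i])
  }, logical(1)))
  expect_equal(es2$occ_obs, brute_obs)
  expect_equal(es2$L_r, 2000L + 1000L + 1501L)
  expect_equal(es2$enrichment, brute_obs / (N * es2$L_r / 10000))

  # additivity over disjoint groups
  a <- tibble::tibble(contig = "chr1", start = 1L, end = 3000L)
  b <- tibble::tibble(contig = "chr1", start = 5001L, end = 8000L)
  both <- dplyr::bind_rows(a, b)
  expect_equal(enrichment_score(occ, both, 10000)$occ_obs,
               enrichment_score(occ, a, 10000)$occ_obs +
                 enrichment_score(occ, b, 10000)$occ_obs)

  # invariance to interval fragmentation of the same covered bases
  frag <- tibble::tibble(contig = "chr1",
                         start = c(1L, 1001L, 4001L, 7500L),
                         end = c(1000L, 2000L, 5000L, 9000L))
  expect_equal(enrichment_score(occ, frag, 10000)$enrichment,
               es2$enrichment)

  expect_error(enrichment_score(occ, whole, genome_length = 100), "L_r")
})

test_that("E concentrates near 1 under uniform random placement", {
  set.seed(5)
  g <- paste(sample(c("A", "C", "G", "T"), 50000, TRUE), collapse = "")
  occ <- count_motif_occurrences(c(chr1 = g), "ACGT")
  es <- withr::with_seed(6, {
    vapply(1:100, function(i) {
      starts <- sort(sample.int(49000, 10))
      grp <- tibble::tibble(contig = "chr1", start = starts,
                            end = starts + 999L)
      enrichment_score(occ, grp, 50000)$enrichment
    }, numeric(1))
  })
  expect_lt(abs(mean(es) - 1), 0.1)
})

test_that("the printed worked example reproduces the 96-fold enrichment", {
  ex <- enrichment_from_counts(1645, 8608, 0.002)
  expect_equal(round(ex$enrichment), 96)
  expect_equal(ex$pct_bound, 19.1, tolerance = 0.01)
})

test_that("SNP enrichment profiles cover the consensus and 24 variants", {
  gs <- simulate_genome_peaks(genome_length = 80000, n_coop = 10,
                              n_indep = 15, n_single = 10, n_decoy = 5,
                              seed = 17)
  prof <- snp_enrichment_profile(gs$genome, gs$gabpa_peaks, gs$creb1_peaks)
  expect_equal(nrow(prof), 25L)
  expect_equal(sum(is.na(prof$position)), 1L)
  # consensus is enriched in the co-bound group well above background
  cons <- prof[is.na(prof$position), ]
  expect_gt(cons$E_plus, 5)
  # per-variant Fisher p-values are defined wherever counts exist
  expect_true(all(is.na(prof$p_fisher) | (prof$p_fisher >= 0 &
                                            prof$p_fisher <= 1)))

  # whole-genome groups force E = 1 for every motif with occurrences
  whole <- tibble::tibble(contig = "chr1", start = 1L, end = 80000L)
  prof2 <- snp_enrichment_profile(gs$genome, whole, whole)
  expect_true(all(abs(prof2$E_plus[prof2$N > 0] - 1) < 1e-12))
})
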