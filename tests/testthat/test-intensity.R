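# Replicate aggregation, normalisation, fold changes, cooperativity
# ratios and the strong/weak comparison.

spot_row <- function(core, intensity, flag = FALSE, condition = "8:0",
                     category = "snp_variant_CC") {
  tibble::tibble(probe_id = seq_along(intensity), core_seq = core,
                 category = category, sector = 1L, array = 1L,
                 condition = condition, intensity = intensity, flag = flag)
}

test_that("replicate aggregation uses unflagged medians", {
  sp <- spot_row("AAAA", rep(7, 40))
  agg <- aggregate_replicates(sp)
  expect_equal(agg$median, 7)
  expect_equal(agg$n, 40L)

  sp2 <- spot_row("AAAA", c(1, 2, 3, 100), flag = c(FALSE, FALSE, FALSE, TRUE))
  agg2 <- aggregate_replicates(sp2)
  expect_equal(agg2$median, 2)
  expect_equal(agg2$n, 3L)

  # even replicate count: mean of the central pair
  sp3 <- spot_row("AAAA", c(1, 2, 3, 4))
  expect_equal(aggregate_replicates(sp3)$median, 2.5)

  # all-flagged sequences are missing, never zero
  sp4 <- dplyr::bind_rows(spot_row("AAAA", 1:4),
                          spot_row("CCCC", 5:8, flag = TRUE))
  expect_warning(agg4 <- aggregate_replicates(sp4), "missing")
  expect_true(is.na(agg4$median[agg4$core_seq == "CCCC"]))
  expect_equal(agg4$n[agg4$core_seq == "CCCC"], 0L)
})

test_that("condition normalisation equalises reference medians", {
  base <- dplyr::bind_rows(
    spot_row("CCGGATTTTTAAAAA", stats::rlnorm(50, 5), category = "core_CC"),
    spot_row("CCGGAAGTGACGTCAC", stats::rlnorm(50, 7))
  )
  other <- dplyr::mutate(base, condition = "8:8", intensity = intensity * 3)
  both <- dplyr::bind_rows(base, other)
  norm <- normalize_conditions(both)
  f <- scale_factors(norm)
  expect_equal(f$factor[f$condition == "8:8"] / f$factor[f$condition == "8:0"],
               1 / 3, tolerance = 1e-12)
  ref <- dplyr::filter(norm, category == "core_CC") %>%
    dplyr::group_by(condition) %>%
    dplyr::summarise(m = median(intensity))
  expect_equal(ref$m[1], ref$m[2], tolerance = 1e-12)

  # identical tables -> unit factors
  same <- dplyr::bind_rows(base, dplyr::mutate(base, condition = "8:8"))
  expect_equal(scale_factors(normalize_conditions(same))$factor, c(1, 1))

  expect_error(normalize_conditions(dplyr::filter(both, category != "core_CC")),
               "reference")
})

test_that("ratio pipeline is invariant to a global gain on one condition", {
  cfg <- sim_config()
  d <- dplyr::filter(full_design(),
                     grepl("^snp", category) | category == "core_CC")
  spm <- simulate_array(d, "8:0", cfg, sectors = 1, arrays = 1, seed = 31)
  spp <- simulate_array(d, "8:8", cfg, sectors = 1, arrays = 1, seed = 32)
  run <- function(gain) {
    spots <- dplyr::bind_rows(
      spm, dplyr::mutate(spp, intensity = intensity * gain))
    norm <- normalize_conditions(spots)
    pp <- summarize_snp_panel(dplyr::filter(norm, condition == "8:8"),
                              ETS_CRE_CC)
    pm <- summarize_snp_panel(dplyr::filter(norm, condition == "8:0"),
                              ETS_CRE_CC)
    cooperativity_ratio(pp, pm)$coop_ratio
  }
  expect_equal(run(1), run(5), tolerance = 1e-9)
})

test_that("replicate correlation matches the shared-signal expectation", {
  cfg <- sim_config()
  d <- snp_design()
  a <- simulate_array(d, "8:0", cfg, sectors = 1, arrays = 1, seed = 41)
  b <- simulate_array(d, "8:0", cfg, sectors = 1, arrays = 1, seed = 42)
  expect_equal(replicate_correlation(a, a), 1.0)
  r <- replicate_correlation(a, b)
  # analytic rho: shared log-signal variance over total log variance
  mu <- expected_intensity(unique(d$core_seq), "8:0", cfg)
  tau2 <- stats::var(log(mu)[match(d$core_seq, unique(d$core_seq))])
  sigma2 <- log(1 + cfg$noise_cv^2)
  rho <- tau2 / (tau2 + sigma2)
  expect_lt(abs(r - rho), 0.05)
  expect_error(replicate_correlation(head(a, 2), head(b, 2)), "3")
})

test_that("SNP fold changes recover programmed reductions and censor at background", {
  cfg <- noiseless_config()
  sp <- simulate_array(snp_design(), "8:0", cfg, sectors = 1, arrays = 1,
                       seed = 3)
  panel <- summarize_snp_panel(sp, ETS_CRE_CC)
  fc <- snp_fold_change(panel, background = cfg$background)
  expect_equal(max(fc$fold_change[fc$position %in% 3:5]), 27)
  expect_false(any(fc$censored))
  # a SNP median equal to consensus gives fold 1 (consensus itself: check
  # via a hand-built panel)
  hand <- panel
  hand$median[hand$seq == "CCGGAAGTGACGTCAA"] <-
    hand$median[hand$role == "consensus"]
  fc2 <- snp_fold_change(hand, background = cfg$background)
  expect_equal(fc2$fold_change[fc2$seq == "CCGGAAGTGACGTCAA"], 1)
  # censoring: a SNP at the floor reports the floor-limited fold
  hand2 <- panel
  hand2$median[hand2$seq == "CCGGAAGTGACGTCAA"] <- cfg$background + 1
  fc3 <- snp_fold_change(hand2, background = cfg$background,
                         floor = cfg$background + 2)
  row <- dplyr::filter(fc3, seq == "CCGGAAGTGACGTCAA")
  expect_true(row$censored)
  expect_equal(row$fold_change, cfg$scale / 2)
})

test_that("cooperativity ratios hit the configured factors without noise", {
  cfg20 <- noiseless_config(gamma_table = c(CCGGAAGT = 2, GCGGAAGT = 2,
                                            CCGGACGT = 20))
  d <- snp_design()
  pm <- summarize_snp_panel(simulate_array(d, "8:0", cfg20, sectors = 1,
                                           arrays = 1, seed = 1), ETS_CRE_CC)
  pp <- summarize_snp_panel(simulate_array(d, "8:8", cfg20, sectors = 1,
                                           arrays = 1, seed = 1), ETS_CRE_CC)
  cr <- cooperativity_ratio(pp, pm, cfg20$background, cfg20$background)
  expect_equal(cr$coop_ratio[cr$role == "consensus"], 2)
  expect_equal(cr$coop_ratio[cr$seq == "CCGGACGTGACGTCAC"], 20)
  # identical panels give unit ratios
  cr2 <- cooperativity_ratio(pm, pm, cfg20$background, cfg20$background)
  expect_true(all(cr2$coop_ratio == 1))
})

test_that("strong/weak ratios compare contexts against the 4-fold consensus", {
  cfg <- noiseless_config()
  d <- snp_design()
  sp <- simulate_array(d, "8:0", cfg, sectors = 1, arrays = 1, seed = 2)
  pcc <- summarize_snp_panel(sp, ETS_CRE_CC)
  pgc <- summarize_snp_panel(sp, ETS_CRE_GC)
  sw <- strong_weak_ratio(pcc, pgc, background = cfg$background,
                          n_boot = 50, seed = 1)
  expect_equal(sw$consensus_ratio[1], 4)
  # positions 2-16 carry the 4-fold context difference; the position-1
  # substitutions give the same sequence in both panels (ratio 1)
  expect_true(all(abs(sw$ratio[sw$position > 1] - 4) < 1e-9))
  expect_true(all(abs(sw$ratio[sw$position == 1] - 1) < 1e-9))
  # identical contexts: every ratio 1
  sw2 <- strong_weak_ratio(pcc, pcc, background = cfg$background,
                           n_boot = 50, seed = 1)
  expect_true(all(abs(sw2$ratio - 1) < 1e-9))
})

test_that("strong/weak bootstrap keeps nominal type-I error on null panels", {
  # null: one SNP whose strong/weak ratio equals the consensus ratio (4)
  sdlog <- sqrt(log(1 + 0.3^2))
  n_panels <- 300
  hits <- withr::with_seed(99, {
    vapply(seq_len(n_panels), function(i) {
      mk_panel <- function(level) {
        sp_cons <- stats::rlnorm(40, log(level), sdlog)
        sp_snp <- stats::rlnorm(40, log(level / 5), sdlog)
        tibble::tibble(
          seq = c("CONS", "SNP1"), role = c("consensus", "snp"),
          position = c(NA, 1L), ref = c(NA, "C"), alt = c(NA, "A"),
          median = c(median(sp_cons), median(sp_snp)),
          mad = 0, n = 40L, spots = list(sp_cons, sp_snp))
      }
      sw <- strong_weak_ratio(mk_panel(4000), mk_panel(1000),
                              n_boot = 199, seed = i)
      sw$sig_05
    }, logical(1))
  })
  rate <- mean(hits)
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.12)
})

test_that("consensus enhancement test behaves under effect and null", {
  cfg <- sim_config()
  d <- dplyr::filter(snp_design(), grepl("consensus_CC", category))
  for (s in 1:5) {
    pm <- suppressWarnings(
      summarize_snp_panel(simulate_array(d, "8:0", cfg, sectors = 1,
                                         arrays = 1, seed = 100 + s),
                          ETS_CRE_CC))
    pp <- suppressWarnings(
      summarize_snp_panel(simulate_array(d, "8:8", cfg, sectors = 1,
                                         arrays = 1, seed = 200 + s),
                          ETS_CRE_CC))
    tt <- consensus_enhancement_test(pp, pm)
    expect_lt(tt$p_value, 1e-4)
    expect_gt(tt$ratio, 1.5)
  }
  # identical replicate sets short-circuit to P = 1
  pm1 <- suppressWarnings(
    summarize_snp_panel(simulate_array(d, "8:0", cfg, sectors = 1,
                                       arrays = 1, seed = 7), ETS_CRE_CC))
  expect_equal(consensus_enhancement_test(pm1, pm1)$p_value, 1)
  # null: no CREB1 effect anywhere -> uniform-ish P
  cfg_null <- sim_config(gamma_table = c(CCGGAAGT = 1, GCGGAAGT = 1),
                         gamma_default = 1, gamma_core = 1)
  ps <- vapply(1:40, function(s) {
    pm <- suppressWarnings(
      summarize_snp_panel(simulate_array(d, "8:0", cfg_null, sectors = 1,
                                         arrays = 1, seed = 300 + s),
                          ETS_CRE_CC))
    pp <- suppressWarnings(
      summarize_snp_panel(simulate_array(d, "8:8", cfg_null, sectors = 1,
                                         arrays = 1, seed = 400 + s),
                          ETS_CRE_CC))
    consensus_enhancement_test(pp, pm)$p_value
  }, numeric(1))
  expect_lt(mean(ps < 0.05), 0.2)
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
})

test_that("external Z-score joins key on canonical 8-mers", {
  cfg <- noiseless_config()
  sp <- simulate_array(snp_design(), "8:0", cfg, sectors = 1, arrays = 1,
                       seed = 1)
  panel <- summarize_snp_panel(sp, ETS_CRE_CC)
  # toy external table: three 8-mers, one reverse-complemented
  z <- tibble::tibble(kmer = c("CCGGAAGT", revcomp("CCAGAAGT"), "TTTTTTTT"),
                      z = c(10, 2, 0))
  j <- join_external_zscores(panel, z)
  expect_equal(nrow(j), 2L)  # TTTTTTTT has no panel partner
  expect_equal(j$z[j$kmer == pmin("CCGGAAGT", revcomp("CCGGAAGT"))], 10)
  # join bound: at most one row per panel 8-mer
  expect_lte(nrow(j), length(unique(substr(panel$seq, 1, 8))))
  # self-join consistency: ranks correlate perfectly
  z2 <- tibble::tibble(kmer = substr(panel$seq, 1, 8), z = panel$median)
  j2 <- join_external_zscores(panel, z2)
  expect_equal(attr(j2, "correlation")$spearman, 1)
  expect_error(join_external_zscores(panel, tibble::tibble(kmer = "TTTTTTTT",
                                                           z = 1)),
               "overlap")
})
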