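# etscre

Analysis toolkit for custom protein binding microarrays (PBMs) that probe
cooperative binding of the ETS-domain transcription factor monomer GABPα
and the B-ZIP dimer CREB1 to overlapping ETS and CRE motifs.

## The problem

The ETS motif (C/G·CGGA**GT**) and the palindromic CRE motif
(**GT**GACGTCAC) can overlap in a shared GT dinucleotide, producing the
16-bp composite ETS↔CRE element `C/G CGGAAGT GACGTCAC`. On this
composite, CREB1 enhances GABPα binding without protein–protein contact —
roughly two-fold on the canonical element and far more strongly on
specific single-base variants (SNPs). Measuring that cooperativity, and
exploiting it to find cooperatively bound loci in ChIP-seq data, takes a
dedicated computational pipeline:

* **Array design** — enumerate the probe content of a 177,440-feature
  custom array: all 4⁸ = 65,536 core 15-mers of each template
  `C/G CGGA―――――CG―――`, 40-fold replicated SNP panels of both composite
  16-mers (1,960 features per panel), genomic 36-mer occurrences, and the
  full 60-mer probe sequences with their constant 24-base
  primer-complement region.
* **Intensity analytics** — aggregate replicate spots to per-sequence
  medians, rescale conditions on probes containing only GABPα sites,
  estimate the array background, and compute SNP fold changes
  (consensus/SNP), cooperativity ratios (±CREB1) and strong/weak motif
  context ratios with bootstrap significance.
* **Binding models** — build a position weight matrix from SNP-panel
  medians (the highest-median sequence *S*ₘₐₓ anchors relative scores;
  per position the best base takes weight 1), convert it to a position
  frequency matrix (columns sum to 1), and scan sequences with a
  BEEML-style energy score: ε_i(b) = −ln(f_i(b)+ψ) + ln(max_b f_i(b)+ψ),
  window score 1/(1+e^{E−μ}).
* **Genomic enrichment** — count motif occurrences genome-wide, split
  GABPα ChIP peaks by CREB1 overlap, and score enrichment
  E = OCC_obs / OCC_exp with OCC_exp = N·L_r/L_g.
* **Cooperative calling** — build one dinucleotide-preserving shuffled
  decoy per peak sequence (Altschul–Erickson Eulerian walk), estimate
  per-model FDRs as the fraction of at-or-above-cutoff sequences that
  are decoys, and call a region cooperative when it reaches FDR < 5%
  under a GABPα+CREB1-derived model while staying at FDR ≥ 15% under
  every single-protein model.
* **Synthetic data** — a generator with programmed affinities and
  cooperativity factors (log-normal spot noise, sector effects, flagged
  spots, toy genomes with planted sites) stands in for the wet-lab
  arrays, so every stage is testable against known ground truth.

The package is tidyverse-native: functions take data frames and return
tibbles, result types have `autoplot()` methods, and models support
`tidy()`/`glance()`.

## Worked example

Simulate both array conditions at the study settings (40-replicate SNP
panels, four sectors, two replicate arrays, 30% spot noise), then
recover the cooperativity profile of the CC-motif panel:

```r
library(etscre)
library(dplyr)

design <- build_design(design_params())      # 134,992 probes
cfg <- sim_config()                          # programmed effect sizes
spots <- bind_rows(
  simulate_array(design, "8:0", cfg, sectors = 1:4, arrays = 2, seed = 1),
  simulate_array(design, "8:8", cfg, sectors = 1:4, arrays = 2, seed = 2))

norm <- normalize_conditions(spots)          # equalise GABPα-only probes
bg <- estimate_background(norm)
panel_minus <- summarize_snp_panel(filter(norm, condition == "8:0"), ETS_CRE_CC)
panel_plus  <- summarize_snp_panel(filter(norm, condition == "8:8"), ETS_CRE_CC)

coop <- cooperativity_ratio(panel_plus, panel_minus,
  background_plus  = bg$background[bg$condition == "8:8"],
  background_minus = bg$background[bg$condition == "8:0"])
coop %>% arrange(desc(coop_ratio)) %>% head(5)
#> # A tibble: 5 × 6
#>   seq              role  position ref   alt   coop_ratio
#>   <chr>            <chr>    <int> <chr> <chr>      <dbl>
#> 1 CCGGACGTGACGTCAC snp          6 A     C          22.0
#> 2 TCGGAAGTGACGTCAC snp          1 C     T          19.8
#> 3 CCGGAACTGACGTCAC snp          7 G     C          18.5
#> 4 CGGGAAGTGACGTCAC snp          2 C     G          18.1
#> 5 CAGGAAGTGACGTCAC snp          2 C     A           6.49
```

The most CREB1-enhanced variants are the flank SNPs of the ETS motif
(CCGGA**C**GT ≈ 22-fold here), exactly the sequences that bind GABPα
poorly on its own. The consensus enhancement is close to two-fold and
overwhelmingly significant across the 40-replicate panels:

```r
consensus_enhancement_test(panel_plus, panel_minus)
#> # A tibble: 1 × 5
#>   ratio statistic   p_value n_plus n_minus
#> 1  1.95      40.6 2.22e-231    632     631
```

The in-vivo enrichment arithmetic, from reported counts alone: 1,645 of
8,608 genomic occurrences of the consensus ETS 8-mer inside peaks
covering 0.2% of the genome is a ~96-fold enrichment with 19.1% of
occurrences bound:

```r
enrichment_from_counts(1645, 8608, 0.002)
#> # A tibble: 1 × 6
#>   occ_obs     n lr_over_lg occ_exp enrichment pct_bound
#> 1    1645  8608      0.002    17.2       95.6      19.1
```

`run_pipeline(pipeline_config(seed = 1))` chains everything — array
simulation, panel analytics, model building, a toy genome with planted
cooperative sites, enrichment profiling and the FDR-based cooperative
caller — into one seeded, fully reproducible run.

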