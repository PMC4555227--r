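---
title: "Methods: measuring and exploiting cooperative GABPa-CREB1 binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring and exploiting cooperative GABPa-CREB1 binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, estimators and design choices behind
`etscre`. The package analyses custom protein binding microarrays (PBMs)
built around the composite ETS↔CRE element — the 16-mer
`C/G CGGAAGT GACGTCAC` in which the ETS motif bound by the GABPα monomer
and the CRE motif bound by the CREB1 dimer overlap in a shared GT
dinucleotide — and uses the derived binding models to locate genomic
regions where the two factors are likely to bind cooperatively.

## The array and its probe classes

The array carries four identical sectors of 177,440 single-stranded
60-mers, each ending in a constant 24-base primer-complement region on
the slide side (`GGACACACTTTAACACATGGAGAG`), used to make the probes
double-stranded before the binding reaction. Three probe classes matter
to the analysis:

* **Core variants.** All 4⁸ 15-mers of each template
  `C/G CGGA―――――CG―――` (65,536 per 5′ base). Most of these carry a
  functional ETS core but a disrupted CRE half-site; `etscre` uses the
  CRE-disrupted subset (two or more mismatches to the CRE half) as the
  GABPα-only normalisation reference, and the bottom decile of their
  per-sequence medians as the background estimate.
* **SNP panels.** The two composite 16-mers plus all 48 single-base
  substitutions each, every sequence printed as 40 replicate features.
  These are the quantitative heart of the design: medians over 40
  replicates are stable enough to support fold-change estimates across
  a dynamic range of two orders of magnitude.
* **Genomic occurrences.** 36-mers covering template matches in real
  genomes. The probe assembler places a 15-mer pattern match with 11 bp
  of upstream and 10 bp of downstream genomic flank; minus-strand
  matches are reverse-complemented so the stored site always carries
  the pattern on the forward (probe) strand. The exact flank split is
  not recoverable from the published layout; centring the core is our
  choice and is configurable. For cores shorter than 16 bases the
  3′ scaffold flank is recycled to keep every probe at exactly 60
  bases — again a convention of this package, since only the 16-mer
  and 36-mer layouts are printed.

## The synthetic intensity model

The generator (`sim_config()`, `simulate_array()`) stands in for the
wet-lab arrays. A probe's expected intensity is

    mu(s) = background + scale * a(s) * g(s, condition)

with

* `a(s)` — relative GABPα affinity, the product of per-position ETS
  mismatch effects (consensus bases = 1) times a mild multiplier (0.9)
  per CRE-half mismatch. The per-position table encodes the reported
  effect sizes: GGA-core substitutions (positions 3–5) reduce binding
  10- to 27-fold; the 5′ base G variant is 4-fold weaker; flank
  substitutions are variable, with the four strongly cooperative SNPs
  (`TCGGAAGT`, `CGGGAAGT`, `CCGGACGT`, `CCGGAACT`) among the most
  deleterious (1/18–1/25). Multi-mismatch sequences multiply their
  per-position effects — an independence assumption adopted for lack of
  higher-order data.
* `g(s)` — the cooperativity factor. With CREB1 present and the CRE
  half-site intact, `g = gamma(s)`: 2 for both consensus composites,
  3 for GGA-core SNPs, and up to 23 for the strongly enhanced flank
  SNPs (`CCGGACGT` carries the maximum). One CRE mismatch damps the
  enhancement by scaling `gamma − 1` by 0.75 (CRE SNPs act through
  CREB1, not GABPα); two or more abolish it. The constraint
  `a(s) * gamma(s) < 2` holds for every SNP, so no variant ever
  outbinds the canonical motif in the presence of CREB1.
* Spot noise is multiplicative log-normal with coefficient of variation
  `noise_cv` (default 0.3): PBM intensities are strictly positive and
  right-skewed, and identical replicates spread about two-fold.
  Defaults: `background = 100`, `scale = 10000` (a clean,
  high-signal-to-background scan), per-sector factors of 1 (the four
  sectors are identical by design), 1% flagged spots.

The defaults are the study conditions; they were chosen once from the
reported effect sizes and are not adjusted per analysis.

What the generator does *not* emulate: scanner saturation (available
only as an optional cap), spatial artifacts and sector gradients beyond
a scalar factor, sequence-dependent probe accessibility, and the
compressed dynamic range of real scans. Passing recovery tests
therefore demonstrate correctness of the estimators under the stated
noise model, not performance on raw array images.

## Intensity analytics

All ratio statistics are computed on normalised, background-subtracted
per-sequence medians; logs are used internally, ratios are reported on
the linear scale.

* **Aggregation** excludes flagged spots and reports sequences with no
  unflagged spots as missing, never zero.
* **Normalisation** rescales each condition so the median over the
  CRE-disrupted core probes (GABPα-only reference) equals the geometric
  mean across conditions. Any global gain applied to one condition is
  absorbed exactly — a property the test suite asserts.
* **Background** is the median of the bottom decile of per-sequence
  core-probe medians; the censoring floor is that value plus twice the
  MAD of the decile. Because even the weakest cores retain a small
  programmed affinity, the estimate sits a few intensity units above
  the true baseline; at the default signal-to-background ratio of 100
  this biases recovered folds by well under 1% (the zero-noise pipeline
  test quantifies it).
* **Fold changes** are consensus/SNP ratios of background-subtracted
  medians. SNP medians at or below the floor are censored: the reported
  fold uses the floor and carries a flag, since the true reduction is
  only bounded from below.
* **Cooperativity ratios** are (+CREB1)/(−CREB1) per sequence after
  normalisation; the consensus row is the reference enhancement.
* **Strong/weak comparison**: per-SNP ratio of CC-context to GC-context
  medians against the 4-fold consensus ratio. The published analysis
  cites an exact test whose dichotomisation of continuous ratios is not
  reconstructible; we instead use a stratified bootstrap over the
  replicate spots of the four groups (default 1,000 resamples,
  percentile two-sided p), which is assumption-light and calibrated —
  the suite checks its type-I error on null panels. Position-1 SNPs are
  shared sequences between the two panels (substituting the 5′ base of
  one motif yields the other), so their context ratio is 1 by
  construction, not 4.
* **Consensus enhancement** is a two-sample t-test on log intensities
  of the consensus replicates ± CREB1, with exact-equality and
  zero-variance short circuits for degenerate (noise-free) input.

## Binding models and energy scoring

The model construction follows the array-derived procedure exactly: the
panel sequence with the highest median over its replicates is `S_max`;
every variant gets the relative score `median / median(S_max)`; column
`i` of the PWM assigns each base the relative score of the
corresponding single-base variant, and the per-position highest-median
base takes weight 1. When `S_max` is not the canonical consensus — the
regular situation in the weak-motif (GC) panel, whose position-1
variant *is* the strong motif — relative scores are still taken against
`S_max` and the per-column maximum still anchors the 1; this literal
reading resolves an ambiguity in the published description and keeps
every column valid. Relative scores are floored at the
pseudo-frequency `pseudo` (default 1e-3) so mismatch energies stay
finite; `pwm_to_pfm()` renormalises columns to sum 1.

Scoring is occupancy-like: per-position energies
`eps_i(b) = −ln(f_i(b)+pseudo) + ln(max_b f_i(b)+pseudo)`, window energy
their sum, window score `1/(1+exp(E−mu))`. The chemical-potential
offset `mu` defaults to 0; the published analysis uses ranks, which are
invariant to `mu`, so the default is immaterial to the caller. Both
strands are scanned by default (the composite is non-palindromic and
ChIP peaks are unstranded); windows containing ambiguous bases are
skipped.

## Genomic enrichment

For a motif with `N` exact genome-wide occurrences (both strands,
palindromic double-hits deduplicated by position) and a peak group
covering `L_r` merged bases of an `L_g`-base genome, the enrichment
score is `E = OCC_obs / (N * L_r / L_g)`, where an occurrence counts as
observed if it overlaps the group by at least one base. Choices the
published description leaves open, made here and exposed as arguments:
regions are merged before `L_r` is computed (otherwise `E` depends on
interval fragmentation), `L_g` defaults to the non-N genome length, and
overlap means ≥ 1 bp rather than containment. GABPα peaks split into
the co-bound group (≥ 1 bp overlap with any CREB1 peak) and its exact
complement. The per-variant significance uses Fisher's exact test on
the 2×2 table of occurrences inside/outside each group; note the two
groups differ in total length, which the enrichment ratio, not the
count table, accounts for.

## The cooperative caller

Each peak sequence gets one dinucleotide-preserving decoy built by the
Altschul–Erickson construction (random last-edge arborescence into the
terminal base plus uniform permutation of remaining out-edges), which
preserves all 16 dinucleotide counts and both terminal bases; any other
letters (Ns) ride along as additional symbols. Per model, real and
decoy sequences are scored with the same best-window reduction, and a
region's FDR is the fraction of at-or-above-its-score sequences that
are decoys — the estimator as published, with ties counted on the
at-or-above side and no monotonisation. A region is called cooperative
when its FDR is below `fdr_coop` (default 5%) under at least one
cooperative model and at or above `fdr_single` (default 15%) under
every single-protein model. The single-side comparison is non-strict
(`>=`) so that the boundary `fdr_single = 0` disables the clause
cleanly; at the default 0.15 the two conventions differ only on exact
ties. Ranks are competition ranks (ties share the minimal rank).

Model sets: the default pipeline derives both sets from the canonical
(CC) composite panel — with CREB1 for the cooperative set, GABPα alone
for the single set. The GC-panel matrix is deliberately excluded from
the caller: because its `S_max` is the position-1 variant, its columns
are sharper than the data warrant and it collapses every region's
single-model FDR to zero. The GC panel instead powers the strong/weak
context analysis. Users may pass any model lists, including matrices
read from external files.

## The toy genome

`simulate_genome_peaks()` plants four site classes: cooperative-only
composites (flank-SNP ETS variants fused to an intact CRE) in peaks of
both factors; independently co-bound regions (consensus ETS plus a CRE
40 bp away) in peaks of both factors; plain consensus ETS sites in
GABPα-only peaks; lone CREs in CREB1-only peaks. The independent
co-bound class is an extension over the minimal three-class layout: the
co-bound call set needs the diagonal population of independently
explained sequences for the FDR competition to be meaningful.

Peak backgrounds are first-order Markov sequence: a GC-rich base
distribution (60% GC, CpG-island-like) mixed with the transition
statistics of the ETS 8-mer at weight `motif_bias = 0.8`. This choice
is load-bearing: a dinucleotide-preserving shuffle of Markov text is
distributionally exchangeable with the text itself, so decoys populate
the same mid-range of single-model scores as the real peak backgrounds
— the property real promoter-derived peaks have and that the FDR rule
needs. (Literal motif fragments spliced into backgrounds fail here:
the intact copy always outscores its own shuffle, and every region's
single-model FDR collapses to zero.) Peaks are 300 bp, placed on an
evenly pitched, shuffled grid with a guaranteed gap. The generator
parameters were fixed by this reasoning before the recovery tests were
frozen, and are not tuned per run.

## Numerical choices and degenerate inputs

* Seeds: every stochastic function takes a `seed` and leaves the
  caller's RNG untouched; the pipeline derives per-stage sub-seeds from
  one global seed, so stages are individually reproducible.
* Medians use R's standard convention (mean of the central pair for
  even counts); competition ranks use `min` tie-breaking so printed
  "rank #k" statements are reproducible under ties.
* Zero-variance replicate sets short-circuit the t-test; sequences
  shorter than a model score missing; sequences with no scorable window
  score 0 with a warning.
* Matrix files are plain text (JASPAR-like); reading auto-detects row-
  versus column-major layout, accepts count, frequency or weight
  scaling, rejects negative entries, and round-trips written models to
  1e-12.

## Problem sizes

The shipped tests simulate the full 134,992-probe design (genomic
blocks omitted) with four sectors and two replicate arrays per
condition for parameter recovery; panel-only designs (3,920 probes)
for model building; 200-kb toy genomes with 220 peaks for caller
recovery; 100-seed loops for shuffle conservation; 300 null panels at
199 bootstrap resamples for the type-I calibration. These sizes were
chosen so the whole suite exercises every estimator at full fidelity
while remaining a desk-scale computation.

## Known limitations

* The intensity model is a stand-in: recovery results validate the
  estimators, not the biology of real scans (saturation, spatial
  artifacts, sequence-dependent background are out of scope).
* Affinities of multi-mismatch sequences are multiplicative by
  assumption; the array's core-variant block could in principle test
  this, but no higher-order model is fitted.
* The caller's FDR estimator is the published fraction-of-decoys
  statistic, not a q-value: it is not monotone in the cutoff and can
  be conservative or anticonservative at sparsely populated scores.
* Real-genome analyses (hg19/ENCODE-scale counts) are outside the
  package's test envelope; the enrichment machinery is validated on
  toy genomes and on printed worked-example arithmetic.
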