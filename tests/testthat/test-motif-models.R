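# PWM construction from SNP panels, PFM conversion, energy scoring and
# matrix file IO.

# hand-built panel: consensus "ACG" with chosen medians for every SNP
toy_panel <- function(meds) {
  panel <- enumerate_snp_panel("ACG")
  panel$median <- unname(meds[panel$seq])
  panel$mad <- 0
  panel$n <- 40L
  panel
}

test_that("panel-derived PWMs follow the S_max relative-score rule", {
  # every SNP at half the consensus: columns are (1, .5, .5, .5)
  meds <- setNames(rep(500, 10), enumerate_snp_panel("ACG")$seq)
  meds["ACG"] <- 1000
  m <- build_pwm_from_panel(toy_panel(meds))
  expect_equal(unname(m$pwm["A", 1]), 1)
  expect_equal(sort(unname(m$pwm[, 2])), c(.5, .5, .5, 1))
  # and the PFM columns are (0.4, 0.2, 0.2, 0.2)
  expect_equal(sort(unname(m$pfm[, 1])), c(.2, .2, .2, .4))

  # hand-computed 3 x 4 matrix from arbitrary medians
  meds2 <- setNames(c(1000, 900, 800, 700, 600, 500, 400, 300, 200, 100),
                    c("ACG", "CCG", "GCG", "TCG", "AAG", "AGG", "ATG",
                      "ACA", "ACC", "ACT"))
  m2 <- build_pwm_from_panel(toy_panel(meds2))
  expect_equal(unname(m2$pwm[, 1]), c(1, .9, .8, .7))           # A C G T
  expect_equal(unname(m2$pwm[, 2]), c(.6, 1, .5, .4))
  expect_equal(unname(m2$pwm[, 3]), c(.3, .2, 1, .1))

  # S_max above the consensus: its base takes the 1 at its position
  meds3 <- meds
  meds3["TCG"] <- 2000
  m3 <- build_pwm_from_panel(toy_panel(meds3))
  expect_equal(unname(m3$pwm["T", 1]), 1)
  expect_equal(unname(m3$pwm["A", 1]), 0.5)   # consensus relative to S_max

  # missing variant -> informative error
  bad <- toy_panel(meds)[-3, ]
  expect_error(build_pwm_from_panel(bad), "missing")
})

test_that("PFM conversion normalises columns and is idempotent", {
  meds <- setNames(rep(500, 10), enumerate_snp_panel("ACG")$seq)
  meds["ACG"] <- 1000
  m <- build_pwm_from_panel(toy_panel(meds))
  expect_equal(unname(colSums(m$pfm)), rep(1, 3), tolerance = 1e-12)
  m2 <- pwm_to_pfm(pwm_to_pfm(m))
  expect_equal(m2$pfm, m$pfm, tolerance = 1e-15)
})

test_that("energy scores match an exhaustive window/strand oracle", {
  meds2 <- setNames(c(1000, 900, 800, 700, 600, 500, 400, 300, 200, 100),
                    c("ACG", "CCG", "GCG", "TCG", "AAG", "AGG", "ATG",
                      "ACA", "ACC", "ACT"))
  model <- build_pwm_from_panel(toy_panel(meds2))

  # the model's consensus scores 0.5 at mu = 0 and tops all sequences
  cons <- energy_score(model, c(x = "ACG"), both_strands = FALSE)
  expect_equal(cons$best_score, 0.5)
  all3 <- enumerate_core_variants("NNN")
  sc_all <- energy_score(model, setNames(all3, all3), both_strands = FALSE)
  expect_equal(sc_all$id[which.max(sc_all$best_score)], "ACG")
  # every single-SNP sequence scores at most the consensus
  expect_true(all(sc_all$best_score <= 0.5 + 1e-12))

  # exhaustive oracle on a 5-mer, both strands
  seq5 <- "TACGT"
  eps <- -log(model$pfm + model$pseudo) +
    rep(log(apply(model$pfm + model$pseudo, 2, max)), each = 4)
  brute <- function(s) {
    best <- -Inf
    for (str in c(s, revcomp(s))) {
      for (o in 1:(nchar(str) - 2)) {
        w <- substr(str, o, o + 2)
        codes <- match(strsplit(w, "")[[1]], c("A", "C", "G", "T"))
        e <- sum(eps[cbind(codes, 1:3)])
        best <- max(best, 1 / (1 + exp(e)))
      }
    }
    best
  }
  got <- energy_score(model, c(s = seq5))
  expect_equal(got$best_score, brute(seq5))

  # reverse-complement invariance with both strands on
  rc <- energy_score(model, c(s = revcomp(seq5)))
  expect_equal(rc$best_score, got$best_score)

  # ambiguous bases: windows skipped; no scorable window -> 0
  expect_warning(z <- energy_score(model, c(s = "NNNN")), "scorable")
  expect_equal(z$best_score, 0)
  part <- energy_score(model, c(s = "NACGN"), both_strands = FALSE)
  expect_equal(part$best_score, 0.5)  # only the central window scores
})

test_that("mismatch scores decrease with the position penalty", {
  meds2 <- setNames(c(1000, 900, 800, 700, 600, 500, 400, 300, 200, 100),
                    c("ACG", "CCG", "GCG", "TCG", "AAG", "AGG", "ATG",
                      "ACA", "ACC", "ACT"))
  model <- build_pwm_from_panel(toy_panel(meds2))
  # position-3 alternatives ordered A > C > T in the panel
  sc <- function(s) energy_score(model, setNames(s, s),
                                 both_strands = FALSE)$best_score
  expect_gt(sc("ACA"), sc("ACC"))
  expect_gt(sc("ACC"), sc("ACT"))
})

test_that("matrix files round-trip and auto-detect layout", {
  meds2 <- setNames(c(1000, 900, 800, 700, 600, 500, 400, 300, 200, 100),
                    c("ACG", "CCG", "GCG", "TCG", "AAG", "AGG", "ATG",
                      "ACA", "ACC", "ACT"))
  model <- build_pwm_from_panel(toy_panel(meds2), mu = 0.5, pseudo = 1e-4,
                                name = "toy")
  path <- withr::local_tempfile(fileext = ".txt")
  write_motif_matrix(model, path)
  back <- read_motif_matrix(path)
  expect_equal(back$pwm, model$pwm, tolerance = 1e-12)
  expect_equal(back$pfm, model$pfm, tolerance = 1e-12)
  expect_equal(back$mu, model$mu)
  expect_equal(back$pseudo, model$pseudo)
  expect_equal(back$name, "toy")

  # column-major external file (8 positions, header row)
  path2 <- withr::local_tempfile(fileext = ".txt")
  set.seed(1)
  freqs <- matrix(stats::runif(32, 0.05, 1), 8, 4)
  freqs <- freqs / rowSums(freqs)
  writeLines(c("A C G T",
               apply(round(freqs, 6), 1, paste, collapse = " ")), path2)
  ext <- read_motif_matrix(path2)
  expect_s3_class(ext, "energy_model")
  expect_equal(ncol(ext$pwm), 8L)
  expect_equal(unname(apply(ext$pwm, 2, max)), rep(1, 8))

  # degenerate one-column uniform matrix: all energies zero
  path3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(">uniform", "A [ 0.25 ]", "C [ 0.25 ]", "G [ 0.25 ]",
               "T [ 0.25 ]"), path3)
  uni <- read_motif_matrix(path3)
  expect_equal(unname(uni$pwm[, 1]), rep(1, 4))
  expect_equal(energy_score(uni, c(s = "A"),
                            both_strands = FALSE)$best_score, 0.5)

  # malformed input
  path4 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("A [ 0.2 ]", "C [ -0.1 ]", "G [ 0.2 ]", "T [ 0.2 ]"), path4)
  expect_error(read_motif_matrix(path4), "negative")
})

test_that("tidy and glance summarise energy models", {
  meds <- setNames(rep(500, 10), enumerate_snp_panel("ACG")$seq)
  meds["ACG"] <- 1000
  m <- build_pwm_from_panel(toy_panel(meds), name = "toy")
  td <- tidy(m)
  expect_equal(nrow(td), 12L)
  expect_equal(td$energy[td$position == 1 & td$base == "A"], 0)
  gl <- glance(m)
  expect_equal(gl$consensus, "ACG")
  expect_equal(gl$length, 3L)
})
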