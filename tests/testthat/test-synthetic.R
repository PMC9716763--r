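test_that("make_spacer honours length, seed and AT composition", {
  expect_equal(make_spacer(0, 0.77, 123), "")
  expect_identical(make_spacer(40, 0.77, 7), make_spacer(40, 0.77, 7))
  expect_false(identical(make_spacer(40, 0.77, 7), make_spacer(40, 0.77, 8)))
  s <- make_spacer(10000, 0.77, 1)
  expect_equal(nchar(s), 10000)
  at <- mean(strsplit(s, "")[[1]] %in% c("A", "T"))
  expect_gt(at, 0.75); expect_lt(at, 0.79)
})

test_that("synthetic amplicons follow the published architecture", {
  for (sp in STUDY_SPECIES) {
    a <- make_amplicon(sp, rng_seed = 3)
    # sequence is the exact concatenation ile + igs1 + gln + igs2 + met
    genus <- igstyper:::genus_of(sp)
    tr <- igstyper:::TRNA_STANDINS[[genus]]
    expect_identical(
      a$sequence,
      paste0(tr$ile, a$truth_igs1, tr$gln, a$truth_igs2, tr$met))
    # anchor segment lengths 56 / 69 / 29
    widths <- vapply(a$truth_anchors, function(iv) iv[2] - iv[1] + 1L,
                     integer(1))
    expect_equal(unname(widths), c(56L, 69L, 29L))
    # primer footprints at the amplicon termini
    expect_identical(substr(a$sequence, 1, 25), igstyper:::MITO_F_SEQ)
    L <- nchar(a$sequence)
    expect_identical(substr(a$sequence, L - 24, L), igstyper:::MITO_R_RC)
  }
  expect_error(make_amplicon("Anastrepha ludens"), "unknown species")
})

test_that("spacer lengths are drawn from the species windows", {
  expect_identical(make_amplicon("Bactrocera dorsalis", rng_seed = 3)$truth_igs1, "")
  expect_equal(nchar(make_amplicon("Ceratitis capitata", rng_seed = 5)$truth_igs1), 40)
  q <- vapply(1:30, function(s) {
    nchar(make_amplicon("Ceratitis quilicii", rng_seed = s)$truth_igs1)
  }, integer(1))
  expect_true(all(q %in% 62:64))
  expect_gt(length(unique(q)), 1)  # the window is actually sampled
  # overrides force exact lengths
  a <- make_amplicon("Ceratitis rosa", rng_seed = 1,
                     igs1_len_override = 7, igs2_len_override = 13)
  expect_equal(nchar(a$truth_igs1), 7)
  expect_equal(nchar(a$truth_igs2), 13)
})

test_that("per-genus tRNA stand-ins are mutually >= 85% identical with shared primer footprints", {
  cer <- igstyper:::TRNA_STANDINS$Ceratitis
  bac <- igstyper:::TRNA_STANDINS$Bactrocera
  ident <- function(a, b) {
    mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  }
  for (seg in c("ile", "gln", "met")) {
    expect_equal(nchar(cer[[seg]]), nchar(bac[[seg]]))
    expect_gte(ident(cer[[seg]], bac[[seg]]), 0.85)
  }
  expect_identical(substr(bac$ile, 1, 25), igstyper:::MITO_F_SEQ)
})

test_that("synthetic genomes embed exactly one primer pair and rotate reproducibly", {
  p <- mito_primers()
  g <- make_genome("Ceratitis rosa", 2000, rng_seed = 1)
  expect_equal(nchar(g$sequence), 2000)
  hf <- find_primer_sites(g$sequence, p$Mito_F, circular = TRUE,
                          require_three_prime_clean = FALSE)
  hr <- find_primer_sites(g$sequence, p$Mito_R, circular = TRUE,
                          require_three_prime_clean = FALSE)
  expect_equal(nrow(hf), 1); expect_equal(hf$strand, "+")
  expect_equal(hf$mismatches, 0)
  expect_equal(nrow(hr), 1); expect_equal(hr$strand, "-")
  # different genome seeds: different rotation, identical extracted product
  g2 <- make_genome("Ceratitis rosa", 2000, rng_seed = 2)
  expect_false(g$rotation == g2$rotation)
  a1 <- virtual_pcr(g$sequence, p$Mito_F, p$Mito_R, circular = TRUE)[[1]]
  a2 <- virtual_pcr(g2$sequence, p$Mito_F, p$Mito_R, circular = TRUE)[[1]]
  expect_identical(a1$sequence, a2$sequence)
  # length contract and minimum-size guard
  expect_equal(nchar(make_genome("Bactrocera dorsalis", 500,
                                 rng_seed = 2)$sequence), 500)
  expect_error(make_genome("Bactrocera dorsalis", 300), "total_length")
})

test_that("noise model is seeded, logged and rate-accurate", {
  s <- make_spacer(10000, 0.5, 3)
  expect_error(noise_model(sub_rate = -0.1), "rates")
  # identity case
  clean <- apply_noise(s, noise_model())
  expect_identical(clean$sequence, s)
  expect_equal(nrow(clean$log), 0)
  # substitution rate concentrates around its target
  nm <- noise_model(sub_rate = 0.01, seed = 9)
  noisy <- apply_noise(s, nm)
  expect_identical(noisy$sequence, apply_noise(s, nm)$sequence)
  expect_equal(nchar(noisy$sequence), nchar(s))
  hd <- sum(strsplit(noisy$sequence, "")[[1]] != strsplit(s, "")[[1]])
  expect_gt(hd / nchar(s), 0.005); expect_lt(hd / nchar(s), 0.015)
  expect_equal(nrow(noisy$log), hd)
  expect_true(all(noisy$log$type == "sub"))
  expect_true(all(noisy$log$from != noisy$log$to))
  # length change equals insertions minus deletions in the log
  nm2 <- noise_model(sub_rate = 0.005, ins_rate = 0.01, del_rate = 0.008,
                     seed = 4)
  out <- apply_noise(s, nm2)
  n_ins <- sum(out$log$type == "ins"); n_del <- sum(out$log$type == "del")
  expect_equal(nchar(out$sequence) - nchar(s), n_ins - n_del)
})

test_that("dissection recovers the generator's truth for every species over 20 seeds", {
  for (sp in STUDY_SPECIES) {
    refs <- synthetic_trna_refs(igstyper:::genus_of(sp))
    for (seed in 1:20) {
      a <- make_amplicon(sp, rng_seed = seed)
      d <- dissect_amplicon(a, refs)
      expect_identical(d$igs$igs1_seq, a$truth_igs1)
      expect_identical(d$igs$igs2_seq, a$truth_igs2)
      expect_equal(d$anchors$ile, a$truth_anchors$ile)
      expect_equal(d$anchors$gln, a$truth_anchors$gln)
      expect_equal(d$anchors$met, a$truth_anchors$met)
    }
  }
})

test_that("genome composition tracks the requested AT fraction", {
  ats <- vapply(1:25, function(i) {
    genome_composition(make_genome("Ceratitis capitata", 16000,
                                   rng_seed = i)$sequence)$at_percent
  }, numeric(1))
  expect_gt(mean(ats) / 100, 0.75)
  expect_lt(mean(ats) / 100, 0.79)
})

test_that("simulated batches pair FASTA records with a truth table", {
  b <- simulate_batch(n = 10, rng_seed = 7)
  expect_length(b$amplicons, 10)
  expect_equal(nrow(b$truth), 10)
  expect_identical(names(b$amplicons), b$truth$id)
  expect_equal(b$truth$igs1_len[b$truth$species == "Ceratitis capitata"],
               rep(40L, 2))
  # batches are reproducible from the seed
  b2 <- simulate_batch(n = 10, rng_seed = 7)
  expect_identical(b, b2)
})
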