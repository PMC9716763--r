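test_that("length calls map every observed length to exactly one status", {
  tab <- default_signature_table()
  statuses <- vapply(0:100, function(len) call_by_length(len, tab)$status,
                     character(1))
  expect_true(all(statuses %in% c("unambiguous", "ambiguous", "no_call")))
  # the five published lengths map to their species
  expect_equal(call_by_length(40, tab)$species, "Ceratitis capitata")
  expect_equal(call_by_length(2, tab)$species, "Ceratitis cosyra")
  for (len in 62:64) {
    expect_equal(call_by_length(len, tab)$species, "Ceratitis quilicii")
  }
  expect_equal(call_by_length(34, tab)$species, "Ceratitis rosa")
  expect_equal(call_by_length(0, tab)$species, "Bactrocera dorsalis")
  expect_equal(call_by_length(20, tab)$status, "no_call")
  # purity: repeated calls agree
  expect_identical(statuses,
                   vapply(0:100, function(len) call_by_length(len, tab)$status,
                          character(1)))
})

test_that("IGS-II lengths never yield an unambiguous call", {
  tab <- default_signature_table()
  for (len in 0:40) {
    expect_false(call_by_igs2_length(len, tab)$status == "unambiguous")
  }
  both <- call_by_igs2_length(18, tab, tolerance = 0)
  expect_setequal(both$candidates, c("Ceratitis rosa", "Ceratitis quilicii"))
  only_q <- call_by_igs2_length(16, tab, tolerance = 0)
  expect_equal(only_q$status, "ambiguous")
  expect_equal(only_q$candidates, "Ceratitis quilicii")
  expect_match(paste(only_q$notes, collapse = " "), "weak")
  expect_equal(call_by_igs2_length(40, tab)$status, "no_call")
})

test_that("percent identity counts gap columns in the denominator", {
  expect_equal(percent_identity("ACGT", "ACGT"), 100)
  expect_equal(percent_identity("ACGT", "ACGA"), 75)
  expect_equal(percent_identity("ACGT", "ACG"), 75)
  set.seed(2)
  s <- random_dna_str(120)
  expect_equal(percent_identity(s, s), 100)
  expect_error(percent_identity("", "ACGT"))
})

test_that("zero-noise amplicons classify unambiguously and correctly for all species x 20 seeds", {
  tab <- default_signature_table()
  for (sp in STUDY_SPECIES) {
    for (seed in 1:20) {
      cl <- classify(make_amplicon(sp, rng_seed = seed), table = tab)
      expect_equal(cl$status, "unambiguous")
      expect_equal(cl$species, sp)
    }
  }
})

test_that("unambiguous calls carry the confounder caveats", {
  cl <- classify(make_amplicon("Ceratitis quilicii", rng_seed = 3))
  expect_equal(cl$caveats$identity[cl$caveats$taxon == "Ceratitis fasciventris"],
               100)
  cl2 <- classify(make_amplicon("Bactrocera dorsalis", rng_seed = 3))
  expect_true("Bactrocera invadens" %in% cl2$caveats$taxon)
})

test_that("classification is orientation-invariant", {
  for (sp in c("Ceratitis cosyra", "Bactrocera dorsalis")) {
    a <- make_amplicon(sp, rng_seed = 9)
    fwd <- classify(a$sequence)
    rev <- classify(revcomp(a$sequence))
    expect_equal(rev$status, fwd$status)
    expect_equal(rev$species, fwd$species)
    expect_equal(rev$evidence$igs1_len, fwd$evidence$igs1_len)
    expect_equal(rev$evidence$orientation, "-")
  }
})

test_that("an IGS-II length incompatible with the called species downgrades to ambiguous", {
  # a quilicii-length IGS-I with a rosa-only IGS-II length (22 bp is
  # outside quilicii's expanded window [15,19])
  a <- make_amplicon("Ceratitis quilicii", rng_seed = 1,
                     igs2_len_override = 22)
  cl <- classify(a)
  expect_equal(cl$status, "ambiguous")
  expect_true("Ceratitis quilicii" %in% cl$candidates)
  expect_match(paste(cl$notes, collapse = " "), "IGS-II")
  # a consistent IGS-II leaves the call unambiguous
  ok <- classify(make_amplicon("Ceratitis quilicii", rng_seed = 1,
                               igs2_len_override = 17))
  expect_equal(ok$status, "unambiguous")
})

test_that("identity fallback rescues anchor failures near a reference and respects its floor and margin", {
  panel <- reference_panel()
  # emulate a resequenced reference specimen whose gln anchor is corrupted
  # beyond the anchoring identity threshold: the length pipeline fails,
  # the identity fallback recovers the species
  ref <- panel[["Ceratitis rosa"]]
  gln <- dissect_amplicon(ref, synthetic_trna_refs())$anchors$gln
  set.seed(77)
  pos <- sample(gln[1]:gln[2], 15)
  b <- strsplit(ref, "")[[1]]
  for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1)
  q <- paste(b, collapse = "")
  expect_error(dissect_amplicon(q, synthetic_trna_refs()),
               class = "anchor_failure")
  cl <- classify(q, panel = panel)
  expect_equal(cl$status, "unambiguous")
  expect_equal(cl$species, "Ceratitis rosa")
  expect_equal(cl$evidence$method, "identity_fallback")
  expect_gte(cl$identity_evidence$best_identity, 90)
  expect_gte(cl$identity_evidence$margin, 2.0)
  # an amplicon with an off-signature spacer length is close to no
  # reference and must not be mislabelled by the fallback
  odd <- make_amplicon("Ceratitis rosa", rng_seed = 2,
                       igs1_len_override = 10)
  expect_false(classify(odd, panel = panel)$status == "unambiguous")
  # without a panel the same query is a no_call
  expect_equal(classify(odd)$status, "no_call")
  # random queries are never called unambiguously
  set.seed(31)
  for (i in 1:50) {
    r <- random_dna_str(300)
    cl <- classify(r, panel = panel)
    expect_false(cl$status == "unambiguous")
  }
})

test_that("anchor failure without a panel propagates as an error", {
  set.seed(12)
  expect_error(classify(random_dna_str(300)), class = "anchor_failure")
})

test_that("batch classification tabulates statuses and survives failures", {
  b <- simulate_batch(n = 5, rng_seed = 3)
  amps <- b$amplicons
  amps[["junk"]] <- random_dna_str(300)
  tabres <- classify_batch(amps)
  expect_equal(nrow(tabres), 6)
  expect_equal(tabres$status[1:5], rep("unambiguous", 5))
  expect_equal(tabres$species[1:5], b$truth$species)
  expect_equal(tabres$status[6], "no_call")
})
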