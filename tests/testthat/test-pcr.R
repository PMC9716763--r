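test_that("primer GC content is computed exactly", {
  p <- mito_primers()
  expect_identical(compute_gc(p$Mito_F), 44.0)
  expect_identical(compute_gc(p$Mito_R), 36.0)
  expect_identical(compute_gc("GGCC"), 100.0)
  expect_identical(compute_gc("ATAT"), 0.0)
  expect_error(compute_gc("ACGN"), "N")
  expect_error(primer("bad", "ACGX"), "X")
})

test_that("primer sites are found on both strands with exact coordinates", {
  p <- mito_primers()
  set.seed(11)
  left <- random_dna_str(11); right <- random_dna_str(40)
  tpl <- paste0(left, p$Mito_F$sequence, right)
  h <- find_primer_sites(tpl, p$Mito_F)
  expect_equal(nrow(h), 1)
  expect_equal(h$strand, "+")
  expect_equal(h$start, 12)  # 0-based offset 11 -> 1-based 12
  expect_equal(h$mismatches, 0)
  expect_true(h$three_prime_clean)
  # a reverse-complemented site is reported on the minus strand
  tpl2 <- paste0(left, revcomp(p$Mito_R$sequence), right)
  h2 <- find_primer_sites(tpl2, p$Mito_R)
  expect_equal(nrow(h2), 1)
  expect_equal(h2$strand, "-")
  expect_equal(h2$mismatches, 0)
})

test_that("3'-end mismatches disqualify hits when required", {
  p <- mito_primers()
  seqs <- p$Mito_F$sequence
  # mutate the primer's 3'-terminal base in the template site
  mut <- paste0(substr(seqs, 1, 24), ifelse(substr(seqs, 25, 25) == "A", "C", "A"))
  tpl <- paste0("TTTTT", mut, "TTTTT")
  expect_equal(nrow(find_primer_sites(tpl, p$Mito_F,
                                      require_three_prime_clean = TRUE)), 0)
  h <- find_primer_sites(tpl, p$Mito_F, require_three_prime_clean = FALSE)
  expect_equal(nrow(h), 1)
  expect_equal(h$mismatches, 1)
  expect_false(h$three_prime_clean)
})

test_that("IUPAC degenerate bases match by set intersection", {
  p <- primer("deg", "ACGTR")  # R = A/G
  for (tpl in c("TTACGTATT", "TTACGTGTT")) {
    h <- find_primer_sites(tpl, p, max_mismatch = 0,
                           require_three_prime_clean = FALSE)
    expect_equal(sum(h$strand == "+"), 1)
    expect_equal(h$start[h$strand == "+"], 3)
    # agrees with the brute-force IUPAC scan on both strands
    expect_identical(h[, c("strand", "start", "mismatches")],
                     oracle_primer_sites(tpl, p$sequence, max_mismatch = 0),
                     ignore_attr = TRUE)
  }
  h <- find_primer_sites("TTACGTCTT", p, max_mismatch = 1,
                         require_three_prime_clean = FALSE)
  expect_equal(h$mismatches[h$strand == "+"], 1)  # C not in {A,G}
})

test_that("site finding matches the brute-force oracle on random templates", {
  p <- mito_primers()
  prim_seqs <- c(p$Mito_F$sequence, p$Mito_R$sequence)
  set.seed(42)
  for (i in 1:50) {
    len <- sample(300:5000, 1)
    circular <- i %% 2 == 0
    tpl <- random_template_with_sites(len, prim_seqs,
                                      n_sites = sample(0:3, 1))
    for (pr in list(p$Mito_F, p$Mito_R)) {
      got <- find_primer_sites(tpl, pr, circular = circular,
                               max_mismatch = 3,
                               require_three_prime_clean = FALSE)
      want <- oracle_primer_sites(tpl, pr$sequence, circular = circular,
                                  max_mismatch = 3)
      expect_identical(got[, c("strand", "start", "mismatches")],
                       want, ignore_attr = TRUE)
    }
  }
})

test_that("circular sites spanning the origin are found once", {
  p <- mito_primers()
  seqs <- p$Mito_F$sequence
  # split the site across the origin: last 10 bases at the start, first 15 at the end
  tpl <- paste0(substr(seqs, 16, 25), random_dna_str(400), substr(seqs, 1, 15))
  h <- find_primer_sites(tpl, p$Mito_F, circular = TRUE, max_mismatch = 0,
                         require_three_prime_clean = FALSE)
  expect_equal(nrow(h), 1)
  expect_equal(h$start, nchar(tpl) - 15 + 1)
  # same site invisible on the linearized template
  expect_equal(nrow(find_primer_sites(tpl, p$Mito_F, circular = FALSE,
                                      max_mismatch = 0,
                                      require_three_prime_clean = FALSE)), 0)
  # equals brute force over the doubled sequence
  want <- oracle_primer_sites(tpl, p$Mito_F$sequence, circular = TRUE,
                              max_mismatch = 0)
  expect_equal(h$start, want$start)
})

test_that("virtual PCR extracts the published 216 bp B. dorsalis product", {
  p <- mito_primers()
  g <- make_genome("Bactrocera dorsalis", 2000, rng_seed = 3)
  prods <- virtual_pcr(g$sequence, p$Mito_F, p$Mito_R, circular = TRUE)
  expect_length(prods, 1)
  expect_equal(prods[[1]]$length, 216)
  expect_identical(prods[[1]]$sequence, g$amplicon$sequence)
  expect_false(prods[[1]]$multi_product)
  # product length equals the sum of the generator's truth segments
  g2 <- make_genome("Ceratitis capitata", 2000, rng_seed = 5)
  a2 <- g2$amplicon
  expected <- 56 + nchar(a2$truth_igs1) + 69 + nchar(a2$truth_igs2) + 29
  prods2 <- virtual_pcr(g2$sequence, p$Mito_F, p$Mito_R, circular = TRUE)
  expect_equal(prods2[[1]]$length, expected)
})

test_that("virtual PCR errors cleanly without a reverse site and flags multiple products", {
  p <- mito_primers()
  tpl <- paste0("TTTTT", p$Mito_F$sequence, random_dna_str(200))
  expect_error(virtual_pcr(tpl, p$Mito_F, p$Mito_R),
               class = "no_product_error")
  # two forward sites -> two products, flagged and warned
  a <- make_amplicon("Ceratitis rosa", rng_seed = 1)$sequence
  tpl2 <- paste0(p$Mito_F$sequence, random_dna_str(30), a)
  expect_warning(
    prods <- virtual_pcr(tpl2, p$Mito_F, p$Mito_R, max_mismatch = 0),
    "multiple products")
  expect_length(prods, 2)
  expect_true(all(vapply(prods, `[[`, logical(1), "multi_product")))
})

test_that("virtual PCR is rotation- and strand-invariant on circular genomes", {
  p <- mito_primers()
  g <- make_genome("Ceratitis quilicii", 1000, rng_seed = 8)
  base <- virtual_pcr(g$sequence, p$Mito_F, p$Mito_R,
                      circular = TRUE)[[1]]$sequence
  L <- nchar(g$sequence)
  for (rot in c(137, 512, 999)) {
    rotated <- paste0(substr(g$sequence, rot + 1, L),
                      substr(g$sequence, 1, rot))
    expect_identical(
      virtual_pcr(rotated, p$Mito_F, p$Mito_R,
                  circular = TRUE)[[1]]$sequence, base)
  }
  rc <- virtual_pcr(revcomp(g$sequence), p$Mito_F, p$Mito_R,
                    circular = TRUE)
  expect_length(rc, 1)
  expect_identical(rc[[1]]$sequence, base)
  expect_equal(rc[[1]]$strand, "-")
})
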