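# Brute-force oracles and fixture builders shared across the suite.

STUDY_SPECIES <- c("Ceratitis capitata", "Ceratitis cosyra",
                   "Ceratitis quilicii", "Ceratitis rosa",
                   "Bactrocera dorsalis")

# Independent sliding-window mismatch scan (IUPAC set-intersection
# semantics), both strands, linear or circular. Deliberately naive: the
# reference against which find_primer_sites() is checked.
oracle_primer_sites <- function(template, primer_seq, circular = FALSE,
                                max_mismatch = 3L) {
  sets <- igstyper:::IUPAC_SETS
  compat <- outer(names(sets), names(sets), Vectorize(function(a, b) {
    length(intersect(sets[[a]], sets[[b]])) > 0
  }))
  dimnames(compat) <- list(names(sets), names(sets))
  L <- nchar(template)
  scan_one <- function(pat, strand) {
    w <- nchar(pat)
    scan <- if (circular) paste0(template, substr(template, 1L, w - 1L))
      else template
    tb <- strsplit(scan, "")[[1]]
    pb <- strsplit(pat, "")[[1]]
    n_pos <- nchar(scan) - w + 1L
    if (n_pos < 1) return(NULL)
    mism <- rep(0L, n_pos)
    for (j in seq_len(w)) {
      mism <- mism + !compat[cbind(tb[seq_len(n_pos) + j - 1L], pb[j])]
    }
    starts <- which(mism <= max_mismatch)
    starts <- starts[starts <= L]
    if (length(starts) == 0) return(NULL)
    data.frame(strand = strand, start = starts,
               mismatches = mism[starts])
  }
  res <- rbind(scan_one(toupper(primer_seq), "+"),
               scan_one(igstyper::revcomp(primer_seq), "-"))
  if (is.null(res)) {
    res <- data.frame(strand = character(), start = integer(),
                      mismatches = integer())
  }
  res[order(res$start, res$strand), c("strand", "start", "mismatches")]
}

# Random template with optional embedded primer variants (for the oracle
# equivalence checks to have non-trivial hits).
random_template_with_sites <- function(len, primer_seqs, n_sites = 2L,
                                       max_muts = 4L) {
  bases <- c("A", "C", "G", "T")
  tpl <- sample(bases, len, replace = TRUE)
  for (k in seq_len(n_sites)) {
    p <- strsplit(sample(primer_seqs, 1L), "")[[1]]
    nmut <- sample.int(max_muts + 1L, 1L) - 1L
    if (nmut > 0) {
      at <- sample.int(length(p), nmut)
      p[at] <- vapply(p[at], function(b) sample(setdiff(bases, b), 1L), "")
    }
    if (runif(1) < 0.5) p <- strsplit(igstyper::revcomp(
      paste(p, collapse = "")), "")[[1]]
    pos <- sample.int(len - length(p) + 1L, 1L)
    tpl[seq(pos, pos + length(p) - 1L)] <- p
  }
  paste(tpl, collapse = "")
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
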