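#' In-silico PCR
#'
#' Primer-site search and virtual amplification on linear or circular DNA
#' templates. Matching follows IUPAC semantics: a template base matches a
#' primer base iff their IUPAC sets intersect. Circular templates are
#' scanned across the origin by searching the doubled sequence and
#' deduplicating hits by modular start.
#'
#' @name insilico_pcr
NULL

#' Construct a primer
#'
#' @param id primer name.
#' @param sequence IUPAC DNA, 5'->3'.
#' @param reported_location optional `c(start, end)` (1-based inclusive) on
#'   the reference accession the primer was designed against.
#' @param reported_tm,reported_gc optional published melting temperature
#'   (deg C) and GC percent, kept as metadata.
#' @return a `primer` object.
#' @export
primer <- function(id, sequence, reported_location = NULL,
                   reported_tm = NULL, reported_gc = NULL) {
  sequence <- toupper(sequence)
  stopifnot(nchar(sequence) > 0)
  assert_iupac(sequence)
  structure(list(id = id, sequence = sequence,
                 reported_location = reported_location,
                 reported_tm = reported_tm, reported_gc = reported_gc),
            class = "primer")
}

#' The Mito_F/R primer pair
#'
#' The diagnostic pair amplifying the region between tRNA-Ile and tRNA-Met
#' in tephritid mitogenomes, with its published coordinates on the
#' B. dorsalis reference accession ON861824. The validation pairs
#' trnI_trnQ_F/R and rrnS_trnI_F/R are also provided; their products are
#' supported generically by [virtual_pcr()] but are not dissected.
#'
#' @return named list of `primer` objects.
#' @export
mito_primers <- function() {
  list(
    Mito_F = primer("Mito_F", "TGACAAAAGGGTTACCTTGATAGGG",
                    reported_location = c(12L, 36L),
                    reported_tm = 56.6, reported_gc = 44.0),
    Mito_R = primer("Mito_R", "ACCCAGTAGCTTAATTAGCTTATCT",
                    reported_location = c(203L, 227L),
                    reported_tm = 53.4, reported_gc = 36.0),
    trnI_trnQ_F = primer("trnI_trnQ_F", "TGAATTGCCTGACAAAAGGG",
                         reported_location = c(3L, 22L),
                         reported_tm = 53.5, reported_gc = 45.0),
    trnI_trnQ_R = primer("trnI_trnQ_R", "GGTATGAACCCAGTAGCTTA",
                         reported_location = c(215L, 234L),
                         reported_tm = 51.1, reported_gc = 45.0),
    rrnS_trnI_F = primer("rrnS_trnI_F", "GCTGGCACAAATTTAACCAA",
                         reported_location = c(14787L, 14806L),
                         reported_tm = 52.0, reported_gc = 40.0),
    rrnS_trnI_R = primer("rrnS_trnI_R", "CCCTTTTGTCAGGCAATTCA",
                         reported_location = c(3L, 22L),
                         reported_tm = 53.5, reported_gc = 45.0)
  )
}

#' GC content of a primer
#'
#' `100 * (G + C) / length`, reported to one decimal. Degenerate bases have
#' no exact GC contribution and raise an error naming the offending symbol.
#'
#' @param x a `primer` or a DNA string.
#' @return GC percent, one decimal.
#' @export
compute_gc <- function(x) {
  seq <- if (inherits(x, "primer")) x$sequence else toupper(x)
  assert_iupac(seq)
  bases <- strsplit(seq, "")[[1]]
  deg <- setdiff(unique(bases), c("A", "C", "G", "T"))
  if (length(deg) > 0) {
    stop("cannot compute exact GC with degenerate base(s): ",
         paste(deg, collapse = ", "), call. = FALSE)
  }
  round(100 * sum(bases %in% c("G", "C")) / length(bases), 1)
}

# Per-position IUPAC-compatible mismatch flags of a template window vs a
# primer, both as character vectors of equal length.
iupac_mismatch_flags <- function(window, primer_seq) {
  wb <- strsplit(window, "")[[1]]
  pb <- strsplit(primer_seq, "")[[1]]
  mapply(function(t, p) {
    length(intersect(IUPAC_SETS[[t]], IUPAC_SETS[[p]])) == 0
  }, wb, pb, USE.NAMES = FALSE)
}

#' Find primer binding sites
#'
#' Searches both strands: plus-strand hits match the primer directly;
#' minus-strand hits are positions where the reverse complement of the
#' primer matches the template (i.e. the primer binds the bottom strand).
#' Coordinates are 1-based inclusive on the given template; on circular
#' templates a site may extend past the template end (it wraps).
#'
#' @param template DNA string (IUPAC).
#' @param primer a `primer` object.
#' @param circular is the template circular?
#' @param max_mismatch maximum IUPAC-incompatible positions (default 3).
#' @param require_three_prime_clean drop hits with any mismatch in the last
#'   5 bases of the primer's 3' end (default TRUE; 3' fidelity is what makes
#'   PCR extension specific).
#' @return data frame: `primer_id`, `strand` (`+`/`-`), `start`, `end`,
#'   `mismatches`, `three_prime_clean`, sorted by `start`.
#' @export
find_primer_sites <- function(template, primer, circular = FALSE,
                              max_mismatch = 3L,
                              require_three_prime_clean = TRUE) {
  template <- toupper(template)
  assert_iupac(template)
  stopifnot(max_mismatch >= 0)
  L <- nchar(template)
  w <- nchar(primer$sequence)
  scan_seq <- if (circular) paste0(template, template) else template
  subj <- Biostrings::DNAString(scan_seq)

  one_strand <- function(pat, strand) {
    if (w > nchar(scan_seq)) return(NULL)
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subj,
                                  max.mismatch = max_mismatch,
                                  with.indels = FALSE, fixed = FALSE)
    if (length(m) == 0) return(NULL)
    starts <- BiocGenerics::start(m)
    if (circular) {
      canon <- ((starts - 1L) %% L) + 1L
      keep <- !duplicated(canon) & starts <= L
      # a hit may have been found only in the second copy (spans origin)
      extra <- !duplicated(canon) & starts > L & !(canon %in% starts[starts <= L])
      keep <- keep | extra
      starts <- canon[keep]
      m <- m[keep]
    }
    if (length(m) == 0) return(NULL)
    rows <- lapply(seq_along(starts), function(i) {
      s <- starts[i]
      window <- if (circular) substr_circ(template, s, w) else
        substr(template, s, s + w - 1L)
      flags <- iupac_mismatch_flags(window, pat)
      # flags are in left-to-right template order of the matched window;
      # the primer's 3'-terminal 5 bases sit at the right end on '+', at
      # the left end on '-' (where pat is the reverse complement).
      three_idx <- if (strand == "+") seq(w - 4L, w) else seq_len(5L)
      data.frame(primer_id = primer$id, strand = strand, start = s,
                 end = s + w - 1L, mismatches = sum(flags),
                 three_prime_clean = !any(flags[three_idx]))
    })
    do.call(rbind, rows)
  }

  hits <- rbind(one_strand(primer$sequence, "+"),
                one_strand(revcomp(primer$sequence), "-"))
  if (is.null(hits)) {
    hits <- data.frame(primer_id = character(), strand = character(),
                       start = integer(), end = integer(),
                       mismatches = integer(), three_prime_clean = logical())
  }
  if (require_three_prime_clean) hits <- hits[hits$three_prime_clean, ]
  hits <- hits[order(hits$start, hits$strand), ]
  rownames(hits) <- NULL
  hits
}

no_product_error <- function(msg) {
  structure(class = c("no_product_error", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Predict PCR products
#'
#' Pairs every forward-primer hit with every opposite-strand reverse-primer
#' hit whose geometry yields a product of at most `max_product_len` bp
#' (and at least the two primer footprints). Products are reported 5'->3'
#' from the forward primer and include both primer footprints. Multiple
#' products are all returned and flagged, with a warning: a clean assay
#' template yields a single band.
#'
#' @param template DNA string.
#' @param fwd,rev `primer` objects.
#' @param circular is the template circular?
#' @param max_mismatch per-primer mismatch tolerance (default 3).
#' @param max_product_len maximum product length in bp (default 2000).
#' @param template_id identifier echoed into the records.
#' @param require_three_prime_clean see [find_primer_sites()].
#' @return list of `amplicon_record` objects: `sequence`, `template_id`,
#'   `start`, `end` (1-based on the template; `end` may exceed the template
#'   length when the product spans a circular origin), `length`, `strand`
#'   (strand carrying the forward primer), `fwd_mismatches`,
#'   `rev_mismatches`, `multi_product`.
#' @export
virtual_pcr <- function(template, fwd, rev, circular = FALSE,
                        max_mismatch = 3L, max_product_len = 2000L,
                        template_id = "template",
                        require_three_prime_clean = TRUE) {
  template <- toupper(template)
  L <- nchar(template)
  hf <- find_primer_sites(template, fwd, circular, max_mismatch,
                          require_three_prime_clean)
  hr <- find_primer_sites(template, rev, circular, max_mismatch,
                          require_three_prime_clean)
  min_len <- nchar(fwd$sequence) + nchar(rev$sequence)
  products <- list()

  pair_up <- function(f, r) {
    # forward hit on '+' at [f$start, f$end]; reverse hit on '-' at
    # [r$start, r$end]: product runs f$start .. r$end on the plus strand.
    len <- r$end - f$start + 1L
    if (circular && len < min_len) len <- len + L
    if (len < min_len || len > max_product_len) return(NULL)
    if (!circular && r$end > L) return(NULL)
    seqs <- if (circular) substr_circ(template, f$start, len) else
      substr(template, f$start, f$start + len - 1L)
    list(sequence = seqs, start = f$start, end = f$start + len - 1L,
         length = len, fwd_mismatches = f$mismatches,
         rev_mismatches = r$mismatches)
  }

  add <- function(p, strand) {
    if (is.null(p)) return()
    p$template_id <- template_id
    p$strand <- strand
    products[[length(products) + 1]] <<- p
  }

  fw_plus <- hf[hf$strand == "+", ]; rv_minus <- hr[hr$strand == "-", ]
  for (i in seq_len(nrow(fw_plus))) for (j in seq_len(nrow(rv_minus)))
    add(pair_up(fw_plus[i, ], rv_minus[j, ]), "+")

  # forward primer binding the minus strand: compute on the reverse
  # complement and map coordinates back.
  fw_minus <- hf[hf$strand == "-", ]; rv_plus <- hr[hr$strand == "+", ]
  if (nrow(fw_minus) > 0 && nrow(rv_plus) > 0) {
    rc <- revcomp(template)
    flip <- function(h) {
      h2 <- h
      h2$start <- L - h$end + 1L
      h2$end <- L - h$start + 1L
      h2
    }
    for (i in seq_len(nrow(fw_minus))) for (j in seq_len(nrow(rv_plus))) {
      f2 <- flip(fw_minus[i, ]); r2 <- flip(rv_plus[j, ])
      # handle origin wrap after flipping
      if (f2$start < 1) { f2$start <- f2$start + L; f2$end <- f2$end + L }
      len <- r2$end - f2$start + 1L
      if (circular && len < min_len) len <- len + L
      if (len < min_len || len > max_product_len) next
      if (!circular && (r2$end > L || f2$start < 1)) next
      seqs <- if (circular) substr_circ(rc, f2$start, len) else
        substr(rc, f2$start, f2$start + len - 1L)
      add(list(sequence = seqs, start = L - (f2$start + len - 1L) + 1L,
               end = L - f2$start + 1L, length = len,
               fwd_mismatches = fw_minus[i, "mismatches"],
               rev_mismatches = rv_plus[j, "mismatches"]), "-")
    }
  }

  if (length(products) == 0) {
    stop(no_product_error(sprintf(
      "no product for %s/%s on %s", fwd$id, rev$id, template_id)))
  }
  multi <- length(products) > 1
  if (multi) {
    warning(sprintf("multiple products (%d) for %s/%s on %s",
                    length(products), fwd$id, rev$id, template_id),
            call. = FALSE)
  }
  lapply(products, function(p) {
    p$multi_product <- multi
    class(p) <- "amplicon_record"
    p
  })
}

#' Wrap a plain sequence as an amplicon record
#'
#' For observed (e.g. Sanger-derived) amplicon sequences read from FASTA
#' rather than extracted by [virtual_pcr()].
#'
#' @param sequence DNA string, 5'->3' on the forward-primer strand (the
#'   orientation is auto-detected downstream).
#' @param id record identifier.
#' @return an `amplicon_record`.
#' @export
amplicon_record <- function(sequence, id = "amplicon") {
  sequence <- toupper(sequence)
  assert_iupac(sequence)
  structure(list(sequence = sequence, template_id = id, start = NA_integer_,
                 end = NA_integer_, length = nchar(sequence), strand = NA,
                 fwd_mismatches = NA_integer_, rev_mismatches = NA_integer_,
                 multi_product = FALSE),
            class = "amplicon_record")
}

#' @export
print.amplicon_record <- function(x, ...) {
  cat(sprintf("Amplicon %s: %d bp", x$template_id, x$length))
  if (!is.na(x$start)) cat(sprintf(" [%d..%d %s]", x$start, x$end, x$strand))
  cat("\n")
  invisible(x)
}
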