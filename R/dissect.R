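#' Amplicon dissection
#'
#' Locates the three tRNA anchor segments (partial Ile, complete Gln,
#' partial Met) inside a Mito_F/R amplicon by semi-global alignment and
#' extracts intergenic regions I and II with exact coordinates. The Ile
#' anchor is pinned to the amplicon 5' end and the Met anchor to the 3'
#' end; Gln is aligned free at both ends within the remaining interior,
#' which removes placement ambiguity for short spacers.
#'
#' @name dissection
NULL

# Alignment scoring shared by anchoring and percent identity:
# match +1, mismatch -1, gap open -2, gap extend -1.
align_params <- function() {
  list(mat = Biostrings::nucleotideSubstitutionMatrix(
         match = 1, mismatch = -1, baseOnly = FALSE),
       gap_opening = 2, gap_extension = 1)
}

# Semi-global alignment: the whole of `ref` aligned (global in pattern),
# free end gaps in `query` (local in subject).
align_anchor <- function(ref, query) {
  p <- align_params()
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(ref),
    subject = Biostrings::DNAString(query),
    type = "global-local", substitutionMatrix = p$mat,
    gapOpening = p$gap_opening, gapExtension = p$gap_extension)
  cols <- nchar(as.character(Biostrings::pattern(aln)))
  list(start = BiocGenerics::start(Biostrings::subject(aln)),
       end = BiocGenerics::end(Biostrings::subject(aln)),
       score = BiocGenerics::score(aln),
       identity = Biostrings::nmatch(aln) / cols)
}

#' Construct a tRNA reference set
#'
#' @param ile the 56 bp amplicon-internal portion of tRNA-Ile.
#' @param gln the complete 69 bp tRNA-Gln.
#' @param met the 29 bp amplicon-internal portion of tRNA-Met.
#' @param source provenance label (synthetic stand-in or the accession the
#'   references were taken from).
#' @return a `trna_reference_set`.
#' @export
trna_reference_set <- function(ile, gln, met, source = "user") {
  for (s in c(ile, gln, met)) assert_iupac(s)
  structure(list(ile = toupper(ile), gln = toupper(gln), met = toupper(met),
                 source = source),
            class = "trna_reference_set")
}

anchor_failure <- function(which, identity) {
  structure(class = c("anchor_failure", "error", "condition"),
            list(message = sprintf(
                   "anchor %s failed: best identity %.3f", which, identity),
                 call = NULL, which = which, identity = identity))
}

order_violation <- function(msg) {
  structure(class = c("order_violation", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Anchor the three tRNA segments in an amplicon
#'
#' @param amplicon an `amplicon_record`, `synthetic_amplicon`, or DNA
#'   string.
#' @param refs a [trna_reference_set()].
#' @param min_identity minimum per-anchor alignment identity (matches over
#'   alignment columns) below which anchoring fails (default 0.80).
#' @return an `anchor_set`: 1-based inclusive `ile`, `gln`, `met` intervals
#'   in amplicon coordinates (Ile starts at 1, Met ends at the amplicon
#'   length), per-anchor `identity` and `score`.
#' @export
anchor_trnas <- function(amplicon, refs, min_identity = 0.80) {
  seqs <- amplicon_seq(amplicon)
  L <- nchar(seqs)
  min_len <- nchar(refs$ile) + nchar(refs$gln) + nchar(refs$met)
  if (L < min_len) {
    stop("amplicon shorter than the three anchor segments (", L, " < ",
         min_len, " bp)", call. = FALSE)
  }

  ile <- align_anchor(refs$ile, seqs)
  if (ile$identity < min_identity) stop(anchor_failure("ile", ile$identity))
  met <- align_anchor(refs$met, seqs)
  if (met$identity < min_identity) stop(anchor_failure("met", met$identity))

  ile_iv <- c(1L, ile$end)                    # pinned to the 5' end
  met_iv <- c(met$start, L)                   # pinned to the 3' end
  if (met_iv[1] <= ile_iv[2]) {
    stop(order_violation("ile and met anchors overlap"))
  }

  interior <- substr(seqs, ile_iv[2] + 1L, met_iv[1] - 1L)
  if (nchar(interior) < nchar(refs$gln)) {
    stop(order_violation("interior too short for the gln anchor"))
  }
  gln <- align_anchor(refs$gln, interior)
  if (gln$identity < min_identity) stop(anchor_failure("gln", gln$identity))
  gln_iv <- c(ile_iv[2] + gln$start, ile_iv[2] + gln$end)

  structure(list(ile = ile_iv, gln = gln_iv, met = met_iv,
                 identity = c(ile = ile$identity, gln = gln$identity,
                              met = met$identity),
                 score = c(ile = ile$score, gln = gln$score,
                           met = met$score)),
            class = "anchor_set")
}

amplicon_seq <- function(x) {
  if (is.character(x)) toupper(x)
  else if (!is.null(x$sequence)) toupper(x$sequence)
  else stop("cannot extract a sequence from this object", call. = FALSE)
}

#' Extract the two intergenic spacers
#'
#' IGS-I spans the gap between the Ile and Gln anchors; IGS-II the gap
#' between Gln and Met. Zero-length spacers yield empty strings.
#'
#' @param amplicon amplicon (as in [anchor_trnas()]).
#' @param anchors an `anchor_set` for this amplicon.
#' @return an `igs_pair`: `igs1_seq`, `igs1_len`, `igs2_seq`, `igs2_len`.
#' @export
extract_igs <- function(amplicon, anchors) {
  seqs <- amplicon_seq(amplicon)
  igs1 <- if (anchors$gln[1] > anchors$ile[2] + 1L)
    substr(seqs, anchors$ile[2] + 1L, anchors$gln[1] - 1L) else ""
  igs2 <- if (anchors$met[1] > anchors$gln[2] + 1L)
    substr(seqs, anchors$gln[2] + 1L, anchors$met[1] - 1L) else ""
  structure(list(igs1_seq = igs1, igs1_len = nchar(igs1),
                 igs2_seq = igs2, igs2_len = nchar(igs2)),
            class = "igs_pair")
}

#' Anchor and extract in one step
#'
#' @inheritParams anchor_trnas
#' @return list with `anchors` and `igs`.
#' @export
dissect_amplicon <- function(amplicon, refs, min_identity = 0.80) {
  anchors <- anchor_trnas(amplicon, refs, min_identity)
  list(anchors = anchors, igs = extract_igs(amplicon, anchors))
}

#' Build tRNA references from a GenBank annotation
#'
#' Extracts the tRNA-Ile, tRNA-Gln and tRNA-Met features from an annotated
#' genome and trims Ile and Met to the amplicon-internal portions using the
#' forward/reverse primer hit coordinates (the amplicon starts inside
#' tRNA-Ile at the forward-primer 5' end and ends inside tRNA-Met at the
#' reverse-primer 5' end).
#'
#' @param genome an `annotated_genome` from [read_annotated_genome()].
#' @param fwd,rev the primer pair (defaults to Mito_F/R).
#' @param max_mismatch primer-site mismatch tolerance.
#' @return a [trna_reference_set()] with `source` set to the accession.
#' @export
trna_refs_from_annotation <- function(genome, fwd = mito_primers()$Mito_F,
                                      rev = mito_primers()$Mito_R,
                                      max_mismatch = 3L) {
  feat <- genome$features
  trna <- feat[feat$type == "tRNA", ]
  pick <- function(aa) {
    hit <- grepl(paste0("trna.?", aa), tolower(trna$label)) |
      grepl(paste0("\\b", aa, "\\b"), tolower(trna$label))
    if (!any(hit)) stop("no tRNA-", aa, " feature in ", genome$id,
                        call. = FALSE)
    trna[which(hit)[1], ]
  }
  f_ile <- pick("ile"); f_gln <- pick("gln"); f_met <- pick("met")

  fh <- find_primer_sites(genome$sequence, fwd, circular = genome$circular,
                          max_mismatch = max_mismatch)
  rh <- find_primer_sites(genome$sequence, rev, circular = genome$circular,
                          max_mismatch = max_mismatch)
  fh <- fh[fh$strand == "+", ]; rh <- rh[rh$strand == "-", ]
  if (nrow(fh) == 0 || nrow(rh) == 0) {
    stop("primer sites not found on ", genome$id, call. = FALSE)
  }
  amp_start <- fh$start[1]
  amp_end <- rh$end[1]

  # references are taken in amplicon orientation (the forward-primer
  # strand), so always the plus-strand substring, whatever strand the
  # tRNA is transcribed from (tRNA-Gln is minus-strand in these genomes).
  sub <- function(a, b) substr(genome$sequence, a, b)
  ile <- sub(max(f_ile$start, amp_start), f_ile$end)
  gln <- sub(f_gln$start, f_gln$end)
  met <- sub(f_met$start, min(f_met$end, amp_end))
  trna_reference_set(ile, gln, met,
                     source = paste("annotation of", genome$id))
}
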