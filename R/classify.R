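#' Species classification
#'
#' The primary evidence is the IGS-I length signature: an observed spacer
#' length is matched against the tolerance-expanded windows of the
#' signature table. IGS-II may corroborate or contradict a call but never
#' promotes one to unambiguous on its own (its windows overlap for the
#' cryptic pair C. rosa / C. quilicii). When the length call fails and a
#' reference panel is available, a nearest-neighbour percent-identity
#' fallback is used, with both an identity floor and a margin requirement.
#' Known database confounders are attached to every unambiguous call as
#' caveats.
#'
#' @name classification
NULL

species_call <- function(status, species = NA_character_,
                         candidates = character(), evidence = list(),
                         identity_evidence = NULL, caveats = NULL,
                         notes = character()) {
  if (is.null(caveats)) {
    caveats <- data.frame(taxon = character(), identity = numeric())
  }
  stopifnot(status %in% c("unambiguous", "ambiguous", "no_call"))
  if (status == "unambiguous") stopifnot(!is.na(species))
  if (status != "unambiguous") species <- NA_character_
  structure(list(status = status, species = species,
                 candidates = candidates, evidence = evidence,
                 identity_evidence = identity_evidence, caveats = caveats,
                 notes = notes),
            class = "species_call")
}

#' Call a species from an IGS-I length
#'
#' Unambiguous iff the length falls in exactly one tolerance-expanded
#' IGS-I window; `no_call` if in none; `ambiguous` if in several (with the
#' default table and tolerance 1 this happens only at the 1 bp boundary
#' between the expanded B. dorsalis and C. cosyra windows).
#'
#' @param igs1_len observed IGS-I length in bp (>= 0).
#' @param table a `signature_table`.
#' @param tolerance matching tolerance; defaults to the table's.
#' @return a `species_call`.
#' @export
call_by_length <- function(igs1_len, table = default_signature_table(),
                           tolerance = table$tolerance) {
  stopifnot(igs1_len >= 0)
  hits <- Filter(function(e) {
    window_contains(expand_window(e$igs1_window, tolerance), igs1_len)
  }, table$entries)
  cand <- vapply(hits, function(e) e$species, character(1))
  ev <- list(igs1_len = igs1_len, tolerance = tolerance,
             matched_windows = lapply(hits, function(e) e$igs1_window))
  if (length(hits) == 1) {
    species_call("unambiguous", species = cand, candidates = cand,
                 evidence = ev, caveats = hits[[1]]$confounders)
  } else if (length(hits) == 0) {
    species_call("no_call", evidence = ev)
  } else {
    species_call("ambiguous", candidates = cand, evidence = ev)
  }
}

#' Candidate species from an IGS-II length
#'
#' IGS-II windows are recorded only for C. rosa and C. quilicii and
#' overlap at 18 bp, so this region can never separate that pair: any
#' length matching both windows returns an ambiguous call naming both.
#' A length matching a single window is returned as ambiguous-weak
#' evidence (single candidate), never an unambiguous call.
#'
#' @param igs2_len observed IGS-II length in bp.
#' @inheritParams call_by_length
#' @return a `species_call` with status `ambiguous` or `no_call`.
#' @export
call_by_igs2_length <- function(igs2_len, table = default_signature_table(),
                                tolerance = table$tolerance) {
  stopifnot(igs2_len >= 0)
  hits <- Filter(function(e) {
    !is.null(e$igs2_window) &&
      window_contains(expand_window(e$igs2_window, tolerance), igs2_len)
  }, table$entries)
  cand <- vapply(hits, function(e) e$species, character(1))
  ev <- list(igs2_len = igs2_len, tolerance = tolerance)
  if (length(hits) == 0) {
    species_call("no_call", evidence = ev)
  } else {
    species_call("ambiguous", candidates = cand, evidence = ev,
                 notes = "IGS-II length is weak evidence and never the sole basis for an unambiguous call")
  }
}

#' Global-alignment percent identity
#'
#' Needleman-Wunsch with the package's anchor scoring (match +1, mismatch
#' -1, gap open -2, gap extend -1); identity is 100 x matches / alignment
#' columns, gap columns counting in the denominator.
#'
#' @param a,b non-empty DNA strings.
#' @return percent identity in \[0, 100\].
#' @export
percent_identity <- function(a, b) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  p <- align_params()
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(toupper(a)),
    subject = Biostrings::DNAString(toupper(b)),
    type = "global", substitutionMatrix = p$mat,
    gapOpening = p$gap_opening, gapExtension = p$gap_extension)
  p_aln <- as.character(Biostrings::pattern(aln))
  s_aln <- as.character(Biostrings::subject(aln))
  # terminal gaps are clipped from the aligned strings; add them back as
  # gap columns so they count in the denominator
  cols <- nchar(p_aln) +
    (nchar(a) - nchar(gsub("-", "", p_aln))) +
    (nchar(b) - nchar(gsub("-", "", s_aln)))
  100 * Biostrings::nmatch(aln) / cols
}

#' Build a reference amplicon panel
#'
#' One reference amplicon per species for the identity fallback. Synthetic
#' mode (the default) uses the generator's own reference amplicons; real
#' mode takes a named character vector of amplicons extracted from
#' user-supplied accessions.
#'
#' @param table a `signature_table` naming the species.
#' @param rng_seed seed for the synthetic references.
#' @return named character vector, one amplicon sequence per species.
#' @export
reference_panel <- function(table = default_signature_table(),
                            rng_seed = 42L) {
  sp <- table_species(table)
  stats::setNames(vapply(seq_along(sp), function(i) {
    make_amplicon(sp[i], rng_seed = split_seed(rng_seed, i),
                  table = table)$sequence
  }, character(1)), sp)
}

identity_fallback <- function(seqs, panel, min_margin = 2.0,
                              min_identity = 90.0) {
  ids <- vapply(panel, function(ref) percent_identity(seqs, ref), numeric(1))
  ord <- order(ids, decreasing = TRUE)
  best <- names(panel)[ord[1]]
  runner <- if (length(ids) > 1) names(panel)[ord[2]] else NA_character_
  margin <- if (length(ids) > 1) ids[ord[1]] - ids[ord[2]] else Inf
  ic <- list(best_species = best, best_identity = unname(ids[ord[1]]),
             runner_up = runner, margin = unname(margin))
  class(ic) <- "identity_call"
  ic
}

#' Classify an amplicon
#'
#' Pipeline: anchor the tRNAs (on both strands, keeping the orientation
#' with the higher total anchor score), extract the spacers, and call the
#' species from the IGS-I length. An IGS-II length incompatible with the
#' called species' recorded window downgrades the call to ambiguous. If
#' anchoring fails or the length gives `no_call` and a reference `panel`
#' is supplied, a nearest-neighbour percent-identity fallback is tried:
#' unambiguous iff best identity >= `min_identity_pct` and the margin over
#' the runner-up is >= `min_margin`. Without a panel, anchoring errors
#' propagate.
#'
#' @param amplicon an `amplicon_record`, `synthetic_amplicon` or DNA
#'   string.
#' @param refs a [trna_reference_set()] (defaults to the Ceratitis
#'   stand-ins; both genus sets share the primer footprints, so either
#'   anchors all five species).
#' @param table signature table.
#' @param panel optional named vector of reference amplicons (see
#'   [reference_panel()]).
#' @param min_identity minimum per-anchor alignment identity.
#' @param min_margin fallback margin in percentage points (default 2.0).
#' @param min_identity_pct fallback identity floor in percent (default 90).
#' @return a `species_call`; its `evidence` carries the IGS lengths,
#'   matched window and tolerance, `identity_evidence` the fallback result
#'   when used, and `caveats` the confounder notes for unambiguous calls.
#' @export
classify <- function(amplicon, refs = synthetic_trna_refs("Ceratitis"),
                     table = default_signature_table(), panel = NULL,
                     min_identity = 0.80, min_margin = 2.0,
                     min_identity_pct = 90.0) {
  seqs <- amplicon_seq(amplicon)

  try_dissect <- function(s) {
    tryCatch(dissect_amplicon(s, refs, min_identity), error = function(e) e)
  }
  fw <- try_dissect(seqs)
  rv <- try_dissect(revcomp(seqs))
  pick_score <- function(d) if (inherits(d, "error")) -Inf else
    sum(d$anchors$score)
  use_rv <- pick_score(rv) > pick_score(fw)
  d <- if (use_rv) rv else fw
  oriented <- if (use_rv) revcomp(seqs) else seqs

  if (inherits(d, "error")) {
    if (is.null(panel)) stop(d)
    return(fallback_call(seqs, panel, table, min_margin, min_identity_pct,
                         note = paste("anchoring failed:",
                                      conditionMessage(d))))
  }

  call <- call_by_length(d$igs$igs1_len, table)
  call$evidence$igs2_len <- d$igs$igs2_len
  call$evidence$orientation <- if (use_rv) "-" else "+"
  call$evidence$anchor_identity <- d$anchors$identity

  if (call$status == "unambiguous") {
    entry <- find_entry(table, call$species)
    if (!is.null(entry$igs2_window)) {
      w2 <- expand_window(entry$igs2_window, table$tolerance)
      if (!window_contains(w2, d$igs$igs2_len)) {
        igs2c <- call_by_igs2_length(d$igs$igs2_len, table)
        call <- species_call(
          "ambiguous",
          candidates = unique(c(call$species, igs2c$candidates)),
          evidence = call$evidence,
          notes = sprintf(
            "IGS-II length %d contradicts the %s window [%d,%d]",
            d$igs$igs2_len, entry$species,
            entry$igs2_window$min, entry$igs2_window$max))
      }
    }
  } else if (call$status == "no_call" && !is.null(panel)) {
    fb <- fallback_call(oriented, panel, table, min_margin,
                        min_identity_pct,
                        note = sprintf("IGS-I length %d matched no window",
                                       d$igs$igs1_len))
    fb$evidence <- utils::modifyList(fb$evidence, call$evidence)
    return(fb)
  }
  call
}

fallback_call <- function(seqs, panel, table, min_margin, min_identity_pct,
                          note = character()) {
  ic <- identity_fallback(seqs, panel, min_margin, min_identity_pct)
  if (ic$best_identity >= min_identity_pct && ic$margin >= min_margin) {
    entry <- find_entry(table, ic$best_species)
    species_call("unambiguous", species = entry$species,
                 candidates = entry$species,
                 evidence = list(method = "identity_fallback"),
                 identity_evidence = ic, caveats = entry$confounders,
                 notes = note)
  } else if (ic$best_identity >= min_identity_pct) {
    cand <- c(ic$best_species, ic$runner_up)
    species_call("ambiguous", candidates = cand[!is.na(cand)],
                 evidence = list(method = "identity_fallback"),
                 identity_evidence = ic,
                 notes = c(note, sprintf("margin %.2f below %.2f",
                                         ic$margin, min_margin)))
  } else {
    species_call("no_call", evidence = list(method = "identity_fallback"),
                 identity_evidence = ic,
                 notes = c(note, sprintf("best identity %.2f below %.2f",
                                         ic$best_identity,
                                         min_identity_pct)))
  }
}

#' Classify a batch of amplicons
#'
#' @param amplicons named list/vector of amplicon sequences.
#' @inheritParams classify
#' @return data frame: id, status, species, candidates, igs1_len,
#'   igs2_len, method, notes.
#' @export
classify_batch <- function(amplicons,
                           refs = synthetic_trna_refs("Ceratitis"),
                           table = default_signature_table(), panel = NULL,
                           ...) {
  rows <- lapply(seq_along(amplicons), function(i) {
    id <- names(amplicons)[i]
    if (is.null(id)) id <- paste0("query", i)
    call <- tryCatch(
      classify(amplicons[[i]], refs = refs, table = table, panel = panel,
               ...),
      error = function(e) {
        species_call("no_call", notes = conditionMessage(e))
      })
    data.frame(
      id = id, status = call$status,
      species = ifelse(is.na(call$species), "", call$species),
      candidates = paste(call$candidates, collapse = ";"),
      igs1_len = if (!is.null(call$evidence$igs1_len))
        call$evidence$igs1_len else NA_integer_,
      igs2_len = if (!is.null(call$evidence$igs2_len))
        call$evidence$igs2_len else NA_integer_,
      method = if (!is.null(call$evidence$method)) call$evidence$method
        else "igs1_length",
      notes = paste(call$notes, collapse = " | "))
  })
  do.call(rbind, rows)
}

#' @export
print.species_call <- function(x, ...) {
  cat("Species call:", x$status)
  if (!is.na(x$species)) cat(" ->", x$species)
  cat("\n")
  if (!is.null(x$evidence$igs1_len))
    cat("  IGS-I length:", x$evidence$igs1_len, "bp (tolerance",
        x$evidence$tolerance, "bp)\n")
  if (!is.null(x$identity_evidence))
    cat(sprintf("  identity fallback: %s at %.2f%% (margin %.2f)\n",
                x$identity_evidence$best_species,
                x$identity_evidence$best_identity,
                x$identity_evidence$margin))
  if (nrow(x$caveats) > 0)
    cat("  caveats:", paste(sprintf("%s (%.2f%%)", x$caveats$taxon,
                                    x$caveats$identity), collapse = ", "),
        "\n")
  if (length(x$notes) > 0) cat("  notes:", paste(x$notes, collapse = "; "),
                               "\n")
  invisible(x)
}
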