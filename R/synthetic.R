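#' Synthetic amplicons and mitogenomes
#'
#' The generator emulates the Mito_F/R amplicon architecture: a 56 bp
#' partial tRNA-Ile segment (beginning with the Mito_F footprint), IGS-I,
#' the complete 69 bp tRNA-Gln, IGS-II, and a 29 bp partial tRNA-Met
#' segment (ending with the reverse complement of Mito_R). Spacer lengths
#' are drawn from the species' signature windows; spacer sequences and
#' genome filler are AT-rich to match tephritid mitogenome composition
#' (AT fraction defaults to 0.77). All randomness is controlled by integer
#' seeds; one seed fans out to per-operation seeds deterministically.
#'
#' The tRNA segments are fixed per-genus stand-in constants: the source
#' does not prescribe tRNA sequences, so one Ceratitis set and one
#' Bactrocera set (>= 85% mutually identical, primer footprints shared)
#' are used. Real annotated genomes supply their own tRNA references via
#' [trna_refs_from_annotation()].
#'
#' @name synthetic_data
NULL

MITO_F_SEQ <- "TGACAAAAGGGTTACCTTGATAGGG"
MITO_R_SEQ <- "ACCCAGTAGCTTAATTAGCTTATCT"
MITO_R_RC <- "AGATAAGCTAATTAAGCTACTGGGT"

ILE_LEN <- 56L
GLN_LEN <- 69L
MET_LEN <- 29L

# Per-genus tRNA stand-ins. The Ceratitis and Bactrocera variants differ at
# a few positions outside the primer footprints (ile 3/56, gln 6/69,
# met 1/29 substitutions), mimicking conserved tRNAs.
TRNA_STANDINS <- list(
  Ceratitis = list(
    ile = paste0(MITO_F_SEQ, "ATTTAGGTTAAACCATTTGACTTGCAATCAA"),
    gln = "TATTCAACAAATCATTTAGGGTATAAATCCTAATAATTTTACAATTAACCTTTGAAAGTTAAAGTTTAC",
    met = paste0("ATTA", MITO_R_RC)
  ),
  Bactrocera = list(
    ile = paste0(MITO_F_SEQ, "ATTTTGGTTAAACCGTTTGACTTGTAATCAA"),
    gln = "TAATCAACAAATTATTTAGGGTTTAAATCCTAGTAATTTTACCATTAACCTTTGAAAGTTAATGTTTAC",
    met = paste0("ACTA", MITO_R_RC)
  )
)

# IGS-II lengths for species without an established window: simulator
# choices, not biological claims. The B. dorsalis value (62) follows from
# the published 216 bp product: 216 = 56 + 0 + 69 + igs2 + 29.
IGS2_SYNTH_DEFAULTS <- c("Ceratitis capitata" = 19L, "Ceratitis cosyra" = 19L,
                         "Bactrocera dorsalis" = 62L)

genus_of <- function(species) strsplit(species, " ")[[1]][1]

#' tRNA reference set for a genus (synthetic stand-ins)
#'
#' @param genus `"Ceratitis"` or `"Bactrocera"`.
#' @return a `trna_reference_set` (see [trna_reference_set()]).
#' @export
synthetic_trna_refs <- function(genus = c("Ceratitis", "Bactrocera")) {
  genus <- match.arg(genus)
  s <- TRNA_STANDINS[[genus]]
  trna_reference_set(s$ile, s$gln, s$met,
                     source = paste("synthetic stand-in:", genus))
}

#' Generate an AT-rich spacer sequence
#'
#' Bases are drawn independently: A or T with total probability
#' `at_fraction` (split evenly), C or G otherwise.
#'
#' @param length spacer length in bp (>= 0).
#' @param at_fraction probability of an A/T base (default 0.77, the
#'   tephritid mitogenome AT fraction).
#' @param rng_seed integer seed; the same seed reproduces the same spacer.
#' @return a DNA string of exactly `length` bases.
#' @export
make_spacer <- function(length, at_fraction = 0.77, rng_seed = 1L) {
  stopifnot(length >= 0, at_fraction >= 0, at_fraction <= 1)
  if (length == 0) return("")
  with_seed(rng_seed, random_dna(length, at_fraction))
}

#' Generate a synthetic amplicon with known truth
#'
#' @param species one of the five species in the default signature table.
#' @param rng_seed integer seed.
#' @param igs1_len_override,igs2_len_override force a spacer length instead
#'   of drawing it from the species' window / simulator default.
#' @param at_fraction spacer base composition.
#' @param table signature table supplying the length windows.
#' @return a `synthetic_amplicon`: `sequence`, `truth_species`,
#'   `truth_igs1`, `truth_igs2`, and `truth_anchors` (list of `ile`, `gln`,
#'   `met` 1-based inclusive intervals in amplicon coordinates).
#' @export
make_amplicon <- function(species, rng_seed = 1L,
                          igs1_len_override = NULL, igs2_len_override = NULL,
                          at_fraction = 0.77,
                          table = default_signature_table()) {
  entry <- find_entry(table, species)   # errors on unknown species
  species <- entry$species
  genus <- genus_of(species)
  if (!genus %in% names(TRNA_STANDINS)) {
    stop("no tRNA stand-ins for genus: ", genus, call. = FALSE)
  }
  tr <- TRNA_STANDINS[[genus]]

  w1 <- entry$igs1_window
  igs1_len <- if (!is.null(igs1_len_override)) as.integer(igs1_len_override)
    else with_seed(split_seed(rng_seed, 11L),
                   sample_one(seq(w1$min, w1$max)))
  igs2_len <- if (!is.null(igs2_len_override)) as.integer(igs2_len_override)
    else if (!is.null(entry$igs2_window)) {
      w2 <- entry$igs2_window
      with_seed(split_seed(rng_seed, 13L), sample_one(seq(w2$min, w2$max)))
    } else {
      unname(IGS2_SYNTH_DEFAULTS[species])
    }

  igs1 <- make_spacer(igs1_len, at_fraction, split_seed(rng_seed, 17L))
  igs2 <- make_spacer(igs2_len, at_fraction, split_seed(rng_seed, 19L))
  seqs <- paste0(tr$ile, igs1, tr$gln, igs2, tr$met)

  ile_iv <- c(1L, ILE_LEN)
  gln_iv <- c(ILE_LEN + igs1_len + 1L, ILE_LEN + igs1_len + GLN_LEN)
  met_iv <- c(gln_iv[2] + igs2_len + 1L, gln_iv[2] + igs2_len + MET_LEN)
  structure(list(sequence = seqs, truth_species = species,
                 truth_igs1 = igs1, truth_igs2 = igs2,
                 truth_anchors = list(ile = ile_iv, gln = gln_iv,
                                      met = met_iv)),
            class = "synthetic_amplicon")
}

#' Generate a toy circular mitogenome hosting one amplicon
#'
#' The species' amplicon is embedded at a seeded random rotation inside
#' AT-rich filler that is guaranteed free of secondary primer sites (filler
#' is resampled if it carries a match to either primer at up to
#' `max_mismatch` mismatches on either strand).
#'
#' `rng_seed` controls rotation and filler only; the embedded amplicon is
#' generated from `amplicon_seed` (or passed in directly), so different
#' genome seeds around the same amplicon change the rotation, never the
#' product.
#'
#' @param species one of the five study species.
#' @param total_length genome length in bp (>= amplicon length + 200).
#' @param rng_seed integer seed for rotation and filler.
#' @param amplicon_seed seed for the embedded amplicon (default 1).
#' @param amplicon optionally a prebuilt [make_amplicon()] result to embed.
#' @param at_fraction filler base composition.
#' @param max_mismatch stringency of the secondary-site exclusion scan.
#' @return a `synthetic_genome`: `sequence` (rotated), `rotation`,
#'   `truth_amplicon_interval` (1-based on the unrotated sequence),
#'   `truth_species`, plus the embedded `amplicon`.
#' @export
make_genome <- function(species, total_length = 2000L, rng_seed = 1L,
                        amplicon_seed = 1L, amplicon = NULL,
                        at_fraction = 0.77, max_mismatch = 3L) {
  if (is.null(amplicon)) {
    amplicon <- make_amplicon(species, rng_seed = amplicon_seed,
                              at_fraction = at_fraction)
  }
  amp <- amplicon$sequence
  La <- nchar(amp)
  if (total_length < La + 200L) {
    stop("total_length must be >= amplicon length + 200 (>= ", La + 200L,
         ")", call. = FALSE)
  }
  primers <- mito_primers()[c("Mito_F", "Mito_R")]
  n_fill <- total_length - La
  fill <- NULL
  for (attempt in seq_len(50L)) {
    cand <- with_seed(split_seed(rng_seed, 23L + attempt),
                      random_dna(n_fill, at_fraction))
    genome <- paste0(amp, cand)
    n_hits <- vapply(primers, function(p) {
      nrow(find_primer_sites(genome, p, circular = TRUE,
                             max_mismatch = max_mismatch,
                             require_three_prime_clean = FALSE))
    }, integer(1))
    if (all(n_hits == 1L)) { fill <- cand; break }
  }
  if (is.null(fill)) {
    stop("could not generate filler free of secondary primer sites",
         call. = FALSE)
  }
  unrotated <- paste0(amp, fill)
  rotation <- with_seed(split_seed(rng_seed, 29L),
                        sample.int(total_length, 1L) - 1L)
  rotated <- if (rotation == 0) unrotated else
    paste0(substr(unrotated, rotation + 1L, total_length),
           substr(unrotated, 1L, rotation))
  structure(list(sequence = rotated, rotation = rotation,
                 truth_amplicon_interval = c(1L, La),
                 truth_species = amplicon$truth_species,
                 amplicon = amplicon),
            class = "synthetic_genome")
}

#' Sanger-style noise model
#'
#' @param sub_rate,ins_rate,del_rate per-base probabilities in \[0, 1),
#'   summing below 1.
#' @param seed integer seed.
#' @return a `noise_model`.
#' @export
noise_model <- function(sub_rate = 0, ins_rate = 0, del_rate = 0, seed = 1L) {
  rates <- c(sub_rate, ins_rate, del_rate)
  stopifnot(all(rates >= 0), all(rates < 1), sum(rates) < 1)
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, seed = as.integer(seed)),
            class = "noise_model")
}

#' Apply substitution/indel noise to a sequence
#'
#' Per original base: deleted with `del_rate`; otherwise substituted (to a
#' uniformly random different base) with `sub_rate`; independently, a
#' uniformly random base is inserted after each original position with
#' `ins_rate`. Every change is recorded in the edit log.
#'
#' @param sequence DNA string.
#' @param model a [noise_model()].
#' @return list with `sequence` (the noisy string) and `log`, a data frame
#'   of edits (`pos` = 1-based position in the original sequence, `type`
#'   in sub/ins/del, `from`, `to`).
#' @export
apply_noise <- function(sequence, model) {
  n <- nchar(sequence)
  empty_log <- data.frame(pos = integer(), type = character(),
                          from = character(), to = character())
  if (n == 0 || (model$sub_rate == 0 && model$ins_rate == 0 &&
                 model$del_rate == 0)) {
    return(list(sequence = sequence, log = empty_log))
  }
  bases <- strsplit(sequence, "")[[1]]
  alphabet <- c("A", "C", "G", "T")
  res <- with_seed(model$seed, {
    u_del <- runif(n) < model$del_rate
    u_sub <- runif(n) < model$sub_rate
    u_ins <- runif(n) < model$ins_rate
    out <- character(0)
    logs <- list()
    for (i in seq_len(n)) {
      if (u_del[i]) {
        logs[[length(logs) + 1]] <- data.frame(
          pos = i, type = "del", from = bases[i], to = "")
      } else if (u_sub[i]) {
        to <- sample(setdiff(alphabet, bases[i]), 1L)
        out <- c(out, to)
        logs[[length(logs) + 1]] <- data.frame(
          pos = i, type = "sub", from = bases[i], to = to)
      } else {
        out <- c(out, bases[i])
      }
      if (u_ins[i]) {
        ins <- sample(alphabet, 1L)
        out <- c(out, ins)
        logs[[length(logs) + 1]] <- data.frame(
          pos = i, type = "ins", from = "", to = ins)
      }
    }
    list(sequence = paste(out, collapse = ""),
         log = if (length(logs) == 0) empty_log else do.call(rbind, logs))
  })
  res
}

#' Simulate a batch of amplicons with truth metadata
#'
#' @param species character vector of species to draw from (cycled).
#' @param n number of amplicons.
#' @param rng_seed integer seed; amplicon i uses a seed derived from it.
#' @param noise optional [noise_model()] applied to each amplicon (each
#'   amplicon gets a derived seed).
#' @param at_fraction spacer composition.
#' @return list with `amplicons` (named list of sequences) and `truth`
#'   (data frame: id, species, igs1_len, igs2_len, anchors).
#' @export
simulate_batch <- function(species = table_species(default_signature_table()),
                           n = length(species), rng_seed = 1L, noise = NULL,
                           at_fraction = 0.77) {
  sp <- rep_len(species, n)
  amps <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    a <- make_amplicon(sp[i], rng_seed = split_seed(rng_seed, 100L + i),
                       at_fraction = at_fraction)
    seqs <- a$sequence
    if (!is.null(noise)) {
      nm <- noise
      nm$seed <- split_seed(rng_seed, 5000L + i)
      seqs <- apply_noise(seqs, nm)$sequence
    }
    id <- sprintf("amp%03d_%s", i, gsub(" ", "_", sp[i]))
    amps[[i]] <- seqs
    names(amps)[i] <- id
    rows[[i]] <- data.frame(
      id = id, species = a$truth_species,
      igs1_len = nchar(a$truth_igs1), igs2_len = nchar(a$truth_igs2),
      anchors = paste(vapply(a$truth_anchors,
                             function(iv) paste(iv, collapse = "-"),
                             character(1)),
                      collapse = ";"))
  }
  list(amplicons = amps, truth = do.call(rbind, rows))
}
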