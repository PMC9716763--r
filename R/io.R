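#' File input/output
#'
#' FASTA reading/writing goes through Biostrings with an added validation
#' layer that reports offending line numbers; GenBank flat files are parsed
#' with a minimal reader covering LOCUS, FEATURES (simple, `complement()`
#' and `join()` locations) and ORIGIN. Coordinates follow the GenBank
#' convention: 1-based inclusive.
#'
#' @name io
NULL

#' Read a FASTA file
#'
#' @param path file path.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  bad <- which(vapply(seqs, function(s) {
    any(!strsplit(s, "")[[1]] %in% names(IUPAC_SETS))
  }, logical(1)))
  if (length(bad) > 0) {
    # locate the first offending line for the error message
    lines <- toupper(readLines(path))
    for (ln in seq_along(lines)) {
      l <- lines[ln]
      if (startsWith(l, ">") || nchar(l) == 0) next
      chars <- strsplit(gsub("\\s", "", l), "")[[1]]
      off <- setdiff(unique(chars), names(IUPAC_SETS))
      if (length(off) > 0) {
        stop(sprintf("invalid sequence character '%s' at line %d of %s",
                     off[1], ln, path), call. = FALSE)
      }
    }
    stop("invalid sequence characters in ", path, call. = FALSE)
  }
  seqs
}

#' Write sequences as FASTA
#'
#' Sequences are wrapped at 70 columns; `write_fasta(read_fasta(f), f2)`
#' round-trips ids and sequences exactly.
#'
#' @param records named character vector or list of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  records <- unlist(records)
  set <- Biostrings::BStringSet(records)
  names(set) <- names(records)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read an annotated genome from a GenBank flat file
#'
#' Parses the LOCUS line (length, circular topology), the FEATURES table
#' (feature type, location with `complement()`/`join()` support, and a
#' gene/product label) and the ORIGIN sequence block. The sequence length
#' is checked against the declared length.
#'
#' @param path GenBank flat file.
#' @return an `annotated_genome`: `id`, `sequence`, `circular`, `length`,
#'   and `features` (data frame: type, label, start, end, strand).
#' @export
read_annotated_genome <- function(path) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0) stop("no LOCUS line in ", path, call. = FALSE)
  toks <- strsplit(trimws(locus[1]), "\\s+")[[1]]
  id <- toks[2]
  declared <- suppressWarnings(as.integer(toks[which(toks == "bp") - 1]))
  circular <- any(grepl("circular", locus[1], ignore.case = TRUE))

  ori <- grep("^ORIGIN", lines)
  if (length(ori) == 0) stop("no ORIGIN/sequence block in ", path,
                             call. = FALSE)
  seq_lines <- lines[seq(ori[1] + 1L, length(lines))]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seqs <- toupper(gsub("[0-9 ]", "", paste(seq_lines, collapse = "")))
  if (nchar(seqs) == 0) stop("missing sequence in ", path, call. = FALSE)
  assert_iupac(seqs)
  if (!is.na(declared) && length(declared) == 1 &&
      nchar(seqs) != declared) {
    stop(sprintf("sequence length %d differs from declared %d in %s",
                 nchar(seqs), declared, path), call. = FALSE)
  }

  fstart <- grep("^FEATURES", lines)
  features <- data.frame(type = character(), label = character(),
                         start = integer(), end = integer(),
                         strand = character())
  if (length(fstart) > 0) {
    fl <- lines[seq(fstart[1] + 1L, ori[1] - 1L)]
    cur <- NULL
    rows <- list()
    flush <- function(cur) {
      if (is.null(cur)) return()
      loc <- cur$loc
      strand <- "+"
      if (grepl("complement", loc)) strand <- "-"
      loc <- gsub("complement\\(|join\\(|order\\(|\\)|<|>", "", loc)
      parts <- strsplit(loc, ",")[[1]]
      nums <- lapply(parts, function(p) {
        v <- suppressWarnings(as.integer(strsplit(p, "\\.\\.")[[1]]))
        if (any(is.na(v))) stop("unparseable feature location: ", cur$loc,
                                call. = FALSE)
        v
      })
      allnum <- unlist(nums)
      rows[[length(rows) + 1]] <<- data.frame(
        type = cur$type, label = cur$label,
        start = min(allnum), end = max(allnum), strand = strand)
    }
    for (l in fl) {
      if (grepl("^ {5}\\S", l)) {                # new feature line
        flush(cur)
        toks <- strsplit(trimws(l), "\\s+")[[1]]
        cur <- list(type = toks[1], loc = paste(toks[-1], collapse = ""),
                    label = "")
      } else if (!is.null(cur)) {
        q <- trimws(l)
        if (grepl('^/(gene|product|note)="?', q)) {
          val <- sub('^/(gene|product|note)="?', "", q)
          val <- sub('"$', "", val)
          if (cur$label == "") cur$label <- val
        } else if (!startsWith(q, "/")) {
          cur$loc <- paste0(cur$loc, q)          # continued location
        }
      }
    }
    flush(cur)
    if (length(rows) > 0) features <- do.call(rbind, rows)
  }
  features <- features[features$type != "source", , drop = FALSE]
  rownames(features) <- NULL
  structure(list(id = id, sequence = seqs, circular = circular,
                 length = nchar(seqs), features = features),
            class = "annotated_genome")
}

#' Write a minimal GenBank flat file
#'
#' Companion writer used to materialise synthetic annotated genomes in the
#' same format the reader consumes (round-trip stable for the fields the
#' reader parses).
#'
#' @param id accession-style identifier.
#' @param sequence DNA string.
#' @param features data frame with columns type, label, start, end, strand.
#' @param path output path.
#' @param circular declare circular topology?
#' @return `path`, invisibly.
#' @export
write_genbank <- function(id, sequence, features, path, circular = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  L <- nchar(sequence)
  topo <- if (circular) "circular" else "linear"
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s INV",
                     id, L, topo), con)
  writeLines(sprintf("DEFINITION  synthetic annotated genome %s.", id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    loc <- sprintf("%d..%d", f$start, f$end)
    if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     %-15s %s", f$type, loc), con)
    writeLines(sprintf("                     /product=\"%s\"", f$label), con)
  }
  writeLines("ORIGIN", con)
  pos <- 1L
  while (pos <= L) {
    chunk <- substr(sequence, pos, min(pos + 59L, L))
    groups <- regmatches(chunk, gregexpr(".{1,10}", chunk))[[1]]
    writeLines(sprintf("%9d %s", pos, tolower(paste(groups, collapse = " "))),
               con)
    pos <- pos + 60L
  }
  writeLines("//", con)
  invisible(path)
}

#' Write a synthetic genome as an annotated GenBank flat file
#'
#' Annotates the three tRNA segments of the embedded amplicon at their
#' rotated coordinates, so the real-mode code path
#' ([read_annotated_genome()] + [trna_refs_from_annotation()] +
#' [virtual_pcr()]) can be exercised end to end on simulator output.
#'
#' @param genome a [make_genome()] result.
#' @param path output path.
#' @param id identifier (defaults to a name derived from the species).
#' @return `path`, invisibly.
#' @export
write_synthetic_genbank <- function(genome, path, id = NULL) {
  if (is.null(id)) {
    id <- paste0("SYN_", gsub(" ", "_", genome$truth_species))
  }
  seqs <- genome$sequence
  L <- nchar(seqs)
  rot <- genome$rotation
  build_feats <- function(rot) {
    shift <- function(iv) ((iv - 1L - rot) %% L) + 1L  # unrotated -> rotated
    a <- genome$amplicon$truth_anchors
    do.call(rbind, lapply(names(a), function(nm) {
      iv <- shift(a[[nm]])
      label <- c(ile = "tRNA-Ile", gln = "tRNA-Gln", met = "tRNA-Met")[[nm]]
      data.frame(type = "tRNA", label = label, start = iv[1], end = iv[2],
                 strand = "+")
    }))
  }
  feats <- build_feats(rot)
  # where a tRNA feature would wrap the origin at this rotation, follow the
  # convention of circular records and re-set the origin (100 bp upstream
  # of the amplicon) instead of writing a split location
  if (any(feats$end < feats$start)) {
    unrot <- if (rot == 0) seqs else
      paste0(substr(seqs, L - rot + 1L, L), substr(seqs, 1L, L - rot))
    rot <- L - 100L
    seqs <- paste0(substr(unrot, rot + 1L, L), substr(unrot, 1L, rot))
    feats <- build_feats(rot)
  }
  write_genbank(id, seqs, feats, path, circular = TRUE)
}

#' Base composition of a sequence
#'
#' @param sequence DNA string.
#' @return list with `length`, `at_percent`, `gc_percent` (three decimals,
#'   GenBank-table precision).
#' @export
genome_composition <- function(sequence) {
  b <- strsplit(toupper(sequence), "")[[1]]
  n <- length(b)
  at <- sum(b %in% c("A", "T"))
  gc <- sum(b %in% c("G", "C"))
  list(length = n,
       at_percent = round(100 * at / n, 3),
       gc_percent = round(100 * gc / n, 3))
}
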