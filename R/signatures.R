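#' Species length-signature tables
#'
#' The diagnostic marker is the length of intergenic region I (IGS-I), the
#' mitochondrial spacer between tRNA-Ile and tRNA-Gln inside the Mito_F/R
#' amplicon. Each of the five pest species carries a characteristic IGS-I
#' length; for the cryptic pair C. rosa / C. quilicii an IGS-II window is
#' also recorded, although IGS-II alone cannot separate them (their windows
#' overlap at 18 bp). Known confounding taxa from public-database searches
#' are attached as caveat metadata, never used to reject a call.
#'
#' @name signatures
NULL

#' Construct a length window
#'
#' @param min_len,max_len non-negative integers (bp), `min_len <= max_len`.
#' @return a `length_window` list with `min` and `max`.
#' @export
length_window <- function(min_len, max_len = min_len) {
  min_len <- as.integer(min_len); max_len <- as.integer(max_len)
  stopifnot(!is.na(min_len), !is.na(max_len))
  structure(list(min = min_len, max = max_len), class = "length_window")
}

# Symmetric tolerance expansion, clamped at zero (lengths are non-negative).
expand_window <- function(w, tolerance) {
  length_window(max(0L, w$min - as.integer(tolerance)),
                w$max + as.integer(tolerance))
}

window_contains <- function(w, len) len >= w$min && len <= w$max

windows_overlap <- function(a, b) a$min <= b$max && b$min <= a$max

#' Construct a species signature
#'
#' @param species full binomial name.
#' @param igs1_window [length_window()] for intergenic region I.
#' @param igs2_window [length_window()] for intergenic region II, or `NULL`
#'   where no within-species range is established.
#' @param confounders data frame with columns `taxon` and `identity`
#'   (percent), taxa known to score high identity against this species'
#'   amplicon in public databases.
#' @return a `species_signature` list.
#' @export
species_signature <- function(species, igs1_window, igs2_window = NULL,
                              confounders = NULL) {
  if (is.null(confounders)) {
    confounders <- data.frame(taxon = character(), identity = numeric())
  }
  structure(list(species = species, igs1_window = igs1_window,
                 igs2_window = igs2_window, confounders = confounders),
            class = "species_signature")
}

#' Build a signature table
#'
#' @param entries list of [species_signature()] objects.
#' @param tolerance integer bp applied symmetrically when matching an
#'   observed spacer length against a window (default 1).
#' @return a `signature_table`.
#' @export
signature_table <- function(entries, tolerance = 1L) {
  structure(list(entries = entries, tolerance = as.integer(tolerance)),
            class = "signature_table")
}

#' The default five-species signature table
#'
#' IGS-I windows: C. capitata 40 bp, C. cosyra 2 bp, C. quilicii 62-64 bp,
#' C. rosa 34 bp, B. dorsalis 0 bp (the spacer is absent in Bactrocera).
#' IGS-II windows are recorded only for the two species with an established
#' within-species range: C. quilicii 16-18 bp and C. rosa 18-22 bp.
#'
#' With the default matching tolerance of 1 bp the expanded IGS-I windows
#' are disjoint except at a single boundary: an observed length of exactly
#' 1 bp falls in both the expanded B. dorsalis window \[0,1\] and the
#' expanded C. cosyra window \[1,3\] and is therefore reported as ambiguous.
#' No species prints that length; it can only arise from an indel error.
#'
#' @param tolerance matching tolerance in bp (default 1).
#' @return a `signature_table` with five entries.
#' @export
default_signature_table <- function(tolerance = 1L) {
  cf <- function(taxon, identity) data.frame(taxon = taxon, identity = identity)
  signature_table(list(
    species_signature("Ceratitis capitata", length_window(40)),
    species_signature("Ceratitis cosyra", length_window(2),
      confounders = cf(c("Ceratitis pallidula", "Ceratitis quinaria"),
                       c(97.04, 96.45))),
    species_signature("Ceratitis quilicii", length_window(62, 64),
      igs2_window = length_window(16, 18),
      confounders = cf(c("Ceratitis fasciventris", "Ceratitis anonae"),
                       c(100, 97.78))),
    species_signature("Ceratitis rosa", length_window(34),
      igs2_window = length_window(18, 22)),
    species_signature("Bactrocera dorsalis", length_window(0),
      confounders = cf(c("Bactrocera invadens", "Bactrocera carambolae",
                         "Bactrocera philippinensis", "Bactrocera papayae",
                         "Bactrocera ruiliensis", "Bactrocera thailandica"),
                       c(99.51, 99.51, 99.51, 99.51, 97.57, 97.57)))
  ), tolerance = tolerance)
}

table_species <- function(table) {
  vapply(table$entries, function(e) e$species, character(1))
}

find_entry <- function(table, species) {
  idx <- which(tolower(table_species(table)) == tolower(species))
  if (length(idx) == 0) stop("unknown species: ", species, call. = FALSE)
  table$entries[[idx]]
}

#' Look up a species' IGS-I or IGS-II window
#'
#' Species matching is case-insensitive exact on the full binomial.
#'
#' @param table a `signature_table`.
#' @param species binomial name.
#' @return a `length_window`, or `NULL` for [igs2_window()] where none is
#'   recorded.
#' @export
igs1_window <- function(table, species) find_entry(table, species)$igs1_window

#' @rdname igs1_window
#' @export
igs2_window <- function(table, species) find_entry(table, species)$igs2_window

#' Validate a signature table
#'
#' Violations are returned as data, not raised: a data frame with columns
#' `component` and `message`, empty when every structural invariant holds
#' and the tolerance-expanded IGS-I windows are pairwise disjoint.
#'
#' @param table a `signature_table`.
#' @param tolerance tolerance to use for the disjointness check; defaults to
#'   the table's own.
#' @return data frame of violations (possibly zero rows).
#' @export
validate_signature_table <- function(table, tolerance = table$tolerance) {
  stopifnot(length(table$entries) >= 1)
  v <- list()
  add <- function(component, message) {
    v[[length(v) + 1]] <<- data.frame(component = component, message = message)
  }
  for (e in table$entries) {
    for (wname in c("igs1_window", "igs2_window")) {
      w <- e[[wname]]
      if (is.null(w)) next
      if (w$min > w$max)
        add(paste(e$species, wname), "min_len > max_len")
      if (w$min < 0 || w$max < 0)
        add(paste(e$species, wname), "negative length")
    }
    if (nrow(e$confounders) > 0 &&
        any(e$confounders$identity <= 0 | e$confounders$identity > 100))
      add(paste(e$species, "confounders"), "identity outside (0, 100]")
  }
  sp <- table_species(table)
  if (anyDuplicated(tolower(sp)))
    add("table", "duplicate species entries")
  n <- length(table$entries)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      wi <- expand_window(table$entries[[i]]$igs1_window, tolerance)
      wj <- expand_window(table$entries[[j]]$igs1_window, tolerance)
      if (windows_overlap(wi, wj))
        add("igs1 disjointness",
            sprintf("expanded windows of %s and %s overlap at tolerance %d",
                    sp[i], sp[j], as.integer(tolerance)))
    }
  }
  if (length(v) == 0)
    data.frame(component = character(), message = character())
  else do.call(rbind, v)
}

#' Serialize a signature table to JSON
#'
#' Schema: `{"tolerance": int, "species": [{"species": str,
#' "igs1": {"min": int, "max": int}, "igs2": {...}|null,
#' "confounders": [{"taxon": str, "identity": num}]}]}`. The JSON document
#' is the extension point for adding taxa beyond the default five.
#'
#' @param table a `signature_table`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_signature_table <- function(table, path) {
  doc <- list(
    tolerance = table$tolerance,
    species = lapply(table$entries, function(e) {
      list(species = e$species,
           igs1 = list(min = e$igs1_window$min, max = e$igs1_window$max),
           igs2 = if (is.null(e$igs2_window)) NULL else
             list(min = e$igs2_window$min, max = e$igs2_window$max),
           confounders = e$confounders)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_signature_table
#' @export
read_signature_table <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  entries <- lapply(doc$species, function(e) {
    cfs <- if (length(e$confounders) == 0) NULL else
      data.frame(taxon = vapply(e$confounders, `[[`, "", "taxon"),
                 identity = vapply(e$confounders, `[[`, 0, "identity"))
    species_signature(
      e$species,
      length_window(e$igs1$min, e$igs1$max),
      igs2_window = if (is.null(e$igs2)) NULL else
        length_window(e$igs2$min, e$igs2$max),
      confounders = cfs)
  })
  signature_table(entries, tolerance = doc$tolerance)
}

# Stable content hash of a table, echoed in reports for provenance.
signature_table_hash <- function(table) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  write_signature_table(table, tf)
  unname(tools::md5sum(tf))
}

#' @export
print.signature_table <- function(x, ...) {
  cat("Signature table (", length(x$entries), " species, tolerance ",
      x$tolerance, " bp)\n", sep = "")
  for (e in x$entries) {
    igs2 <- if (is.null(e$igs2_window)) "-" else
      paste0("[", e$igs2_window$min, ",", e$igs2_window$max, "]")
    cat(sprintf("  %-22s IGS-I [%d,%d]  IGS-II %s  (%d confounder%s)\n",
                e$species, e$igs1_window$min, e$igs1_window$max, igs2,
                nrow(e$confounders),
                if (nrow(e$confounders) == 1) "" else "s"))
  }
  invisible(x)
}
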