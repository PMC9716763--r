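#' @import methods
#' @importFrom stats runif
#' @importFrom utils write.table read.delim packageVersion
NULL

# All coordinates in this package are 1-based inclusive (GenBank / IRanges
# convention), both internally and in reports.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement of a DNA string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()]
#' that accepts the full IUPAC alphabet.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Check that a string is valid IUPAC DNA
#' @param x character scalar.
#' @return `TRUE` invisibly; errors naming the first offending symbol.
#' @keywords internal
assert_iupac <- function(x) {
  bad <- setdiff(unique(strsplit(toupper(x), "")[[1]]), names(IUPAC_SETS))
  if (length(bad) > 0) {
    stop("invalid IUPAC DNA symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Derive a per-operation seed from one user-facing seed. Keeps every derived
# seed a valid 32-bit integer.
split_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + as.double(k) * 104729) %%
               (.Machine$integer.max - 1L)) + 1L
}

# Run code under a seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Random DNA with a given AT fraction, A/T and C/G split evenly.
random_dna <- function(n, at_fraction = 0.77) {
  if (n == 0) return("")
  p <- c(at_fraction / 2, at_fraction / 2,
         (1 - at_fraction) / 2, (1 - at_fraction) / 2)
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE, prob = p),
        collapse = "")
}

# sample() treats a scalar first argument as 1:n; this doesn't
sample_one <- function(x) if (length(x) == 1L) x else sample(x, 1L)

substr_circ <- function(seq, start, len) {
  # 1-based circular substring of length len starting at start
  L <- nchar(seq)
  doubled <- paste0(seq, seq)
  substr(doubled, start, start + len - 1)
}
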