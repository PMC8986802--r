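#' @useDynLib sctem, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Derive a reproducible stream seed from a master seed
#'
#' All randomness in the package flows from a single master seed through
#' named streams (master -> per-cell -> per-stage). Stream seeds are derived
#' with a Lehmer-style multiplicative hash of the label so that adding or
#' reordering cells never perturbs another cell's stream.
#'
#' @param master integer master seed.
#' @param ... one or more character/numeric labels naming the stream.
#' @return An integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483587 # prime < 2^31
  labels <- vapply(list(...), as.character, character(1L))
  h <- as.numeric(master) %% m
  for (lab in labels) {
    for (v in utf8ToInt(lab)) {
      h <- (h * 48271 + v) %% m
    }
  }
  as.integer(h)
}

#' Reverse-complement DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Bisulfite-reduce a DNA string
#'
#' C->T reduction models the fully converted top strand; G->A models its
#' complement. Used for primer design and reduced-alphabet comparisons.
#'
#' @param x character vector of DNA sequences.
#' @param mode `"CT"` or `"GA"`.
#' @return Converted character vector.
#' @export
bisulfite_reduce <- function(x, mode = c("CT", "GA")) {
  mode <- match.arg(mode)
  if (mode == "CT") chartr("C", "T", x) else chartr("G", "A", x)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Enumerate CpG dinucleotide start offsets
#'
#' @param sequence a single DNA string.
#' @return Sorted 0-based offsets `i` with `substr(sequence, i+1, i+2) == "CG"`.
#' @export
cpg_offsets <- function(sequence) {
  stopifnot(length(sequence) == 1L)
  hits <- gregexpr("(?=CG)", sequence, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) return(integer(0))
  as.integer(hits) - 1L
}

# split strings of equal length into an n x width character matrix
seq_char_matrix <- function(x) {
  w <- unique(nchar(x))
  stopifnot(length(w) == 1L)
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = length(x), ncol = w, byrow = TRUE)
}

# collapse a character matrix back into strings (vectorised over columns)
collapse_char_matrix <- function(m) {
  if (nrow(m) == 0L) return(character(0))
  do.call(paste0, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  mapply(function(x, y) {
    sum(strsplit(x, "")[[1L]] != strsplit(y, "")[[1L]])
  }, a, b, USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
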