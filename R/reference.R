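#' Construct a TE consensus object
#'
#' A consensus is the alignment/simulation anchor sequence for a transposable
#' element family (an AluYa5-like element by default). CpG start offsets are
#' always recomputed from the sequence, never trusted from the caller.
#'
#' @param sequence uppercase DNA string over A/C/G/T, length >= 100.
#' @param name label for the consensus.
#' @return An object of class `te_consensus`: list with `name`, `sequence`,
#'   `cpg_positions` (sorted 0-based offsets of CpG starts).
#' @export
te_consensus <- function(sequence, name = "TE_consensus") {
  sequence <- toupper(sequence)
  if (nchar(sequence) < 100L) {
    stop("consensus sequence must be at least 100 nt", call. = FALSE)
  }
  if (grepl("[^ACGT]", sequence)) {
    stop("consensus sequence may only contain A/C/G/T", call. = FALSE)
  }
  structure(
    list(name = name, sequence = sequence, cpg_positions = cpg_offsets(sequence)),
    class = "te_consensus"
  )
}

#' Generate a synthetic TE consensus sequence
#'
#' Plants `round(cpg_density * length)` CpG dinucleotides at random
#' non-adjacent offsets and fills the remaining positions with random bases,
#' repairing any accidental CpG so the planted set is exactly the CpG
#' complement of the sequence. A 300 nt sequence at density 0.08 is a
#' desk-scale stand-in for an AluYa5 consensus (~25 CpGs / ~300 nt).
#'
#' @param length sequence length, >= 100.
#' @param cpg_density target CpG starts per nucleotide, in (0, 0.5).
#' @param seed integer seed; output is deterministic per seed.
#' @param name consensus label.
#' @return A [te_consensus()] object.
#' @export
build_consensus <- function(length, cpg_density, seed = 1L,
                            name = "AluYa5-like") {
  if (length < 100L) stop("length must be at least 100", call. = FALSE)
  if (cpg_density <= 0 || cpg_density >= 0.5) {
    stop("cpg_density must be in (0, 0.5)", call. = FALSE)
  }
  set.seed(seed)
  n_cpg <- max(1L, round(cpg_density * length))
  # greedy non-adjacent placement of CpG start offsets (0-based)
  cand <- sample(0:(length - 2L))
  planted <- integer(0)
  for (p in cand) {
    if (length(planted) >= n_cpg) break
    if (!any(abs(planted - p) <= 1L)) planted <- c(planted, p)
  }
  planted <- sort(planted)
  chars <- sample(DNA_BASES, length, replace = TRUE)
  chars[planted + 1L] <- "C"
  chars[planted + 2L] <- "G"
  # repair accidental CpGs outside the planted set; replacing the filler G
  # with A cannot create a new CpG nor touch a planted one
  seqstr <- paste(chars, collapse = "")
  stray <- setdiff(cpg_offsets(seqstr), planted)
  if (length(stray)) {
    chars[stray + 2L] <- "A"
    seqstr <- paste(chars, collapse = "")
  }
  te_consensus(seqstr, name = name)
}

#' Synthesise a mini-genome of diverged TE copies
#'
#' Inserts `n_copies` independently mutated copies of the consensus on one
#' contig, separated by random non-TE flanks, and returns matching BED-style
#' annotations. A desk-scale surrogate for a repeat-annotated reference
#' genome.
#'
#' @param consensus a [te_consensus()] object.
#' @param n_copies number of TE copies, >= 1.
#' @param divergence per-base substitution probability in `[0, 0.2]`.
#' @param flank_len length of random flank between copies.
#' @param seed integer seed.
#' @param families character vector of family labels sampled per copy.
#' @param chrom contig name.
#' @return List of class `te_genome`: `genome` (list `name`, `seq`) and
#'   `annotations` (data.frame chrom/start/end/strand/family/element_id,
#'   0-based half-open, sorted, non-overlapping).
#' @export
synth_genome <- function(consensus, n_copies, divergence = 0.05,
                         flank_len = 100L, seed = 1L,
                         families = c("AluY", "AluSx", "AluSg"),
                         chrom = "te_contig") {
  stopifnot(inherits(consensus, "te_consensus"))
  if (n_copies < 1L) stop("n_copies must be >= 1", call. = FALSE)
  if (divergence < 0 || divergence > 0.2) {
    stop("divergence must be in [0, 0.2]", call. = FALSE)
  }
  set.seed(seed)
  L <- nchar(consensus$sequence)
  cons_chars <- strsplit(consensus$sequence, "")[[1L]]
  copy_mat <- matrix(rep(cons_chars, each = n_copies), nrow = n_copies)
  if (divergence > 0) {
    mut <- matrix(stats::runif(n_copies * L) < divergence, nrow = n_copies)
    n_mut <- sum(mut)
    if (n_mut > 0L) {
      shift <- sample(1:3, n_mut, replace = TRUE)
      cur <- match(copy_mat[mut], DNA_BASES)
      copy_mat[mut] <- DNA_BASES[((cur - 1L + shift) %% 4L) + 1L]
    }
  }
  copies <- collapse_char_matrix(copy_mat)
  flanks <- vapply(seq_len(n_copies + 1L), function(i) random_dna(flank_len),
                   character(1L))
  pieces <- character(2L * n_copies + 1L)
  pieces[seq(1L, by = 2L, length.out = n_copies + 1L)] <- flanks
  pieces[seq(2L, by = 2L, length.out = n_copies)] <- copies
  genome_seq <- paste(pieces, collapse = "")
  starts <- as.integer(flank_len + (0:(n_copies - 1L)) * (L + flank_len))
  fam <- sample(families, n_copies, replace = TRUE,
                prob = if (length(families) == 3L) c(0.6, 0.3, 0.1) else NULL)
  ann <- data.frame(
    chrom = chrom,
    start = starts,
    end = starts + as.integer(L),
    strand = "+",
    family = fam,
    element_id = sprintf("%s_%05d", fam, seq_len(n_copies)),
    stringsAsFactors = FALSE
  )
  structure(list(genome = list(name = chrom, seq = genome_seq),
                 annotations = ann),
            class = "te_genome")
}

# choose a primer anchor window with no CpG overlap where possible;
# side = "left" prefers the smallest admissible start, "right" the largest
find_anchor_window <- function(consensus, width, side, margin = 5L,
                               min_start = margin) {
  L <- nchar(consensus$sequence)
  if (min_start > L - width - margin) return(NA_integer_)
  starts <- min_start:(L - width - margin)
  cpg <- consensus$cpg_positions
  n_overlap <- vapply(starts, function(s) {
    sum(cpg >= s - 1L & cpg <= s + width - 1L)
  }, integer(1L))
  free <- starts[n_overlap == 0L]
  if (length(free)) {
    if (side == "left") min(free) else max(free)
  } else {
    best <- starts[n_overlap == min(n_overlap)]
    if (side == "left") min(best) else max(best)
  }
}

#' Design a combinatorial dual-index primer plate
#'
#' Models the internal-index amplicon architecture: each well carries a
#' unique 8 bp forward/reverse index pair, a fixed 0-5 N spacer cycled
#' across wells (to phase low-diversity amplicons on the flow cell), and
#' bisulfite-space priming sequences taken from fixed CpG-free anchor
#' windows on the consensus. Exactly `floor(n_wells / 2)` wells have the
#' read orientation reversed.
#'
#' Priming sequences live in bisulfite space: the forward primer is the
#' C->T-converted top strand of its anchor window; the reverse primer is the
#' reverse complement of its window with G->A conversion.
#'
#' @param consensus a [te_consensus()] object.
#' @param n_wells number of wells, 1-96.
#' @param seed integer seed.
#' @param primer_len priming-sequence length.
#' @param max_mismatch index mismatch tolerance the plate must support;
#'   index pairs are regenerated until all concatenated pairs are separated
#'   by Hamming distance `> 2 * max_mismatch`.
#' @return A `primer_plate` data.frame (one row per well) with columns
#'   `well_id`, `index_f`, `index_r`, `spacer_f`, `spacer_r`, `orientation`,
#'   `prime_f`, `prime_r`, `adaptor_f`, `adaptor_r`, and attributes
#'   `fwd_offset`, `rev_offset`, `primer_len`, `amplicon_len`,
#'   `n_internal_combinations`, `max_mismatch`.
#' @export
design_plate <- function(consensus, n_wells = 96L, seed = 1L,
                         primer_len = 22L, max_mismatch = 1L) {
  stopifnot(inherits(consensus, "te_consensus"))
  if (n_wells < 1L || n_wells > 96L) {
    stop("n_wells must be between 1 and 96", call. = FALSE)
  }
  set.seed(seed)
  L <- nchar(consensus$sequence)
  w1 <- find_anchor_window(consensus, primer_len, "left")
  # the reverse anchor must leave an interior between the priming sites
  w2 <- find_anchor_window(consensus, primer_len, "right",
                           min_start = w1 + primer_len + 20L)
  if (is.na(w1) || is.na(w2)) {
    stop("consensus too short to place two disjoint anchor windows",
         call. = FALSE)
  }
  win1 <- substr(consensus$sequence, w1 + 1L, w1 + primer_len)
  win2 <- substr(consensus$sequence, w2 + 1L, w2 + primer_len)
  prime_f <- bisulfite_reduce(win1, "CT")
  prime_r <- bisulfite_reduce(revcomp(win2), "GA")

  well_ids <- as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))[seq_len(n_wells)]
  min_dist <- 2L * max_mismatch + 1L
  draw_idx <- function(n) {
    vapply(seq_len(n), function(i) random_dna(8L), character(1L))
  }
  index_f <- draw_idx(n_wells)
  index_r <- draw_idx(n_wells)
  for (attempt in seq_len(100L)) {
    key <- seq_char_matrix(paste0(index_f, index_r))
    bad <- rep(FALSE, n_wells)
    if (n_wells > 1L) {
      for (i in seq_len(n_wells - 1L)) {
        d <- rowSums(key[(i + 1L):n_wells, , drop = FALSE] !=
                       matrix(key[i, ], n_wells - i, 16L, byrow = TRUE))
        hit <- which(d < min_dist)
        if (length(hit)) bad[c(i, i + hit)] <- TRUE
      }
    }
    if (!any(bad)) break
    if (attempt == 100L) {
      stop("failed to generate an index set at the requested distance",
           call. = FALSE)
    }
    index_f[bad] <- draw_idx(sum(bad))
    index_r[bad] <- draw_idx(sum(bad))
  }

  n_rev <- n_wells %/% 2L
  orientation <- sample(c(rep("reversed", n_rev),
                          rep("forward", n_wells - n_rev)))
  plate <- data.frame(
    well_id = well_ids,
    index_f = index_f,
    index_r = index_r,
    spacer_f = (seq_len(n_wells) - 1L) %% 6L,
    spacer_r = (seq_len(n_wells) + 2L) %% 6L,
    orientation = orientation,
    prime_f = prime_f,
    prime_r = prime_r,
    adaptor_f = "ACACTCTTTCCCTACACGACGCTCTTCCGATCT",
    adaptor_r = "GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT",
    stringsAsFactors = FALSE
  )
  attr(plate, "fwd_offset") <- w1
  attr(plate, "rev_offset") <- w2
  attr(plate, "primer_len") <- primer_len
  attr(plate, "amplicon_len") <- w2 + primer_len - w1
  attr(plate, "n_internal_combinations") <- n_wells
  attr(plate, "max_mismatch") <- max_mismatch
  class(plate) <- c("primer_plate", "data.frame")
  plate
}

assert_plate <- function(plate) {
  need <- c("well_id", "index_f", "index_r", "spacer_f", "spacer_r",
            "orientation", "prime_f", "prime_r")
  miss <- setdiff(need, names(plate))
  if (length(miss)) {
    stop("plate sheet is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(paste(plate$index_f, plate$index_r))) {
    stop("plate index pairs must be unique", call. = FALSE)
  }
  if (any(nchar(plate$index_f) != 8L) || any(nchar(plate$index_r) != 8L)) {
    stop("plate indexes must be exactly 8 nt", call. = FALSE)
  }
  if (any(plate$spacer_f < 0L | plate$spacer_f > 5L |
            plate$spacer_r < 0L | plate$spacer_r > 5L)) {
    stop("spacer lengths must be between 0 and 5", call. = FALSE)
  }
  if (!all(plate$orientation %in% c("forward", "reversed"))) {
    stop("unknown orientation value in plate sheet", call. = FALSE)
  }
  invisible(plate)
}
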