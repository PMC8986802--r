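#' Read a FASTA file
#'
#' @param path FASTA file (optionally gzipped).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file; `.gz` suffix triggers compression.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ file (optionally gzipped).
#' @return Named character vector of read sequences (names = read ids).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write reads to FASTQ
#'
#' Emits Illumina-style 4-line records with a constant Phred+33 quality
#' (`I`, Q40) by default.
#'
#' @param reads named character vector of read sequences.
#' @param path output file; `.gz` suffix triggers compression.
#' @param quality_char single quality character applied to every base.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- names(reads)
  quals <- Biostrings::BStringSet(strrep(quality_char, nchar(reads)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

stop_format <- function(path, line, msg) {
  stop(sprintf("%s: line %d: %s", path, line, msg), call. = FALSE)
}

#' Read TE annotations from BED6
#'
#' BED columns are chrom, start, end, name (element id), score, strand.
#' Coordinates are 0-based half-open on disk and kept that way internally.
#' The `family` of each element is recovered from the id prefix before the
#' last underscore (e.g. `AluY_00012` -> `AluY`).
#'
#' @param path BED6 file.
#' @return Annotation data.frame (chrom/start/end/strand/family/element_id).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = "character", fill = TRUE)
  if (nrow(dt) && ncol(dt) < 6L) {
    stop_format(path, 1L, "expected 6 tab-separated BED columns")
  }
  s <- suppressWarnings(as.numeric(dt[[2L]]))
  e <- suppressWarnings(as.numeric(dt[[3L]]))
  bad <- which(is.na(s) | is.na(e))
  if (length(bad)) stop_format(path, bad[1L], "non-numeric coordinates")
  bad <- which(s < 0 | s >= e)
  if (length(bad)) stop_format(path, bad[1L], "requires 0 <= start < end")
  bad <- which(!dt[[6L]] %in% c("+", "-"))
  if (length(bad)) stop_format(path, bad[1L], "bad strand")
  ids <- dt[[4L]]
  if (anyDuplicated(ids)) {
    stop_format(path, which(duplicated(ids))[1L], "duplicate element_id")
  }
  data.frame(
    chrom = dt[[1L]],
    start = as.integer(dt[[2L]]),
    end = as.integer(dt[[3L]]),
    strand = dt[[6L]],
    family = sub("_[^_]*$", "", ids),
    element_id = ids,
    stringsAsFactors = FALSE
  )
}

#' Write TE annotations to BED6
#'
#' @param annotations annotation data.frame as produced by [synth_genome()].
#' @param path output file.
#' @export
write_bed <- function(annotations, path) {
  out <- data.table::data.table(
    annotations$chrom, annotations$start, annotations$end,
    annotations$element_id, 0L, annotations$strand
  )
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a Bismark-dialect coverage file
#'
#' Dialect: tab-separated chrom, start (1-based), end (= start), methylation
#' percent, methylated count, unmethylated count.
#'
#' @param path `.cov` file.
#' @return data.frame with columns `chrom`, `pos` (1-based),
#'   `meth_percent`, `count_meth`, `count_unmeth`.
#' @export
read_cov <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (nrow(dt) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      meth_percent = numeric(0), count_meth = integer(0),
                      count_unmeth = integer(0), stringsAsFactors = FALSE))
  }
  if (ncol(dt) != 6L) stop_format(path, 1L, "expected 6 coverage columns")
  if (!is.numeric(dt[[2L]]) || !is.numeric(dt[[3L]])) {
    stop_format(path, 1L, "non-numeric positions")
  }
  bad <- which(dt[[2L]] != dt[[3L]])
  if (length(bad)) {
    stop_format(path, bad[1L], "start and end must be equal 1-based positions")
  }
  m <- dt[[5L]]; u <- dt[[6L]]
  bad <- which(is.na(m) | is.na(u) | m < 0 | u < 0 | (m + u) == 0)
  if (length(bad)) {
    stop_format(path, bad[1L], "counts must be >= 0 and not both zero")
  }
  bad <- which(abs(dt[[4L]] - 100 * m / (m + u)) > 1e-3)
  if (length(bad)) stop_format(path, bad[1L], "percent inconsistent with counts")
  # the percent is redundant with the counts; recompute it at full precision
  data.frame(chrom = as.character(dt[[1L]]), pos = as.integer(dt[[2L]]),
             meth_percent = 100 * as.numeric(m) / (as.numeric(m) + u),
             count_meth = as.integer(dt[[5L]]),
             count_unmeth = as.integer(dt[[6L]]),
             stringsAsFactors = FALSE)
}

#' Write a Bismark-dialect coverage file
#'
#' Percentages are printed with up to 6 significant digits; output is
#' byte-stable for a given table.
#'
#' @param cov coverage data.frame (see [read_cov()]).
#' @param path output `.cov` path.
#' @export
write_cov <- function(cov, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d",
                   cov$chrom, cov$pos, cov$pos,
                   formatC(cov$meth_percent, digits = 6, format = "g"),
                   cov$count_meth, cov$count_unmeth)
  writeLines(lines, path)
  invisible(path)
}

#' Read a primer-plate sheet
#'
#' Tab-separated with header columns `well_id`, `index_f`, `index_r`,
#' `spacer_f`, `spacer_r`, `orientation`, `prime_f`, `prime_r` (adaptors
#' optional). A user-supplied sheet for a real primer set drops in here.
#'
#' @param path plate sheet TSV.
#' @return A `primer_plate` data.frame.
#' @export
read_plate <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- as.data.frame(data.table::fread(path, header = TRUE, sep = "\t"))
  plate <- assert_plate(dt)
  attr(plate, "primer_len") <- nchar(plate$prime_f[1L])
  class(plate) <- c("primer_plate", "data.frame")
  plate
}

#' Write a primer-plate sheet
#'
#' @param plate a `primer_plate` data.frame.
#' @param path output TSV path.
#' @export
write_plate <- function(plate, path) {
  data.table::fwrite(as.data.frame(plate), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a pipeline configuration
#'
#' YAML with a versioned schema; see [pipeline_config()] for the fields.
#'
#' @param path YAML file.
#' @return A validated `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' Write a pipeline configuration
#'
#' @param config a `pipeline_config` list.
#' @param path output YAML path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a counts matrix (features x cells) from TSV
#'
#' First column holds feature ids, header row holds cell ids.
#'
#' @param path TSV file.
#' @return Integer matrix with feature rownames and cell colnames.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  m <- as.matrix(dt[, -1L, with = FALSE])
  rownames(m) <- dt[[1L]]
  if (any(m < 0)) stop(path, ": negative counts are not allowed", call. = FALSE)
  storage.mode(m) <- "integer"
  m
}

#' Write a counts matrix (features x cells) to TSV
#'
#' @param counts matrix with feature rownames and cell colnames.
#' @param path output TSV path.
#' @export
write_counts <- function(counts, path) {
  dt <- data.table::data.table(feature = rownames(counts))
  dt <- cbind(dt, data.table::as.data.table(counts))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}
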