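BS_CONFIGS <- c("OT", "CTOT", "CTOB", "OB")

#' Align bisulfite reads in the three-letter reduced alphabet
#'
#' Each read is compared against the C->T-reduced top strand and the
#' G->A-reduced bottom strand of the reference in up to four strand
#' configurations (OT, CTOT, CTOB, OB; all four when `non_directional`,
#' matching post-PCR amplicon chemistry). The reported hit is the unique
#' minimal-mismatch placement with mismatch rate at most
#' `max_mismatch_rate`; ties are flagged non-unique and excluded from the
#' `proper` set. Mates must align uniquely, on consistent strand
#' configurations and within `max_insert`, else both are marked improper.
#'
#' @param r1 named character vector of (trimmed) reads.
#' @param r2 optional mate vector, same names/order.
#' @param genome list with `name` and `seq`.
#' @param non_directional consider all four strand configurations.
#' @param max_mismatch_rate maximal mismatches per base of read length.
#' @param max_insert maximal mate start distance for a proper pair.
#' @param seed_k seed k-mer length for the index.
#' @return A `bs_alignments` data.frame: read_id, frag_id, mate, seq,
#'   start (0-based), config, mismatches, unique, proper.
#' @export
align_bisulfite <- function(r1, r2 = NULL, genome, non_directional = TRUE,
                            max_mismatch_rate = 0.1, max_insert = 2000L,
                            seed_k = 20L) {
  if (!nzchar(genome$seq %||% "")) {
    stop("empty reference genome", call. = FALSE)
  }
  paired <- !is.null(r2)
  if (paired) stopifnot(length(r1) == length(r2))
  all_reads <- c(r1, r2) # one C++ call so the seed index is built once
  res <- cpp_align_bisulfite(genome$seq, unname(all_reads), non_directional,
                             max_mismatch_rate, as.integer(seed_k))
  ids <- names(all_reads) %||% as.character(seq_along(all_reads))
  aln <- data.frame(read_id = ids, frag_id = ids,
                    mate = rep(if (paired) 1:2 else 1L,
                               each = length(r1)),
                    seq = unname(all_reads),
                    start = res$start,
                    config = ifelse(res$config >= 0,
                                    BS_CONFIGS[res$config + 1L],
                                    NA_character_),
                    mismatches = res$mismatches, unique = res$unique,
                    stringsAsFactors = FALSE)
  if (!paired) {
    aln$proper <- aln$start >= 0L & aln$unique
    class(aln) <- c("bs_alignments", "data.frame")
    return(aln)
  }
  a1 <- aln[aln$mate == 1L, , drop = FALSE]
  a2 <- aln[aln$mate == 2L, , drop = FALSE]
  fam1 <- match(a1$config, BS_CONFIGS) <= 2L
  fam2 <- match(a2$config, BS_CONFIGS) <= 2L
  proper <- a1$start >= 0L & a2$start >= 0L & a1$unique & a2$unique &
    !is.na(fam1) & !is.na(fam2) & fam1 == fam2 &
    abs(a1$start - a2$start) <= max_insert
  a1$proper <- proper
  a2$proper <- proper
  out <- rbind(a1, a2)
  rownames(out) <- NULL
  class(out) <- c("bs_alignments", "data.frame")
  out
}

#' Extract per-cytosine methylation calls from alignments
#'
#' Every reference cytosine covered by a properly aligned read yields one
#' call. Context (CpG/CHG/CHH) is classified from the reference alone;
#' state comes from the read base at the cytosine position (C = methylated,
#' T = unmethylated on the C->T-converted strand, G/A respectively for
#' bottom-strand configurations). Bottom-strand CpG calls are reported at
#' the top-strand C position so the two strands merge per site. When mates
#' overlap, the first mate wins.
#'
#' @param alignments a `bs_alignments` data.frame.
#' @param genome list with `name` and `seq`.
#' @return A `meth_calls` data.frame: frag_id, mate, pos (0-based), context,
#'   meth (logical).
#' @export
extract_methylation <- function(alignments, genome) {
  aln <- alignments[alignments$proper, , drop = FALSE]
  if (nrow(aln) == 0L) {
    out <- data.frame(frag_id = character(0), mate = integer(0),
                      pos = integer(0), context = character(0),
                      meth = logical(0), stringsAsFactors = FALSE)
    class(out) <- c("meth_calls", "data.frame")
    return(out)
  }
  raw <- cpp_extract_calls(genome$seq, aln$seq, aln$start,
                           match(aln$config, BS_CONFIGS) - 1L)
  dt <- data.table::data.table(
    frag_id = aln$frag_id[raw$read_index],
    mate = aln$mate[raw$read_index],
    pos = raw$pos,
    context = c("CpG", "CHG", "CHH")[raw$context],
    meth = raw$meth == 1L
  )
  data.table::setorder(dt, frag_id, pos, mate)
  dt <- unique(dt, by = c("frag_id", "pos"))
  out <- as.data.frame(dt)
  class(out) <- c("meth_calls", "data.frame")
  out
}

#' Aggregate CpG calls into a coverage table
#'
#' @param calls a `meth_calls` data.frame.
#' @param chrom contig name for the table.
#' @return Coverage data.frame (see [read_cov()]), positions 1-based.
#' @export
calls_to_cov <- function(calls, chrom = "te_contig") {
  dt <- data.table::as.data.table(calls)[context == "CpG"]
  if (nrow(dt) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      meth_percent = numeric(0), count_meth = integer(0),
                      count_unmeth = integer(0), stringsAsFactors = FALSE))
  }
  agg <- dt[, list(count_meth = sum(meth), count_unmeth = sum(!meth)),
            by = pos]
  data.table::setorder(agg, pos)
  data.frame(chrom = chrom, pos = agg$pos + 1L,
             meth_percent = 100 * agg$count_meth /
               (agg$count_meth + agg$count_unmeth),
             count_meth = as.integer(agg$count_meth),
             count_unmeth = as.integer(agg$count_unmeth),
             stringsAsFactors = FALSE)
}

count_overlapped_elements <- function(pos_1based, annotations) {
  if (length(pos_1based) == 0L || nrow(annotations) == 0L) return(0L)
  q <- IRanges::IRanges(start = pos_1based, width = 1L)
  s <- IRanges::IRanges(start = annotations$start + 1L,
                        end = annotations$end)
  ov <- IRanges::findOverlaps(q, s)
  length(unique(S4Vectors::subjectHits(ov)))
}

#' Per-cell methylation estimate with TE-annotation QC
#'
#' The estimator is the unweighted mean over covered CpG sites of each
#' site's methylation percentage ("site mean"), not the read-weighted mean
#' (also reported, for diagnostics). QC requires at least
#' `te_site_threshold` distinct annotated TE elements overlapped by a
#' covered CpG (1000 by default; 500 in the HL60 preset).
#'
#' @param cov coverage data.frame.
#' @param annotations TE annotation data.frame.
#' @param te_site_threshold minimal distinct elements for `qc_pass`.
#' @param cell_id label carried into the summary.
#' @param n_aligned_reads optional aligned fragment count for reporting.
#' @param calls optional `meth_calls` for non-CpG conversion rates.
#' @return One-row data.frame: cell_id, mean_site_methylation,
#'   read_weighted_methylation, n_covered_cpg_sites,
#'   n_unique_te_annotations, chg_rate, chh_rate, n_aligned_reads, qc_pass.
#' @export
cell_methylation <- function(cov, annotations, te_site_threshold = 1000L,
                             cell_id = NA_character_,
                             n_aligned_reads = NA_integer_, calls = NULL) {
  n_sites <- nrow(cov)
  mean_site <- if (n_sites) mean(cov$meth_percent) else NA_real_
  read_weighted <- if (n_sites) {
    100 * sum(cov$count_meth) / sum(cov$count_meth + cov$count_unmeth)
  } else NA_real_
  n_elem <- count_overlapped_elements(cov$pos, annotations)
  qc <- !is.na(mean_site) && n_elem >= te_site_threshold
  rates <- if (!is.null(calls)) conversion_qc(calls) else
    list(chg_rate = NA_real_, chh_rate = NA_real_)
  data.frame(cell_id = cell_id,
             mean_site_methylation = mean_site,
             read_weighted_methylation = read_weighted,
             n_covered_cpg_sites = n_sites,
             n_unique_te_annotations = n_elem,
             chg_rate = rates$chg_rate,
             chh_rate = rates$chh_rate,
             n_aligned_reads = n_aligned_reads,
             qc_pass = qc,
             stringsAsFactors = FALSE)
}

#' Bisulfite conversion QC from non-CpG contexts
#'
#' Mammalian non-CpG methylation is near zero, so apparent CHG/CHH
#' methylation measures conversion failure. The flag is raised when the
#' CHG rate exceeds the ceiling or when no non-CpG calls are available.
#'
#' @param calls a `meth_calls` data.frame.
#' @param ceiling CHG percentage above which the flag is raised.
#' @return List with `chg_rate`, `chh_rate` (percent) and `flag`.
#' @export
conversion_qc <- function(calls, ceiling = 2) {
  chg <- calls$meth[calls$context == "CHG"]
  chh <- calls$meth[calls$context == "CHH"]
  chg_rate <- if (length(chg)) 100 * mean(chg) else NA_real_
  chh_rate <- if (length(chh)) 100 * mean(chh) else NA_real_
  flag <- is.na(chg_rate) || chg_rate > ceiling
  list(chg_rate = chg_rate, chh_rate = chh_rate, flag = flag)
}

#' Depth-stability analysis by read down-sampling
#'
#' Subsamples aligned fragments without replacement at each depth,
#' recomputes the site-mean methylation estimate per replicate, and reports
#' the per-depth range (max - min). Sampling without replacement matches
#' read-count rarefaction semantics; a with-replacement (classical
#' bootstrap) mode is flag-gated.
#'
#' @param calls a `meth_calls` data.frame for one cell.
#' @param depths fragment counts to subsample to.
#' @param n_reps replicates per depth.
#' @param seed integer seed.
#' @param replace subsample with replacement instead.
#' @return List with `table` (depth/replicate/estimate) and `ranges`
#'   (depth/range).
#' @export
bootstrap_stability <- function(calls, depths, n_reps = 20L, seed = 1L,
                                replace = FALSE) {
  stopifnot(n_reps >= 1L)
  dt <- data.table::as.data.table(calls)[context == "CpG"]
  frags <- unique(dt$frag_id)
  set.seed(seed)
  rows <- list()
  for (d in depths) {
    if (d > length(frags)) {
      warning("depth ", d, " exceeds available fragments (", length(frags),
              "); skipped")
      next
    }
    for (rep_i in seq_len(n_reps)) {
      sel <- sample(frags, d, replace = replace)
      sub <- dt[data.table::chmatch(frag_id, sel, nomatch = 0L) > 0L]
      est <- sub[, list(m = sum(meth), t = .N), by = pos][, mean(100 * m / t)]
      rows[[length(rows) + 1L]] <-
        data.frame(depth = d, replicate = rep_i, estimate = est)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(depth = integer(0), replicate = integer(0),
               estimate = numeric(0))
  ranges <- if (nrow(tab)) {
    stats::aggregate(estimate ~ depth, tab,
                     function(x) max(x) - min(x))
  } else data.frame(depth = integer(0), estimate = numeric(0))
  names(ranges) <- c("depth", "range")
  list(table = tab, ranges = ranges)
}

#' Tiled bulk methylation averages
#'
#' Partitions the genome into fixed tiles from coordinate 0 (3000 bp in the
#' bulk comparison), averages site percentages per tile, and reports the
#' mean over tiles containing at least one site.
#'
#' @param cov coverage data.frame.
#' @param tile_size tile width in bp, >= 1.
#' @return List with `tiles` (tile/start/end/n_sites/mean_methylation) and
#'   `global` (mean over covered tiles).
#' @export
bulk_tile_methylation <- function(cov, tile_size = 3000L) {
  stopifnot(tile_size >= 1L)
  if (nrow(cov) == 0L) {
    return(list(tiles = data.frame(tile = integer(0), start = integer(0),
                                   end = integer(0), n_sites = integer(0),
                                   mean_methylation = numeric(0)),
                global = NA_real_))
  }
  dt <- data.table::as.data.table(cov)
  dt[, tile := (pos - 1L) %/% as.integer(tile_size)]
  agg <- dt[, list(n_sites = .N, mean_methylation = mean(meth_percent)),
            by = tile]
  data.table::setorder(agg, tile)
  tiles <- data.frame(tile = agg$tile,
                      start = agg$tile * tile_size,
                      end = (agg$tile + 1L) * tile_size,
                      n_sites = agg$n_sites,
                      mean_methylation = agg$mean_methylation)
  list(tiles = tiles, global = mean(tiles$mean_methylation))
}

#' TE-methylation-as-surrogate validation
#'
#' For each cell computes the global site-mean methylation and the
#' site-mean within annotations of one TE family, then fits the
#' ordinary-least-squares regression of family methylation on global
#' methylation across cells. Strong fits (R-squared near 1) justify using
#' TE methylation as a surrogate for the global level.
#'
#' @param cov_list named list of per-cell coverage data.frames covering the
#'   whole genome (not only TE amplicons).
#' @param annotations TE annotation data.frame with a `family` column.
#' @param family family label to restrict to (e.g. `"AluY"`).
#' @return List with `slope`, `intercept`, `r_squared`, `p_value` and
#'   `cells` (cell/global/te_family data.frame, percent units).
#' @export
surrogate_validation <- function(cov_list, annotations, family) {
  if (length(cov_list) < 3L) {
    stop("surrogate validation requires at least 3 cells", call. = FALSE)
  }
  fam_ann <- annotations[annotations$family == family, , drop = FALSE]
  if (nrow(fam_ann) == 0L) {
    stop("no annotations of family ", family, call. = FALSE)
  }
  s <- IRanges::IRanges(start = fam_ann$start + 1L, end = fam_ann$end)
  per_cell <- lapply(names(cov_list) %||% seq_along(cov_list), function(nm) {
    cov <- cov_list[[nm]]
    q <- IRanges::IRanges(start = cov$pos, width = 1L)
    inside <- IRanges::overlapsAny(q, s)
    data.frame(cell = nm,
               global = mean(cov$meth_percent),
               te_family = if (any(inside)) {
                 mean(cov$meth_percent[inside])
               } else NA_real_,
               stringsAsFactors = FALSE)
  })
  cells <- do.call(rbind, per_cell)
  fit <- stats::lm(te_family ~ global, data = cells)
  sm <- suppressWarnings(summary(fit))
  pval <- tryCatch(stats::coef(sm)[2L, 4L], error = function(e) NA_real_)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = sm$r.squared,
       p_value = pval,
       cells = cells)
}

#' Run alignment and methylation calling for one demultiplexed well
#'
#' Convenience wrapper: end-trims both mates (dropping a pair when either
#' mate becomes too short), aligns, extracts calls, aggregates the CpG
#' coverage table and produces the per-cell summary.
#'
#' @param r1,r2 trimmed per-well mates from [demultiplex()].
#' @param genome,annotations reference objects.
#' @param cell_id label for the summary row.
#' @param te_site_threshold QC threshold (1000; 500 for the HL60 preset).
#' @param trim5,trim3 end-trim widths applied before alignment.
#' @param ... passed to [align_bisulfite()].
#' @return List with `alignments`, `calls`, `cov`, `summary`.
#' @export
process_well <- function(r1, r2, genome, annotations,
                         cell_id = NA_character_, te_site_threshold = 1000L,
                         trim5 = 10L, trim3 = 10L, ...) {
  len1 <- nchar(r1); len2 <- nchar(r2)
  keep <- len1 >= (trim5 + trim3 + 1L) & len2 >= (trim5 + trim3 + 1L)
  r1 <- r1[keep]; r2 <- r2[keep]
  r1 <- stats::setNames(substr(r1, trim5 + 1L, nchar(r1) - trim3), names(r1))
  r2 <- stats::setNames(substr(r2, trim5 + 1L, nchar(r2) - trim3), names(r2))
  aln <- align_bisulfite(r1, r2, genome = genome, ...)
  calls <- extract_methylation(aln, genome)
  cov <- calls_to_cov(calls, chrom = genome$name)
  n_aligned <- sum(aln$proper[aln$mate == 1L])
  summary <- cell_methylation(cov, annotations,
                              te_site_threshold = te_site_threshold,
                              cell_id = cell_id,
                              n_aligned_reads = n_aligned, calls = calls)
  list(alignments = aln, calls = calls, cov = cov, summary = summary)
}
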