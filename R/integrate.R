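#' Normalize expression counts to log2 reads-per-million
#'
#' `value = log2(1 + count * 1e6 / library_size)` with the library size
#' taken as the column sum of raw counts. Base 2 and pseudocount 1 are
#' configurable. Cells with zero library size are excluded with a warning.
#'
#' @param counts integer matrix (features x cells).
#' @param base logarithm base.
#' @param pseudocount added before the log.
#' @return Numeric matrix of normalized values.
#' @export
normalize_expression <- function(counts, base = 2, pseudocount = 1) {
  libsize <- colSums(counts)
  zero <- libsize == 0
  if (any(zero)) {
    warning("excluding ", sum(zero), " cell(s) with zero library size: ",
            paste(colnames(counts)[zero], collapse = ", "))
    counts <- counts[, !zero, drop = FALSE]
    libsize <- libsize[!zero]
  }
  rpm <- sweep(counts, 2L, libsize, "/") * 1e6
  log(pseudocount + rpm, base = base)
}

#' Filter features by minimal expression breadth
#'
#' Keeps features with at least `min_reads` counts in at least `min_cells`
#' cells. Two named presets match common analysis stages: `"standard"`
#' (2 reads in 10 cells, correlation analysis) and `"de"` (5 reads in 3
#' cells, differential-expression style).
#'
#' @param counts raw counts matrix (features x cells).
#' @param min_reads,min_cells explicit thresholds (ignored when `preset`
#'   is given).
#' @param preset `"standard"`, `"de"`, or NULL for explicit thresholds.
#' @return Filtered counts matrix.
#' @export
filter_features <- function(counts, min_reads = 2L, min_cells = 10L,
                            preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("standard", "de"))
    if (preset == "standard") { min_reads <- 2L; min_cells <- 10L }
    else { min_reads <- 5L; min_cells <- 3L }
  }
  stopifnot(min_reads >= 0L, min_cells >= 0L)
  keep <- rowSums(counts >= min_reads) >= min_cells
  counts[keep, , drop = FALSE]
}

#' Correlate per-cell methylation with feature expression
#'
#' Pearson correlation of each feature's normalized expression with the
#' per-cell methylation estimate over shared cells, two-sided p-values from
#' the t transform `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees
#' of freedom, and Benjamini-Hochberg FDR over all tested features.
#' Constant features (or constant methylation) have undefined correlation
#' and are skipped, reported in the `skipped_features` attribute.
#'
#' @param meth named numeric vector of per-cell methylation percentages
#'   (QC-passing cells only).
#' @param expr normalized expression matrix (features x cells).
#' @return data.frame feature/r/p/fdr/n ordered by p, with attribute
#'   `skipped_features`.
#' @export
correlate_methylation_expression <- function(meth, expr) {
  cells <- intersect(names(meth), colnames(expr))
  if (length(cells) < 3L) {
    stop("need at least 3 shared cells for correlation", call. = FALSE)
  }
  m <- meth[cells]
  e <- expr[, cells, drop = FALSE]
  if (stats::sd(m) == 0) {
    stop("methylation is constant across cells; correlation undefined",
         call. = FALSE)
  }
  sds <- apply(e, 1L, stats::sd)
  skipped <- rownames(e)[sds == 0]
  e <- e[sds > 0, , drop = FALSE]
  n <- length(cells)
  r <- as.vector(stats::cor(t(e), m))
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- ifelse(abs(r) >= 1, 0, 2 * stats::pt(-abs(tstat), df = n - 2))
  res <- data.frame(feature = rownames(e), r = r, p = p,
                    fdr = stats::p.adjust(p, method = "fdr"), n = n,
                    stringsAsFactors = FALSE)
  res <- res[order(res$p, res$feature), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "skipped_features") <- skipped
  res
}

#' Aggregate TE element counts to family level
#'
#' TE feature ids carry `element:family:class` labels; counts of all
#' elements of one family are summed per cell and reported under the
#' `family:class` label (e.g. `Alu:SINE`, `L1:LINE`). Features without a
#' family label land in `unknown` with a warning. Gene rows (no `:` in the
#' id) are passed through unchanged.
#'
#' @param counts raw counts matrix (features x cells).
#' @return Matrix with gene rows and one row per TE family.
#' @export
aggregate_te_families <- function(counts) {
  ids <- rownames(counts)
  is_te <- grepl(":", ids, fixed = TRUE)
  genes <- counts[!is_te, , drop = FALSE]
  if (!any(is_te)) return(genes)
  te <- counts[is_te, , drop = FALSE]
  parts <- strsplit(rownames(te), ":", fixed = TRUE)
  fam <- vapply(parts, function(p) {
    if (length(p) >= 3L) paste(p[2L], p[3L], sep = ":") else NA_character_
  }, character(1L))
  if (anyNA(fam)) {
    warning(sum(is.na(fam)), " TE feature(s) without family label placed ",
            "in 'unknown'")
    fam[is.na(fam)] <- "unknown"
  }
  agg <- rowsum(te, group = fam)
  storage.mode(agg) <- "integer"
  rbind(genes, agg)
}

#' Export ranked significant and background gene lists
#'
#' Writes two one-id-per-line files for downstream gene-ontology analysis:
#' the features significant at `fdr < fdr_threshold` ordered by p-value,
#' and the expressed background under the "at least 10 reads in 2 cells"
#' rule applied to the raw counts.
#'
#' @param results output of [correlate_methylation_expression()].
#' @param counts raw counts matrix used to define the background.
#' @param dir output directory (created if needed).
#' @param fdr_threshold significance cutoff.
#' @param min_reads,min_cells background expression rule.
#' @return Invisible named character vector of the two file paths.
#' @export
export_ranked_genes <- function(results, counts, dir,
                                fdr_threshold = 0.05,
                                min_reads = 10L, min_cells = 2L) {
  if (nrow(results) == 0L) stop("empty correlation results", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sig <- results[results$fdr < fdr_threshold, , drop = FALSE]
  sig <- sig[order(sig$p, sig$feature), , drop = FALSE]
  background <- rownames(filter_features(counts, min_reads = min_reads,
                                         min_cells = min_cells))
  sig_path <- file.path(dir, "significant_genes.txt")
  bg_path <- file.path(dir, "background_genes.txt")
  writeLines(sig$feature, sig_path)
  writeLines(background, bg_path)
  invisible(c(significant = sig_path, background = bg_path))
}

#' Mean-centred hierarchical clustering diagnostic
#'
#' A plain diagnostic (not the canonical differential-expression workflow):
#' mean-centres log-normalized values and clusters rows and columns by
#' Euclidean distance, for a quick look at coordinated TE expression.
#'
#' @param expr normalized expression matrix.
#' @return List with `matrix` (centred values), `row_order`, `col_order`.
#' @export
cluster_diagnostic <- function(expr) {
  centred <- expr - rowMeans(expr)
  ro <- stats::hclust(stats::dist(centred))$order
  co <- stats::hclust(stats::dist(t(centred)))$order
  list(matrix = centred, row_order = ro, col_order = co)
}
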