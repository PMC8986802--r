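#' Per-cell simulation parameters
#'
#' Bundles the chemistry and sampling model for one simulated cell:
#' per-CpG Bernoulli methylation, bisulfite conversion failure (unmethylated
#' C read as C; mirrors the sub-1% CHG rates seen in well-converted
#' libraries), inappropriate conversion (methylated C read as T),
#' methylation-dependent amplification bias, and uniform sequencing error.
#'
#' @param cell_id cell label.
#' @param well_id plate well the cell's library is indexed with.
#' @param true_methylation per-CpG methylation probability (proportion).
#' @param conversion_failure P(unmethylated C retained as C).
#' @param inappropriate_conversion P(methylated C converted to T).
#' @param amp_bias amplification weight exponent base offset: template loci
#'   are drawn with weight `(1 + amp_bias)^m` where `m` is the number of
#'   methylated CpGs in the template.
#' @param n_read_pairs number of read pairs to emit.
#' @param seq_error per-base substitution error probability.
#' @param read_length read length in nt; reads shorter than the amplicon are
#'   truncated, never padded.
#' @param seed per-cell stream seed.
#' @return A `cell_sim_params` list.
#' @export
cell_sim_params <- function(cell_id, well_id, true_methylation,
                            conversion_failure = 0.007,
                            inappropriate_conversion = 0.002,
                            amp_bias = 0.1,
                            n_read_pairs = 20000L,
                            seq_error = 0.001,
                            read_length = 150L,
                            seed = 1L) {
  fracs <- c(true_methylation, conversion_failure, inappropriate_conversion,
             seq_error)
  if (any(fracs < 0 | fracs > 1)) {
    stop("all rate parameters must be in [0, 1]", call. = FALSE)
  }
  if (amp_bias < 0) stop("amp_bias must be >= 0", call. = FALSE)
  if (n_read_pairs < 0) stop("n_read_pairs must be >= 0", call. = FALSE)
  structure(list(cell_id = cell_id, well_id = well_id,
                 true_methylation = true_methylation,
                 conversion_failure = conversion_failure,
                 inappropriate_conversion = inappropriate_conversion,
                 amp_bias = amp_bias, n_read_pairs = as.integer(n_read_pairs),
                 seq_error = seq_error, read_length = as.integer(read_length),
                 seed = as.integer(seed)),
            class = "cell_sim_params")
}

# Precompute the amplicon templates shared by all cells of one genome/plate:
# primer-substituted template character matrix, CpG / non-CpG cytosine masks
# (contexts taken from the reference genome), and per-locus amplicon starts.
amplicon_model <- function(genome, annotations, plate) {
  plen <- attr(plate, "primer_len")
  w1 <- attr(plate, "fwd_offset")
  w2 <- attr(plate, "rev_offset")
  if (is.null(plen) || is.null(w1) || is.null(w2)) {
    stop("plate lacks anchor-offset attributes; use design_plate() output ",
         "for simulation", call. = FALSE)
  }
  amp_len <- w2 + plen - w1
  ok <- (annotations$end - annotations$start) >= (w2 + plen)
  ann <- annotations[ok, , drop = FALSE]
  if (nrow(ann) == 0L) {
    return(list(n_loci = 0L))
  }
  amp_start <- ann$start + w1
  # genome slice per locus, one extra base for CpG context at the right edge
  tmpl <- substring(genome$seq, amp_start + 1L, amp_start + amp_len)
  nxt <- substring(genome$seq, amp_start + amp_len + 1L, amp_start + amp_len + 1L)
  full <- seq_char_matrix(paste0(tmpl, ifelse(nchar(nxt) == 1L, nxt, "N")))
  tmpl_mat <- full[, seq_len(amp_len), drop = FALSE]
  is_c <- tmpl_mat == "C"
  next_g <- full[, 2L:(amp_len + 1L), drop = FALSE] == "G"
  cpg_mask <- is_c & next_g
  nonc_mask <- is_c & !next_g
  # primer bases overwrite the template at both anchor sites
  pre <- strsplit(plate$prime_f[1L], "")[[1L]]
  suf <- strsplit(revcomp(plate$prime_r[1L]), "")[[1L]]
  tmpl_mat[, seq_len(plen)] <- matrix(pre, nrow(tmpl_mat), plen, byrow = TRUE)
  tmpl_mat[, (amp_len - plen + 1L):amp_len] <-
    matrix(suf, nrow(tmpl_mat), plen, byrow = TRUE)
  # no methylation state is simulated inside primer-overwritten windows
  cpg_mask[, c(seq_len(plen), (amp_len - plen + 1L):amp_len)] <- FALSE
  nonc_mask[, c(seq_len(plen), (amp_len - plen + 1L):amp_len)] <- FALSE
  list(n_loci = nrow(ann), ann = ann, amp_start = amp_start,
       amp_len = amp_len, plen = plen, tmpl_mat = tmpl_mat,
       cpg_mask = cpg_mask, nonc_mask = nonc_mask)
}

apply_seq_error <- function(m, rate) {
  if (rate <= 0 || length(m) == 0L) return(m)
  err <- which(stats::runif(length(m)) < rate)
  if (length(err)) {
    shift <- sample(1:3, length(err), replace = TRUE)
    cur <- match(m[err], DNA_BASES)
    m[err] <- DNA_BASES[((cur - 1L + shift) %% 4L) + 1L]
  }
  m
}

#' Simulate one scTEM-seq cell library
#'
#' Draws one methylation state per (cell, CpG site), samples template loci
#' with amplification weight `(1 + amp_bias)^methylated-CpGs`, converts the
#' top strand in bisulfite space, and emits paired reads with the internal
#' `index + N-spacer + primer + insert` layout. For reversed wells the R1/R2
#' roles are swapped. All decisions are recorded in the returned truth
#' object.
#'
#' @param genome list with `name` and `seq` (see [synth_genome()]).
#' @param annotations TE annotation data.frame.
#' @param plate a `primer_plate` from [design_plate()].
#' @param params a [cell_sim_params()] object.
#' @param model optional precomputed amplicon model (internal reuse).
#' @return List with `r1`, `r2` (named read vectors) and `truth`: list of
#'   `cell_id`, `true_methylation`, `realized_methylation`, `sites`
#'   (data.frame pos/state over all CpG sites in amplifiable loci, 0-based
#'   genome positions of the CpG cytosine) and `reads` (read id ->
#'   element_id, template start, well).
#' @export
simulate_cell <- function(genome, annotations, plate, params, model = NULL) {
  stopifnot(inherits(params, "cell_sim_params"))
  assert_plate(plate)
  wrow <- match(params$well_id, plate$well_id)
  if (is.na(wrow)) {
    stop("unknown well: ", params$well_id, call. = FALSE)
  }
  if (is.null(model)) model <- amplicon_model(genome, annotations, plate)
  empty <- list(r1 = character(0), r2 = character(0),
                truth = list(cell_id = params$cell_id,
                             true_methylation = params$true_methylation,
                             realized_methylation = NA_real_,
                             sites = data.frame(pos = integer(0),
                                                state = logical(0)),
                             reads = data.frame(read_id = character(0),
                                                element_id = character(0),
                                                start = integer(0),
                                                well_id = character(0))))
  if (model$n_loci == 0L) {
    warning("no amplifiable loci in genome; emitting an empty library")
    return(empty)
  }
  set.seed(params$seed)
  nl <- model$n_loci
  # one epiallele per (cell, site); diploidy is deliberately ignored
  state_mat <- matrix(FALSE, nl, model$amp_len)
  ncpg <- sum(model$cpg_mask)
  state_mat[model$cpg_mask] <- stats::runif(ncpg) < params$true_methylation
  site_rowcol <- which(model$cpg_mask, arr.ind = TRUE)
  sites <- data.frame(
    pos = model$amp_start[site_rowcol[, 1L]] + site_rowcol[, 2L] - 1L,
    state = state_mat[model$cpg_mask]
  )
  sites <- sites[order(sites$pos), , drop = FALSE]
  rownames(sites) <- NULL
  n <- params$n_read_pairs
  truth <- list(cell_id = params$cell_id,
                true_methylation = params$true_methylation,
                realized_methylation = mean(sites$state),
                sites = sites,
                reads = empty$truth$reads)
  if (n == 0L) {
    out <- empty
    out$truth <- truth
    return(out)
  }
  m_per_locus <- rowSums(state_mat)
  w <- (1 + params$amp_bias)^m_per_locus
  idx <- sample.int(nl, n, replace = TRUE, prob = w)

  rmat <- model$tmpl_mat[idx, , drop = FALSE]
  u <- matrix(stats::runif(length(rmat)), nrow(rmat))
  sel <- model$cpg_mask[idx, , drop = FALSE]
  st <- state_mat[idx, , drop = FALSE]
  rmat[sel] <- c("T", "C")[(st[sel] &
                              u[sel] >= params$inappropriate_conversion) + 1L]
  sel2 <- model$nonc_mask[idx, , drop = FALSE]
  rmat[sel2] <- c("T", "C")[(u[sel2] < params$conversion_failure) + 1L]

  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rcmat <- matrix(comp[rmat], nrow(rmat))[, ncol(rmat):1L, drop = FALSE]

  build_side <- function(index, spacer, insert_mat) {
    keep <- min(ncol(insert_mat), params$read_length - 8L - spacer)
    parts <- cbind(
      matrix(strsplit(index, "")[[1L]], n, 8L, byrow = TRUE),
      if (spacer > 0L) matrix(sample(DNA_BASES, n * spacer, replace = TRUE),
                              n, spacer) else NULL,
      insert_mat[, seq_len(keep), drop = FALSE]
    )
    collapse_char_matrix(apply_seq_error(parts, params$seq_error))
  }
  fwd_reads <- build_side(plate$index_f[wrow], plate$spacer_f[wrow], rmat)
  rev_reads <- build_side(plate$index_r[wrow], plate$spacer_r[wrow], rcmat)

  ids <- sprintf("%s:frag%06d", params$cell_id, seq_len(n))
  if (plate$orientation[wrow] == "reversed") {
    r1 <- stats::setNames(rev_reads, ids)
    r2 <- stats::setNames(fwd_reads, ids)
  } else {
    r1 <- stats::setNames(fwd_reads, ids)
    r2 <- stats::setNames(rev_reads, ids)
  }
  truth$reads <- data.frame(read_id = ids,
                            element_id = model$ann$element_id[idx],
                            start = model$amp_start[idx],
                            well_id = params$well_id,
                            stringsAsFactors = FALSE)
  list(r1 = r1, r2 = r2, truth = truth)
}

#' Simulate a pooled multi-cell scTEM-seq run
#'
#' Runs [simulate_cell()] for every parameter set, pools and shuffles the
#' read pairs (seeded), and returns a truth table mapping each read pair to
#' its cell. Negative-control wells (no cell) can be included; by default
#' they contribute zero contaminating reads.
#'
#' @param genome,annotations,plate as in [simulate_cell()].
#' @param per_cell_params list of [cell_sim_params()]; wells must be unique.
#' @param include_negatives number of no-cell wells to reserve.
#' @param contamination_pairs read pairs of reagent contamination emitted per
#'   negative well (drawn from a high-methylation contaminant profile).
#' @param seed pool shuffling seed.
#' @return List with `r1`, `r2`, `truth_table` (read_id/cell_id/well_id),
#'   `cell_truths` (named list of per-cell truth objects) and
#'   `negative_wells`.
#' @export
simulate_plate <- function(genome, annotations, plate, per_cell_params,
                           include_negatives = 0L, contamination_pairs = 0L,
                           seed = 1L) {
  wells <- vapply(per_cell_params, `[[`, character(1L), "well_id")
  if (anyDuplicated(wells)) {
    stop("duplicate well assignment across cells", call. = FALSE)
  }
  model <- amplicon_model(genome, annotations, plate)
  neg_wells <- character(0)
  if (include_negatives > 0L) {
    free <- setdiff(plate$well_id, wells)
    if (length(free) < include_negatives) {
      stop("not enough free wells for negative controls", call. = FALSE)
    }
    neg_wells <- free[seq_len(include_negatives)]
  }
  sims <- lapply(per_cell_params, function(p) {
    simulate_cell(genome, annotations, plate, p, model = model)
  })
  names(sims) <- vapply(per_cell_params, `[[`, character(1L), "cell_id")
  if (contamination_pairs > 0L) {
    for (nw in neg_wells) {
      p <- cell_sim_params(cell_id = paste0("neg_", nw), well_id = nw,
                           true_methylation = 0.85,
                           n_read_pairs = contamination_pairs,
                           seed = derive_seed(seed, "contam", nw))
      sims[[p$cell_id]] <- simulate_cell(genome, annotations, plate, p,
                                         model = model)
    }
  }
  r1 <- unlist(lapply(sims, `[[`, "r1"), use.names = TRUE)
  r2 <- unlist(lapply(sims, `[[`, "r2"), use.names = TRUE)
  names(r1) <- sub("^[^.]*\\.", "", names(r1))
  names(r2) <- sub("^[^.]*\\.", "", names(r2))
  truth_table <- do.call(rbind, lapply(sims, function(s) {
    data.frame(read_id = s$truth$reads$read_id,
               cell_id = s$truth$cell_id,
               well_id = s$truth$reads$well_id,
               stringsAsFactors = FALSE)
  }))
  rownames(truth_table) <- NULL
  set.seed(derive_seed(seed, "pool"))
  ord <- sample.int(length(r1))
  list(r1 = r1[ord], r2 = r2[ord], truth_table = truth_table,
       cell_truths = lapply(sims, `[[`, "truth"),
       negative_wells = neg_wells)
}

TE_FAMILY_CATALOG <- c(
  Alu = "SINE", L1 = "LINE", MIR = "SINE", L2 = "LINE", ERV1 = "LTR",
  ERVK = "LTR", ERVL = "LTR", `ERVL-MaLR` = "LTR", `TcMar-Tigger` = "DNA",
  `hAT-Charlie` = "DNA", acro = "Satellite"
)

#' Simulate a gene/TE expression counts matrix with planted correlations
#'
#' Counts are negative-binomial around cell-specific means. Planted
#' features have log2 means depending linearly on the cell's true
#' methylation with the requested sign and effect size; all other features
#' are independent of methylation. TE features carry
#' `element:family:class` ids so family aggregation can be exercised.
#'
#' @param n_genes,n_tes number of gene and TE element features.
#' @param cells either a list of cell truth objects (from the simulator) or
#'   a data.frame with `cell_id` and `true_methylation` (proportion).
#' @param planted data.frame with columns `feature` (id or row index),
#'   `sign` (+1/-1) and `effect` (log2 fold change across the full
#'   methylation range 0 -> 1); NULL for a global null.
#' @param library_size expected per-cell total count.
#' @param seed integer seed.
#' @param dispersion_size NB `size` parameter (1/dispersion).
#' @return Integer matrix (features x cells) with a `planted` attribute.
#' @export
simulate_expression <- function(n_genes, n_tes, cells, planted = NULL,
                                library_size = 1e6, seed = 1L,
                                dispersion_size = 10) {
  if (is.data.frame(cells)) {
    cell_ids <- cells$cell_id
    meth <- cells$true_methylation
  } else {
    cell_ids <- vapply(cells, `[[`, character(1L), "cell_id")
    meth <- vapply(cells, `[[`, numeric(1L), "true_methylation")
  }
  set.seed(seed)
  fams <- sample(names(TE_FAMILY_CATALOG), n_tes, replace = TRUE)
  te_ids <- if (n_tes > 0L) {
    sprintf("%s_el%04d:%s:%s", fams, seq_len(n_tes), fams,
            TE_FAMILY_CATALOG[fams])
  } else character(0)
  feat_ids <- c(sprintf("GENE%05d", seq_len(n_genes)), te_ids)
  nf <- length(feat_ids)
  base_w <- stats::rlnorm(nf, meanlog = 0, sdlog = 1.5)
  logfc <- matrix(0, nf, length(cell_ids))
  if (!is.null(planted) && nrow(planted) > 0L) {
    ridx <- if (is.numeric(planted$feature)) as.integer(planted$feature)
            else match(planted$feature, feat_ids)
    if (anyNA(ridx) || any(ridx < 1L | ridx > nf)) {
      stop("planted feature index out of range", call. = FALSE)
    }
    for (i in seq_len(nrow(planted))) {
      logfc[ridx[i], ] <- planted$sign[i] * planted$effect[i] * meth
    }
  }
  mu <- base_w * 2^logfc
  mu <- sweep(mu, 2L, colSums(mu), "/") * library_size
  counts <- matrix(stats::rnbinom(nf * length(cell_ids), mu = mu,
                                  size = dispersion_size),
                   nf, length(cell_ids),
                   dimnames = list(feat_ids, cell_ids))
  attr(counts, "planted") <-
    if (is.null(planted)) NULL else
      data.frame(feature = feat_ids[if (is.numeric(planted$feature))
        as.integer(planted$feature) else match(planted$feature, feat_ids)],
        sign = planted$sign, effect = planted$effect)
  counts
}
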