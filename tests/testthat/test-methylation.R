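mk_aln <- function(seq, start, config = "OT", mate = 1L, frag = "f1") {
  out <- data.frame(read_id = frag, frag_id = frag, mate = mate, seq = seq,
                    start = start, config = config, mismatches = 0L,
                    unique = TRUE, proper = TRUE, stringsAsFactors = FALSE)
  class(out) <- c("bs_alignments", "data.frame")
  out
}

test_that("the smallest extraction case yields one methylated CpG call", {
  genome <- list(name = "g", seq = "ACGT")
  calls <- extract_methylation(mk_aln("ACGT", 0L), genome)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$pos, 1)       # 0-based C of the CG
  expect_equal(calls$context, "CpG")
  expect_true(calls$meth)
  cov <- calls_to_cov(calls, chrom = "g")
  expect_equal(cov$pos, 2)         # 1-based on disk
  expect_equal(cov$meth_percent, 100)
})

test_that("contexts are classified from the reference and states from the read", {
  # reference: C in CpG, CHG and CHH contexts; read converted at all three
  genome <- list(name = "g", seq = "ACGACGGACTTA")
  calls <- extract_methylation(mk_aln("ATGATGGATTTA", 0L), genome)
  expect_equal(calls$context[order(calls$pos)], c("CpG", "CpG", "CHH"))
  expect_false(any(calls$meth))
  # bottom-strand configuration reports the G positions, merged onto the C
  calls_b <- extract_methylation(mk_aln("ACGACGGACTTA", 0L, config = "CTOB"),
                                 genome)
  cpg_b <- calls_b[calls_b$context == "CpG", ]
  expect_true(all(cpg_b$pos %in% c(1, 4)))
  expect_true(all(cpg_b$meth))
})

test_that("overlapping mates count each cytosine once, first mate wins", {
  genome <- list(name = "g", seq = "ACGTACGT")
  a1 <- mk_aln("ACGTATGT", 0L, mate = 1L)           # CpG at 1 meth, at 5 unmeth
  a2 <- mk_aln("ATGTACGT", 0L, mate = 2L)           # disagrees at both sites
  aln <- rbind(a1, a2)
  class(aln) <- c("bs_alignments", "data.frame")
  calls <- extract_methylation(aln, genome)
  cpg <- calls[calls$context == "CpG", ]
  expect_equal(nrow(cpg), 2)
  expect_true(all(cpg$mate == 1))
  expect_equal(cpg$meth[order(cpg$pos)], c(TRUE, FALSE))
})

test_that("the estimator is the unweighted site mean, not the read mean", {
  cov <- data.frame(chrom = "g", pos = c(10, 20, 30),
                    meth_percent = c(100, 50, 0),
                    count_meth = c(2L, 1L, 0L), count_unmeth = c(0L, 1L, 2L))
  ann <- data.frame(chrom = "g", start = 0L, end = 100L, strand = "+",
                    family = "AluY", element_id = "AluY_1")
  cm <- cell_methylation(cov, ann, te_site_threshold = 1)
  expect_equal(cm$mean_site_methylation, 50)
  cov2 <- data.frame(chrom = "g", pos = c(10, 20),
                     meth_percent = c(100, 0),
                     count_meth = c(10L, 0L), count_unmeth = c(0L, 1L))
  cm2 <- cell_methylation(cov2, ann, te_site_threshold = 1)
  expect_equal(cm2$mean_site_methylation, 50)
  expect_equal(cm2$read_weighted_methylation, 1000 / 11, tolerance = 1e-10)
})

test_that("QC thresholds on distinct TE elements behave at the boundaries", {
  ann <- data.frame(chrom = "g", start = seq(0, by = 10, length.out = 1000),
                    end = seq(5, by = 10, length.out = 1000), strand = "+",
                    family = "AluY",
                    element_id = sprintf("AluY_%04d", 1:1000))
  mk_cov <- function(n) {
    data.frame(chrom = rep("g", n), pos = ann$start[seq_len(n)] + 1,
               meth_percent = rep(100, n), count_meth = rep(1L, n),
               count_unmeth = rep(0L, n))
  }
  expect_false(cell_methylation(mk_cov(999), ann, 1000)$qc_pass)
  expect_true(cell_methylation(mk_cov(1000), ann, 1000)$qc_pass)
  expect_true(cell_methylation(mk_cov(500), ann, 500)$qc_pass)  # HL60 preset
  expect_false(cell_methylation(mk_cov(0), ann, 1000)$qc_pass)
})

test_that("non-CpG rates track the conversion failure rate", {
  mkcalls <- function(context, meth) {
    data.frame(frag_id = "f", mate = 1L, pos = seq_along(meth),
               context = context, meth = meth, stringsAsFactors = FALSE)
  }
  qc <- conversion_qc(mkcalls(rep("CHG", 1000), rep(c(TRUE, FALSE),
                                                    c(25, 975))))
  expect_equal(qc$chg_rate, 2.5)
  expect_true(qc$flag)
  expect_true(conversion_qc(mkcalls(rep("CpG", 10), rep(TRUE, 10)))$flag)

  # simulated regime: conversion failure 0.0067 should reproduce ~0.67% CHG
  tg <- fix_genome(); plate <- fix_plate()
  p <- cell_sim_params("q", plate$well_id[6], 0.85,
                       conversion_failure = 0.0067, seq_error = 0,
                       n_read_pairs = 4000, seed = 66)
  sim <- simulate_cell(tg$genome, tg$annotations, plate, p)
  dm <- demultiplex(sim$r1, sim$r2, plate)
  w <- dm$wells[[p$well_id]]
  pw <- process_well(w$r1, w$r2, tg$genome, tg$annotations)
  n_chg <- sum(pw$calls$context == "CHG")
  se <- 100 * sqrt(0.0067 * (1 - 0.0067) / n_chg)
  expect_lt(abs(pw$summary$chg_rate - 0.67), 3 * se)
  expect_false(conversion_qc(pw$calls)$flag)
})

test_that("down-sampling at full depth or with one replicate has zero range", {
  cell <- fix_cell()
  frags <- length(unique(cell$pw$calls$frag_id[
    cell$pw$calls$context == "CpG"]))
  bs_full <- bootstrap_stability(cell$pw$calls, depths = frags, n_reps = 5,
                                 seed = 1)
  expect_equal(bs_full$ranges$range, 0)
  expect_equal(length(unique(bs_full$table$estimate)), 1)
  bs_one <- bootstrap_stability(cell$pw$calls, depths = 500, n_reps = 1,
                                seed = 1)
  expect_equal(bs_one$ranges$range, 0)
  expect_warning(
    bootstrap_stability(cell$pw$calls, depths = frags + 10, n_reps = 2),
    "exceeds available"
  )
})

test_that("estimates stabilise with depth", {
  cell <- fix_cell()
  bs <- bootstrap_stability(cell$pw$calls, depths = c(500, 4000),
                            n_reps = 20, seed = 7)
  expect_lt(bs$ranges$range[bs$ranges$depth == 4000],
            bs$ranges$range[bs$ranges$depth == 500])
})

test_that("tiled averages match a brute-force tiling", {
  single <- data.frame(chrom = "g", pos = 10, meth_percent = 73.5,
                       count_meth = 3L, count_unmeth = 1L)
  # percent column is validated against counts only on disk; here use exact
  single$meth_percent <- 75
  bt <- bulk_tile_methylation(single, 3000)
  expect_equal(nrow(bt$tiles), 1)
  expect_equal(bt$global, 75)

  set.seed(42)
  n <- 200
  cov <- data.frame(chrom = "g", pos = sort(sample(1:5000, n)),
                    meth_percent = NA, count_meth = 0L, count_unmeth = 0L)
  cov$count_meth <- rbinom(n, 5, 0.5); cov$count_unmeth <- 5 - cov$count_meth
  cov$meth_percent <- 100 * cov$count_meth / 5
  bt <- bulk_tile_methylation(cov, 1000)
  tiles <- (cov$pos - 1) %/% 1000
  manual <- sapply(sort(unique(tiles)), function(t) {
    mean(cov$meth_percent[tiles == t])
  })
  expect_equal(bt$tiles$mean_methylation, unname(manual))
  expect_equal(bt$global, mean(manual))

  uniform <- cov; uniform$meth_percent <- 100
  expect_equal(bulk_tile_methylation(uniform, 1000)$global, 100)
})

test_that("surrogate regression is exact for uniform per-cell methylation", {
  ann <- data.frame(chrom = "g", start = c(100L, 300L), end = c(200L, 400L),
                    strand = "+", family = "AluY",
                    element_id = c("AluY_1", "AluY_2"))
  pos <- c(50, 150, 250, 350, 450)
  lv <- c(20, 45, 70, 88, 95)
  covs <- lapply(lv, function(p) {
    data.frame(chrom = "g", pos = pos, meth_percent = p,
               count_meth = 1L, count_unmeth = 0L)
  })
  names(covs) <- sprintf("cell%d", seq_along(covs))
  fit <- surrogate_validation(covs, ann, "AluY")
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_error(surrogate_validation(covs[1:2], ann, "AluY"),
               "at least 3 cells")
})

test_that("surrogate regression recovers a planted TE offset", {
  ann <- data.frame(chrom = "g", start = 0L, end = 500L, strand = "+",
                    family = "AluY", element_id = "AluY_1")
  set.seed(8)
  n_cells <- 20
  globals <- seq(30, 90, length.out = n_cells)
  offsets <- rnorm(n_cells, 6.8, 1)
  covs <- lapply(seq_len(n_cells), function(i) {
    # TE sites (pos <= 500) methylated at global + offset, others at global
    data.frame(chrom = "g", pos = c(100, 200, 300, 600, 700, 800),
               meth_percent = c(rep(globals[i] + offsets[i] * 2, 3),
                                rep(globals[i] - offsets[i], 3)),
               count_meth = 1L, count_unmeth = 0L)
  })
  names(covs) <- sprintf("c%d", seq_len(n_cells))
  fit <- surrogate_validation(covs, ann, "AluY")
  # global = mean of all sites = g + offset/2; TE = g + 2*offset
  # so TE = global + 1.5*offset and the slope stays ~1
  expect_equal(fit$slope, 1, tolerance = 0.1)
  expect_equal(fit$intercept, 1.5 * 6.8, tolerance = 2.5)
  expect_gt(fit$r_squared, 0.95)
  # OLS agrees with the closed-form oracle
  o <- oracle_ols(fit$cells$global, fit$cells$te_family)
  expect_equal(fit$slope, unname(o["slope"]), tolerance = 1e-12)
  expect_equal(fit$intercept, unname(o["intercept"]), tolerance = 1e-12)
})

test_that("independent TE and global methylation give near-zero R squared", {
  ann <- data.frame(chrom = "g", start = 0L, end = 500L, strand = "+",
                    family = "AluY", element_id = "AluY_1")
  set.seed(9)
  covs <- lapply(1:30, function(i) {
    data.frame(chrom = "g", pos = c(100, 200, 600, 700),
               meth_percent = c(rep(runif(1, 0, 100), 2),
                                rep(runif(1, 0, 100), 2)),
               count_meth = 1L, count_unmeth = 0L)
  })
  names(covs) <- sprintf("c%d", 1:30)
  fit <- surrogate_validation(covs, ann, "AluY")
  expect_lt(fit$r_squared, 0.45)
})

test_that("estimator converges to the realized truth on simulated cells", {
  cell <- fix_cell()
  truth <- cell$sim$truth
  est <- cell$pw$summary$mean_site_methylation
  covered <- cell$pw$cov$pos - 1
  realized <- 100 * mean(truth$sites$state[truth$sites$pos %in% covered])
  n <- cell$pw$summary$n_covered_cpg_sites
  se <- 100 * sqrt(0.7 * 0.3 / n)
  expect_lt(abs(est - realized), 3 * se + 1) # +1 pp for chemistry noise
})
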