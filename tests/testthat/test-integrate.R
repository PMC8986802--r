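test_that("log2-RPM normalization matches hand arithmetic and is scale-free", {
  counts <- matrix(c(10L, 999990L), ncol = 1,
                   dimnames = list(c("a", "b"), "cell1"))
  norm <- normalize_expression(counts)
  expect_equal(norm["a", 1], log2(11), tolerance = 1e-12)
  counts0 <- matrix(c(0L, 100L), ncol = 1,
                    dimnames = list(c("a", "b"), "c"))
  expect_equal(normalize_expression(counts0)["a", 1], 0)
  m <- matrix(rpois(50, 20), 10, 5,
              dimnames = list(letters[1:10], paste0("c", 1:5)))
  m2 <- m; m2[, 3] <- m2[, 3] * 2L
  expect_equal(normalize_expression(m), normalize_expression(m2))
  mz <- m; mz[, 2] <- 0L
  expect_warning(nz <- normalize_expression(mz), "zero library size")
  expect_equal(ncol(nz), 4)
})

test_that("breadth filters keep boundary features and named presets apply", {
  counts <- rbind(
    keep = c(rep(2L, 10), rep(0L, 5)),
    drop = c(rep(2L, 9), rep(0L, 6)),
    high = c(rep(5L, 3), rep(0L, 12))
  )
  colnames(counts) <- paste0("c", 1:15)
  expect_equal(rownames(filter_features(counts, preset = "standard")),
               "keep")
  expect_equal(rownames(filter_features(counts, preset = "de")), "high")
  zero <- matrix(0L, 3, 15, dimnames = list(letters[1:3], paste0("c", 1:15)))
  expect_equal(nrow(filter_features(zero, preset = "standard")), 0)
})

test_that("exact linear relations give correlation of plus or minus one", {
  meth <- setNames(seq(30, 90, length.out = 10), paste0("c", 1:10))
  expr <- rbind(up = 2 * meth + 5, down = -0.5 * meth + 40,
                flat = rep(3, 10))
  colnames(expr) <- names(meth)
  res <- correlate_methylation_expression(meth, expr)
  expect_equal(res$r[res$feature == "up"], 1)
  expect_equal(res$r[res$feature == "down"], -1)
  expect_equal(res$p[res$feature %in% c("up", "down")], c(0, 0))
  expect_equal(attr(res, "skipped_features"), "flat")
  expect_error(correlate_methylation_expression(meth[1:2], expr[, 1:2]),
               "at least 3")
})

test_that("Pearson and BH agree with brute-force oracles to 1e-12", {
  set.seed(13)
  meth <- setNames(runif(12, 20, 95), paste0("c", 1:12))
  expr <- matrix(rnorm(12 * 25), 25, 12,
                 dimnames = list(paste0("f", 1:25), names(meth)))
  res <- correlate_methylation_expression(meth, expr)
  for (f in res$feature) {
    expect_equal(res$r[res$feature == f],
                 oracle_pearson(meth, expr[f, ]), tolerance = 1e-12)
  }
  expect_equal(res$fdr, oracle_bh(res$p), tolerance = 1e-12)
})

test_that("BH step-up collapses the textbook example", {
  meth <- setNames(c(1, 2, 3, 4, 5), paste0("c", 1:5))
  # engineered p-values via direct check of the adjustment only
  p <- c(0.01, 0.02, 0.03)
  expect_equal(oracle_bh(p), rep(0.03, 3))
  expect_equal(stats::p.adjust(p, "fdr"), rep(0.03, 3))
})

test_that("TE family aggregation sums elements and conserves totals", {
  counts <- rbind(
    GENE00001 = c(5L, 6L),
    `AluYa5_1:Alu:SINE` = c(3L, 1L),
    `AluSx_2:Alu:SINE` = c(4L, 0L),
    `L1PA11_1:L1:LINE` = c(7L, 2L)
  )
  colnames(counts) <- c("c1", "c2")
  agg <- aggregate_te_families(counts)
  expect_equal(agg["Alu:SINE", ], c(c1 = 7L, c2 = 1L))
  expect_equal(agg["L1:LINE", ], counts["L1PA11_1:L1:LINE", ])
  expect_equal(sum(agg), sum(counts))
  expect_true("GENE00001" %in% rownames(agg))
  bad <- rbind(counts, `odd:thing` = c(1L, 1L))
  expect_warning(agg2 <- aggregate_te_families(bad), "unknown")
  expect_equal(agg2["unknown", ], c(c1 = 1L, c2 = 1L))
})

test_that("ranked exports recover planted genes and obey the background rule", {
  cells <- data.frame(cell_id = sprintf("c%02d", 1:40),
                      true_methylation = seq(0.3, 0.9, length.out = 40))
  planted <- data.frame(feature = 1:10, sign = rep(c(1, -1), 5),
                        effect = 6)
  counts <- simulate_expression(300, 30, cells, planted = planted,
                                library_size = 3e5, seed = 17)
  kept <- filter_features(counts, preset = "standard")
  norm <- normalize_expression(kept)
  meth <- setNames(100 * cells$true_methylation, cells$cell_id)
  res <- correlate_methylation_expression(meth, norm)
  dir <- withr::local_tempdir()
  paths <- export_ranked_genes(res, counts, dir)
  sig <- readLines(paths[["significant"]])
  bg <- readLines(paths[["background"]])
  planted_ids <- attr(counts, "planted")$feature
  expect_gte(mean(planted_ids %in% sig), 0.9)
  expect_true(all(sig %in% bg))
  # background rule: >= 10 reads in >= 2 cells
  manual_bg <- rownames(counts)[rowSums(counts >= 10) >= 2]
  expect_setequal(bg, manual_bg)
})

test_that("an empty significant list still writes a non-empty background", {
  set.seed(99)
  meth <- setNames(runif(10, 20, 90), paste0("c", 1:10))
  expr <- matrix(rnorm(10 * 20), 20, 10,
                 dimnames = list(paste0("f", 1:20), names(meth)))
  counts <- matrix(20L, 20, 10, dimnames = dimnames(expr))
  res <- correlate_methylation_expression(meth, expr)
  dir <- withr::local_tempdir()
  paths <- export_ranked_genes(res, counts, dir, fdr_threshold = 1e-12)
  expect_length(readLines(paths[["significant"]]), 0)
  expect_gt(length(readLines(paths[["background"]])), 0)
})
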