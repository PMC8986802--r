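perfect_params <- function(well, true_meth, n = 200, seed = 11) {
  cell_sim_params("pc", well, true_meth,
                  conversion_failure = 0, inappropriate_conversion = 0,
                  amp_bias = 0, seq_error = 0, n_read_pairs = n, seed = seed)
}

test_that("fully unmethylated perfect chemistry leaves no cytosine in inserts", {
  tg <- fix_genome(); plate <- fix_plate()
  fwd <- plate$well_id[plate$orientation == "forward"][1]
  wrow <- match(fwd, plate$well_id)
  sim <- simulate_cell(tg$genome, tg$annotations, plate,
                       perfect_params(fwd, 0))
  body <- substr(sim$r1, 9 + plate$spacer_f[wrow], nchar(sim$r1))
  expect_false(any(grepl("C", body, fixed = TRUE)))
  # and the mate (reverse complement side) consequently carries no G
  body2 <- substr(sim$r2, 9 + plate$spacer_r[wrow], nchar(sim$r2))
  expect_false(any(grepl("G", body2, fixed = TRUE)))
})

test_that("fully methylated perfect chemistry retains every CpG cytosine", {
  tg <- fix_genome(); plate <- fix_plate()
  fwd <- plate$well_id[plate$orientation == "forward"][1]
  sim <- simulate_cell(tg$genome, tg$annotations, plate,
                       perfect_params(fwd, 1))
  expect_true(all(sim$truth$sites$state))
  # verified through the calling path: every CpG call methylated, every
  # non-CpG call unmethylated
  dm <- demultiplex(sim$r1, sim$r2, plate, max_mismatch = 0)
  w <- dm$wells[[fwd]]
  pw <- process_well(w$r1, w$r2, tg$genome, tg$annotations)
  expect_true(all(pw$calls$meth[pw$calls$context == "CpG"]))
  expect_false(any(pw$calls$meth[pw$calls$context != "CpG"]))
  expect_true(all(pw$cov$count_unmeth == 0))
})

test_that("realized site methylation matches the Bernoulli rate", {
  tg <- fix_genome(); plate <- fix_plate()
  p <- cell_sim_params("bc", plate$well_id[2], 0.8648, amp_bias = 0,
                       n_read_pairs = 20000, seed = 21)
  sim <- simulate_cell(tg$genome, tg$annotations, plate, p)
  n_sites <- nrow(sim$truth$sites)
  se <- sqrt(0.8648 * (1 - 0.8648) / n_sites)
  expect_lt(abs(sim$truth$realized_methylation - 0.8648), 3 * se)
})

test_that("pooled plates conserve reads, map truth and reproduce exactly", {
  tg <- fix_genome(); plate <- fix_plate()
  params <- list(
    cell_sim_params("c1", plate$well_id[1], 0.8, n_read_pairs = 100, seed = 1),
    cell_sim_params("c2", plate$well_id[2], 0.4, n_read_pairs = 100, seed = 2)
  )
  pool <- simulate_plate(tg$genome, tg$annotations, plate, params,
                         include_negatives = 2, seed = 9)
  expect_length(pool$r1, 200)
  expect_length(pool$r2, 200)
  expect_equal(nrow(pool$truth_table), 200)
  expect_length(pool$negative_wells, 2)
  expect_false(any(pool$truth_table$well_id %in% pool$negative_wells))
  pool2 <- simulate_plate(tg$genome, tg$annotations, plate, params,
                          include_negatives = 2, seed = 9)
  expect_identical(pool, pool2)
  dup <- list(params[[1]], params[[1]])
  expect_error(
    simulate_plate(tg$genome, tg$annotations, plate, dup),
    "duplicate well"
  )
})

test_that("template sampling is uniform over loci when amp_bias is zero", {
  tg <- fix_genome(); plate <- fix_plate()
  p <- cell_sim_params("u", plate$well_id[3], 0.5, amp_bias = 0,
                       n_read_pairs = 50000, seed = 31)
  sim <- simulate_cell(tg$genome, tg$annotations, plate, p)
  counts <- table(factor(sim$truth$reads$element_id,
                         levels = tg$annotations$element_id))
  gof <- suppressWarnings(stats::chisq.test(as.vector(counts)))
  expect_gt(gof$p.value, 0.001)
})

test_that("amplification bias over-samples methylated templates", {
  tg <- fix_genome(); plate <- fix_plate()
  p <- cell_sim_params("b", plate$well_id[4], 0.5, amp_bias = 0.5,
                       n_read_pairs = 20000, seed = 41)
  sim <- simulate_cell(tg$genome, tg$annotations, plate, p)
  # realized methylated fraction of each locus, from the truth site states
  st <- sim$truth$sites
  starts <- sort(unique(sim$truth$reads$start))
  locus_of_site <- findInterval(st$pos, starts)
  locus_mean <- tapply(st$state, locus_of_site, mean)
  sampled <- locus_mean[as.character(findInterval(sim$truth$reads$start,
                                                  starts))]
  expect_gt(mean(sampled), mean(locus_mean))
})

test_that("expression counts honour library size and planted structure", {
  cells <- data.frame(cell_id = sprintf("c%02d", 1:40),
                      true_methylation = seq(0.3, 0.9, length.out = 40))
  planted <- data.frame(feature = c(1L, 2L), sign = c(1, -1),
                        effect = c(4, 4))
  counts <- simulate_expression(200, 20, cells, planted = planted,
                                library_size = 1e6, seed = 5)
  expect_equal(dim(counts), c(220, 40))
  cs <- colSums(counts)
  # expected column total is the library size; deviations are NB sampling
  # noise (dominated by the few most abundant features)
  expect_lt(abs(mean(cs) - 1e6), 4 * sd(cs) / sqrt(length(cs)))
  expect_true(all(abs(cs - 1e6) < 6 * sd(cs)))
  norm <- normalize_expression(counts)
  r_pos <- oracle_pearson(cells$true_methylation, norm[1, ])
  r_neg <- oracle_pearson(cells$true_methylation, norm[2, ])
  expect_gt(r_pos, 0.5)
  expect_lt(r_neg, -0.5)
  # unplanted features stay near-uncorrelated on average (a small
  # compositional coupling with the planted features is expected under
  # per-cell renormalisation)
  r_null <- vapply(3:50, function(i) {
    oracle_pearson(cells$true_methylation, norm[i, ])
  }, numeric(1))
  expect_lt(abs(mean(r_null)), 0.25)
})

test_that("unknown wells and empty libraries are handled", {
  tg <- fix_genome(); plate <- fix_plate()
  expect_error(
    simulate_cell(tg$genome, tg$annotations, plate,
                  cell_sim_params("x", "Z99", 0.5)),
    "unknown well"
  )
  empty <- simulate_cell(tg$genome, tg$annotations, plate,
                         perfect_params(plate$well_id[1], 0.5, n = 0))
  expect_length(empty$r1, 0)
  expect_equal(nrow(empty$truth$reads), 0)
})
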