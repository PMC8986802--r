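# Shared fixtures, built once per test run. Seeds are fixed so every test
# sees identical synthetic data.

.fix <- new.env()

fix_consensus <- function() {
  if (is.null(.fix$cons)) .fix$cons <- build_consensus(300, 0.08, seed = 101)
  .fix$cons
}

fix_genome <- function() {
  if (is.null(.fix$tg)) {
    .fix$tg <- synth_genome(fix_consensus(), 300, divergence = 0.05,
                            flank_len = 100, seed = 202)
  }
  .fix$tg
}

fix_plate <- function() {
  if (is.null(.fix$plate)) .fix$plate <- design_plate(fix_consensus(), 96,
                                                      seed = 303)
  .fix$plate
}

# one processed 5000-pair cell reused by alignment/methylation tests
fix_cell <- function() {
  if (is.null(.fix$cell)) {
    tg <- fix_genome(); plate <- fix_plate()
    p <- cell_sim_params("fixcell", plate$well_id[1], 0.7,
                         n_read_pairs = 5000, seq_error = 0, seed = 404)
    sim <- simulate_cell(tg$genome, tg$annotations, plate, p)
    dm <- demultiplex(sim$r1, sim$r2, plate, max_mismatch = 0)
    w <- dm$wells[[p$well_id]]
    pw <- process_well(w$r1, w$r2, tg$genome, tg$annotations,
                       cell_id = "fixcell")
    .fix$cell <- list(params = p, sim = sim, pw = pw)
  }
  .fix$cell
}

# --- independent brute-force oracles (never call package internals) ---

oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  # step-up enforcement from the largest p downwards
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

oracle_ols <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  c(slope = slope, intercept = intercept)
}

# brute-force CpG scan over a sequence string
oracle_cpg_scan <- function(s) {
  hits <- integer(0)
  for (i in seq_len(nchar(s) - 1L)) {
    if (substr(s, i, i + 1L) == "CG") hits <- c(hits, i - 1L)
  }
  hits
}
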