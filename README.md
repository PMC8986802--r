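# sctem

Single-cell transposable element methylation sequencing (scTEM-seq)
estimates the **global DNA methylation level of individual cells** from
amplicon bisulfite sequencing of high-copy SINE Alu elements. Because Alu
CpG methylation tracks genome-wide methylation, thousands of Alu loci
sampled at only ~20,000 reads per cell stand in for a full methylome —
three orders of magnitude cheaper than genome-wide single-cell bisulfite
sequencing — and matched scRNA-seq from the same cells links methylation
heterogeneity (for example after hypomethylating-agent treatment of AML
cells) to transcriptional programs.

`sctem` is an R implementation of the computational pipeline for this
assay, plus a full generative simulator with ground truth, for anyone who
wants to run, audit or stress-test the method:

* **reference** — synthetic Alu-like consensus, mini-genome of diverged
  TE copies with BED annotations, and the 96-well combinatorial
  dual-index primer plate (8 bp indexes, 0–5 N spacers, priming sequences
  in bisulfite space, half the wells reversed).
* **simulate** — per-cell read-pair libraries with one methylation state
  per (cell, CpG site), bisulfite conversion failure, methylation-dependent
  amplification bias, sequencing error, and matched gene/TE expression
  counts with planted correlations.
* **demux** — internal dual-index demultiplexing with mismatch tolerance,
  ambiguity reporting and index/spacer/primer stripping.
* **methylation** — three-letter (C→T / G→A) bisulfite alignment in all
  four strand configurations, CpG/CHG/CHH methylation extraction to
  Bismark-style `.cov` tables, per-cell site-mean estimation with
  TE-annotation QC (≥ 1000 elements; 500 in the HL60 preset), depth
  down-sampling stability, 3000 bp tiled bulk averages and TE-vs-global
  surrogate regression.
* **integrate** — log2-RPM normalisation, breadth filters, Pearson
  correlation of expression with methylation under Benjamini–Hochberg
  FDR, TE family aggregation and ranked gene-list export.
* **cli_io** — strict readers/writers for FASTA/FASTQ/BED6/`.cov`/plate
  sheets/counts/YAML configs, an orchestrated `run_all()` with a checksum
  manifest, and a thin command-line front end (`inst/cli/sctem.R`).

## The estimator

For a cell with covered CpG sites $s = 1..n$ carrying $m_s$ methylated
and $u_s$ unmethylated calls, the global estimate is the **unweighted
site mean**

$$\hat{M} = \frac{100}{n}\sum_s \frac{m_s}{m_s + u_s}\ ,$$

not the read-weighted mean (also reported as a diagnostic). Conversion
efficiency is audited through apparent CHG/CHH methylation, and cells
covering too few distinct TE elements fail QC. Because methylated
templates amplify slightly better (modelled as weight $(1+\beta)^m$),
shallow libraries over-sample methylated loci: the estimate is inflated
at low read counts but stable within a 3-percentage-point range once
subsamples exceed 5000 aligned reads — the package reproduces both
effects from simulation.

## Worked example

```r
library(sctem)

# 1. Reference: Alu-like consensus, mini-genome of diverged copies, plate
cons  <- build_consensus(length = 300, cpg_density = 0.08, seed = 1)
tg    <- synth_genome(cons, n_copies = 2000, divergence = 0.05, seed = 2)
plate <- design_plate(cons, n_wells = 96, seed = 3)

# 2. Simulate one untreated-like and one decitabine-treated-like cell
params <- list(
  cell_sim_params("untreated", plate$well_id[1], true_methylation = 0.865,
                  n_read_pairs = 20000, seed = derive_seed(1, "cell", 1)),
  cell_sim_params("dac", plate$well_id[2], true_methylation = 0.42,
                  n_read_pairs = 20000, seed = derive_seed(1, "cell", 2))
)
pool <- simulate_plate(tg$genome, tg$annotations, plate, params, seed = 1)

# 3. Demultiplex by the internal dual indexes, then align and estimate
dm <- demultiplex(pool$r1, pool$r2, plate, max_mismatch = 1)
summaries <- do.call(rbind, lapply(params, function(p) {
  w <- dm$wells[[p$well_id]]
  process_well(w$r1, w$r2, tg$genome, tg$annotations,
               cell_id = p$cell_id)$summary
}))
summaries[, c("cell_id", "mean_site_methylation",
              "n_unique_te_annotations", "chg_rate", "qc_pass")]
```

```
    cell_id mean_site_methylation n_unique_te_annotations  chg_rate qc_pass
1 untreated              86.14528                    1794 0.7513855    TRUE
2       dac              41.68107                    1786 0.7489040    TRUE
```

The untreated-like cell (true per-CpG methylation 86.5%) is estimated at
86.1% and the treated-like cell (42%) at 41.7%, each from ~1800 distinct
Alu elements; the ~0.75% apparent CHG methylation reflects the simulated
0.7% conversion-failure rate and confirms efficient conversion. An
end-to-end run (simulation → demux → alignment → estimation → bootstrap →
correlation) is available as `run_all(pipeline_config(...))` or through
the CLI: `Rscript inst/cli/sctem.R run-all --config config.yaml`.

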