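---
title: "Estimating global DNA methylation from single-cell TE amplicons: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating global DNA methylation from single-cell TE amplicons: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sctem)
```

## The measurement problem

Genome-wide single-cell bisulfite sequencing needs millions of reads per
cell to say anything, yet many questions — hypomethylating-agent response
in AML, reprogramming fidelity, embryonic remodelling — only require the
*global* methylation level of each cell. Because SINE Alu and LINE-1
retrotransposons are present in hundreds of thousands of copies and their
internal CpGs track genome-wide methylation, amplicon bisulfite sequencing
of a TE consensus recovers a global estimate from ~20,000 reads: three
orders of magnitude cheaper. `sctem` implements the computational half of
this assay — simulation with ground truth, demultiplexing, bisulfite
alignment, estimation, QC, stability analysis and methylation–expression
integration — so the estimator and its failure modes can be studied
quantitatively.

## The assay model

A 96-well plate carries one primer pair per well. Each primer contributes,
5' to 3': a partial sequencing adaptor, a unique 8 bp index, a 0–5 N
spacer, and a priming sequence matching the bisulfite-converted consensus.
Both mates therefore begin with `index + spacer + primer`, giving every
library an *internal* dual index in addition to the later adaptor indexes;
the spacer phases otherwise low-diversity amplicon cycles on the flow
cell, and read direction is reversed in half the wells for the same
reason. `design_plate()` reproduces this architecture: priming sequences
are taken from fixed anchor windows on the consensus chosen to be CpG-free
where possible (so primer binding is insensitive to methylation state),
the forward primer is the C→T-converted top strand and the reverse primer
the reverse complement with G→A conversion, spacer lengths cycle 0–5
across wells (fixed per well, as a physical primer must be), and index
pairs are regenerated until every concatenated pair differs by Hamming
distance ≥ 3, which makes 1-mismatch correction provably unambiguous.
A real primer sheet can be supplied as a TSV through `read_plate()` and
drops in unchanged.

## What the simulator emulates

`simulate_cell()` draws one methylation state per (cell, CpG site) — a
single epiallele per locus; diploidy is deliberately ignored — and emits
read pairs with four noise processes:

* **Conversion failure** (`conversion_failure`, default 0.007): an
  unmethylated cytosine read as C. The default reproduces the ~0.67%
  apparent CHG methylation seen in well-converted libraries, which is how
  conversion efficiency is audited in practice.
* **Inappropriate conversion** (`inappropriate_conversion`, default
  0.002): a methylated cytosine read as T; a small, typical
  over-conversion rate.
* **Amplification bias** (`amp_bias`, default 0.1): template loci are
  sampled with weight $(1+\beta)^m$ where $m$ is the number of methylated
  CpGs in the template — the simplest monotone model of the preferential
  amplification of methylated fragments in bisulfite PCR.
* **Sequencing error** (`seq_error`, default 0.001 per base), uniform
  substitutions over the whole read including the index.

The default study conditions mirror the assay's operating regime: a
300 nt Alu-like consensus at CpG density 0.08 (~24 CpGs), 2000 diverged
copies (5% substitution) separated by 100 nt random flanks, 20,000 read
pairs of 150 nt per cell, and per-cell true methylation around 0.86
(untreated-like) or 0.42 (hypomethylating-agent-treated-like). With these
settings each cell covers 1000–2000 distinct annotated elements, matching
the 1000–6000 range the assay reports per cell.

The simulator does **not** model diploid epialleles, PCR duplicate
families, learned quality-score error profiles, indels, or the external
(Illumina-side) indexing round, and its copies diverge under a uniform
substitution model rather than the indel-rich history of real Alu
lineages. Passing tests therefore demonstrate correctness of the
*computational* pipeline under a faithful statistical model of the
chemistry, not performance on real sequencing artefacts.

All randomness flows from one master seed through named streams
(`derive_seed(master, "cell", i)`), so fixtures are bit-reproducible and
adding a cell never perturbs another cell's reads.

## Demultiplexing

A pair is assigned to a well when the first 8 nt of R1 and R2 each match
the well's index pair within `max_mismatch` substitutions (default 1),
with roles swapped for reversed wells. Matching is substitution-only and
anchored at position zero — indexes are primer-synthesised, so indel rates
are negligible. Pairs tying across wells are reported ambiguous and never
rescued. Index, the well's declared spacer length and the priming
sequence are then stripped; an optional primer-anchored search
(`primer_search = TRUE`) absorbs spacer drift at the cost of determinism.
After assignment, 10 bp is trimmed from both ends of each mate
(`trim_insert_ends()`) to remove residual adapter bases.

## Three-letter bisulfite alignment

Bisulfite conversion erases the C/T distinction, so reads are aligned in
a reduced alphabet: the genome is reduced C→T (top strand) and G→A
(bottom strand), and each read is tested in the four post-PCR strand
configurations (OT, CTOT, CTOB, OB) — non-directional mode, as amplicon
libraries require. The aligner (`src/align.cpp`) is seed-and-verify: a
k-mer table (k = 20) over both reduced genomes proposes candidate
placements from three seeds per read; candidates are verified by direct
mismatch counting with early abort, visiting high-multiplicity candidates
first so the bound tightens before the long tail of similar TE copies.
Numerical choices:

* a hit is kept when its mismatch rate is ≤ `max_mismatch_rate`
  (default 0.1 of read length);
* **uniqueness is per location**: ties across distinct positions at the
  minimal mismatch count mark the read non-unique and it is discarded
  (identical TE copies are genuinely unresolvable); the same position
  reached in two strand configurations — an unconverted read — counts as
  one alignment, reported under the first configuration;
* mates must align uniquely, on the same strand family (OT/CTOT vs
  CTOB/OB) and within `max_insert` (default 2000 bp), else both are
  dropped;
* three disjoint seeds guarantee that any placement with ≤ 2 mismatches
  is found; placements found through fewer seeds degrade gracefully.

This is a purpose-built aligner for amplicon-scale references (≤ a few
Mb); it makes no claim to FM-index genome-scale performance.

## Methylation calling and the per-cell estimator

`extract_methylation()` classifies every covered reference cytosine by
context from the reference alone (CG → CpG, C-H-G → CHG, else CHH) and
reads its state from the aligned base (C = methylated, T = unmethylated
on the converted strand; G/A for bottom-strand configurations).
Bottom-strand CpG calls are reported at the top-strand C so both strands
merge per site. Overlapping mates count each cytosine once, first mate
wins — the common default in extraction tools. CpG calls aggregate to a
Bismark-dialect `.cov` table (1-based positions, percent with six
significant digits; the percent is recomputed from the counts on read, so
round trips are exact).

The per-cell estimator is the **unweighted mean over covered CpG sites**
of each site's methylation percentage — not the read-weighted mean, which
a handful of deep sites would dominate. Both are reported; only the site
mean is used downstream. QC requires ≥ 1000 distinct annotated TE
elements overlapped by a covered CpG (≥ 500 in the HL60 preset).
"Annotated TE sites" is interpreted as distinct annotation *elements*
(consistent with per-cell counts of unique Alu annotations), not CpG
positions; both counts appear in the summary so the other reading remains
auditable. Apparent CHG/CHH methylation is reported as conversion QC with
a default 2% CHG ceiling.

## Depth stability and the low-depth bias

`bootstrap_stability()` subsamples aligned fragments *without*
replacement — the analysis is read-count rarefaction, and
without-replacement sampling has the right semantics (at full depth every
replicate is the full library and the range is exactly zero); a
with-replacement mode is flag-gated. The unit of subsampling is the
aligned fragment (read pair), since both mates of a fragment carry the
same template.

The site-mean estimator interacts with amplification bias in a subtle
way: each site's percentage is unbiased, but *which* sites are covered at
low depth is not — templates with more methylated CpGs amplify better, so
shallow libraries over-represent methylated loci and the site mean rises.
At higher depth nearly every site is covered at least once and the bias
vanishes. The simulation reproduces this: at $\beta = 0.2$ and true
methylation 0.9, estimates at depth 500 exceed estimates at depth 10,000
on average across seeds, while estimates remain stable within well under
3 percentage points at depths ≥ 5000.

## Bulk comparison and surrogate validation

`bulk_tile_methylation()` averages site percentages over fixed tiles
(3000 bp by default) from coordinate 0 and reports the mean over covered
tiles — the convention used for low-depth genome-wide bulk libraries.
`surrogate_validation()` regresses per-cell TE-family methylation on
per-cell global methylation (ordinary least squares via `lm()`); a high
R² is the quantitative justification for using TE methylation as a global
surrogate, and the TE-vs-global intercept measures the over-estimation
expected from TE enrichment in hypermethylated regions.

## Methylation–expression integration

Counts (consumed as a features × cells matrix; TE features carry
`element:family:class` ids) are normalised to `log2(1 + RPM)` — base 2
and pseudocount 1 are the package's documented, configurable reading of
"log-transformed RPM". Features are filtered by breadth with two named
presets: (2 reads, 10 cells) for correlation and (5 reads, 3 cells) for
differential-expression-style analyses. Per feature, Pearson correlation
with the per-cell site-mean methylation is computed over shared,
QC-passing cells; p-values use the t transform with n − 2 degrees of
freedom and are adjusted by Benjamini–Hochberg. Constant features are
skipped and reported, not assigned r = 0 — undefined is not zero. Treated
and untreated cells are pooled in one correlation (matching analyses that
place both groups on one methylation axis); within-group analysis is a
matter of subsetting the inputs. `aggregate_te_families()` sums element
counts per family for family-level tools, and `export_ranked_genes()`
writes the significant list plus the expressed background
(≥ 10 reads in ≥ 2 cells) for external gene-ontology services.
Negative-binomial differential expression itself is out of scope;
`cluster_diagnostic()` offers only a labelled, non-canonical
mean-centred clustering view.

## Problem sizes used by the test suite

The package's own checks run at deliberately chosen sizes: unit tests use
a 300-copy genome with 400–5000-pair libraries; the end-to-end regime
checks use the full 2000-copy genome with two 20,000-pair cells for the
depth-stability bound, 46 cells at true methylation 0.8648 for the
accuracy bound, and 20 simulation seeds at 15,000 pairs on a 500-copy
genome for the bias-direction property. These sizes reproduce the assay's
reported operating envelope (thousands of elements per cell at ~20k
reads) while remaining desk-scale.

## Known limitations

* The aligner is exhaustive over candidate seeds and suited to
  amplicon-scale references, not whole genomes.
* Uniform substitution divergence understates the repeat-family structure
  of real Alu subfamilies; unique-alignment rates in simulation (~90%)
  are accordingly higher than the ~67% reported on real data.
* No diploidy: per-site truth is a single epiallele, so allele-specific
  methylation cannot be studied.
* The surrogate-validation regression needs genome-wide coverage per
  cell, which the amplicon simulator does not produce; it is exercised on
  constructed coverage tables.
* Expression counts are negative-binomial with a global dispersion;
  zero-inflation and gene-length effects are not modelled.
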