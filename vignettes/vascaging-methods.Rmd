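---
title: "Models and methods behind vascaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vascaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vascaging)
```

vascaging implements the computational chain of STRT-style single-cell
studies of vascular aging — from barcoded reads to a ranked table of
candidate master regulators — together with a synthetic-data generator that
plants known age effects, so that every stage can be validated by recovery
of ground truth rather than by eyeballing. This vignette explains the
models, the tunable parameters, the numerical choices, and what the
validation does and does not demonstrate.

## The read layout and demultiplexing

Libraries follow a tagged reverse-transcription design: Read 1 carries the
cDNA; the first 8 nt of Read 2 are a cell barcode drawn from a 96-barcode
pool and the next 8 nt a unique molecular identifier (UMI), followed by
oligo-dT. `parse_read_pairs()` slices these positionally (positions 1–8 and
9–16, 1-based inclusive). Barcode matching is exact by default; the
conservative reading of a fixed whitelist. With `max_mismatch = 1` a
barcode is rescued only when it has a *unique* whitelist neighbour at
Hamming distance 1 — ambiguity rejects the read rather than guessing.

Read 1 is trimmed of a configurable template-switch-oligo prefix, one
adapter occurrence (longest adapter prefix of at least 5 nt at the 3' end),
and a trailing polyA run of ≥ 10 nt. The protocol this emulates does not
publish its oligo sequences, so both are user-supplied placeholders and
default to off. Read QC then removes reads shorter than 37 nt or with more
than 10% undetermined bases (exactly 10% passes; 36 nt fails).

Genome alignment is deliberately out of scope. `assign_genes()` is a toy
exact-match assigner: each transcript's k-mers (k = 21) are indexed, k-mers
shared between transcripts are discarded as ambiguous, and a read is
assigned to the gene winning a strict majority of its k-mer matches — ties
and no-matches stay unassigned, mirroring the uniquely-mapped-reads-only
convention. On the random toy transcriptomes the generator builds, distinct
transcripts essentially never share a 21-mer, which is what makes the
end-to-end round trip (reads → counts equal to the generating truth,
exactly) a meaningful test. `collapse_umis()` merges reads sharing
(cell, gene, UMI) into one molecule; no UMI error correction is applied
(a plain merge), so the count is the number of distinct UMI strings.

## Quality control and normalization

Cell filters come in two presets. The STRT preset keeps cells with
1000–10,000 detected genes (inclusive — a 999-gene cell fails, a 1000-gene
cell passes), strictly more than 3000 UMIs, mapping ratio strictly above
10%, and 1e4–3e6 aligned reads. The 10x preset keeps cells with more than
2000 genes and mitochondrial fraction below 0.15. Detected genes and UMI
totals are computed on non-ERCC rows: spike-ins are not cellular
transcripts. Both `mapping_ratio` (assigned / QC-passing reads) and
`aligned_reads` are emitted by the demultiplexer so the filters can run on
its output directly.

Gene filtering keeps genes with more than one count (≥ 2) in at least three
cells; ERCC rows are exempt because the noise statistic needs them
regardless of biological support. Normalization is global scaling,
`ln(count · scale / total + 1)` with scale 1e5 (1e4 for the 10x preset),
natural log; the fold-change convention below inherits this base.

The mean–dispersion trend behind highly-variable-gene selection uses the
method-of-moments negative-binomial dispersion, `(var − mean)/mean²` floored
at zero, and a loess trend of log dispersion on log10 mean (span 0.3,
degree 1, exposed as a parameter — the reference behaviour is
smooth-trend-based but the exact smoother is unspecified). A gene is highly
variable when its empirical dispersion exceeds three times the trend value.

## Old-versus-young differential expression

Within each cell type, each gene passing the detection filter *in that cell
type's cells* is tested old vs young with a two-sided Wilcoxon rank-sum
test on log-normalized expression: exact when both groups have ≤ 8
observations without ties, otherwise the normal approximation with
midranks, tie-corrected variance and continuity correction. (Exhaustive
enumeration at n = 8/8 shows the approximation is within 0.011 of exact in
the worst case.) The Bonferroni family is the number of genes tested in
that cell type. The reported effect size is the de-log/re-log average fold
change, `ln(mean(exp(x) − 1) + 1) − ln(mean(exp(y) − 1) + 1)`, in natural
log by default — the threshold 0.5 is applied on whichever base is
configured (`base = "log2"` switches), since the two conventions circulate
interchangeably in this literature. A DEG satisfies |avg logFC| ≥ 0.5 *and*
adjusted p ≤ 0.05, both boundaries inclusive. Groups below three cells
produce skipped records, not errors.

`shared_deg_summary()` reports per-type up/down counts, genes called in at
least two cell types, per-type unique genes, and direction-stratified
pairwise intersections (up with up, down with down);
`intersect_tf_list()` annotates shared genes against a user-supplied TF
list.

## The transcriptional-noise statistic

Per cell, noise is biological variation over technical variation: the
Euclidean distance between the cell's expression vector and the mean vector
of its cell type *within its monkey*, divided by the Euclidean distance of
the cell's ERCC vector to the same group's ERCC mean. Masks: biological
coordinates are the non-ERCC genes expressed (count ≥ 1) in at least three
cells of the cell type; the ERCC mask applies the same detection rule to
spike-in rows. Cells with zero technical distance are flagged and excluded
from group comparisons rather than dividing by zero.

Three choices were genuinely open and are configurable:

* **Scale.** Distances are computed on log-normalized expression by
  default (`scale = "raw"` is available). On raw counts the distance is
  dominated by the few highest-expressed genes; the log scale matches the
  normalization used everywhere else.
* **ERCC reference.** The technical reference is the per-monkey,
  per-cell-type ERCC mean, mirroring the biological reference.
* **Dimension.** `sqrt_dim_norm = TRUE` divides each distance by the
  square root of its mask size, removing the √dimension dependence of the
  two distances; the default is the plain ratio. An `hvg` argument
  restricts the biological mask to highly variable genes; the default uses
  the expressed-gene mask only.

`compare_noise()` reports per-cell-type group medians and a rank-sum p,
reusing the same Wilcoxon implementation as the DE module.

## Simplified master-regulator analysis

This module is an explicitly simplified, offline stand-in for
tree-ensemble + motif-database regulon workflows; motif support enters only
through a user-supplied (tf, target) map via `prune_by_motif()`.

Edges: for every target gene, TFs are ranked by absolute Spearman
correlation (a permutation-importance random-forest alternative sits behind
`method = "tree_importance"`), and the top k become edges. The default is
k = 1 — the single best-supported regulator per target. This is deliberate:
with ~20 TFs, keeping five regulators per target admits a quarter of all
possible edges, and regulons so diluted with spurious targets lose their
activity signal entirely; one edge per target keeps regulons close to their
generating truth while still recovering essentially all planted edges.

The aging signature scores each gene
`sign(avg logFC) · Φ⁻¹(1 − p/2)`, capped at ±8 (p = 0 maps to the cap);
when several cell types are pooled each gene keeps its most significant
record. Regulon activity is the standardized mean rank of the regulon's
targets among all signature scores, using the exact mean and variance of
the mean of n draws without replacement from N midranks — so the statistic
is distribution-free and invariant under any strictly monotone transform of
the scores; empirically it is standard normal for random regulons. Across
TFs, Benjamini–Hochberg FDR is computed and candidate master regulators
must have both p and FDR strictly below 0.05. Hubs are ranked by the number
of regulon targets that are called DEGs, descending, with deterministic
tie-breaks (|activity z|, then TF identifier), so rank 1 is the dominant
regulator of the aging signature. Regulons below five targets are skipped.

## The synthetic-data generator

`simulate_counts()` draws UMI counts from a negative binomial with
log-normal gene means — the standard overdispersed count model the
dispersion-trend HVG rule presumes. The default design mirrors the
emulated study: eight young and eight old monkeys, four vascular cell
types (EC/SMC/AF/IMM), 96-barcode pools, 8 + 8 nt read tags.

Parameters a user will actually touch, with defaults and reasoning:

* `baseline_log_mean_mu = log(20)`, `baseline_log_mean_sigma = 0.8` —
  per-gene mean counts. The generator simulates a reduced panel
  (2000 genes rather than a full transcriptome), so for a realistic
  deep-coverage UMI budget (~50k UMIs/cell) the per-gene depth is
  correspondingly high. Depth matters: planted noise factors transfer to
  the distance statistic only when count sampling does not dominate
  (see *Attenuation*, below).
* `nb_dispersion = 0.05` — technical overdispersion beyond Poisson,
  typical of UMI data; ERCC rows use the same value.
* `bio_noise_sd = 0.5` — the log-sd of the per-cell multiplicative
  biological deviation around the gene mean (a mean-one lognormal factor).
  This is the quantity the noise statistic measures. ERCC rows never
  receive it, and their expected counts are identical across a monkey's
  cells — they are pure technical variation by construction.
* `deg_fraction`, `deg_log2fc`, `deg_share_fraction` — planted DEGs are
  shifted by `deg_log2fc` (log2) in old cells of one cell type (two types
  for a 20% share fraction, emulating partial cross-type sharing). Planted
  DEGs are drawn outside all regulons so the two effects stay separable.
* `noise_inflation_old` — multiplies `bio_noise_sd` in old cells of the
  configured `noise_cell_types`. It scales the *deviation*, not the mean,
  so group means (and hence the DE module) are untouched.
* `n_tfs = 20`, `targets_per_tf = 15`, `tf_activity_sd = 0.8` — each TF
  carries a per-cell lognormal activity factor shared with its (disjoint)
  target set; this co-expression is what edge inference detects. One
  random TF is the hub with a double-size regulon, and `mr_effect` shifts
  the hub and its whole regulon down by that many log2 units in old cells.
* ERCC content: the emulated protocol does not state its spike-in
  dilution, so `n_ercc` (default 92) and the shared mean law are free
  parameters, not claims about any real library.

`simulate_reads()` turns a simulated count matrix into paired FASTQ with
the exact tag layout, optional polyA tails to exercise trimming, and
Poisson PCR duplication; the truth table records every UMI event, which
is what makes the demultiplexer's round trip checkable *exactly*.

**Attenuation.** On log-normalized counts the measured old/young noise
ratio is always somewhat below the generating inflation factor: count
sampling and NB overdispersion contribute deviation components that the
inflation does not scale, and very large inflated deviations saturate at
the dropout floor. Under the defaults, a planted factor of 2 is measured
as ≈ 1.7–1.8 — comfortably detected and within 20% of the planted value,
but a user comparing measured ratios to a generative model should expect
this compression, and it will be stronger in shallow libraries.

**What the generator does not emulate:** batch effects beyond monkey
identity, doublets, ambient RNA, read-quality errors, chimeric reads,
cell-type-specific baseline expression programs, and realistic full-depth
gene panels. Passing recovery tests therefore demonstrates correctness of
the statistics under their stated model, not robustness to every artifact
of real libraries.

## Problem sizes and determinism

The validation suite runs at deliberately reduced sizes chosen to keep the
statistical properties testable: DEG recovery at 300 cells per age group
over 20 simulation seeds (planted log2 fold change 1.5); noise recovery at
200 cells per group over 10 seeds (inflation 2, planted in ECs only); hub
recovery at 250 cells over 20 seeds; a 10,000-event UMI-collapse oracle;
and a ~300-cell demonstration pipeline. All randomness flows from a single
configuration seed (`withr::with_seed`), so any run — including the full
pipeline with its manifest of md5 checksums — is reproducible bit for bit.

## Known limitations

* The gene assigner is a toy; real data need a real aligner upstream, and
  the package consumes its count matrix via `read_experiment()`.
* Regulon inference is correlation-based and direction-blind
  (|Spearman|); activating and repressing edges are not distinguished,
  and no motif discovery is performed.
* The Bonferroni-within-cell-type convention makes DEG calls conservative;
  cross-cell-type comparisons inherit whatever dependence exists between
  cell types from shared animals.
* The noise statistic's plain ratio retains a √dimension dependence
  between masks of different sizes (an optional normalisation is
  provided), and attenuates large planted factors as described above.
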