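---
title: "Virtual microarray splice profiling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual microarray splice profiling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model behind `spliceArray`, the
parameters that matter, the numerical conventions, the choices we made where
the design was genuinely open, and what the built-in simulator does and does
not emulate.

## The counting model

The unit of the method is the **splice event**: a unique intron identified by
its chromosome, strand and intron start/end coordinates, joining two exonic
anchors. The pipeline observes events only through reads that *span* a
junction, by mapping reads onto **junction probes** rather than the genome.

A probe for read length $R$ and required overhang $m$ concatenates the last
$F = R - m$ exonic bases upstream of the intron with the first $F$ bases
downstream (length $L = 2F$, reported in transcribed orientation). The
geometry gives a sharp combinatorial guarantee: a read of length $R$ placed
entirely within the probe must start within $F$ bases of the junction on
either side, so it overlaps each adjoining exon by at least
$m = R - F$ bases. With the default $R=36$, $m=8$: $F=28$, $L=56$, and all
$L - R + 1 = 21$ fully-contained placements overlap both exons by 8–28
bases. Reads that do not span a junction cannot be placed at all, which is
the point of the construction.

Mapping is Hamming-only (no indels), both strands, with mismatch budget $k$
(default 2); `N` mismatches every base, including `N`. "Uniquely mapped" is
adjudicated at the probe level: a read counts one unit for a probe if and
only if every placement it has lands on that single probe and the probe is
not flagged ambiguous. Two placements on the *same* probe (possible for
periodic sequence) still count once — the unit of counting is the junction,
and that is also how conventional aligners define uniqueness relative to a
reference sequence. Probes with identical sequences (e.g. from segmental
duplications) are collapsed to one representative flagged `ambiguous`; hits
to them are never unique, but the event catalog retains the merged
annotations rather than silently deleting events.

The production mapper is seed-and-verify: for budget $k$ the read is split
into $k+1$ disjoint segments, so any placement within budget contains at
least one exact segment (pigeonhole); candidate placements found by exact
segment lookup are verified by direct mismatch counting. A brute-force
sliding-window scanner with the identical contract
(`map_read_bruteforce()`) exists purely as an independent reference, and
the test suite asserts equivalence on randomized instances.

## Database construction

From each transcript model with $x$ exons we emit $x-1$ exon–exon
observations (optionally also exon–intron boundary observations for
intron-retention probes, off by default because their probe geometry is the
only thing the construction fixes). Observations pass an
**anchor filter** — the flanking exon on each side must be at least $F$
bases, the minimal rule the probe geometry forces; truncated anchors in
real alignments are typically low-quality alignment artifacts, which is the
filter's purpose. Deduplication merges observations by
(chrom, strand, intron start, intron end, kind), unioning evidence
accessions, gene symbols and source classes, and assigns serial event ids
after coordinate sorting so the database is independent of input order.

Two open points we resolved:

* **Strand in the uniqueness key.** Uniqueness could be defined by intron
  coordinates alone; we include strand, because same-coordinate
  opposite-strand junctions would otherwise merge events whose donor and
  acceptor motifs contradict each other.
* **Which transcript's exons define the flank.** None needs to: after the
  anchor filter, the flank is genomic sequence immediately adjacent to the
  intron, identical for every supporting transcript whose anchor passes.
  A priority rule over evidence classes (RefSeq before mRNA before EST)
  was considered and is unnecessary; builds are reproducible without it.

The **motif filter** keeps events whose donor–acceptor pair is canonical or
that carry at least `min_multi_evidence = 2` independent evidence
sequences. The canonical set defaults to GT‑AG plus the minor spliceosomal
classes GC‑AG and AT‑AC; a stricter GT‑AG-only set is a configuration away.

## Quantification

Counts are normalized to RPKM with the probe as the feature:
$\mathrm{RPKM} = c / ((L_e/1000)(N_s/10^6))$ with $L_e$ the probe length
(56 by default) and $N_s$ the sample's library size. We use
**total uniquely probe-mapped reads** as $N_s$ (overridable): the pipeline
never sees non-junction reads, so normalizing by total sequenced reads
would import signal the counting model cannot observe.

Gene-level expression, needed by the confound filter, is computed by
projecting unique probe hits to genes — the sum of a gene's junction counts
over the union length of its exons. The pipeline maps reads only to probes,
so probe-hit projection is the natural genome-level assignment available;
an external gene count matrix (e.g. from a conventional quantifier) can be
supplied instead. Base-level coverage around a junction
(`base_level_profile()`) is likewise obtained by projecting each uniquely
mapped read's probe placement through the probe's genomic anchors, giving
per-base coverage over the exonic windows flanking donor and acceptor.

## Differential splicing

Per event we test log2(RPKM + $\varepsilon$) between condition and control
with a paired t-test by default — the intended design is matched
tumor/normal samples from the same individuals, and pairing removes the
shared individual effect — falling back to Welch's t for unpaired designs.
The pseudocount $\varepsilon = 1$ RPKM stabilizes logs where junction
counts are zero; fold changes use the same pseudocount,
$\log_2((\bar{x}_T + \varepsilon)/(\bar{x}_N + \varepsilon))$.

Numerical edge cases are pinned down: both groups all zero → p = 1,
flagged untestable; zero variance with equal means → p = 1; zero variance
with unequal means (constant nonzero paired differences) → the smallest
positive double, since the test statistic diverges. Raw p-value thresholds
drive the signature filters (strict 1e-4 and relaxed 1e-3, with linear
fold change > 1.5); Benjamini–Hochberg q-values are reported as an extra
column for modern FDR-based use but never applied to the threshold
filters, which are deliberately raw-p to match the method's definition.

The **confound filter** removes a signature event when *any* of its genes
tests differentially expressed at gene p < 0.01 — such events are
parsimoniously explained by expression change rather than splicing change.
Events whose gene cannot be resolved are kept and flagged.

**Clustering** of samples uses correlation distance (1 − Pearson on
log2(RPKM+1) profiles) with average linkage — the standard choice for
expression signatures. `stats::hclust` provides deterministic merging
(ties are resolved by its fixed internal order, so a given input always
yields the same tree); zero-variance profiles get correlation 0, i.e.
maximal distance, rather than NA.

## The simulator

`simulate_genome_and_models()` lays out genes on a synthetic chromosome
with exon/intron lengths drawn from configurable ranges (exons at least
56 bases so probes are always constructible) and plants canonical GT‑AG
motifs at every intron boundary of every isoform. Isoforms beyond the full
model cycle through exon skipping, alternative donor and alternative
acceptor edits (9–15 base shifts), optionally intron retention.

`simulate_reads()` draws reads **from transcript space**: read starts are
uniform over each transcript, so the expected number of probe-mappable
reads for a junction has the closed form
$n_{\text{tx}} \cdot \#\{s : x-F \le s \le x+F-R\} / (T-R+1)$
(21 interior placements for the default geometry), which the ground-truth
tables record per event and sample. Per-gene read totals are negative
binomial around depth-scaled means; matched samples share a per-individual
log-normal expression effect, so the paired test has exactly the structure
it assumes; planted splicing genes switch minor-isoform usage by a chosen
fold (default 0.2 → 0.8, linear fold 4) in the condition samples, and
planted expression genes scale whole-gene output with usage untouched.
Defaults mirror the target study design: ten individuals, two matched
samples each, 36-base reads.

Count-level generators (`simulate_event_counts()`,
`simulate_confound_study()`) produce the same matched-pair count structure
directly, for statistical experiments at scales where read-level
simulation is wasteful. Their defaults are the conditions we treat as
"adequate depth": mean 150 uniquely mapped reads per event per sample —
what constitutive junctions of moderately expressed genes receive at the
30–40 million read depth junction profiling requires — with residual
within-pair dispersion size 60 (mildly overdispersed relative to Poisson;
the biological individual effect, SD 0.25 log2, is modeled separately and
shared within pairs) .

What the simulator does **not** emulate: sequencing quality score
structure, indels, PCR duplicates, fragment-length and positional bias,
multi-gene families (so genuine cross-probe ambiguity is rare), incomplete
transcript annotation, and intron-spanning mismapping from the genome —
passing tests demonstrate the pipeline's internal correctness and
statistical behavior under its own model, not robustness to every artifact
of real libraries.

## Validation experiment design

The test suite fixes seeds and problem sizes chosen once:

* Mapper/reference equivalence on 10,000 randomized read–probe pairs with
  budgets 0–3, reads derived from probes with 0–3 mutations, `N`
  injections and reverse-complemented cases.
* Null calibration: 12,000 no-difference events, 5 matched pairs at the
  default depth; the fraction of p-values below α must sit within 3
  binomial standard deviations of α for α ∈ {0.05, 0.01, 0.001}.
* Recovery: 300 events planted at linear fold 4 among 300 nulls, 5 pairs;
  sensitivity of the relaxed signature (p < 0.001, FC > 1.5) and the
  confound filter's removal/retention rates are required to reach 90%.
* Clustering under depth reduction: a weak heterogeneous signature (30
  up, 30 down at linear fold 2, 240 nulls; log-normal baselines, SD 1;
  dispersion size 150 so counting noise dominates) across 6 replicate
  simulations per arm. High depth is mean 60 counts per event; the
  comparison arm is exactly 4-fold lower. We assert perfect 2-cut
  condition purity at high depth (median over replicates) and strictly
  lower mean purity after reduction. The depth levels were chosen by a
  power analysis of this design before the assertions were frozen: high
  depth sits well inside the always-separable regime, quarter depth well
  inside the noise-dominated regime, mirroring the empirical observation
  that low-coverage samples fail to cluster on splicing signatures even
  after RPKM normalization.

## Known limitations

* Hamming-only placement means reads with indels or spanning unannotated
  junctions are simply unmapped; the database bounds what can be seen.
* The t-test on log2(RPKM+1) is a pragmatic location test, not a count
  model; at very low depth its calibration depends on the pseudocount.
* Gene expression from junction-count projection underestimates genes with
  few junctions and is blind to single-exon genes.
* Exact intron-coordinate keys make cross-method junction comparison
  strict: a caller that shifts a boundary by one base does not intersect.
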