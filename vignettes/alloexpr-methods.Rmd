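---
title: "Methods: additivity, dominance and homoeolog bias in allopolyploid RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: additivity, dominance and homoeolog bias in allopolyploid RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alloexpr)
```

## The biological question

An allopolyploid or interspecific hybrid carries two divergent parental
genomes — call them A and C — in one nucleus. For every gene one can ask
how the merged genome expresses it relative to three references: the A
parent, the C parent, and the in-silico mid-parent value (MPV), the
average of the two parental levels. The answers organize into a small
taxonomy:

* **additive** — hybrid statistically equal to the MPV;
* **expression-level dominance (ELD)** — hybrid equal to one parent and
  different from the other (named for the mimicked parent, with an
  up/down direction relative to the other parent);
* **transgressive** — hybrid above or below both parents;
* **homoeolog expression bias** — within a homoeologous A/C gene pair,
  unequal expression of the two copies, measured between the parents and
  again inside the hybrid, which yields a parental-legacy reading
  (bias maintained, lost, novel, or reversed).

`alloexpr` implements this pipeline from fragment counts (or from
paired-end SAM alignments) through all of the classifications, together
with a simulator that plants each class with known truth labels.

## Statistical model

### Fisher's exact test on pooled counts

Replicates of a sample are pooled by summation and each gene is reduced
to the 2×2 table of (its count, the rest of the library) in the two
samples. `fisher_exact_two_sided()` sums hypergeometric probabilities no
larger than the observed table's (relative tie tolerance 1e-7, the
`fisher.test` convention), implemented directly on `dhyper` so that tens
of thousands of genome-scale tests are affordable. Within every contrast
family the p-values are Benjamini–Hochberg adjusted (`stats::p.adjust`)
and a gene is called at adjusted *P* < `alpha` (default 0.05), signed by
the depth-normalized count difference.

This test models *counting* noise only. Pooling replicates discards
biological replicate variance; with genuinely overdispersed replicates
the test is anticonservative. That is a property of the method being
reproduced, not an accident: the simulator's default
`nb_dispersion = 0` (pure Poisson) is the regime in which the pooled
exact test is calibrated, and the replicate-variance knob is exposed for
sensitivity analyses rather than used by default.

### The MPV pseudo-sample

The MPV is defined on expression levels, but an exact test needs an
integer count and a library. Each parent's pooled count is normalized to
the common depth L\* = (N_A + N_C)/2, the two normalized counts are
averaged and rounded half-up; L\* (rounded) is the pseudo-library. Exact
ties at .5 round away from zero throughout the package
(`round_half_up()`), matching conventional reporting arithmetic.

### 19 patterns and 9 categories

A gene's sign triple (hybrid vs A, hybrid vs C, A vs C) can formally
take 27 values, but signs derived from confidence-interval comparisons
are constrained (a hybrid above A and below C forces A < C, and so on).
`admissible_triples()` derives the realizable set by brute-force
enumeration over interval placements — exactly 19 triples — and
`assign_pattern()` maps them to the roman numerals I–XIX, with the 8
unrealizable triples mapped to `INCONSISTENT` (they can still occur
empirically because the three tests are run independently). Within the
groups pinned by the taxonomy (equal-to-both {VII, XI, XVII},
transgressive {I, IX, XV} and {II, X, XVI}, equal-to-one-parent,
intermediate {VIII, XIV}), numerals follow the canonical order
s\_pc = +, 0, −; the four ELD numerals XII/XIII/XVIII/XIX are fixed by
the taxonomy itself. `assign_category()` crosses the hybrid-vs-MPV sign
with the parental sign into the letters a–i (rows additive/up/down,
columns A=C, A>C, A<C).

Genes expressed in only some of the three samples are classified with
their actual counts (zeros included); `expressed_in = "all"` restricts
to the three-way-expressed universe instead.

### Homoeolog bias and parental legacy

For each A/C pair, two contrasts are run: A copy in the A parent vs C
copy in the C parent (each margin its own library), and both copies
within the hybrid (one library on both margins). Because the two
homoeologs differ in length and fragment counts scale with length, both
counts are first adjusted to the pair's mean length
(`c' = round_half_up(c · mean_len/len)`); a pair of equally expressed
homoeologs then tests null regardless of their length ratio. BH runs per
family (all pairs of one contrast). The (parent sign, hybrid sign) pair
is a pure function into nine categories; overall A-bias is the total of
pairs whose hybrid sign favors A (maintained + novel + reversed-to-A),
and a chi-square goodness-of-fit tests A:C against 1:1. The pair
universe defaults to `"either"` (each copy expressed in its parent or
the hybrid); `"all_samples"` is the stricter reading.

### Balance tests

Count balances (A- vs C-dominance, transgressive up vs down) are tested
with a two-sided exact binomial against 0.5. A t-test on two totals is
not well defined, so the binomial is the package's convention; the raw
totals are always reported alongside.

## Counting from SAM

`filter_and_count()` consumes a headered SAM (via Rsamtools) and applies
the paired-fragment acceptance rules:

1. both mates **best-unique**: mapped, primary, mapping quality ≥
   `min_mapq` (default 1), no `XA` alternative-hit tag;
2. both mates overlap the **same gene** with opposite strands → +1;
3. mates overlap two genes **adjacent** in start-coordinate order on one
   chromosome (irrespective of strand or distance) → +0.5 to each gene.

Everything else — unmapped or missing mates, single-end gene hits,
non-adjacent genes, same-strand pairs — is rejected and logged by
reason, and `accepted + rejected = pairs examined` always holds. A mate
overlaps a gene at ≥1 bp; ties go to the larger overlap, then
lexicographic gene id. The 0.5 split for adjacent-gene fragments avoids
double counting; counts may therefore be half-integral and are rounded
half-up before any exact test. Library size for SAM-derived columns is
the total assigned mass.

## The simulator

`sim_config()` describes a five-library design mirroring a two-hybrid
study: parents `AA1`, `AA2`, a shared `CC`, hybrids `AC1`, `AC2`, two
biological replicates each. Counts are gamma-Poisson with
variance μ + μ²·dispersion; dispersion 0 (the default, see above)
degrades to Poisson. Replicates share their gene-level mean.

Planted classes are assigned per *unit* (an unpaired gene, or a
homoeolog pair whose two copies are coordinated): additive at equal or
fold-different parental levels, the four ELD forms (hybrid mean set to
the dominant parent's), transgressive up/down (hybrid mean
`effect_fold` above, or below, both parents), novel homoeolog bias
(parents equal, hybrid copies fold apart — only meaningful for pairs, so
unpaired draws of it fold into the additive background), and silent.
Genes that never produce a fragment are relabeled `silent` post hoc.

Three modeling choices matter for interpretation:

* **Declared depth.** The simulated genes are a subset of the
  transcriptome a library samples, so the configured `lib_sizes` is the
  *declared* sequencing depth and travels with the count table
  (`#library_size` lines in the TSV). Defining library size as the
  column sum of simulated genes instead would make planted folds shift
  every other gene's relative abundance — a composition artifact, not a
  property of the planted truth; with a declared depth, relative
  abundances equal the planted structure exactly. SAM-derived tables
  keep the accepted-mass convention. The generator refuses
  configurations whose planted mass exceeds the declared depth.
* **Length scaling.** Expected counts scale with gene length
  (level × len/1200 bp × depth), the FPKM model; this is what makes the
  pair test's length adjustment exact rather than approximate.
* **Constant baseline.** All genes of a class share the configured
  `mean_expression` at the reference length and depth, so planted effect
  sizes are exact and per-class recovery is measurable. Real data spread
  expression over orders of magnitude; passing recovery tests here shows
  the machinery is correct at the planted signal-to-noise, not that real
  libraries at those depths reach the same power.

Defaults were chosen once to echo the study conditions: ~46% of genes
expressed in leaf tissue (silent mass 0.54), ELD classes ≈ one third of
the parent-differential mass, more transgressive-up than -down, two
replicates, fold 4, mean 100 fragments, 5e6 fragments per library.
`generate_dataset()` is fully determined by the configuration (including
its seed), and `write_fixture()` emits byte-identical files for
identical configurations.

The synthetic SAM writer realizes one count column as read pairs:
planted counts become same-gene opposite-strand pairs, and where both
members of an adjacent gene pair have counts available, two bridging
pairs replace one count of each (so each gene still receives an integer
total). A fixed set of distractor pairs exercises every rejection
reason. The writer returns the expected acceptance log, making
`filter_and_count()` testable as an exact oracle.

## Numerical conventions and degenerate inputs

* Signs are integers −1/0/+1 everywhere; `format_sign()`/`parse_sign()`
  convert to the `-`/`0`/`+` notation used in output tables.
* Percentages round half-up at one decimal by default (`percent()`);
  stored counts always accompany them so rounding never compounds.
* Averages reported as integers use the floor (`mean_integer()`).
* A zero-gene configuration yields empty, well-formed tables; an
  all-zero contrast is an error (no expressed genes), while an all-zero
  homoeolog pair simply gets sign 0.
* Coordinates are 0-based half-open internally; BED is native, GFF3 is
  converted on read/write, and the two writers describe identical
  intervals.

## Problem sizes

The shipped tests run the calibration studies at 10000 genes (null
calibration: spurious-call rate against 0.05 + 3 binomial SEs; ≥95% of
null genes in the equal-to-both patterns; ≥(1−α)² of null pairs in
maintained-equal) and at 10000 genes for planted-effect recovery
(effect fold 8, mean 500 fragments, 1000 genes per class, ≥90% recovery
of every ELD form, transgressive direction and bias direction), with
smaller replicas in the per-module tests. The `analysis/` scripts use
20000 genes. These sizes give stable rates while keeping a full run in
minutes on one core.

## Known limitations

* No biological replicate variance by default (see above); dispersion is
  a knob, but the pooled exact test itself is then anticonservative —
  as is the method the package reproduces.
* Homoeolog counts are assumed already resolved per subgenome copy by
  the upstream mapping; there is no SNP-aware read phasing and no
  modeling of homoeologous exchange.
* Gene length is the full annotated interval (no exon-resolved lengths),
  and the SAM path has no spliced-alignment awareness or duplicate
  marking.
* The simulator's constant baseline and clean fold-changes favor
  detectability; empirical class proportions (e.g. the share of
  non-additive genes) are not calibrated to any particular tissue and
  should not be read as predictions.
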