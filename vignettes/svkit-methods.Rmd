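---
title: "Methods behind svkit: simulation, consensus SV calling, CNV genotyping and transience"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind svkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svkit)
```

svkit implements the computational core of a population-scale structural
variant (SV) study in a unicellular eukaryote such as fission yeast:
benchmark SV callers on simulated genomes, merge their outputs into a
high-specificity consensus callset, genotype copy-number variants (CNVs)
from windowed read depth, quantify how quickly CNVs churn inside
near-clonal populations, and relate SV and SNP divergence between strains
to the viability of their hybrid offspring. This vignette explains the
models and decision rules, the tunable parameters, what the synthetic-data
generators do and do not emulate, and the numerical choices made where the
design was genuinely open.

## Coordinates and data model

All internal coordinates are 1-based inclusive, the VCF convention, because
variant positions are reported and compared in that form. BED input/output
(truth files, annotation intervals) is 0-based half-open on disk and
converted at the boundary, so round trips are exact. SV length is
`end - start + 1` for deletions, duplications and inversions; an
insertion's length is the length of the inserted sequence.

Five SV types form a closed set: `DEL`, `DUP`, `INS`, `INV`, `TRA`. A
translocation is modelled as a single two-locus record (`chrom`/`start`
plus `chrom2`/`pos2`), the DELLY-style encoding; on VCF output it can also
be written as a reciprocal breakend (BND) mate pair, and both dialects are
accepted on input. A single canonical internal form was chosen because
callers disagree on which breakend is "first", and the unordered-pair
comparison in the match predicate removes the remaining ambiguity.

Missing paired-end support is stored as `NA`, never as zero: the support
filter must distinguish "no evidence recorded" from "zero supporting
pairs", and it drops both, but reports the unknown ones separately.

## Simulating genomes with known SVs

`plan_svs()` places the requested number of events of each type uniformly
on the reference, with lengths uniform within per-type ranges. Placement
rejects positions within `min_gap_bp` (default 1000 bp) of a chromosome
end, of another event, or overlapping a run of `N` bases, retrying each
event up to 1000 times before failing loudly — silent partial plans would
corrupt downstream sensitivity estimates. Truth coordinates are always
*reference* coordinates, which is what a truth-versus-calls comparison
needs; the altered genome is a separate artifact.

`apply_svs()` edits the sequence: deletions excise, insertions add,
duplications are tandem (`copies - 1` extra copies immediately after the
source segment — tandem is the arrangement consistent with the read-depth
signature the CNV caller detects), inversions reverse-complement in place,
and a translocation reciprocally exchanges the chromosome tails downstream
of its two junctions. Non-translocation events are applied per chromosome
in decreasing coordinate order so earlier reference coordinates stay
valid; translocation junctions are then shifted by the net length change
upstream before the tail swap. Per-chromosome length accounting is exact
and tested: `len(out) = len(ref) - sum(DEL) + sum(INS) + sum((copies-1) *
len(DUP))`, with inversions neutral and translocations conserving total
genome length.

Background point variation defaults to a substitution rate of 0.1% per bp
— the density of segregating sites between divergent fission-yeast strains
— with small indels (1–10 bp) an order of magnitude rarer, a typical
SNP:indel ratio for yeast. Sequencing *error* is deliberately out of
scope: it belongs to read simulation, downstream of this toolkit. The
`spec_benchmark_mix()` preset draws a total SV count uniformly in 30–170 (the
range used in the simulated benchmark datasets) and splits it
141:112:26:36 across DEL:DUP:INV:TRA, the composition of the real
consensus callset.

## Benchmarking callsets

A call matches a truth record iff it has the same type, the same
chromosome(s), and both breakpoints within `tolerance_bp` (default 1 kb; 2
kb is conventional for window-based CNV callers whose resolution is
coarser). Translocation locus pairs are compared unordered. Counting is
many-to-many: a truth record is detected if *any* call matches it; a call
is a false positive if it matches *nothing*. No one-to-one assignment is
attempted — the match predicate alone defines the benchmark, and set-level
counting makes sensitivity non-decreasing and FDR non-increasing in the
tolerance, which the tests verify. Duplicate calls of one truth event are
therefore not false positives at this stage; collapsing duplicates is the
consensus module's job.

## Consensus merging and filtering

Within one caller's output, calls of the same type whose start and end
both lie within 1 kb are single-linkage clustered and collapsed to one
representative. Across callers the same predicate clusters the pooled
calls, and a cluster is kept only if at least `min_callers = 2` *distinct*
callers contributed — two calls from one caller never constitute a vote.
Single linkage is the transitive closure of the pairwise rule; a chain of
calls can therefore span more than the tolerance end-to-end, a documented
caveat of defining only a pairwise predicate.

The consensus coordinate is the member median, floored to an integer (for
two members, their midpoint). A median is order-independent and robust to
one outlying member, and the resulting boundary always lies within
tolerance of at least one input call — the pipeline fabricates no loci.
Representative paired-end support is the member maximum.

Post-consensus filters run in a fixed order, each logging in/out counts:
calls with paired-end support of 10 or fewer are discarded
(`min_support = 11`); calls with either breakpoint in a low
mapping-quality region (where reads map with MQ=0) are discarded; calls
with *both* breakpoints inside annotated retrotransposon LTRs are
discarded (one LTR breakpoint is tolerated — requiring both distinguishes
repeat-mediated artefacts from genuine variants that happen to abut a
repeat).

## CNV allele calling from windowed coverage

Candidate CNV regions are genotyped per strain by comparing read counts in
100-bp windows against *two* reference strains. The allele is a
duplication only if, for each reference independently, (i) the one-sided
Wilcoxon rank-sum test of alternate versus reference window counts gives
`P < 1e-10` and (ii) the ratio of alternate to reference mean coverage
exceeds 1.8; deletions analogously with direction "less" and ratio below
0.2; anything else is the reference allele. The direction of the one-sided
test follows the candidate class — the only reading consistent with a
one-sided test guarding a two-sided-looking ratio gate. The
both-references conjunction is strict: failing either reference yields
`REF`. Windows straddling the region boundary are excluded to avoid
diluting the signal, and a region with fewer than two interior windows, or
a reference with zero mean coverage, is flagged uncallable rather than
called.

Ratios use window *means* (matching the location-shift alternative of the
rank-sum test); the reported copy number is the *median* across windows of
`alt / mean(refs)` on a haploid baseline of 1, because the median
stabilises the estimate against isolated window artefacts. The exact
estimator behind the published copy numbers was not specified; this
median-ratio form is this package's choice.

P values below 30 windows per group come from exact enumeration of the
rank-sum null distribution via a dynamic program over doubled average
ranks (a shift-algorithm; exact under ties, feasible to 29+29). From 30
windows the tie- and continuity-corrected normal approximation takes over;
near that handoff the two agree within 0.01, which the acceptance tests
measure. A CNV *segregates* within a near-clonal cluster when at least two
distinct callable alleles occur among its members.

## Transience of CNVs within clonal clusters

For each CNV the package builds two per-locus trees over strains: a
flank-SNP tree from all SNPs within 20 kb upstream and downstream of the
region (a window wide enough to carry local genealogical signal but
narrow enough to stay local), and a copy-number tree from Euclidean
distances between strains' copy numbers at that CNV. Both use
neighbour joining. SNP distances are normalized Hamming distances over
shared non-missing sites; an approximate-maximum-likelihood builder could
be substituted via newick import, but branch-length *totals*, not
topologies, drive the analysis, so the self-contained NJ route is the
default.

Neighbour joining delegates to the standard Saitou–Nei implementation;
negative branch lengths (possible for non-additive inputs) are clamped to
zero with the deficit transferred to the sister edge, preserving the total
branch length. NJ recovers additive matrices exactly, which the tests
check against path-length oracles on random trees. Ties are broken
deterministically by index order, so tree length is invariant to strain
input order.

The relative transience of a CNV in a cluster is
`sigma_rc = sigma_ic / sigma_oc`, the ratio of the within-cluster standard
deviation of its copy number to the standard deviation across all strains
outside the cluster. Sample (n-1) standard deviations are used throughout
(the denominator convention was unspecified; the sample form is the
unbiased default). `sigma_oc = 0` yields a flagged missing value, never
infinity, and such rows are excluded from summaries. The statistic is
scale-invariant, and a fixed CNV has `sigma_rc = 0` — both property-tested.
The dataset-wide association between per-CNV copy-number SD and
copy-number tree length is summarised by Spearman rank correlation over
all genotyped strains per CNV.

## Distances, viability and partial correlations

Pairwise SV distance between two strains counts SVs at which both are
genotyped and differ. CNVs are first collapsed when their reciprocal
overlap exceeds 50% — both overlap fractions must exceed the threshold,
the symmetric reading of ">50% overlap" — *and* their per-strain allele
vectors are identical, so one event reported twice is counted once.

All Kendall correlations are tau-b (tie-corrected): distances are heavily
tied counts, for which the uncorrected tau-a understates association. The
partial correlation of x and y given z is computed on the tau scale,
`(t_xy - t_xz t_yz) / sqrt((1 - t_xz^2)(1 - t_yz^2))`, with a P value from
the standard normal approximation for tau applied to the partial
coefficient (Kim's approximation); for n <= 8 the plain tau P value is an
exact permutation enumeration instead, valid under ties. A control
correlation of +/-1 degenerates the formula and is flagged undefined.
Linkage between an SV and a SNP is the squared Pearson correlation of
their 0/1 genotype vectors over co-genotyped strains, with a scan helper
reporting each SV's best-tagging SNP.

## What the generators emulate — and what they do not

The fixture generators give every module a download-free, seed-
deterministic test surface with known ground truth:

* `random_genome()` draws IID bases at 36% GC (the fission-yeast nuclear
  genome's composition). Real genomes have repeats, LTRs and composition
  heterogeneity; none of that is emulated, so tests passing here say
  nothing about repeat-mediated miscalling.
* `mock_caller()` reduces a caller's error structure to three parameters —
  detection probability, breakpoint jitter (rounded Gaussian truncated at
  3 SD, so jittered calls stay inside a 1-kb tolerance whenever
  `jitter_sd <= 300`, mirroring the observation that real consensus
  members sit within ~300 nt of the boundary), and uniformly placed false
  positives kept 1 kb clear of truth. Real callers have correlated,
  type- and size-dependent errors; consensus results on mock callers are
  closed-form checks, not caller benchmarks.
* `synth_coverage()` draws window counts Poisson with mean
  `depth x copy number` (default depth 40, i.e. 40x coverage in 100-bp
  windows), with a negative-binomial option for over-dispersion. Default
  Poisson keeps the closed forms exact.
* `synth_clonal_population()` builds clusters whose members differ by at
  most 150 SNPs (the near-clonal criterion) by construction, and flips
  CNV states along the pedigree at a configurable rate, producing
  segregating CNVs.
* `synth_viability_crosses()` plants independent SNP and rearrangement
  effects on offspring viability with an uninformative CNV distance — the
  structure the partial-correlation battery should recover. Its default
  panel size of 58 crosses matches a realistic viability panel.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at deliberately modest
sizes chosen to give stable statistics on a single CPU: a 2-Mb,
3-chromosome genome with 60 SVs for round trips; 500 truth events for the
two-of-three consensus closed form (Monte-Carlo SD ~0.014); 100 replicate
seeds for the false-positive-suppression and partial-correlation rates;
100 random 4–8 taxon trees for NJ recovery; 60-window regions at depth 40
for the CNV decision rule. Retry caps (1000), the exact/approximate
rank-sum handoff (30 windows per group), the enumeration-free Kendall P
cutoff (n > 8) and the clamping rule for negative NJ branches are all
fixed constants documented above, not tuning knobs.

## Known limitations

* Read-level evidence (BAM parsing, split reads, insert sizes) is out of
  scope; paired-end support is consumed as an annotation, not computed.
* The consensus chain caveat: single-linkage clusters can exceed the
  pairwise tolerance end-to-end.
* `sigma_rc` compares one cluster against the rest of the population; it
  does not model shared ancestry among clusters.
* The partial-tau P value is asymptotic; for very small cross panels it
  should be read qualitatively.
* Mock callers do not emulate caller-specific biases beyond the
  three-parameter profile, and the simulator does not generate reads.
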