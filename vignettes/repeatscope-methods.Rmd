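---
title: "Validating T2T assemblies and dissecting repeat architecture with repeatscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating T2T assemblies and dissecting repeat architecture with repeatscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Telomere-to-telomere (T2T) assemblies expose the parts of a genome that
draft assemblies used to hide: megabase satellite arrays, ribosomal DNA
(rDNA) arrays with thousands of near-identical copies, centromeres, and
telomere/subtelomere transitions. Quality control and repeat dissection of
such assemblies rest on a family of small, bespoke procedures — k-mer
based consensus accuracy, long-read artifact triage, sliding-window array
calling, monomer variant analysis, rDNA genotyping, landmark calling.
`repeatscope` implements these procedures as tested, reusable functions,
and pairs them with a synthetic miniature-genome generator that plants
every feature with known truth, so each caller can be scored against an
exact answer. This vignette explains the models and procedures, the
parameters that matter, and the design decisions taken where the
methodology is conventionally left informal.

## The synthetic study conditions

`standard_genome_config()` defines the reference conditions used by the
test suite and the analysis scripts:

* a 5 Mb chromosome with 3,700-copy telomeres at both ends (25.9 kb of
  TTTAGGG repeats, the scale seen in complete plant assemblies), a
  two-family subtelomeric block stack inside the left telomere (629 bp
  and 532 bp units, base ratio ≈ 71:1), knob180- (180 bp), TR-1- (360 bp)
  and CentC-like (156 bp) satellite arrays with a per-copy substitution
  rate of 0.02, and a 2 Mb centromere spanning two large CentC arrays
  separated by 214 kb;
* a 1 Mb chromosome carrying a 200-copy rDNA-like array (500 bp unit)
  with a 70/30 two-haplotype mixture over three SNPs and one 6 bp
  deletion, a 20-copy inversion block, and three TE insertions;
* a 0.30 transposable-element background drawn from a small pool of
  synthetic LTR-like motifs (3–5 motifs of 0.4–2.5 kb), not a curated TE
  library.

Every planted feature is emitted to a truth table (BED-compatible,
0-based half-open), and the rDNA array additionally returns the gapped
per-copy alignment it was built from. Construction is fully determined by
`(config, seed)`; one seeded generator is used per operation, and the
global RNG state of the session is never touched.

What the generator deliberately does **not** emulate: realistic nanopore
error profiles (reads are exact copies of the genome, artifacts aside),
heterozygosity, nested TE structure, and alignment noise — the
exact-origin alignment records produced by `alignments_from_truth()` are
what a perfect aligner would report. Recovery rates near 100% on these
conditions therefore demonstrate the correctness of the decision rules,
not robustness to noisy mapping; on real data the alignment step is the
dominant additional source of error.

## Mapped k-mer accuracy (QV)

Every k-mer instance of the assembly is looked up in a read-derived
database of canonical k-mers (`k = 21` by convention; canonical = the
lexicographic minimum of a k-mer and its reverse complement). With $T$
total assembly k-mers of which $E$ are absent from the read set, the
per-base error probability is estimated as

$$ p = 1 - \left(1 - \frac{E}{T}\right)^{1/k}, \qquad
   \mathrm{QV} = -10\log_{10} p, \qquad
   \mathrm{accuracy} = 100 - 100\cdot 10^{-\mathrm{QV}/10}. $$

Two choices are load-bearing. First, $E$ and $T$ count k-mer *instances*
(with multiplicity), not distinct k-mers — that is the convention under
which $T$ approximates the genome length and the published worked
examples of this estimator are arithmetically consistent. Second, the
logarithm is base 10; `qv_from_counts(2676840, 2178604120, 21)` then
returns QV 42.3252 and accuracy 99.9941%. `E = 0` returns an infinite QV
sentinel with accuracy 100.

A caveat the package makes measurable: substitutions inside large,
internally similar satellite arrays can produce 21-mers that already
exist elsewhere in the array, deflating $E$. `qv_genome_config()`
(1 Mb, 5% satellite content) is the condition under which a planted
$10^{-4}$ substitution rate is recovered within a few percent; on the
satellite-heavy 5 Mb chromosome the same estimator is biased upward in
QV, which is a property of the method, not a bug of the implementation.

k-mer completeness is the fraction of distinct *reliable* read k-mers
(count ≥ `min_read_count`, default 2, suppressing singleton read errors)
present in the assembly database. The reliability cutoff is not part of
the published formulas; 2 is the smallest value that removes singleton
noise.

## Read-artifact classification and coverage anomalies

Alignment records are filtered to primary and supplementary alignments
(SAM flags 0, 16, 2048, 2064 — secondary alignments are always dropped)
and a read is retained only if the union of its query intervals covers at
least 0.85 of the read. Union coverage counts each read base once even
when alignments overlap on the read. Retained reads are then classified:

* **proper** — all records in one genomic neighborhood. "Neighborhood"
  is implemented as a single target sequence with target-interval gaps
  ≤ 100 kb; the quantity is conventionally left unspecified, and 100 kb
  tolerates split alignments across mid-size insertions while still
  separating genuinely distant origins (the read simulator places fused
  origins ≥ 500 kb apart).
* **symmetrical** — the read splits into two parts that are reverse
  complements of each other (identity ≥ 0.95 over the shorter half,
  verified on the sequence, not just the alignment geometry) and both
  parts align to the same region.
* **fused** — coverage passes but records land in two or more distant
  regions.
* **unmapped_or_other** — everything else; chimeric reads with junk
  halves land here because their genomic half covers only ~0.5 of the
  read. No attempt is made to sub-classify residual reads (e.g.
  organelle origins).

Classification order is symmetrical → proper → fused, since a
symmetrical read also satisfies the one-chromosome test.

Depth is per-base coverage by retained target intervals, averaged in
1 kb bins (terminal partial bins averaged over their actual length).
Anomalies use strict thresholds — depth *below* `low` is a low-coverage
region (LCR), *above* `high` a high-coverage region (HCR); a bin exactly
at a threshold is normal — with adjacent same-kind bins merged. The
profile presets are (100, 250) for the ultralong-ONT depth regime and
(20, 105) for HiFi.

## Satellite, TE-array and segmental-duplication calling

Satellite hit density is computed in 100 kb windows stepped every 10 kb
as the covered-base fraction of the window (not a hit count — "fraction
of the window that is this satellite" is the quantity the >10% rule is
stated in). Windows strictly above 0.10 are selected, overlapping
selected windows merged, and each merged interval trimmed inward to the
outermost hit it contains, which makes final boundaries hit-level rather
than window-level: a planted block ≥ 20 kb is recovered exactly. Two
blocks closer than roughly 170 kb are bridged by shared windows and merge
into one array — inherent resolution of the window rule, documented
rather than patched. Family assignment of hits is an input (the homology
search that produces them is out of scope).

TE arrays use the same windowing restricted to intergenic intervals, a
strict 0.95 TE-fraction threshold, discard of any merged array containing
a gene, and a reporting length filter (`min_length = 0` in the library;
700 kb is the genome-survey convention).

Tandem-repeat tables (TRF `.dat` dialect) are classified by unit length —
< 10 bp microsatellite, 10–100 bp inclusive minisatellite, > 100 bp
satellite — after dropping records with fewer than 5 copies. The
redundancy removal that is conventionally manual is automated as: among
records with > 50% reciprocal overlap keep the highest score, ties broken
by longer interval then leftmost.

Segmental duplications keep alignment pairs with identity strictly over
0.99 and length strictly over 1,000 bp, project both sides to intervals,
and merge overlapping and book-ended intervals. Survey summaries of the
same analysis sometimes quote a 98% identity convention; 0.99 is the
default here and the parameter is exposed.

## Higher-order repeat (HOR) analysis

A position probability matrix (PPM) over `{A, C, G, T, -}` is tallied per
alignment column, excluding N from numerator and denominator. The
*variant distance* of a monomer is the sum over columns of one minus the
PPM frequency of its symbol (N contributes zero).

The *pairwise variant score* between two monomers is deliberately simple:
the count of alignment columns at which they differ, with the gap treated
as a fifth symbol and columns where either is N skipped. A PPM-weighted
variant (`method = "ppm"`: each disagreeing column contributes the mean
disagreeing probability of the two symbols) is provided for comparison,
but the plain count is the default because the grouping threshold ("score
of 5 or less") reads naturally as a column count.

Groups are *neighborhoods*, not linkage clusters: for each monomer, the
set of monomers within the threshold of it (plus itself); deduplicated
neighborhoods with ≥ 2 members are the HOR groups. This is the only
construction consistent with one monomer belonging to several groups —
any partitioning linkage would forbid that. Only full-length monomers
should enter the alignment; fragment filtering is the caller's
responsibility, and running the MSA itself (e.g. MAFFT) is out of scope —
the functions consume an aligned FASTA.

## rDNA genotyping and orientation

Variant sites across aligned rDNA copies are substitution columns and gap
runs; a site is kept only when its minor allele is carried by strictly
more than 10% of copies. Gap runs are keyed by exact column span
(start, length) — partially overlapping runs are distinct alleles, the
most conservative reading since no indel normalization is specified in
this setting. `long_indel` mode restricts to runs strictly longer than
5 bp and is intended for the 45S-style analysis confined (via
`region_mask`) to the intergenic spacer; the mask accepts any column set,
so it covers both the full-unit and IGS-only readings of that analysis.

A copy's genotype is its allele tuple across selected sites; genotypes
are labeled type 1, type 2, … by descending frequency with ties broken by
canonical allele-tuple order, making labels invariant under permutation
of the input copies.

Orientation profiling reports per-strand fractions and inversion blocks
as maximal runs of at least `min_run = 3` consecutive minority-strand
copies. The threshold exists only to keep single mis-oriented copies from
being reported as inversions; any planted block of meaningful size (the
standard conditions use 20 copies) is far above it.

## Landmarks: telomeres, subtelomeres, centromeres

**Telomeres.** From each terminus the caller chains tandem motif matches
(TTTAGGG at the right end, its reverse complement CCCTAAA at the left, so
the G-rich strand runs off the end), tolerating interruptions up to 50 bp
and requiring ≥ 10 copies. A qualifying run of the wrong-strand motif is
still called with `orientation_ok = FALSE`, because strand orientation of
terminal repeats is itself a biological observable worth reporting. The
50 bp / 10-copy defaults are this package's own calibration — no formal
telomere-calling rule exists in the source methodology, which reports
lengths and orientation only; the planted 3,700-copy telomeres are
recovered within ±1 copy (chance motif matches adjacent to the run can
add one).

**Subtelomeres.** Anchored at the inner telomere edge, the call grows
inward over 10 kb windows with hit density ≥ 0.30, tolerating
sub-threshold stretches up to 50 kb (this absorbs the interrupted
telomere–subtelomere configuration seen on some chromosome arms), then
trims to the outermost hits. Per-family covered fractions and the
first-to-second family base ratio are reported. These parameters replace
a "visual inspection" step and are exposed for exactly that reason.

**Centromeres.** Bins of a CENH3 enrichment track strictly above 5 are
retained, retained bins closer than 1 Mb are merged, and merged intervals
shorter than 100 kb are dropped — the length filter again standing in for
manual end-point inspection. Composition typing intersects calls with
repeat annotations: CentC-rich means CentC-array coverage ≥ 0.50 of the
call, else CentC-poor (satellite-free centromeres type as poor with zero
CentC). Producing the enrichment track (ChIP–seq alignment and ratio
computation) is an input contract, emulated by
`simulate_enrichment_track()` as two Gaussian levels truncated at zero.

## Numerical conventions and degenerate inputs

* Coordinates are 0-based half-open everywhere internally (BED
  convention); 1-based closed appears only inside IRanges calls.
* All thresholds stated as "more than" / "lower than" are strict
  inequalities, and the boundary cases are tested (a bin exactly at 100
  is not an LCR; identity exactly 0.99 is not a segmental duplication; a
  100 bp unit is a minisatellite).
* Empty inputs return empty, correctly typed tables rather than errors,
  except where the operation is undefined (QV with `T = 0`, PPM with
  fewer than 2 rows, completeness with an empty reliable set).
* `E = 0` QV returns `Inf`; downstream consumers treat it as a sentinel.

## Problem sizes and runtime

The shipped conditions are sized so the full test suite runs in about two
minutes: 5 Mb + 1 Mb genome, 1,000 simulated reads, 21-mer databases over
1 Mb, 200 monomers and 200 rDNA copies. These sizes are large enough that
every statistical check (binomial recovery of mixtures and artifact
rates, Poisson depth fluctuation) has power, and small enough to iterate
on. The k-mer module holds databases in memory and is not intended for
genomes beyond ~100 Mb; disk-backed counting is explicitly out of scope.

## Known limitations

* Recovery rates on the synthetic conditions bound correctness of the
  decision rules, not performance on noisy alignments (see above).
* The satellite window rule cannot separate arrays closer than ~170 kb.
* HOR grouping is quadratic in monomer count; it is meant for per-family
  full-length monomer sets (hundreds to low thousands).
* The chimeric/organelle sub-classification of residual reads and the
  decomposition of undetected k-mers into error sources have no stated
  procedures in the source methodology and are not implemented.
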