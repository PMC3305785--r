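---
title: "Methods: a genome-wide census of retrotransposon-associated minisatellites"
author: "rtms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a genome-wide census of retrotransposon-associated minisatellites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtms)
```

## The problem

Some plant LTR retrotransposons carry a polymorphic minisatellite (MS)
region between the 3' end of their coding sequence and the downstream long
terminal repeat.  In soybean, the high-copy Ty3-gypsy family Gmr9/GmOgre
hosts five distinct monomer families (labelled A-E, 26/38/37/105/43 bp)
that are tandemly *interleaved* -- the repeating unit of an array is a short
word over the monomer alphabet, such as `[ABAC]n` or `[ABC]n`, rather than a
single monomer.  Cataloguing every copy of these monomers in a genome,
organizing copies into loci, attributing loci to elements, and describing
the array grammar and its sequence variation is the job of this package.

`rtms` implements the census pipeline end to end: approximate monomer
scanning, cross-family deduplication, locus clustering, element
attribution, tandem-array decomposition, variant profiling, census tables
and windowed density tracks -- plus a synthetic-genome generator with full
ground truth so that every stage can be validated without any external
download.

## Containers and coordinates

Genomes and monomer sets are `DNAStringSet` objects (monomers wrapped in
the validated `MotifSet` class); hits, loci, annotations and simulation
truth are `GRanges` with documented metadata columns.  All in-memory
coordinates are therefore 1-based and closed, the native GRanges
convention.  File-format conventions are handled strictly at the boundary:
BED's 0-based half-open intervals and the BLAST-tabular subject-strand
encoding (`sstart > send` on the minus strand) are converted on read and
write, and GFF3 round-trips its 1-based closed coordinates unchanged.

## The scan model

A hit is a semi-global alignment of a full monomer consensus (length $L$)
against a genomic window: the whole consensus must be consumed, while the
window's ends are free.  With $e$ the minimal number of substitutions plus
indels for the best such alignment we define

$$\mathrm{identity} = 1 - e/L ,$$

so a 26-bp monomer tolerates at most two edits at the default census
threshold of 0.90.  This form is unambiguous across co-optimal alignments
(alignment-column counts are not), agrees with the substitution-only worked
examples exactly, and counts indels against identity as BLAST-style
pipelines do.  Window lengths are confined to $[L(1-b), L(1+b)]$ with band
$b = 0.10$ by default; note that at the default threshold the edit budget
already implies the band, since every net indel costs one edit.

The scanner is a banded dynamic program written in C++ (one column per
genome position, one row per consensus position).  For each end position it
keeps the minimal cost and, among co-optimal alignments, the shortest
window; the (cost, start) pair is optimized lexicographically cell by cell,
which is exact because every prefix of an optimal path is optimal.  Minus
strand hits come from scanning the reverse-complemented consensus and are
reported in plus-strand coordinates.  `N` bases mismatch every consensus
base, so assembly gaps can never seed hits.  Overlapping same-family
candidates are reduced to local maxima (highest identity, tie leftmost, tie
longest, tie plus strand); the test suite checks the scanner against an
independent vectorized DP oracle, exactly, hit for hit.

One consequence of positional tie-breaking is worth stating: hits with
$e = 0$ mirror exactly under reverse complementation of the genome, while a
mutated hit may mirror with a window shift of up to $e$ bases, because
co-optimal windows are resolved from opposite directions.

## Unique hits, loci, attribution

Monomer families can share sub-repeats (the packaged synthetic B and C
share nine of their last eleven bases, mirroring the biological situation),
so cross-family matches at one locus must be resolved.  Two hits conflict
when they overlap by more than half the shorter hit; conflicts resolve by
identity, then length, then lexicographic family label, making the unique
hit set independent of input order.

Unique hits are clustered into discrete loci by a single linear pass per
chromosome: a gap of more than `max_gap_locus` (default 250 bp) between
consecutive hits starts a new locus.  The default sits above the ~100-bp
breaks observed inside real arrays and far below typical inter-element
spacing; per-family clustering (for per-repeat locus counts in the census
table) uses the same gap.

A locus is attributed to an annotated element when at least half its span
(configurable, up to strict containment) lies inside one annotation; the
largest overlap wins ties.  Loci outside annotations are compared -- with
1000 bp of flanking context -- against one exemplar sequence per element
family using local alignment under BLAST-like scoring (match +1, mismatch
-2, gap open 5, extend 2).  The stringent mismatch and gap costs matter:
under a weak scheme (+1/-1, linear gaps) the optimal local alignment chains
through non-homologous sequence and its column identity becomes
meaningless.  A locus is `similarity_assigned` when some exemplar aligns at
>= 80% identity over >= 400 columns; otherwise it stays `unknown_repeat`.
Every locus receives exactly one of the three statuses.

## Array decomposition

Each locus's ordered monomer labels form a string over the family alphabet.
The decomposition first splits the string at junction gaps larger than
`max_gap_tandem` (default 10 bp -- the operational meaning of "unbroken",
against the ~100-bp breaks), then repeatedly extracts the maximal-cover
tandem run (largest `count x unit_length`, ties to the smaller unit, then
the leftmost start) and recurses on both sides; monomers belonging to no
run accumulate into remainder segments.

A plain left-to-right greedy scan was considered and rejected: it provably
misses the maximal run when a short run prefix overlaps a longer,
later-starting run (label string `ABABCABCABC` is a minimal counterexample
-- greedy consumes `AB AB` and finds `[CAB]x2`, while the maximal run is
`[ABC]x3`).  The maximal-run-first recursion matches an exhaustive search
over all unit lengths and phases on every tested input, and its segments
always reconstruct the input string exactly.

Units are reported both as they occur (phase matters when comparing arrays:
`[ABAC]`, `[ABC]` and `[ACB]` are distinct patterns) and as their
lexicographically smallest rotation for phase-independent grouping.  Note
that a minus-strand array reads as the *reversal* of its unit along the
plus strand, which for odd unit lengths is a different canonical rotation.
Genomic spans (`end - start + 1`) include internal spacers, so a reported
array span can exceed `count x unit bp`.

## Census tables, variants, densities

The census table has one row per element family: intact annotated copies,
per-monomer-family hit and locus counts restricted to that family's
attributed loci, and similarity-assigned "additional" loci, with `Others`
and `Unknown` rows and a recomputed `Total` row.  The published census can
be supplied in the same TSV layout (the package bundles it under
`inst/extdata/`), so its internal arithmetic -- column totals, the
hits-per-element ratios, the outside-elements balance and the headline
percentages -- is recomputed rather than quoted.

Variant profiles tabulate, per family, the edit distance from consensus and
the observed length of every unique hit; `frac_identical` is the mass at
zero edits.  Density tracks count unique hits (by start position) and
elements per fixed half-open window, the latter either as midpoints
(default) or as covered bp per window; both rank and linear correlations of
the two tracks are reported.  At desk scale the coverage mode is the robust
choice for the correlation: with tens rather than thousands of elements, a
single element straddling a window boundary moves its midpoint away from
the window holding its array and visibly distorts the rank statistic.

## The synthetic genome generator

The generator is first-class, tested code, and its defaults are the study
conditions used throughout the test suite: two chromosomes of 250 kb,
eight copies of one element family (a shared 4-kb random body followed by
its minisatellite array, mirroring an element carrying the MS region
downstream of its coding sequence), array patterns `[ABAC]x8` /
`[ABC]x6` / `[ACB]x4` weighted 0.60/0.25/0.15, two orphan arrays flanked by
600 bp of 10%-diverged element sequence, two orphan arrays in plain
background, per-base substitution rate 0.01 and indel rate 0.001 inside
monomers (at most two indel events per monomer, keeping edit accounting
interpretable), 30% minus-strand arrays, and >= 1 kb spacing between
planted features.  Each element also carries the downstream structure seen
in real elements: a ~120-bp gap, one D and one E monomer, a ~100-bp break
and a second E monomer.  Larger or noisier designs used by specific checks
(for example 12 elements of `[ABAC]x10` for variant calibration, or 16
elements over two 500-kb chromosomes for the density correlation) are
stated where they are used.

The background is i.i.d. uniform DNA.  That means the generator emulates
monomer mutation, array interleaving, strand, element embedding and orphan
loci -- but not base composition bias, nested insertions, segmental
duplications or the sheer repeat density of a real pericentromere.  Passing
tests therefore demonstrate algorithmic correctness and calibration under
the stated noise model, not performance on a real assembly.

Ground truth records every element, array and monomer (with its true edit
count), so precision and recall are measurable at each stage.  A detected
hit matches a truth monomer at equal label and >= 50% reciprocal overlap; a
locus matches a truth array when it covers >= 50% of the truth span
(one-sided, because loci legitimately extend over the downstream D-E
monomers bookkept outside the array record).  Generation is deterministic
given the spec's seed and leaves the caller's RNG state untouched.

With all mutation rates at zero the pipeline census equals the planted
census exactly -- every monomer at identity 1.0 and exact coordinates, one
locus per planted array, correct statuses, units and counts.  At
substitution rate $r$ the fraction of copies identical to consensus has
closed form $(1-r)^L$, and the observed fraction matches within three
binomial standard errors; recall degrades to zero as $r$ pushes expected
identity below the scan threshold.

## Numerical and degenerate-input choices

* Thresholds are exclusive where the contract says "exceeds" (a gap of
  exactly 250 bp joins a locus; 251 splits) and inclusive where it says
  "at least" (identity 0.90, containment 0.5, span 400).
* Rounding of repeats-per-element ratios is `round(x, 1)` to match printed
  precision.
* Zero-variance density tracks yield `NA` correlations, not errors; empty
  hit sets propagate as empty objects through every stage.
* Monomers shorter than 10 bp are refused by the scanner (the identity
  model is meaningless there); empty exemplar libraries and unsorted hit
  input are usage errors rather than silent fixes.
* The packaged monomer set is synthetic (clearly labelled so in its file
  name): five random sequences with the field-typical lengths, B and C
  sharing 9 of their last 11 bp to exercise the cross-family path.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data:
oracle equivalence uses 50 random 20-50-kb genomes and 500 random label
strings; recovery and calibration use the generator designs above (up to
two 500-kb chromosomes).  These sizes were chosen so the full validation
remains a desk-scale computation while every statistical check retains
enough copies (>= 100 monomers per family) for its stated tolerance.

## Known limitations

* The scanner is exact but quadratic per motif (O(L x genome)); it is
  intended for desk-scale genomes and planted validation, not for
  chromosome-scale production scans, where a seeded search feeding
  `readHitTable()` is the intended route.
* Similarity assignment uses one exemplar per family, not every annotated
  copy of the family elsewhere in the genome; divergent family members can
  therefore be missed at the 80%/400-bp rule.
* Array decomposition operates on monomer labels only; monomer-internal
  variation does not influence unit inference.
* The generator plants one element family; multi-family annotation tables
  are exercised through the bundled published census instead.
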