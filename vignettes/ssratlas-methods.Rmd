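---
title: "Methods: mining and annotating a gene-centered microsatellite atlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining and annotating a gene-centered microsatellite atlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssratlas)
```

## The problem

Microsatellites (simple sequence repeats, SSRs) are tandem arrays of short
motifs whose unit-count variation makes them cheap, codominant molecular
markers. For marker-assisted selection one wants more than coordinates: a
marker is most useful when it sits in or near a gene, when its genomic
context (exon, splice junction, intron, intergenic) is known — intronic
markers tend to be more polymorphic than exonic ones, and junction-spanning
primers risk amplification failure — when it is anchored to a linkage
group, and when a reliable primer pair exists. `ssratlas` builds exactly
that catalog from a genome FASTA, a GFF3 annotation, a scaffold-to-linkage
group map, and (optionally) a protein-alignment hit table for candidate-gene
nomination.

## Repeat detection

`find_repeats()` reports every *perfect maximal* repeat run with

* motif length (period) 2–6,
* total array size ≥ 12 bases (inclusive; size-11 arrays are rejected),
* at least 2 repeat units (the exponent `size / period` may be fractional,
  e.g. `(GATC)3.25` for a 13-base array),

subject to two structural rules:

* **Primitive period.** A run is reported once, at the smallest period
  under which it is perfectly periodic. A `(AT)6` array also satisfies the
  period-4 equality but is a dinucleotide repeat, not a tetranucleotide
  one. Homopolymers (primitive period 1) satisfy the period-2 equality too
  and are excluded by default — mononucleotide arrays are not treated as
  markers — but `scan_params(exclude_homopolymers = FALSE)` reports them
  at period 1 for surveys that want them.
* **Run integrity.** Runs never cross `N` or any other ambiguity code; the
  sequence is segmented at non-ACGT characters before scanning, because a
  "perfect" repeat requires exact base equality. Soft-masking (lowercase)
  is recorded on input but deliberately ignored by the scanner: the whole
  assembly is scanned, and only primer design consults masking — which it
  computes itself.

Overlapping runs of *different* primitive periods are all reported; only
same-period redundancy is collapsed (a maximal run is unique for its
period). Output order is (scaffold, start, period), so results are
deterministic and independent of scan order.

Some genome-scale repeat miners additionally prune "statistically
insignificant" repeats with a model-based filter. We do not: with a
12-base size floor the effect is marginal, the filter is hard to specify
exactly, and omitting it keeps the scanner's contract simple enough to be
verified against an independent oracle (below).

### The reference oracle

`oracle_find_repeats()` implements the same contract a second time, as an
explicit position-by-position extension loop, sharing no scanning code
with the vectorized production path. The test suite asserts exact
equality of the two on 1,000+ random sequences (lengths 100–10,000,
GC 10–80%, with and without ambiguity codes). The same oracle certifies
synthetic backgrounds repeat-free, which is what makes "recall and
precision = 100%" a meaningful end-to-end statement rather than a
tautology of one implementation against itself.

## Motif classes

Two motifs name the same repeat if one is a circular permutation of the
other or of its reverse complement — the same array read in a different
phase or from the other strand. `canonical_motif()` closes a motif under
both operations; the class representative is the lexicographically
smallest member under A < C < G < T, and the printed label lists the
rotations of the representative followed by their reverse complements
(e.g. `AG/GA/CT/TC`, `ACG/CGA/GAC/CGT/TCG/GTC`). This yields the
classical class counts 4, 10, 33, 102 and 350 for motif lengths 2–6; the
di- and trinucleotide counts are fixed points of the field's conventions,
the k ≥ 4 counts are frozen as regression values from exhaustive
enumeration.

Primitivity here is *cyclic*: a motif is rejected only when it is a
proper power (`ATAT`), not when it merely has a shorter string period
(`ATGCAT` has string period 4 but is a perfectly good hexanucleotide
motif). The scanner guarantees observed motifs are primitive in this
sense, so reduction never happens silently inside the class algebra.

## Genomic context

`classify_locations()` assigns each repeat exactly one category with
priority **exon > exon_intron > intron > intergenic**:

* *exon* — entirely within a single exon (or CDS segment, see below) of
  any transcript of a containing gene;
* *exon_intron* — inside some transcript and overlapping both exonic and
  intronic sequence (a splice-junction repeat);
* *intron* — entirely within the gap between two consecutive exons of
  some transcript (introns are always derived from exon gaps, never read
  from GFF intron features);
* *intergenic* — everything else.

Decisions the format forces, and how we took them:

* **Exon vs CDS.** Annotations without UTR features blur "exonic" and
  "coding". The default (`mode = "exon"`) classifies against exon
  features; `mode = "cds"` substitutes CDS segments throughout, which is
  the stricter coding-region reading — under it, UTR sequence outside the
  CDS extent of a transcript does not count as genic context.
* **Isoforms.** An SSR fully inside one transcript's exon is exonic even
  if intronic in another isoform: the priority is applied across all
  transcripts, the most generous reading of "entirely within".
* **Gene-boundary straddlers.** A repeat overlapping a gene span without
  being contained in it is classified intergenic and flagged
  (`boundary = TRUE`) so downstream users can audit these rare cases
  rather than have them silently absorbed into either category.
* **Overlapping genes.** All containing gene ids are kept, sorted by
  coordinate; the first is the atlas' primary gene column.

Linkage groups come from a two-column scaffold map; unmapped scaffolds are
`"Un"` (unplaced), and conflicting duplicate map entries are a load-time
error.

## Length classes and summaries

Arrays of ≥ 20 bases are class I — typically hypervariable, the preferred
diversity markers — and 12–19 bases class II. Summary tables
(`summarize_atlas()`, `summary_table()`) cross-tabulate any two of
location, period, motif class, linkage group and length class, with
totals and percentages. All reported percentages round half *up* (one
decimal in tables, whole percents for screen outcomes), matching how such
tables are conventionally printed; IEEE half-to-even would disagree on
exact halves. The same arithmetic applied to a previously published
genome-wide papaya survey's printed counts (shipped under
`inst/extdata/`) reproduces its headline figures — 86.8% intergenic,
9.9% intronic, 69.9% AT/TA among dinucleotides, 72.6% of repeats mapped
to linkage groups, 36% of genes carrying a repeat, a 26% polymorphism
rate from 19/73 screened markers, and 2.3 / 2.8 markers per candidate
gene — which the acceptance script recomputes at run time.

## Primer design

`design_pair()` is a self-contained approximation of a stringent
Primer3-style configuration, not a Primer3 reimplementation. The printed
constraints are honored exactly as gates; the thermodynamic machinery
behind them is simplified and documented:

| parameter | value | note |
|---|---|---|
| flank | 250 bp each side | clipped at sequence ends, flagged |
| primer length | 18 / 20 / 25 nt (min/opt/max) | |
| Tm | 57 / 60 / 63 °C | nearest-neighbor model below |
| product size | 250 / 300 / 350 bp | must contain the repeat |
| GC | 20–60% | |
| hairpin score | ≤ 24 | 4 points per stem pair ⇒ stems ≤ 6 bp |
| 3′ masked window | 2 bases | neither of the last two bases masked |
| masked fraction | ≤ 50% | "low-complexity primer" rejection |
| pair ΔTm | ≤ 3 °C | standard practice, config-exposed |

* **Tm** uses the unified nearest-neighbor ΔH/ΔS parameter set with the
  entropic salt correction `0.368·(N−1)·ln[Na+]` at 50 mM monovalent
  cation and 50 nM oligo (`R·ln(CT/4)` for a non-self-complementary
  duplex). Deterministic to well below 0.01 °C; the test suite pins it to
  a hand-summed duplex and to the model's symmetries (a primer and its
  reverse complement share a Tm; appending G to an A/T-rich primer raises
  it).
* **Low-complexity masking** is a windowed triplet score in the DUST
  family: for each 64-base window, `Σ c_t(c_t−1)/2 / (w−3)` over 3-mer
  counts; windows scoring > 2.0 are masked and merged. A 64-base
  homopolymer scores 31; a window of all-distinct triplets scores 0.
  Raising the threshold can only shrink the mask (tested as a property).
* **Mispriming.** The design intent of a repeat mispriming library is to
  keep primers out of repeats; we implement it directly — any candidate
  containing a qualifying repeat run (same thresholds as the scanner) is
  rejected, as is any candidate overlapping the target repeat itself.
* **Hairpins** are scored by the longest self-complementary stem with a
  loop of ≥ 3 bases, 4 points per stem pair, rather than by full
  secondary-structure thermodynamics; with the ceiling of 24 this means
  stems of 7+ bp fail. Stems are found by exact base-4 coding of arm
  k-mers, so the gate is exact for its own definition.

Among all passing pairs whose product lies in bounds and covers the
repeat, the returned pair minimizes
`|len−20| + |Tm−60|` (both primers) `+ |product−300| / 10`, with ties
broken to the leftmost forward primer, then the shortest product — fully
deterministic. Failures return a reason tally (`tm`, `gc`, `hairpin`,
`ssr_content`, `masked_3prime`, `low_complexity`, `ambiguous_base`, …)
instead of an error: a no-primer repeat is still an atlas record.

On 200 synthetic templates with clean GC-50% flanks the suite requires a
≥ 95% design rate (observed: ~100%); with fully masked flanks the rate is
0% by construction. On the AT-rich (GC 0.35) canned fixture the rate is
~70% — Tm is the binding constraint in AT-rich flanks, which mirrors how
stringent settings behave on real plant genomes.

## Candidate-gene markers

`filter_hits()` applies inclusive thresholds to an extended tabular
alignment format (qseqid, sseqid, evalue, ppos, length, qlen, slen):
E ≤ 1e-30, similarity ≥ 50%, query and hit coverage ≥ 75%. "Similarity"
is percent positives — a similarity measure, as the criterion says — with
a switch to percent identity for tables that carry `pident`. Coverage is
alignment length over each sequence's full length, with no gap
compression; where a pipeline sums HSPs instead, our single-alignment
reading is the more conservative one. Surviving subject genes are joined
to genic atlas records with designed primers (`nominate_genes()`);
`ssrs_per_gene()` averages markers over the genes that have at least one,
matching the "genes with primer pairs" framing of per-gene means.

## The synthetic-fixture generator

`simulate_genome()` emulates exactly what the downstream stages consume:
i.i.d. background sequence at a chosen GC (default 0.35, a typical
AT-rich plant genome; the primer suite uses 0.5 where the design-rate
contract assumes neutral composition), certified repeat-free by the
*oracle* with local resampling; repeat arrays planted verbatim at
declared positions (bases flanking a plant are resampled if any scan
reports a run differing from the planted truth, so junction effects
cannot silently extend an array); single-transcript two-exon gene models;
a partial linkage-group map (one scaffold deliberately unplaced). The
canned `example_sim_spec()` builds three scaffolds (~100 kb), five genes
and twenty plants covering periods 2–6, both length classes, fractional
exponents and all four contexts.

What the generator does *not* emulate — isochore structure, transposable
elements, nested or compound repeats, sequencing gaps, alternative
isoforms — bounds what passing tests prove: they validate the detection,
classification and design *logic* under controlled truth, not performance
on the idiosyncrasies of any real assembly.

All randomness is seeded; there is no unseeded entropy anywhere in the
package, and re-running any pipeline stage on unchanged inputs is
byte-identical (no timestamps inside data files).

## Problem sizes

The shipped test and acceptance workloads are sized for a laptop-class
single core: the oracle-equivalence suite uses 1,000 sequences of
100–10,000 bases; the planted-genome fixture is ~100 kb with 20 arrays;
the primer success suite uses 200 (tests) / 60 (acceptance script)
templates of ~520 bases. These sizes were chosen to exercise every code
path and boundary rather than to benchmark genome-scale throughput; the
scanner itself processes a few hundred kilobases per second in pure R,
so a full plant genome is feasible but not what the checks are about.

## Known limitations

* The hairpin gate counts stem pairs; it will disagree with full
  thermodynamic folders near the threshold.
* The Tm model omits divalent cations, dNTP correction and dangling ends.
* `mode = "cds"` treats UTR sequence outside a transcript's CDS extent as
  non-genic context (see above) — a documented consequence of swapping
  segment sets wholesale.
* Abutting exons with a zero-length gap would classify a junction repeat
  as intergenic; such annotations do not occur in well-formed GFF3 and
  are rejected by the simulator.
* Statistical-significance pruning of repeats is intentionally absent
  (see Repeat detection).
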