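# ssratlas

Gene-centered microsatellite (SSR) atlas construction from genome
assemblies, in R.

Simple sequence repeats — tandem arrays of 2–6 bp motifs — are workhorse
codominant markers for plant breeding and population genetics, but a
coordinate list alone is a weak resource. What a marker-assisted
selection program wants is a *catalog*: each repeat placed in its genomic
context (exon, splice junction, intron, intergenic), tied to a gene and
its functional annotation, anchored to a linkage group, and equipped with
a stringently filtered PCR primer pair. `ssratlas` builds that catalog
from four plain-text inputs — a genome FASTA, a GFF3 gene annotation, a
scaffold→linkage-group TSV and, optionally, a protein-alignment hit table
for candidate-gene nomination — and ships a seeded synthetic-genome
generator so the entire pipeline is testable offline against known truth.

## What it computes

* **Detection** (`find_repeats`, `scan_genome`): every perfect maximal
  repeat run with period *p* ∈ [2, 6], size ≥ 12 nt and exponent
  (size / *p*, fractional allowed) ≥ 2, reported once at its primitive
  period; runs never cross `N`. An independent loop-based oracle
  (`oracle_find_repeats`) re-derives the same contract for
  cross-validation.
* **Motif algebra** (`canonical_motif`, `enumerate_classes`): motifs
  grouped under circular permutation + reverse complement into the
  classical 4 / 10 / 33 / 102 / 350 classes for k = 2…6, labelled
  `AG/GA/CT/TC`-style from the lexicographically smallest member.
* **Context** (`classify_locations`): exon > exon_intron > intron >
  intergenic, against exon or CDS features, with gene ids, boundary
  flags and linkage-group assignment (`"Un"` when unplaced).
* **Atlas & summaries** (`build_atlas`, `summarize_atlas`): class I
  (≥ 20 nt) vs class II (12–19 nt) binning, joined records, and
  cross-tabulations with half-up-rounded percentages.
* **Primer design** (`design_pair`, `design_primers`): 250 bp flanks,
  DUST-style triplet-score masking, nearest-neighbor Tm (57–63 °C),
  length 18–25 nt, GC 20–60 %, product 250–350 bp spanning the repeat,
  no repeat run inside a primer, unmasked 3′ ends, hairpin stems ≤ 6 bp;
  best pair by a deterministic penalty.
* **Candidate genes** (`filter_hits`, `nominate_genes`,
  `ssrs_per_gene`): inclusive ortholog gates E ≤ 1e-30, similarity
  ≥ 50 %, query/hit coverage ≥ 75 %.

## Worked example

Twenty repeats planted in a ~100 kb three-scaffold toy genome with five
gene models, recovered and annotated end to end:

```r
library(ssratlas)

sim   <- simulate_genome(example_sim_spec(seed = 1))
hits  <- scan_genome(sim$genome)                   # 20 hits, = truth table
ctx   <- classify_locations(hits, sim$annotation)
prim  <- design_primers(sim$genome, hits)
atlas <- build_atlas(hits, ctx, sim$lg_map, primers = prim)

summarize_atlas(atlas, "location", "period")
#> ssr_summary_table (20 repeats; percents per col)
#>             2 3 4 5 6 Total
#> exon        2 3 1 0 1     7
#> exon_intron 2 1 0 0 0     3
#> intron      1 2 1 1 0     5
#> intergenic  0 0 2 2 1     5
#> Total       5 6 4 3 2    20
```

Each row of the atlas is one marker; here a class I `(AG)10` array inside
an exon of `geneA1` on linkage group 1, with its designed pair:

```r
atlas[2, c("ssr_id", "canonical_class", "length_class", "location",
           "gene_id", "linkage_group", "fwd_primer", "product_size")]
#>           ssr_id canonical_class length_class location gene_id linkage_group
#> 2 sA:5801-5820:2     AG/GA/CT/TC            I     exon  geneA1           LG1
#>                  fwd_primer product_size
#> 2 CTGCTTTCCACTGTTACTTCGGAGT          325
```

Seventeen of the twenty repeats get a passing pair under the stringent
gates; the three failures (AT-rich flanks that cannot reach the 57 °C Tm
floor) are retained as `no_primer` records with their reason codes —
which is the expected behavior of these settings on AT-rich plant
sequence. Coordinates are 0-based half-open in memory and 1-based
inclusive in every printed table (`sA:5801-5820:2` above).

The same workflow runs from a shell:

```sh
Rscript inst/scripts/ssr-atlas simulate --out-dir out --seed 1
Rscript inst/scripts/ssr-atlas all      --out-dir out --seed 1
```

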