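---
title: "Surveying group II introns and their homing sites: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying group II introns and their homing sites: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intronscout)
```

## The question the pipeline answers

Group II introns are self-splicing retroelements of bacteria and organelles.
Each intron recognises a specific target ("homing") site through base
pairing between short exon-binding motifs on the intron RNA (EBS1–3) and
their complements on the target (IBS1–3, spanning roughly positions −12 to
+1 around the insertion point), and copies itself into intron-free
occurrences of that site by target-primed reverse transcription
(retrohoming). Two models of their long-term dynamics make different
predictions about how full the set of potential homing sites should be in a
colonized genome: under saturation-driven extinction, proliferation stops
only when (nearly) all sites are occupied; under selection-driven
extinction, heavily colonized genomes are purged from the population before
saturation, so colonized genomes should typically show many *free* homing
sites. Deciding between the two therefore requires, per intron and genome,
the pair of counts (occupied sites, still-available sites) and their ratio
— the occupancy proportion.

`intronscout` implements the full inference chain that produces those
counts from genome sequences and a reference intron library: copy
detection, full-length/fragment classification, orthology resolution
between strains, homing-site model construction by four schemes, genomic
site scanning, and the occupancy and abundance statistics. A synthetic
genome generator with a complete truth manifest makes every stage testable
without any external downloads.

## Copy detection

Detection is a two-round local-alignment search of the reference library
(nucleotide sequences and, via 6-frame translation, the intron-encoded
proteins) against every replicon:

* **Search.** Exact k-mer seeds (12 nt; 4 aa) select subject windows; a
  full affine-gap Smith–Waterman (match +1, mismatch −2, gap open −5, gap
  extend −2; BLOSUM62 with −11/−1 for proteins) with iterative masking then
  reports *every* local alignment above a raw floor (identity ≥ 0.60 over
  ≥ 50 bp). The contract is identity-over-length rather than an E-value:
  E-value reproduction would require score-statistics calibration that adds
  nothing at the genome sizes the package targets, whereas the identity
  contract is directly testable against an exhaustive quadratic aligner
  (the test suite does exactly that, on dozens of seeded instances).
* **Filtering.** Overlapping hits are clustered by single-linkage genomic
  overlap and the hit with the most identical sites wins (ties: higher
  similarity, then leftmost); the rule recurses on the remainder. Hits with
  a footprint under 100 bp are discarded, as are nucleotide hits under 75%
  similarity — both thresholds strict, and the similarity filter applies to
  the nucleotide search only, so protein evidence can rescue old, eroded
  copies.
* **Round two.** All round-1 copies are re-used as queries to catch copies
  too divergent from the original references; the genome stretches already
  assigned are masked first, so round two only reports new loci.
* **Classification.** A locus is *full-length* when its merged alignment
  reaches within 15 bp of both reference extremities (`edge_slack`; the
  notion of an "unambiguously defined" extremity needs a number, and 15 bp
  tolerates ragged alignment ends without admitting real truncations), or
  when both boundaries are confirmed by flanking evidence. Copies more than
  10% diverged from their reference receive a new systematic name
  (`<genome>.I<n>`); the rule is strict, so exactly 10% keeps the
  reference name. ORF integrity requires an uninterrupted reading frame
  covering ≥ 90% of the projected reference ORF.

## Orthology and distinct elements

Counting every strain's copy of a single ancestral insertion once requires
orthology calls. For each copy the immediate 3 kb flanks are aligned
against every other genome of the same genus/complex (identity ≥ 0.80 over
≥ 500 bp; these thresholds are declared package defaults — chosen to
separate true same-species flanks from chance repeats in synthetic tests —
not values inherited from any published protocol):

* both flanks contiguous in the subject (gap ≤ 20 bp, no intron between)
  → the copy arose by **retrohoming** in the query genome;
* a flank matching the flank of a subject copy of the same intron at the
  same insertion point → the copies are **orthologous**;
* otherwise **unresolved**.

Orthology is made transitive by taking connected components (`igraph`), so
the "distinct elements" form a partition — necessary for counting, even
though pairwise evidence alone does not guarantee transitivity. Copies
carried by independently inserted mobile genetic elements (genomic
islands, prophages) are not orthologous in the descent sense; since
automated island discovery is out of scope, an explicit override table
reclassifies such pairs as `DISTINCT_MGE`, splitting them back into
separate elements. In the per-genus abundance table a distinct element
counts as full-length if *any* member copy is full-length.

## Homing-site models: four schemes

Which scheme applies depends on what is known about the intron:

1. **Flank similarity** — for introns that target a specific position in a
   known mobile element: the 90 bp around a known insertion site (45 bp
   each side; the package splits the region symmetrically) is searched by
   local alignment, and hits with identity ≥ 0.90 over ≥ 72 bp (80% of 90)
   that cover the integration point count as sites.
2. **EBS consensus** — IBS positions are fixed from the EBS motifs under
   Watson–Crick pairing *plus* G:U wobble (EBS G accepts target T, EBS U/T
   accepts target G); when several windows disagree, the most frequent
   wobble-consistent base wins and ties give N. If a reference-copy flank
   is supplied, positions identical across all windows and the reference
   extend the consensus. All other positions are N; N matches any real
   base but never a genomic N (ambiguity codes collapse to N on input, so
   ambiguous sequence can never create a site).
3. **Class C / terminator-gated** — bacterial class C introns carry only
   EBS1 and EBS3 and insert just downstream of Rho-independent
   transcription terminators. Their consensus (scheme 2 restricted to
   EBS1/EBS3) only counts at positions whose IBS1 begins within 20 nt
   downstream of a terminator stem-loop on the same strand (class C
   introns insert essentially immediately after the stem; the exact
   distance is a package default).
4. **Conservation consensus** — when no EBS model is available but ≥ 5
   full-length copies exist, each window column whose modal base reaches
   80% is fixed, the rest are N.

The window defaults to −25..+10 around the insertion point and is a model
field, configurable per intron.

The terminator finder reports every inverted repeat with stem 5–18 bp
(G:U pairs allowed, at most one interior mismatch — the two boundary pairs
of the stem must be genuine pairs, which keeps hit ends meaningful),
loop 3–10 nt, followed within 3 nt by a U-tract (≥ 5 T in the next 8
bases), keeping only maximal hits (none strictly contained in another on
the same strand). It is deliberately simple enough to be verified against
a brute-force enumerator over every (position, stem, loop) combination,
which the test suite does, including on a 100 kb sequence. Because real
terminator predictors disagree near the margins, scan gating also accepts
user-supplied terminator intervals in place of the built-in finder.

Scanning marks each genomic occurrence **available**; every detected copy
of the modelled intron contributes an **occupied** occurrence, and
candidate sites falling inside any intron copy are removed (an
uninterrupted copy is not a target). Occupancy is
`round-half-up(100 × occupied/(occupied + available))` — half-up because
the published tables this mirrors round 12.5 to 13 — with the undefined
0/0 case kept as NA. Fragment occupancy is computed "at the expected time
of fragment acquisition": fragments count as occupied, and sites currently
occupied by full-length copies count as available.

## The synthetic generator, and what it does not emulate

`generate_population()` plants cassettes into i.i.d. random backgrounds of
configurable GC content: occupied sites (site template split by an intron
copy), free sites, class C sites behind planted terminators, orthologous
cassettes sharing 3 kb flanks across strains, retrohoming-testable loci
(the same flanked locus intron-free in other strains), and MGE-transfer
scenarios (same island flanks, different chromosomal locus). Everything is
recorded in a truth manifest, and identical configurations with identical
seeds produce byte-identical output.

Design choices that keep recovery *exact*, so tests can assert equality
with the manifest rather than approximate agreement:

* **Substitution-only divergence.** `mutate_sequence()` changes an exact
  number of positions and can spare the extremities, so a copy planted at
  10% divergence measures exactly 0.90 identity in the aligner (no
  end-trimming, no gap ambiguity). An indel-free model is unrealistic for
  old fragments but makes threshold arithmetic (the 100 bp / 75% boundary
  tests) deterministic.
* **Motif scrubbing.** Chance occurrences of each intron's fixed site
  motif are removed from the background (and from the intron body, without
  ever creating a stop codon in its ORF) before planting, so the number of
  scan matches equals the number of planted sites. A real genome of course
  carries whatever motif occurrences it carries — in real data the scan
  count *is* the estimate, with no truth to compare against.
* **Junction guard.** The first intron base is forced to differ from the
  IBS3 base so an occupied junction can never look like a free site.
* Planted features sit on the forward strand; strand symmetry of every
  scanner is exercised by dedicated reverse-complement unit tests instead.

Passing on these populations therefore demonstrates that the inference
chain is internally correct, not that its defaults are optimal for real
genomes: real data add repeat families, indel-eroded copies, horizontal
transfer between genera, and motif occurrences that are genuinely
ambiguous.

## Numerical and procedural choices

* Coordinates are 1-based closed intervals throughout (the
  IRanges/GenomicRanges and GFF3 convention), so GFF3 emission involves no
  coordinate shift. Interval arithmetic in a 0-based half-open system
  would be equally unambiguous but would fight the entire R ecosystem the
  package is built on.
* Alignment tie-breaks are fully deterministic (best score, then smallest
  subject end, then smallest query end; traceback prefers diagonal, then
  gap-in-query, then gap-in-subject), and every report is sorted, so
  reruns are byte-identical.
* The strains-vs-abundance test is a chi-square goodness-of-fit with
  expectation proportional to the number of sequenced strains per
  genus/complex; genera with zero expectation are dropped with a warning.
  p-values are reported, never asserted against any external value: the
  construction of such a test is not unique (goodness-of-fit versus binned
  independence tables give very different p on the same counts), so only
  the computation itself is under test.
* Third-position divergence takes every third column of an in-frame
  concatenated MLST alignment and averages pairwise p-distances with
  complete pairwise deletion (columns gapped in either sequence of a pair
  are skipped); `ape::dist.dna` on the third-position sub-alignment is the
  cross-check in the tests.
* Circular replicons are handled in scanning operations by appending the
  first (motif length − 1) bases and normalising hit starts into the
  replicon; flank extraction wraps across the origin.
* Problem sizes in the shipped tests — chromosomes of 40–120 kb, a 400 kb
  intron-free false-positive check, 50-instance oracle batteries on
  sequences up to 100 kb — are chosen as the smallest sizes at which every
  planted scenario (26 + 17 sites, six-strain orthology, threshold
  boundaries) fits without crowding; all scale linearly if enlarged.

## Known limitations

* The E-value-free search contract means sensitivity at the raw floor
  (60% identity over 50 bp) is not comparable to BLAST E-values; the
  published-style 100 bp / 75% filters dominate in practice.
* Round-2 queries are detected copies, whose reference coordinates are
  those of the query copy, so completeness of a round-2-only locus is
  conservative (a fragment query cannot certify a full-length copy).
* Orthology evidence is flank alignment only; rearranged flanks (e.g.
  inversions at exactly the insertion point) fall back to `UNRESOLVED`.
* The conservation scheme needs ≥ 5 full-length copies; introns with
  fewer copies and no EBS model get no site model, and their occupancy is
  reported as undefined, mirroring the "/" cells of survey tables.

## A worked example

```{r example, eval = FALSE}
library(intronscout)

cfg <- sim_config(
  n_strains = 1, chromosome_length = 120000,
  intron_specs = list(
    intron_spec("cHa.I1", length = 1200, scheme = "ebs_consensus",
                n_full = 26, n_free = 17),
    intron_spec("Cc.I1", length = 1000, orf_class = "C",
                scheme = "classc_terminator", n_full = 2, n_free = 17)),
  seed = 11)
pop <- generate_population(cfg)
sv <- survey_population(pop$genomes, pop$library)
sv$occupancy_full_length
#> # A tibble: 2 x 5
#>   intron genome  occupied available proportion_pct
#>   <chr>  <chr>      <int>     <int>          <dbl>
#> 1 Cc.I1  strain1        2        17             11
#> 2 cHa.I1 strain1       26        17             60
autoplot(sv)
```

An intron holding 26 of 43 recognisable sites (60%) with 17 still free is
the signature the selection-driven model predicts; a saturated genome
would show available counts near zero.
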