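---
title: "MITE annotation and simulation: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MITE annotation and simulation: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mitescope)
```

This vignette documents the models behind `mitescope`: what the synthetic
genome generator emulates and deliberately omits, how the homology search
and its e-values are defined, the structural statistics, the numerical
conventions, and the design choices made where more than one reasonable
option existed.

## The scientific setting

Miniature inverted-repeat transposable elements (MITEs) are short,
non-autonomous Class II DNA transposons. Structurally a MITE is a sequence
bounded by a terminal inverted repeat — a 5' prefix whose reverse
complement recurs as the 3' suffix — and flanked on both sides by a target
site duplication (TSD), a short host motif duplicated on insertion. The
TSD is a superfamily signature: *Stowaway* elements duplicate the `TA`
dinucleotide, *Tourist* elements a `TWA` trinucleotide (W = A/T), and
*Mutator* elements a long variable target of 7–10 bp with no base
constraint (`tsd_rule()`). In allopolyploid wheat, insertions distribute
across the A, B and D sub-genomes, and comparing two genomes at the level
of insertion *loci* — identical flanking sequence on both sides of a copy —
separates insertions inherited across a polyploidization event from those
unique to one lineage.

The packaged catalog (`wheat_mite_catalog()`) transcribes the published
characterization of 36 wheat MITE families: superfamily, consensus length,
target-site preference, and copy numbers in the four genome drafts of
*T. aestivum*, *T. turgidum* ssp. *dicoccoides*, *Ae. tauschii* and
*T. urartu*, together with sub-genome counts for the two polyploids
(`wheat_subgenome_counts()`). These copy numbers are **inputs**: the
package's summary arithmetic (`mite_summary()`, `subgenome_percent()`)
reproduces the published fractions from them, and nothing in the package
attempts to recompute genome-scale counts from wheat assemblies. The
catalog stores the consensus length of the *Inbar* family as 58 bp; the
source material elsewhere reports 68 bp for the same element, and the
discrepancy is recorded in the catalog's notes column rather than silently
resolved. Consensus sequences of the public families live in the public
repeat databases and are not shipped; `synthetic_consensus()` builds
TIR-bounded stand-ins for testing, and the loader accepts any user FASTA.

## The synthetic genome generator

`generate_genome()` builds each chromosome as i.i.d. background sequence
at a configurable GC content (default 0.46, a realistic value for grass
genomes), then lays out synthetic host TEs (one class I entry of 6 kb and
one class II entry of 4 kb, instantiated per chromosome) and gene models
with a fixed 5'UTR(200)–CDS(300)–intron(400)–CDS(300)–3'UTR(300)
architecture on random strands. MITE copies are planted by sampling an
insertion context from the requested nesting fractions (host TE, intron,
exon, UTRs, the 100-bp upstream/downstream windows, or intergenic), then
splicing in `TSD + element + TSD` at a random admissible point. The element
is the family consensus mutated at the stated divergence and inserted on a
random strand; the TSD is generated from the family's rule (`TA` verbatim;
`TWA` with W sampled; a uniform random 9-mer for *Mutator*-type rules —
within the 7–10 bp range while exercising variable-length calling).

Divergence is modeled as substitutions only: exactly `round(rate × length)`
positions are substituted, sampled uniformly. The fixed count (rather than
an independent per-site Bernoulli draw) makes the generator's guarantee
exact — every planted copy realigns to its consensus at identity
`1 − rate` — which the retrieval and discovery contracts rely on. Indels,
nested truncation, and empirical wheat base composition are deliberately
not modeled: the i.i.d. background keeps false-positive analysis
interpretable, and the tests on these genomes demonstrate correctness of
the machinery, not performance on real repeat-dense wheat sequence, where
homology search faces segmental duplication and diverged element nests
that these simulations do not contain.

`derive_polyploid()` models an allopolyploidization: the child carries
every parental chromosome; each parental insertion is retained with
probability `inherit_fraction`, or excised by removing the element plus
one TSD copy, leaving a single TSD at the empty site. The single-TSD
excision convention is a simulator choice (documented, asserted in tests),
not a biological claim — real excision footprints vary. Fresh child-unique
insertions are placed intergenically. The returned parental truth table
labels every original insertion `inherited` or `parent_unique`, which is
the oracle for the common-insertion analysis.

Coordinates are 1-based inclusive throughout the package (the native
convention of the R/Bioconductor containers used); emitted GFF3 is 1-based
as the format requires, and BED6 output converts to 0-based half-open.

## Homology retrieval

`retrieve_insertions()` searches a family consensus against both strands
of each chromosome by exact 11-mer seeding. Seed matches are projected to
putative element starts, clustered into candidate windows, and each window
is extended by maximal-scoring local alignment under the package scheme:
match +1, mismatch −2, and affine gaps costing `5 + 2L` for a gap of
length `L`. Because a window can span several neighboring copies, the
segments flanking each accepted hit are re-aligned until nothing above the
score floor remains. The test suite holds the implementation to an
exhaustive Smith–Waterman-style dynamic program written independently:
on embedded-homology pairs up to 300 bp the reported best score equals the
oracle's exactly.

Significance uses the Karlin–Altschul form `E = K·m·n·exp(−λ·score)` with
`λ` solved from `Σ pᵢpⱼ exp(λ sᵢⱼ) = 1` at uniform base composition
(λ ≈ 1.3327 for +1/−2) and `K = 0.621`, the documented constant for this
scheme. The retrieval contract is: e-value ≤ 1e-3 **and** the alignment
reaches within 20 consensus bases of *both* termini, so near-full-length
(possibly end-truncated) copies are kept while internal fragments are not.
500 bp of flanking sequence is captured per side; at contig edges whatever
is available is kept and flagged truncated rather than dropping the
record. Overlapping hits (e.g., the same TIR-bounded locus found on both
strands) are resolved by score, ties by genomic order. `deduplicate()`
removes records whose element plus both flanks are character-identical —
assembly duplicates of one locus — keeping the lowest (chrom, start).

## Structural statistics

- `find_tir()` returns the *longest* terminal prefix within 8–30 bp whose
  reverse complement matches the terminal suffix with at most 2
  mismatches. Because mismatches are tolerated, the reported length can
  exceed the length of the perfect repeat by chance extension; tests
  therefore pin the exact length only under `max_mismatch = 0`.
- `call_tsd()` compares the k-mer immediately left of the element with the
  k-mer immediately right: a single comparison at the rule length for
  fixed rules, the longest exact duplication within 7–10 bp for variable
  rules. Flanks shorter than the rule yield a flagged, non-matching call
  rather than an error.
- `build_pfm()` right-pads unequal sequences with `N` (excluded from
  counts); `information_content()` is the sequence-logo stack height
  `R = 2 − H` in bits, with no small-sample correction (intended use is
  hundreds of TSDs per family; both the frequency matrix and the IC vector
  are available so either a frequency-height or an IC-height logo can be
  rendered).
- `haplotype_diversity()` is `Hd = n/(n−1)·(1 − Σ pᵢ²)` over distinct
  sequences, 0 for a single sequence.
- `build_consensus()` is a lightweight center-star scheme: members align
  globally to the longest member, columns are called by majority, ties
  yield IUPAC ambiguity codes, gap-majority columns are dropped. The
  contract is consensus recovery on simulated families (within one
  mismatch of the founder at 2% member divergence), not equivalence with
  any particular multiple-alignment program.

## De novo family discovery

`discover_families()` reconstructs how a new TIR/TSD-bounded family can be
found without a query: (1) enumerate segments bounded by a duplicated
fixed-pattern TSD (`TA` first — cheap and the *Stowaway*-type signature —
then `TWA`) whose interior carries a qualifying TIR and a length within
50–800 bp; (2) cluster candidates by single linkage at ≥ 0.80 identity,
strand-insensitively (a copy and its reverse complement are the same
element); (3) drop clusters homologous to a known catalog consensus at
e-value ≤ 1e-3, checking both orientations; (4) report clusters with at
least `min_copies` members, with a consensus rebuilt from
strand-oriented members.

Two resolution rules matter in practice. Within a cluster, overlapping
candidates at one locus (nested or staggered TSD pairings of one physical
copy) are collapsed by preferring the boundary whose element length is the
best-supported in the cluster — family copies share one length under the
substitution-only model, while chance super- or sub-pairings are
singletons. And the `min_copies` default of 20 with 0.80 clustering
identity has no published value; both are exposed parameters, chosen so
that random TA pairs over i.i.d. background (which pass the TIR test at a
rate of about 0.4%) essentially never assemble into a reportable cluster.
Variable-length (*Mutator*-style) TSDs are not enumerated de novo — a
genome-wide scan over all 7–10-mer duplications is quadratic and the
signature is weak; families with such targets are found by homology once a
consensus exists. This is a known limitation of the discovery stage, not
of retrieval.

## Annotation

`annotate_insertions()` aligns three queries per record — the element body
and each flank separately (concatenating the flanks could create chimeric
seeds) — in both orientations against the pooled reference set (spliced
cDNAs, the host-TE library with class labels, ncRNA). Hits are filtered at
e-value ≤ 1e-10 and the single best hit (lowest e-value, then higher
score, then lexicographic target id — so permuting reference order can
never change a call) fixes the category. TE class comes from the library
label, never from sequence heuristics. Independently,
`classify_gene_association()` applies interval logic: exon overlap, else
intron overlap, else association when the gap to the nearest gene is at
most 100 bp (boundary inclusive — "up to 100 bp" read inclusively), with
upstream/downstream assigned by gene strand. Distances are gaps in bases
between boundaries (half-open arithmetic: adjacent features are 0 apart).
`locate_in_transcript()` assigns the region (5'UTR/CDS/3'UTR) containing
the insertion midpoint, or `spanning` when more than 10% of the insertion
lies on each side of a region boundary.

One behavior worth knowing: when simulated transcripts themselves contain
planted MITEs (3'UTR insertions, say), the element body of *any* copy of
that family aligns to those transcripts, and distant intergenic copies can
legitimately annotate as genic. This mirrors how homology annotation
behaves on real transcriptomes containing mobile elements; tests that
check category agreement against planted truth therefore use genomes
whose gene contexts are insertion-free.

## Comparative analysis

`tabulate_insertions()` bins records by family, sub-genome and
homoeologous group, parsing chromosome names against `^[1-7][ABD]` and
sending anything unmatched (unplaced scaffolds) to the `unknown` bin;
explicit chromosome metadata overrides the name pattern. `mite_summary()`
reports percentages with the mixed precision conventional in this
literature — two decimals for superfamily fractions, one for family
fractions, integers for sub-genome fractions — rounding half-up (not
banker's rounding), all configurable.

`match_common_insertions()` declares two records the same locus when both
flank pairs align locally at ≥ 0.90 identity over ≥ 50 aligned columns.
The thresholds are not published values; they are chosen to tolerate 5%
flank divergence while making chance matches on i.i.d. background
negligible, and are exposed as parameters. Candidate pairs are proposed by
exact 24-mer probes anchored at the element boundary and then verified by
alignment; matching is greedy, best identity first, each record used once.
On simulated inheritance sweeps (500 parental insertions,
`inherit_fraction` 0.2–0.8) the recovered shared fraction tracks the
realized inherited proportion to within 0.002.

## Problem sizes and determinism

The shipped tests and the acceptance script run on genomes of 0.1–0.7 Mb
with 100–500 planted copies per scenario — large enough that recall,
false-positive and recovery rates are measured on hundreds of events,
small enough to run in minutes on one core. Every stochastic operation
takes an explicit seed and runs under a private RNG scope
(`with_seed()`), so a spec plus seed reproduces FASTA, truth tables and
every downstream table byte for byte; the caller's RNG stream is never
touched.

## Known limitations

- The generator's substitution-only divergence means indel-containing or
  heavily truncated copies are untested; the 20-nt end tolerance is
  exercised only by terminal substitutions.
- De novo discovery covers fixed-pattern TSDs (TA, TWA) only.
- The aligner's (K, λ) are exact for ungapped uniform-composition scoring
  and approximate once gaps enter; e-values are used as a filter, not as
  calibrated p-values.
- Host TEs are clean library copies; real nested, diverged TE landscapes
  will blur flank annotation in ways these simulations do not measure.
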