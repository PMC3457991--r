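---
title: "Methods: how mirindel models indel effects on miRNA targeting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how mirindel models indel effects on miRNA targeting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mirindel asks a focused question: when a small insertion or deletion falls
inside a microRNA gene or a miRNA target site, what does it do to seed-based
target recognition? The package provides the four analyses needed to answer
it — indel classification, region density profiling, reference-vs-mutant
seed-site diffing, and LD-based linking to association-study markers — plus
a synthetic-data generator that makes every stage testable with known
ground truth. This vignette records the models, the parameters that matter,
and the design choices that were genuinely open.

## Coordinates and variant representation

All internal coordinates are 0-based half-open; conversion to and from the
1-based conventions of VCF happens only at I/O boundaries, so off-by-one
drift cannot accumulate. Variants use VCF anchor-base alleles: an
insertion's REF is a prefix of its ALT and a deletion's ALT is a prefix of
its REF. Multi-allelic records are split and each alternate allele is
analyzed independently. Mature miRNA sequences may be supplied as RNA; `U`
is mapped to `T` internally because all comparisons happen in genome (DNA)
space, and reported motifs are DNA.

## Indel classes

Indels are assigned to one of three classes with a size-first precedence:

1. **single_base_pair** — any net length-1 indel, regardless of sequence
   context;
2. **repeat_expansion** — the inserted/deleted sequence is a whole number
   of copies of some unit that also occurs immediately adjacent in the
   reference;
3. **other** — everything else of net length ≥ 2.

The size-first rule keeps the classes disjoint. For the adjacency test we
check both sides of the variant and accept one full adjacent unit copy;
this is the minimal operational reading of "repeated sequences adjacent to
the site", and the brute-force oracle in the test suite (which enumerates
every unit length and copy count explicitly) agrees with the vectorized
implementation on 1,000 random indels in random contexts.

## Region systems and density profiling

For each pre-miRNA of length $L$ (about 100 nt), flanking regions 1 and 2
are successive windows adjacent to the precursor, each exactly $L$ long,
with 5′/3′ assignment following the transcriptional orientation (on the
minus strand the 5′ flanks have the larger genomic coordinates). The seed
region defaults to mature positions 2–8, the canonical 7-nt seed; because
the literature also uses 2–7, the span is exposed as `seed_span` rather
than hard-coded. PAR-CLIP footprints (canonically 41 nt) get left/right
flanks of footprint length by the same construction.

Density is computed **per unit** — one miRNA or one footprint — as variants
per nucleotide, counting a variant in a region when its anchor base falls
inside the half-open interval. Unit-level densities are then averaged, so
the standard error of the mean describes between-unit spread; this is what
makes error bars meaningful, and it is why the package does not pool counts
over pooled lengths. The pooled "flank average" is the per-unit mean over
the four flank densities. Comparisons use a two-sided Welch (unequal
variance) t-test; region variances differ by construction, so the pooled
variance test would be wrong more often than right. Two degenerate cases
are defined explicitly: two identical constant groups give $t = 0$,
$p = 1$, and distinct constant groups give $t = \pm\infty$, $p = 0$,
because the generic formula is 0/0 there.

Overlapping flanks of clustered miRNAs may double-count a variant (once per
unit); unit-level statistics make no attempt to deduplicate, since no
principled ownership rule exists for a variant between two miRNAs.

## Seed-site scanning and impact calls

Six canonical seed-site types are generated per mature miRNA: 8mer,
7mer-m8, 7mer-A1, 6mer, offset-6mer (positions 3–8) and offset-7mer
(3–9). The site motif for a span is the reverse complement of that mature
span, with an `A` appended at the site's 3′ end for the A1-requiring types.
Because the composition of the canonical six-type set varies slightly
between authors, the set is a configurable table, not a constant.

For each variant a window of `half_width` (default 50) nt per side is
extracted around the reference allele — a ~100-bp window for the default —
and the mutant window is the same flanks with the alternate allele
substituted. Both windows are scanned for every motif, overlapping
occurrences included; `N` never matches. Impact calls come from a set
difference with **offset mapping**: mutant match offsets right of the
indel's left edge are shifted back by the net allele-length change before
comparison, so unchanged downstream sites cancel exactly. Without this
mapping every downstream site would falsely appear disrupted-and-created.
A reference match with no equivalent mutant match is *disrupted*; the
converse is *created*. Matches strictly in the flanks can never be called —
a property the tests verify on random fixtures — and a destroyed 8mer whose
nested 7mer/6mer also vanish yields calls for each affected type.

Scanning is done on the transcript sense strand: for minus-strand genes the
motifs are reverse-complemented into genome space before scanning, which is
equivalent and keeps all offsets in one coordinate system.

Two orchestrations use this engine. The *footprint scan* runs every indel
anchored inside a PAR-CLIP footprint against the full miRNA catalog,
because the footprint itself evidences binding without naming a site
position. The *pair scan* restricts each gene's 3′ UTR indels to the miRNAs
experimentally paired with that gene, because low-throughput evidence names
the pair but not the site. SNVs flow through the identical code path when a
SNP column is needed — there is deliberately no second implementation.

The pathway summary counts genes, not sites: a gene is flagged if any of
its variants carries at least one impact call. Percentages are computed
over the user-supplied pathway membership (whose denominators are therefore
the user's responsibility), rounded half-up to two decimals. Pathways with
fewer than `min_genes` (default 10) indel-flagged genes are dropped. An
optional hypergeometric enrichment p-value can be added, but the core
report is plain counting. Consistency between the indel and SNP columns —
their percentage ratio must equal their count ratio, since the denominator
is shared — is asserted in the tests.

## LD blocks and GWAS linking

The block caller implements the confidence-interval (Gabriel) definition of
strong LD from scratch. Pairwise haplotype frequencies for two biallelic
markers come from the standard two-locus EM: all genotype combinations
except double heterozygotes are phase-unambiguous, and the double-het split
is re-estimated each iteration (tolerance 1e-9, cap 1000 iterations). |D′|
is |D| over its allele-frequency-constrained maximum. The one-sided 95%
bounds (cl, cu) are read from the multinomial likelihood evaluated on a
101-point |D′| grid with allele frequencies held at their MLE — a coarse
grid with linear interpolation, matching how the original software behaves
within testing tolerance at a fraction of the cost.

A marker run `[i..j]` is a block when its end pair is strong LD
(cl ≥ 0.7 and cu ≥ 0.98) and at least 95% of informative pairs inside are
strong LD, where informative means strong LD or strong recombination
(cu < 0.9). Markers with minor allele frequency below 0.05 are excluded
beforehand. Non-overlapping qualifying runs are chosen greedily, largest
genomic span first, ties to the leftmost. The distance-dependent special
rules some implementations add for 2- and 3-marker blocks are deliberately
not replicated: only the four parameters above are part of the definition
used here, and anything further would be guesswork; this divergence is
documented rather than hidden.

Linking then takes every candidate indel (in a miRNA, or carrying a
target-site impact) that is genotyped in the panel, finds GWAS markers
within 100 kb, calls blocks on the panel's markers for that chromosome, and
reports a link exactly when indel and marker fall inside the same block,
with the block's first/last member positions as boundaries. Phase is
estimated per pair only; no multi-marker phasing is attempted, since D′ is
intrinsically pairwise. Missing genotypes are dropped pairwise.

## The synthetic-data generator

The generator emulates the statistical structure of the study's inputs so
that every pipeline stage can be tested against construction truth:

* i.i.d. genome at a configurable GC fraction (default 0.5), sized
  automatically to hold the annotations;
* pre-miRNAs of 100 nt in non-colliding slots, one 22-nt mature each, both
  strands represented; 3′ UTRs (default 0.8–1.5 kb) with 41-nt footprints
  inside them; supported mRNA:miRNA pairs; pathway membership groups;
* per-region indel densities (defaults: flanks and UTR bodies 0.010/nt,
  precursors 0.008, matures 0.005, footprints 0.004) — lower in matures and
  footprints than in flanks, the pattern the density profiler must detect;
  SNVs at a configurable multiple of each region's indel density;
* indel classes drawn from the mix 0.55/0.14/0.31
  (single/repeat/other), with sequence contexts engineered to satisfy each
  class definition — repeat insertions copy an adjacent unit, "other"
  events are rejected-and-redrawn until no repeat reading exists;
* a fraction (default 0.2) of UTR/footprint indels planted to overlap a
  seed-match site of a paired miRNA, written into the genome with the
  expected status recorded. Planted indels replace background draws from
  the same Poisson budget, so region densities are unaffected by planting.
  For disrupted sites the inserted base is chosen so that the insertion can
  neither match the motif in place nor regenerate a shifted copy of a
  periodic motif one base downstream (the one case where a naive choice
  silently cancels the disruption); for created sites a motif with one
  interior base removed is planted and the variant restores it, with the
  following base forced off-motif so the reference cannot match;
* a genotype panel in which each block descends from two complementary
  founder haplotypes (within-block |D′| = 1 in expectation, founder
  frequency 0.25–0.75, 120 individuals) while blocks assort independently,
  plus one designated GWAS marker and one designated genotyped indel for
  the linking stage.

Every output is a pure function of the configuration: each component draws
from its own sub-seed derived by a stable hash of the component name, and
rerunning a configuration reproduces every file byte for byte.

What the generator does *not* emulate: mutation-rate heterogeneity,
coalescent genealogies, sequencing error, overlapping genes, alternative
UTR isoforms, and chance LD between unlinked markers beyond sampling noise.
Passing tests therefore demonstrate correctness of the algorithms under
the stated statistical structure, not performance on real population data,
where annotation error and ascertainment bias dominate.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use study sizes chosen so each
statistical check has adequate power while a full run stays comfortably
interactive: 1,000 random fixtures for the seed-diff oracle, ~2,000
engineered indels for class-mix recovery (99% binomial bands), 300 miRNAs
for the suppressed-mature density contrast (expected t ≈ 5), 400 null
replicates for type-I calibration, and 100 two-block panels of 120
individuals for block recovery (required: exact membership in ≥ 90).
Tolerances follow the quantity: exact formula reimplementations (Welch)
must agree to 1e-10; EM against a 1e-4 grid-search oracle to 1e-3;
stochastic recoveries within their binomial or simulation error.

Degenerate inputs are handled explicitly rather than by accident:
zero-length regions are errors; comparisons with fewer than two units per
group are refused with a message; monomorphic markers and zero-D-max pairs
are flagged non-informative and excluded from block calling; windows
crossing a chromosome edge are truncated and flagged; footprints deviating
from 41 nt warn but are kept.

## Known limitations

* Seed matching is exact complementarity; no thermodynamic or context
  scoring, and no conservation filtering — by design, since the analysis
  targets experimentally supported sites.
* The Table-style pathway report performs no enrichment inference unless
  explicitly asked; its denominators come from the supplied membership.
* The block caller omits the 2-/3-marker special-casing described above,
  so very short blocks may differ from other implementations.
* Real dbSNP ingestion would need an allele normalizer: records without an
  anchor base are not auto-converted, the anchor-base convention is
  assumed throughout.
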