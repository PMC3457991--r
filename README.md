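# mirindel

Small insertions and deletions (indels) are the second most abundant class
of genetic variation, yet most analyses of variants that perturb microRNA
regulation have focused on SNPs. mirindel is an R package for geneticists
and regulatory genomicists who want to ask, systematically: *what does an
indel in a miRNA gene or a miRNA target site do to seed-based target
recognition?* It covers the full analysis arc:

1. **Indel classification** — single-base-pair, repeat-expansion (the
   inserted/deleted sequence is copies of a unit also found adjacent in the
   reference), or other;
2. **Variant density profiling** — per-unit densities of variants in
   pre-miRNAs, mature sequences, seed regions, PAR-CLIP footprints, 3′ UTRs
   and equal-length flanking windows, with standard errors and Welch
   t-tests between regions;
3. **Seed-site impact calling** — extract a ~100-bp reference window around
   each variant and the corresponding mutant window, scan both for the six
   canonical seed-site motifs (8mer, 7mer-m8, 7mer-A1, 6mer, offset-6mer,
   offset-7mer) of each miRNA, and diff the match sets: a site present in
   the reference but not the mutant is **disrupted**, the converse is
   **created**. Matches downstream of the indel are offset-mapped by the
   net length change so unchanged sites cancel;
4. **Pathway summarization** — genes with impacted target sites counted
   per pathway with shared-denominator percentages;
5. **GWAS linking** — a from-scratch confidence-interval (Gabriel) LD block
   caller (two-locus EM haplotype frequencies, likelihood-grid bounds on
   |D′|, strong LD = cl ≥ 0.7 & cu ≥ 0.98, strong recombination cu < 0.9,
   MAF ≥ 0.05, ≥ 95% informative pairs strong) links genotyped indels to
   association markers within 100 kb that share a block.

A first-class synthetic-data generator (`simulate_study()`) produces every
input — genome, miRNA/UTR/footprint annotations, variants with engineered
classes and planted seed-site impacts, and a genotype panel with block LD
structure — with a complete truth table, so the whole pipeline is testable
offline with known ground truth.

## The statistics in brief

For a mature miRNA *m* and seed span *i..j*, the site motif is
revcomp(m[i..j]) in DNA space (plus a 3′ `A` for A1-anchored types). For
variant windows W<sub>ref</sub>, W<sub>mut</sub> and motif set *M*, calls
are the symmetric set difference of exact-match offset sets after mapping
mutant offsets o > o<sub>indel</sub> by −(|alt| − |ref|). Region density is
variants per nt per unit; groups are compared with Welch's t. Pairwise LD
uses EM haplotype frequencies (double heterozygotes resolved iteratively),
D′ = D / D<sub>max</sub>, and a 101-point likelihood grid for one-sided 95%
bounds, feeding the Gabriel block rule above.

## Worked example

Everything is data-frame in, tibble out, so stages chain with the pipe:

```r
library(mirindel)
library(dplyr)

cfg <- generator_config(rng_seed = 42, n_mirnas = 40, n_utrs = 20)
sim <- simulate_study(cfg)

# densities per region, indels only, with the pooled flank average
dens <- region_density(sim$variants, mirna_regions(sim$mirnas),
                       kinds = c("insertion", "deletion")) |>
  add_flank_average()
density_test(dens, "mature", "flank_avg")
#> Welch two-sample density test: mature vs flank_avg
#>   mean mature = 0.00454545 (n = 40), mean flank_avg = 0.0106875 (n = 40)
#>   t = -2.597, df = 52.11, two-sided p = 0.01219
```

The generator suppressed the mature-sequence indel density (0.005/nt
configured) relative to the flanks (0.010/nt); the test recovers the ~2×
contrast and flags it at p ≈ 0.01. Impact scanning and the pathway summary:

```r
imp <- run_impact(sim, min_genes = 3)
imp$pairs |> select(rsid, mirna, seed_type, status, unit_id) |> head(4)
#>   rsid     mirna   seed_type status  unit_id
#> 1 rs000774 mir-033 6mer      created gene001
#> 2 rs000774 mir-033 7mer-A1   created gene001
#> 3 rs000774 mir-033 7mer-m8   created gene001
#> 4 rs000774 mir-033 8mer      created gene001

imp$pathways
#>   pathway_id        pathway_name n_pathway_genes n_genes_with_indel_impacts
#> 1       pw01 Synthetic pathway 1              10                          9
#> 2       pw03 Synthetic pathway 3               6                          6
#>   pct_indel n_genes_with_snp_impacts pct_snp
#> 1        90                        3   30.00
#> 2       100                        0    0.00
```

Here a single inserted base in the 3′ UTR of `gene001` completes a site
for its paired miRNA: the 8mer and its nested shorter types all appear as
*created* at that locus. The pathway rows count genes (not call rows), with
percentages over each pathway's size.

Linking runs the block caller on the simulated genotype panel:

```r
run_link(sim$link_candidates, sim$gwas, sim$panel) |>
  select(indel_rsid, marker_rsid, block_left, block_right, trait)
```

A shell entry point wraps the same functions
(`inst/scripts/mirindel simulate|density|impact|link|all --config cfg.yaml
[--out DIR] [--seed N]`), writing TSVs whose header comments carry the tool
version and configuration hash.

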